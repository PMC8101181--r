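# Cross-validation protocol: ten iterations of fourfold cross-validation,
# with hyperparameters tuned per training sub-cohort by the worst-of-four
# rule. The same forty train/test splits are shared by every task on a
# cohort, so cv-AUCs of different tasks are iteration-aligned and directly
# comparable.

#' Generate the shared cross-validation scheme for a cohort
#'
#' Partitions the cohort samples into `n_folds` random folds, independently
#' `n_iterations` times. Within an iteration the test folds partition the
#' cohort, so every sample receives exactly one out-of-fold score per
#' iteration. The scheme is generated once per cohort and reused by every
#' task, making per-iteration AUCs comparable across tasks.
#'
#' @param cohort An `expression_cohort`, or a character vector of sample ids.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param n_iterations,n_folds Protocol constants (defaults 10 and 4).
#' @return A `cv_scheme`: list with `folds` (samples x iterations matrix of
#'   fold ids), `sample_ids`, `n_iterations`, `n_folds`, `seed`.
#' @export
make_cv_splits <- function(cohort, seed = 1, n_iterations = 10, n_folds = 4) {
  sample_ids <- if (inherits(cohort, "expression_cohort")) cohort_samples(cohort)
                else as.character(cohort)
  n <- length(sample_ids)
  if (n < 2 * n_folds) {
    abort_input(sprintf("cohort of %d samples is too small for %d-fold splits", n, n_folds))
  }
  folds <- withr::with_seed(derive_seed(seed, "cv_scheme"), {
    vapply(seq_len(n_iterations),
           function(i) sample(rep_len(seq_len(n_folds), n)),
           integer(n))
  })
  rownames(folds) <- sample_ids
  structure(list(folds = folds, sample_ids = sample_ids,
                 n_iterations = n_iterations, n_folds = n_folds, seed = seed),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("<cv_scheme> %d samples, %d iterations x %d folds (seed %s)\n",
              length(x$sample_ids), x$n_iterations, x$n_folds, format(x$seed)))
  invisible(x)
}

#' Hyperparameter grids for the supported classifier kinds
#'
#' Ridge-penalised logistic regression tunes the inverse regularisation
#' strength C over the eight values `10^-7..10^0`; the RBF support vector
#' machine tunes C over `10^-3..10^4`; random forests tune the minimum
#' samples per leaf over `{1,2,3,4,6,8,10,15}`; the deeper ridge grid
#' covers `10^-8.2..10^-4.2` in 0.4 decade steps. All kinds use balanced
#' class weighting (each class weighted inversely to its frequency in the
#' fitting set).
#'
#' @param kind One of `"ridge"`, `"svm"`, `"forest"`, `"ridge_deep"`.
#' @return List with `kind` and numeric `values`.
#' @export
hyperparam_grid <- function(kind = c("ridge", "svm", "forest", "ridge_deep")) {
  kind <- arg_match(kind)
  values <- switch(kind,
    ridge = 10^seq(-7, 0),
    svm = 10^seq(-3, 4),
    forest = c(1, 2, 3, 4, 6, 8, 10, 15),
    ridge_deep = 10^seq(-8.2, -4.2, by = 0.4))
  list(kind = kind, values = values)
}

balanced_weights <- function(y) {
  # class_weight = "balanced": n / (2 * n_class)
  n <- length(y)
  w <- ifelse(y, n / (2 * sum(y)), n / (2 * sum(!y)))
  w
}

# --- classifier backends -----------------------------------------------------
# Each backend fits on (x, y, weights) for one or all grid values and returns
# positive-class scores for new data. Ridge kinds exploit glmnet's path fit:
# one call covers the whole 8-value C grid via lambda = 1 / (n * C).

GLMNET_THRESH <- 1e-5

fit_ridge_path <- function(x, y, C_values) {
  n <- nrow(x)
  pad <- ncol(x) < 2 # glmnet requires >= 2 columns; a zero column is inert
  if (pad) x <- cbind(x, .pad. = 0)
  lambda <- sort(1 / (n * C_values), decreasing = TRUE)
  fit <- quiet_small_class(glmnet::glmnet(
    x, factor(y, levels = c(FALSE, TRUE)),
    family = "binomial", alpha = 0, lambda = lambda,
    weights = balanced_weights(y), standardize = FALSE,
    thresh = GLMNET_THRESH))
  list(fit = fit, lambda_for_C = 1 / (n * C_values), pad = pad)
}

predict_ridge_path <- function(path_fit, newx) {
  if (isTRUE(path_fit$pad)) newx <- cbind(newx, .pad. = 0)
  # matrix: rows = newx samples, cols = C grid order
  predict(path_fit$fit, newx, s = path_fit$lambda_for_C, type = "response")
}

# glmnet warns whenever a class has fewer than eight observations; routine
# on the deliberately small fixtures, so that one warning is muffled.
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

fit_one <- function(kind, x, y, value, num_trees, seed) {
  yf <- factor(y, levels = c(FALSE, TRUE))
  w <- balanced_weights(y)
  if (kind %in% c("ridge", "ridge_deep")) {
    fit_ridge_path(x, y, value)
  } else if (kind == "svm") {
    cw <- c("FALSE" = length(y) / (2 * sum(!y)), "TRUE" = length(y) / (2 * sum(y)))
    e1071::svm(x, yf, kernel = "radial", cost = value, probability = TRUE,
               class.weights = cw, scale = FALSE)
  } else if (kind == "forest") {
    withr::with_seed(seed, ranger::ranger(
      x = x, y = yf, probability = TRUE, min.node.size = value,
      num.trees = num_trees, class.weights = unname(
        c(length(y) / (2 * sum(!y)), length(y) / (2 * sum(y)))),
      num.threads = 1))
  } else {
    abort_config(paste0("unknown classifier kind: ", kind))
  }
}

predict_one <- function(kind, model, newx) {
  if (kind %in% c("ridge", "ridge_deep")) {
    as.numeric(predict_ridge_path(model, newx))
  } else if (kind == "svm") {
    pr <- attr(predict(model, newx, probability = TRUE), "probabilities")
    as.numeric(pr[, "TRUE"])
  } else {
    as.numeric(predict(model, data = newx, num.threads = 1)$predictions[, "TRUE"])
  }
}

#' Worst-of-four hyperparameter tuning on one training sub-cohort
#'
#' For each value of the tuning grid, fits the classifier on four
#' randomly-chosen subsets of 80% of the training sub-cohort and measures
#' the AUC on each complementary 20%. A value's merit is its worst
#' (minimum) AUC over the four subsets; the value with the highest merit is
#' selected. Ties are broken toward the more regularised value (smaller C;
#' larger minimum leaf size for forests). Tuning subsets whose held-out
#' part lacks a class are redrawn.
#'
#' @param x,y Training feature matrix and logical labels.
#' @param kind Classifier kind (see [hyperparam_grid()]).
#' @param grid Grid from [hyperparam_grid()]; defaults to the kind's grid.
#' @param seed Integer seed for the subset draws.
#' @param n_subsets,train_fraction Tuning protocol constants (4 and 0.8).
#' @param num_trees Trees per forest fit.
#' @return List with `value` (chosen setting) and `merits` (named vector of
#'   min-AUCs per grid value).
#' @export
tune_fold <- function(x, y, kind = "ridge", grid = NULL, seed = 1,
                      n_subsets = 4, train_fraction = 0.8, num_trees = 500) {
  grid <- grid %||% hyperparam_grid(kind)
  values <- grid$values
  if (!any(y) || all(y)) abort_input("tuning requires both classes in the training set")
  if (length(values) == 1) {
    return(list(value = values, merits = setNames(NA_real_, as.character(values))))
  }
  n <- nrow(x)
  n_tr <- max(2L, floor(train_fraction * n))
  aucs <- matrix(NA_real_, n_subsets, length(values))
  for (s in seq_len(n_subsets)) {
    sub <- draw_tuning_subset(y, n_tr, derive_seed(seed, "tune", s))
    x_tr <- x[sub, , drop = FALSE]; y_tr <- y[sub]
    x_ho <- x[-sub, , drop = FALSE]; y_ho <- y[-sub]
    if (kind %in% c("ridge", "ridge_deep")) {
      path <- fit_ridge_path(x_tr, y_tr, values)
      pr <- predict_ridge_path(path, x_ho)
      aucs[s, ] <- vapply(seq_along(values),
                          function(j) pairwise_auc(pr[, j], y_ho), numeric(1))
    } else {
      for (j in seq_along(values)) {
        model <- fit_one(kind, x_tr, y_tr, values[j], num_trees,
                         derive_seed(seed, "tune_fit", s, j))
        aucs[s, ] <- replace(aucs[s, ], j, pairwise_auc(predict_one(kind, model, x_ho), y_ho))
      }
    }
  }
  merits <- apply(aucs, 2, min)
  best <- merits == max(merits)
  reg_order <- if (kind == "forest") order(-values) else order(values)
  chosen <- values[reg_order][which(best[reg_order])[1]]
  list(value = chosen, merits = setNames(merits, as.character(values)))
}

# 80% subsets must leave both classes in train and held-out parts; redraw
# (with a log message) otherwise, up to a bounded number of attempts.
draw_tuning_subset <- function(y, n_tr, seed) {
  n <- length(y)
  for (attempt in seq_len(25)) {
    sub <- withr::with_seed(seed + attempt - 1L, sample(n, n_tr))
    if (any(y[sub]) && !all(y[sub]) && any(y[-sub]) && !all(y[-sub])) {
      if (attempt > 1) inform(sprintf("tuning subset redrawn %d time(s) (single class)", attempt - 1))
      return(sub)
    }
  }
  abort_input("could not draw a tuning subset containing both classes")
}

#' Fit the forty cross-validated classifiers of a task
#'
#' Executes the full protocol for one classification task: for each of the
#' forty train/test splits of the shared [make_cv_splits()] scheme, tunes
#' the hyperparameter on the training sub-cohort with the worst-of-four
#' rule, refits on the whole training sub-cohort at the chosen value, and
#' scores the held-out quarter with the continuous positive-class
#' confidence. Scores are therefore always out-of-fold, and each sample
#' receives exactly one score per iteration. Features on the task gene's
#' chromosome are excluded via [task_feature_mask()].
#'
#' Training folds that contain no positive sample cannot be fit; their test
#' scores are set to the negative-class constant 0 and the fold is flagged
#' in `degenerate`.
#'
#' @param task A `mutation_task`.
#' @param cohort An `expression_cohort` (labels must cover its samples).
#' @param scheme A `cv_scheme` for the same cohort.
#' @param kind Classifier kind; ridge-penalised logistic regression by
#'   default.
#' @param grid Optional tuning grid override.
#' @param seed Experiment seed; per-fold tuning seeds derive from it and
#'   the task id.
#' @param num_trees Trees per forest fit (forest kind only).
#' @param scale_within_folds Leakage-safe mode: refit the per-feature
#'   z-score scaler on each training sub-cohort's log-scale values instead
#'   of using the full-cohort scaling. Off by default, reproducing the
#'   prepare-then-split protocol order; requires a cohort built by
#'   [prepare_cohort()].
#' @return A `task_result`: list with the samples x iterations `scores`
#'   matrix, `coef` (40 x features matrix, ridge kinds) and `intercepts`,
#'   `chosen` hyperparameters and tuning `merits`, `degenerate` flags,
#'   `features` used, and task metadata.
#' @export
fit_predict <- function(task, cohort, scheme, kind = "ridge", grid = NULL,
                        seed = 1, num_trees = 500, scale_within_folds = FALSE) {
  stopifnot(inherits(task, "mutation_task"), inherits(scheme, "cv_scheme"))
  samples <- cohort_samples(cohort)
  if (!setequal(samples, scheme$sample_ids)) {
    abort_input("cv scheme was built for a different cohort")
  }
  if (!all(samples %in% names(task$labels))) {
    abort_input("task labels do not cover all cohort samples")
  }
  grid <- grid %||% hyperparam_grid(kind)
  features <- task_feature_mask(cohort, task$gene)
  x <- cohort$expr[, features, drop = FALSE]
  if (scale_within_folds && is.null(cohort$log_expr)) {
    abort_config("leakage-safe scaling needs a cohort built by prepare_cohort()")
  }
  lx <- if (scale_within_folds) cohort$log_expr[, features, drop = FALSE]
  y <- unname(task$labels[samples])

  n_iter <- scheme$n_iterations; n_folds <- scheme$n_folds
  scores <- matrix(NA_real_, length(samples), n_iter,
                   dimnames = list(samples, paste0("iter", seq_len(n_iter))))
  n_models <- n_iter * n_folds
  is_ridge <- kind %in% c("ridge", "ridge_deep")
  coefs <- if (is_ridge) matrix(NA_real_, n_models, length(features),
                                dimnames = list(NULL, features))
  intercepts <- rep(NA_real_, n_models)
  chosen <- rep(NA_real_, n_models)
  degenerate <- rep(FALSE, n_models)
  models <- vector("list", if (is_ridge) 0 else n_models)

  folds <- scheme$folds[samples, , drop = FALSE]
  m <- 0L
  for (it in seq_len(n_iter)) {
    for (fd in seq_len(n_folds)) {
      m <- m + 1L
      test <- folds[, it] == fd
      if (scale_within_folds) {
        ctr <- colMeans(lx[!test, , drop = FALSE])
        sdv <- apply(lx[!test, , drop = FALSE], 2, sd)
        sdv[sdv == 0] <- Inf # train-constant features carry no information
        x <- scale(lx, center = ctr, scale = sdv)
      }
      y_tr <- y[!test]
      if (!any(y_tr)) {
        scores[test, it] <- 0
        degenerate[m] <- TRUE
        next
      }
      fold_seed <- derive_seed(seed, task$task_id, it, fd)
      tuned <- tune_fold(x[!test, , drop = FALSE], y_tr, kind = kind,
                         grid = grid, seed = fold_seed, num_trees = num_trees)
      chosen[m] <- tuned$value
      model <- fit_one(kind, x[!test, , drop = FALSE], y_tr, tuned$value,
                       num_trees, derive_seed(fold_seed, "final"))
      scores[test, it] <- predict_one(kind, model, x[test, , drop = FALSE])
      if (is_ridge) {
        cf <- coef(model$fit, s = model$lambda_for_C)
        coefs[m, ] <- as.numeric(cf[-1])
        intercepts[m] <- as.numeric(cf[1])
      } else {
        models[[m]] <- model
      }
    }
  }
  structure(
    list(task_id = task$task_id, gene = task$gene,
         description = task$description, provenance = task$provenance,
         kind = kind, labels = task$labels[samples],
         scores = scores, coef = coefs, intercepts = intercepts,
         chosen = chosen, degenerate = degenerate, features = features,
         models = if (is_ridge) NULL else models,
         n_models = n_models, seed = seed),
    class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result> %s\n  %s classifier, %d models over %d samples x %d iterations\n",
              x$task_id, x$kind, x$n_models, nrow(x$scores), ncol(x$scores)))
  if (any(x$degenerate)) cat(sprintf("  %d degenerate fold(s)\n", sum(x$degenerate)))
  invisible(x)
}
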