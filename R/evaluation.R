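#' Pairwise (Mann-Whitney) AUC of continuous scores against binary labels
#'
#' The probability that a randomly chosen mutated sample's score exceeds a
#' randomly chosen wild-type sample's score, over all mutant x wild-type
#' pairs, with ties receiving half credit:
#' `(#\{s_m > s_w\} + 0.5 #\{s_m = s_w\}) / (n1 * n0)`. Computed through the
#' rank-statistic identity `U / (n1 * n0)`, which is exactly the pairwise
#' definition under midranks.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector, `TRUE` = mutated.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' pairwise_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE))
pairwise_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort_input("AUC is undefined when a class is absent")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted task: task AUC and per-iteration cv-AUCs
#'
#' The task AUC is the pairwise AUC of the samples' mean scores across the
#' ten cross-validation iterations; each cv-AUC uses a single iteration's
#' out-of-fold scores only.
#'
#' @param result A `task_result` from [fit_predict()].
#' @return A `task_evaluation`: list with `task_id`, `auc`, `cv_aucs`,
#'   `mean_scores` (named per sample), `n_pos`, and task metadata.
#' @export
evaluate_task <- function(result) {
  stopifnot(inherits(result, "task_result"))
  labels <- as.logical(result$labels)
  mean_scores <- rowMeans(result$scores)
  structure(
    list(task_id = result$task_id, gene = result$gene,
         description = result$description, provenance = result$provenance,
         auc = pairwise_auc(mean_scores, labels),
         cv_aucs = apply(result$scores, 2, pairwise_auc, labels = labels),
         mean_scores = mean_scores, labels = result$labels,
         n_pos = sum(labels)),
    class = "task_evaluation")
}

#' @export
print.task_evaluation <- function(x, ...) {
  cat(sprintf("<task_evaluation> %s\n  task AUC %.3f (cv-AUCs %.3f-%.3f), %d mutated samples\n",
              x$task_id, x$auc, min(x$cv_aucs), max(x$cv_aucs), x$n_pos))
  invisible(x)
}

#' cv-significance: all-ten comparison of iteration-aligned cv-AUCs
#'
#' Task X performs cv-significantly better than task Y iff `x_i > y_i`
#' strictly for every one of the ten iteration-aligned cv-AUC pairs. The
#' comparison is only meaningful for tasks evaluated under the same
#' [make_cv_splits()] scheme. Under exchangeability the chance of an
#' all-ten sweep in a fixed direction is at most `2^-10`.
#'
#' @param x,y Numeric vectors of cv-AUCs (equal length, iteration-aligned),
#'   or `task_evaluation` objects.
#' @return Logical scalar.
#' @export
cv_significant <- function(x, y) {
  if (inherits(x, "task_evaluation")) x <- x$cv_aucs
  if (inherits(y, "task_evaluation")) y <- y$cv_aucs
  if (length(x) != length(y)) {
    abort_input("cv-AUC vectors must have equal length and aligned iterations")
  }
  all(x > y)
}

# Placement values of DeLong's method: for each positive, the fraction of
# negatives scored below it (ties half credit), and vice versa.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(s) (sum(neg < s) + 0.5 * sum(neg == s)) / length(neg),
                numeric(1))
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / length(pos),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' One-tailed paired DeLong test for divergence of a subgrouping classifier
#'
#' Tests whether the subgrouping classifier's mean scores discriminate the
#' subgrouping's own mutation labels better than the gene-wide classifier's
#' mean scores do, on the same samples. Both score vectors are evaluated
#' against the subgrouping labels; the paired DeLong placement-value
#' covariance estimator gives the variance of the AUC difference, and the
#' one-tailed p-value is `1 - pnorm(z)` for
#' `H1: AUC(sub) > AUC(gene-wide)`.
#'
#' When the estimated variance of the difference is zero (e.g. both AUCs
#' exactly 1), the test is degenerate and `p = 1` is returned with the
#' `degenerate` attribute set, rather than `NaN`.
#'
#' @param gene_scores,sub_scores Mean scores of the gene-wide and
#'   subgrouping classifiers over the same samples.
#' @param sub_labels Logical labels of the subgrouping task.
#' @return One-tailed p-value in `(0, 1]`, with attributes `z`, `auc_sub`,
#'   `auc_gene` and `degenerate`.
#' @export
delong_divergence <- function(gene_scores, sub_scores, sub_labels) {
  stopifnot(length(gene_scores) == length(sub_scores),
            length(sub_scores) == length(sub_labels))
  sub_labels <- as.logical(sub_labels)
  if (!any(sub_labels) || all(sub_labels)) {
    abort_input("both classes must be present in the subgrouping labels")
  }
  if (identical(as.numeric(gene_scores), as.numeric(sub_scores))) {
    auc <- pairwise_auc(sub_scores, sub_labels)
    return(structure(0.5, z = 0, auc_sub = auc, auc_gene = auc,
                     degenerate = FALSE))
  }
  pg <- delong_placements(gene_scores, sub_labels)
  ps <- delong_placements(sub_scores, sub_labels)
  m <- sum(sub_labels); n <- sum(!sub_labels)
  s10 <- stats::var(cbind(ps$v10, pg$v10))
  s01 <- stats::var(cbind(ps$v01, pg$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= 0) {
    # degenerate variance (e.g. both AUCs exactly 1): conservative p = 1
    return(structure(1, z = NA_real_, auc_sub = ps$auc, auc_gene = pg$auc,
                     degenerate = TRUE))
  }
  z <- (ps$auc - pg$auc) / sqrt(var_diff)
  structure(1 - pnorm(z), z = z, auc_sub = ps$auc, auc_gene = pg$auc,
            degenerate = FALSE)
}

#' Compare a subgrouping task against its random null backgrounds
#'
#' Locates the subgrouping's task AUC within the AUC distribution of its
#' size-matched random background tasks (percentile, ties half credit) and
#' tests cv-significance against the best-performing background.
#'
#' @param sub_eval `task_evaluation` of the subgrouping task.
#' @param background_evals List of `task_evaluation`s of background tasks.
#' @return One-row tibble: `task_id`, `auc`, `n_backgrounds`,
#'   `null_percentile` (0-100), `best_background_auc`,
#'   `cv_significant_vs_best`.
#' @export
null_comparison <- function(sub_eval, background_evals) {
  stopifnot(length(background_evals) >= 1)
  bg_aucs <- map_dbl(background_evals, "auc")
  pct <- 100 * (sum(bg_aucs < sub_eval$auc) + 0.5 * sum(bg_aucs == sub_eval$auc)) /
    length(bg_aucs)
  best <- background_evals[[which.max(bg_aucs)]]
  tibble(task_id = sub_eval$task_id, auc = sub_eval$auc,
         n_backgrounds = length(bg_aucs), null_percentile = pct,
         best_background_auc = best$auc,
         cv_significant_vs_best = cv_significant(sub_eval$cv_aucs, best$cv_aucs))
}

#' Full divergence report for a subgrouping against its gene-wide task
#'
#' Combines the three divergence measures: the cv-significance flag over
#' the ten iteration-aligned cv-AUCs, the one-tailed DeLong divergence
#' p-value on the subgrouping labels, and (when background evaluations are
#' given) the subgrouping AUC's percentile among its random backgrounds.
#'
#' @param sub_eval,gene_eval `task_evaluation`s of the subgrouping and
#'   gene-wide tasks (same cohort and cv scheme).
#' @param background_evals Optional list of background `task_evaluation`s.
#' @return One-row tibble: `task_id`, `gene_task_id`, `auc`,
#'   `gene_wide_auc`, `cv_significant`, `p_divg`, `delong_degenerate`,
#'   `null_percentile` (NA without backgrounds).
#' @export
divergence_report <- function(sub_eval, gene_eval, background_evals = NULL) {
  p <- delong_divergence(gene_eval$mean_scores[names(sub_eval$mean_scores)],
                         sub_eval$mean_scores, as.logical(sub_eval$labels))
  pct <- NA_real_
  if (!is.null(background_evals) && length(background_evals) > 0) {
    pct <- null_comparison(sub_eval, background_evals)$null_percentile
  }
  tibble(task_id = sub_eval$task_id, gene_task_id = gene_eval$task_id,
         gene = sub_eval$gene, description = sub_eval$description,
         n_pos = sub_eval$n_pos,
         auc = sub_eval$auc, gene_wide_auc = gene_eval$auc,
         cv_significant = cv_significant(sub_eval$cv_aucs, gene_eval$cv_aucs),
         p_divg = as.numeric(p), delong_degenerate = attr(p, "degenerate"),
         null_percentile = pct)
}

#' Transfer a trained task's classifiers to another cohort
#'
#' Applies each of the forty trained classifier iterations of a ridge-kind
#' task to a target cohort's prepared expression and averages the forty
#' outputs per sample. Features are aligned by intersecting feature symbols
#' and re-applying the task gene's chromosome mask on the target
#' annotation; coefficients of features absent from the target contribute
#' nothing. By default the target cohort is used on its own prepared
#' (z-scored) scale.
#'
#' @param result A ridge-kind `task_result`.
#' @param target An `expression_cohort`.
#' @param scale `"target"` (default) evaluates the models on the target's
#'   own prepared z-scores; `"training"` re-standardises the target's
#'   log-scale values with the training cohort's per-feature scaling
#'   parameters, which requires a target built by [prepare_cohort()] and
#'   `training_scale`.
#' @param training_scale The training cohort's `$scale` element (per-feature
#'   `center` and `sd` on the log scale); only used with
#'   `scale = "training"`.
#' @return Named numeric vector of mean transferred scores, one per target
#'   sample.
#' @export
transfer_scores <- function(result, target, scale = c("target", "training"),
                            training_scale = NULL) {
  stopifnot(inherits(result, "task_result"))
  scale <- arg_match(scale)
  if (!result$kind %in% c("ridge", "ridge_deep")) {
    abort_config("transfer is supported for ridge classifier kinds")
  }
  feats <- intersect(result$features, colnames(target$expr))
  if (!is.na(result$gene) && result$gene %in% target$annotation$gene) {
    feats <- intersect(feats, task_feature_mask(target, result$gene))
  }
  if (length(feats) == 0) {
    abort_input("no shared expression features between task and target cohort")
  }
  if (scale == "training") {
    if (is.null(target$log_expr) || is.null(training_scale)) {
      abort_config("training-scale transfer needs a prepare_cohort() target and training_scale")
    }
    feats <- intersect(feats, names(training_scale$center))
    if (length(feats) == 0) {
      abort_input("no shared expression features between task and target cohort")
    }
    x <- base::scale(target$log_expr[, feats, drop = FALSE],
                     center = training_scale$center[feats],
                     scale = training_scale$sd[feats])
  } else {
    x <- target$expr[, feats, drop = FALSE]
  }
  cf <- result$coef[, feats, drop = FALSE]
  cf[is.na(cf)] <- 0
  ic <- ifelse(is.na(result$intercepts), 0, result$intercepts)
  lin <- x %*% t(cf) + matrix(ic, nrow(x), length(ic), byrow = TRUE)
  rowMeans(stats::plogis(lin))
}

#' Transfer AUC on a labelled target cohort
#'
#' @param result A ridge-kind `task_result`.
#' @param target An `expression_cohort`.
#' @param target_labels Logical labels for the target samples (named or in
#'   target sample order). Required: an unlabelled target yields scores via
#'   [transfer_scores()] but no AUC.
#' @return Transfer AUC, with the per-sample mean scores as the `scores`
#'   attribute.
#' @export
transfer_auc <- function(result, target, target_labels) {
  if (missing(target_labels) || is.null(target_labels)) {
    abort_input("transfer AUC is undefined without target labels; use transfer_scores()")
  }
  sc <- transfer_scores(result, target)
  if (!is.null(names(target_labels))) {
    target_labels <- target_labels[names(sc)]
  }
  structure(pairwise_auc(sc, as.logical(target_labels)), scores = sc)
}

#' Average coefficient vectors across subgrouping tasks and cluster them
#'
#' Averages each ridge-kind task's forty coefficient vectors, drops tasks
#' below the AUC floor, computes pairwise distances `1 - Spearman(coef_i,
#' coef_j)` and clusters the tasks by average-linkage agglomerative
#' clustering cut at `k` groups. Optionally marks tasks for display
#' filtering: a task is hidden when another task in its cluster has a
#' higher AUC and a Jaccard index of at least `jaccard_cut` between the two
#' mutated-sample sets.
#'
#' @param results List of ridge-kind `task_result`s for one gene.
#' @param evals Optional list of matching `task_evaluation`s (computed if
#'   missing).
#' @param auc_floor Minimum task AUC to include (0.7).
#' @param k Number of clusters (5, reduced when fewer tasks remain).
#' @param jaccard_cut Sample-set Jaccard threshold for display filtering
#'   (0.9).
#' @return A `coefficient_summary`: list with `table` (task_id, auc,
#'   cluster, displayed), `coef` (tasks x features mean-coefficient
#'   matrix), `dist`, and `hclust` (NULL when < 2 eligible tasks).
#' @export
coefficient_summary <- function(results, evals = NULL, auc_floor = 0.7,
                                k = 5, jaccard_cut = 0.9) {
  stopifnot(length(results) >= 1)
  if (!all(map_chr(results, "kind") %in% c("ridge", "ridge_deep"))) {
    abort_config("coefficient summaries require ridge classifier kinds")
  }
  evals <- evals %||% lapply(results, evaluate_task)
  aucs <- map_dbl(evals, "auc")
  keep <- aucs >= auc_floor
  results <- results[keep]; evals <- evals[keep]; aucs <- aucs[keep]
  if (length(results) == 0) {
    return(structure(list(table = tibble(task_id = character(), auc = numeric(),
                                         cluster = integer(), displayed = logical()),
                          coef = NULL, dist = NULL, hclust = NULL),
                     class = "coefficient_summary"))
  }
  coef_means <- do.call(rbind, lapply(results, function(r) {
    colMeans(r$coef[!r$degenerate, , drop = FALSE])
  }))
  rownames(coef_means) <- map_chr(results, "task_id")
  if (length(results) < 2) {
    tb <- tibble(task_id = rownames(coef_means), auc = aucs,
                 cluster = 1L, displayed = TRUE)
    return(structure(list(table = tb, coef = coef_means, dist = NULL, hclust = NULL),
                     class = "coefficient_summary"))
  }
  d <- as.dist(1 - cor(t(coef_means), method = "spearman"))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = min(k, length(results)))
  displayed <- rep(TRUE, length(results))
  sets <- lapply(results, function(r) names(r$labels)[as.logical(r$labels)])
  for (i in seq_along(results)) {
    for (j in seq_along(results)) {
      if (i == j || cl[i] != cl[j] || aucs[j] <= aucs[i]) next
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      if (jac >= jaccard_cut) displayed[i] <- FALSE
    }
  }
  structure(list(table = tibble(task_id = rownames(coef_means), auc = aucs,
                                cluster = unname(cl), displayed = displayed),
                 coef = coef_means, dist = d, hclust = hc),
            class = "coefficient_summary")
}

#' @export
print.coefficient_summary <- function(x, ...) {
  cat(sprintf("<coefficient_summary> %d task(s) in %d cluster(s)\n",
              nrow(x$table), length(unique(x$table$cluster))))
  invisible(x)
}

#' Correlate transferred classifier scores with cell-line drug response
#'
#' For each drug measured in at least `min_lines` cell lines that also
#' carry classifier scores, computes the Spearman rho between the drug's
#' AUC50 response values and the mean classifier predictions over the
#' shared lines. Both the raw rho and its negation are reported: under the
#' sign convention used for presentation, correlations are multiplied by
#' -1 so that larger values correspond to stronger association with
#' increased drug sensitivity (lower AUC50).
#'
#' @param scores Named numeric vector of mean classifier scores per cell
#'   line (e.g. from [transfer_scores()]).
#' @param response Tidy drug-response tibble: columns `drug`, `sample_id`,
#'   `auc50`; missing responses may be absent rows or `NA`.
#' @param min_lines Minimum measured cell lines per drug (100).
#' @return Tibble with `drug`, `n_lines`, `rho`, `rho_sensitivity`
#'   (`-rho`); empty when no drug passes the filter.
#' @export
drug_response_correlation <- function(scores, response, min_lines = 100) {
  stopifnot(all(c("drug", "sample_id", "auc50") %in% names(response)))
  response %>%
    filter(!is.na(.data$auc50), .data$sample_id %in% names(scores)) %>%
    group_by(.data$drug) %>%
    filter(n() >= min_lines) %>%
    summarise(n_lines = n(),
              rho = suppressWarnings(
                cor(.data$auc50, scores[.data$sample_id], method = "spearman")),
              .groups = "drop") %>%
    mutate(rho_sensitivity = -.data$rho)
}

#' Write the per-task AUC table ("auc-mat") to TSV
#'
#' @param evals List of `task_evaluation`s.
#' @param reports Optional divergence-report tibble to join in `p_divg`,
#'   `cv_significant` and `null_percentile` columns.
#' @param path Output file.
#' @return The written tibble, invisibly.
#' @export
write_auc_table <- function(evals, path, reports = NULL) {
  tb <- purrr::map_dfr(evals, function(e) {
    cv <- as.list(setNames(e$cv_aucs, paste0("cv_auc_", seq_along(e$cv_aucs))))
    as_tibble(c(list(task_id = e$task_id, gene = e$gene,
                     provenance = e$provenance, n_pos = e$n_pos, auc = e$auc), cv))
  })
  if (!is.null(reports) && nrow(reports) > 0) {
    tb <- left_join(tb,
                    select(reports, "task_id", "p_divg", "cv_significant",
                           "null_percentile"),
                    by = "task_id")
  }
  readr::write_tsv(tb, path)
  invisible(tb)
}

#' Write per-task mean coefficients ("coef-means") to TSV
#'
#' Gene features in rows, tasks in columns.
#'
#' @param summary A `coefficient_summary`, or a tasks x features matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coef_means <- function(summary, path) {
  m <- if (inherits(summary, "coefficient_summary")) summary$coef else summary
  if (is.null(m)) abort_input("no coefficients to write")
  out <- as_tibble(t(m), rownames = "feature")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a task x target-cohort transfer AUC matrix ("trnsf-aucs") to TSV
#'
#' @param transfer_tbl Tibble with columns `task_id`, `target`, `auc`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transfer_table <- function(transfer_tbl, path) {
  transfer_tbl %>%
    tidyr::pivot_wider(names_from = "target", values_from = "auc") %>%
    readr::write_tsv(path)
  invisible(path)
}
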