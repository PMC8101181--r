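test_that("pairwise AUC equals the stated examples", {
  expect_equal(pairwise_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_equal(pairwise_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(pairwise_auc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(pairwise_auc(1:4, rep(TRUE, 4)), class = "mutsubsig_input_error")
})

test_that("pairwise AUC matches the brute-force pair oracle on random instances", {
  for (seed in 1:100) {
    inst <- withr::with_seed(seed, {
      n <- sample(4:50, 1)
      scores <- sample(round(rnorm(n), 1)) # coarse rounding forces ties
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(labels)) labels[1] <- FALSE
      if (!any(labels)) labels[1] <- TRUE
      list(scores = scores, labels = labels)
    })
    expect_equal(pairwise_auc(inst$scores, inst$labels),
                 oracle_auc(inst$scores, inst$labels))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(2, {
    scores <- rnorm(40)
    labels <- rep(c(TRUE, FALSE), 20)
    a <- pairwise_auc(scores, labels)
    expect_equal(pairwise_auc(exp(scores), labels), a)
    expect_equal(pairwise_auc(rank(scores), labels), a)
    expect_equal(pairwise_auc(stats::plogis(3 * scores + 1), labels), a)
  })
})

test_that("cv-significance requires a strict sweep of all ten comparisons", {
  y <- seq(0.5, 0.59, by = 0.01)
  expect_true(cv_significant(y + 0.01, y))
  x <- y + 0.01; x[4] <- y[4] # one exact tie
  expect_false(cv_significant(x, y))
  x2 <- y + 0.01; x2[7] <- y[7] - 0.005 # one reversal
  expect_false(cv_significant(x2, y))
  expect_error(cv_significant(y[1:9], y), class = "mutsubsig_input_error")
  # antisymmetry over random vectors
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- runif(10); b <- runif(10)
      expect_false(cv_significant(a, b) && cv_significant(b, a))
    })
  }
})

test_that("DeLong divergence handles the neutral and degenerate cases", {
  withr::with_seed(4, {
    labels <- rep(c(TRUE, FALSE), 25)
    scores <- rnorm(50)
    p_same <- delong_divergence(scores, scores, labels)
    expect_equal(as.numeric(p_same), 0.5)
    expect_equal(attr(p_same, "z"), 0)

    # both classifiers perfect: zero variance, conservative p = 1 with flag
    perfect <- ifelse(labels, 1, 0)
    p_perf <- delong_divergence(perfect, perfect + ifelse(labels, 1, -1), labels)
    expect_equal(as.numeric(p_perf), 1)
    expect_true(attr(p_perf, "degenerate"))

    expect_error(delong_divergence(scores, scores, rep(TRUE, 50)),
                 class = "mutsubsig_input_error")
  })
})

test_that("DeLong divergence agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    inst <- withr::with_seed(seed, {
      n <- 120
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
      gene_scores <- 0.8 * labels + rnorm(n)
      sub_scores <- 1.2 * labels + rnorm(n)
      list(g = gene_scores, s = sub_scores, y = labels)
    })
    mine <- delong_divergence(inst$g, inst$s, inst$y)
    ref <- suppressMessages(pROC::roc.test(
      pROC::roc(inst$y, inst$s, quiet = TRUE),
      pROC::roc(inst$y, inst$g, quiet = TRUE),
      method = "delong", alternative = "greater", paired = TRUE))
    expect_equal(as.numeric(mine), ref$p.value, tolerance = 1e-8)
  }
})

test_that("DeLong divergence tracks the permutation oracle, including sign", {
  # sub classifier clearly better
  inst <- withr::with_seed(21, {
    labels <- rep(c(TRUE, FALSE), c(40, 160))
    list(g = 0.2 * labels + rnorm(200), s = 1.0 * labels + rnorm(200), y = labels)
  })
  p <- as.numeric(delong_divergence(inst$g, inst$s, inst$y))
  p_oracle <- oracle_delong_p(inst$g, inst$s, inst$y, B = 2000, seed = 1)
  expect_lt(p, 0.01)
  expect_lt(p_oracle, 0.02)

  # sub classifier worse: p above one half, matching the oracle's side
  p_rev <- as.numeric(delong_divergence(inst$s, inst$g, inst$y))
  expect_gt(p_rev, 0.5)
  expect_gt(oracle_delong_p(inst$s, inst$g, inst$y, B = 500, seed = 2), 0.5)

  # a mid-range case agrees quantitatively
  inst2 <- withr::with_seed(22, {
    labels <- rep(c(TRUE, FALSE), c(50, 150))
    list(g = 0.5 * labels + rnorm(200), s = 0.75 * labels + rnorm(200), y = labels)
  })
  p2 <- as.numeric(delong_divergence(inst2$g, inst2$s, inst2$y))
  p2_oracle <- oracle_delong_p(inst2$g, inst2$s, inst2$y, B = 4000, seed = 3)
  expect_lt(abs(p2 - p2_oracle), 0.03)
})

test_that("null comparison locates the subgrouping in its background distribution", {
  fake_eval <- function(auc, cv = rep(auc, 10), id = paste0("t", auc)) {
    structure(list(task_id = id, auc = auc, cv_aucs = cv), class = "task_evaluation")
  }
  sub <- fake_eval(0.9, cv = seq(0.88, 0.97, by = 0.01))
  bgs <- lapply(c(0.45, 0.5, 0.55, 0.6), fake_eval)
  nc <- null_comparison(sub, bgs)
  expect_equal(nc$null_percentile, 100)
  expect_equal(nc$best_background_auc, 0.6)
  expect_true(nc$cv_significant_vs_best)

  nc2 <- null_comparison(fake_eval(0.5), bgs)
  expect_equal(nc2$null_percentile, 100 * 1.5 / 4) # one below, one tied
})

test_that("divergence report combines cv-significance, DeLong p and null percentile", {
  pf <- planted_fit()
  bg_task <- random_backgrounds(
    list(gene = "TG1", description = "exon=1",
         samples = pf$sim$truth$branches$samples[[1]]),
    pf$sim$cohort, sort(unique(pf$sim$variants$sample_id)),
    n_each = 1, seed = 301)
  bg_evals <- lapply(bg_task, function(t)
    evaluate_task(fit_predict(t, pf$sim$cohort, pf$scheme, seed = 301)))
  rep <- divergence_report(pf$ev_s, pf$ev_g, bg_evals)
  expect_equal(rep$auc, pf$ev_s$auc)
  expect_true(rep$auc > rep$gene_wide_auc)
  expect_lt(rep$p_divg, 0.5)
  expect_gte(rep$null_percentile, 50)
})

test_that("transfer scores reproduce held-in performance and survive feature loss", {
  pf <- planted_fit()
  # self-transfer: mean over the forty models tracks the cross-validated scores
  auc_self <- transfer_auc(pf$res_s, pf$sim$cohort, pf$res_s$labels)
  expect_gt(auc_self, 0.9)
  expect_gt(cor(attr(auc_self, "scores"), pf$ev_s$mean_scores, method = "spearman"), 0.3)

  # an independent cohort from the same generative parameters
  cfg2 <- pf$sim$config
  cfg2$seed <- 777
  sim2 <- generate_cohort(cfg2)
  labels2 <- rownames(sim2$cohort$expr) %in% sim2$truth$branches$samples[[1]]
  auc_t <- transfer_auc(pf$res_s, sim2$cohort,
                        setNames(labels2, rownames(sim2$cohort$expr)))
  expect_gt(auc_t, 0.75)

  expect_error(transfer_auc(pf$res_s, sim2$cohort, NULL),
               class = "mutsubsig_input_error")

  # training-scale transfer requires a raw-prepared target
  expect_error(transfer_scores(pf$res_s, sim2$cohort, scale = "training",
                               training_scale = list(center = 0, sd = 1)),
               class = "mutsubsig_config_error")

  # a target sharing no features cannot be scored
  alien <- as_expression_cohort(
    matrix(rnorm(20), 4, 5, dimnames = list(paste0("a", 1:4), paste0("z", 1:5))),
    tibble::tibble(gene = paste0("z", 1:5), chromosome = "1",
                   biotype = "protein_coding"))
  expect_error(transfer_scores(pf$res_s, alien), class = "mutsubsig_input_error")
})

test_that("coefficient distances behave at the extremes and recover planted structure", {
  fake_result <- function(id, coef_vec, samples, auc) {
    list(result = structure(list(
      task_id = id, kind = "ridge",
      coef = matrix(rep(coef_vec, each = 4), 4,
                    dimnames = list(NULL, paste0("f", seq_along(coef_vec)))),
      degenerate = rep(FALSE, 4),
      labels = setNames(sprintf("s%02d", 1:30) %in% samples, sprintf("s%02d", 1:30))),
      class = "task_result"),
      eval = structure(list(task_id = id, auc = auc), class = "task_evaluation"))
  }
  v <- c(1, -2, 3, -1, 2, 0.5, -0.25, 1.5)
  a <- fake_result("a", v, sprintf("s%02d", 1:10), 0.9)
  b <- fake_result("b", 2 * v, sprintf("s%02d", 1:10), 0.85)     # same direction
  c_ <- fake_result("c", -v, sprintf("s%02d", 11:20), 0.8)       # anti-correlated
  cs <- coefficient_summary(list(a$result, b$result, c_$result),
                            evals = list(a$eval, b$eval, c_$eval), k = 2)
  d <- as.matrix(cs$dist)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(cs$table$cluster[1], cs$table$cluster[2])
  expect_false(cs$table$cluster[1] == cs$table$cluster[3])

  # display filter: b dominated by a (same cluster, higher AUC, identical set)
  expect_true(cs$table$displayed[cs$table$task_id == "a"])
  expect_false(cs$table$displayed[cs$table$task_id == "b"])

  # AUC floor exclusion and the <2 eligible tasks path
  cs2 <- coefficient_summary(list(a$result, b$result, c_$result),
                             evals = list(a$eval, b$eval, c_$eval),
                             auc_floor = 0.88)
  expect_equal(nrow(cs2$table), 1L)
  expect_null(cs2$hclust)
})

test_that("orthogonal planted programs land in different coefficient clusters", {
  scen <- generate_scenarios(seed = 5, n_samples = 200, n_features = 300)
  sim <- generate_cohort(scen$orthogonal)
  scheme <- make_cv_splits(sim$cohort, seed = 5, n_iterations = 4)
  results <- lapply(1:2, function(b) {
    t <- make_task(list(gene = "GENE1", description = paste0("exon=", b),
                        samples = sim$truth$branches$samples[[b]]),
                   sim$cohort, provenance = "tree")
    fit_predict(t, sim$cohort, scheme, seed = 5)
  })
  cs <- coefficient_summary(results, auc_floor = 0, k = 2)
  expect_false(cs$table$cluster[1] == cs$table$cluster[2])
  expect_gt(as.matrix(cs$dist)[1, 2], 0.5)
})

test_that("drug-response correlations respect the cell-line filter and sign convention", {
  withr::with_seed(30, {
    lines <- sprintf("CL%03d", 1:120)
    scores <- setNames(runif(120), lines)
    resp <- dplyr::bind_rows(
      tibble::tibble(drug = "monotone", sample_id = lines, auc50 = 2 - 3 * scores[lines]),
      tibble::tibble(drug = "null", sample_id = lines, auc50 = runif(120)),
      tibble::tibble(drug = "sparse", sample_id = lines[1:99], auc50 = runif(99)))
    out <- drug_response_correlation(scores, resp, min_lines = 100)
    expect_setequal(out$drug, c("monotone", "null"))
    mono <- out[out$drug == "monotone", ]
    expect_equal(mono$rho, -1)
    expect_equal(mono$rho_sensitivity, 1)
    expect_lt(abs(out$rho[out$drug == "null"]), 0.25)
  })
})

test_that("auc table and coefficient writers produce the documented layouts", {
  pf <- planted_fit()
  path <- withr::local_tempfile(fileext = ".tsv")
  tb <- write_auc_table(list(pf$ev_g, pf$ev_s), path)
  on_disk <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(on_disk), 2L)
  expect_true(all(paste0("cv_auc_", 1:10) %in% names(on_disk)))
  expect_equal(on_disk$auc, c(pf$ev_g$auc, pf$ev_s$auc))

  cs <- coefficient_summary(list(pf$res_g, pf$res_s), auc_floor = 0)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_coef_means(cs, cpath)
  cm <- readr::read_tsv(cpath, show_col_types = FALSE)
  expect_equal(names(cm)[1], "feature")
  expect_equal(nrow(cm), length(pf$res_g$features))
})

test_that("tidiers return tibbles in the documented shapes", {
  pf <- planted_fit()
  td <- tidy(pf$res_s)
  expect_true(tibble::is_tibble(td))
  expect_named(td, c("sample_id", "mutated", "mean_score"))
  expect_equal(nrow(td), 150L)
  long <- tidy(pf$res_s, long = TRUE)
  expect_equal(nrow(long), 150L * 10L)
  gl <- glance(pf$res_s)
  expect_equal(gl$auc, pf$ev_s$auc)
  expect_equal(gl$n_models, 40L)
  expect_s3_class(autoplot(pf$res_s), "ggplot")
})
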