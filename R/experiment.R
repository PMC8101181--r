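# End-to-end orchestration: enumerate a subgrouping catalogue, run the
# shared cross-validation protocol over gene-wide, subgrouping and random
# background tasks, and report divergence. All randomness flows from the
# single experiment seed via stable per-task derivations; no global RNG
# state is consumed.

#' Experiment configuration with protocol defaults
#'
#' Collects every tunable of the pipeline with its default: enumeration
#' thresholds (20 samples for a single branch, 10 per branch of a pair,
#' 5/20 for the expanded triple search), CNA augmentation minima (5 extra
#' carriers; 20 for a standalone CNA task), classifier kind and grid, the
#' cross-validation protocol (10 iterations of 4 folds), background counts
#' (5 cohort-specific and 5 gene-specific per subgrouping), and evaluation
#' options (coefficient-summary AUC floor 0.7).
#'
#' @param min_single,min_pair,expanded,min_triple,min_triple_total
#'   Enumeration thresholds (see [enumerate_subgroupings()]).
#' @param cna_min_extra,cna_min_standalone CNA thresholds (see
#'   [augment_with_cnas()]).
#' @param kind Classifier kind (see [hyperparam_grid()]).
#' @param n_iterations,n_folds Cross-validation protocol.
#' @param n_backgrounds_cohort,n_backgrounds_gene Random background counts.
#' @param auc_floor Coefficient-summary AUC floor.
#' @param num_trees Trees per forest fit.
#' @param seed Experiment seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(min_single = 20, min_pair = 10, expanded = FALSE,
                              min_triple = 5, min_triple_total = 20,
                              cna_min_extra = 5, cna_min_standalone = 20,
                              kind = "ridge", n_iterations = 10, n_folds = 4,
                              n_backgrounds_cohort = 5, n_backgrounds_gene = 5,
                              auc_floor = 0.7, num_trees = 500, seed = 1) {
  structure(list(
    min_single = min_single, min_pair = min_pair, expanded = expanded,
    min_triple = min_triple, min_triple_total = min_triple_total,
    cna_min_extra = cna_min_extra, cna_min_standalone = cna_min_standalone,
    kind = kind, n_iterations = n_iterations, n_folds = n_folds,
    n_backgrounds_cohort = n_backgrounds_cohort,
    n_backgrounds_gene = n_backgrounds_gene,
    auc_floor = auc_floor, num_trees = num_trees, seed = seed),
    class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file of configuration overrides.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0) {
    abort_config(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(experiment_config, overrides)
}

config_hash <- function(config) {
  stable_hash(paste(names(config), vapply(config, format, character(1)),
                    collapse = ";"))
}

#' Enumerate the subgrouping catalogue for a cohort's variants
#'
#' Builds the four property-hierarchy trees for each gene with enough
#' mutated samples, enumerates branch subgroupings under the configured
#' size rules, optionally augments with deep copy-number alterations and
#' deleteriousness-score thresholds, and flags duplicate sample sets
#' across hierarchies as aliases. Counts of candidates discarded as
#' gene-wide-equivalent or below threshold are reported as a message.
#'
#' @param variants Variant tibble (any number of genes).
#' @param config An [experiment_config()].
#' @param genes Genes to enumerate; defaults to all genes with at least
#'   `min_single` mutated samples.
#' @param cna Optional tidy CNA calls for [augment_with_cnas()].
#' @param score_thresholds Also emit PolyPhen/SIFT threshold subgroupings
#'   when scores are present (default TRUE).
#' @return Subgrouping catalogue tibble with alias flags.
#' @export
run_enumerate <- function(variants, config = experiment_config(), genes = NULL,
                          cna = NULL, score_thresholds = TRUE) {
  counts <- variants %>%
    distinct(.data$gene, .data$sample_id) %>%
    dplyr::count(.data$gene)
  genes <- genes %||% counts$gene[counts$n >= config$min_single]
  n_genewide <- 0L; n_below <- 0L
  rows <- list()
  for (g in genes) {
    vg <- filter(variants, .data$gene == g)
    for (h in names(hierarchy_specs())) {
      tree <- build_mutation_tree(vg, h)
      sg <- enumerate_subgroupings(tree, min_single = config$min_single,
                                   min_pair = config$min_pair,
                                   expanded = config$expanded,
                                   min_triple = config$min_triple,
                                   min_triple_total = config$min_triple_total)
      n_genewide <- n_genewide + attr(sg, "n_discarded_genewide")
      n_below <- n_below + attr(sg, "n_below_threshold")
      rows <- c(rows, list(sg))
    }
    if (score_thresholds) {
      for (metric in c("polyphen", "sift")) {
        if (any(!is.na(vg[[metric]]))) {
          rows <- c(rows, list(threshold_subgroupings(vg, metric,
                                                      min_samples = config$min_single)))
        }
      }
    }
  }
  catalogue <- bind_rows(rows)
  if (!is.null(cna) && nrow(catalogue) > 0) {
    catalogue <- augment_with_cnas(catalogue, cna,
                                   min_extra = config$cna_min_extra,
                                   min_standalone = config$cna_min_standalone)
  }
  catalogue <- dedupe_subgroupings(catalogue)
  inform(sprintf(
    "enumerated %d subgroupings over %d gene(s); discarded %d gene-wide-equivalent and %d below-threshold candidates",
    nrow(catalogue), length(genes), n_genewide, n_below))
  catalogue
}

gene_mutant_sets <- function(variants) {
  variants %>%
    distinct(.data$gene, .data$sample_id) %>%
    group_by(.data$gene) %>%
    summarise(samples = list(sort(.data$sample_id)), .groups = "drop")
}

#' Run the full classification experiment
#'
#' Builds the shared cross-validation scheme, then fits and evaluates the
#' gene-wide task of every gene, one task per non-alias catalogued
#' subgrouping, and the configured number of size-matched random
#' background tasks per subgrouping. When `out_dir` is given, results are
#' written there (per-task score matrices under `scores/`, a task
#' manifest, the `auc-mat` table and the coefficient means) and completed
#' tasks are skipped on re-runs; a run refuses to resume over a directory
#' written under a different configuration hash.
#'
#' @param cohort An `expression_cohort`.
#' @param variants Variant tibble for the cohort's samples.
#' @param config An [experiment_config()].
#' @param catalogue Subgrouping catalogue; enumerated from `variants` when
#'   omitted.
#' @param out_dir Optional results directory.
#' @param progress Print one line per fitted task.
#' @return A `subgrouping_experiment`: list with `results` and
#'   `evaluations` (named by task id), the task `manifest`, `catalogue`,
#'   `scheme`, `config` and `dir`.
#' @export
run_experiment <- function(cohort, variants, config = experiment_config(),
                           catalogue = NULL, out_dir = NULL, progress = FALSE) {
  catalogue <- catalogue %||% run_enumerate(variants, config)
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    prepare_results_dir(out_dir, hash)
  }
  mutants <- gene_mutant_sets(variants)
  genes <- sort(unique(c(catalogue$gene,
                         mutants$gene[lengths(mutants$samples) >= config$min_single])))
  scheme <- make_cv_splits(cohort, seed = config$seed,
                           n_iterations = config$n_iterations,
                           n_folds = config$n_folds)

  tasks <- list(); roles <- list()
  for (g in genes) {
    gm <- mutants$samples[[match(g, mutants$gene)]]
    t <- make_task(list(gene = g, description = "any point mutation", samples = gm),
                   cohort, provenance = "gene_wide")
    tasks <- c(tasks, list(t))
    roles <- c(roles, list(tibble(task_id = t$task_id, gene = g, role = "gene_wide",
                                  parent = NA_character_)))
  }
  todo <- if (nrow(catalogue) > 0) filter(catalogue, is.na(.data$alias_of)) else catalogue
  for (i in seq_len(nrow(todo))) {
    row <- todo[i, ]
    t <- make_task(row, cohort)
    tasks <- c(tasks, list(t))
    roles <- c(roles, list(tibble(task_id = t$task_id, gene = row$gene,
                                  role = "subgrouping", parent = row$description)))
    gm <- mutants$samples[[match(row$gene, mutants$gene)]] %||% character()
    bgs <- random_backgrounds(row, cohort, gm,
                              n_each = config$n_backgrounds_cohort,
                              n_gene = config$n_backgrounds_gene,
                              seed = config$seed)
    for (bt in bgs) {
      tasks <- c(tasks, list(bt))
      roles <- c(roles, list(tibble(task_id = bt$task_id, gene = row$gene,
                                    role = "background", parent = row$description)))
    }
  }
  manifest <- bind_rows(roles)
  if (anyDuplicated(manifest$task_id)) {
    dup <- manifest$task_id[duplicated(manifest$task_id)]
    manifest <- manifest[!duplicated(manifest$task_id), ]
    tasks <- tasks[match(manifest$task_id, map_chr(tasks, "task_id"))]
    inform(sprintf("%d duplicate task id(s) collapsed", length(dup)))
  }

  results <- list()
  for (t in tasks) {
    res <- NULL
    score_path <- if (!is.null(out_dir))
      file.path(out_dir, "scores", paste0(sanitize_filename(t$task_id), ".tsv"))
    if (!is.null(out_dir) && file.exists(score_path)) {
      res <- load_task_scores(score_path, t, config$kind)
      if (progress) inform(paste0("resumed ", t$task_id))
    } else {
      elapsed <- system.time(
        res <- fit_predict(t, cohort, scheme, kind = config$kind,
                           seed = config$seed, num_trees = config$num_trees))
      if (progress) inform(sprintf("fit %s in %.1fs", t$task_id, elapsed[["elapsed"]]))
      if (!is.null(out_dir)) write_task_scores(res, score_path)
    }
    results[[t$task_id]] <- res
  }
  evaluations <- lapply(results, evaluate_task)

  out <- structure(list(results = results, evaluations = evaluations,
                        manifest = manifest, catalogue = catalogue,
                        scheme = scheme, config = config, dir = out_dir),
                   class = "subgrouping_experiment")
  if (!is.null(out_dir)) {
    write_task_manifest(tasks, file.path(out_dir, "manifest.tsv"))
    write_auc_table(evaluations, file.path(out_dir, "auc-mat.tsv"),
                    reports = divergence_table(out))
    main <- results[manifest$task_id[manifest$role != "background"]]
    main <- purrr::keep(main, ~ !is.null(.x$coef))
    if (length(main) > 0) {
      cs <- try(coefficient_summary(main, auc_floor = -Inf), silent = TRUE)
      if (!inherits(cs, "try-error") && !is.null(cs$coef)) {
        write_coef_means(cs, file.path(out_dir, "coef-means.tsv"))
      }
    }
  }
  out
}

#' @export
print.subgrouping_experiment <- function(x, ...) {
  cat(sprintf("<subgrouping_experiment> %d task(s): %d gene-wide, %d subgrouping, %d background\n",
              nrow(x$manifest), sum(x$manifest$role == "gene_wide"),
              sum(x$manifest$role == "subgrouping"),
              sum(x$manifest$role == "background")))
  invisible(x)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

prepare_results_dir <- function(out_dir, hash) {
  dir.create(file.path(out_dir, "scores"), recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  if (file.exists(cfg_path)) {
    prev <- jsonlite::read_json(cfg_path)
    if (!identical(as.integer(prev$config_hash), as.integer(hash))) {
      abort_config("results directory was written under a different configuration; refusing to resume")
    }
  } else {
    jsonlite::write_json(list(config_hash = hash), cfg_path, auto_unbox = TRUE)
  }
}

write_task_scores <- function(result, path) {
  tb <- as_tibble(result$scores, rownames = "sample_id") %>%
    mutate(label = as.logical(result$labels[.data$sample_id]), .after = "sample_id")
  readr::write_tsv(tb, path)
  invisible(path)
}

load_task_scores <- function(path, task, kind) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), label = readr::col_logical(),
    .default = readr::col_double()), progress = FALSE)
  scores <- as.matrix(tb[, -(1:2)])
  rownames(scores) <- tb$sample_id
  structure(
    list(task_id = task$task_id, gene = task$gene,
         description = task$description, provenance = task$provenance,
         kind = kind, labels = setNames(tb$label, tb$sample_id),
         scores = scores, coef = NULL, intercepts = NULL, chosen = NULL,
         degenerate = NULL, features = NULL, models = NULL,
         n_models = ncol(scores) * 4L, seed = NA_integer_),
    class = "task_result")
}

#' Per-subgrouping divergence table of an experiment
#'
#' One row per fitted subgrouping task, comparing it to its gene-wide task
#' and its random backgrounds (see [divergence_report()]).
#'
#' @param experiment A `subgrouping_experiment`.
#' @return Divergence tibble (possibly empty).
#' @export
divergence_table <- function(experiment) {
  m <- experiment$manifest
  subs <- m[m$role == "subgrouping", ]
  rows <- list()
  for (i in seq_len(nrow(subs))) {
    g <- subs$gene[i]
    gene_id <- m$task_id[m$role == "gene_wide" & m$gene == g]
    if (length(gene_id) != 1) next
    bg_ids <- m$task_id[m$role == "background" & m$gene == g &
                          !is.na(m$parent) & m$parent == subs$parent[i]]
    rows <- c(rows, list(divergence_report(
      experiment$evaluations[[subs$task_id[i]]],
      experiment$evaluations[[gene_id]],
      background_evals = experiment$evaluations[bg_ids])))
  }
  bind_rows(rows)
}

#' Per-gene divergence summary (best subgrouping per gene)
#'
#' The machine-readable analogue of a gene-level divergence overview: for
#' each gene the gene-wide task AUC, plus — when the gene has subgroupings
#' — the best subgrouping's description, AUC, cv-significance flag, DeLong
#' divergence p-value and null-background percentile. Genes without
#' subgroupings keep their gene-wide row with NA subgrouping columns.
#'
#' @param experiment A `subgrouping_experiment`.
#' @return Per-gene tibble.
#' @export
report_divergence <- function(experiment) {
  m <- experiment$manifest
  tbl <- divergence_table(experiment)
  purrr::map_dfr(unique(m$gene[m$role == "gene_wide"]), function(g) {
    gene_eval <- experiment$evaluations[[m$task_id[m$role == "gene_wide" & m$gene == g]]]
    gene_rows <- if (nrow(tbl) > 0) filter(tbl, .data$gene == g) else tbl
    if (nrow(gene_rows) == 0) {
      return(tibble(gene = g, gene_wide_auc = gene_eval$auc,
                    best_subgrouping = NA_character_, best_auc = NA_real_,
                    n_subgroupings = 0L, cv_significant = NA,
                    p_divg = NA_real_, null_percentile = NA_real_))
    }
    best <- gene_rows[which.max(gene_rows$auc), ]
    tibble(gene = g, gene_wide_auc = gene_eval$auc,
           best_subgrouping = best$description, best_auc = best$auc,
           n_subgroupings = nrow(gene_rows),
           cv_significant = best$cv_significant, p_divg = best$p_divg,
           null_percentile = best$null_percentile)
  })
}
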