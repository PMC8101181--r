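# broom-style tidiers and ggplot2 methods for the fitted objects.

#' @describeIn fit_predict Tidy per-sample scores: one row per sample with
#'   its label, mean score across iterations, and per-iteration scores in
#'   long form when `long = TRUE`.
#' @param x A `task_result`.
#' @param long Return one row per sample x iteration instead of means.
#' @param ... Unused.
#' @export
tidy.task_result <- function(x, long = FALSE, ...) {
  tb <- as_tibble(x$scores, rownames = "sample_id") %>%
    mutate(mutated = as.logical(x$labels[.data$sample_id]), .after = "sample_id")
  if (long) {
    tidyr::pivot_longer(tb, -c("sample_id", "mutated"),
                        names_to = "iteration", values_to = "score")
  } else {
    iters <- setdiff(names(tb), c("sample_id", "mutated"))
    tb %>%
      mutate(mean_score = rowMeans(across(all_of(iters)))) %>%
      select("sample_id", "mutated", "mean_score")
  }
}

#' @describeIn fit_predict One-row model summary: task AUC, cv-AUC range,
#'   number of models, chosen-hyperparameter spread and degenerate folds.
#' @export
glance.task_result <- function(x, ...) {
  e <- evaluate_task(x)
  tibble(task_id = x$task_id, gene = x$gene, provenance = x$provenance,
         kind = x$kind, n_pos = e$n_pos, n_models = x$n_models,
         auc = e$auc, cv_auc_min = min(e$cv_aucs), cv_auc_max = max(e$cv_aucs),
         n_degenerate = if (is.null(x$degenerate)) NA_integer_ else sum(x$degenerate))
}

#' @describeIn evaluate_task Tidy evaluation: one row per cross-validation
#'   iteration with its cv-AUC.
#' @param x A `task_evaluation`.
#' @param ... Unused.
#' @export
tidy.task_evaluation <- function(x, ...) {
  tibble(task_id = x$task_id, iteration = seq_along(x$cv_aucs),
         cv_auc = unname(x$cv_aucs))
}

#' @describeIn evaluate_task One-row summary with the task AUC.
#' @export
glance.task_evaluation <- function(x, ...) {
  tibble(task_id = x$task_id, gene = x$gene, provenance = x$provenance,
         n_pos = x$n_pos, auc = x$auc,
         cv_auc_min = min(x$cv_aucs), cv_auc_max = max(x$cv_aucs))
}

#' @describeIn coefficient_summary Tidy cluster assignments, one row per
#'   task.
#' @param x A `coefficient_summary`.
#' @param ... Unused.
#' @export
tidy.coefficient_summary <- function(x, ...) x$table

#' Mutation-score distributions of a fitted task
#'
#' Densities of the samples' mean cross-validated scores, split by true
#' mutation label — the per-task picture of how separable the subgrouping
#' is in expression space.
#'
#' @param object A `task_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot task_result
#' @export
autoplot.task_result <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$mean_score, fill = .data$mutated)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "mean mutation score", fill = "mutated",
                  title = object$task_id,
                  subtitle = sprintf("task AUC %.3f",
                                     evaluate_task(object)$auc)) +
    ggplot2::theme_minimal()
}

#' Gene-level divergence overview plot
#'
#' Gene-wide task AUC against the best subgrouping AUC per gene; genes
#' above the diagonal harbour subgroupings whose transcriptomic signature
#' outperforms the gene-wide one, with cv-significant cases highlighted.
#'
#' @param report Per-gene tibble from [report_divergence()].
#' @return A ggplot object.
#' @export
plot_divergence <- function(report) {
  report %>%
    filter(!is.na(.data$best_auc)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$gene_wide_auc, y = .data$best_auc)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cv_significant,
                                     size = .data$n_subgroupings)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "gene-wide task AUC", y = "best subgrouping AUC",
                  colour = "cv-significant", size = "subgroupings") +
    ggplot2::theme_minimal()
}

#' Coefficient-cluster dendrogram-free overview
#'
#' Plots each eligible task's AUC against its coefficient cluster, the
#' quick look at whether well-performing subgroupings of a gene share one
#' expression program or split into several.
#'
#' @param object A `coefficient_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coefficient_summary
#' @export
autoplot.coefficient_summary <- function(object, ...) {
  object$table %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$cluster), y = .data$auc)) +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$displayed), width = 0.1,
                         height = 0) +
    ggplot2::labs(x = "coefficient cluster", y = "task AUC",
                  shape = "displayed") +
    ggplot2::theme_minimal()
}
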