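#' Build a binary classification task from a subgrouping
#'
#' A task labels every cohort sample `TRUE` iff it belongs to the
#' subgrouping's mutated-sample set; all other samples — including other
#' mutants of the same gene, for subgrouping tasks — are labelled `FALSE`.
#'
#' @param subgrouping One row of a subgrouping tibble, or a list with at
#'   least `gene`, `description` and `samples` elements.
#' @param cohort An `expression_cohort` whose samples cover the subgrouping.
#' @param provenance Task provenance label, defaulting to the subgrouping's.
#' @return A `mutation_task`: list with `task_id`, `gene`, `description`,
#'   `provenance`, logical `labels` named by sample, `n_pos`, `n_neg`.
#' @export
#' @examples
#' fx <- pik3ca_fixture()
#' task <- gene_wide_task(fx$variants, fx$cohort)
#' task$n_pos
make_task <- function(subgrouping, cohort, provenance = NULL) {
  sg <- as_subgrouping_row(subgrouping)
  samples <- cohort_samples(cohort)
  if (length(sg$samples) == 0) {
    abort_input("subgrouping has an empty sample set")
  }
  outside <- setdiff(sg$samples, samples)
  if (length(outside) > 0) {
    abort_input(paste0(length(outside), " subgrouping sample(s) not in cohort"))
  }
  labels <- setNames(samples %in% sg$samples, samples)
  new_task(gene = sg$gene, description = sg$description,
           provenance = provenance %||% sg$provenance %||% "tree",
           labels = labels)
}

as_subgrouping_row <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    list(gene = x$gene, description = x$description,
         provenance = x$provenance %||% NULL,
         samples = x$samples[[1]])
  } else {
    x
  }
}

new_task <- function(gene, description, provenance, labels) {
  structure(
    list(task_id = paste0(gene, "__", gsub("[^A-Za-z0-9._=<>-]+", "_", description),
                          "__", provenance),
         gene = gene, description = description, provenance = provenance,
         labels = labels, n_pos = sum(labels), n_neg = sum(!labels)),
    class = "mutation_task")
}

#' @export
print.mutation_task <- function(x, ...) {
  cat(sprintf("<mutation_task> %s [%s]\n  %d mutated vs %d wild-type of %d samples\n",
              x$task_id, x$provenance, x$n_pos, x$n_neg, length(x$labels)))
  invisible(x)
}

#' Gene-wide classification task
#'
#' Labels every sample carrying any point mutation of the gene `TRUE`.
#'
#' @param variants Variant tibble (one or more genes).
#' @param cohort An `expression_cohort`.
#' @param gene Gene symbol; defaults to the single gene in `variants`.
#' @return A `mutation_task` with provenance `"gene_wide"`.
#' @export
gene_wide_task <- function(variants, cohort, gene = NULL) {
  gene <- gene %||% unique(variants$gene)
  stopifnot(length(gene) == 1)
  mutants <- sort(unique(variants$sample_id[variants$gene == gene]))
  make_task(list(gene = gene, description = "any point mutation",
                 samples = mutants),
            cohort, provenance = "gene_wide")
}

#' Size-matched random background tasks
#'
#' Constructs null classification tasks whose positive sets are random
#' sample draws matched in size to a subgrouping: `n_each` cohort-specific
#' tasks drawing uniformly without replacement from all cohort samples, and
#' `n_each` gene-specific tasks drawing from the samples carrying any point
#' mutation of the subgrouping's gene. Draws are reproducible: the task
#' seeds derive from the experiment seed and a stable hash of the
#' subgrouping descriptor, so enlarging a catalogue never perturbs the
#' backgrounds of other subgroupings.
#'
#' When the gene has fewer mutants than the subgrouping size the
#' gene-specific draws are impossible and are skipped with a warning; when
#' it has exactly as many, every gene-specific draw equals the gene-wide
#' set and the tasks are flagged via the `degenerate_gene_draws` attribute.
#'
#' @param subgrouping One subgrouping row (or list with `gene`,
#'   `description`, `samples`).
#' @param cohort An `expression_cohort`.
#' @param gene_mutants Character vector of all samples with any point
#'   mutation of the gene (donor pool for gene-specific draws).
#' @param n_each Number of cohort-specific tasks (default 5).
#' @param seed Experiment seed.
#' @param n_gene Number of gene-specific tasks (defaults to `n_each`).
#' @return List of `mutation_task` objects with provenance
#'   `"random_cohort"` / `"random_gene"`.
#' @export
random_backgrounds <- function(subgrouping, cohort, gene_mutants,
                               n_each = 5, seed = 1, n_gene = n_each) {
  sg <- as_subgrouping_row(subgrouping)
  k <- length(sg$samples)
  samples <- cohort_samples(cohort)
  tasks <- list()
  for (i in seq_len(n_each)) {
    rng_seed <- derive_seed(seed, sg$gene, sg$description, "cohort", i)
    pos <- withr::with_seed(rng_seed, sample(samples, k))
    tasks <- c(tasks, list(new_task(
      gene = sg$gene,
      description = paste0("random cohort draw ", i, " (n=", k, ") for ",
                           sg$description),
      provenance = "random_cohort",
      labels = setNames(samples %in% pos, samples))))
  }
  degenerate <- FALSE
  if (n_gene == 0) {
    # gene-specific draws not requested
  } else if (length(gene_mutants) < k) {
    warn(sprintf("gene has %d mutants < subgrouping size %d; skipping gene-specific draws",
                 length(gene_mutants), k))
  } else {
    if (length(gene_mutants) == k) {
      inform("subgrouping covers all gene mutants; gene-specific draws are all identical")
      degenerate <- TRUE
    }
    for (i in seq_len(n_gene)) {
      rng_seed <- derive_seed(seed, sg$gene, sg$description, "gene", i)
      pos <- withr::with_seed(rng_seed, sample(gene_mutants, k))
      tasks <- c(tasks, list(new_task(
        gene = sg$gene,
        description = paste0("random gene draw ", i, " (n=", k, ") for ",
                             sg$description),
        provenance = "random_gene",
        labels = setNames(samples %in% pos, samples))))
    }
  }
  structure(tasks, degenerate_gene_draws = degenerate)
}

#' Write a task manifest to TSV
#'
#' @param tasks List of `mutation_task` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_task_manifest <- function(tasks, path) {
  purrr::map_dfr(tasks, function(t) tibble(
    task_id = t$task_id, gene = t$gene, descriptor = t$description,
    n_pos = t$n_pos, provenance = t$provenance)) %>%
    readr::write_tsv(path)
  invisible(path)
}
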