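#' Read an expression matrix from TSV
#'
#' Reads a samples x genes (or genes x samples) tab-separated expression
#' matrix with row identifiers in the first column. When an annotation table
#' is supplied the orientation is detected automatically: if the row
#' identifiers match annotated gene symbols better than the column names do,
#' the matrix is transposed so that rows are always samples.
#'
#' @param path TSV file; first column holds row identifiers.
#' @param annotation Optional gene annotation tibble (see
#'   [read_gene_annotation()]) used to auto-orient the matrix.
#' @return Numeric matrix, samples in rows, gene features in columns.
#' @export
read_expression <- function(path, annotation = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()), progress = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  if (!is.null(annotation)) {
    genes <- annotation$gene
    if (sum(rownames(m) %in% genes) > sum(colnames(m) %in% genes)) {
      m <- t(m)
    }
  }
  m
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene`, `chromosome`, `biotype`.
#' @return Tibble with those columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("gene", "chromosome", "biotype"), names(ann))
  if (length(missing_cols) > 0) {
    abort_input(paste0("annotation is missing columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  ann
}

#' Prepare an expression cohort for classification
#'
#' Filters and normalises a raw expression matrix into the classifier
#' feature space, in this fixed order:
#'
#' 1. drop features that are not protein-coding or lie on the X/Y sex
#'    chromosomes;
#' 2. drop features with any missing value;
#' 3. drop the bottom decile of the remaining features by mean raw value
#'    across the cohort;
#' 4. log-transform (`log2(x + 1)`);
#' 5. z-score each feature across samples.
#'
#' Features that are constant after filtering would produce divide-by-zero
#' z-scores and are dropped with a warning. The per-feature log-scale means
#' and standard deviations are retained so that transfer targets can reuse
#' the training cohort's scaling if requested.
#'
#' @param expr Numeric matrix, samples x features (see [read_expression()]).
#' @param annotation Gene annotation tibble covering all features.
#' @param low_expression_quantile Fraction of lowest-mean features dropped
#'   in step 3 (default 0.1, i.e. the bottom decile).
#' @return An `expression_cohort`: list with the z-scored `expr` matrix,
#'   the retained feature `annotation`, `scale` parameters (log-scale mean
#'   and sd per feature) and a record of dropped feature counts.
#' @export
prepare_cohort <- function(expr, annotation, low_expression_quantile = 0.1) {
  stopifnot(is.matrix(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort_input("expression matrix must carry sample and feature names")
  }
  if (any(apply(expr, 1, function(r) all(is.na(r))))) {
    abort_input("cohort contains a sample with all-missing expression")
  }
  missing_ann <- setdiff(colnames(expr), annotation$gene)
  if (length(missing_ann) > 0) {
    abort_input(paste0(length(missing_ann), " features lack annotation (e.g. ",
                       head(missing_ann, 3)[1], ")"))
  }
  ann <- annotation[match(colnames(expr), annotation$gene), ]
  dropped <- list()

  keep <- ann$biotype == "protein_coding" &
    !(toupper(sub("^chr", "", ann$chromosome)) %in% c("X", "Y"))
  dropped$non_coding_or_sex <- sum(!keep)
  expr <- expr[, keep, drop = FALSE]; ann <- ann[keep, ]

  keep <- !apply(expr, 2, anyNA)
  dropped$missing_values <- sum(!keep)
  expr <- expr[, keep, drop = FALSE]; ann <- ann[keep, ]

  means <- colMeans(expr)
  cut <- quantile(means, low_expression_quantile, type = 7)
  keep <- means > cut
  # quantile ties can push the retained fraction off target; fall back to a
  # rank rule so exactly ceiling(q * p) features are dropped
  n_drop <- ceiling(low_expression_quantile * length(means))
  if (sum(!keep) != n_drop) {
    keep <- rank(means, ties.method = "first") > n_drop
  }
  dropped$low_expression <- sum(!keep)
  expr <- expr[, keep, drop = FALSE]; ann <- ann[keep, ]

  expr <- log2(expr + 1)
  sds <- apply(expr, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0), " constant feature(s) dropped before z-scoring"))
    keepc <- sds > 0
    dropped$constant <- sum(!keepc)
    expr <- expr[, keepc, drop = FALSE]; ann <- ann[keepc, ]
    sds <- sds[keepc]
  }
  mus <- colMeans(expr)
  log_expr <- expr
  expr <- scale(expr, center = mus, scale = sds)
  attr(expr, "scaled:center") <- NULL
  attr(expr, "scaled:scale") <- NULL

  co <- new_expression_cohort(expr, ann,
                              scale = list(center = mus, sd = sds),
                              dropped = dropped, prepared_from_raw = TRUE)
  # log-scale values are kept so the leakage-safe mode of fit_predict()
  # can refit the per-feature scaler on training folds only
  co$log_expr <- log_expr
  co
}

new_expression_cohort <- function(expr, annotation, scale = NULL,
                                  dropped = list(), prepared_from_raw = FALSE) {
  structure(
    list(expr = expr, annotation = as_tibble(annotation), scale = scale,
         dropped = dropped, prepared_from_raw = prepared_from_raw),
    class = "expression_cohort")
}

#' Wrap an already-normalised matrix as an expression cohort
#'
#' Used for matrices already on the prepared (z-scored) scale, such as the
#' output of the synthetic cohort generator.
#'
#' @param expr Numeric matrix, samples x features, with dimnames.
#' @param annotation Annotation tibble covering all features.
#' @return An `expression_cohort`.
#' @export
as_expression_cohort <- function(expr, annotation) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (!all(colnames(expr) %in% annotation$gene)) {
    abort_input("annotation does not cover all features")
  }
  new_expression_cohort(expr, annotation[match(colnames(expr), annotation$gene), ])
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> %d samples x %d features\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

cohort_samples <- function(cohort) rownames(cohort$expr)

#' Per-task feature mask: exclude the task gene's chromosome
#'
#' Expression features annotated to the same chromosome as the gene whose
#' subgrouping defines a task are excluded from that task's feature space,
#' so a classifier cannot read the mutation off cis effects or the gene's
#' own transcript. The mask depends only on the chromosome annotation,
#' never on labels.
#'
#' @param cohort An `expression_cohort`.
#' @param gene Task gene symbol, or `NA` for no masking (e.g. random
#'   cohort-wide background tasks unlinked to a gene).
#' @return Character vector of retained feature names.
#' @export
task_feature_mask <- function(cohort, gene) {
  feats <- colnames(cohort$expr)
  if (is.na(gene)) return(feats)
  ann <- cohort$annotation
  hit <- ann$chromosome[match(gene, ann$gene)]
  if (is.na(hit)) {
    abort_config(paste0("gene ", gene, " absent from cohort annotation"))
  }
  feats[ann$chromosome != hit]
}

#' Intersect cohorts on shared features
#'
#' Restricts each cohort to the features present in every cohort, for
#' transfer evaluation across cohorts whose expression panels differ.
#'
#' @param cohorts List of `expression_cohort` objects.
#' @return List of cohorts over the common feature set.
#' @export
intersect_cohort_features <- function(cohorts) {
  common <- Reduce(intersect, lapply(cohorts, function(co) colnames(co$expr)))
  if (length(common) == 0) abort_input("cohorts share no expression features")
  lapply(cohorts, function(co) {
    new_expression_cohort(co$expr[, common, drop = FALSE],
                          co$annotation[match(common, co$annotation$gene), ],
                          scale = if (!is.null(co$scale))
                            lapply(co$scale, function(s) s[common]) else NULL)
  })
}
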