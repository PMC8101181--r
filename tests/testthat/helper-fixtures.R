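# Shared fixtures and independent oracles, all built in code.

# Tiny variant table builder: one row per sample x variant.
toy_variants <- function(gene = "TG1", branches) {
  # branches: list of list(exon=, n=, aa_location=, samples=, ...)
  rows <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    samples <- b$samples %||% sprintf("%s_b%d_%03d", gene, i, seq_len(b$n))
    tibble::tibble(
      sample_id = samples, gene = gene,
      exon = b$exon %||% as.character(i),
      aa_location = b$aa_location %||% as.character(100 * i),
      aa_substitution = b$aa_substitution %||% paste0("A", 100 * i, "V"),
      consequence = b$consequence %||% "missense",
      smart_domain = b$smart_domain %||% "no overlapping domain",
      pfam_domain = b$pfam_domain %||% "no overlapping domain",
      polyphen = b$polyphen %||% NA_real_, sift = b$sift %||% NA_real_)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal prepared cohort over given samples: pure-noise features.
toy_cohort <- function(samples, n_features = 12, seed = 42, gene_on_chr = NULL) {
  expr <- withr::with_seed(seed, matrix(
    rnorm(length(samples) * n_features), length(samples), n_features,
    dimnames = list(samples, sprintf("G%03d", seq_len(n_features)))))
  chroms <- rep_len(as.character(1:4), n_features)
  ann <- tibble::tibble(gene = colnames(expr), chromosome = chroms,
                        biotype = "protein_coding")
  if (!is.null(gene_on_chr)) {
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      gene = names(gene_on_chr), chromosome = unname(gene_on_chr),
      biotype = "protein_coding"))
    # annotation must cover exactly the features; add gene as extra feature
    extra <- matrix(rnorm(length(samples) * length(gene_on_chr)),
                    length(samples), length(gene_on_chr),
                    dimnames = list(samples, names(gene_on_chr)))
    expr <- cbind(expr, extra)
  }
  as_expression_cohort(expr, ann)
}

# Brute-force subgrouping enumeration oracle: enumerate every subset of at
# most `max_branches` tree nodes via set arithmetic, apply the size rules
# directly, and return the distinct sample sets as sorted key strings.
oracle_enumerate <- function(tree, min_single = 20, min_pair = 10,
                             expanded = FALSE, min_triple = 5,
                             min_triple_total = 20) {
  root <- attr(tree, "root_samples")
  nodes <- seq_len(nrow(tree))
  keysets <- character()
  nested <- function(a, b) {
    startsWith(tree$path[b], paste0(tree$path[a], ":")) ||
      startsWith(tree$path[a], paste0(tree$path[b], ":"))
  }
  add <- function(samples) {
    if (setequal(samples, root)) return()
    keysets <<- c(keysets, paste(sort(samples), collapse = "|"))
  }
  for (i in nodes) {
    if (tree$n_samples[i] >= min_single) add(tree$samples[[i]])
  }
  if (length(nodes) >= 2) {
    for (i in nodes) for (j in nodes) {
      if (i >= j || nested(i, j)) next
      if (tree$n_samples[i] >= min_pair && tree$n_samples[j] >= min_pair) {
        u <- union(tree$samples[[i]], tree$samples[[j]])
        if (length(u) >= 2 * min_pair) add(u)
      }
    }
  }
  if (expanded && length(nodes) >= 3) {
    for (i in nodes) for (j in nodes) for (k in nodes) {
      if (i >= j || j >= k) next
      if (nested(i, j) || nested(i, k) || nested(j, k)) next
      if (min(tree$n_samples[c(i, j, k)]) >= min_triple) {
        u <- union(union(tree$samples[[i]], tree$samples[[j]]), tree$samples[[k]])
        if (length(u) >= min_triple_total) add(u)
      }
    }
  }
  sort(unique(keysets))
}

subgrouping_keys <- function(sg) {
  sort(unique(vapply(sg$samples, function(s) paste(sort(s), collapse = "|"),
                     character(1))))
}

# Brute-force pairwise AUC oracle: enumerate all mutant x wild-type pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Permutation oracle for the paired DeLong comparison: permute the pairing
# of the two score vectors by swapping them per sample with probability
# one half, and locate the observed AUC difference in the null.
oracle_delong_p <- function(gene_scores, sub_scores, labels, B = 2000, seed = 1) {
  obs <- pairwise_auc(sub_scores, labels) - pairwise_auc(gene_scores, labels)
  withr::with_seed(seed, {
    hits <- 0L
    n <- length(labels)
    for (b in seq_len(B)) {
      swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
      s1 <- ifelse(swap, gene_scores, sub_scores)
      s2 <- ifelse(swap, sub_scores, gene_scores)
      d <- pairwise_auc(s1, labels) - pairwise_auc(s2, labels)
      if (d >= obs) hits <- hits + 1L
    }
    (hits + 1) / (B + 1)
  })
}

# Small planted cohort + fitted gene-wide/subgrouping results, shared by
# the slower evaluation tests. Cached per session.
planted_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(150, 120, tibble::tibble(
      gene = "TG1", exon = c("1", "2"), n_samples = c(25, 25),
      delta = c(4.5, 0), program = c("P1", NA)),
      program_size = 25, seed = 301)
    sim <- generate_cohort(cfg)
    scheme <- make_cv_splits(sim$cohort, seed = 301, n_iterations = 10, n_folds = 4)
    gw <- gene_wide_task(sim$variants, sim$cohort)
    sub <- make_task(list(gene = "TG1", description = "exon=1",
                          samples = sim$truth$branches$samples[[1]]),
                     sim$cohort, provenance = "tree")
    res_g <- fit_predict(gw, sim$cohort, scheme, seed = 301)
    res_s <- fit_predict(sub, sim$cohort, scheme, seed = 301)
    cache <<- list(sim = sim, scheme = scheme,
                   res_g = res_g, res_s = res_s,
                   ev_g = evaluate_task(res_g), ev_s = evaluate_task(res_s))
    cache
  }
})
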