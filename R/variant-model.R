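#' Fixed mutation property hierarchies
#'
#' Point mutations of a gene are organised into trees along ordered lists of
#' variant annotation properties. Four fixed hierarchies are used: exon then
#' codon location then amino-acid substitution; consequence then exon; SMART
#' domain then consequence; and Pfam domain then consequence. Each hierarchy
#' yields one tree per gene, and tree branches (leaves or internal nodes)
#' are the building blocks of mutation subgroupings.
#'
#' @return Named list of character vectors of variant-table column names, in
#'   root-to-leaf order.
#' @export
#' @examples
#' hierarchy_specs()
hierarchy_specs <- function() {
  list(
    exon_location_substitution = c("exon", "aa_location", "aa_substitution"),
    consequence_exon           = c("consequence", "exon"),
    smart_consequence          = c("smart_domain", "consequence"),
    pfam_consequence           = c("pfam_domain", "consequence")
  )
}

variant_columns <- c(
  "sample_id", "gene", "exon", "aa_location", "aa_substitution",
  "consequence", "smart_domain", "pfam_domain", "polyphen", "sift"
)

# The annotation convention for "no value": exon/codon/substitution fields
# are never empty strings; unassigned values are encoded as ".".
MISSING <- "."
NO_DOMAIN <- "no overlapping domain"

#' Read an annotated variant table
#'
#' Reads a tab-separated variant table (one row per sample x variant) in the
#' dialect produced by consequence annotators such as VEP: columns `Sample`,
#' `Gene`, `Exon`, `Protein_position`, `Amino_acids`, `Consequence`,
#' `DOMAINS`, and optionally `PolyPhen` and `SIFT`. Missing values are
#' encoded `"."`.
#'
#' Exon and protein-position fields of the form `"5/23"` are reduced to their
#' numerator. `Amino_acids` of the form `"H/R"` are combined with the protein
#' position into a substitution label (`"H1047R"`); already-combined labels
#' are kept as is. `DOMAINS` entries prefixed `SMART:` and `Pfam:` (or the
#' `_domain` variants) populate the two domain columns; variants without a
#' matching entry are assigned `"no overlapping domain"`. PolyPhen/SIFT
#' values such as `"probably_damaging(0.967)"` are reduced to their numeric
#' score.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `gene`, `exon`, `aa_location`,
#'   `aa_substitution`, `consequence`, `smart_domain`, `pfam_domain`,
#'   `polyphen`, `sift`.
#' @export
#' @examples
#' path <- system.file("extdata", "example_variants.tsv", package = "mutsubsig")
#' read_variants(path)
read_variants <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("Sample", "Gene", "Exon", "Protein_position", "Amino_acids",
                "Consequence", "DOMAINS")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_input(paste0("variant table is missing required columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  tibble(
    sample_id = raw$Sample,
    gene = raw$Gene,
    exon = parse_fraction(raw$Exon),
    aa_location = parse_fraction(raw$Protein_position),
    aa_substitution = make_substitution(raw$Amino_acids, parse_fraction(raw$Protein_position)),
    consequence = dot_fill(raw$Consequence),
    smart_domain = parse_domain(raw$DOMAINS, c("SMART", "SMART_domains")),
    pfam_domain = parse_domain(raw$DOMAINS, c("Pfam", "Pfam_domain")),
    polyphen = parse_score(raw[["PolyPhen"]] %||% rep(NA_character_, nrow(raw))),
    sift = parse_score(raw[["SIFT"]] %||% rep(NA_character_, nrow(raw)))
  ) %>%
    validate_variants()
}

validate_variants <- function(variants) {
  if (any(is.na(variants$sample_id) | variants$sample_id == "")) {
    abort_input("variant table contains empty sample ids")
  }
  if (any(is.na(variants$gene) | variants$gene == "")) {
    abort_input("variant table contains empty gene symbols")
  }
  variants %>%
    mutate(across(all_of(c("exon", "aa_location", "aa_substitution", "consequence")),
                  dot_fill),
           across(all_of(c("smart_domain", "pfam_domain")),
                  ~ ifelse(is.na(.x) | .x == "" | .x == MISSING, NO_DOMAIN, .x)))
}

dot_fill <- function(x) ifelse(is.na(x) | x == "", MISSING, x)

parse_fraction <- function(x) {
  x <- dot_fill(x)
  ifelse(grepl("/", x, fixed = TRUE), sub("/.*$", "", x), x)
}

make_substitution <- function(aa, pos) {
  aa <- dot_fill(aa)
  out <- aa
  split <- grepl("^[A-Za-z*]+/[A-Za-z*]+$", aa)
  out[split] <- paste0(sub("/.*$", "", aa[split]), pos[split], sub("^.*/", "", aa[split]))
  out[aa == MISSING | (split & pos == MISSING)] <- MISSING
  out
}

parse_domain <- function(domains, prefixes) {
  domains <- dot_fill(domains)
  vapply(strsplit(domains, "[,;&]"), function(tokens) {
    for (pre in prefixes) {
      hit <- grep(paste0("^", pre, ":"), tokens, value = TRUE)
      if (length(hit) > 0) return(sub("^[^:]+:", "", hit[[1]]))
    }
    NO_DOMAIN
  }, character(1))
}

parse_score <- function(x) {
  x <- as.character(x)
  inner <- regmatches(x, regexpr("\\(([0-9.eE+-]+)\\)", x))
  has_inner <- lengths(regmatches(x, gregexpr("\\(([0-9.eE+-]+)\\)", x))) > 0 &
    !is.na(x)
  x[has_inner] <- gsub("[()]", "", regmatches(x, regexpr("\\(([0-9.eE+-]+)\\)", x)))
  suppressWarnings(as.numeric(ifelse(x %in% c(MISSING, ""), NA, x)))
}

#' Build a mutation property tree for one gene
#'
#' Groups the distinct mutated samples of one gene by attribute-value path
#' under an ordered property hierarchy. A node of the tree is an
#' attribute-value path (e.g. exon `"21"`, or exon `"21"` then codon
#' `"1047"`) together with the set of samples carrying a matching variant.
#' Samples are counted once per node (sets, not multisets); a sample with
#' variants on two branches appears in both. The unassigned value `"."` is a
#' first-class branch value, so e.g. splice variants without an exon
#' assignment form their own branch under exon-rooted hierarchies.
#'
#' @param variants Variant tibble (see [read_variants()]) for a single gene.
#' @param hierarchy Either the name of one of the four fixed hierarchies (see
#'   [hierarchy_specs()]) or a character vector of variant-table columns.
#' @return A tibble of tree nodes with class `mutation_tree`: columns `path`
#'   (levels joined by `":"`), `level`, `description`, `n_samples`, `samples`
#'   (list column of sample ids). Attributes `gene`, `hierarchy`,
#'   `hierarchy_name` and `root_samples` (all mutated samples of the gene).
#' @export
#' @examples
#' fx <- pik3ca_fixture()
#' tree <- build_mutation_tree(fx$variants, "exon_location_substitution")
#' dplyr::filter(tree, level == 1)
build_mutation_tree <- function(variants, hierarchy = "exon_location_substitution") {
  levels <- resolve_hierarchy(hierarchy)
  hierarchy_name <- if (is.character(hierarchy) && length(hierarchy) == 1 &&
                        hierarchy %in% names(hierarchy_specs())) hierarchy else
                        paste(levels, collapse = ">")
  missing_cols <- setdiff(levels, names(variants))
  if (length(missing_cols) > 0) {
    abort_config(paste0("unknown hierarchy properties: ",
                        paste(missing_cols, collapse = ", ")))
  }
  gene <- unique(variants$gene)
  if (length(gene) > 1) {
    abort_input("build_mutation_tree() expects variants of a single gene")
  }
  if (nrow(variants) == 0) {
    gene <- if (length(gene) == 0) NA_character_ else gene
    nodes <- tibble(path = character(), level = integer(),
                    description = character(), n_samples = integer(),
                    samples = list())
  } else {
    nodes <- purrr::map_dfr(seq_along(levels), function(d) {
      cols <- levels[seq_len(d)]
      tmp <- variants
      tmp$.path <- do.call(paste, c(as.list(tmp[cols]), sep = ":"))
      tmp %>%
        group_by(.data$.path) %>%
        summarise(samples = list(sort(unique(.data$sample_id))), .groups = "drop") %>%
        mutate(level = d,
               description = describe_path(.data$.path, levels),
               n_samples = lengths(samples)) %>%
        rename(path = ".path")
    }) %>%
      arrange(.data$level, .data$path) %>%
      select("path", "level", "description", "n_samples", "samples")
  }
  root_samples <- sort(unique(variants$sample_id))
  structure(nodes,
            gene = gene, hierarchy = levels, hierarchy_name = hierarchy_name,
            root_samples = root_samples,
            class = c("mutation_tree", class(nodes)))
}

resolve_hierarchy <- function(hierarchy) {
  specs <- hierarchy_specs()
  if (is.character(hierarchy) && length(hierarchy) == 1 && hierarchy %in% names(specs)) {
    specs[[hierarchy]]
  } else if (is.character(hierarchy) && length(hierarchy) >= 1) {
    hierarchy
  } else {
    abort_config("hierarchy must be a spec name or a character vector of properties")
  }
}

describe_path <- function(path, levels) {
  vapply(strsplit(path, ":", fixed = TRUE), function(vals) {
    paste(paste0(levels[seq_along(vals)], "=", vals), collapse = ",")
  }, character(1))
}

# TRUE if path a is a strict ancestor of path b (levels joined by ":").
path_is_ancestor <- function(a, b) {
  startsWith(b, paste0(a, ":"))
}

paths_nested <- function(a, b) {
  path_is_ancestor(a, b) || path_is_ancestor(b, a)
}

empty_subgroupings <- function() {
  tibble(gene = character(), hierarchy = character(), provenance = character(),
         description = character(), branches = list(), samples = list(),
         n_samples = integer())
}

#' Enumerate candidate mutation subgroupings from a tree
#'
#' Searches the branches of a mutation property tree for subgroupings with
#' enough mutated samples to train a classifier on. The default search emits
#' (a) every branch — leaf or internal, at any depth — carrying at least
#' `min_single` samples, and (b) every pair of non-nested branches each
#' carrying at least `min_pair` samples, the subgrouping being the union of
#' the two branch sample sets. With `expanded = TRUE` the search additionally
#' emits three-branch combinations with at least `min_triple` samples per
#' branch and `min_triple_total` samples in total.
#'
#' Subgroupings whose sample set equals the gene-wide mutant set are
#' discarded as equivalent to the gene-wide task, and subgroupings with
#' identical sample sets within the tree are deduplicated, keeping the
#' shallowest description. Nested branch pairs (ancestor plus descendant)
#' are never emitted since their union equals the ancestor branch. Pair
#' unions must reach `2 * min_pair` samples so every emitted subgrouping has
#' at least twenty samples under the default thresholds even when branches
#' overlap through samples carrying several variants.
#'
#' @param tree A [build_mutation_tree()] result.
#' @param min_single Minimum samples for a single-branch subgrouping (20).
#' @param min_pair Minimum samples per branch for a pair (10).
#' @param expanded Also emit three-branch subgroupings (off by default).
#' @param min_triple,min_triple_total Per-branch and total minimum sizes for
#'   the expanded three-branch search (5 and 20).
#' @return Subgrouping tibble: `gene`, `hierarchy`, `provenance` (`"tree"`),
#'   `description`, `branches` (list of branch paths), `samples` (list),
#'   `n_samples`. Attributes `n_discarded_genewide` and `n_below_threshold`
#'   report how many candidates were dropped.
#' @export
enumerate_subgroupings <- function(tree, min_single = 20, min_pair = 10,
                                   expanded = FALSE, min_triple = 5,
                                   min_triple_total = 20) {
  stopifnot(inherits(tree, "mutation_tree"), min_single >= 1, min_pair >= 1)
  gene <- attr(tree, "gene")
  hierarchy <- attr(tree, "hierarchy_name")
  root <- attr(tree, "root_samples")
  n_below <- 0L
  n_genewide <- 0L
  out <- list()

  if (nrow(tree) > 0) {
    singles <- tree[tree$n_samples >= min_single, ]
    n_below <- n_below + sum(tree$n_samples < min_single)
    if (nrow(singles) > 0) {
      out <- c(out, pmap(list(singles$path, singles$description, singles$samples),
                         function(p, d, s) list(branches = p, description = d, samples = s)))
    }
    pair_pool <- tree[tree$n_samples >= min_pair, ]
    if (nrow(pair_pool) >= 2) {
      idx <- combn(nrow(pair_pool), 2)
      for (j in seq_len(ncol(idx))) {
        a <- idx[1, j]; b <- idx[2, j]
        if (paths_nested(pair_pool$path[a], pair_pool$path[b])) next
        u <- union(pair_pool$samples[[a]], pair_pool$samples[[b]])
        if (length(u) < 2 * min_pair) { n_below <- n_below + 1L; next }
        out <- c(out, list(list(
          branches = c(pair_pool$path[a], pair_pool$path[b]),
          description = paste(pair_pool$description[a], pair_pool$description[b],
                              sep = " OR "),
          samples = sort(u))))
      }
    }
    if (expanded) {
      tri_pool <- tree[tree$n_samples >= min_triple, ]
      if (nrow(tri_pool) >= 3) {
        idx <- combn(nrow(tri_pool), 3)
        for (j in seq_len(ncol(idx))) {
          ii <- idx[, j]
          ps <- tri_pool$path[ii]
          if (paths_nested(ps[1], ps[2]) || paths_nested(ps[1], ps[3]) ||
              paths_nested(ps[2], ps[3])) next
          u <- Reduce(union, tri_pool$samples[ii])
          if (length(u) < min_triple_total) { n_below <- n_below + 1L; next }
          out <- c(out, list(list(
            branches = ps,
            description = paste(tri_pool$description[ii], collapse = " OR "),
            samples = sort(u))))
        }
      }
    }
  }

  if (length(out) == 0) {
    res <- empty_subgroupings()
  } else {
    res <- tibble(
      gene = gene, hierarchy = hierarchy, provenance = "tree",
      description = map_chr(out, "description"),
      branches = map(out, "branches"),
      samples = map(out, "samples"),
      n_samples = map_int(out, ~ length(.x$samples))
    )
    genewide <- map_lgl(res$samples, ~ setequal(.x, root))
    n_genewide <- sum(genewide)
    res <- res[!genewide, ]
    res <- dedupe_within_tree(res)
  }
  structure(res,
            n_discarded_genewide = n_genewide,
            n_below_threshold = n_below)
}

# Keep one subgrouping per distinct sample set inside a tree: fewest
# branches, then shallowest (fewest path levels), then lexicographic.
dedupe_within_tree <- function(res) {
  if (nrow(res) == 0) return(res)
  key <- map_chr(res$samples, ~ as.character(sample_set_key(.x)))
  depth <- map_int(res$branches, ~ sum(lengths(strsplit(.x, ":", fixed = TRUE))))
  ord <- order(lengths(res$branches), depth, res$description)
  res <- res[ord, ]
  res[!duplicated(key[ord]), ]
}

#' Flag duplicate sample sets across hierarchies
#'
#' Subgroupings built from different property hierarchies of the same gene
#' can resolve to identical mutated-sample sets. All are retained in the
#' catalogue, but duplicates are flagged as aliases of a canonical
#' description so evaluation runs once per distinct sample set.
#'
#' @param catalogue Subgrouping tibble (rows from one or more hierarchies).
#' @return The catalogue with columns `set_id` (stable key of the sample
#'   set) and `alias_of` (`NA` for the canonical row of each set).
#' @export
dedupe_subgroupings <- function(catalogue) {
  if (nrow(catalogue) == 0) {
    return(mutate(catalogue, set_id = integer(), alias_of = character()))
  }
  catalogue %>%
    mutate(set_id = map_int(samples, sample_set_key),
           .n_branches = lengths(.data$branches),
           .depth = map_int(.data$branches, ~ sum(lengths(
             strsplit(.x, ":", fixed = TRUE))))) %>%
    group_by(.data$gene, .data$set_id) %>%
    arrange(.data$.n_branches, .data$.depth, nchar(.data$description),
            .data$description, .by_group = TRUE) %>%
    mutate(alias_of = if (n() == 1) NA_character_ else
      c(NA_character_, rep(description[[1]], n() - 1))) %>%
    ungroup() %>%
    select(-".n_branches", -".depth")
}

#' Augment subgroupings with deep copy-number alterations
#'
#' For each input subgrouping, forms up to two new subgroupings by adding
#' the samples carrying deep amplifications (discretised call +2) of the
#' same gene, and the samples carrying deep deletions (-2). An augmented
#' subgrouping is emitted only when at least `min_extra` samples carry the
#' alteration and are not already in the subgrouping. Genes with at least
#' `min_standalone` deep amplifications (or deletions) also yield a
#' standalone CNA-only subgrouping.
#'
#' @param subgroupings Subgrouping tibble.
#' @param cna Tidy copy-number calls: columns `sample_id`, `gene`, `cna`
#'   with integer values in `-2..2` (GISTIC-style discretisation).
#' @param min_extra Minimum novel CNA carriers to augment (5).
#' @param min_standalone Minimum carriers for a CNA-only subgrouping (20).
#' @return The input rows plus the new `cna_augmented` / `cna_only` rows.
#' @export
augment_with_cnas <- function(subgroupings, cna, min_extra = 5, min_standalone = 20) {
  stopifnot(all(c("sample_id", "gene", "cna") %in% names(cna)))
  if (!all(cna$cna %in% -2:2)) {
    abort_input("copy-number calls must be discretised integers in -2..2")
  }
  new_rows <- list()
  for (i in seq_len(nrow(subgroupings))) {
    row <- subgroupings[i, ]
    for (kind in c("amp", "del")) {
      call_value <- if (kind == "amp") 2L else -2L
      carriers <- cna$sample_id[cna$gene == row$gene & cna$cna == call_value]
      extra <- setdiff(carriers, row$samples[[1]])
      if (length(extra) >= min_extra) {
        u <- sort(union(row$samples[[1]], carriers))
        new_rows <- c(new_rows, list(
          row %>% mutate(
            provenance = "cna_augmented",
            description = paste0(description, " OR deep_", kind),
            samples = list(u), n_samples = length(u))))
      }
    }
  }
  for (g in unique(subgroupings$gene)) {
    for (kind in c("amp", "del")) {
      call_value <- if (kind == "amp") 2L else -2L
      carriers <- sort(unique(cna$sample_id[cna$gene == g & cna$cna == call_value]))
      if (length(carriers) >= min_standalone) {
        new_rows <- c(new_rows, list(tibble(
          gene = g, hierarchy = NA_character_, provenance = "cna_only",
          description = paste0("deep_", kind),
          branches = list(character()), samples = list(carriers),
          n_samples = length(carriers))))
      }
    }
  }
  bind_rows(subgroupings, bind_rows(new_rows))
}

#' Subgroupings from variant deleteriousness score thresholds
#'
#' Sweeps over the distinct PolyPhen or SIFT scores observed among a gene's
#' variants and emits the subgrouping of samples carrying a variant passing
#' each threshold. PolyPhen thresholds are applied in the damaging
#' direction (score `>= v`), SIFT thresholds in the tolerated-to-damaging
#' direction (score `<= v`). Each distinct sample set of at least
#' `min_samples` samples is emitted once; the set equal to the gene-wide
#' mutant set is discarded. The emitted sets are totally ordered by
#' inclusion by construction.
#'
#' @param variants Variant tibble for a single gene.
#' @param metric `"polyphen"` or `"sift"`.
#' @param min_samples Minimum subgrouping size (20).
#' @return Subgrouping tibble with provenance `"polyphen"`/`"sift"`; empty
#'   when no variant carries the metric.
#' @export
threshold_subgroupings <- function(variants, metric = c("polyphen", "sift"),
                                   min_samples = 20) {
  metric <- arg_match(metric)
  gene <- unique(variants$gene)
  if (length(gene) > 1) {
    abort_input("threshold_subgroupings() expects variants of a single gene")
  }
  scores <- variants[[metric]]
  if (all(is.na(scores))) return(empty_subgroupings())
  root <- sort(unique(variants$sample_id))
  observed <- sort(unique(scores[!is.na(scores)]))
  op_label <- if (metric == "polyphen") ">=" else "<="
  rows <- list()
  seen <- character()
  for (v in observed) {
    pass <- if (metric == "polyphen") !is.na(scores) & scores >= v
            else !is.na(scores) & scores <= v
    set <- sort(unique(variants$sample_id[pass]))
    if (length(set) < min_samples || setequal(set, root)) next
    key <- as.character(sample_set_key(set))
    if (key %in% seen) next
    seen <- c(seen, key)
    rows <- c(rows, list(tibble(
      gene = gene, hierarchy = NA_character_, provenance = metric,
      description = paste0(metric, op_label, format(v)),
      branches = list(character()), samples = list(set),
      n_samples = length(set))))
  }
  if (length(rows) == 0) empty_subgroupings() else bind_rows(rows)
}

#' Read discretised copy-number calls
#'
#' Reads a genes x samples matrix of GISTIC-style discretised calls
#' (integers in `-2..2`; -2 deep deletion, +2 deep amplification) and
#' returns it in the tidy form [augment_with_cnas()] consumes.
#'
#' @param path TSV file; first column gene symbols, remaining columns one
#'   per sample.
#' @return Tibble with columns `sample_id`, `gene`, `cna`.
#' @export
read_cna_calls <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_integer()), progress = FALSE)
  names(raw)[1] <- "gene"
  out <- tidyr::pivot_longer(raw, -"gene", names_to = "sample_id",
                             values_to = "cna")
  if (!all(out$cna %in% -2:2 | is.na(out$cna))) {
    abort_input("copy-number calls must be discretised integers in -2..2")
  }
  select(filter(out, !is.na(.data$cna)), "sample_id", "gene", "cna")
}

#' Write a subgrouping catalogue to TSV
#'
#' @param catalogue Subgrouping tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_subgrouping_catalogue <- function(catalogue, path) {
  catalogue %>%
    mutate(n_mutated = .data$n_samples) %>%
    select("gene", "hierarchy", "provenance", "description", "n_mutated") %>%
    readr::write_tsv(path)
  invisible(path)
}
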