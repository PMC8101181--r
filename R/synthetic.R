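# Synthetic cohorts with known ground truth. The generative model is the
# minimal one under which a linear classifier is well specified: a
# standard-normal expression background plus, for each planted mutation
# branch, an additive shift delta * v applied to its member samples, where
# v is a unit effect vector supported on a dedicated feature block.
# Distinct program ids occupy disjoint feature blocks, so distinct programs
# are exactly orthogonal; sharing a program id shares the direction, and a
# negative delta plants the anti-correlated direction.

#' Configure a synthetic cohort
#'
#' @param n_samples,n_features Cohort dimensions.
#' @param branches Mutation plan: tibble with one row per planted branch.
#'   Required columns `gene`, `n_samples`, `delta`; optional hierarchy
#'   attribute columns `exon`, `aa_location`, `aa_substitution`,
#'   `consequence`, `smart_domain`, `pfam_domain` (defaults are generated),
#'   and `program` (shared program id; `NA` for branches with no expression
#'   program, e.g. `delta = 0`).
#' @param program_size Features per expression program block (50).
#' @param noise_sd Background standard deviation (1).
#' @param seed Integer seed; the whole cohort is reproducible under it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples, n_features, branches = NULL,
                              program_size = 50, noise_sd = 1, seed = 1) {
  branches <- fill_branch_defaults(branches)
  if (sum(branches$n_samples) > n_samples) {
    abort_config("planted branch sample counts exceed the cohort size")
  }
  programs <- unique(branches$program[!is.na(branches$program) & branches$delta != 0])
  if (length(programs) * program_size > n_features) {
    abort_config("not enough features for the requested expression programs")
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 branches = branches, program_size = program_size,
                 noise_sd = noise_sd, seed = seed),
            class = "simulation_config")
}

fill_branch_defaults <- function(branches) {
  if (is.null(branches) || nrow(branches) == 0) {
    return(tibble(gene = character(), n_samples = integer(), delta = numeric(),
                  program = character(), exon = character(),
                  aa_location = character(), aa_substitution = character(),
                  consequence = character(), smart_domain = character(),
                  pfam_domain = character()))
  }
  branches <- as_tibble(branches)
  stopifnot(all(c("gene", "n_samples", "delta") %in% names(branches)))
  n <- nrow(branches)
  defaults <- list(
    program = rep(NA_character_, n),
    exon = as.character(seq_len(n)),
    aa_location = as.character(100 * seq_len(n)),
    consequence = rep("missense", n),
    smart_domain = rep(NO_DOMAIN, n),
    pfam_domain = rep(NO_DOMAIN, n))
  for (col in names(defaults)) {
    if (!col %in% names(branches)) branches[[col]] <- defaults[[col]]
  }
  if (!"aa_substitution" %in% names(branches)) {
    branches$aa_substitution <- paste0("A", branches$aa_location, "V")
  }
  branches
}

#' Generate a synthetic expression cohort with planted mutation programs
#'
#' Draws a standard-normal expression background, adds `delta * v` to the
#' members of each planted branch (v the branch program's unit effect
#' vector), and emits the matching variant table and a truth record of
#' memberships, effect vectors and sizes. Branch sample sets are disjoint.
#' Planted genes are placed on reserved chromosomes with their own (pure
#' background) expression feature, and program feature blocks live on other
#' chromosomes, so the per-task chromosome mask never removes planted
#' signal.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (an `expression_cohort` on the prepared
#'   z-like scale), `variants` (tibble in the standard variant dialect),
#'   `truth` (branch memberships, program features and effect vectors) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(derive_seed(config$seed, "generate_cohort"), {
    n <- config$n_samples; p <- config$n_features
    samples <- sprintf("S%04d", seq_len(n))
    branches <- config$branches
    genes <- unique(branches$gene)
    gene_chrs <- as.character(rev(seq_len(22)))[seq_along(genes)]
    bg_chrs <- setdiff(as.character(seq_len(22)), gene_chrs)

    features <- sprintf("F%04d", seq_len(p))
    if (length(genes) > 0) {
      # planted genes take over the last features so dimensions stay p
      features[p - seq_along(genes) + 1] <- genes
    }
    chromosome <- rep_len(bg_chrs, p)
    if (length(genes) > 0) {
      chromosome[p - seq_along(genes) + 1] <- gene_chrs
    }
    annotation <- tibble(gene = features, chromosome = chromosome,
                         biotype = "protein_coding")

    expr <- matrix(rnorm(n * p, sd = config$noise_sd), n, p,
                   dimnames = list(samples, features))

    program_ids <- unique(branches$program[!is.na(branches$program)])
    programs <- list()
    next_feat <- 1L
    for (pid in program_ids) {
      block <- features[next_feat:(next_feat + config$program_size - 1)]
      next_feat <- next_feat + config$program_size
      v <- sample(c(-1, 1), config$program_size, replace = TRUE) /
        sqrt(config$program_size)
      programs[[pid]] <- list(features = block, v = setNames(v, block))
    }

    pool <- sample(samples)
    memberships <- vector("list", nrow(branches))
    taken <- 0L
    for (b in seq_len(nrow(branches))) {
      k <- branches$n_samples[b]
      memberships[[b]] <- sort(pool[(taken + 1):(taken + k)])
      taken <- taken + k
      pid <- branches$program[b]
      if (!is.na(pid) && branches$delta[b] != 0) {
        prog <- programs[[pid]]
        expr[memberships[[b]], prog$features] <-
          expr[memberships[[b]], prog$features] +
          branches$delta[b] * matrix(prog$v, length(memberships[[b]]),
                                     config$program_size, byrow = TRUE)
      }
    }

    variants <- purrr::map_dfr(seq_len(nrow(branches)), function(b) {
      tibble(sample_id = memberships[[b]],
             gene = branches$gene[b],
             exon = branches$exon[b],
             aa_location = branches$aa_location[b],
             aa_substitution = branches$aa_substitution[b],
             consequence = branches$consequence[b],
             smart_domain = branches$smart_domain[b],
             pfam_domain = branches$pfam_domain[b],
             polyphen = NA_real_, sift = NA_real_)
    })

    truth <- list(
      branches = mutate(branches, samples = memberships),
      programs = programs,
      gene_chromosomes = setNames(gene_chrs, genes))

    list(cohort = as_expression_cohort(expr, annotation),
         variants = variants, truth = truth, config = config)
  })
}

#' Worked-example decomposition fixture
#'
#' A 1017-sample cohort shell with 488 samples carrying a point mutation of
#' PIK3CA, whose exon- and codon-level branch sizes equal the worked
#' example used throughout the documentation: 248 mutants on exon 21 (226
#' of them at codon 1047), 177 on exon 10 (109 at codon 545, 56 at codon
#' 542) and 45 on exon 5 (40 at codon 345). Remainders not pinned by those
#' figures are filled with filler branches on other exons so the level
#' totals stay consistent. A small deterministic background expression
#' cohort is attached so tasks can be constructed directly.
#'
#' @param n_background_features Features in the attached cohort shell (25).
#' @return List with `variants`, `samples` (1017 ids), `gene` and `cohort`.
#' @export
#' @examples
#' fx <- pik3ca_fixture()
#' sum(fx$variants$exon == "21")
pik3ca_fixture <- function(n_background_features = 25) {
  plan <- tibble(
    exon = c("21", "21", "10", "10", "10", "5", "5", "14", "3"),
    aa_location = c("1047", "984", "545", "542", "538", "345", "340", "800", "170"),
    aa_substitution = c("H1047R", "A984T", "E545K", "E542K", "Q538E",
                        "C345S", "E340K", "K800N", "R170W"),
    n = c(226L, 22L, 109L, 56L, 12L, 40L, 5L, 10L, 8L))
  stopifnot(sum(plan$n) == 488L)
  samples <- sprintf("S%04d", seq_len(1017))
  starts <- cumsum(c(0L, plan$n[-nrow(plan)]))
  variants <- purrr::map_dfr(seq_len(nrow(plan)), function(b) {
    tibble(sample_id = samples[(starts[b] + 1):(starts[b] + plan$n[b])],
           gene = "PIK3CA",
           exon = plan$exon[b],
           aa_location = plan$aa_location[b],
           aa_substitution = plan$aa_substitution[b],
           consequence = "missense",
           smart_domain = NO_DOMAIN, pfam_domain = NO_DOMAIN,
           polyphen = NA_real_, sift = NA_real_)
  })
  expr <- withr::with_seed(20211017, {
    p <- n_background_features
    m <- matrix(rnorm(1017 * p), 1017, p,
                dimnames = list(samples, c(sprintf("F%03d", seq_len(p - 1)), "PIK3CA")))
    m
  })
  annotation <- tibble(gene = colnames(expr),
                       chromosome = c(rep_len(as.character(1:2), n_background_features - 1), "3"),
                       biotype = "protein_coding")
  list(variants = variants, samples = samples, gene = "PIK3CA",
       cohort = as_expression_cohort(expr, annotation))
}

#' Canned simulation scenarios with qualitatively distinct ground truths
#'
#' Named cohort configurations covering the qualitative regimes a
#' subgrouping analysis must distinguish:
#'
#' * `homogeneous` — all branches of the gene drive one shared expression
#'   program, so no subgrouping should diverge from the gene-wide task;
#' * `active_inactive` — one branch drives a program, the other is inert,
#'   so the active subgrouping should be cv-significant over the gene-wide
#'   task;
#' * `orthogonal` — two branches drive orthogonal programs, so their
#'   subgrouping classifiers should score samples independently;
#' * `graded` — branch effect sizes are ordered (full, half, none);
#' * `null` — no expression program at all; every AUC should sit near 0.5.
#'
#' The default effect size was calibrated once so that a 50-mutant active
#' subgrouping reaches a task AUC near 0.9 at the default cohort size.
#'
#' @param seed Integer seed.
#' @param n_samples,n_features Cohort dimensions (500 x 1000; 20% of the
#'   samples are mutants of the planted gene).
#' @param effect_size Calibrated planted effect delta.
#' @return Named list of `simulation_config`s.
#' @export
generate_scenarios <- function(seed = 1, n_samples = 500, n_features = 1000,
                               effect_size = 4.5) {
  gene <- "GENE1"
  branch <- function(exon, n, delta, program = NA_character_) {
    tibble(gene = gene, exon = exon, aa_location = paste0(exon, "00"),
           aa_substitution = paste0("A", exon, "00V"), n_samples = n,
           delta = delta, program = program)
  }
  list(
    homogeneous = simulation_config(
      n_samples, n_features,
      bind_rows(branch("1", 40, effect_size, "P1"),
                branch("2", 35, effect_size, "P1"),
                branch("3", 25, effect_size, "P1")),
      seed = derive_seed(seed, "homogeneous")),
    active_inactive = simulation_config(
      n_samples, n_features,
      bind_rows(branch("1", 50, effect_size, "P1"),
                branch("2", 50, 0)),
      seed = derive_seed(seed, "active_inactive")),
    orthogonal = simulation_config(
      n_samples, n_features,
      bind_rows(branch("1", 50, effect_size, "P1"),
                branch("2", 50, effect_size, "P2")),
      seed = derive_seed(seed, "orthogonal")),
    graded = simulation_config(
      n_samples, n_features,
      bind_rows(branch("1", 40, effect_size, "P1"),
                branch("2", 30, effect_size / 2, "P1"),
                branch("3", 30, 0)),
      seed = derive_seed(seed, "graded")),
    null = simulation_config(
      n_samples, n_features,
      bind_rows(branch("1", 50, 0), branch("2", 50, 0)),
      seed = derive_seed(seed, "null"))
  )
}
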