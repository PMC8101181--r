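test_that("mutation tree recovers the worked-example branch sizes", {
  fx <- pik3ca_fixture()
  tree <- build_mutation_tree(fx$variants, "exon_location_substitution")

  exon_counts <- setNames(tree$n_samples[tree$level == 1], tree$path[tree$level == 1])
  expect_equal(unname(exon_counts[c("21", "10", "5")]), c(248L, 177L, 45L))
  expect_equal(tree$n_samples[tree$path == "21:1047"], 226L)
  expect_equal(tree$n_samples[tree$path == "10:545"], 109L)
  expect_length(attr(tree, "root_samples"), 488L)
})

test_that("tree nodes nest: children are subsets of parents, root covers all", {
  vars <- toy_variants("TG1", list(
    list(exon = "1", aa_location = "10", n = 8),
    list(exon = "1", aa_location = "20", n = 5),
    list(exon = "2", aa_location = "30", n = 7)))
  # one sample carries variants on two branches
  vars <- dplyr::bind_rows(vars, dplyr::mutate(vars[1, ], exon = "2", aa_location = "30"))
  tree <- build_mutation_tree(vars, "exon_location_substitution")
  for (i in which(tree$level > 1)) {
    parent_path <- sub(":[^:]*$", "", tree$path[i])
    parent <- which(tree$path == parent_path)
    expect_true(all(tree$samples[[i]] %in% tree$samples[[parent]]))
    expect_lte(tree$n_samples[i], tree$n_samples[parent])
  }
  expect_setequal(unique(unlist(tree$samples[tree$level == 1])),
                  attr(tree, "root_samples"))
  # the double-branch sample is counted once per node
  expect_equal(sum(tree$n_samples[tree$level == 1]), 8 + 5 + 7 + 1)
})

test_that("empty variant list yields an empty tree", {
  tree <- build_mutation_tree(toy_variants("TG1", list(list(exon = "1", n = 1)))[0, ])
  expect_equal(nrow(tree), 0L)
  expect_length(attr(tree, "root_samples"), 0L)
})

test_that("unknown hierarchy property is a configuration error", {
  vars <- toy_variants("TG1", list(list(exon = "1", n = 3)))
  expect_error(build_mutation_tree(vars, c("exon", "nonexistent_property")),
               class = "mutsubsig_config_error")
})

test_that("enumeration drops gene-wide-equivalent and under-sized branches", {
  # single branch holding all mutants -> nothing
  vars <- toy_variants("TG1", list(list(exon = "1", n = 30)))
  tree <- build_mutation_tree(vars, "exon_location_substitution")
  sg <- enumerate_subgroupings(tree)
  expect_equal(nrow(sg), 0L)
  expect_gte(attr(sg, "n_discarded_genewide"), 1L)

  # 19-sample branch below the single threshold, nothing else >= 10
  vars <- toy_variants("TG1", list(list(exon = "1", n = 19),
                                   list(exon = "2", n = 5)))
  sg <- enumerate_subgroupings(build_mutation_tree(vars))
  expect_equal(nrow(sg), 0L)
})

test_that("two disjoint branches of 12 and 15 yield exactly one pair subgrouping", {
  vars <- toy_variants("TG1", list(list(exon = "1", n = 12),
                                   list(exon = "2", n = 15),
                                   list(exon = "3", n = 13)))
  tree <- build_mutation_tree(vars)
  sg <- enumerate_subgroupings(tree, min_single = 20, min_pair = 10)
  # no single branch reaches 20; pairs of the three branches qualify
  expect_true(all(lengths(sg$branches) == 2))
  pair_12_15 <- sg[sg$n_samples == 27, ]
  expect_equal(nrow(pair_12_15), 1L)
  expect_setequal(
    pair_12_15$samples[[1]],
    union(tree$samples[[which(tree$path == "1" & tree$level == 1)]],
          tree$samples[[which(tree$path == "2" & tree$level == 1)]]))
})

test_that("enumeration matches the brute-force subset oracle on random trees", {
  for (seed in 1:6) {
    vars <- withr::with_seed(seed, {
      n_branch <- sample(3:5, 1)
      toy_variants("TG1", lapply(seq_len(n_branch), function(i) list(
        exon = as.character(sample(3, 1)),
        aa_location = as.character(10 * i),
        n = sample(5:30, 1))))
    })
    tree <- build_mutation_tree(vars, "exon_location_substitution")
    for (expanded in c(FALSE, TRUE)) {
      sg <- enumerate_subgroupings(tree, min_single = 20, min_pair = 10,
                                   expanded = expanded)
      expect_identical(subgrouping_keys(sg),
                       oracle_enumerate(tree, expanded = expanded),
                       info = paste("seed", seed, "expanded", expanded))
    }
  }
})

test_that("every emitted subgrouping has >= 20 samples and is not gene-wide", {
  fx <- pik3ca_fixture()
  for (h in names(hierarchy_specs())) {
    tree <- build_mutation_tree(fx$variants, h)
    sg <- enumerate_subgroupings(tree)
    if (nrow(sg) == 0) next
    expect_true(all(sg$n_samples >= 20))
    expect_false(any(vapply(sg$samples, setequal, logical(1),
                            attr(tree, "root_samples"))))
  }
})

test_that("nested branch pairs are never emitted", {
  fx <- pik3ca_fixture()
  tree <- build_mutation_tree(fx$variants, "exon_location_substitution")
  sg <- enumerate_subgroupings(tree)
  pairs <- sg[lengths(sg$branches) == 2, ]
  for (b in pairs$branches) {
    expect_false(startsWith(b[2], paste0(b[1], ":")))
    expect_false(startsWith(b[1], paste0(b[2], ":")))
  }
})

test_that("duplicate sample sets across hierarchies are alias-flagged", {
  # one branch: exon 1 == consequence missense == same sample set
  vars <- toy_variants("TG1", list(list(exon = "1", n = 25),
                                   list(exon = "2", n = 25, consequence = "stop_gained")))
  cat1 <- enumerate_subgroupings(build_mutation_tree(vars, "exon_location_substitution"))
  cat2 <- enumerate_subgroupings(build_mutation_tree(vars, "consequence_exon"))
  deduped <- dedupe_subgroupings(dplyr::bind_rows(cat1, cat2))
  expect_true(any(!is.na(deduped$alias_of)))
  # one canonical row per distinct set
  canon <- deduped[is.na(deduped$alias_of), ]
  expect_equal(anyDuplicated(canon$set_id), 0L)
  # aliases point at a canonical description of the same set
  for (i in which(!is.na(deduped$alias_of))) {
    target <- canon[canon$set_id == deduped$set_id[i], ]
    expect_equal(deduped$alias_of[i], target$description)
  }
})

test_that("CNA augmentation follows the set arithmetic and thresholds", {
  vars <- toy_variants("TG1", list(list(exon = "1", n = 20),
                                   list(exon = "2", n = 10)))
  sg <- enumerate_subgroupings(build_mutation_tree(vars), min_single = 10,
                               min_pair = 30)
  sg <- sg[sg$n_samples == 20, ]
  expect_equal(nrow(sg), 1L)
  amp <- sprintf("AMP%02d", 1:6)
  del <- sprintf("DEL%02d", 1:25)
  cna <- dplyr::bind_rows(
    tibble::tibble(sample_id = amp, gene = "TG1", cna = 2L),
    tibble::tibble(sample_id = del, gene = "TG1", cna = -2L))
  out <- augment_with_cnas(sg, cna)
  expect_equal(nrow(out), 1 + 2 + 1) # original + amp-augmented + del-augmented + del-only
  aug <- out[out$provenance == "cna_augmented", ]
  expect_setequal(aug$n_samples, c(26L, 45L))
  only <- out[out$provenance == "cna_only", ]
  expect_equal(only$n_samples, 25L)
  expect_setequal(only$samples[[1]], del)

  # fewer than five novel deep deletions -> no deletion-augmented subgrouping
  out2 <- augment_with_cnas(sg, cna[cna$cna == -2, ][1:4, ])
  expect_equal(nrow(out2), nrow(sg))

  # no CNAs at all -> unchanged
  out3 <- augment_with_cnas(sg, cna[0, ])
  expect_equal(nrow(out3), nrow(sg))

  expect_error(augment_with_cnas(sg, tibble::tibble(
    sample_id = "s", gene = "TG1", cna = 3L)), class = "mutsubsig_input_error")
})

test_that("score-threshold subgroupings sweep observed values directionally", {
  # PolyPhen 0.1 x10, 0.5 x15, 0.99 x20: sets of 45 (gene-wide), 35, 20
  vars <- toy_variants("TG1", list(
    list(exon = "1", n = 10, polyphen = 0.1),
    list(exon = "2", n = 15, polyphen = 0.5),
    list(exon = "3", n = 20, polyphen = 0.99)))
  sg <- threshold_subgroupings(vars, "polyphen", min_samples = 20)
  expect_equal(sort(sg$n_samples), c(20L, 35L))
  expect_true(all(grepl("polyphen>=", sg$description)))

  # single shared score -> set equals gene-wide -> empty
  vars1 <- toy_variants("TG1", list(list(exon = "1", n = 30, polyphen = 0.7)))
  expect_equal(nrow(threshold_subgroupings(vars1, "polyphen")), 0L)

  # SIFT thresholds run in the opposite direction
  vars2 <- toy_variants("TG1", list(
    list(exon = "1", n = 25, sift = 0.01),
    list(exon = "2", n = 25, sift = 0.8)))
  sg2 <- threshold_subgroupings(vars2, "sift", min_samples = 20)
  expect_equal(sg2$n_samples, 25L)
  expect_true(grepl("sift<=0.01", sg2$description))

  # metric absent everywhere -> empty
  expect_equal(nrow(threshold_subgroupings(
    toy_variants("TG1", list(list(exon = "1", n = 30))), "polyphen")), 0L)
})

test_that("threshold subgroupings of one metric are totally ordered by inclusion", {
  vars <- withr::with_seed(9, toy_variants("TG1", lapply(1:6, function(i) list(
    exon = as.character(i), n = sample(8:20, 1),
    polyphen = round(stats::runif(1), 2)))))
  sg <- threshold_subgroupings(vars, "polyphen", min_samples = 10)
  if (nrow(sg) >= 2) {
    sets <- sg$samples[order(sg$n_samples)]
    for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i]] %in% sets[[i + 1]]))
    }
  }
})

test_that("variant reader parses the annotation dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    Sample = c("s1", "s2", "s3"),
    Gene = "TG1",
    Exon = c("5/23", "21/21", "."),
    Protein_position = c("345/1068", "1047/1068", "."),
    Amino_acids = c("C/S", "H/R", "."),
    Consequence = c("missense", "missense", "splice_acceptor"),
    DOMAINS = c("SMART:SM00219,Pfam:PF07714", ".", "Pfam:PF00001"),
    PolyPhen = c("probably_damaging(0.967)", "0.41", "."),
    SIFT = c(".", "deleterious(0.02)", ".")), path)
  v <- read_variants(path)
  expect_equal(v$exon, c("5", "21", "."))
  expect_equal(v$aa_substitution, c("C345S", "H1047R", "."))
  expect_equal(v$smart_domain, c("SM00219", "no overlapping domain",
                                 "no overlapping domain"))
  expect_equal(v$pfam_domain, c("PF07714", "no overlapping domain", "PF00001"))
  expect_equal(v$polyphen, c(0.967, 0.41, NA))
  expect_equal(v$sift, c(NA, 0.02, NA))

  readr::write_tsv(tibble::tibble(Sample = "s", Gene = "g"), path)
  expect_error(read_variants(path), "missing required columns")

  shipped <- read_variants(system.file("extdata", "example_variants.tsv",
                                       package = "mutsubsig"))
  expect_equal(nrow(shipped), 8L)
  expect_equal(shipped$aa_substitution[1], "H1047R")
  expect_equal(shipped$exon[6], ".")
  expect_equal(shipped$smart_domain[8], "SM00401")
})

test_that("CNA matrix reader produces tidy in-range calls", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- tibble::tibble(Gene = c("TG1", "TG2"),
                      s1 = c(2L, 0L), s2 = c(-2L, NA), s3 = c(0L, 1L))
  readr::write_tsv(m, path)
  cna <- read_cna_calls(path)
  expect_named(cna, c("sample_id", "gene", "cna"))
  expect_equal(nrow(cna), 5L) # NA dropped
  expect_equal(cna$cna[cna$gene == "TG1" & cna$sample_id == "s2"], -2L)

  readr::write_tsv(tibble::tibble(Gene = "TG1", s1 = 3L), path)
  expect_error(read_cna_calls(path), class = "mutsubsig_input_error")
})

test_that("catalogue writer emits the expected columns", {
  fx <- pik3ca_fixture()
  sg <- enumerate_subgroupings(build_mutation_tree(fx$variants))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subgrouping_catalogue(sg, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(tab, c("gene", "hierarchy", "provenance", "description", "n_mutated"))
  expect_equal(nrow(tab), nrow(sg))
})
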