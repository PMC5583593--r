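test_that("cohort simulation is deterministic and honors degenerate probs", {
  cfg <- cohort_config(n_genomes = 15, n_taxa = 3, seed = 41)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  n_gh <- length(unique(default_gh_map()$gh_class))
  n_gene <- length(all_pathway_genes())
  ones <- cohort_config(
    n_genomes = 5, n_taxa = 2,
    gh_prob = matrix(1, 2, n_gh,
                     dimnames = list(NULL, unique(default_gh_map()$gh_class))),
    gene_prob = matrix(1, 2, n_gene,
                       dimnames = list(NULL, all_pathway_genes())),
    transporter_prob = 1, seed = 1)
  for (p in simulate_cohort(ones)) {
    expect_length(p$gh_classes, n_gh)
    expect_length(p$genes, n_gene)
  }
  zeros <- cohort_config(
    n_genomes = 5, n_taxa = 2,
    gh_prob = matrix(0, 2, n_gh,
                     dimnames = list(NULL, unique(default_gh_map()$gh_class))),
    gene_prob = matrix(0, 2, n_gene,
                       dimnames = list(NULL, all_pathway_genes())),
    transporter_prob = 0, seed = 1)
  for (p in simulate_cohort(zeros)) {
    expect_length(p$gh_classes, 0L)
    expect_length(p$genes, 0L)
    expect_length(p$transporters, 0L)
  }
  expect_error(cohort_config(n_genomes = 5, n_taxa = 2,
                             gh_prob = matrix(1.5, 2, n_gh)),
               "\\[0, 1\\]")
})

test_that("genomes are assigned round-robin to taxon blocks", {
  cohort <- simulate_cohort(cohort_config(n_genomes = 7, n_taxa = 3,
                                          seed = 2))
  taxa <- vapply(cohort, function(p) p$lineage[1], character(1))
  expect_equal(unname(taxa[1:6]),
               rep(paste0("taxon_", 1:3), 2))
  expect_equal(unname(table(taxa)[paste0("taxon_", 1:3)]), c(3L, 2L, 2L),
               ignore_attr = TRUE)
})

test_that("zero dependence leaves GH and CP features uncorrelated", {
  n_gh <- length(unique(default_gh_map()$gh_class))
  n_gene <- length(all_pathway_genes())
  cfg <- cohort_config(
    n_genomes = 2000, n_taxa = 1,
    gh_prob = matrix(0.5, 1, n_gh,
                     dimnames = list(NULL, unique(default_gh_map()$gh_class))),
    gene_prob = matrix(0.5, 1, n_gene,
                       dimnames = list(NULL, all_pathway_genes())),
    gh_cp_dependence = 0, seed = 43)
  cohort <- simulate_cohort(cfg)
  has <- function(feature, slot) {
    vapply(cohort, function(p) feature %in% p[[slot]], logical(1))
  }
  pairs <- list(c("alpha-L-fucosidase", "fucI"),
                c("neuraminidase", "nanA"),
                c("beta-galactosidase", "galK"))
  for (fp in pairs) {
    r <- stats::cor(has(fp[1], "gh_classes"), has(fp[2], "genes"))
    expect_lt(abs(r), 0.05)
  }
})

test_that("positive dependence couples same-sugar GH and CP features", {
  n_gh <- length(unique(default_gh_map()$gh_class))
  n_gene <- length(all_pathway_genes())
  cfg <- cohort_config(
    n_genomes = 2000, n_taxa = 1,
    gh_prob = matrix(0.5, 1, n_gh,
                     dimnames = list(NULL, unique(default_gh_map()$gh_class))),
    gene_prob = matrix(0.5, 1, n_gene,
                       dimnames = list(NULL, all_pathway_genes())),
    gh_cp_dependence = 0.6, seed = 47)
  cohort <- simulate_cohort(cfg)
  has <- function(feature, slot) {
    vapply(cohort, function(p) feature %in% p[[slot]], logical(1))
  }
  r <- stats::cor(has("alpha-L-fucosidase", "gh_classes"),
                  has("fucI", "genes"))
  expect_gt(r, 0.15)
  # a feature pair from unrelated sugars stays near zero
  r0 <- stats::cor(has("alpha-L-fucosidase", "gh_classes"),
                   has("nanA", "genes"))
  expect_lt(abs(r0), 0.1)
})

test_that("empirical feature frequencies converge to the configured probs", {
  n_gh <- length(unique(default_gh_map()$gh_class))
  n_gene <- length(all_pathway_genes())
  p0 <- 0.35
  n <- 1500
  cfg <- cohort_config(
    n_genomes = n, n_taxa = 1,
    gh_prob = matrix(p0, 1, n_gh,
                     dimnames = list(NULL, unique(default_gh_map()$gh_class))),
    gene_prob = matrix(p0, 1, n_gene,
                       dimnames = list(NULL, all_pathway_genes())),
    gh_cp_dependence = 0.3, seed = 53)
  cohort <- simulate_cohort(cfg)
  tol <- 3 * sqrt(p0 * (1 - p0) / n)
  for (cls in unique(default_gh_map()$gh_class)) {
    freq <- mean(vapply(cohort, function(p) cls %in% p$gh_classes,
                        logical(1)))
    expect_lt(abs(freq - p0), tol)
  }
})

test_that("library simulation respects its configuration", {
  cfg <- library_config(n_glycans = 30, min_bonds = 2, max_bonds = 5,
                        peptide_prob = 1, seed = 59)
  lib <- simulate_library(cfg)
  expect_length(lib, 30L)
  expect_identical(simulate_library(cfg), lib)
  for (g in unclass(lib)) {
    glycosidic <- g$bonds[!is_peptide_bond(g$bonds)]
    expect_gte(length(glycosidic), 2L)
    expect_lte(length(glycosidic), 5L)
    expect_equal(sum(is_peptide_bond(g$bonds)), 1L)  # peptide_prob = 1
    expect_false(anyDuplicated(glycosidic) > 0)
  }
  single <- simulate_library(library_config(n_glycans = 10, min_bonds = 1,
                                            max_bonds = 1, peptide_prob = 0,
                                            seed = 61))
  for (g in unclass(single)) expect_length(g$bonds, 1L)
  expect_length(simulate_library(library_config(n_glycans = 0, seed = 1)), 0L)
  expect_error(library_config(min_bonds = 0), "min_bonds")
})

test_that("planting is deterministic, additive and verifiable", {
  lib <- default_glycan_library()
  base <- simulate_cohort(cohort_config(n_genomes = 6, n_taxa = 2, seed = 67))
  unchanged <- plant_mutualistic_pairs(base, lib, k = 0, seed = 1)
  expect_identical(unchanged$cohort, base)
  expect_equal(nrow(unchanged$truth), 0L)

  planted <- plant_mutualistic_pairs(base, lib, k = 3, seed = 71)
  expect_identical(plant_mutualistic_pairs(base, lib, k = 3, seed = 71),
                   planted)
  expect_length(planted$cohort, 12L)
  # each planted pair: neither member cleaves the target, the union does
  for (i in seq_len(3)) {
    a <- planted$cohort[[planted$truth$genome_a[i]]]
    b <- planted$cohort[[planted$truth$genome_b[i]]]
    g <- lib[[planted$truth$glycan[i]]]
    expect_false(can_cleave(cleavable_bonds(a), g))
    expect_false(can_cleave(cleavable_bonds(b), g))
    expect_true(can_cleave(union(cleavable_bonds(a), cleavable_bonds(b)), g))
  }

  # a library with no multi-bond glycan cannot host a planted pair
  flat <- glycan_library(list(glycan("one", bond("Gal", "b1,3", "GalNAc"))))
  expect_error(plant_mutualistic_pairs(list(), flat, k = 1, seed = 1),
               "two-way GH split")
})
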