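test_that("pair analysis is symmetric and gains only what pooling unlocks", {
  # disjoint capabilities that jointly cover a two-bond glycan
  target <- glycan("target", c(bond("Gal", "b1,3", "GalNAc"),
                               bond("Neu5Ac", "a2,3", "Gal")))
  lib <- glycan_library(list(target,
                             glycan("easy", bond("Gal", "b1,3", "GalNAc"))))
  a <- genome_profile("a", gh_classes = "beta-galactosidase")
  b <- genome_profile("b", gh_classes = "neuraminidase")
  ab <- pair_analysis(a, b, lib)
  ba <- pair_analysis(b, a, lib)
  expect_equal(ab[], ba[])
  expect_equal(ab$summary_pattern, "easy")
  expect_setequal(ab$mutualistic_pattern, c("target", "easy"))
  expect_equal(ab$gained, "target")
  expect_true(ab$is_mutualistic)
  expect_true(ab$is_highly_beneficial)
  expect_error(pair_analysis(a, a, lib), "distinct")
})

test_that("identical or nested GH repertoires are never mutualistic", {
  lib <- default_glycan_library()
  gh <- unique(default_gh_map()$gh_class)
  set.seed(17)
  for (rep in 1:15) {
    inner <- gh[stats::runif(length(gh)) < 0.4]
    outer <- union(inner, gh[stats::runif(length(gh)) < 0.4])
    a <- genome_profile("a", gh_classes = inner)
    b <- genome_profile("b", gh_classes = outer)
    expect_false(pair_analysis(a, b, lib)$is_mutualistic)
  }
  twin_pairs <- find_mutualistic_pairs(
    list(genome_profile("t1", gh_classes = gh[1:3]),
         genome_profile("t2", gh_classes = gh[1:3])), lib)
  expect_length(twin_pairs, 0L)
})

test_that("the mutualistic pattern always contains the summary pattern", {
  set.seed(19)
  lib <- simulate_library(library_config(n_glycans = 15, seed = 6))
  cohort <- random_cohort(8, p_gh = 0.35)
  ids <- names(cohort)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      pa <- pair_analysis(cohort[[i]], cohort[[j]], lib)
      expect_true(all(pa$summary_pattern %in% pa$mutualistic_pattern))
      expect_setequal(pa$gained,
                      setdiff(pa$mutualistic_pattern, pa$summary_pattern))
      expect_equal(pa$is_mutualistic, length(pa$gained) > 0)
    }
  }
})

test_that("pair search results agree with unscreened re-derivation", {
  set.seed(29)
  lib <- simulate_library(library_config(n_glycans = 12, seed = 9))
  cohort <- random_cohort(10, p_gh = 0.3)
  got <- find_mutualistic_pairs(cohort, lib)
  # naive: re-derive every unordered pair from scratch, no screens
  n_deg <- vapply(cohort, function(p) cleavage_pattern(p, lib)$n, integer(1))
  want <- list()
  ids <- names(cohort)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      if (n_deg[i] == length(lib) || n_deg[j] == length(lib)) next
      pa <- pair_analysis(cohort[[i]], cohort[[j]], lib)
      if (pa$is_mutualistic) want[[length(want) + 1]] <- pa
    }
  }
  key <- function(ps) sort(vapply(ps, function(p) {
    paste(p$genome_a, p$genome_b)
  }, character(1)))
  expect_equal(key(got), key(want))
  # and the result is sorted by gain size, descending
  gains <- vapply(got, function(p) length(p$gained), integer(1))
  expect_true(all(diff(gains) <= 0))
})

test_that("genomes that already cleave the whole library join no pair", {
  lib <- default_glycan_library()
  omnivore <- genome_profile("omni",
                             gh_classes = unique(default_gh_map()$gh_class))
  partner <- genome_profile("p", gh_classes = "beta-galactosidase")
  other <- genome_profile("q", gh_classes = "neuraminidase")
  pairs <- find_mutualistic_pairs(list(omnivore, partner, other), lib)
  involved <- unlist(lapply(pairs, function(p) c(p$genome_a, p$genome_b)))
  expect_false("omni" %in% involved)
})

test_that("planted pairs are recovered and participation counts are exact", {
  lib <- default_glycan_library()
  planted <- plant_mutualistic_pairs(list(), lib, k = 5, seed = 31)
  expect_length(planted$cohort, 10L)
  pairs <- find_mutualistic_pairs(planted$cohort, lib)
  found <- vapply(pairs, function(p) paste(p$genome_a, p$genome_b),
                  character(1))
  expect_true(all(paste(planted$truth$genome_a,
                        planted$truth$genome_b) %in% found))
  part <- mutualism_participation(pairs, planted$cohort)
  expect_true(all(c(planted$truth$genome_a, planted$truth$genome_b) %in%
                    part$participants))
  expect_equal(part$fraction, part$n / length(planted$cohort))

  none <- mutualism_participation(list(), planted$cohort)
  expect_equal(none$n, 0L)
  expect_equal(none$fraction, 0)

  one <- mutualism_participation(pairs[1], planted$cohort)
  expect_equal(one$n, 2L)
})

test_that("pair tables carry the set sizes and the beneficial flag", {
  lib <- default_glycan_library()
  planted <- plant_mutualistic_pairs(list(), lib, k = 2, seed = 33)
  pairs <- find_mutualistic_pairs(planted$cohort, lib)
  tab <- pair_table(pairs)
  expect_equal(nrow(tab), length(pairs))
  expect_true(all(tab$n_gained >= 1))
  expect_equal(tab$n_gained, tab$n_mutualistic - tab$n_summary)
  expect_equal(nrow(pair_table(list())), 0L)
})
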