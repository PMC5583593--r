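test_that("pattern vectors project CP and GH presence onto the 5 sugars", {
  # Gal (Leloir) and GlcNAc (nag) pathways, no GHs at all
  p <- genome_profile("g", genes = c("galK", "galT", "galE",
                                     "nagK", "nagA", "nagB"))
  pv <- pattern_vector(p)
  expect_equal(sum(pv$cp), 2L)
  expect_true(all(pv$cp[c("Gal", "GlcNAc")]))
  expect_false(any(pv$gh))
  expect_equal(pv$gh_key, "00000")

  empty <- pattern_vector(genome_profile("e"))
  expect_false(any(empty$cp) || any(empty$gh))
  expect_equal(empty$combined_key, strrep("0", 10))

  everything <- genome_profile("all",
                               gh_classes = unique(default_gh_map()$gh_class),
                               genes = all_pathway_genes())
  full <- pattern_vector(everything)
  expect_true(all(full$cp) && all(full$gh))
  expect_equal(full$combined_key, strrep("1", 10))
})

test_that("a GH counts toward every monosaccharide it releases", {
  hex <- pattern_vector(genome_profile("h",
                                       gh_classes = "beta-N-hexosaminidase"))
  expect_true(all(hex$gh[c("GalNAc", "GlcNAc")]))
  expect_equal(sum(hex$gh), 2L)
  sial <- pattern_vector(genome_profile("s", gh_classes = "neuraminidase"))
  expect_equal(names(which(sial$gh)), "Neu5Ac")
})

test_that("frequency tables span the full category spaces with zeros kept", {
  p <- genome_profile("a", genes = c("galK", "galT", "galE"))
  cohort <- list(p, genome_profile("b", genes = p$genes),
                 genome_profile("c", genes = p$genes))
  freqs <- pattern_frequencies(cohort)
  expect_equal(attr(freqs$cp, "k"), 32L)
  expect_equal(attr(freqs$combined, "k"), 1024L)
  expect_equal(sum(freqs$cp), 3L)
  expect_equal(sum(freqs$cp > 0), 1L)
  expect_equal(max(freqs$cp), 3L)

  set.seed(31)
  cohort <- random_cohort(25)
  freqs <- pattern_frequencies(cohort)
  for (tab in freqs[c("cp", "gh", "combined")]) {
    expect_equal(sum(tab), 25L)
  }
  expect_lte(observed_patterns(freqs$combined),
             observed_patterns(freqs$cp) * observed_patterns(freqs$gh))
  expect_equal(combined_pattern_bound(freqs$cp, freqs$gh),
               observed_patterns(freqs$cp) * observed_patterns(freqs$gh))
})

test_that("uniformity statistic matches hand computations", {
  k2 <- structure(c(`0` = 10L, `1` = 0L), k = 2L, n = 10L,
                  class = "pattern_freq_table")
  res <- chisq_uniform(k2)
  expect_equal(res$statistic, 10)  # (10-5)^2/5 + (0-5)^2/5
  expect_equal(res$df, 1L)

  flat <- structure(rep(3L, 32), k = 32L, n = 96L,
                    class = "pattern_freq_table")
  expect_equal(chisq_uniform(flat)$statistic, 0)
  expect_equal(chisq_uniform(flat)$df, 31L)
  expect_equal(chisq_uniform(flat)$p_value, 1)

  expect_error(chisq_uniform(structure(rep(0L, 4), class = "pattern_freq_table")),
               "no observations")
})

test_that("statistic equals N(K-1) when one pattern is shared, any labels", {
  set.seed(5)
  for (k in c(8, 32)) {
    for (n in c(7, 40)) {
      counts <- integer(k)
      slot <- sample.int(k, 1)
      counts[slot] <- n
      res <- chisq_uniform(structure(counts, class = "pattern_freq_table"))
      expect_equal(res$statistic, n * (k - 1))
      # invariance under category relabeling
      perm <- sample.int(k)
      expect_equal(chisq_uniform(structure(counts[perm],
                                           class = "pattern_freq_table"))$statistic,
                   res$statistic)
    }
  }
})

test_that("tiny p-values print with the conventional floor", {
  expect_equal(format_p_value(1e-20), "< 2.2e-16")
  expect_match(format_p_value(0.05), "0.05")
})

test_that("precomputed presence matrices give identical frequency tables", {
  set.seed(8)
  cohort <- random_cohort(30)
  freqs <- pattern_frequencies(cohort)
  mono <- mucin_monosaccharides()
  mat <- do.call(rbind, lapply(freqs$vectors, function(v) {
    stats::setNames(as.integer(c(v$cp, v$gh)),
                    c(paste0("cp_", mono), paste0("gh_", mono)))
  }))
  from_matrix <- pattern_frequencies_from_matrix(as.data.frame(mat))
  expect_equal(as.integer(from_matrix$cp), as.integer(freqs$cp))
  expect_equal(as.integer(from_matrix$gh), as.integer(freqs$gh))
  expect_equal(as.integer(from_matrix$combined), as.integer(freqs$combined))
  expect_error(pattern_frequencies_from_matrix(data.frame(cp_Fuc = 1)),
               "lacks columns")
})

test_that("pattern tables are written with all categories", {
  set.seed(9)
  freqs <- pattern_frequencies(random_cohort(10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_table(freqs$cp, path)
  tab <- utils::read.delim(path, colClasses = c("character", "integer"))
  expect_equal(nrow(tab), 32L)
  expect_equal(sum(tab$count), 10L)
})
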