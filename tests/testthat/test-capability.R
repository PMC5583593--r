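test_that("cleavable bonds are the union over the genome's GH classes", {
  bgal <- genome_profile("b", gh_classes = "beta-galactosidase")
  expect_setequal(cleavable_bonds(bgal),
                  c(bond("Gal", "b1,3", "GalNAc"),
                    bond("Gal", "b1,3", "GlcNAc"),
                    bond("Gal", "b1,4", "GlcNAc")))

  expect_length(cleavable_bonds(genome_profile("e")), 0L)

  # distributivity: bonds of a merged profile = union of member bonds
  sial <- genome_profile("s", gh_classes = "neuraminidase")
  both <- genome_profile("sb", gh_classes = c("neuraminidase",
                                              "beta-galactosidase"))
  expect_setequal(cleavable_bonds(both),
                  union(cleavable_bonds(bgal), cleavable_bonds(sial)))

  expect_error(
    cleavable_bonds(genome_profile("x", gh_classes = "made-up-enzyme")),
    "made-up-enzyme")
  # the sulfatase is tolerated and contributes no bonds
  sulf <- genome_profile("su", gh_classes = sulfatase_id())
  expect_length(cleavable_bonds(sulf), 0L)
})

test_that("a glycan is cleavable iff every glycosidic bond is covered", {
  core1 <- glycan("core1", c(bond("Gal", "b1,3", "GalNAc"),
                             bond("GalNAc", "a", "Peptide")))
  bgal_bonds <- cleavable_bonds(genome_profile("b",
                                               gh_classes = "beta-galactosidase"))
  expect_true(can_cleave(bgal_bonds, core1))
  expect_false(can_cleave(character(0), core1))
  # with the peptide bond counted, beta-galactosidase alone is not enough
  expect_false(can_cleave(bgal_bonds, core1, exclude_peptide = FALSE))
})

test_that("cleavability is monotone in capability, antitone in bond sets", {
  # brute force over all capability subsets of a 4-bond alphabet
  alphabet <- default_bond_alphabet()[1:4]
  g_small <- glycan("sub", alphabet[1:2])
  g_large <- glycan("sup", alphabet[1:3])
  for (mask in 0:15) {
    capable <- alphabet[as.logical(intToBits(mask)[1:4])]
    if (can_cleave(capable, g_large)) {
      expect_true(can_cleave(capable, g_small))
    }
    # monotone in capability: adding a bond never breaks cleavage
    for (extra in setdiff(alphabet, capable)) {
      if (can_cleave(capable, g_small)) {
        expect_true(can_cleave(c(capable, extra), g_small))
      }
    }
  }
})

test_that("cleavage patterns match a naive per-bond oracle", {
  set.seed(11)
  lib <- simulate_library(library_config(n_glycans = 25, seed = 2))
  for (i in 1:20) {
    p <- random_profile(sprintf("g%02d", i))
    got <- cleavage_pattern(p, lib)
    expect_setequal(got$degradable_glycans, oracle_degradable(p, lib,
                                                              default_gh_map()))
    expect_equal(got$n, length(got$degradable_glycans))
  }
})

test_that("full and empty GH repertoires bound the cleavage pattern", {
  lib <- default_glycan_library()
  all_gh <- genome_profile("all", gh_classes = unique(default_gh_map()$gh_class))
  expect_setequal(cleavage_pattern(all_gh, lib)$degradable_glycans,
                  library_ids(lib))
  expect_length(cleavage_pattern(genome_profile("none"), lib)$degradable_glycans,
                0L)
})

test_that("pattern growth is monotone in the GH repertoire", {
  set.seed(13)
  lib <- simulate_library(library_config(n_glycans = 20, seed = 4))
  gh <- unique(default_gh_map()$gh_class)
  for (i in 1:15) {
    small_set <- gh[stats::runif(length(gh)) < 0.3]
    big_set <- union(small_set, sample(gh, 2))
    small <- cleavage_pattern(genome_profile("s", gh_classes = small_set), lib)
    big <- cleavage_pattern(genome_profile("b", gh_classes = big_set), lib)
    expect_true(all(small$degradable_glycans %in% big$degradable_glycans))
  }
})

test_that("strict sulfatase mode gates sulfated glycans only", {
  sulfo <- glycan("sulfo", bond("Gal", "b1,4", "GlcNAc"),
                  sulfated_glcnac = TRUE)
  plain <- glycan("plain", bond("Gal", "b1,4", "GlcNAc"))
  lib <- glycan_library(list(sulfo, plain))
  bgal <- genome_profile("b", gh_classes = "beta-galactosidase")
  bgal_sulf <- genome_profile("bs", gh_classes = c("beta-galactosidase",
                                                   sulfatase_id()))
  default_mode <- cleavage_pattern(bgal, lib)
  expect_setequal(default_mode$degradable_glycans, c("sulfo", "plain"))
  strict <- cleavage_pattern(bgal, lib, strict_sulfatase = TRUE)
  expect_equal(strict$degradable_glycans, "plain")
  strict_with <- cleavage_pattern(bgal_sulf, lib, strict_sulfatase = TRUE)
  expect_setequal(strict_with$degradable_glycans, c("sulfo", "plain"))
})

test_that("degrader classes follow the published bins with gaps reported", {
  expect_equal(classify_degrader(0), "non-degrader")
  expect_equal(classify_degrader(c(1, 3)), rep("specialist", 2))
  expect_equal(classify_degrader(4), "unbinned")
  expect_equal(classify_degrader(c(5, 13)), rep("intermediate", 2))
  expect_equal(classify_degrader(c(14, 20)), rep("unbinned", 2))
  expect_equal(classify_degrader(c(21, 56)), rep("generalist", 2))
  # snapping assigns the between-bin counts to the nearest bin (ties lower)
  expect_equal(classify_degrader(4, snap = TRUE), "specialist")
  expect_equal(classify_degrader(c(14, 17), snap = TRUE),
               rep("intermediate", 2))
  expect_equal(classify_degrader(c(18, 20), snap = TRUE),
               rep("generalist", 2))
  expect_error(classify_degrader(-1), "between 0")
  expect_error(classify_degrader(57), "between 0")
  expect_error(classify_degrader(18, library_size = 17), "between 0")
})
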