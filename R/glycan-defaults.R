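#' Default library of intestinal mucin O-glycan structures
#'
#' A curated set of 17 O-glycan structures assembled from the default bond
#' alphabet: the four mucin cores, sialylated and fucosylated core-1
#' elaborations, Lewis- and blood-group-type termini, a poly-lacto-N-biose
#' backbone, a 6-sulfated LacNAc structure and an alpha-GlcNAc-capped
#' structure. Together they exercise every bond type of
#' [default_bond_alphabet()]. The set is a best-effort stand-in for a full
#' experimentally derived intestinal glycan catalogue (such catalogues run to
#' dozens of structures); treat it as replaceable input data, via
#' [load_glycan_library()], whenever a curated catalogue is available.
#'
#' @return A `"glycan_library"` of 17 structures.
#' @export
default_glycan_library <- function() {
  pep <- bond("GalNAc", "a", "Peptide")
  core1 <- bond("Gal", "b1,3", "GalNAc")
  lnb <- bond("Gal", "b1,3", "GlcNAc")      # lacto-N-biose unit
  lacnac <- bond("Gal", "b1,4", "GlcNAc")   # N-acetyllactosamine unit
  ext <- bond("GlcNAc", "b1,3", "Gal")      # backbone extension
  g <- list(
    glycan("core1", c(core1, pep), core_label = "Core 1"),
    glycan("core2", c(core1, bond("GlcNAc", "b1,6", "GalNAc"), pep),
           core_label = "Core 2"),
    glycan("core3", c(bond("GlcNAc", "b1,3", "GalNAc"), pep),
           core_label = "Core 3"),
    glycan("core4", c(bond("GlcNAc", "b1,3", "GalNAc"),
                      bond("GlcNAc", "b1,6", "GalNAc"), pep),
           core_label = "Core 4"),
    glycan("sialyl-T", c(bond("Neu5Ac", "a2,3", "Gal"), core1, pep),
           core_label = "Core 1"),
    glycan("sialyl-6-T", c(bond("Neu5Ac", "a2,6", "Gal"), core1, pep),
           core_label = "Core 1"),
    glycan("disialyl-T", c(bond("Neu5Ac", "a2,3", "Gal"),
                           bond("Neu5Ac", "a2,6", "GalNAc"), core1, pep),
           core_label = "Core 1"),
    glycan("H-type", c(bond("Fuc", "a1,2", "Gal"), lacnac, ext, core1, pep),
           core_label = "Core 1"),
    glycan("Lewis-b-like", c(bond("Fuc", "a1,4", "GlcNAc"),
                             bond("Fuc", "a1,2", "Gal"), lnb, ext, core1, pep),
           core_label = "Core 1"),
    glycan("Lewis-x-like", c(bond("Fuc", "a1,3", "GlcNAc"), lacnac, ext,
                             core1, pep),
           core_label = "Core 1"),
    glycan("fucosyl-GlcNAc", c(bond("Fuc", "a1,2", "GlcNAc"),
                               bond("GlcNAc", "b1,3", "GalNAc"), pep),
           core_label = "Core 3"),
    glycan("blood-A-like", c(bond("GalNAc", "a1,3", "Gal"),
                             bond("Fuc", "a1,2", "Gal"), lnb, ext, core1, pep),
           core_label = "Core 1"),
    glycan("blood-B-like", c(bond("Gal", "a1,3", "Gal"),
                             bond("Fuc", "a1,2", "Gal"), lacnac, ext, core1,
                             pep),
           core_label = "Core 1"),
    glycan("poly-LNB", c(lnb, lnb, ext, ext, core1, pep),
           core_label = "Core 1"),
    glycan("sulfo-LacNAc", c(lacnac, ext, core1, pep),
           sulfated_glcnac = TRUE, core_label = "Core 1"),
    glycan("alpha-GlcNAc-cap", c(bond("GlcNAc", "a1,4", "Gal"), lnb, ext,
                                 core1, pep),
           core_label = "Core 1"),
    glycan("GalNAc-extended", c(bond("GalNAc", "b1,4", "Gal"),
                                bond("GalNAc", "a1,6", "GalNAc"), core1, pep),
           core_label = "Core 1")
  )
  glycan_library(g, bond_alphabet = default_bond_alphabet())
}
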