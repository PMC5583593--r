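#' Default GH class to cleavable-bond map
#'
#' Maps the eight extracellular glycoside hydrolase (GH) classes that
#' hydrolyze mucin-glycan linkages to the bond types each can cleave, one row
#' per (class, bond):
#'
#' * alpha-L-fucosidase (EC 3.2.1.51): all Fuc linkages,
#' * neuraminidase/sialidase (EC 3.2.1.18): all Neu5Ac linkages,
#' * alpha-galactosidase (EC 3.2.1.22): Gal a1,3 Gal,
#' * beta-galactosidase (EC 3.2.1.23): Gal b1,3 GalNAc, Gal b1,3 GlcNAc,
#'   Gal b1,4 GlcNAc,
#' * alpha-N-acetylgalactosaminidase (EC 3.2.1.49): alpha GalNAc linkages,
#' * alpha-N-acetylglucosaminidase (EC 3.2.1.50): GlcNAc a1,4 Gal,
#' * beta-N-hexosaminidase (EC 3.2.1.52): beta GalNAc and beta GlcNAc
#'   linkages (one enzyme class releasing both amino sugars),
#' * endo-alpha-N-acetylgalactosaminidase (EC 3.2.1.97): the GalNAc-Ser/Thr
#'   peptide attachment.
#'
#' The monosaccharide a class releases is the donor of the bonds it cleaves.
#' The mucin-desulfating sulfatase ([sulfatase_id()]) is deliberately not a
#' row here: it removes sulfate groups, not glycosidic bonds.
#'
#' @return Data frame with columns `gh_class`, `ec`, `bond`.
#' @export
default_gh_map <- function() {
  rows <- list(
    list("alpha-L-fucosidase", "3.2.1.51",
         c(bond("Fuc", "a1,2", "Gal"), bond("Fuc", "a1,2", "GlcNAc"),
           bond("Fuc", "a1,3", "GlcNAc"), bond("Fuc", "a1,4", "GlcNAc"))),
    list("neuraminidase", "3.2.1.18",
         c(bond("Neu5Ac", "a2,3", "Gal"), bond("Neu5Ac", "a2,6", "Gal"),
           bond("Neu5Ac", "a2,6", "GalNAc"))),
    list("alpha-galactosidase", "3.2.1.22", bond("Gal", "a1,3", "Gal")),
    list("beta-galactosidase", "3.2.1.23",
         c(bond("Gal", "b1,3", "GalNAc"), bond("Gal", "b1,3", "GlcNAc"),
           bond("Gal", "b1,4", "GlcNAc"))),
    list("alpha-N-acetylgalactosaminidase", "3.2.1.49",
         c(bond("GalNAc", "a1,3", "Gal"), bond("GalNAc", "a1,6", "GalNAc"))),
    list("alpha-N-acetylglucosaminidase", "3.2.1.50",
         bond("GlcNAc", "a1,4", "Gal")),
    list("beta-N-hexosaminidase", "3.2.1.52",
         c(bond("GalNAc", "b1,4", "Gal"), bond("GalNAc", "b1,3", "GalNAc"),
           bond("GlcNAc", "b1,3", "Gal"), bond("GlcNAc", "b1,3", "GalNAc"),
           bond("GlcNAc", "b1,6", "GalNAc"))),
    list("endo-alpha-N-acetylgalactosaminidase", "3.2.1.97",
         bond("GalNAc", "a", PEPTIDE))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gh_class = r[[1]], ec = r[[2]], bond = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

validate_gh_map <- function(gh_map, alphabet = NULL) {
  need <- c("gh_class", "ec", "bond")
  if (!all(need %in% names(gh_map))) {
    stop("GH map must have columns gh_class, ec, bond")
  }
  bond_parts(gh_map$bond)
  counts <- table(gh_map$gh_class)
  if (any(counts == 0)) stop("GH class with empty cleaves set")
  if (!is.null(alphabet)) {
    unknown <- setdiff(gh_map$bond, alphabet)
    if (length(unknown) > 0) {
      stop("GH map references bonds absent from the alphabet: ",
           paste(unknown, collapse = ", "))
    }
  }
  invisible(gh_map)
}

#' Read and write GH maps
#'
#' GH maps are tab-separated tables with a header and columns `gh_class`,
#' `ec`, `donor`, `linkage`, `acceptor` (one row per cleavable bond).
#'
#' @param path Path to a TSV file.
#' @param alphabet Optional bond alphabet to validate against.
#' @return `load_gh_map()` returns a data frame with columns `gh_class`,
#'   `ec`, `bond`; the writer returns `path` invisibly.
#' @export
load_gh_map <- function(path, alphabet = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gh_class", "ec", "donor", "linkage", "acceptor")
  if (!all(need %in% names(tab))) {
    stop("GH map table must have columns gh_class, ec, donor, linkage, acceptor")
  }
  gh_map <- data.frame(
    gh_class = tab$gh_class, ec = tab$ec,
    bond = bond(tab$donor, tab$linkage, tab$acceptor),
    stringsAsFactors = FALSE
  )
  validate_gh_map(gh_map, alphabet)
}

#' @rdname load_gh_map
#' @param gh_map Data frame as returned by [default_gh_map()].
#' @export
write_gh_map <- function(gh_map, path) {
  validate_gh_map(gh_map)
  parts <- bond_parts(gh_map$bond)
  out <- data.frame(gh_class = gh_map$gh_class, ec = gh_map$ec,
                    donor = parts$donor, linkage = parts$linkage,
                    acceptor = parts$acceptor, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Monosaccharides released by each GH class
#'
#' A GH class releases the donor sugars of the bonds it cleaves (e.g.
#' beta-N-hexosaminidase releases both GalNAc and GlcNAc). Used to project GH
#' repertoires onto the five-monosaccharide axis for pattern statistics and
#' cross-feeding roles.
#'
#' @param gh_map A GH map data frame.
#' @return Named list mapping each GH class to the character vector of
#'   monosaccharides it releases.
#' @export
gh_released <- function(gh_map = default_gh_map()) {
  parts <- bond_parts(gh_map$bond)
  split(parts$donor, gh_map$gh_class) |> lapply(unique)
}
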