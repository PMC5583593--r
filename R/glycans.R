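#' The five mucin monosaccharides
#'
#' Intestinal mucin O-glycans are built from five monosaccharides: L-fucose
#' (Fuc), D-galactose (Gal), N-acetyl-D-galactosamine (GalNAc),
#' N-acetyl-D-glucosamine (GlcNAc) and N-acetylneuraminic acid (Neu5Ac).
#' Their alphabetical order fixes the bit layout of every 5-bit presence
#' pattern used in this package.
#'
#' @return Character vector of the five monosaccharide labels, in canonical
#'   (alphabetical) order.
#' @export
#' @examples
#' mucin_monosaccharides()
mucin_monosaccharides <- function() {
  c("Fuc", "Gal", "GalNAc", "GlcNAc", "Neu5Ac")
}

# Sentinel acceptor for the glycan-peptide attachment (GalNAc alpha-linked
# to mucin Ser/Thr residues).
PEPTIDE <- "Peptide"

# Feature id recognized as the mucin-desulfating sulfatase
# (GlcNAc-6-sulfatase, EC 3.1.6.14). It removes sulfate groups rather than
# cleaving a glycosidic bond, so it never appears in a GH-to-bond map; it is
# consulted only by the strict sulfatase mode of cleavability prediction.
SULFATASE_ID <- "GlcNAc-6-sulfatase"

#' @rdname mucin_monosaccharides
#' @export
sulfatase_id <- function() SULFATASE_ID

# Normalize a linkage label: unicode anomeric characters to ascii, lowercase,
# strip whitespace. "α1,2" and "A1, 2" both become "a1,2".
normalize_linkage <- function(x) {
  x <- gsub("α", "a", x)
  x <- gsub("β", "b", x)
  x <- gsub("[[:space:]]", "", x)
  tolower(x)
}

#' Construct glycosidic bond identifiers
#'
#' A bond type is the triple (donor sugar, linkage label, acceptor), e.g.
#' Fuc alpha1,2 Gal. Bonds are represented as canonical strings
#' `"donor|linkage|acceptor"`; equality of bond types is string equality.
#' The acceptor may be the sentinel `"Peptide"` for the GalNAc-Ser/Thr
#' attachment of the glycan to the mucin protein backbone. Linkage labels are
#' normalized to lowercase ascii (`"a1,2"`, `"b1,4"`, `"a2,3"`).
#'
#' @param donor Monosaccharide released when the bond is hydrolyzed.
#' @param linkage Linkage label such as `"a1,2"`; Greek anomeric characters
#'   are accepted and normalized.
#' @param acceptor Monosaccharide (or `"Peptide"`) the donor is attached to.
#' @return Character vector of canonical bond ids.
#' @export
#' @examples
#' bond("Fuc", "a1,2", "Gal")
#' bond("GalNAc", "a", "Peptide")
bond <- function(donor, linkage, acceptor) {
  mono <- mucin_monosaccharides()
  bad <- setdiff(donor, mono)
  if (length(bad) > 0) {
    stop("unknown donor monosaccharide: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(acceptor, c(mono, PEPTIDE))
  if (length(bad) > 0) {
    stop("unknown acceptor: ", paste(bad, collapse = ", "))
  }
  paste(donor, normalize_linkage(linkage), acceptor, sep = "|")
}

#' Decompose bond ids into their parts
#'
#' @param bonds Character vector of canonical bond ids (see [bond()]).
#' @return A data frame with columns `donor`, `linkage`, `acceptor` and
#'   logical `is_peptide_linkage`.
#' @export
bond_parts <- function(bonds) {
  parts <- strsplit(bonds, "|", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 3L
  if (!all(ok)) {
    stop("malformed bond id: ", paste(bonds[!ok], collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  data.frame(
    donor = m[, 1L], linkage = m[, 2L], acceptor = m[, 3L],
    is_peptide_linkage = m[, 3L] == PEPTIDE,
    stringsAsFactors = FALSE
  )
}

#' @rdname bond_parts
#' @export
is_peptide_bond <- function(bonds) {
  bond_parts(bonds)$is_peptide_linkage
}

#' Default bond alphabet of intestinal mucin glycans
#'
#' The glycosidic linkages reported for human intestinal mucin O-glycans:
#' Fuc attached a1,2 to Gal and a1,2/a1,3/a1,4 to GlcNAc; GalNAc attached
#' a1,3/b1,4 to Gal and a1,6/b1,3 to GalNAc; GlcNAc attached a1,4/b1,3 to Gal
#' and b1,3/b1,6 to GalNAc; Neu5Ac attached a2,3 to Gal and a2,6 to Gal or
#' GalNAc; Gal attached a1,3 to Gal and b1,3 to GalNAc/GlcNAc and b1,4 to
#' GlcNAc; plus the GalNAc-Ser/Thr peptide attachment. 20 bond types in
#' total. The alphabet is plain data and can be replaced by
#' [load_bond_alphabet()].
#'
#' @return Character vector of canonical bond ids.
#' @export
default_bond_alphabet <- function() {
  c(
    bond("Fuc", "a1,2", "Gal"),
    bond("Fuc", "a1,2", "GlcNAc"),
    bond("Fuc", "a1,3", "GlcNAc"),
    bond("Fuc", "a1,4", "GlcNAc"),
    bond("Gal", "a1,3", "Gal"),
    bond("Gal", "b1,3", "GalNAc"),
    bond("Gal", "b1,3", "GlcNAc"),
    bond("Gal", "b1,4", "GlcNAc"),
    bond("GalNAc", "a1,3", "Gal"),
    bond("GalNAc", "b1,4", "Gal"),
    bond("GalNAc", "a1,6", "GalNAc"),
    bond("GalNAc", "b1,3", "GalNAc"),
    bond("GalNAc", "a", PEPTIDE),
    bond("GlcNAc", "a1,4", "Gal"),
    bond("GlcNAc", "b1,3", "Gal"),
    bond("GlcNAc", "b1,3", "GalNAc"),
    bond("GlcNAc", "b1,6", "GalNAc"),
    bond("Neu5Ac", "a2,3", "Gal"),
    bond("Neu5Ac", "a2,6", "Gal"),
    bond("Neu5Ac", "a2,6", "GalNAc")
  )
}

#' Read and write bond alphabets
#'
#' Bond alphabets are stored as tab-separated tables with a header row and
#' columns `donor`, `linkage`, `acceptor`. Duplicate triples are deduplicated
#' with a warning; malformed records raise an error naming the line.
#'
#' @param path Path to a TSV file.
#' @return `load_bond_alphabet()` returns a character vector of canonical
#'   bond ids; `write_bond_alphabet()` returns `path` invisibly.
#' @export
load_bond_alphabet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("donor", "linkage", "acceptor")
  if (!all(need %in% names(tab))) {
    stop("bond alphabet table must have columns donor, linkage, acceptor")
  }
  if (nrow(tab) == 0) return(character(0))
  bad <- which(is.na(tab$donor) | is.na(tab$linkage) | is.na(tab$acceptor) |
                 tab$donor == "" | tab$linkage == "" | tab$acceptor == "")
  if (length(bad) > 0) {
    stop("malformed bond record at line ", bad[1] + 1L, " of ", path)
  }
  bonds <- bond(tab$donor, tab$linkage, tab$acceptor)
  if (anyDuplicated(bonds)) {
    warning("duplicate bond triples in ", path, "; deduplicated")
    bonds <- unique(bonds)
  }
  bonds
}

#' @rdname load_bond_alphabet
#' @param alphabet Character vector of canonical bond ids.
#' @export
write_bond_alphabet <- function(alphabet, path) {
  parts <- bond_parts(alphabet)
  utils::write.table(parts[, c("donor", "linkage", "acceptor")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a glycan structure
#'
#' A glycan is an identified multiset of bond types with an optional
#' GlcNAc-sulfation flag. Branching topology and cleavage order are not
#' modeled: cleavability is pure bond-type coverage, so the multiset of bond
#' types carries all the information the prediction rule uses.
#'
#' @param id Unique glycan identifier.
#' @param bonds Character vector (multiset) of canonical bond ids; non-empty,
#'   at most one peptide linkage.
#' @param sulfated_glcnac Logical; does the glycan carry 6-sulfated GlcNAc?
#' @param core_label Optional free-text core annotation (e.g. `"Core 1"`).
#' @return An object of class `"glycan"`.
#' @export
#' @examples
#' core1 <- glycan("core1",
#'   c(bond("Gal", "b1,3", "GalNAc"), bond("GalNAc", "a", "Peptide")),
#'   core_label = "Core 1")
glycan <- function(id, bonds, sulfated_glcnac = FALSE, core_label = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(bonds) == 0) stop("glycan '", id, "' has no bonds")
  bond_parts(bonds)  # validates format
  if (sum(is_peptide_bond(bonds)) > 1L) {
    stop("glycan '", id, "' has more than one peptide linkage")
  }
  structure(
    list(id = id, bonds = bonds,
         sulfated_glcnac = isTRUE(sulfated_glcnac),
         core_label = as.character(core_label)),
    class = "glycan"
  )
}

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan>", x$id,
      if (!is.na(x$core_label)) paste0("(", x$core_label, ")"), "\n")
  cat("  bonds:", paste(x$bonds, collapse = ", "), "\n")
  if (x$sulfated_glcnac) cat("  sulfated GlcNAc\n")
  invisible(x)
}

#' Assemble a glycan library
#'
#' A glycan library is an ordered collection of [glycan()] structures with
#' unique ids, validated exhaustively against a bond alphabet.
#'
#' @param glycans List of [glycan()] objects.
#' @param bond_alphabet Character vector of canonical bond ids; every bond of
#'   every glycan must be a member.
#' @return An object of class `"glycan_library"` (a list of glycans with the
#'   alphabet attached as attribute `"bond_alphabet"`).
#' @export
glycan_library <- function(glycans, bond_alphabet = default_bond_alphabet()) {
  ids <- vapply(glycans, function(g) g$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate glycan ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (g in glycans) {
    unknown <- setdiff(g$bonds, bond_alphabet)
    if (length(unknown) > 0) {
      stop("glycan '", g$id, "' uses bonds absent from the alphabet: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(stats::setNames(glycans, ids),
            bond_alphabet = bond_alphabet,
            class = "glycan_library")
}

#' @export
print.glycan_library <- function(x, ...) {
  cat("<glycan_library> with", length(x), "glycans over",
      length(attr(x, "bond_alphabet")), "bond types\n")
  invisible(x)
}

#' @rdname glycan_library
#' @param library A `"glycan_library"`.
#' @export
library_ids <- function(library) {
  vapply(unclass(library), function(g) g$id, character(1), USE.NAMES = FALSE)
}

#' Read and write glycan libraries (JSON)
#'
#' Libraries are serialized as JSON documents
#' `{"bond_alphabet": [{donor, linkage, acceptor}, ...],
#'   "glycans": [{id, bonds: [...], sulfated_glcnac, core_label}, ...]}`.
#' Loading validates every glycan against the alphabet and round-trips
#' losslessly with [write_glycan_library()].
#'
#' @param path Path to a JSON file.
#' @param alphabet Optional bond alphabet overriding the one stored in the
#'   document.
#' @return A `"glycan_library"`; the writer returns `path` invisibly.
#' @export
load_glycan_library <- function(path, alphabet = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(alphabet)) {
    alphabet <- vapply(doc$bond_alphabet, function(b) {
      bond(b$donor, b$linkage, b$acceptor)
    }, character(1))
  }
  glycans <- lapply(doc$glycans, function(rec) {
    bonds <- vapply(rec$bonds, function(b) bond(b$donor, b$linkage, b$acceptor),
                    character(1))
    glycan(rec$id, bonds,
           sulfated_glcnac = isTRUE(rec$sulfated_glcnac),
           core_label = if (is.null(rec$core_label)) NA_character_ else rec$core_label)
  })
  glycan_library(glycans, bond_alphabet = alphabet)
}

#' @rdname load_glycan_library
#' @param library A `"glycan_library"`.
#' @export
write_glycan_library <- function(library, path) {
  bond_list <- function(bonds) {
    p <- bond_parts(bonds)
    lapply(seq_len(nrow(p)), function(i) {
      list(donor = p$donor[i], linkage = p$linkage[i], acceptor = p$acceptor[i])
    })
  }
  doc <- list(
    bond_alphabet = bond_list(attr(library, "bond_alphabet")),
    glycans = lapply(unclass(library), function(g) {
      rec <- list(id = g$id, bonds = bond_list(g$bonds),
                  sulfated_glcnac = g$sulfated_glcnac)
      if (!is.na(g$core_label)) rec$core_label <- g$core_label
      rec
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Bonds a genome must cleave to degrade a glycan
#'
#' Returns the distinct bond types of a glycan. With
#' `exclude_peptide = TRUE` (the standard setting) the GalNAc-Ser/Thr
#' peptide attachment is dropped: that bond is cleaved by
#' endo-alpha-N-acetylgalactosaminidases found in very few genomes, and the
#' cleavability prediction assesses the glycosidic bonds only.
#'
#' @param g A [glycan()].
#' @param exclude_peptide Drop the peptide linkage from the requirement set?
#' @return Character vector of distinct canonical bond ids.
#' @export
bonds_requiring_cleavage <- function(g, exclude_peptide = TRUE) {
  bonds <- unique(g$bonds)
  if (exclude_peptide) bonds <- bonds[!is_peptide_bond(bonds)]
  bonds
}
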