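#' Bonds cleavable by a genome's GH repertoire
#'
#' Union of the cleavable-bond sets of the GH classes encoded by a genome.
#' The mucin-desulfating sulfatase is tolerated in `gh_classes` but
#' contributes no bonds; any other GH id absent from the map is an error.
#'
#' @param profile A [genome_profile()].
#' @param gh_map GH map data frame ([default_gh_map()]).
#' @return Character vector of canonical bond ids.
#' @export
cleavable_bonds <- function(profile, gh_map = default_gh_map()) {
  classes <- setdiff(profile$gh_classes, SULFATASE_ID)
  unknown <- setdiff(classes, gh_map$gh_class)
  if (length(unknown) > 0) {
    stop("unknown GH class in genome '", profile$genome_id, "': ",
         paste(unknown, collapse = ", "))
  }
  unique(gh_map$bond[gh_map$gh_class %in% classes])
}

#' Can a bond repertoire cleave a glycan?
#'
#' A glycan is predicted cleavable when GHs for all of its glycosidic bonds
#' are available, i.e. when its required bond set (peptide attachment
#' excluded) is contained in `capable`. In strict sulfatase mode a glycan
#' carrying 6-sulfated GlcNAc additionally requires the mucin-desulfating
#' sulfatase; by default sulfation does not block cleavability.
#'
#' @param capable Character vector of cleavable bond ids (from
#'   [cleavable_bonds()]).
#' @param g A [glycan()].
#' @param strict_sulfatase Require the sulfatase for sulfated glycans?
#' @param has_sulfatase Does the genome encode the sulfatase?
#' @param exclude_peptide Exclude the peptide attachment from the
#'   requirement (the standard setting)?
#' @return Logical scalar.
#' @export
can_cleave <- function(capable, g, strict_sulfatase = FALSE,
                       has_sulfatase = FALSE, exclude_peptide = TRUE) {
  needed <- bonds_requiring_cleavage(g, exclude_peptide = exclude_peptide)
  covered <- all(needed %in% capable)
  covered && (!strict_sulfatase || !g$sulfated_glcnac || has_sulfatase)
}

#' Per-genome glycan cleavage pattern
#'
#' Applies [can_cleave()] to every glycan in the library and records the set
#' of degradable glycan ids for the genome.
#'
#' @param profile A [genome_profile()].
#' @param library A `"glycan_library"`.
#' @param gh_map GH map data frame.
#' @param strict_sulfatase Require the sulfatase for sulfated glycans?
#' @param exclude_peptide Exclude the peptide attachment from bond
#'   requirements?
#' @return An object of class `"cleavage_pattern"`: list with `genome_id`,
#'   `degradable_glycans` (character) and `n`.
#' @export
cleavage_pattern <- function(profile, library = default_glycan_library(),
                             gh_map = default_gh_map(),
                             strict_sulfatase = FALSE,
                             exclude_peptide = TRUE) {
  capable <- cleavable_bonds(profile, gh_map)
  has_sulf <- SULFATASE_ID %in% profile$gh_classes
  ok <- vapply(unclass(library), function(g) {
    can_cleave(capable, g, strict_sulfatase = strict_sulfatase,
               has_sulfatase = has_sulf, exclude_peptide = exclude_peptide)
  }, logical(1))
  ids <- library_ids(library)[ok]
  structure(
    list(genome_id = profile$genome_id, degradable_glycans = ids,
         n = length(ids)),
    class = "cleavage_pattern"
  )
}

#' @export
print.cleavage_pattern <- function(x, ...) {
  cat("<cleavage_pattern>", x$genome_id, "degrades", x$n, "glycans\n")
  invisible(x)
}

#' Classify a genome by its degradation breadth
#'
#' Bins a genome by the number of glycans it is predicted to degrade:
#' 0 is a non-degrader, 1-3 a specialist, 5-13 intermediate, 21 up to the
#' library size a generalist. The counts 4 and 14-20 fall between the
#' published bins and are reported as `"unbinned"` rather than silently
#' merged; `snap = TRUE` instead assigns them to the nearest bin edge (ties
#' snap to the lower bin).
#'
#' @param n Number of degradable glycans.
#' @param library_size Size of the active glycan library.
#' @param snap Snap the between-bin counts to the nearest bin?
#' @return One of `"non-degrader"`, `"specialist"`, `"intermediate"`,
#'   `"generalist"`, `"unbinned"` (vectorized over `n`).
#' @export
classify_degrader <- function(n, library_size = 56L, snap = FALSE) {
  if (any(n < 0) || any(n > library_size)) {
    stop("n must be between 0 and the library size")
  }
  one <- function(k) {
    if (k == 0) return("non-degrader")
    if (k >= 1 && k <= 3) return("specialist")
    if (k >= 5 && k <= 13) return("intermediate")
    if (k >= 21) return("generalist")
    if (!snap) return("unbinned")
    # nearest bin edge; ties go to the lower bin
    if (k == 4) return("specialist")
    if (k <= 17) return("intermediate") else return("generalist")
  }
  vapply(as.integer(n), one, character(1))
}

#' Degrader classes for a cohort
#'
#' @param profiles Named list of [genome_profile()]s.
#' @inheritParams cleavage_pattern
#' @inheritParams classify_degrader
#' @return Data frame with columns `genome_id`, `n_glycans`, `class`.
#' @export
degrader_classes <- function(profiles, library = default_glycan_library(),
                             gh_map = default_gh_map(),
                             strict_sulfatase = FALSE, snap = FALSE) {
  profiles <- validate_cohort(profiles)
  pats <- lapply(profiles, cleavage_pattern, library = library,
                 gh_map = gh_map, strict_sulfatase = strict_sulfatase)
  n <- vapply(pats, `[[`, integer(1), "n")
  data.frame(
    genome_id = cohort_ids(profiles),
    n_glycans = unname(n),
    class = classify_degrader(unname(n), library_size = length(library),
                              snap = snap),
    stringsAsFactors = FALSE
  )
}
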