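#' Analyze one genome pair for mutualistic glycan degradation
#'
#' For an unordered pair of genomes, the *summary pattern* is the union of
#' the glycan sets each genome degrades alone; the *mutualistic pattern* is
#' the glycan set degradable by the pooled GH repertoire of both genomes.
#' The pair is mutualistic when the mutualistic pattern strictly exceeds the
#' summary pattern - pooling enzymes unlocks glycans neither member can
#' degrade alone. A mutualistic pair whose pooled repertoire covers the
#' entire library is flagged highly beneficial.
#'
#' @param a,b Distinct [genome_profile()]s.
#' @param library A `"glycan_library"`.
#' @param gh_map GH map data frame.
#' @param strict_sulfatase Require the sulfatase for sulfated glycans?
#' @return An object of class `"pair_analysis"`: list with `genome_a`,
#'   `genome_b` (sorted ids), `summary_pattern`, `mutualistic_pattern`,
#'   `gained` (character vectors of glycan ids), `is_mutualistic`,
#'   `is_highly_beneficial`.
#' @export
pair_analysis <- function(a, b, library = default_glycan_library(),
                          gh_map = default_gh_map(),
                          strict_sulfatase = FALSE) {
  if (identical(a$genome_id, b$genome_id)) {
    stop("pair_analysis requires two distinct genomes")
  }
  pat_a <- cleavage_pattern(a, library, gh_map, strict_sulfatase)
  pat_b <- cleavage_pattern(b, library, gh_map, strict_sulfatase)
  pooled <- genome_profile(
    paste0(a$genome_id, "+", b$genome_id),
    gh_classes = union(a$gh_classes, b$gh_classes)
  )
  pat_ab <- cleavage_pattern(pooled, library, gh_map, strict_sulfatase)
  ids <- sort(c(a$genome_id, b$genome_id))
  all_ids <- library_ids(library)
  summary_pattern <- all_ids[all_ids %in%
                               union(pat_a$degradable_glycans,
                                     pat_b$degradable_glycans)]
  mutualistic_pattern <- pat_ab$degradable_glycans
  gained <- setdiff(mutualistic_pattern, summary_pattern)
  structure(
    list(genome_a = ids[1], genome_b = ids[2],
         summary_pattern = summary_pattern,
         mutualistic_pattern = mutualistic_pattern,
         gained = gained,
         is_mutualistic = length(gained) > 0,
         is_highly_beneficial = length(gained) > 0 &&
           length(mutualistic_pattern) == length(library)),
    class = "pair_analysis"
  )
}

#' @export
print.pair_analysis <- function(x, ...) {
  cat("<pair_analysis>", x$genome_a, "+", x$genome_b, "\n")
  cat("  summary:", length(x$summary_pattern),
      "| mutualistic:", length(x$mutualistic_pattern),
      "| gained:", length(x$gained), "\n")
  if (x$is_highly_beneficial) cat("  highly beneficial\n")
  invisible(x)
}

#' Find all mutualistic pairs in a cohort
#'
#' Enumerates unordered genome pairs, excluding any pair in which at least
#' one member alone degrades the entire library, and keeps the mutualistic
#' ones. Pairs whose pooled bond repertoire equals one member's repertoire
#' are skipped before glycan scoring (a pooled set equal to one member's can
#' never unlock new glycans), which prunes most of the quadratic work.
#'
#' @param profiles Named list of [genome_profile()]s (at least 2).
#' @inheritParams pair_analysis
#' @return List of mutualistic [pair_analysis()] objects, sorted by number
#'   of gained glycans (descending), then by genome ids.
#' @export
find_mutualistic_pairs <- function(profiles, library = default_glycan_library(),
                                   gh_map = default_gh_map(),
                                   strict_sulfatase = FALSE) {
  profiles <- validate_cohort(profiles)
  if (length(profiles) < 2) stop("need at least two genomes")
  bonds <- lapply(profiles, cleavable_bonds, gh_map = gh_map)
  sulf <- vapply(profiles, function(p) SULFATASE_ID %in% p$gh_classes,
                 logical(1))
  n_deg <- vapply(profiles, function(p) {
    cleavage_pattern(p, library, gh_map, strict_sulfatase)$n
  }, integer(1))
  eligible <- which(n_deg < length(library))
  pairs <- list()
  for (ii in seq_along(eligible)) {
    i <- eligible[ii]
    for (jj in seq_len(ii - 1L)) {
      j <- eligible[jj]
      pooled <- union(bonds[[i]], bonds[[j]])
      # capability screen: if the pooled capability (bonds, and in strict
      # mode the sulfatase) adds nothing over one member, no gain is possible
      covers <- function(m, other) {
        length(pooled) == length(bonds[[m]]) &&
          (!strict_sulfatase || sulf[m] || !sulf[other])
      }
      if (covers(i, j) || covers(j, i)) next
      pa <- pair_analysis(profiles[[i]], profiles[[j]], library, gh_map,
                          strict_sulfatase)
      if (pa$is_mutualistic) pairs[[length(pairs) + 1L]] <- pa
    }
  }
  if (length(pairs) == 0) return(pairs)
  ord <- order(-vapply(pairs, function(p) length(p$gained), integer(1)),
               vapply(pairs, `[[`, "", "genome_a"),
               vapply(pairs, `[[`, "", "genome_b"))
  pairs[ord]
}

#' Mutualism participation of a cohort
#'
#' Counts the distinct genomes appearing in at least one mutualistic pair.
#'
#' @param pairs List of [pair_analysis()] objects.
#' @param profiles Named list of [genome_profile()]s (the cohort the pairs
#'   were drawn from).
#' @return List with `participants` (sorted ids), `n` and `fraction` (over
#'   the cohort size).
#' @export
mutualism_participation <- function(pairs, profiles) {
  ids <- sort(unique(unlist(lapply(pairs, function(p) {
    c(p$genome_a, p$genome_b)
  }))))
  n_total <- length(profiles)
  list(participants = ids, n = length(ids),
       fraction = if (n_total > 0) length(ids) / n_total else 0)
}

#' Tabulate pair analyses
#'
#' @param pairs List of [pair_analysis()] objects.
#' @return Data frame with columns `genome_a`, `genome_b`, `n_summary`,
#'   `n_mutualistic`, `n_gained`, `highly_beneficial`.
#' @export
pair_table <- function(pairs) {
  if (length(pairs) == 0) {
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      n_summary = integer(0), n_mutualistic = integer(0),
                      n_gained = integer(0), highly_beneficial = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(genome_a = p$genome_a, genome_b = p$genome_b,
               n_summary = length(p$summary_pattern),
               n_mutualistic = length(p$mutualistic_pattern),
               n_gained = length(p$gained),
               highly_beneficial = p$is_highly_beneficial,
               stringsAsFactors = FALSE)
  }))
}
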