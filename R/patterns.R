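#' CP and GH presence vectors over the five monosaccharides
#'
#' For one genome, derives two 5-bit vectors in the canonical monosaccharide
#' order: the CP bits (bit m set when monosaccharide m is catabolizable
#' under the gap rule) and the GH bits (bit m set when the genome encodes at
#' least one GH class releasing m). The combined pattern is their 10-bit
#' concatenation.
#'
#' @param profile A [genome_profile()].
#' @param pathways A `"pathway_set"`.
#' @param gh_map GH map data frame.
#' @return An object of class `"pattern_vector"`: list with named logical
#'   vectors `cp` and `gh` and bitstrings `cp_key`, `gh_key`,
#'   `combined_key`.
#' @export
pattern_vector <- function(profile, pathways = default_pathways(),
                           gh_map = default_gh_map()) {
  mono <- mucin_monosaccharides()
  cp <- mono %in% catabolizable_monosaccharides(profile, pathways)
  released <- gh_released(gh_map)
  present <- intersect(profile$gh_classes, names(released))
  gh <- mono %in% unique(unlist(released[present]))
  names(cp) <- names(gh) <- mono
  structure(
    list(cp = cp, gh = gh,
         cp_key = paste(as.integer(cp), collapse = ""),
         gh_key = paste(as.integer(gh), collapse = ""),
         combined_key = paste(c(as.integer(cp), as.integer(gh)),
                              collapse = "")),
    class = "pattern_vector"
  )
}

#' @export
print.pattern_vector <- function(x, ...) {
  cat("<pattern_vector> CP:", x$cp_key, "GH:", x$gh_key, "\n")
  invisible(x)
}

all_pattern_keys <- function(nbits) {
  vapply(seq_len(2^nbits) - 1L, function(k) {
    paste(as.integer(intToBits(k)[seq_len(nbits)]) , collapse = "")
  }, character(1))
}

#' Presence-pattern frequency tables
#'
#' Tabulates the CP, GH and combined presence patterns of a cohort over the
#' full category spaces (2^5 = 32 one-sided categories, 2^10 = 1024
#' combined), retaining never-observed categories as zero counts.
#'
#' @param profiles Named list of [genome_profile()]s.
#' @param pathways A `"pathway_set"`.
#' @param gh_map GH map data frame.
#' @return A list of class `"pattern_freqs"` with elements `cp`, `gh`,
#'   `combined`, each of class `"pattern_freq_table"` (named integer counts
#'   over all categories, with attributes `k` and `n`), plus the per-genome
#'   `vectors`.
#' @export
pattern_frequencies <- function(profiles, pathways = default_pathways(),
                                gh_map = default_gh_map()) {
  profiles <- validate_cohort(profiles)
  vecs <- lapply(profiles, pattern_vector, pathways = pathways,
                 gh_map = gh_map)
  tab <- function(keys, nbits) {
    space <- all_pattern_keys(nbits)
    counts <- table(factor(keys, levels = space))
    structure(stats::setNames(as.integer(counts), space),
              k = length(space), n = length(keys),
              class = "pattern_freq_table")
  }
  structure(
    list(
      cp = tab(vapply(vecs, `[[`, "", "cp_key"), 5L),
      gh = tab(vapply(vecs, `[[`, "", "gh_key"), 5L),
      combined = tab(vapply(vecs, `[[`, "", "combined_key"), 10L),
      vectors = vecs
    ),
    class = "pattern_freqs"
  )
}

#' @export
print.pattern_freq_table <- function(x, ...) {
  cat("<pattern_freq_table>", attr(x, "n"), "genomes over", attr(x, "k"),
      "categories;", sum(x > 0), "observed\n")
  invisible(x)
}

#' @export
print.pattern_freqs <- function(x, ...) {
  cat("<pattern_freqs>\n  CP:      ", sum(x$cp > 0), "of", attr(x$cp, "k"),
      "patterns observed\n  GH:      ", sum(x$gh > 0), "of",
      attr(x$gh, "k"), "observed\n  combined:", sum(x$combined > 0), "of",
      attr(x$combined, "k"), "observed\n")
  invisible(x)
}

#' @rdname pattern_frequencies
#' @param table A `"pattern_freq_table"`.
#' @export
observed_patterns <- function(table) sum(table > 0)

#' Pattern frequencies from a precomputed presence matrix
#'
#' For cohorts whose CP/GH calls were made elsewhere, accepts a per-genome
#' 0/1 matrix directly instead of re-deriving the calls from annotations.
#' Expected columns: `cp_<monosaccharide>` and `gh_<monosaccharide>` for
#' each of [mucin_monosaccharides()] (any additional columns, e.g.
#' `genome_id`, are ignored). A file path to such a TSV is also accepted.
#'
#' @param x Data frame or TSV path with the ten 0/1 columns.
#' @return A `"pattern_freqs"` list (without per-genome `vectors`).
#' @export
pattern_frequencies_from_matrix <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
  mono <- mucin_monosaccharides()
  cp_cols <- paste0("cp_", mono)
  gh_cols <- paste0("gh_", mono)
  missing_cols <- setdiff(c(cp_cols, gh_cols), names(x))
  if (length(missing_cols) > 0) {
    stop("presence matrix lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cp <- as.matrix(x[, cp_cols]) == 1
  gh <- as.matrix(x[, gh_cols]) == 1
  key <- function(m) apply(m, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- function(keys, nbits) {
    space <- all_pattern_keys(nbits)
    counts <- table(factor(keys, levels = space))
    structure(stats::setNames(as.integer(counts), space),
              k = length(space), n = length(keys),
              class = "pattern_freq_table")
  }
  structure(
    list(cp = tab(key(cp), 5L), gh = tab(key(gh), 5L),
         combined = tab(paste0(key(cp), key(gh)), 10L)),
    class = "pattern_freqs"
  )
}

#' Upper bound on combinable patterns
#'
#' The number of combined CP-GH patterns that could arise from independent
#' combination of the observed one-sided patterns: the product of the two
#' observed-category counts. Comparing the bound with the number of combined
#' patterns actually observed measures the interdependence of GH and CP
#' repertoires.
#'
#' @param n_cp,n_gh Observed CP and GH pattern counts (integers), or
#'   `"pattern_freq_table"`s.
#' @return Integer bound.
#' @export
combined_pattern_bound <- function(n_cp, n_gh) {
  if (inherits(n_cp, "pattern_freq_table")) n_cp <- observed_patterns(n_cp)
  if (inherits(n_gh, "pattern_freq_table")) n_gh <- observed_patterns(n_gh)
  as.integer(n_cp) * as.integer(n_gh)
}

#' Chi-squared test of pattern uniformity
#'
#' Pearson goodness-of-fit of the observed pattern counts against a uniform
#' expectation over the full category space (all 2^5 or 2^10 categories,
#' including never-observed ones), so the degrees of freedom are K - 1 (31
#' one-sided, 1023 combined). No continuity correction is applied. Large
#' statistics yield p-values below machine precision; [format_p_value()]
#' renders those as `"< 2.2e-16"`.
#'
#' @param table A `"pattern_freq_table"` (or a bare vector of category
#'   counts covering the full space).
#' @return A list of class `"chisq_uniform"` with `statistic`, `df`,
#'   `p_value`.
#' @export
chisq_uniform <- function(table) {
  counts <- as.integer(table)
  n <- sum(counts)
  if (n == 0) stop("no observations: cannot test an empty table")
  k <- length(counts)
  res <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / k, k), correct = FALSE)
  )
  structure(
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value)),
    class = "chisq_uniform"
  )
}

#' @rdname chisq_uniform
#' @param p A p-value.
#' @export
format_p_value <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4)
}

#' @export
print.chisq_uniform <- function(x, ...) {
  cat("Chi-squared uniformity test: X-squared =",
      format(x$statistic, digits = 6), ", df =", x$df,
      ", p-value", if (x$p_value < 2.2e-16) "< 2.2e-16" else
        paste("=", format(x$p_value, digits = 4)), "\n")
  invisible(x)
}

#' Write a pattern frequency table to TSV
#'
#' Two columns: the pattern bitstring (CP bits then GH bits, canonical
#' monosaccharide order) and its count. All categories are written,
#' including zero counts.
#'
#' @param table A `"pattern_freq_table"`.
#' @param path Output path.
#' @export
write_pattern_table <- function(table, path) {
  out <- data.frame(pattern = names(table), count = as.integer(table),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
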