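#' Screen a genome cohort for mucin glycan foraging
#'
#' The package's top-level analysis: runs the full inference chain on a
#' cohort of annotated genomes and returns one classed result object.
#' Stages, in order:
#'
#' 1. pathway calling - each monosaccharide's catabolic pathway variants are
#'    evaluated under the gap rule ([evaluate_variant()]);
#' 2. glycan cleavability - per-genome degradable-glycan sets and degrader
#'    classes ([cleavage_pattern()], [classify_degrader()]);
#' 3. pattern statistics - CP/GH/combined presence-pattern frequencies with
#'    chi-squared uniformity tests ([pattern_frequencies()],
#'    [chisq_uniform()]);
#' 4. cross-feeding - donor/acceptor roles and feeding edges
#'    ([role_table()], [feeding_edges()]);
#' 5. mutualism - mutualistic pair detection and participation
#'    ([find_mutualistic_pairs()]).
#'
#' @param profiles Named list of [genome_profile()]s (cohort).
#' @param library A `"glycan_library"`.
#' @param gh_map GH map data frame.
#' @param pathways A `"pathway_set"`.
#' @param strict_sulfatase Require the sulfatase for sulfated glycans?
#' @param exclude_peptide Exclude the peptide attachment from cleavability
#'   requirements?
#' @param snap Snap between-bin degradation counts to the nearest class?
#' @return An object of class `"mucin_screen"` with components `patterns`,
#'   `chisq`, `roles`, `role_summary`, `edges`, `degraders`, `pairs`,
#'   `participation` and `counts` (headline numerators/denominators).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_genomes = 30, seed = 7))
#' scr <- mucin_screen(cohort)
#' scr
mucin_screen <- function(profiles, library = default_glycan_library(),
                         gh_map = default_gh_map(),
                         pathways = default_pathways(),
                         strict_sulfatase = FALSE, exclude_peptide = TRUE,
                         snap = FALSE) {
  profiles <- validate_cohort(profiles)
  check_feature_ids(profiles, gh_map)
  n <- length(profiles)

  patterns <- pattern_frequencies(profiles, pathways, gh_map)
  chisq <- list(cp = chisq_uniform(patterns$cp),
                gh = chisq_uniform(patterns$gh),
                combined = chisq_uniform(patterns$combined))

  cleavage <- lapply(profiles, cleavage_pattern, library = library,
                     gh_map = gh_map, strict_sulfatase = strict_sulfatase,
                     exclude_peptide = exclude_peptide)
  n_glycans <- vapply(cleavage, `[[`, integer(1), "n")
  degraders <- data.frame(
    genome_id = cohort_ids(profiles),
    n_glycans = unname(n_glycans),
    class = classify_degrader(unname(n_glycans),
                              library_size = length(library), snap = snap),
    stringsAsFactors = FALSE
  )

  roles <- role_table(profiles, pathways, gh_map)
  rsum <- role_summary(roles)
  edges <- feeding_edges(profiles, pathways, gh_map)

  pairs <- find_mutualistic_pairs(profiles, library, gh_map,
                                  strict_sulfatase)
  participation <- mutualism_participation(pairs, profiles)

  with_gh <- sum(vapply(profiles, function(p) {
    length(setdiff(p$gh_classes, SULFATASE_ID)) > 0
  }, logical(1)))
  with_cp <- sum(vapply(patterns$vectors, function(v) any(v$cp), logical(1)))
  counts <- list(
    n_genomes = n,
    with_gh = c(n = with_gh, total = n),
    with_cp = c(n = with_cp, total = n),
    partial_pathway = c(n = rsum$n_partial, total = n),
    glycan_degrading = c(n = sum(n_glycans > 0), total = n),
    mutualism_participants = c(n = participation$n, total = n)
  )

  structure(
    list(patterns = patterns, chisq = chisq, cleavage = cleavage,
         degraders = degraders, roles = roles, role_summary = rsum,
         edges = edges, pairs = pairs, participation = participation,
         counts = counts, library_size = length(library)),
    class = "mucin_screen"
  )
}

check_feature_ids <- function(profiles, gh_map) {
  known <- c(unique(gh_map$gh_class), SULFATASE_ID)
  offenders <- lapply(profiles, function(p) setdiff(p$gh_classes, known))
  bad <- vapply(offenders, length, integer(1)) > 0
  if (any(bad)) {
    msg <- vapply(which(bad), function(i) {
      paste0(profiles[[i]]$genome_id, ": ",
             paste(offenders[[i]], collapse = ", "))
    }, character(1))
    stop("GH class ids not present in the GH map:\n  ",
         paste(msg, collapse = "\n  "))
  }
  invisible(TRUE)
}

pct <- function(x) sprintf("%d/%d (%.0f%%)", x["n"], x["total"],
                           100 * x["n"] / x["total"])

#' @export
print.mucin_screen <- function(x, ...) {
  cat("Mucin glycan foraging screen of", x$counts$n_genomes, "genomes\n")
  cat("  with >=1 glycan-cleaving GH: ", pct(x$counts$with_gh), "\n")
  cat("  with >=1 catabolic pathway:  ", pct(x$counts$with_cp), "\n")
  cat("  partial pathway (>=1 role):  ", pct(x$counts$partial_pathway), "\n")
  cat("  degrading >=1 glycan:        ", pct(x$counts$glycan_degrading), "\n")
  cat("  in mutualistic pairs:        ",
      pct(x$counts$mutualism_participants), "\n")
  invisible(x)
}

#' @export
summary.mucin_screen <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPresence patterns (", attr(x$patterns$cp, "k"),
      " categories per side):\n", sep = "")
  cat("  CP:", observed_patterns(x$patterns$cp), "observed; ")
  print(x$chisq$cp)
  cat("  GH:", observed_patterns(x$patterns$gh), "observed; ")
  print(x$chisq$gh)
  cat("  combined:", observed_patterns(x$patterns$combined),
      "observed (bound",
      combined_pattern_bound(x$patterns$cp, x$patterns$gh), "); ")
  print(x$chisq$combined)
  cat("\nOrganism classes:",
      paste(names(x$role_summary$class_counts),
            x$role_summary$class_counts, sep = " = ", collapse = ", "), "\n")
  cat("Donor roles:", x$role_summary$n_donor_roles,
      "| acceptor roles:", x$role_summary$n_acceptor_roles,
      "| feeding edges:", nrow(x$edges), "\n")
  cat("\nDegrader classes:\n")
  print(table(x$degraders$class))
  cat("\nMutualistic pairs:", length(x$pairs))
  hb <- sum(vapply(x$pairs, `[[`, logical(1), "is_highly_beneficial"))
  cat(" (", hb, " highly beneficial)\n", sep = "")
  invisible(x)
}

#' @export
plot.mucin_screen <- function(x, ...) {
  classes <- c("non-degrader", "specialist", "intermediate", "generalist",
               "unbinned")
  counts <- vapply(classes, function(cl) sum(x$degraders$class == cl),
                   integer(1))
  graphics::barplot(counts, names.arg = classes, las = 2,
                    ylab = "genomes",
                    main = "Glycan degradation breadth", ...)
  invisible(x)
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON documents with optional fields
#' `profiles`, `library`, `gh_map`, `pathways` (input paths; package
#' defaults are used where omitted), flags `strict_sulfatase`,
#' `exclude_peptide`, `snap`, and `out_dir`. Relative paths resolve against
#' the configuration file's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  structure(
    list(profiles = resolve(doc$profiles), library = resolve(doc$library),
         gh_map = resolve(doc$gh_map), pathways = resolve(doc$pathways),
         strict_sulfatase = isTRUE(doc$strict_sulfatase),
         exclude_peptide = !isFALSE(doc$exclude_peptide),
         snap = isTRUE(doc$snap),
         out_dir = doc$out_dir %||% "."),
    class = "run_config"
  )
}

#' Run the full pipeline and write all outputs
#'
#' Loads the configured inputs (validating them before any output is
#' written), runs [mucin_screen()] and writes tab-separated pattern, role,
#' edge, degrader and pair tables plus a machine-readable `summary.json`
#' reporting every headline count with numerator and denominator. Re-running
#' with identical inputs produces byte-identical outputs.
#'
#' @param config A `"run_config"` (see [read_run_config()]), or a path to a
#'   configuration file.
#' @param out_dir Output directory (created if needed); overrides the
#'   configuration's `out_dir`.
#' @return The `"mucin_screen"` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  for (field in c("profiles", "library", "gh_map", "pathways")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured ", field, " file not found: ", p)
    }
  }
  if (is.null(config$profiles)) stop("run configuration names no profiles")
  profiles <- read_genome_profiles(config$profiles)
  gh_map <- if (is.null(config$gh_map)) default_gh_map()
    else load_gh_map(config$gh_map)
  library <- if (is.null(config$library)) default_glycan_library()
    else load_glycan_library(config$library)
  pathways <- if (is.null(config$pathways)) default_pathways()
    else load_pathways(config$pathways)

  scr <- mucin_screen(profiles, library, gh_map, pathways,
                      strict_sulfatase = config$strict_sulfatase,
                      exclude_peptide = config$exclude_peptide,
                      snap = config$snap)

  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pattern_table(scr$patterns$cp, file.path(out_dir, "cp_patterns.tsv"))
  write_pattern_table(scr$patterns$gh, file.path(out_dir, "gh_patterns.tsv"))
  write_pattern_table(scr$patterns$combined,
                      file.path(out_dir, "combined_patterns.tsv"))
  utils::write.table(scr$roles, file.path(out_dir, "roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scr$edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scr$degraders, file.path(out_dir, "degraders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pair_table(scr$pairs), file.path(out_dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  chisq_out <- lapply(scr$chisq, function(ct) {
    list(statistic = ct$statistic, df = ct$df,
         p_value = format_p_value(ct$p_value))
  })
  summary_doc <- list(
    n_genomes = scr$counts$n_genomes,
    counts = lapply(scr$counts[-1], function(x) {
      list(n = unname(x["n"]), total = unname(x["total"]),
           fraction = unname(x["n"] / x["total"]))
    }),
    observed_patterns = list(
      cp = observed_patterns(scr$patterns$cp),
      gh = observed_patterns(scr$patterns$gh),
      combined = observed_patterns(scr$patterns$combined),
      combined_bound = combined_pattern_bound(scr$patterns$cp,
                                              scr$patterns$gh)
    ),
    chisq = chisq_out,
    organism_classes = as.list(scr$role_summary$class_counts),
    n_mutualistic_pairs = length(scr$pairs)
  )
  jsonlite::write_json(summary_doc, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(scr)
}
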