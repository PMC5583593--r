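#' Construct a catabolic pathway variant
#'
#' A catabolic pathway (CP) is the ordered chain of reactions from an
#' intracellular monosaccharide to an intermediate of central carbohydrate
#' metabolism. Each step carries the canonical gene symbols encoding the
#' reaction plus any gene symbols accepted as non-orthologous replacements
#' (functional analogues unrelated by orthology, e.g. galY standing in for
#' galT). A step is covered when any of its canonical or replacement genes is
#' present; gene symbols are matched case-insensitively. Converging routes
#' are linearized: each route is its own variant.
#'
#' @param id Variant identifier, e.g. `"Gal.Leloir"`.
#' @param monosaccharide One of [mucin_monosaccharides()].
#' @param steps List of steps; each step is a list with elements `id`
#'   (character), `canonical` (non-empty character vector) and optionally
#'   `replacement` (character vector).
#' @param transporters Character vector of transporter symbols associated
#'   with the route (informational; transporter absence never vetoes pathway
#'   presence).
#' @return An object of class `"pathway_variant"`.
#' @export
pathway_variant <- function(id, monosaccharide, steps,
                            transporters = character(0)) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!monosaccharide %in% mucin_monosaccharides()) {
    stop("unknown monosaccharide: ", monosaccharide)
  }
  if (length(steps) < 1L) stop("variant '", id, "' has no steps")
  steps <- lapply(steps, function(s) {
    if (is.null(s$id) || is.null(s$canonical) || length(s$canonical) == 0) {
      stop("each step needs an id and non-empty canonical genes")
    }
    list(id = s$id,
         canonical = as.character(s$canonical),
         replacement = as.character(s$replacement %||% character(0)))
  })
  structure(
    list(id = id, monosaccharide = monosaccharide, steps = steps,
         transporters = as.character(transporters)),
    class = "pathway_variant"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pathway_variant <- function(x, ...) {
  cat("<pathway_variant>", x$id, "->", x$monosaccharide, "\n")
  for (s in x$steps) {
    cat("  ", s$id, ": ", paste(s$canonical, collapse = "|"), sep = "")
    if (length(s$replacement) > 0) {
      cat(" (repl: ", paste(s$replacement, collapse = "|"), ")", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Default catabolic pathway definitions
#'
#' Encodes the known routes from each mucin monosaccharide to central
#' metabolism as replaceable data:
#'
#' * `Fuc.fucIKA` - fucose isomerase/fuculokinase/fuculose-phosphate
#'   aldolase route to lactaldehyde + DHAP;
#' * `Fuc.fcl` - the oxidative fucolactone route (`fclABCDE`), with the
#'   bifunctional FclA2/FclD2 replacing both FclA and FclD and FclE2
#'   replacing FclE;
#' * `Gal.Leloir` - galactokinase, uridylyltransferase (GalT, or its
#'   non-orthologous replacement GalY), UDP-glucose 4-epimerase;
#' * `Gal.tagatose6P` - galactose-6P isomerase (LacAB), tagatose-6P kinase,
#'   tagatose-1,6-bisP aldolase;
#' * `GalNAc.aga` - GalNAc-6P deacetylase (AgaA), galactosamine-6P
#'   isomerase/deaminase (AgaS), then the shared tagatose-6P kinase and
#'   aldolase tail;
#' * `GlcNAc.nag` - GlcNAc kinase, GlcNAc-6P deacetylase (NagA),
#'   glucosamine-6P deaminase (NagB);
#' * `Neu5Ac.NanE` - Neu5Ac lyase, ManNAc kinase, ManNAc-6P 2-epimerase
#'   (NanE), then the shared NagA/NagB tail;
#' * `Neu5Ac.NanE-II` - Neu5Ac lyase, GlcNAc 2-epimerase (NanE-II), then the
#'   shared NagK/NagA/NagB tail;
#' * `Gal.gnb`, `GalNAc.gnb`, `GlcNAc.gnb` - the same chains entered through
#'   the intracellular hydrolysis of lacto-/galacto-N-biose (GnbG or LnbP),
#'   the disaccharide route imported by GnbPTS or LnbABC.
#'
#' Shared tails (the tagatose-6P tail of Gal/GalNAc; the Nag tail of
#' GlcNAc/Neu5Ac) are listed in each variant's own chain, so the gap rule
#' sees the full reaction sequence.
#'
#' @return An object of class `"pathway_set"` (named list of
#'   [pathway_variant()]s).
#' @export
default_pathways <- function() {
  step <- function(id, canonical, replacement = character(0)) {
    list(id = id, canonical = canonical, replacement = replacement)
  }
  leloir <- list(
    step("galactokinase", "galK"),
    step("uridylyltransferase", "galT", "galY"),
    step("UDP-glucose-4-epimerase", "galE")
  )
  tagatose_tail <- list(
    step("tagatose-6P-kinase", c("lacC", "agaK")),
    step("tagatose-16bP-aldolase", c("lacD", "agaY", "gatY"))
  )
  aga <- c(list(
    step("GalNAc-6P-deacetylase", "agaA"),
    step("galactosamine-6P-isomerase", "agaS", "agaI")
  ), tagatose_tail)
  nag_tail <- list(
    step("GlcNAc-6P-deacetylase", "nagA"),
    step("glucosamine-6P-deaminase", "nagB", c("nagB2"))
  )
  nag <- c(list(step("GlcNAc-kinase", c("nagK"), c("nagK2"))), nag_tail)
  gnb_entry <- step("biose-hydrolysis", c("gnbG", "lnbP"))
  variants <- list(
    pathway_variant("Fuc.fucIKA", "Fuc", list(
      step("fucose-isomerase", "fucI"),
      step("fuculokinase", "fucK"),
      step("fuculose-P-aldolase", "fucA")
    ), transporters = c("fucP1", "fucP2", "fucABC")),
    pathway_variant("Fuc.fcl", "Fuc", list(
      step("fucose-dehydrogenase", "fclA", "fclA2D2"),
      step("fuconolactonase", "fclB"),
      step("fuconate-dehydratase", "fclC"),
      step("keto-deoxy-fuconate-dehydrogenase", "fclD", "fclA2D2"),
      step("keto-deoxy-fuconate-aldolase", "fclE", "fclE2")
    ), transporters = c("fucP1", "fucABC")),
    pathway_variant("Gal.Leloir", "Gal", leloir,
                    transporters = c("galP1", "galP2", "galP3", "mglABC",
                                     "galPTS")),
    pathway_variant("Gal.tagatose6P", "Gal", c(list(
      step("galactose-6P-isomerase", c("lacA", "lacB"))
    ), tagatose_tail), transporters = c("galPTS")),
    pathway_variant("Gal.gnb", "Gal", c(list(gnb_entry), leloir),
                    transporters = c("gnbPTS", "lnbABC")),
    pathway_variant("GalNAc.aga", "GalNAc", aga,
                    transporters = c("agaPTS", "gnbPTS", "lnbABC")),
    pathway_variant("GalNAc.gnb", "GalNAc", c(list(gnb_entry), aga),
                    transporters = c("gnbPTS", "lnbABC")),
    pathway_variant("GlcNAc.nag", "GlcNAc", nag,
                    transporters = c("nagE", "nagP", "ngcEFG", "ngcABCD",
                                     "gnbPTS", "lnbABC")),
    pathway_variant("GlcNAc.gnb", "GlcNAc", c(list(gnb_entry), nag),
                    transporters = c("gnbPTS", "lnbABC")),
    pathway_variant("Neu5Ac.NanE", "Neu5Ac", c(list(
      step("Neu5Ac-lyase", "nanA"),
      step("ManNAc-kinase", "nanK"),
      step("ManNAc-6P-epimerase", "nanE")
    ), nag_tail), transporters = c("nanT", "nanX", "nanABC", "nanABC2",
                                   "neuT")),
    pathway_variant("Neu5Ac.NanE-II", "Neu5Ac", c(list(
      step("Neu5Ac-lyase", "nanA"),
      step("GlcNAc-epimerase", "nanE2")
    ), nag), transporters = c("nanT", "nanX", "nanABC", "nanABC2", "neuT"))
  )
  structure(stats::setNames(variants, vapply(variants, `[[`, "", "id")),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("<pathway_set> with", length(x), "variants:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write pathway definitions (JSON or YAML)
#'
#' Pathway sets are serialized as a list of records
#' `{variant_id, monosaccharide, steps: [{id, canonical_genes,
#' replacement_genes}], transporters}`. The format is chosen by file
#' extension (`.json`, `.yml`/`.yaml`).
#'
#' @param path File path.
#' @return A `"pathway_set"`; the writer returns `path` invisibly.
#' @export
load_pathways <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  variants <- lapply(doc, function(rec) {
    steps <- lapply(rec$steps, function(s) {
      list(id = s$id, canonical = unlist(s$canonical_genes),
           replacement = unlist(s$replacement_genes))
    })
    pathway_variant(rec$variant_id, rec$monosaccharide, steps,
                    transporters = unlist(rec$transporters) %||% character(0))
  })
  structure(stats::setNames(variants, vapply(variants, `[[`, "", "id")),
            class = "pathway_set")
}

#' @rdname load_pathways
#' @param pathways A `"pathway_set"`.
#' @export
write_pathways <- function(pathways, path) {
  doc <- lapply(unclass(pathways), function(v) {
    list(
      variant_id = v$id,
      monosaccharide = v$monosaccharide,
      steps = lapply(v$steps, function(s) {
        rec <- list(id = s$id, canonical_genes = as.list(s$canonical))
        if (length(s$replacement) > 0) {
          rec$replacement_genes <- as.list(s$replacement)
        }
        rec
      }),
      transporters = as.list(v$transporters)
    )
  })
  names(doc) <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

step_missing <- function(variant, present_genes) {
  present <- tolower(present_genes)
  vapply(variant$steps, function(s) {
    !any(tolower(c(s$canonical, s$replacement)) %in% present)
  }, logical(1))
}

#' Locate gaps in a pathway chain
#'
#' A gap is a maximal run of consecutive reaction steps for which no
#' encoding gene (canonical or replacement) is present; its length is the
#' number of successive uncovered reactions. All chain positions, including
#' the first and last step, are treated identically.
#'
#' @param variant A [pathway_variant()].
#' @param present_genes Character vector of gene symbols present in the
#'   genome (case-insensitive).
#' @return An object of class `"gap_report"`: a list with `variant_id`,
#'   `missing_steps` (integer indices), `gap_runs` (data frame with columns
#'   `start`, `length`), `transporter_found`, and `decision`
#'   (`NA` until set by [evaluate_variant()]).
#' @export
find_gaps <- function(variant, present_genes) {
  missing <- step_missing(variant, present_genes)
  runs <- rle(missing)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  gap_runs <- data.frame(start = starts[keep], length = runs$lengths[keep])
  structure(
    list(variant_id = variant$id,
         missing_steps = which(missing),
         gap_runs = gap_runs,
         transporter_found = any(tolower(variant$transporters) %in%
                                   tolower(present_genes)),
         decision = NA),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>", x$variant_id, "-",
      if (isTRUE(x$decision)) "present" else if (isFALSE(x$decision)) "absent"
      else "undecided", "\n")
  if (nrow(x$gap_runs) == 0) {
    cat("  no gaps\n")
  } else {
    cat("  gaps at:", paste0(x$gap_runs$start, "(len ", x$gap_runs$length,
                             ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Decide pathway presence from its gap structure
#'
#' A catabolic pathway is called present when no more than two gaps are
#' found and every gap spans at most one reaction. Replacement genes are
#' honored before gap counting ([find_gaps()] treats a step as covered by
#' canonical or replacement genes alike), matching the re-evaluation pass
#' performed after a search for non-orthologous displacements.
#'
#' @inheritParams find_gaps
#' @return A `"gap_report"` with `decision` set to `TRUE` (present) or
#'   `FALSE` (absent).
#' @export
evaluate_variant <- function(variant, present_genes) {
  report <- find_gaps(variant, present_genes)
  report$decision <- nrow(report$gap_runs) <= 2L &&
    (nrow(report$gap_runs) == 0L || max(report$gap_runs$length) <= 1L)
  report
}

#' Monosaccharides a genome can catabolize
#'
#' A monosaccharide is catabolizable when at least one of its pathway
#' variants evaluates as present under the gap rule.
#'
#' @param profile A [genome_profile()].
#' @param pathways A `"pathway_set"`.
#' @return Character vector of catabolizable monosaccharides (subset of
#'   [mucin_monosaccharides()], canonical order).
#' @export
catabolizable_monosaccharides <- function(profile, pathways = default_pathways()) {
  present <- vapply(unclass(pathways), function(v) {
    evaluate_variant(v, profile$genes)$decision
  }, logical(1))
  monos <- vapply(unclass(pathways), `[[`, "", "monosaccharide")
  out <- unique(monos[present])
  mucin_monosaccharides()[mucin_monosaccharides() %in% out]
}
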