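#' Construct a genome annotation profile
#'
#' A genome profile is a genome's binary feature sets: the GH classes it
#' encodes, its pathway/reaction gene symbols, its transporter symbols, and
#' an ordered taxonomic lineage (phylum down to strain). Any set may be
#' empty.
#'
#' @param genome_id Unique genome identifier within a cohort.
#' @param lineage Ordered character vector of taxon labels.
#' @param gh_classes Character vector of GH class ids (see
#'   [default_gh_map()]); may include [sulfatase_id()].
#' @param genes Character vector of gene symbols.
#' @param transporters Character vector of transporter symbols.
#' @return An object of class `"genome_profile"`.
#' @export
#' @examples
#' genome_profile("g1", lineage = c("Bacteroidetes", "Bacteroides"),
#'                gh_classes = "neuraminidase", genes = c("nanA", "nanK"))
genome_profile <- function(genome_id, lineage = character(0),
                           gh_classes = character(0),
                           genes = character(0),
                           transporters = character(0)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            nzchar(genome_id))
  structure(
    list(genome_id = genome_id,
         lineage = as.character(lineage),
         gh_classes = unique(as.character(gh_classes)),
         genes = unique(as.character(genes)),
         transporters = unique(as.character(transporters))),
    class = "genome_profile"
  )
}

#' @export
print.genome_profile <- function(x, ...) {
  cat("<genome_profile>", x$genome_id, "\n")
  if (length(x$lineage) > 0) {
    cat("  lineage:", paste(x$lineage, collapse = " > "), "\n")
  }
  cat("  GH classes:", length(x$gh_classes),
      "| genes:", length(x$genes),
      "| transporters:", length(x$transporters), "\n")
  invisible(x)
}

validate_cohort <- function(profiles) {
  if (length(profiles) == 0) stop("cohort is empty")
  ok <- vapply(profiles, inherits, logical(1), "genome_profile")
  if (!all(ok)) stop("cohort must be a list of genome_profile objects")
  ids <- vapply(profiles, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(stats::setNames(profiles, ids))
}

#' @rdname genome_profile
#' @param profiles List of `"genome_profile"` objects.
#' @export
cohort_ids <- function(profiles) {
  vapply(profiles, `[[`, "", "genome_id", USE.NAMES = FALSE)
}

#' Read and write genome profiles
#'
#' Two tab-separated dialects are accepted and auto-detected by the header
#' row:
#'
#' * long: columns `genome_id`, `feature_type` (one of `gh`, `gene`,
#'   `transporter`, `taxon`), `feature_id`; `taxon` rows, in file order,
#'   form the lineage;
#' * wide: column `genome_id`, optional `lineage` (taxa joined by `;`), and
#'   one 0/1 column per feature with a `gh:`, `gene:` or `transporter:`
#'   prefix.
#'
#' Writers and readers round-trip losslessly.
#'
#' @param path Path to a TSV file.
#' @return `read_genome_profiles()` returns a named list of
#'   [genome_profile()]s; writers return `path` invisibly.
#' @export
read_genome_profiles <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if ("feature_type" %in% header) {
    read_profiles_long(path)
  } else {
    read_profiles_wide(path)
  }
}

read_profiles_long <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "feature_type", "feature_id")
  if (!all(need %in% names(tab))) {
    stop("long profile table must have columns genome_id, feature_type, feature_id")
  }
  bad <- setdiff(unique(tab$feature_type), c("gh", "gene", "transporter", "taxon"))
  if (length(bad) > 0) {
    stop("unknown feature_type values: ", paste(bad, collapse = ", "))
  }
  profiles <- lapply(split(tab, tab$genome_id), function(rows) {
    genome_profile(
      rows$genome_id[1],
      lineage = rows$feature_id[rows$feature_type == "taxon"],
      gh_classes = rows$feature_id[rows$feature_type == "gh"],
      genes = rows$feature_id[rows$feature_type == "gene"],
      transporters = rows$feature_id[rows$feature_type == "transporter"]
    )
  })
  # preserve file order of genomes
  profiles <- profiles[unique(tab$genome_id)]
  validate_cohort(unname(profiles))
}

read_profiles_wide <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genome_id" %in% names(tab)) {
    stop("wide profile table must have a genome_id column")
  }
  feat_cols <- setdiff(names(tab), c("genome_id", "lineage"))
  types <- sub(":.*$", "", feat_cols)
  bad <- setdiff(unique(types), c("gh", "gene", "transporter"))
  if (length(bad) > 0) {
    stop("wide profile columns must be prefixed gh:, gene: or transporter:; found: ",
         paste(bad, collapse = ", "))
  }
  ids <- sub("^[^:]*:", "", feat_cols)
  profiles <- lapply(seq_len(nrow(tab)), function(i) {
    on <- as.logical(unlist(tab[i, feat_cols, drop = TRUE]) == 1)
    lineage <- if ("lineage" %in% names(tab) && nzchar(tab$lineage[i])) {
      strsplit(tab$lineage[i], ";", fixed = TRUE)[[1]]
    } else character(0)
    genome_profile(
      tab$genome_id[i], lineage = lineage,
      gh_classes = ids[on & types == "gh"],
      genes = ids[on & types == "gene"],
      transporters = ids[on & types == "transporter"]
    )
  })
  validate_cohort(profiles)
}

#' @rdname read_genome_profiles
#' @param profiles Named list of [genome_profile()]s.
#' @param format `"long"` or `"wide"`.
#' @export
write_genome_profiles <- function(profiles, path, format = c("long", "wide")) {
  profiles <- validate_cohort(profiles)
  format <- match.arg(format)
  if (format == "long") {
    rows <- lapply(profiles, function(p) {
      data.frame(
        genome_id = p$genome_id,
        feature_type = c(rep("taxon", length(p$lineage)),
                         rep("gh", length(p$gh_classes)),
                         rep("gene", length(p$genes)),
                         rep("transporter", length(p$transporters))),
        feature_id = c(p$lineage, p$gh_classes, p$genes, p$transporters),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    feats <- unique(unlist(lapply(profiles, function(p) {
      c(paste0("gh:", p$gh_classes), paste0("gene:", p$genes),
        paste0("transporter:", p$transporters))
    })))
    feats <- sort(feats)
    mat <- t(vapply(profiles, function(p) {
      as.integer(feats %in% c(paste0("gh:", p$gh_classes),
                              paste0("gene:", p$genes),
                              paste0("transporter:", p$transporters)))
    }, integer(length(feats))))
    out <- data.frame(
      genome_id = cohort_ids(profiles),
      lineage = vapply(profiles, function(p) paste(p$lineage, collapse = ";"),
                       character(1)),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    out <- cbind(out, as.data.frame(mat, check.names = FALSE))
    names(out) <- c("genome_id", "lineage", feats)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
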