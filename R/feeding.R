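#' Donor/acceptor role assignment
#'
#' For each monosaccharide a genome is a *donor* when it encodes a releasing
#' GH but no catabolic pathway (it liberates the sugar for others), an
#' *acceptor* when it has the pathway but no releasing GH (it consumes what
#' others liberate), *self-sufficient* when it has both, and *uninvolved*
#' when it has neither. At the organism level a genome is classed
#' `donor-only`, `acceptor-only`, `mixed` (at least one donor and one
#' acceptor role) or `none`.
#'
#' @param profile A [genome_profile()].
#' @param pathways A `"pathway_set"`.
#' @param gh_map GH map data frame.
#' @return An object of class `"role_assignment"`: list with `genome_id`,
#'   `roles` (named character over the five monosaccharides) and
#'   `organism_class`.
#' @export
assign_roles <- function(profile, pathways = default_pathways(),
                         gh_map = default_gh_map()) {
  pv <- pattern_vector(profile, pathways, gh_map)
  roles <- ifelse(pv$gh & !pv$cp, "donor",
                  ifelse(pv$cp & !pv$gh, "acceptor",
                         ifelse(pv$cp & pv$gh, "self-sufficient",
                                "uninvolved")))
  names(roles) <- mucin_monosaccharides()
  has_donor <- any(roles == "donor")
  has_acceptor <- any(roles == "acceptor")
  organism_class <- if (has_donor && has_acceptor) "mixed"
    else if (has_donor) "donor-only"
    else if (has_acceptor) "acceptor-only"
    else "none"
  structure(
    list(genome_id = profile$genome_id, roles = roles,
         organism_class = organism_class),
    class = "role_assignment"
  )
}

#' @export
print.role_assignment <- function(x, ...) {
  cat("<role_assignment>", x$genome_id, "-", x$organism_class, "\n")
  involved <- x$roles[x$roles %in% c("donor", "acceptor")]
  if (length(involved) > 0) {
    cat(" ", paste(names(involved), involved, sep = ": ", collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Role table for a cohort
#'
#' @param profiles Named list of [genome_profile()]s.
#' @inheritParams assign_roles
#' @return Data frame with one row per genome: `genome_id`, one column per
#'   monosaccharide holding its role, and `organism_class`.
#' @export
role_table <- function(profiles, pathways = default_pathways(),
                       gh_map = default_gh_map()) {
  profiles <- validate_cohort(profiles)
  assignments <- lapply(profiles, assign_roles, pathways = pathways,
                        gh_map = gh_map)
  roles <- t(vapply(assignments, `[[`, character(5), "roles"))
  out <- data.frame(genome_id = cohort_ids(profiles), roles,
                    organism_class = vapply(assignments, `[[`, "",
                                            "organism_class"),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  names(out) <- c("genome_id", mucin_monosaccharides(), "organism_class")
  out
}

#' Summarize donor/acceptor involvement
#'
#' Tallies organism classes and total donor/acceptor roles (one role per
#' genome-monosaccharide combination), with computed fractions over the
#' cohort size.
#'
#' @param roles A data frame from [role_table()].
#' @return List with `n_genomes`, `class_counts`, `n_donor_roles`,
#'   `n_acceptor_roles`, `n_partial` (genomes with at least one donor or
#'   acceptor role) and `fraction_partial`.
#' @export
role_summary <- function(roles) {
  mono <- mucin_monosaccharides()
  role_mat <- as.matrix(roles[, mono, drop = FALSE])
  n_donor <- sum(role_mat == "donor")
  n_acceptor <- sum(role_mat == "acceptor")
  partial <- rowSums(role_mat == "donor" | role_mat == "acceptor") > 0
  classes <- c("donor-only", "acceptor-only", "mixed", "none")
  list(
    n_genomes = nrow(roles),
    class_counts = vapply(classes, function(cl) {
      sum(roles$organism_class == cl)
    }, integer(1)),
    n_donor_roles = n_donor,
    n_acceptor_roles = n_acceptor,
    n_partial = sum(partial),
    fraction_partial = sum(partial) / nrow(roles)
  )
}

#' Enumerate potential cross-feeding edges
#'
#' A directed edge donor -> acceptor exists for every ordered genome pair
#' sharing at least one monosaccharide for which the first genome is a donor
#' and the second an acceptor. Self-pairs are excluded; genomes
#' self-sufficient for a monosaccharide generate no edge for it.
#'
#' @param profiles Named list of [genome_profile()]s (at least 2).
#' @inheritParams assign_roles
#' @return Data frame with columns `donor`, `acceptor`, `monosaccharides`
#'   (comma-joined, canonical order).
#' @export
feeding_edges <- function(profiles, pathways = default_pathways(),
                          gh_map = default_gh_map()) {
  profiles <- validate_cohort(profiles)
  if (length(profiles) < 2) stop("need at least two genomes")
  roles <- role_table(profiles, pathways, gh_map)
  mono <- mucin_monosaccharides()
  role_mat <- as.matrix(roles[, mono, drop = FALSE])
  rownames(role_mat) <- roles$genome_id
  donors <- role_mat == "donor"
  acceptors <- role_mat == "acceptor"
  edges <- list()
  for (i in seq_len(nrow(role_mat))) {
    if (!any(donors[i, ])) next
    for (j in seq_len(nrow(role_mat))) {
      if (i == j) next
      shared <- mono[donors[i, ] & acceptors[j, ]]
      if (length(shared) > 0) {
        edges[[length(edges) + 1L]] <- data.frame(
          donor = roles$genome_id[i], acceptor = roles$genome_id[j],
          monosaccharides = paste(shared, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(edges) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      monosaccharides = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Taxon-level donor/acceptor matrix
#'
#' Aggregates donor and acceptor role counts by a taxon level of the
#' lineage, heat-map ready.
#'
#' @param profiles Named list of [genome_profile()]s.
#' @param roles Data frame from [role_table()].
#' @param level Lineage position to aggregate on (1 = first/coarsest label).
#' @return Data frame with columns `taxon`, `n_genomes`, `donor_roles`,
#'   `acceptor_roles`.
#' @export
taxon_role_matrix <- function(profiles, roles = NULL, level = 1L) {
  profiles <- validate_cohort(profiles)
  if (is.null(roles)) roles <- role_table(profiles)
  taxa <- vapply(profiles, function(p) {
    if (length(p$lineage) >= level) p$lineage[level] else "unclassified"
  }, character(1))
  mono <- mucin_monosaccharides()
  role_mat <- as.matrix(roles[, mono, drop = FALSE])
  by_taxon <- split(seq_along(profiles), taxa)
  out <- lapply(names(by_taxon), function(tx) {
    idx <- by_taxon[[tx]]
    data.frame(taxon = tx, n_genomes = length(idx),
               donor_roles = sum(role_mat[idx, , drop = FALSE] == "donor"),
               acceptor_roles = sum(role_mat[idx, , drop = FALSE] ==
                                      "acceptor"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
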