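# Independent naive oracles and small fixture builders. These deliberately
# re-derive results along different code paths than the implementation
# (per-bond class lookups, double loops, direct predicates on missing-step
# vectors) so agreement is informative.

# Gap rule as a direct predicate on the missing-step vector: present iff at
# most two steps are missing and no two missing steps are adjacent.
oracle_gap_present <- function(missing) {
  sum(missing) <= 2 &&
    (length(missing) < 2 || !any(missing[-1] & missing[-length(missing)]))
}

# Chain of `len` anonymous steps with per-step singleton genes s1..s<len>.
toy_chain <- function(len, monosaccharide = "Fuc") {
  steps <- lapply(seq_len(len), function(i) {
    list(id = paste0("step", i), canonical = paste0("s", i))
  })
  pathway_variant(paste0("toy", len), monosaccharide, steps)
}

# Genes covering all but the given step indices of a toy chain.
toy_genes <- function(len, missing_idx) {
  paste0("s", setdiff(seq_len(len), missing_idx))
}

# Naive per-glycan cleavability: walk each glycan's bonds and look up the
# classes cleaving that exact bond, never forming the capability union.
oracle_degradable <- function(profile, library, gh_map) {
  ids <- character(0)
  for (g in unclass(library)) {
    ok <- TRUE
    for (b in unique(g$bonds)) {
      if (is_peptide_bond(b)) next
      classes <- gh_map$gh_class[gh_map$bond == b]
      if (!any(classes %in% profile$gh_classes)) {
        ok <- FALSE
        break
      }
    }
    if (ok) ids <- c(ids, g$id)
  }
  ids
}

# Brute-force feeding edges: double loop over genomes x monosaccharides
# using raw GH/CP presence, independent of role_table.
oracle_edges <- function(profiles, pathways, gh_map) {
  mono <- mucin_monosaccharides()
  released <- gh_released(gh_map)
  gh_of <- function(p) {
    unique(unlist(released[intersect(p$gh_classes, names(released))]))
  }
  cp_of <- function(p) catabolizable_monosaccharides(p, pathways)
  out <- list()
  for (a in profiles) {
    for (b in profiles) {
      if (identical(a$genome_id, b$genome_id)) next
      shared <- character(0)
      for (m in mono) {
        a_donor <- (m %in% gh_of(a)) && !(m %in% cp_of(a))
        b_acceptor <- (m %in% cp_of(b)) && !(m %in% gh_of(b))
        if (a_donor && b_acceptor) shared <- c(shared, m)
      }
      if (length(shared) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          donor = a$genome_id, acceptor = b$genome_id,
          monosaccharides = paste(shared, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      monosaccharides = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

all_pathway_genes <- function(pathways = default_pathways()) {
  unique(unlist(lapply(unclass(pathways), function(v) {
    unlist(lapply(v$steps, function(s) c(s$canonical, s$replacement)))
  })))
}

# Random annotation profile over the default feature universe.
random_profile <- function(id, p_gh = 0.4, p_gene = 0.5,
                           gh_map = default_gh_map(),
                           pathways = default_pathways()) {
  gh <- unique(gh_map$gh_class)
  genes <- all_pathway_genes(pathways)
  genome_profile(id,
                 gh_classes = gh[stats::runif(length(gh)) < p_gh],
                 genes = genes[stats::runif(length(genes)) < p_gene])
}

random_cohort <- function(n, ...) {
  profiles <- lapply(seq_len(n), function(i) {
    random_profile(sprintf("r%03d", i), ...)
  })
  stats::setNames(profiles, vapply(profiles, `[[`, "", "genome_id"))
}
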