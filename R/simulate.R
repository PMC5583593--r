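# Evaluate code under a temporary RNG state; the caller's stream is
# untouched. Each generator component seeds its own substream so adding a
# stage never perturbs another stage's draws.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configure a synthetic genome cohort
#'
#' Describes a cohort of genomes with taxon-structured Bernoulli feature
#' presence. Genomes are assigned round-robin to `n_taxa` taxon blocks; each
#' block has its own presence probability per GH class and per pathway gene.
#' The default probability matrices grade the taxon baselines evenly from
#' 0.25 to 0.75, mimicking the strong taxon dependence of glycan-foraging
#' gene repertoires; pass explicit matrices to control individual features.
#'
#' `gh_cp_dependence` couples, within a genome, the GH features and pathway
#' genes that concern the same monosaccharide: the paired Bernoulli draws
#' share a per-monosaccharide Gaussian latent with weight
#' `sqrt(|dependence|)` (sign flipped on the GH side for negative values),
#' so the latent correlation between a GH feature and a CP gene of the same
#' monosaccharide approaches the configured value while marginal
#' probabilities are preserved exactly.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param n_taxa Number of taxon blocks.
#' @param gh_prob Matrix `n_taxa x n_gh_classes` of presence probabilities
#'   (dimnames: taxa x GH class ids), or `NULL` for the graded default.
#' @param gene_prob Matrix `n_taxa x n_genes` (dimnames: taxa x gene
#'   symbols), or `NULL` for the graded default.
#' @param transporter_prob Scalar presence probability for each variant
#'   transporter symbol (drawn independently).
#' @param gh_cp_dependence Coupling in `[-1, 1]` between same-monosaccharide
#'   GH and CP features.
#' @param seed Integer seed; identical configs yield identical cohorts.
#' @param gh_map,pathways Feature universe used to build default matrices
#'   and to map features onto monosaccharides for the coupling.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_genomes = 200L, n_taxa = 8L,
                          gh_prob = NULL, gene_prob = NULL,
                          transporter_prob = 0.3,
                          gh_cp_dependence = 0.3,
                          seed = 1L,
                          gh_map = default_gh_map(),
                          pathways = default_pathways()) {
  stopifnot(n_genomes >= 1, n_taxa >= 1,
            gh_cp_dependence >= -1, gh_cp_dependence <= 1)
  taxa <- paste0("taxon_", seq_len(n_taxa))
  baseline <- if (n_taxa == 1) 0.5 else seq(0.25, 0.75, length.out = n_taxa)
  gh_ids <- unique(gh_map$gh_class)
  gene_ids <- unique(unlist(lapply(unclass(pathways), function(v) {
    unlist(lapply(v$steps, function(s) c(s$canonical, s$replacement)))
  })))
  if (is.null(gh_prob)) {
    gh_prob <- matrix(baseline, n_taxa, length(gh_ids),
                      dimnames = list(taxa, gh_ids))
  }
  if (is.null(gene_prob)) {
    gene_prob <- matrix(pmin(baseline + 0.1, 1), n_taxa, length(gene_ids),
                        dimnames = list(taxa, gene_ids))
  }
  check_prob <- function(m, what) {
    if (!is.matrix(m) || nrow(m) != n_taxa) {
      stop(what, " must be a matrix with n_taxa rows")
    }
    if (any(m < 0) || any(m > 1) || anyNA(m)) {
      stop(what, " probabilities must lie in [0, 1]")
    }
  }
  check_prob(gh_prob, "gh_prob")
  check_prob(gene_prob, "gene_prob")
  stopifnot(transporter_prob >= 0, transporter_prob <= 1)
  structure(
    list(n_genomes = as.integer(n_genomes), n_taxa = as.integer(n_taxa),
         gh_prob = gh_prob, gene_prob = gene_prob,
         transporter_prob = transporter_prob,
         gh_cp_dependence = gh_cp_dependence,
         seed = as.integer(seed), gh_map = gh_map, pathways = pathways),
    class = "cohort_config"
  )
}

# Map each feature to the monosaccharides it concerns, as a weight matrix
# (5 x n_features) with columns scaled to unit latent variance.
feature_mono_weights <- function(feature_monos) {
  mono <- mucin_monosaccharides()
  w <- vapply(feature_monos, function(ms) {
    col <- as.numeric(mono %in% ms)
    k <- sum(col)
    if (k > 0) col / sqrt(k) else col
  }, numeric(5))
  rownames(w) <- mono
  w
}

#' Simulate a genome cohort
#'
#' Draws genome profiles under a [cohort_config()]: taxon-block Bernoulli
#' presence for GH classes and pathway genes, independent Bernoulli
#' transporters, and the configured within-genome GH-CP coupling.
#' Reproducible: identical configs yield identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return Named list of [genome_profile()]s with lineage
#'   `c(taxon, genome_id)`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  mono <- mucin_monosaccharides()
  gh_ids <- colnames(config$gh_prob)
  gene_ids <- colnames(config$gene_prob)
  released <- gh_released(config$gh_map)
  gh_monos <- lapply(gh_ids, function(f) released[[f]] %||% character(0))
  gene_monos_map <- list()
  for (v in unclass(config$pathways)) {
    for (s in v$steps) {
      for (g in c(s$canonical, s$replacement)) {
        gene_monos_map[[g]] <- union(gene_monos_map[[g]], v$monosaccharide)
      }
    }
  }
  gene_monos <- lapply(gene_ids, function(g) {
    gene_monos_map[[g]] %||% character(0)
  })
  w_gh <- feature_mono_weights(gh_monos)
  w_gene <- feature_mono_weights(gene_monos)
  n <- config$n_genomes
  taxon_of <- rep_len(seq_len(config$n_taxa), n)
  rho <- config$gh_cp_dependence
  a <- abs(rho)
  s <- if (rho < 0) -1 else 1
  transporter_ids <- unique(unlist(lapply(unclass(config$pathways),
                                          `[[`, "transporters")))
  with_seed(config$seed, {
    z <- matrix(stats::rnorm(n * 5L), n, 5L)  # per-genome monosaccharide latents
    draw_block <- function(w, prob_matrix, flip) {
      p <- ncol(w)
      if (p == 0) return(matrix(logical(0), n, 0))
      zbar <- z %*% w
      eps <- matrix(stats::rnorm(n * p), n, p)
      x <- flip * sqrt(a) * zbar + sqrt(1 - a) * eps
      stats::pnorm(x) < prob_matrix[taxon_of, , drop = FALSE]
    }
    gh_on <- draw_block(w_gh, config$gh_prob, s)
    gene_on <- draw_block(w_gene, config$gene_prob, 1)
    tr_on <- matrix(stats::runif(n * length(transporter_ids)) <
                      config$transporter_prob,
                    n, length(transporter_ids))
    profiles <- lapply(seq_len(n), function(i) {
      gid <- sprintf("genome_%04d", i)
      genome_profile(
        gid,
        lineage = c(paste0("taxon_", taxon_of[i]), gid),
        gh_classes = gh_ids[gh_on[i, ]],
        genes = gene_ids[gene_on[i, ]],
        transporters = transporter_ids[tr_on[i, ]]
      )
    })
    validate_cohort(profiles)
  })
}

#' Configure and simulate a random glycan library
#'
#' Each synthetic glycan draws a number of distinct glycosidic bond types
#' uniformly from `min_bonds:max_bonds` (sampled without replacement from
#' the non-peptide alphabet) and carries the GalNAc-peptide attachment with
#' probability `peptide_prob`.
#'
#' @param n_glycans Number of glycans (0 allowed).
#' @param bond_alphabet Bond alphabet to draw from.
#' @param min_bonds,max_bonds Bounds of the per-glycan bond count
#'   (`1 <= min <= max <=` number of non-peptide bonds).
#' @param peptide_prob Probability of the peptide attachment.
#' @param seed Integer seed.
#' @return `library_config()` returns a list of class `"library_config"`;
#'   [simulate_library()] returns a `"glycan_library"`.
#' @export
library_config <- function(n_glycans = 50L,
                           bond_alphabet = default_bond_alphabet(),
                           min_bonds = 1L, max_bonds = 4L,
                           peptide_prob = 0.9, seed = 1L) {
  glycosidic <- bond_alphabet[!is_peptide_bond(bond_alphabet)]
  stopifnot(n_glycans >= 0, min_bonds >= 1, max_bonds >= min_bonds,
            max_bonds <= length(glycosidic),
            peptide_prob >= 0, peptide_prob <= 1)
  structure(
    list(n_glycans = as.integer(n_glycans), bond_alphabet = bond_alphabet,
         min_bonds = as.integer(min_bonds), max_bonds = as.integer(max_bonds),
         peptide_prob = peptide_prob, seed = as.integer(seed)),
    class = "library_config"
  )
}

#' @rdname library_config
#' @param config A `"library_config"`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  glycosidic <- config$bond_alphabet[!is_peptide_bond(config$bond_alphabet)]
  peptide <- config$bond_alphabet[is_peptide_bond(config$bond_alphabet)]
  with_seed(config$seed, {
    glycans <- lapply(seq_len(config$n_glycans), function(i) {
      nb <- sample(config$min_bonds:config$max_bonds, 1L)
      bonds <- sample(glycosidic, nb)
      if (length(peptide) > 0 && stats::runif(1) < config$peptide_prob) {
        bonds <- c(bonds, peptide[1])
      }
      glycan(sprintf("glycan_%03d", i), bonds)
    })
    glycan_library(glycans, bond_alphabet = config$bond_alphabet)
  })
}

# Find a two-way split of the GH classes covering a glycan's required bonds
# such that neither side alone covers all bonds but the union does.
partition_gh_for_glycan <- function(g, gh_map) {
  needed <- bonds_requiring_cleavage(g, exclude_peptide = TRUE)
  if (length(needed) < 2) return(NULL)
  classes_for <- lapply(needed, function(b) {
    unique(gh_map$gh_class[gh_map$bond == b])
  })
  if (any(vapply(classes_for, length, integer(1)) == 0)) return(NULL)
  cleaves_of <- function(cls) {
    intersect(unique(gh_map$bond[gh_map$gh_class %in% cls]), needed)
  }
  for (b_idx in seq_along(needed)) {
    for (c1 in classes_for[[b_idx]]) {
      if (length(cleaves_of(c1)) == length(needed)) next  # c1 covers alone
      rest <- setdiff(needed, cleaves_of(c1))
      # greedy cover of the remaining bonds
      c2 <- character(0)
      uncovered <- rest
      while (length(uncovered) > 0) {
        cands <- unique(gh_map$gh_class[gh_map$bond %in% uncovered])
        gains <- vapply(cands, function(cl) {
          length(intersect(cleaves_of(cl), uncovered))
        }, integer(1))
        pick <- cands[which.max(gains)]
        c2 <- c(c2, pick)
        uncovered <- setdiff(uncovered, cleaves_of(pick))
      }
      if (length(cleaves_of(c2)) < length(needed)) {
        return(list(gh_a = c1, gh_b = c2, glycan_id = g$id))
      }
    }
  }
  NULL
}

#' Plant ground-truth mutualistic pairs into a cohort
#'
#' Appends `k` genome pairs constructed so that, for a chosen target glycan,
#' the two members' GH sets partition the glycan's bond requirements:
#' neither member can degrade the target alone, their pooled repertoire can.
#' Planted pairs are therefore guaranteed mutualistic and are always
#' recovered by [find_mutualistic_pairs()]; incidental mutualistic pairs
#' among planted and background genomes may coexist with them.
#'
#' @param cohort Named list of [genome_profile()]s (may be empty).
#' @param library A `"glycan_library"` containing at least one glycan whose
#'   bond requirements admit a two-way GH split.
#' @param k Number of pairs to plant (0 returns the cohort unchanged).
#' @param seed Integer seed for target-glycan choice.
#' @param gh_map GH map data frame.
#' @return List with `cohort` (input plus `2 k` planted genomes) and `truth`
#'   (data frame: `genome_a`, `genome_b`, `glycan` targeted).
#' @export
plant_mutualistic_pairs <- function(cohort, library, k, seed = 1L,
                                    gh_map = default_gh_map()) {
  stopifnot(k >= 0)
  if (k == 0) {
    return(list(cohort = cohort,
                truth = data.frame(genome_a = character(0),
                                   genome_b = character(0),
                                   glycan = character(0),
                                   stringsAsFactors = FALSE)))
  }
  splits <- Filter(Negate(is.null),
                   lapply(unclass(library), partition_gh_for_glycan,
                          gh_map = gh_map))
  if (length(splits) == 0) {
    stop("no glycan in the library admits a two-way GH split ",
         "(need a glycan with >= 2 distinct cleavable bonds)")
  }
  with_seed(seed, {
    chosen <- splits[sample.int(length(splits), k, replace = TRUE)]
    planted <- list()
    truth <- vector("list", k)
    for (i in seq_len(k)) {
      sp <- chosen[[i]]
      ida <- sprintf("planted_%02da", i)
      idb <- sprintf("planted_%02db", i)
      planted[[2 * i - 1]] <- genome_profile(ida, lineage = c("planted", ida),
                                             gh_classes = sp$gh_a)
      planted[[2 * i]] <- genome_profile(idb, lineage = c("planted", idb),
                                         gh_classes = sp$gh_b)
      truth[[i]] <- data.frame(genome_a = ida, genome_b = idb,
                               glycan = sp$glycan_id,
                               stringsAsFactors = FALSE)
    }
    out <- c(cohort, planted)
    list(cohort = validate_cohort(out), truth = do.call(rbind, truth))
  })
}
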