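# Ground-truth QTL planting and phenotype generation.

#' Plant ground-truth QTL and conservation structure
#'
#' Chooses planted QTL among immune-set genes that carry a polymorphic exonic
#' locus with a reasonably balanced founder allele split (minor founder count
#' >= 2), assigns each a target cell type, a cyto-cis or cyto-trans mode and a
#' per-founder additive effect vector (`qtl_effect` times the founder allele at
#' the planted locus), and records the conservation group means used by the
#' conservation generator.
#'
#' @param founders A `founder_panel`.
#' @param config A [panel_config()].
#' @return An object of class `truth_record`: list with `qtl` (data.frame:
#'   `gene`, `locus`, `cell_type`, `mode`, `effect`), `founder_effects` (list
#'   of per-founder effect vectors), `trans_genes`, and
#'   `conservation_group_means` (named vector, `cis` and `trans`).
#' @export
make_truth <- function(founders, config) {
  stopifnot(inherits(founders, "founder_panel"), inherits(config, "panel_config"))
  with_seed(stage_seed(config$seed, 3L), {
    loci <- founders$loci
    al <- founders$alleles
    minor <- pmin(colSums(al), nrow(al) - colSums(al))
    eligible <- which(!is.na(loci$gene) & loci$exonic & minor >= 2L &
                        loci$gene %in% founders$immune_genes)
    eligible_genes <- unique(loci$gene[eligible])
    n_qtl <- min(config$n_qtl, length(eligible_genes))
    if (n_qtl < config$n_qtl)
      warning("only ", n_qtl, " genes eligible for QTL planting")
    cts <- cell_type_names(config$n_cell_types)
    genes <- sample(eligible_genes, n_qtl)
    qtl <- data.frame(gene = genes,
                      locus = vapply(genes, function(g) {
                        cand <- eligible[loci$gene[eligible] == g]
                        loci$locus[cand[sample.int(length(cand), 1L)]]
                      }, character(1)),
                      cell_type = rep_len(sample(cts), n_qtl),
                      mode = rep_len("cis", n_qtl),
                      effect = rep_len(config$qtl_effect, n_qtl),
                      stringsAsFactors = FALSE)
    n_trans <- round(config$trans_fraction * n_qtl)
    if (n_trans > 0L) qtl$mode[sample.int(n_qtl, n_trans)] <- "trans"
    rownames(qtl) <- NULL
    fx <- lapply(qtl$locus, function(l) config$qtl_effect * al[, l])
    names(fx) <- qtl$locus
    structure(list(qtl = qtl, founder_effects = fx,
                   trans_genes = qtl$gene[qtl$mode == "trans"],
                   conservation_group_means = c(cis = config$cons_mean_cis,
                                                trans = config$cons_mean_trans)),
              class = "truth_record")
  })
}

#' Generate replicate immune-cell-frequency phenotypes
#'
#' Frequencies are generated on the logit scale and mapped through the
#' logistic function, so they always lie in (0, 1):
#' `logit(freq) = baseline(cell type) + sum of planted founder effects +
#' strain-level shared noise (sd `kinship_sd`) + replicate noise (sd
#' `noise_sd`)`. The strain-level draw is shared by all replicates of a strain,
#' which is the strain-structured covariance the mixed-model scan models. Two
#' cohorts (discovery and validation) are generated from disjoint strain sets
#' in the same call so that planted effects are identical in both.
#'
#' @param mosaics A `strain_mosaics` from [generate_strains()].
#' @param truth A `truth_record` from [make_truth()].
#' @param config A [panel_config()].
#' @return A data.frame with columns `sample`, `strain`, `cohort`
#'   (`"discovery"` or `"validation"`), `replicate`, and one numeric column per
#'   cell type. Masked (strain, cell type) traits are `NA`.
#' @export
generate_phenotypes <- function(mosaics, truth, config) {
  stopifnot(inherits(mosaics, "strain_mosaics"), inherits(truth, "truth_record"),
            inherits(config, "panel_config"))
  geno <- mosaics$genotypes
  for (l in truth$qtl$locus) {
    a <- geno$founders[, l]
    if (length(unique(a)) < 2L)
      stop("planted locus ", l, " is monomorphic across founders", call. = FALSE)
  }
  with_seed(stage_seed(config$seed, 4L), {
    S <- config$n_strains
    R <- config$n_replicates
    cts <- cell_type_names(config$n_cell_types)
    strains <- rownames(mosaics$origins)
    cohort <- rep(c("discovery", "validation"),
                  c(config$n_discovery, S - config$n_discovery))
    # realistic bone-marrow fractions for the canonical nine subsets
    base_freq <- c(HSC = 0.005, NK = 0.02, CD4 = 0.05, CD8 = 0.04, B = 0.2,
                   proB = 0.05, lateB = 0.08, GN = 0.35, MO = 0.05)
    baseline <- stats::qlogis(ifelse(cts %in% names(base_freq),
                                     base_freq[cts], 0.05))
    names(baseline) <- cts

    # strain-level genetic signal + shared noise, per cell type
    eta_strain <- matrix(rep(baseline, each = S), S, length(cts),
                         dimnames = list(strains, cts))
    for (i in seq_len(nrow(truth$qtl))) {
      q <- truth$qtl[i, ]
      fx <- truth$founder_effects[[q$locus]]
      origin <- mosaics$origins[, q$locus]
      eta_strain[, q$cell_type] <- eta_strain[, q$cell_type] + fx[origin]
    }
    eta_strain <- eta_strain +
      matrix(stats::rnorm(S * length(cts), 0, config$kinship_sd), S)

    samples <- data.frame(
      strain = rep(strains, each = R),
      cohort = rep(cohort, each = R),
      replicate = rep(seq_len(R), times = S),
      stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_%s_r%d", samples$strain,
                              substr(samples$cohort, 1, 1), samples$replicate)
    n <- nrow(samples)
    eta <- eta_strain[samples$strain, , drop = FALSE] +
      matrix(stats::rnorm(n * length(cts), 0, config$noise_sd), n)
    freq <- stats::plogis(eta)
    colnames(freq) <- cts

    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(S * length(cts)) < config$missing_rate, S,
                     dimnames = list(strains, cts))
      freq[mask[samples$strain, , drop = FALSE]] <- NA_real_
    }
    cbind(samples[, c("sample", "strain", "cohort", "replicate")],
          as.data.frame(freq))
  })
}
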