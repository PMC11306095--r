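#' Configuration of a synthetic Collaborative-Cross-like panel
#'
#' Bundles and validates all parameters of the synthetic panel generator.
#' Defaults emulate the study design the package targets: eight founder
#' strains, a discovery cohort of 30 recombinant inbred strains with two
#' replicate mice each, a disjoint validation cohort of 24 strains, and nine
#' gated immune cell types in bone marrow.
#'
#' @param n_founders Number of inbred founder strains (>= 2).
#' @param n_strains Total number of recombinant inbred strains across both
#'   cohorts.
#' @param n_discovery Number of strains assigned to the discovery cohort; the
#'   remaining `n_strains - n_discovery` strains form the validation cohort.
#' @param n_replicates Replicate mice per strain per cohort.
#' @param n_chromosomes Number of chromosomes.
#' @param n_loci Total number of genotyped loci (spread evenly over
#'   chromosomes).
#' @param n_genes Number of annotated genes; each locus is assigned to at most
#'   one gene.
#' @param n_cell_types Number of assayed immune cell types. The first nine are
#'   labelled HSC, NK, CD4, CD8, B, proB, lateB, GN, MO so that downstream
#'   lineage-collapsing rules are exercised with their real names.
#' @param recomb_rate Expected number of recombination breakpoints per
#'   chromosome per strain.
#' @param genotype_error Probability that an observed strain genotype differs
#'   from its founder-of-origin allele.
#' @param noise_sd Replicate-level residual standard deviation on the logit
#'   scale.
#' @param kinship_sd Strain-level shared-noise standard deviation on the logit
#'   scale (the same draw is added to every replicate of a strain, creating
#'   the strain-structured covariance the mixed-model scan accounts for).
#' @param n_qtl Number of planted quantitative trait loci.
#' @param qtl_effect Additive allele effect of a planted QTL on the logit
#'   scale.
#' @param trans_fraction Fraction of planted QTL whose gene is silent in the
#'   associated cell type (cyto-trans mode).
#' @param immune_fraction Fraction of genes flagged as members of the
#'   immune-function gene set used for locus filtering.
#' @param exonic_fraction Fraction of loci flagged exonic.
#' @param monomorphic_fraction Fraction of loci forced monomorphic across
#'   founders (to exercise polymorphism filtering).
#' @param ld_within_gene Probability, per founder, that a locus copies the
#'   allele of its gene's base founder pattern rather than drawing an
#'   independent allele. Variants within one gene sit on shared founder
#'   haplotypes, so their founder allele patterns are strongly correlated in
#'   real panels; 0 makes every locus independent.
#' @param expr_silent_mean,expr_expressed_mean,expr_sd Means and common
#'   standard deviation (arbitrary microarray-like units) of the silent and
#'   expressed components of the two-Gaussian expression mixture. Defaults
#'   place the silent component well below the 47 a.u. detection threshold and
#'   the expressed component above the 120 a.u. confident-expression level.
#' @param cons_mean_cis,cons_mean_trans Mean per-site conservation score (in
#'   (0,1)) for genes without and with a planted cyto-trans association.
#' @param cons_kappa Concentration of the Beta distribution used for per-site
#'   conservation scores.
#' @param cons_missing_rate Probability that a gene receives no conserved
#'   element overlapping its coding sequence (its mean conservation score is
#'   then undefined; downstream analyses must drop it).
#' @param missing_rate Probability that a (strain, cell type) trait is masked
#'   (emulating antibody-panel exclusions). Default 0.
#' @param seed Integer seed; every generator consumes it deterministically.
#'
#' @return An object of class `panel_config` (a validated named list).
#' @export
#' @examples
#' cfg <- panel_config(n_strains = 10, n_discovery = 6, n_loci = 40,
#'                     n_genes = 10, seed = 1)
#' cfg$n_founders
panel_config <- function(n_founders = 8,
                         n_strains = 54,
                         n_discovery = 30,
                         n_replicates = 2,
                         n_chromosomes = 3,
                         n_loci = 240,
                         n_genes = 60,
                         n_cell_types = 9,
                         recomb_rate = 2,
                         genotype_error = 0,
                         noise_sd = 0.25,
                         kinship_sd = 0.15,
                         n_qtl = 4,
                         qtl_effect = 2,
                         trans_fraction = 0.5,
                         immune_fraction = 0.7,
                         exonic_fraction = 0.7,
                         monomorphic_fraction = 0.05,
                         ld_within_gene = 0.9,
                         expr_silent_mean = 20,
                         expr_expressed_mean = 200,
                         expr_sd = 5,
                         cons_mean_cis = 0.7,
                         cons_mean_trans = 0.4,
                         cons_kappa = 10,
                         cons_missing_rate = 0.05,
                         missing_rate = 0,
                         seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders), n_strains = as.integer(n_strains),
    n_discovery = as.integer(n_discovery),
    n_replicates = as.integer(n_replicates),
    n_chromosomes = as.integer(n_chromosomes), n_loci = as.integer(n_loci),
    n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
    recomb_rate = recomb_rate, genotype_error = genotype_error,
    noise_sd = noise_sd, kinship_sd = kinship_sd,
    n_qtl = as.integer(n_qtl), qtl_effect = qtl_effect,
    trans_fraction = trans_fraction,
    immune_fraction = immune_fraction, exonic_fraction = exonic_fraction,
    monomorphic_fraction = monomorphic_fraction,
    ld_within_gene = ld_within_gene,
    expr_silent_mean = expr_silent_mean,
    expr_expressed_mean = expr_expressed_mean, expr_sd = expr_sd,
    cons_mean_cis = cons_mean_cis, cons_mean_trans = cons_mean_trans,
    cons_kappa = cons_kappa, cons_missing_rate = cons_missing_rate,
    missing_rate = missing_rate,
    seed = as.integer(seed))

  counts <- c("n_founders", "n_strains", "n_replicates", "n_chromosomes",
              "n_loci", "n_genes", "n_cell_types")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("`", nm, "` must be a count >= 1", call. = FALSE)
  }
  if (cfg$n_founders < 2L) stop("`n_founders` must be >= 2", call. = FALSE)
  if (cfg$n_loci < cfg$n_genes)
    stop("`n_loci` must be >= `n_genes` (each gene needs at least one locus)",
         call. = FALSE)
  if (cfg$n_discovery < 1L || cfg$n_discovery > cfg$n_strains)
    stop("`n_discovery` must lie in [1, n_strains]", call. = FALSE)
  scales <- c("recomb_rate", "genotype_error", "noise_sd", "kinship_sd",
              "qtl_effect", "expr_sd", "cons_kappa", "missing_rate")
  for (nm in scales) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("`", nm, "` must be a finite non-negative number", call. = FALSE)
  }
  for (nm in c("trans_fraction", "immune_fraction", "exonic_fraction",
               "monomorphic_fraction", "ld_within_gene", "cons_missing_rate",
               "missing_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("cons_mean_cis", "cons_mean_trans")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("`", nm, "` must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("Synthetic CC-like panel configuration\n")
  cat(sprintf("  %d founders, %d strains (%d discovery + %d validation) x %d replicates\n",
              x$n_founders, x$n_strains, x$n_discovery,
              x$n_strains - x$n_discovery, x$n_replicates))
  cat(sprintf("  %d loci in %d genes on %d chromosomes; %d cell types\n",
              x$n_loci, x$n_genes, x$n_chromosomes, x$n_cell_types))
  cat(sprintf("  %d planted QTL (effect %.2g, %.0f%% cyto-trans), seed %d\n",
              x$n_qtl, x$qtl_effect, 100 * x$trans_fraction, x$seed))
  invisible(x)
}

# canonical cell-type labels; extended generically past the assayed nine
cell_type_names <- function(n) {
  base <- c("HSC", "NK", "CD4", "CD8", "B", "proB", "lateB", "GN", "MO")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("CT", seq_len(n - length(base))))
}

# derive a stage-specific RNG seed from the panel seed, kept below 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 7919L) %% 2147483647L
}
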