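# Second-cohort validation: per-association ANOVA with Benjamini-Hochberg
# correction, plus a cross-cohort directionality (Spearman) check.

#' Validate stage-1 associations in a second cohort
#'
#' For each stage-1 association, runs a one-way analysis of variance of the
#' validation-cohort trait across the biallelic genotype classes at the lead
#' locus, adjusts the p-values jointly with Benjamini-Hochberg, and checks
#' that the allele-stratified trait means are ordered consistently across the
#' two cohorts (Spearman correlation strictly greater than 0). An association
#' is validated iff `p_adj < 0.05` and `rho > 0`.
#'
#' @param assoc data.frame of stage-1 associations with columns `gene`,
#'   `cell_type`, `locus` (lead locus) and `lod`.
#' @param phenotypes Phenotype data.frame as produced by
#'   [generate_phenotypes()] (must contain both cohorts).
#' @param genotypes A `cc_genotypes` with strain alleles at the lead loci.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param pool_replicates If `TRUE`, replicate mice are averaged to one value
#'   per strain before the ANOVA; by default every mouse enters individually.
#' @return data.frame `assoc` extended with `p`, `p_adj`, `rho`, `testable`
#'   and `validated` columns; class `validation_result`.
#' @export
validate_associations <- function(assoc, phenotypes, genotypes, alpha = 0.05,
                                  pool_replicates = FALSE) {
  stopifnot(inherits(genotypes, "cc_genotypes"))
  n <- nrow(assoc)
  p <- rho <- rep(NA_real_, n)
  testable <- rep(FALSE, n)
  for (i in seq_len(n)) {
    a <- assoc[i, ]
    v <- anova_at_locus(a$locus, a$cell_type, phenotypes, genotypes,
                        cohort = "validation",
                        pool_replicates = pool_replicates)
    if (is.null(v)) next
    testable[i] <- TRUE
    p[i] <- v$p
    m1 <- allele_means(a$locus, a$cell_type, phenotypes, genotypes,
                       "discovery")
    m2 <- allele_means(a$locus, a$cell_type, phenotypes, genotypes,
                       "validation")
    rho[i] <- check_directionality(m1, m2)$rho
  }
  p_adj <- rep(NA_real_, n)
  p_adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  out <- cbind(assoc,
               data.frame(p = p, p_adj = p_adj, rho = rho,
                          testable = testable,
                          validated = testable & !is.na(p_adj) &
                            p_adj < alpha & !is.na(rho) & rho > 0))
  class(out) <- c("validation_result", "data.frame")
  out
}

# one-way ANOVA of a trait across biallelic genotype groups at one locus;
# NULL when untestable (any allele group has < 2 samples, or only one group)
anova_at_locus <- function(locus, cell_type, phenotypes, genotypes,
                           cohort = NULL, pool_replicates = FALSE) {
  d <- phenotypes
  if (!is.null(cohort)) d <- d[d$cohort == cohort, , drop = FALSE]
  li <- match(locus, genotypes$loci$locus)
  if (is.na(li)) stop("unknown locus ", locus, call. = FALSE)
  y <- d[[cell_type]]
  allele <- genotypes$strains[d$strain, li]
  keep <- is.finite(y) & !is.na(allele)
  y <- y[keep]; allele <- allele[keep]; strn <- d$strain[keep]
  if (pool_replicates) {
    y <- tapply(y, strn, mean)
    allele <- tapply(allele, strn, function(a) a[1L])
  }
  g <- factor(allele)
  if (nlevels(g) < 2L || any(table(g) < 2L)) return(NULL)
  if (stats::var(y) < 1e-300) return(list(f = 0, p = 1))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1L]]
  list(f = s[["F value"]][1L], p = s[["Pr(>F)"]][1L])
}

# mean trait per biallelic genotype class within one cohort
allele_means <- function(locus, cell_type, phenotypes, genotypes, cohort) {
  d <- phenotypes[phenotypes$cohort == cohort, , drop = FALSE]
  li <- match(locus, genotypes$loci$locus)
  y <- d[[cell_type]]
  allele <- genotypes$strains[d$strain, li]
  keep <- is.finite(y) & !is.na(allele)
  tapply(y[keep], factor(allele[keep]), mean)
}

#' Cross-cohort directionality check
#'
#' Spearman correlation between the allele-stratified trait means of the two
#' cohorts, over the allele groups present in both. The check passes iff the
#' correlation is strictly positive.
#'
#' @param means1,means2 Named numeric vectors of allele-group means (names =
#'   allele codes) for cohort 1 and cohort 2.
#' @return list with `rho` and logical `pass`; `rho` is `NA` (not passed)
#'   when fewer than two allele groups are shared.
#' @export
check_directionality <- function(means1, means2) {
  common <- intersect(names(means1), names(means2))
  if (length(common) < 2L) return(list(rho = NA_real_, pass = FALSE))
  if (stats::sd(means1[common]) == 0 || stats::sd(means2[common]) == 0)
    return(list(rho = NA_real_, pass = FALSE))  # constant means: undefined
  rho <- stats::cor(means1[common], means2[common], method = "spearman")
  list(rho = rho, pass = !is.na(rho) && rho > 0)
}
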