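# Founder and recombinant-inbred genotype generators.
#
# The panel is fully homozygous: one allele per (individual, locus), coded
# 0/1. Recombinant strains are per-chromosome mosaics of founder blocks.

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate founder genotypes and gene annotation
#'
#' Draws biallelic founder alleles for every locus, lays loci out along
#' chromosomes, assigns each locus to at most one gene, flags exonic loci and
#' an immune-function gene subset, and forces a configurable fraction of loci
#' monomorphic across founders so that polymorphism filtering has work to do.
#'
#' @param config A [panel_config()].
#' @return An object of class `founder_panel`: a list with
#'   * `loci` — data.frame with columns `locus`, `chrom`, `pos`, `gene`,
#'     `exonic`, one row per locus, sorted by (chrom, pos);
#'   * `alleles` — founders x loci 0/1 matrix;
#'   * `immune_genes` — character vector of immune-set gene ids.
#' @export
#' @examples
#' fp <- generate_founders(panel_config(n_strains = 6, n_discovery = 4,
#'                                      n_loci = 20, n_genes = 5, seed = 1))
#' dim(fp$alleles)
generate_founders <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(stage_seed(config$seed, 1L), {
    L <- config$n_loci
    Fn <- config$n_founders
    G <- config$n_genes
    C <- config$n_chromosomes

    # spread loci evenly over chromosomes; positions sorted within chromosome
    chrom_idx <- sort(rep_len(seq_len(C), L))
    pos <- integer(L)
    for (c in seq_len(C)) {
      n_c <- sum(chrom_idx == c)
      pos[chrom_idx == c] <- sort(sample.int(2e8L, n_c))
    }

    # genes occupy contiguous locus blocks within a chromosome
    gene_of_chrom <- sort(rep_len(seq_len(C), G))
    gene_ids <- sprintf("G%04d", seq_len(G))
    gene <- character(L)
    for (c in seq_len(C)) {
      loc_c <- which(chrom_idx == c)
      genes_c <- which(gene_of_chrom == c)
      if (length(genes_c) == 0L) { gene[loc_c] <- NA_character_; next }
      blocks <- sort(rep_len(genes_c, length(loc_c)))
      gene[loc_c] <- gene_ids[blocks]
    }

    exonic <- stats::runif(L) < config$exonic_fraction
    alleles <- matrix(stats::rbinom(Fn * L, 1L, 0.5), nrow = Fn,
                      dimnames = list(sprintf("F%d", seq_len(Fn)),
                                      sprintf("L%05d", seq_len(L))))
    if (config$ld_within_gene > 0) {
      # variants within a gene share founder haplotypes: each gene has a base
      # founder pattern its loci copy per founder with prob ld_within_gene
      for (g in gene_ids) {
        loc_g <- which(!is.na(gene) & gene == g)
        if (length(loc_g) < 2L) next
        base <- stats::rbinom(Fn, 1L, 0.5)
        copy <- matrix(stats::runif(Fn * length(loc_g)) <
                         config$ld_within_gene, Fn)
        alleles[, loc_g][copy] <- rep(base, length(loc_g))[copy]
      }
    }
    n_mono <- floor(config$monomorphic_fraction * L)
    if (n_mono > 0L) {
      mono <- sample.int(L, n_mono)
      alleles[, mono] <- rep(alleles[1L, mono], each = Fn)
    }

    loci <- data.frame(locus = colnames(alleles),
                       chrom = paste0("chr", chrom_idx),
                       pos = pos, gene = gene, exonic = exonic,
                       stringsAsFactors = FALSE)
    ord <- order(chrom_idx, pos)
    loci <- loci[ord, , drop = FALSE]
    alleles <- alleles[, ord, drop = FALSE]
    rownames(loci) <- NULL

    immune <- sort(sample(gene_ids, round(config$immune_fraction * G)))
    structure(list(loci = loci, alleles = alleles, immune_genes = immune),
              class = "founder_panel")
  })
}

#' Generate recombinant inbred strain mosaics and observed genotypes
#'
#' Each strain is, per chromosome, a mosaic of founder blocks: breakpoint
#' counts are Poisson with mean `recomb_rate`, breakpoints fall uniformly on
#' the inter-locus gaps, and successive blocks come from distinct founders.
#' Observed genotypes equal the founder-of-origin allele, flipped with
#' probability `genotype_error`.
#'
#' @param founders A `founder_panel` from [generate_founders()].
#' @param config The same [panel_config()].
#' @return An object of class `strain_mosaics`: a list with
#'   * `origins` — strains x loci integer matrix of founder-of-origin indices;
#'   * `genotypes` — a `cc_genotypes` object bundling the locus annotation,
#'     founder alleles and observed strain alleles.
#' @export
generate_strains <- function(founders, config) {
  stopifnot(inherits(founders, "founder_panel"), inherits(config, "panel_config"))
  with_seed(stage_seed(config$seed, 2L), {
    S <- config$n_strains
    Fn <- config$n_founders
    loci <- founders$loci
    L <- nrow(loci)
    chroms <- unique(loci$chrom)
    origins <- matrix(NA_integer_, S, L,
                      dimnames = list(sprintf("S%03d", seq_len(S)),
                                      loci$locus))
    for (s in seq_len(S)) {
      for (ch in chroms) {
        idx <- which(loci$chrom == ch)
        n_c <- length(idx)
        k <- stats::rpois(1L, config$recomb_rate)
        k <- min(k, n_c - 1L)
        fs <- sample.int(Fn, 1L)
        if (k == 0L) {
          origins[s, idx] <- fs
        } else {
          gaps <- sort(sample.int(n_c - 1L, k))  # breakpoint after these loci
          seg <- findInterval(seq_len(n_c), gaps + 1L) + 1L
          block_founder <- integer(k + 1L)
          block_founder[1L] <- fs
          for (b in seq_len(k) + 1L) {
            others <- setdiff(seq_len(Fn), block_founder[b - 1L])
            block_founder[b] <- others[sample.int(length(others), 1L)]
          }
          origins[s, idx] <- block_founder[seg]
        }
      }
    }
    obs <- matrix(founders$alleles[cbind(as.vector(origins),
                                         rep(seq_len(L), each = S))],
                  S, L, dimnames = dimnames(origins))
    if (config$genotype_error > 0) {
      flip <- matrix(stats::runif(S * L) < config$genotype_error, S, L)
      obs[flip] <- 1L - obs[flip]
    }
    geno <- new_cc_genotypes(loci, founders$alleles, obs)
    structure(list(origins = origins, genotypes = geno),
              class = "strain_mosaics")
  })
}

# constructor for the genotype-table container used throughout the pipeline
new_cc_genotypes <- function(loci, founder_alleles, strain_alleles) {
  stopifnot(nrow(loci) == ncol(founder_alleles),
            is.null(strain_alleles) || nrow(loci) == ncol(strain_alleles))
  structure(list(loci = loci, founders = founder_alleles,
                 strains = strain_alleles),
            class = "cc_genotypes")
}

#' @export
print.cc_genotypes <- function(x, ...) {
  cat(sprintf("cc_genotypes: %d loci on %d chromosomes, %d founders, %d strains\n",
              nrow(x$loci), length(unique(x$loci$chrom)),
              nrow(x$founders),
              if (is.null(x$strains)) 0L else nrow(x$strains)))
  cat(sprintf("  %d loci annotated to %d genes; %d exonic\n",
              sum(!is.na(x$loci$gene)),
              length(unique(stats::na.omit(x$loci$gene))),
              sum(x$loci$exonic)))
  invisible(x)
}
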