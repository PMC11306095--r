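# Locus filtering, founder-haplotype reconstruction and kinship.

#' Filter loci to polymorphic exonic variants in immune-set genes
#'
#' Keeps exactly the loci that (1) lie within a gene belonging to the supplied
#' immune-function gene set, (2) are exonic, and (3) are polymorphic among the
#' founders (at least one founder differs). This is the testing-burden
#' reduction step applied before the genome scan.
#'
#' @param genotypes A `cc_genotypes` object.
#' @param immune_genes Character vector of immune-set gene ids.
#' @return The filtered `cc_genotypes`, with an attached `"filter_report"`
#'   attribute (named integer vector: loci in, loci out, genes out).
#' @export
filter_loci <- function(genotypes, immune_genes) {
  stopifnot(inherits(genotypes, "cc_genotypes"))
  if (length(immune_genes) == 0L)
    warning("empty immune gene set: no loci retained")
  loci <- genotypes$loci
  poly <- apply(genotypes$founders, 2L, function(a) length(unique(a)) > 1L)
  keep <- !is.na(loci$gene) & loci$gene %in% immune_genes & loci$exonic & poly
  out <- new_cc_genotypes(
    loci[keep, , drop = FALSE],
    genotypes$founders[, keep, drop = FALSE],
    if (is.null(genotypes$strains)) NULL
    else genotypes$strains[, keep, drop = FALSE])
  rownames(out$loci) <- NULL
  attr(out, "filter_report") <- c(
    loci_in = nrow(loci), loci_out = sum(keep),
    genes_out = length(unique(out$loci$gene)))
  out
}

#' Reconstruct founder-haplotype posterior probabilities
#'
#' Runs, per strain and per chromosome, the forward-backward algorithm over a
#' hidden Markov chain whose states are the homozygous founder origins (the
#' panel is inbred, so no heterozygous states are needed). Emission: the
#' observed allele matches the founder allele with probability `1 - epsilon`;
#' a missing observation is uninformative (uniform emission). Transition
#' between adjacent loci: stay on the same founder with probability `1 - tau`,
#' switch to each other founder with probability `tau / (n_founders - 1)`.
#'
#' @param genotypes A `cc_genotypes` with strain alleles; loci must be sorted
#'   by (chromosome, position).
#' @param epsilon Genotyping-error probability (default 0.01).
#' @param tau Per-interval founder-switch probability (default 0.002).
#' @return An object of class `haplotype_probs`: a strains x loci x founders
#'   array; each (strain, locus) slice sums to 1.
#' @export
reconstruct_haplotypes <- function(genotypes, epsilon = 0.01, tau = 0.002) {
  stopifnot(inherits(genotypes, "cc_genotypes"),
            !is.null(genotypes$strains),
            epsilon >= 0, epsilon < 1, tau >= 0, tau < 1)
  loci <- genotypes$loci
  if (anyDuplicated(rle(loci$chrom)$values) ||
      any(tapply(loci$pos, loci$chrom, is.unsorted)))
    stop("loci must be sorted by (chromosome, position)", call. = FALSE)
  Fn <- nrow(genotypes$founders)
  S <- nrow(genotypes$strains)
  L <- nrow(loci)
  probs <- array(NA_real_, c(S, L, Fn),
                 dimnames = list(rownames(genotypes$strains), loci$locus,
                                 rownames(genotypes$founders)))
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    fa <- genotypes$founders[, idx, drop = FALSE]  # founders x loci
    for (s in seq_len(S)) {
      obs <- genotypes$strains[s, idx]
      # emission matrix: loci x founders
      em <- matrix(1, length(idx), Fn)
      known <- !is.na(obs)
      if (any(known)) {
        match_ <- t(fa[, known, drop = FALSE]) == obs[known]
        em[known, ] <- ifelse(match_, 1 - epsilon, epsilon)
      }
      probs[s, idx, ] <- forward_backward_uniform(em, tau)
    }
  }
  structure(probs, chrom = loci$chrom, class = "haplotype_probs")
}

# forward-backward with uniform-switch transitions; em is loci x states.
# exploits the symmetric transition kernel: pred = a*(1-tau*K/(K-1)) +
# tau/(K-1), with sum(a) = 1 after scaling.
forward_backward_uniform <- function(em, tau) {
  L <- nrow(em)
  K <- ncol(em)
  stay_extra <- 1 - tau - tau / (K - 1)   # coefficient on own mass
  mix <- tau / (K - 1)                    # uniform leak from total mass 1
  alpha <- matrix(0, L, K)
  a <- em[1L, ] / K
  a <- a / sum(a)
  alpha[1L, ] <- a
  if (L > 1L) for (t in 2L:L) {
    pred <- a * stay_extra + mix
    a <- pred * em[t, ]
    a <- a / sum(a)
    alpha[t, ] <- a
  }
  beta <- matrix(1, L, K)
  b <- rep(1, K)
  if (L > 1L) for (t in (L - 1L):1L) {
    v <- b * em[t + 1L, ]
    b <- v * stay_extra + mix * sum(v)
    b <- b / sum(b)
    beta[t, ] <- b
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Compute the strain kinship matrix from haplotype probabilities
#'
#' `K[i, j]` is the mean over loci of the inner product of the two strains'
#' founder-probability vectors — the probability, averaged along the genome,
#' that the two strains carry the same founder allele.
#'
#' @param probs A `haplotype_probs` array.
#' @return A symmetric positive semi-definite strains x strains matrix with
#'   entries in \[0, 1\].
#' @export
compute_kinship <- function(probs) {
  stopifnot(length(dim(probs)) == 3L)
  L <- dim(probs)[2L]
  if (L == 0L) stop("cannot compute kinship over zero loci", call. = FALSE)
  P <- matrix(probs, nrow = dim(probs)[1L])  # strains x (loci*founders)
  K <- tcrossprod(P) / L
  dimnames(K) <- list(dimnames(probs)[[1L]], dimnames(probs)[[1L]])
  K
}

#' Leave-one-chromosome-out kinship matrices
#'
#' For each chromosome, computes the kinship matrix from the loci on all
#' *other* chromosomes. Using the LOCO matrix when scanning a chromosome
#' prevents the tested QTL from being absorbed into the polygenic random
#' effect (proximal contamination), which otherwise deflates LOD scores for
#' large-effect loci.
#'
#' @param probs A `haplotype_probs` array carrying a `"chrom"` attribute (as
#'   returned by [reconstruct_haplotypes()]).
#' @return A named list of strain x strain kinship matrices, one per
#'   chromosome. With a single chromosome the global matrix is returned for
#'   it, with a warning.
#' @export
compute_kinship_loco <- function(probs) {
  ch <- attr(probs, "chrom")
  if (is.null(ch)) stop("probs carries no chromosome annotation", call. = FALSE)
  chroms <- unique(ch)
  S <- dim(probs)[1L]
  L <- dim(probs)[2L]
  P <- matrix(probs, nrow = S)
  if (length(chroms) == 1L) {
    warning("single chromosome: LOCO kinship falls back to the global matrix")
    K <- tcrossprod(P) / L
    dimnames(K) <- list(dimnames(probs)[[1L]], dimnames(probs)[[1L]])
    return(stats::setNames(list(K), chroms))
  }
  total <- tcrossprod(P)
  out <- lapply(chroms, function(c_) {
    idx <- which(ch == c_)
    cols <- as.vector(outer(idx, (seq_len(dim(probs)[3L]) - 1L) * L, "+"))
    K <- (total - tcrossprod(P[, cols, drop = FALSE])) / (L - length(idx))
    dimnames(K) <- list(dimnames(probs)[[1L]], dimnames(probs)[[1L]])
    K
  })
  stats::setNames(out, chroms)
}
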