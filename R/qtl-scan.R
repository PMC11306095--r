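# Kinship-aware additive-haplotype genome scan.
#
# Model: y = mu + locus effects + g + e, with cov(g) = sigma_g^2 * K at the
# strain level. Per trait, the heritability is profiled under the null
# (intercept-only) model after a single eigendecomposition of the
# sample-level kinship; the null and every locus model are then generalized
# least-squares fits in the rotated space, so a whole-genome scan costs one
# QR decomposition per locus. LOD = log10 likelihood ratio under the
# profiled Gaussian likelihood, which with shared weights equals
# (n/2) * log10(RSS_null / RSS_locus). Permutation scans re-profile the
# heritability for each shuffled phenotype (snapped to a 0.05 grid so
# permutations with equal weights share locus decompositions).

# Align inputs, drop missing traits, eigendecompose the sample-level kinship
# and rotate everything once.
scan_setup <- function(y, strain, probs, kinship) {
  stopifnot(length(y) == length(strain))
  keep <- is.finite(y)
  y <- y[keep]
  strain <- as.character(strain)[keep]
  S_names <- dimnames(probs)[[1L]]
  if (!all(strain %in% S_names))
    stop("strains in phenotype not found in haplotype probabilities",
         call. = FALSE)
  n <- length(y)
  Fn <- dim(probs)[3L]
  if (length(unique(strain)) <= Fn + 1L)
    stop("need more strains than founders + 1 for the additive scan",
         call. = FALSE)
  si <- match(strain, S_names)
  Ks <- kinship[S_names, S_names][si, si, drop = FALSE]
  eig <- eigen(Ks, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ystar <- drop(crossprod(U, y))
  onestar <- drop(crossprod(U, rep(1, n)))
  # rotated (unweighted) founder-dosage columns for every locus at once:
  # column (f-1)*L + l of `Rraw` is founder f's dosage at locus l
  L <- dim(probs)[2L]
  big <- matrix(probs[si, , , drop = FALSE], nrow = n)
  Rraw <- crossprod(U, big)
  h2 <- est_h2(ystar, onestar, d, n)
  list(y = y, strain = strain, si = si, n = n, L = L, Fn = Fn,
       U = U, d = d, ystar = ystar, onestar = onestar, h2 = h2,
       Rraw = Rraw, loci = dimnames(probs)[[2L]])
}

# average replicate samples to one phenotype value per strain (NAs dropped)
pool_strain_means <- function(y, strain) {
  keep <- is.finite(y)
  y <- y[keep]
  strain <- as.character(strain)[keep]
  m <- tapply(y, factor(strain, levels = unique(strain)), mean)
  list(y = as.numeric(m), strain = names(m))
}

# profile-likelihood heritability under the intercept-only null
est_h2 <- function(ystar, onestar, d, n) {
  negll <- function(h) {
    w <- h * d + (1 - h)
    x0 <- onestar / sqrt(w)
    yw <- ystar / sqrt(w)
    beta <- sum(x0 * yw) / sum(x0 * x0)
    rss <- sum((yw - beta * x0)^2)
    0.5 * (n * log(max(rss, 1e-300) / n) + sum(log(w)))
  }
  stats::optimize(negll, c(0, 0.99))$minimum
}

# weighted null and per-locus designs for a given heritability (intercept +
# founder dosages with the first founder column dropped against collinearity)
design_for_h2 <- function(setup, h2) {
  w <- h2 * setup$d + (1 - h2)
  sw <- sqrt(w)
  x0 <- setup$onestar / sw
  q0 <- qr(cbind(x0))
  qrs <- lapply(seq_len(setup$L), function(l) {
    cols <- l + setup$L * seq_len(setup$Fn - 1L)
    qr(cbind(x0, setup$Rraw[, cols, drop = FALSE] / sw))
  })
  list(w = w, sw = sw, x0 = x0, q0 = q0, qrs = qrs)
}

# split loci into scan blocks: one per chromosome when `kinship` is a LOCO
# list of matrices, otherwise a single genome-wide block
scan_blocks <- function(probs, kinship) {
  if (!is.list(kinship))
    return(list(list(idx = seq_len(dim(probs)[2L]), K = kinship)))
  ch <- attr(probs, "chrom")
  if (is.null(ch))
    stop("LOCO kinship requires chromosome annotation on probs", call. = FALSE)
  if (!all(unique(ch) %in% names(kinship)))
    stop("LOCO kinship list does not cover every chromosome", call. = FALSE)
  lapply(unique(ch), function(c_)
    list(idx = which(ch == c_), K = kinship[[c_]]))
}

# subset a haplotype-probability array by locus index, keeping attributes
probs_subset <- function(probs, idx) {
  out <- probs[, idx, , drop = FALSE]
  class(out) <- "haplotype_probs"
  out
}

# LOD scores for one or more (already rotated+weighted) phenotype columns
lod_from_qrs <- function(qrs, Yrw, q0, n) {
  Yrw <- as.matrix(Yrw)
  tot <- colSums(Yrw^2)
  rss0 <- tot - colSums(qr.qty(q0, Yrw)[seq_len(q0$rank), , drop = FALSE]^2)
  lod <- matrix(0, length(qrs), ncol(Yrw))
  for (l in seq_along(qrs)) {
    qrl <- qrs[[l]]
    fit <- colSums(qr.qty(qrl, Yrw)[seq_len(qrl$rank), , drop = FALSE]^2)
    rss1 <- pmax(tot - fit, 1e-300)
    lod[l, ] <- (n / 2) * log10(pmax(rss0, 1e-300) / rss1)
  }
  lod[lod < 0] <- 0
  lod[, rss0 < 1e-12] <- 0  # constant (after rotation) phenotype
  lod
}

#' Genome scan for one trait
#'
#' Fits, for every locus, the additive haplotype model (intercept plus the
#' founder-dosage columns given by the haplotype posterior probabilities, one
#' column dropped against collinearity) against the intercept-only null, both
#' as generalized least squares under the strain-kinship covariance with
#' heritability profiled once per trait, and returns the LOD score per locus.
#'
#' @param y Numeric vector of per-sample trait values (missing values are
#'   dropped).
#' @param strain Character vector mapping each sample to its strain (row name
#'   of `probs`). Replicate mice share a strain.
#' @param probs A `haplotype_probs` array (strains x loci x founders).
#' @param kinship Strain kinship matrix from [compute_kinship()], or a named
#'   list of per-chromosome matrices from [compute_kinship_loco()] (each
#'   chromosome is then scanned under its leave-one-chromosome-out kinship).
#' @param pool_replicates Average replicate mice to one value per strain
#'   before fitting (default `TRUE`). The panel is inbred, so replicates are
#'   genetically identical; scanning strain means avoids the identical
#'   kinship rows that would otherwise let any strain-level variance —
#'   including the tested QTL's — masquerade as heritability and compress
#'   LOD scores.
#' @return An object of class `cc_scan`: list with `lod` (named numeric per
#'   locus), `h2` (profiled heritability, per scan block), and `n`
#'   (phenotype rows used in the fit).
#' @export
qtl_scan <- function(y, strain, probs, kinship, pool_replicates = TRUE) {
  if (pool_replicates) {
    pooled <- pool_strain_means(y, strain)
    y <- pooled$y
    strain <- pooled$strain
  }
  blocks <- scan_blocks(probs, kinship)
  lod <- numeric(0)
  h2 <- numeric(0)
  n <- NA_integer_
  deficient <- FALSE
  for (b in blocks) {
    setup <- scan_setup(y, strain, probs_subset(probs, b$idx), b$K)
    des <- design_for_h2(setup, setup$h2)
    p_full <- 1L + setup$Fn - 1L
    deficient <- deficient ||
      any(vapply(des$qrs, function(q) q$rank, 0L) < p_full)
    lb <- drop(lod_from_qrs(des$qrs, setup$ystar / des$sw, des$q0, setup$n))
    names(lb) <- setup$loci
    lod <- c(lod, lb)
    h2 <- c(h2, setup$h2)
    n <- setup$n
  }
  if (deficient)
    warning("rank-deficient locus design(s): affected loci fall back to the ",
            "fitted rank (monomorphic posteriors give LOD 0)")
  lod <- lod[dimnames(probs)[[2L]]]
  structure(list(lod = lod, h2 = h2, n = n), class = "cc_scan")
}

#' @export
print.cc_scan <- function(x, ...) {
  cat(sprintf("cc_scan: %d loci, n = %d, h2 = %s, max LOD = %.2f at %s\n",
              length(x$lod), x$n,
              paste(sprintf("%.3f", x$h2), collapse = "/"), max(x$lod),
              names(x$lod)[which.max(x$lod)]))
  invisible(x)
}

# all permutations of 1..n (n <= 7), one per column
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  if (n > 7L) stop("exhaustive enumeration limited to 7 strains", call. = FALSE)
  sub <- all_perms(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(k, matrix(c(seq_len(n)[-k])[sub], nrow = n - 1L))
  }))
}

#' Permutation-based FDR threshold for a genome scan
#'
#' Strain labels are shuffled relative to the genotypes with replicate mice
#' always moving together, the scan is recomputed for every shuffle
#' (re-profiling the heritability per shuffle), and the empirical false
#' discovery rate at a candidate threshold `t` is
#' `FDR(t) = mean over permutations of #[loci with permuted LOD >= t] /
#' max(1, #[loci with observed LOD >= t])`. The returned threshold is the
#' smallest observed LOD value whose estimated FDR is at or below
#' `fdr_level`, or `Inf` when none qualifies.
#'
#' With `pool_replicates = TRUE` (default) strain means are permuted, which
#' moves replicates together by construction; at the sample level the label
#' shuffles require equal replicate counts per strain (after dropping
#' missing traits). Permutation heritabilities are snapped to a 0.05 grid so
#' shuffles with equal variance weights can share the per-locus
#' decompositions.
#'
#' @inheritParams qtl_scan
#' @param n_perm Number of random permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param fdr_level Target false discovery rate (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @param exhaustive If `TRUE`, enumerate all strain-label permutations
#'   (feasible up to 7 strains) instead of sampling.
#' @return An object of class `perm_threshold`: list with `threshold`,
#'   `lod_obs`, `fdr` (data.frame of candidate thresholds and estimated FDR),
#'   `n_perm`, and `perm_lod_max` (per-permutation genome-wide maxima).
#' @export
permutation_threshold <- function(y, strain, probs, kinship, n_perm = 200L,
                                  fdr_level = 0.05, seed = 1L,
                                  exhaustive = FALSE, pool_replicates = TRUE) {
  if (!exhaustive && n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (!exhaustive && n_perm < 20L)
    warning("fewer than 20 permutations give an unstable FDR estimate")
  if (pool_replicates) {
    pooled <- pool_strain_means(y, strain)
    y <- pooled$y
    strain <- pooled$strain
  }
  keep <- is.finite(y)
  y2 <- y[keep]
  strain2 <- as.character(strain)[keep]
  n <- length(y2)

  # strain blocks must be balanced so label shuffles permute whole blocks
  sf <- factor(strain2, levels = unique(strain2))
  counts <- table(sf)
  if (length(unique(counts)) != 1L)
    stop("strain-label permutation requires equal replicate counts per ",
         "strain after dropping missing traits", call. = FALSE)
  idx <- matrix(order(as.integer(sf)), nrow = counts[1L])  # replicates x strains
  S <- ncol(idx)
  perms <- if (exhaustive) all_perms(S)
  else with_seed(seed, {
    vapply(seq_len(n_perm), function(p) sample.int(S), integer(S))
  })
  P <- ncol(perms)
  Y <- matrix(0, n, P)
  for (p in seq_len(P)) {
    yp <- y2
    yp[idx] <- y2[idx[, perms[, p]]]
    Y[, p] <- yp
  }

  lod_obs <- numeric(0)
  lod_perm <- NULL
  for (b in scan_blocks(probs, kinship)) {
    setup <- scan_setup(y2, strain2, probs_subset(probs, b$idx), b$K)
    des_obs <- design_for_h2(setup, setup$h2)
    lb <- drop(lod_from_qrs(des_obs$qrs, setup$ystar / des_obs$sw,
                            des_obs$q0, setup$n))
    names(lb) <- setup$loci
    lod_obs <- c(lod_obs, lb)
    Ystar <- crossprod(setup$U, Y)
    h2p <- vapply(seq_len(P), function(p)
      est_h2(Ystar[, p], setup$onestar, setup$d, setup$n), 0)
    # snap to a 0.05 grid, keeping an extra knot near the upper boundary so
    # high-heritability shuffles get the same extreme weighting regime as an
    # observed high-heritability trait
    h2g <- ifelse(h2p > 0.97, 0.99, round(h2p / 0.05) * 0.05)
    lp <- matrix(0, setup$L, P)
    for (h in unique(h2g)) {
      cols <- which(h2g == h)
      des <- design_for_h2(setup, h)
      lp[, cols] <- lod_from_qrs(des$qrs,
                                 Ystar[, cols, drop = FALSE] / des$sw,
                                 des$q0, setup$n)
    }
    lod_perm <- rbind(lod_perm, lp)
  }
  lod_obs <- lod_obs[dimnames(probs)[[2L]]]

  ts <- sort(unique(lod_obs))
  perm_all <- as.vector(lod_perm)
  fdr <- vapply(ts, function(t) {
    (sum(perm_all >= t) / P) / max(1, sum(lod_obs >= t))
  }, 0)
  ok <- fdr <= fdr_level
  threshold <- if (any(ok)) min(ts[ok]) else Inf
  structure(list(threshold = threshold, lod_obs = lod_obs,
                 fdr = data.frame(threshold = ts, fdr = fdr),
                 n_perm = P, perm_lod_max = apply(lod_perm, 2L, max)),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("perm_threshold: %.3f (%d permutations); %d loci pass\n",
              x$threshold, x$n_perm, sum(x$lod_obs >= x$threshold)))
  invisible(x)
}

#' Leave-one-out stability filter
#'
#' Re-runs the scan at the candidate loci with each sample (mouse) left out
#' in turn, re-profiling the heritability on the reduced data. A locus is
#' retained only if its LOD stays at or above `threshold` in every
#' leave-one-out refit.
#'
#' @inheritParams qtl_scan
#' @param candidate_loci Character vector of locus ids that passed the FDR
#'   threshold on the full data.
#' @param threshold The full-data LOD threshold.
#' @return Character vector of retained locus ids.
#' @export
loo_stability <- function(y, strain, probs, kinship, candidate_loci,
                          threshold, pool_replicates = TRUE) {
  if (length(candidate_loci) == 0L) return(character(0))
  keep <- is.finite(y)
  y <- y[keep]
  strain <- as.character(strain)[keep]
  li <- match(candidate_loci, dimnames(probs)[[2L]])
  if (anyNA(li)) stop("unknown candidate loci", call. = FALSE)
  ok <- rep(TRUE, length(candidate_loci))
  for (b in scan_blocks(probs, kinship)) {
    in_b <- li %in% b$idx
    if (!any(in_b)) next
    sub <- probs_subset(probs, li[in_b])
    for (i in seq_along(y)) {
      if (length(unique(strain[-i])) < 3L)
        stop("fewer than 3 strains remain after leaving one sample out",
             call. = FALSE)
      yi <- y[-i]
      si <- strain[-i]
      if (pool_replicates) {
        pooled <- pool_strain_means(yi, si)
        yi <- pooled$y
        si <- pooled$strain
      }
      setup <- scan_setup(yi, si, sub, b$K)
      des <- design_for_h2(setup, setup$h2)
      lod <- drop(lod_from_qrs(des$qrs, setup$ystar / des$sw, des$q0,
                               setup$n))
      ok[in_b] <- ok[in_b] & (lod >= threshold)
      if (!any(ok[in_b])) break
    }
  }
  candidate_loci[ok]
}

#' Collapse retained loci to gene-level lead associations
#'
#' For each gene with at least one retained locus, reports the lead locus:
#' the retained locus with the highest LOD, ties broken by smallest genomic
#' position.
#'
#' @param lod Named numeric vector of LOD scores (as in `cc_scan$lod`).
#' @param retained Character vector of retained locus ids.
#' @param loci Locus annotation data.frame (`locus`, `chrom`, `pos`, `gene`).
#' @return data.frame with columns `gene`, `locus`, `lod`; zero rows when
#'   nothing is retained.
#' @export
collapse_to_genes <- function(lod, retained, loci) {
  out <- data.frame(gene = character(0), locus = character(0),
                    lod = numeric(0), stringsAsFactors = FALSE)
  retained <- intersect(retained, loci$locus[!is.na(loci$gene)])
  if (length(retained) == 0L) return(out)
  tab <- loci[match(retained, loci$locus), c("locus", "pos", "gene")]
  tab$lod <- lod[retained]
  tab <- tab[order(tab$gene, -tab$lod, tab$pos), ]
  lead <- tab[!duplicated(tab$gene), ]
  data.frame(gene = lead$gene, locus = lead$locus, lod = lead$lod,
             stringsAsFactors = FALSE, row.names = NULL)
}
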