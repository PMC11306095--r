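# Independent oracles and small fixture builders shared across tests.

# small default panel configuration that keeps test runtimes low
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_strains = 14, n_discovery = 10, n_loci = 40, n_genes = 10,
         n_chromosomes = 2, n_cell_types = 3, n_qtl = 1,
         cons_missing_rate = 0, seed = seed),
    list(...))
  do.call(panel_config, args)
}

# random scan fixture with one strain per sample so K = identity makes the
# mixed model collapse onto ordinary least squares
ols_fixture <- function(seed, n = 20, L = 6, Fn = 3) {
  set.seed(seed)
  origins <- matrix(sample.int(Fn, n * L, replace = TRUE), n, L,
                    dimnames = list(sprintf("S%03d", 1:n),
                                    sprintf("L%05d", 1:L)))
  probs <- hard_probs(origins, Fn)
  # soften the assignments so the design exercises real posteriors
  probs[] <- probs * 0.9 + 0.1 / Fn
  class(probs) <- "haplotype_probs"
  y <- rnorm(n)
  K <- diag(n)
  dimnames(K) <- list(rownames(origins), rownames(origins))
  list(y = y, strain = rownames(origins), probs = probs, K = K)
}

# brute-force OLS LOD: (n/2) log10(RSS0/RSS1) from lm fits
ols_lod_oracle <- function(y, X) {
  rss0 <- sum(stats::lm.fit(cbind(rep(1, length(y))), y)$residuals^2)
  rss1 <- sum(stats::lm.fit(cbind(1, X), y)$residuals^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# forward-backward posterior by explicit enumeration of all hidden paths
fb_enum_oracle <- function(obs, founder_alleles, epsilon, tau) {
  Fn <- nrow(founder_alleles)
  L <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(Fn)), L)))
  lik <- apply(paths, 1L, function(path) {
    p <- 1 / Fn
    for (t in seq_len(L)) {
      if (t > 1L)
        p <- p * if (path[t] == path[t - 1L]) 1 - tau else tau / (Fn - 1)
      if (!is.na(obs[t]))
        p <- p * if (founder_alleles[path[t], t] == obs[t]) 1 - epsilon
      else epsilon
    }
    p
  })
  post <- matrix(0, L, Fn)
  for (t in seq_len(L)) for (f in seq_len(Fn))
    post[t, f] <- sum(lik[paths[, t] == f])
  post / rowSums(post)
}

# one-sided KS D by brute force: sup of ECDF_a - ECDF_b over both samples
ks_D_bruteforce <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0))
}

# minimal haplotype-probability array with hard (one-hot) founder assignments
hard_probs <- function(origins, n_founders) {
  S <- nrow(origins)
  L <- ncol(origins)
  p <- array(0, c(S, L, n_founders),
             dimnames = list(rownames(origins),
                             colnames(origins),
                             sprintf("F%d", seq_len(n_founders))))
  for (s in seq_len(S)) for (l in seq_len(L)) p[s, l, origins[s, l]] <- 1
  class(p) <- "haplotype_probs"
  p
}

# genotype container straight from matrices (loci on one chromosome)
toy_genotypes <- function(founders, strains = NULL, gene = NA, exonic = TRUE,
                          chrom = "chr1") {
  L <- ncol(founders)
  loci <- data.frame(locus = sprintf("L%05d", seq_len(L)),
                     chrom = rep_len(chrom, L),
                     pos = seq_len(L) * 1000L,
                     gene = rep_len(gene, L), exonic = rep_len(exonic, L),
                     stringsAsFactors = FALSE)
  colnames(founders) <- loci$locus
  if (!is.null(strains)) colnames(strains) <- loci$locus
  ccimmune:::new_cc_genotypes(loci, founders, strains)
}
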