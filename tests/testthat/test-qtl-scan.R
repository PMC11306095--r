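# Genome scan, permutation FDR threshold, leave-one-out filter, collapsing.

test_that("constant phenotype gives LOD 0 everywhere", {
  fx <- ols_fixture(41)
  sc <- qtl_scan(rep(1, length(fx$y)), fx$strain, fx$probs, fx$K)
  expect_true(all(sc$lod == 0))
})

test_that("scan with identity kinship matches the OLS LOD oracle", {
  for (seed in 1:20) {
    fx <- ols_fixture(100 + seed)
    sc <- qtl_scan(fx$y, fx$strain, fx$probs, fx$K)
    for (l in seq_len(dim(fx$probs)[2])) {
      X <- fx$probs[, l, -1]
      expect_equal(unname(sc$lod[l]), ols_lod_oracle(fx$y, X),
                   tolerance = 1e-6)
    }
  }
})

test_that("scan is equivariant under a common strain reordering", {
  fx <- ols_fixture(42)
  sc1 <- qtl_scan(fx$y, fx$strain, fx$probs, fx$K)
  ord <- sample(length(fx$y))
  sc2 <- qtl_scan(fx$y[ord], fx$strain[ord], fx$probs, fx$K)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-9)
})

test_that("scan errors when strains do not outnumber founders", {
  fx <- ols_fixture(43, n = 4, Fn = 3)
  expect_error(qtl_scan(fx$y, fx$strain, fx$probs, fx$K), "founders")
})

test_that("genome-wide argmax lands on the planted locus in a seeded panel", {
  cfg <- tiny_config(seed = 44, n_qtl = 1, qtl_effect = 2.5)
  panel <- simulate_panel(cfg)
  geno <- filter_loci(panel$genotypes, panel$immune_genes)
  probs <- reconstruct_haplotypes(geno)
  K <- compute_kinship(probs)
  disc <- panel$phenotypes[panel$phenotypes$cohort == "discovery", ]
  q <- panel$truth$qtl[1, ]
  sc <- suppressWarnings(qtl_scan(disc[[q$cell_type]], disc$strain, probs, K))
  # lead locus is in the planted gene (within-gene LD makes its loci tie)
  lead <- names(sc$lod)[which.max(sc$lod)]
  expect_equal(geno$loci$gene[geno$loci$locus == lead], q$gene)
})

test_that("permutation FDR matches exhaustive enumeration on a 4-strain case", {
  set.seed(45)
  n <- 8  # 4 strains x 2 replicates
  origins <- matrix(sample.int(2, 4 * 3, replace = TRUE), 4, 3,
                    dimnames = list(sprintf("S%03d", 1:4),
                                    sprintf("L%05d", 1:3)))
  probs <- hard_probs(origins, 2)
  strain <- rep(rownames(origins), each = 2)
  y <- rnorm(n)
  K <- diag(4)
  dimnames(K) <- list(rownames(origins), rownames(origins))

  # scan needs more strains than founders + 1: 4 > 3 holds for 2 founders
  pt <- permutation_threshold(y, strain, probs, K, exhaustive = TRUE)
  expect_equal(pt$n_perm, factorial(4))

  # brute-force oracle: recompute the scan for all 24 strain-label
  # assignments via qtl_scan itself applied to permuted phenotype blocks
  perms <- ccimmune:::all_perms(4)
  lods <- sapply(seq_len(ncol(perms)), function(p) {
    idx <- as.vector(matrix(1:8, 2)[, perms[, p]])
    qtl_scan(y[idx], strain, probs, K)$lod
  })
  lod_obs <- qtl_scan(y, strain, probs, K)$lod
  for (t in sort(unique(lod_obs))) {
    fdr_oracle <- mean(colSums(lods >= t)) / max(1, sum(lod_obs >= t))
    expect_equal(pt$fdr$fdr[pt$fdr$threshold == t], fdr_oracle,
                 tolerance = 1e-9)
  }
})

test_that("permutation threshold is non-increasing in the FDR level", {
  cfg <- tiny_config(seed = 46, n_qtl = 1, qtl_effect = 2.5)
  panel <- simulate_panel(cfg)
  geno <- filter_loci(panel$genotypes, panel$immune_genes)
  probs <- reconstruct_haplotypes(geno)
  K <- compute_kinship(probs)
  disc <- panel$phenotypes[panel$phenotypes$cohort == "discovery", ]
  q <- panel$truth$qtl[1, ]
  th <- vapply(c(0.01, 0.05, 0.2, 0.5), function(level) {
    suppressWarnings(permutation_threshold(disc[[q$cell_type]], disc$strain,
                                           probs, K, n_perm = 50,
                                           fdr_level = level,
                                           seed = 9)$threshold)
  }, 0)
  th <- pmin(th, 1e6)  # Inf-to-Inf steps compare as equal
  expect_true(all(diff(th) <= 0))
})

test_that("sample-level label shuffles demand balanced replicates; pooling does not", {
  fx <- ols_fixture(47, n = 12, Fn = 3)
  strain <- fx$strain
  strain[2] <- strain[3]  # sample 2 becomes a replicate of strain 3
  expect_error(
    suppressWarnings(permutation_threshold(fx$y[-1], strain[-1], fx$probs,
                                           fx$K, n_perm = 30,
                                           pool_replicates = FALSE)),
    "equal replicate counts")
  # pooling to strain means handles arbitrary replicate structure
  pt <- suppressWarnings(permutation_threshold(fx$y[-1], strain[-1],
                                               fx$probs, fx$K, n_perm = 30))
  expect_s3_class(pt, "perm_threshold")
})

test_that("leave-one-out filtering matches per-sample refit enumeration", {
  fx <- ols_fixture(48, n = 12, L = 4, Fn = 3)
  sc <- qtl_scan(fx$y, fx$strain, fx$probs, fx$K)
  cand <- names(sort(sc$lod, decreasing = TRUE))[1:2]
  threshold <- min(sc$lod[cand]) * 0.9
  kept <- suppressWarnings(
    loo_stability(fx$y, fx$strain, fx$probs, fx$K, cand, threshold))
  # oracle: 12 refits per candidate via qtl_scan on the reduced data
  oracle_keep <- vapply(cand, function(l) {
    all(vapply(seq_along(fx$y), function(i) {
      sc_i <- suppressWarnings(
        qtl_scan(fx$y[-i], fx$strain[-i],
                 ccimmune:::probs_subset(fx$probs,
                                         match(l, dimnames(fx$probs)[[2]])),
                 fx$K))
      sc_i$lod[l] >= threshold
    }, logical(1)))
  }, logical(1))
  expect_setequal(kept, cand[oracle_keep])
})

test_that("an association driven by one extreme sample is not LOO-stable", {
  set.seed(49)
  n <- 16
  origins <- matrix(sample.int(2, n * 3, replace = TRUE), n, 3,
                    dimnames = list(sprintf("S%03d", 1:n),
                                    sprintf("L%05d", 1:3)))
  probs <- hard_probs(origins, 2)
  K <- diag(n)
  dimnames(K) <- list(rownames(origins), rownames(origins))
  y <- rnorm(n, sd = 0.05)
  y[1] <- 8  # single extreme mouse creates the apparent association
  sc <- qtl_scan(y, rownames(origins), probs, K)
  top <- names(sc$lod)[which.max(sc$lod)]
  kept <- loo_stability(y, rownames(origins), probs, K, top,
                        max(sc$lod) * 0.95)
  expect_length(kept, 0)
})

test_that("collapse_to_genes picks lead loci with position tie-breaks", {
  loci <- data.frame(locus = c("L1", "L2", "L3", "L4"),
                     chrom = "chr1", pos = c(100, 200, 300, 400),
                     gene = c("gA", "gA", "gB", NA),
                     stringsAsFactors = FALSE)
  lod <- c(L1 = 7.1, L2 = 9.3, L3 = 5, L4 = 11)
  out <- collapse_to_genes(lod, c("L1", "L2", "L3", "L4"), loci)
  expect_equal(out$locus[out$gene == "gA"], "L2")  # 9.3 beats 7.1
  expect_equal(nrow(out), 2)                       # unannotated L4 dropped

  lod_tie <- c(L1 = 9.3, L2 = 9.3, L3 = 5, L4 = 1)
  out_tie <- collapse_to_genes(lod_tie, c("L1", "L2", "L3"), loci)
  expect_equal(out_tie$locus[out_tie$gene == "gA"], "L1")  # smaller position

  expect_equal(nrow(collapse_to_genes(lod, character(0), loci)), 0)
})
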