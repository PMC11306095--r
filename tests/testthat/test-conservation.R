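# Gene conservation scoring, group assignment, KS and chi-square tests.

# conservation input built by hand (coordinates 0-based half-open)
hand_cons <- function() {
  structure(list(
    cds = data.frame(chrom = "chr1", start = 10L, end = 20L, gene = "gA",
                     stringsAsFactors = FALSE),
    elements = data.frame(chrom = "chr1", start = c(0L, 15L),
                          end = c(12L, 18L), stringsAsFactors = FALSE),
    scores = data.frame(chrom = "chr1",
                        start = c(0:11, 15:17),
                        end = c(0:11, 15:17) + 1L,
                        score = c(rep(0.9, 12), rep(0.6, 3)),
                        stringsAsFactors = FALSE)),
    class = "conservation_input")
}

test_that("gene conservation averages sites inside elements-in-CDS", {
  # CDS [10,20) meets elements [0,12) at sites 10,11 (score 0.9) and
  # [15,18) at sites 15,16,17 (score 0.6): (2*0.9 + 3*0.6)/5 = 0.72
  expect_equal(gene_conservation_score("gA", hand_cons()), 0.72,
               tolerance = 1e-9)
  # element-weighted alternative averages the two element means
  expect_equal(gene_conservation_score("gA", hand_cons(),
                                       weighting = "element"),
               (0.9 + 0.6) / 2, tolerance = 1e-9)
})

test_that("degenerate and missing-overlap cases behave", {
  ci <- hand_cons()
  ci$scores$score <- 1
  expect_equal(gene_conservation_score("gA", ci), 1)
  ci2 <- hand_cons()
  ci2$elements <- data.frame(chrom = "chr1", start = 100L, end = 120L)
  expect_true(is.na(gene_conservation_score("gA", ci2)))
  expect_error(gene_conservation_score("gB", hand_cons()), "CDS")
  # a scored site missing from the track is an error
  ci3 <- hand_cons()
  ci3$scores <- ci3$scores[-1, ]  # drop site 0 (outside CDS: still fine)
  expect_equal(gene_conservation_score("gA", ci3), 0.72, tolerance = 1e-9)
  ci3$scores <- ci3$scores[ci3$scores$start != 10L, ]
  expect_error(gene_conservation_score("gA", ci3), "no conservation score")
})

test_that("splitting an element into adjacent sub-elements changes nothing", {
  ci <- hand_cons()
  split_ci <- ci
  split_ci$elements <- data.frame(chrom = "chr1",
                                  start = c(0L, 6L, 15L, 16L),
                                  end = c(6L, 12L, 16L, 18L))
  expect_equal(gene_conservation_score("gA", split_ci),
               gene_conservation_score("gA", ci), tolerance = 1e-12)
})

test_that("group assignment collapses lineages before counting cell types", {
  cl <- structure(data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g4"),
    cell_type = c("proB", "lateB", "GN", "CD4", "HSC", "GN"),
    mode = c("cis", "cis", "cis", "trans", "cis", "trans"),
    expressed_in = "", stringsAsFactors = FALSE),
    class = c("classified_associations", "data.frame"))
  g <- assign_groups(cl)
  # proB + lateB collapse to one B-lineage type
  expect_false(g$multi_cell_type[g$gene == "g1"])
  # GN and CD4 stay distinct
  expect_true(g$multi_cell_type[g$gene == "g2"])
  expect_true(g$has_cyto_trans[g$gene == "g2"])
  expect_false(g$has_cyto_trans[g$gene == "g1"])
  expect_true(g$has_cyto_trans[g$gene == "g4"])
})

test_that("one-sided KS statistic and asymptotic p match hand computation", {
  same <- ks_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  # a entirely below b: D = 1, p = exp(-2 * 1 * 9/6) = exp(-3)
  r <- ks_one_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$D, 1)
  expect_equal(r$p, exp(-3), tolerance = 1e-9)
  expect_error(ks_one_sided(numeric(0), 1:3), "non-empty")
})

test_that("KS D matches the brute-force ECDF supremum on small instances", {
  set.seed(91)
  for (i in 1:40) {
    a <- runif(sample(2:10, 1))
    b <- runif(sample(2:10, 1))
    r <- ks_one_sided(a, b)
    expect_equal(r$D, ks_D_bruteforce(a, b), tolerance = 1e-12)
    expect_gte(r$D, 0)
    expect_lte(r$D, 1)
    expect_gt(r$p, 0)
    expect_lte(r$p, 1)
    # cross-check against the independent stats implementation
    expect_equal(r$D,
                 unname(suppressWarnings(
                   stats::ks.test(a, b, alternative = "greater")$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("exact small-sample KS p matches permutation enumeration", {
  a <- c(0.1, 0.35, 0.6)
  b <- c(0.2, 0.5, 0.8, 0.9)
  r <- ks_one_sided(a, b, exact = TRUE)
  # enumerate all C(7,3) assignments of the pooled values to group a
  pool <- c(a, b)
  combs <- utils::combn(7, 3)
  ds <- apply(combs, 2, function(ix)
    ks_D_bruteforce(pool[ix], pool[-ix]))
  expect_equal(r$p, mean(ds >= r$D - 1e-12), tolerance = 1e-9)
  # ties fall back to the asymptotic formula with a warning
  expect_warning(ks_one_sided(c(1, 2), c(2, 3), exact = TRUE), "ties")
})

test_that("chi-square enrichment matches the hand oracle", {
  expect_equal(chi2_enrichment(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi2_enrichment(matrix(10, 2, 2))$p, 1)
  tab <- matrix(c(20, 10, 10, 20), 2, 2)
  r <- chi2_enrichment(tab)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)  # 6.667 by hand
  expect_equal(r$p, stats::pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # swapping rows leaves the statistic unchanged
  expect_equal(chi2_enrichment(tab[2:1, ])$statistic, r$statistic)
  expect_error(chi2_enrichment(matrix(c(0, 0, 5, 5), 2, 2)), "expected")
})

test_that("run_comparisons wires groups, skips small ones and reports ECDFs", {
  set.seed(92)
  rec <- structure(data.frame(
    gene = sprintf("g%02d", 1:40),
    mean_conservation = c(rbeta(20, 4, 6), rbeta(20, 7, 3)),
    has_cyto_trans = rep(c(TRUE, FALSE), each = 20),
    multi_cell_type = rep(c(TRUE, FALSE), 20),
    stringsAsFactors = FALSE), class = c("gene_evolution", "data.frame"))
  rep_ <- run_comparisons(rec, background = list(bg = runif(10)))
  expect_true(rep_$comparisons$trans_vs_cis_only$p < 0.5)
  expect_setequal(unique(rep_$ecdf$group),
                  c("cyto_trans", "cis_only", "bg"))
  expect_equal(sum(rep_$table), 40)

  # single-gene group: that comparison is skipped, others still run
  rec2 <- rec
  rec2$has_cyto_trans <- c(TRUE, rep(FALSE, 39))
  rep2 <- run_comparisons(rec2)
  expect_false(is.null(rep2$comparisons$trans_vs_cis_only$skipped))
  expect_null(rep2$comparisons$multi_vs_single$skipped)

  # missing conservation scores are dropped with a count
  rec3 <- rec
  rec3$mean_conservation[1:5] <- NA
  expect_equal(run_comparisons(rec3)$n_missing, 5)
})
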