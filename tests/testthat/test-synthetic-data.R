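# Synthetic panel generators: determinism, domain contracts, planted truth.

test_that("panel_config validates counts, rates and fractions", {
  expect_s3_class(panel_config(), "panel_config")
  expect_error(panel_config(n_founders = 1), "n_founders")
  expect_error(panel_config(n_loci = 5, n_genes = 10), "n_loci")
  expect_error(panel_config(noise_sd = -1), "noise_sd")
  expect_error(panel_config(cons_mean_trans = 1.2), "cons_mean_trans")
  expect_error(panel_config(n_discovery = 99, n_strains = 10), "n_discovery")
})

test_that("generate_founders obeys shape, domain and determinism contracts", {
  cfg <- tiny_config(seed = 11)
  fp1 <- generate_founders(cfg)
  fp2 <- generate_founders(cfg)
  expect_identical(fp1, fp2)
  expect_equal(dim(fp1$alleles), c(cfg$n_founders, cfg$n_loci))
  expect_true(all(fp1$alleles %in% c(0L, 1L)))
  expect_equal(nrow(fp1$loci), cfg$n_loci)
  # loci sorted by (chromosome, position)
  expect_false(anyDuplicated(rle(fp1$loci$chrom)$values) > 0)
  expect_false(any(tapply(fp1$loci$pos, fp1$loci$chrom, is.unsorted)))
  # forced monomorphic loci exist at the configured fraction
  poly <- apply(fp1$alleles, 2, function(a) length(unique(a)) > 1)
  expect_gte(sum(!poly), floor(cfg$monomorphic_fraction * cfg$n_loci))
})

test_that("forcing all loci monomorphic leaves zero polymorphic loci", {
  cfg <- tiny_config(seed = 2, monomorphic_fraction = 1, n_qtl = 0)
  fp <- generate_founders(cfg)
  poly <- apply(fp$alleles, 2, function(a) length(unique(a)) > 1)
  expect_equal(sum(poly), 0)
})

test_that("strain mosaics honour the no-recombination limit", {
  cfg <- tiny_config(seed = 3, recomb_rate = 0)
  fp <- generate_founders(cfg)
  sm <- generate_strains(fp, cfg)
  for (ch in unique(fp$loci$chrom)) {
    idx <- fp$loci$chrom == ch
    per_chrom <- apply(sm$origins[, idx, drop = FALSE], 1,
                       function(o) length(unique(o)))
    expect_true(all(per_chrom == 1))
  }
})

test_that("zero genotyping error reproduces founder alleles exactly", {
  cfg <- tiny_config(seed = 4, genotype_error = 0)
  fp <- generate_founders(cfg)
  sm <- generate_strains(fp, cfg)
  expected <- matrix(fp$alleles[cbind(as.vector(sm$origins),
                                      rep(seq_len(cfg$n_loci),
                                          each = cfg$n_strains))],
                     cfg$n_strains, cfg$n_loci)
  expect_equal(unname(sm$genotypes$strains), expected)
})

test_that("breakpoint counts match the Poisson oracle", {
  cfg <- panel_config(n_strains = 100, n_discovery = 50, n_chromosomes = 1,
                      n_loci = 1000, n_genes = 100, recomb_rate = 1,
                      seed = 5)
  fp <- generate_founders(cfg)
  sm <- generate_strains(fp, cfg)
  breaks <- apply(sm$origins, 1, function(o) sum(diff(o) != 0))
  # mean breakpoints per strain ~ Poisson(1): within 3 SE of 1
  se <- sqrt(1 / 100)
  expect_lt(abs(mean(breaks) - 1), 3 * se)
})

test_that("phenotypes are deterministic, bounded and respect planted nulls", {
  cfg <- tiny_config(seed = 6)
  fp <- generate_founders(cfg)
  tr <- make_truth(fp, cfg)
  sm <- generate_strains(fp, cfg)
  ph1 <- generate_phenotypes(sm, tr, cfg)
  ph2 <- generate_phenotypes(sm, tr, cfg)
  expect_identical(ph1, ph2)
  cts <- setdiff(colnames(ph1), c("sample", "strain", "cohort", "replicate"))
  vals <- as.matrix(ph1[, cts])
  expect_true(all(vals > 0 & vals < 1))
  expect_setequal(unique(ph1$cohort), c("discovery", "validation"))
  # disjoint strain sets between cohorts
  expect_length(intersect(ph1$strain[ph1$cohort == "discovery"],
                          ph1$strain[ph1$cohort == "validation"]), 0)

  # no planted effects + no noise -> every sample identical per cell type
  cfg0 <- tiny_config(seed = 6, n_qtl = 0, noise_sd = 0, kinship_sd = 0)
  fp0 <- generate_founders(cfg0)
  tr0 <- make_truth(fp0, cfg0)
  sm0 <- generate_strains(fp0, cfg0)
  ph0 <- generate_phenotypes(sm0, tr0, cfg0)
  for (ct in cts) expect_equal(stats::var(ph0[[ct]]), 0)
})

test_that("a single strong planted QTL separates strains by founder allele", {
  cfg <- tiny_config(seed = 7, n_qtl = 1, qtl_effect = 3, noise_sd = 0.01,
                     kinship_sd = 0)
  fp <- generate_founders(cfg)
  tr <- make_truth(fp, cfg)
  sm <- generate_strains(fp, cfg)
  ph <- generate_phenotypes(sm, tr, cfg)
  q <- tr$qtl[1, ]
  allele <- fp$alleles[, q$locus][sm$origins[, q$locus]]
  strain_mean <- tapply(ph[[q$cell_type]], ph$strain, mean)[rownames(sm$origins)]
  # direct group comparison: all carrier strains above all non-carriers
  expect_gt(min(strain_mean[allele == 1]), max(strain_mean[allele == 0]))
})

test_that("planted phenotypes fail cleanly when the locus is monomorphic", {
  cfg <- tiny_config(seed = 8)
  fp <- generate_founders(cfg)
  tr <- make_truth(fp, cfg)
  sm <- generate_strains(fp, cfg)
  fp_broken <- fp
  fp_broken$alleles[, tr$qtl$locus[1]] <- 0L
  sm$genotypes$founders <- fp_broken$alleles
  expect_error(generate_phenotypes(sm, tr, cfg), "monomorphic")
})

test_that("expression honours planted modes and the two-Gaussian design", {
  cfg <- tiny_config(seed = 9, n_qtl = 2, trans_fraction = 0.5)
  fp <- generate_founders(cfg)
  tr <- make_truth(fp, cfg)
  ex1 <- generate_expression(tr, cfg)
  ex2 <- generate_expression(tr, cfg)
  expect_identical(ex1, ex2)
  expect_true(all(ex1$matrix >= 0))
  expect_setequal(names(ex1$population_map),
                  cell_type_names(cfg$n_cell_types))
  for (i in seq_len(nrow(tr$qtl))) {
    q <- tr$qtl[i, ]
    own <- ex1$population_map[[q$cell_type]]
    if (q$mode == "trans") {
      expect_true(all(ex1$matrix[own, q$gene] < 47))
      expect_true(any(ex1$matrix[setdiff(rownames(ex1$matrix), own),
                                 q$gene] >= 47))
    } else {
      expect_true(any(ex1$matrix[own, q$gene] >= 47))
    }
  }
})

test_that("binarization at 47 recovers mixture labels within the Gaussian tail bound", {
  # silent N(20, 5) vs expressed N(200, 5): both tails beyond 47 are
  # negligible, so misclassification over 10,000 draws stays under 1%
  set.seed(10)
  truth_lab <- rbinom(10000, 1, 0.5)
  draws <- rnorm(10000, ifelse(truth_lab == 1, 200, 20), 5)
  called <- as.integer(draws >= 47)
  expect_lt(mean(called != truth_lab), 0.01)
})

test_that("conservation tracks are valid BED-like structures with planted groups", {
  cfg <- tiny_config(seed = 12, n_qtl = 2, trans_fraction = 1,
                     cons_missing_rate = 0)
  fp <- generate_founders(cfg)
  tr <- make_truth(fp, cfg)
  cons <- generate_conservation(tr, cfg)
  expect_true(all(cons$cds$start < cons$cds$end))
  expect_true(all(cons$elements$start < cons$elements$end))
  expect_true(all(cons$scores$score >= 0 & cons$scores$score <= 1))
  expect_setequal(unique(cons$cds$gene), sprintf("G%04d", 1:cfg$n_genes))
  # trans-planted genes draw from the lower-mean group (each gene occupies
  # its own 10 kb window, so the window index recovers the gene)
  gene_idx <- cons$scores$start %/% 10000L + 1L
  trans_idx <- match(tr$trans_genes, sprintf("G%04d", 1:cfg$n_genes))
  expect_lt(mean(cons$scores$score[gene_idx %in% trans_idx]), 0.55)
  expect_gt(mean(cons$scores$score[!(gene_idx %in% trans_idx)]), 0.55)

  bad <- tr
  bad$conservation_group_means <- c(cis = 1.5, trans = 0.4)
  expect_error(generate_conservation(bad, cfg), "group means")
})

test_that("genes can lack conserved elements in their CDS and score missing", {
  cfg <- tiny_config(seed = 13, cons_missing_rate = 1)
  fp <- generate_founders(cfg)
  tr <- make_truth(fp, cfg)
  cons <- generate_conservation(tr, cfg)
  expect_true(is.na(gene_conservation_score("G0001", cons)))
})

test_that("simulate_panel is bit-reproducible and round-trips through disk", {
  cfg <- tiny_config(seed = 14)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)

  dir <- withr::local_tempdir()
  write_panel(p1, dir)
  back <- load_panel(dir)
  expect_equal(back$genotypes$founders, p1$genotypes$founders)
  expect_equal(back$genotypes$strains, p1$genotypes$strains)
  expect_equal(back$phenotypes$sample, p1$phenotypes$sample)
  expect_equal(unname(back$expression$matrix),
               unname(p1$expression$matrix), tolerance = 1e-8)
  expect_setequal(back$immune_genes, p1$immune_genes)
  expect_equal(back$truth$qtl$locus, p1$truth$qtl$locus)
  expect_error(load_panel(file.path(dir, "nope")), "genotypes.tsv")
})
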