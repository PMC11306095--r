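# End-to-end orchestration: synth -> prep -> scan -> replicate -> propagate
# -> classify -> conserve, plus the human-data re-run entry point.

#' Run the full association-and-conservation pipeline
#'
#' Executes every stage on a panel: locus filtering, haplotype
#' reconstruction, kinship, per-cell-type genome scan with permutation FDR
#' threshold and leave-one-out stability filtering on the discovery cohort,
#' gene-level collapsing, validation-cohort ANOVA with Benjamini-Hochberg
#' correction and directionality check, LOD-profile clustering with signal
#' propagation, cyto-cis/cyto-trans classification, and the conservation
#' comparisons. When the panel carries a truth record, recovery metrics are
#' added to the report.
#'
#' @param panel A `cc_panel` (from [simulate_panel()] or [load_panel()]) or a
#'   [panel_config()] (simulated first).
#' @param n_perm Permutations per cell type for the FDR threshold.
#' @param fdr_level Target FDR for the scan threshold.
#' @param epsilon,tau Haplotype-HMM genotyping-error and founder-switch
#'   probabilities.
#' @param k_range Candidate cluster counts for signal propagation.
#' @param threshold_fraction Propagation median-LOD fraction (default 0.4).
#' @param expr_threshold Expression binarization threshold in a.u.
#'   (default 47).
#' @param loo Apply the leave-one-out stability filter (default `TRUE`).
#' @param seed Seed for the stochastic stages (permutations, k-means);
#'   defaults to the panel seed.
#' @param out_dir Optional directory: stage artifacts are written as TSV/JSON.
#' @return A list of class `cc_report` with per-stage results (`filter`,
#'   `scans`, `thresholds`, `stage1`, `validation`, `propagation`,
#'   `classified`, `tally`, `conservation`, `recovery`, `params`).
#' @export
run_pipeline <- function(panel, n_perm = 200L, fdr_level = 0.05,
                         epsilon = 0.01, tau = 0.002, k_range = 2:8,
                         threshold_fraction = 0.4, expr_threshold = 47,
                         loo = TRUE, seed = NULL, out_dir = NULL) {
  if (inherits(panel, "panel_config")) panel <- simulate_panel(panel)
  stopifnot(inherits(panel, "cc_panel"))
  if (is.null(seed)) seed <- panel$config$seed
  cts <- setdiff(colnames(panel$phenotypes),
                 c("sample", "strain", "cohort", "replicate"))

  geno <- filter_loci(panel$genotypes, panel$immune_genes)
  if (nrow(geno$loci) == 0L)
    stop("locus filtering retained no loci", call. = FALSE)
  probs <- reconstruct_haplotypes(geno, epsilon = epsilon, tau = tau)
  K <- compute_kinship(probs)
  K_scan <- if (length(unique(geno$loci$chrom)) > 1L)
    compute_kinship_loco(probs) else K

  disc <- panel$phenotypes[panel$phenotypes$cohort == "discovery", ,
                           drop = FALSE]
  lod_mat <- matrix(0, nrow(geno$loci), length(cts),
                    dimnames = list(geno$loci$locus, cts))
  thresholds <- stats::setNames(rep(Inf, length(cts)), cts)
  stage1 <- NULL
  for (j in seq_along(cts)) {
    ct <- cts[j]
    y <- disc[[ct]]
    pt <- permutation_threshold(y, disc$strain, probs, K_scan, n_perm = n_perm,
                                fdr_level = fdr_level,
                                seed = stage_seed(seed, 10L + j))
    lod_mat[, ct] <- pt$lod_obs
    thresholds[ct] <- pt$threshold
    cand <- names(pt$lod_obs)[pt$lod_obs >= pt$threshold]
    retained <- if (loo)
      loo_stability(y, disc$strain, probs, K_scan, cand, pt$threshold)
    else cand
    genes <- collapse_to_genes(pt$lod_obs, retained, geno$loci)
    if (nrow(genes)) {
      genes$cell_type <- ct
      stage1 <- rbind(stage1, genes)
    }
  }
  if (is.null(stage1))
    stage1 <- data.frame(gene = character(0), locus = character(0),
                         lod = numeric(0), cell_type = character(0))

  validation <- validate_associations(stage1, panel$phenotypes, geno)
  valid <- validation[validation$validated, , drop = FALSE]

  # LOD profile per validated gene: max LOD over the gene's loci per cell type
  if (nrow(valid)) {
    vg <- unique(valid$gene)
    gene_lod <- matrix(0, length(vg), length(cts),
                       dimnames = list(vg, cts))
    for (g in vg) {
      rows <- geno$loci$locus[!is.na(geno$loci$gene) & geno$loci$gene == g]
      gene_lod[g, ] <- apply(lod_mat[rows, , drop = FALSE], 2L, max)
    }
    cl <- cluster_genes(gene_lod, k_range = k_range,
                        seed = stage_seed(seed, 30L))
    prop <- propagate(cl$labels, gene_lod, valid,
                      threshold_fraction = threshold_fraction)
  } else {
    gene_lod <- matrix(0, 0L, length(cts), dimnames = list(NULL, cts))
    cl <- list(labels = integer(0), k = 0L)
    prop <- structure(list(associations = data.frame(
      gene = character(0), cell_type = character(0), origin = character(0)),
      cluster_medians = NULL, cluster_cell_types = NULL, labels = integer(0)),
      class = "propagation_result")
  }

  expressed <- binarize_expression(panel$expression$matrix,
                                   threshold = expr_threshold)
  classified <- classify_associations(prop$associations, expressed,
                                      panel$expression$population_map)
  tall <- tally_classifications(classified)

  records <- if (nrow(classified)) {
    gene_evolution_records(classified, panel$conservation)
  } else structure(data.frame(gene = character(0),
                              mean_conservation = numeric(0),
                              has_cyto_trans = logical(0),
                              multi_cell_type = logical(0)),
                   class = c("gene_evolution", "data.frame"))
  all_genes <- unique(panel$conservation$cds$gene)
  bg_scores <- vapply(all_genes, function(g)
    gene_conservation_score(g, panel$conservation), 0)
  background <- list(
    immune_background = stats::na.omit(bg_scores[all_genes %in%
                                                   panel$immune_genes]),
    non_immune_background = stats::na.omit(bg_scores[!(all_genes %in%
                                                         panel$immune_genes)]))
  conservation <- run_comparisons(records, background = background)

  recovery <- if (!is.null(panel$truth)) {
    planted <- paste(panel$truth$qtl$gene, panel$truth$qtl$cell_type)
    got_valid <- paste(valid$gene, valid$cell_type)
    got_final <- paste(classified$gene, classified$cell_type)
    modes_ok <- vapply(seq_len(nrow(panel$truth$qtl)), function(i) {
      q <- panel$truth$qtl[i, ]
      hit <- classified$gene == q$gene & classified$cell_type == q$cell_type
      any(hit) && all(classified$mode[hit] == q$mode, na.rm = TRUE)
    }, logical(1))
    list(n_planted = nrow(panel$truth$qtl),
         recovered_validated = mean(planted %in% got_valid),
         recovered_final = mean(planted %in% got_final),
         mode_accuracy = if (any(planted %in% got_final))
           mean(modes_ok[planted %in% got_final]) else NA_real_)
  } else NULL

  report <- structure(list(
    filter = attr(geno, "filter_report"), loci = geno$loci,
    kinship = K, lod = lod_mat, thresholds = thresholds, stage1 = stage1,
    validation = validation, clusters = cl, propagation = prop,
    classified = classified, tally = tall,
    gene_records = records, conservation = conservation,
    recovery = recovery,
    params = list(n_perm = n_perm, fdr_level = fdr_level, epsilon = epsilon,
                  tau = tau, threshold_fraction = threshold_fraction,
                  expr_threshold = expr_threshold, loo = loo, seed = seed)),
    class = "cc_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    pr <- data.frame(strain = rep(dimnames(probs)[[1L]],
                                  times = dim(probs)[2L]),
                     locus = rep(dimnames(probs)[[2L]],
                                 each = dim(probs)[1L]),
                     matrix(probs, ncol = dim(probs)[3L],
                            dimnames = list(NULL, dimnames(probs)[[3L]])),
                     check.names = FALSE)
    utils::write.table(pr, file.path(out_dir, "haplotype_probs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.cc_report <- function(x, ...) {
  cat("cc_report\n")
  cat(sprintf("  loci after filtering: %d (of %d)\n",
              x$filter[["loci_out"]], x$filter[["loci_in"]]))
  cat(sprintf("  stage-1 associations: %d; validated: %d; final: %d\n",
              nrow(x$stage1), sum(x$validation$validated),
              nrow(x$classified)))
  print(x$tally)
  print(x$conservation)
  if (!is.null(x$recovery))
    cat(sprintf("  truth recovery: %.0f%% validated, %.0f%% final, mode accuracy %s\n",
                100 * x$recovery$recovered_validated,
                100 * x$recovery$recovered_final,
                ifelse(is.na(x$recovery$mode_accuracy), "NA",
                       sprintf("%.0f%%", 100 * x$recovery$mode_accuracy))))
  invisible(x)
}

# serialize the per-stage artifacts as TSV/JSON
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  w <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  w(data.frame(locus = rownames(report$lod), report$lod, check.names = FALSE),
    "scan_lod.tsv")
  w(data.frame(strain = rownames(report$kinship), report$kinship,
               check.names = FALSE), "kinship.tsv")
  w(report$conservation$ecdf, "ecdf_scores.tsv")
  w(data.frame(cell_type = names(report$thresholds),
               threshold = report$thresholds), "thresholds.tsv")
  w(report$stage1, "associations_stage1.tsv")
  w(as.data.frame(report$validation), "validation.tsv")
  w(report$propagation$associations, "propagated_associations.tsv")
  w(as.data.frame(report$classified), "classified_associations.tsv")
  w(report$tally$trans_edges, "trans_edges.tsv")
  w(as.data.frame(report$gene_records), "gene_conservation.tsv")
  if (length(report$clusters$labels))
    w(data.frame(gene = names(report$clusters$labels),
                 cluster = report$clusters$labels), "clusters.tsv")
  jsonlite::write_json(
    list(tally = report$tally[c("n_cis", "n_trans", "pct_cis", "pct_trans",
                                "total", "genes_cis", "genes_trans")],
         comparisons = report$conservation$comparisons,
         chi2 = report$conservation$chi2,
         recovery = report$recovery, params = report$params),
    p("report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(p("report.json"))
}

#' Load a panel from plain-text artifacts
#'
#' Reads back the files written by [write_panel()], failing with a clear
#' error naming any missing path. The truth record is optional.
#'
#' @param dir Directory holding the panel artifacts.
#' @return A `cc_panel` (without mosaics; `truth` is `NULL` when absent).
#' @export
load_panel <- function(dir) {
  need <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    path
  }
  geno <- read_genotypes(need("genotypes.tsv"))
  pheno <- utils::read.table(need("phenotypes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
  expr_d <- utils::read.table(need("expression.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE)
  em <- as.matrix(expr_d[, -1, drop = FALSE])
  rownames(em) <- expr_d[[1L]]
  pm_d <- utils::read.table(need("population_map.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  pmap <- split(pm_d$population, pm_d$cell_type)
  bed <- function(f, extra = character(0)) {
    utils::read.table(need(f), header = FALSE, sep = "\t",
                      col.names = c("chrom", "start", "end", extra),
                      stringsAsFactors = FALSE)
  }
  cons <- structure(list(cds = bed("cds.bed", "gene"),
                         elements = bed("conserved_elements.bed"),
                         scores = bed("site_scores.bedgraph", "score")),
                    class = "conservation_input")
  immune <- readLines(need("immune_genes.txt"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    t <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    structure(list(qtl = as.data.frame(t$qtl),
                   trans_genes = t$trans_genes,
                   conservation_group_means = unlist(
                     t$conservation_group_means)),
              class = "truth_record")
  } else NULL
  cfg_stub <- panel_config(
    n_founders = nrow(geno$founders),
    n_strains = length(unique(pheno$strain)),
    n_discovery = length(unique(pheno$strain[pheno$cohort == "discovery"])),
    n_loci = nrow(geno$loci), n_genes = length(unique(cons$cds$gene)),
    n_cell_types = ncol(pheno) - 4L,
    n_chromosomes = length(unique(geno$loci$chrom)))
  structure(list(config = cfg_stub, truth = truth, genotypes = geno,
                 phenotypes = pheno,
                 expression = structure(list(matrix = em,
                                             population_map = pmap,
                                             expressed = NULL),
                                        class = "expression_panel"),
                 conservation = cons, immune_genes = immune),
            class = "cc_panel")
}

#' Re-run classification and conservation on human gene lists
#'
#' The human entry point skips every QTL stage: it takes a pre-computed
#' association table (gene, blood cell type), a pre-binarized expression
#' table, and per-gene conservation scores, classifies each association as
#' cyto-cis or cyto-trans, tallies, and runs the cyto-trans vs cis-only
#' conservation comparison.
#'
#' @param assoc data.frame with columns `gene` and `cell_type`; cell types
#'   must be among basophil, eosinophil, lymphocyte, monocyte, neutrophil.
#' @param expressed Logical cell-types x genes matrix (pre-binarized
#'   detected/not-detected calls). If `lymphocyte_rule = TRUE`, rows `B` and
#'   `T` must be present and the lymphocyte row is derived as their AND
#'   (genes expressed in both B and T cells).
#' @param conservation_scores Named numeric vector of per-gene mean
#'   conservation scores.
#' @param lymphocyte_rule Derive the lymphocyte composite from B and T rows.
#' @return list of class `human_report`: `classified`, `tally`,
#'   `comparison` (one-sided KS of cyto-trans vs cis-only genes).
#' @export
run_human_mode <- function(assoc, expressed, conservation_scores,
                           lymphocyte_rule = FALSE) {
  allowed <- c("basophil", "eosinophil", "lymphocyte", "monocyte",
               "neutrophil")
  bad <- setdiff(unique(assoc$cell_type), allowed)
  if (length(bad))
    stop("unknown cell type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (lymphocyte_rule) {
    if (!all(c("B", "T") %in% rownames(expressed)))
      stop("lymphocyte_rule requires B and T rows", call. = FALSE)
    expressed <- rbind(expressed,
                       lymphocyte = expressed["B", ] & expressed["T", ])
    expressed <- expressed[setdiff(rownames(expressed), c("B", "T")), ,
                           drop = FALSE]
  }
  pmap <- stats::setNames(as.list(intersect(allowed, rownames(expressed))),
                          intersect(allowed, rownames(expressed)))
  missing_ct <- setdiff(unique(assoc$cell_type), names(pmap))
  if (length(missing_ct))
    stop("expression table lacks cell type(s): ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  classified <- classify_associations(assoc, expressed, pmap)
  tall <- tally_classifications(classified)
  flags <- assign_groups(classified)
  flags$mean_conservation <- conservation_scores[flags$gene]
  ok <- !is.na(flags$mean_conservation)
  a <- flags$mean_conservation[ok & flags$has_cyto_trans]
  b <- flags$mean_conservation[ok & !flags$has_cyto_trans]
  comparison <- if (length(a) >= 2L && length(b) >= 2L) ks_one_sided(a, b)
  else list(skipped = "fewer than 2 genes in a group", n_a = length(a),
            n_b = length(b))
  structure(list(classified = classified, tally = tall,
                 comparison = comparison),
            class = "human_report")
}
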