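# Evolutionary conservation: per-gene mean PhastCons-style scores over
# conserved elements intersected with coding sequence, group assignment, and
# the one-sided Kolmogorov-Smirnov / chi-square comparisons.

#' Per-gene mean conservation score
#'
#' Averages per-site conservation scores over the positions lying in the
#' intersection of the gene's coding intervals with the conserved elements
#' (all intervals 0-based half-open). By default every site carries equal
#' weight; `weighting = "element"` instead averages, over elements, each
#' element's mean site score within the CDS.
#'
#' @param gene Gene id (matched against `input$cds$gene`).
#' @param input A `conservation_input` (see [generate_conservation()] for the
#'   layout: `cds`, `elements`, `scores` data.frames).
#' @param weighting `"site"` (default) or `"element"`.
#' @return The mean score in \[0, 1\], or `NA` when no conserved element
#'   overlaps the gene's CDS.
#' @export
gene_conservation_score <- function(gene, input, weighting = c("site",
                                                               "element")) {
  weighting <- match.arg(weighting)
  cds <- input$cds[input$cds$gene == gene, , drop = FALSE]
  if (nrow(cds) == 0L) stop("gene has no CDS annotation: ", gene,
                            call. = FALSE)
  chrom <- cds$chrom[1L]
  el <- input$elements[input$elements$chrom == chrom, , drop = FALSE]
  if (nrow(el) == 0L) return(NA_real_)
  cds_r <- IRanges::reduce(IRanges::IRanges(cds$start + 1L, cds$end))
  el_r <- IRanges::IRanges(el$start + 1L, el$end)
  hits <- IRanges::findOverlaps(el_r, cds_r)
  if (length(hits) == 0L) return(NA_real_)
  pieces <- IRanges::pintersect(el_r[S4Vectors::queryHits(hits)],
                                cds_r[S4Vectors::subjectHits(hits)])
  pos <- unlist(Map(seq.int, IRanges::start(pieces),
                    IRanges::end(pieces))) - 1L  # 0-based
  element_of <- rep(S4Vectors::queryHits(hits), IRanges::width(pieces))
  scores <- site_scores(pos, chrom, input$scores)
  per_element <- split(scores, element_of)
  if (weighting == "site") mean(unlist(per_element))
  else mean(vapply(per_element, mean, 0))
}

# look up per-site scores (0-based positions) in the bedgraph-style table;
# errors if any position lacks a score
site_scores <- function(pos, chrom, scores) {
  sc <- scores[scores$chrom == chrom, , drop = FALSE]
  r <- IRanges::IRanges(sc$start + 1L, sc$end)
  hit <- IRanges::findOverlaps(IRanges::IRanges(pos + 1L, pos + 1L), r,
                               select = "first")
  if (anyNA(hit))
    stop("no conservation score at ", chrom, ":", pos[which(is.na(hit))[1L]],
         call. = FALSE)
  sc$score[hit]
}

#' Score every gene and attach comparison-group flags
#'
#' @param classified A `classified_associations` data.frame (the final
#'   association list).
#' @param input A `conservation_input`.
#' @param weighting Passed to [gene_conservation_score()].
#' @return data.frame of class `gene_evolution`: one row per associated
#'   classifiable gene with `gene`, `mean_conservation` (`NA` when no
#'   conserved element overlaps the CDS), `has_cyto_trans` and
#'   `multi_cell_type` (after lineage collapsing).
#' @export
gene_evolution_records <- function(classified, input, weighting = "site") {
  flags <- assign_groups(classified)
  flags$mean_conservation <- vapply(flags$gene, function(g)
    gene_conservation_score(g, input, weighting), 0)
  out <- flags[, c("gene", "mean_conservation", "has_cyto_trans",
                   "multi_cell_type")]
  class(out) <- c("gene_evolution", "data.frame")
  out
}

#' Assign evolutionary comparison groups to genes
#'
#' `has_cyto_trans`: the gene has at least one cyto-trans association.
#' `multi_cell_type`: the gene is associated with at least two cell types
#' after lineage collapsing, where all B-cell subtypes (B, proB, lateB) count
#' as a single cell type, as do granulocytes and monocytes (GN, MO).
#'
#' @param classified A `classified_associations` data.frame (unclassifiable
#'   rows are ignored).
#' @return data.frame with `gene`, `has_cyto_trans`, `multi_cell_type`.
#' @export
assign_groups <- function(classified) {
  cl <- classified[!is.na(classified$mode), , drop = FALSE]
  genes <- unique(cl$gene)
  collapse <- function(ct) {
    ct[ct %in% c("B", "proB", "lateB")] <- "Blineage"
    ct[ct %in% c("GN", "MO")] <- "myeloid"
    ct
  }
  data.frame(
    gene = genes,
    has_cyto_trans = vapply(genes, function(g)
      any(cl$mode[cl$gene == g] == "trans"), logical(1)),
    multi_cell_type = vapply(genes, function(g)
      length(unique(collapse(cl$cell_type[cl$gene == g]))) >= 2L, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether sample `a` is stochastically smaller than sample `b` (its
#' ECDF lies above): `D = sup over pooled points of (ECDF_a - ECDF_b)`.
#' The asymptotic p-value is `exp(-2 D^2 n_a n_b / (n_a + n_b))`; with
#' `exact = TRUE` (feasible for small samples, no ties) the p-value is the
#' exact tail probability of D+ computed by lattice-path counting.
#'
#' @param a,b Numeric vectors (non-empty). `a` is the focal group
#'   hypothesized to be stochastically smaller (e.g. less conserved).
#' @param exact Use the exact small-sample null distribution.
#' @return list with `D`, `p`, `n_a`, `n_b`.
#' @export
ks_one_sided <- function(a, b, exact = FALSE) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  D <- max(Fa - Fb)
  na <- length(a); nb <- length(b)
  if (exact) {
    if (anyDuplicated(c(a, b))) {
      warning("ties present: falling back to the asymptotic p-value")
      p <- exp(-2 * D^2 * na * nb / (na + nb))
    } else p <- ks_exact_tail(na, nb, D)
  } else {
    p <- exp(-2 * D^2 * na * nb / (na + nb))
  }
  list(D = max(D, 0), p = min(1, p), n_a = na, n_b = nb)
}

# exact P(D+ >= d) by counting monotone lattice paths that never reach
# Fa - Fb >= d; each interleaving of the two samples is equally likely
ks_exact_tail <- function(na, nb, d) {
  if (d <= 0) return(1)
  # N[i+1, j+1] = number of orderings of i a's and j b's with
  # max(i'/na - j'/nb) < d along the whole prefix path
  N <- matrix(0, na + 1L, nb + 1L)
  N[1L, 1L] <- 1
  for (i in 0:na) for (j in 0:nb) {
    if (i == 0L && j == 0L) next
    if (i / na - j / nb >= d - 1e-12) { N[i + 1L, j + 1L] <- 0; next }
    acc <- 0
    if (i > 0L) acc <- acc + N[i, j + 1L]
    if (j > 0L) acc <- acc + N[i + 1L, j]
    N[i + 1L, j + 1L] <- acc
  }
  1 - N[na + 1L, nb + 1L] / choose(na + nb, na)
}

#' Chi-square test of cyto-trans enrichment among multi-cell-type genes
#'
#' Pearson chi-square with 1 degree of freedom on the 2x2 table of gene
#' counts (has_cyto_trans x multi_cell_type), without continuity correction
#' by default.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction.
#' @return list with `statistic`, `p`, and `low_expected` (`TRUE` when any
#'   expected cell count is below 5, where the asymptotic chi-square
#'   approximation is unreliable).
#' @export
chi2_enrichment <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || sum(table) == 0)
    stop("table must contain non-negative counts with a positive total",
         call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0))
    stop("zero expected cell count: test undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       low_expected = any(expected < 5))
}

#' Conservation comparisons between association classes
#'
#' Runs the three one-sided KS comparisons — (a) genes with any cyto-trans
#' association vs cis-only genes, (b) multi- vs single-cell-type genes, and
#' (c) within multi-cell-type genes, cyto-trans vs not — plus the chi-square
#' test of cyto-trans enrichment among multi-cell-type genes, and exports
#' ECDF tables (including optional background score sets). In every KS
#' comparison the focal group (named first) is tested as stochastically less
#' conserved. Genes with missing conservation scores are dropped per
#' comparison; a comparison with fewer than two genes in either group is
#' skipped with a report entry.
#'
#' @param records A `gene_evolution` data.frame.
#' @param background Optional named list of numeric score vectors (e.g.
#'   immune-set and genome background) added to the ECDF export.
#' @param exact Passed to [ks_one_sided()].
#' @return list of class `conservation_report`: `comparisons` (named list
#'   with `D`, `p`, group sizes or a `skipped` reason), `chi2`, `table`
#'   (the 2x2 gene count table), `ecdf` (long data.frame `group`, `score`),
#'   `n_missing` (genes dropped for missing scores).
#' @export
run_comparisons <- function(records, background = NULL, exact = FALSE) {
  ok <- !is.na(records$mean_conservation)
  r <- records[ok, , drop = FALSE]
  cmp <- list()
  one <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
      return(list(skipped = "fewer than 2 genes in a group",
                  n_a = length(a), n_b = length(b)))
    ks_one_sided(a, b, exact = exact)
  }
  cmp$trans_vs_cis_only <- one(r$mean_conservation[r$has_cyto_trans],
                               r$mean_conservation[!r$has_cyto_trans])
  cmp$multi_vs_single <- one(r$mean_conservation[r$multi_cell_type],
                             r$mean_conservation[!r$multi_cell_type])
  m <- r[r$multi_cell_type, , drop = FALSE]
  cmp$multi_trans_vs_multi_cis <- one(m$mean_conservation[m$has_cyto_trans],
                                      m$mean_conservation[!m$has_cyto_trans])
  tab <- with(records, table(factor(has_cyto_trans, c(FALSE, TRUE)),
                             factor(multi_cell_type, c(FALSE, TRUE))))
  tab <- matrix(as.numeric(tab), 2L, 2L,
                dimnames = list(has_cyto_trans = c("no", "yes"),
                                multi_cell_type = c("no", "yes")))
  chi2 <- tryCatch(chi2_enrichment(tab),
                   error = function(e) list(skipped = conditionMessage(e)))
  ecdf_tab <- data.frame(
    group = rep(c("cyto_trans", "cis_only"),
                c(sum(r$has_cyto_trans), sum(!r$has_cyto_trans))),
    score = c(r$mean_conservation[r$has_cyto_trans],
              r$mean_conservation[!r$has_cyto_trans]))
  for (nm in names(background)) {
    ecdf_tab <- rbind(ecdf_tab, data.frame(group = nm,
                                           score = background[[nm]]))
  }
  structure(list(comparisons = cmp, chi2 = chi2, table = tab,
                 ecdf = ecdf_tab, n_missing = sum(!ok)),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("conservation_report\n")
  for (nm in names(x$comparisons)) {
    c_ <- x$comparisons[[nm]]
    if (!is.null(c_$skipped))
      cat(sprintf("  %s: skipped (%s)\n", nm, c_$skipped))
    else
      cat(sprintf("  %s: D = %.3f, one-sided KS p = %.3g (n = %d vs %d)\n",
                  nm, c_$D, c_$p, c_$n_a, c_$n_b))
  }
  if (is.null(x$chi2$skipped))
    cat(sprintf("  chi-square enrichment: X2 = %.3f, p = %.3g\n",
                x$chi2$statistic, x$chi2$p))
  if (x$n_missing > 0L)
    cat(sprintf("  %d genes dropped (no conserved element in CDS)\n",
                x$n_missing))
  invisible(x)
}
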