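# Cyto-cis / cyto-trans classification of gene-cell-type associations.
#
# A gene associated with the frequency of a cell type in which it is
# expressed acts in cyto-cis; a gene silent in the associated cell type (but
# expressed elsewhere) acts in cyto-trans and must influence that cell type
# through interaction between cell types.

#' Binarize a reference expression matrix
#'
#' A gene is called expressed in a population iff its intensity is at or
#' above `threshold`. The default, 47 a.u., is the microarray level below
#' which a gene is silent with 95% or greater probability under the
#' two-Gaussian decomposition of expression histograms; using this low bound
#' (rather than the 120 a.u. confident-expression bound) is conservative
#' against over-calling cyto-trans. Exact equality with the threshold counts
#' as expressed.
#'
#' @param matrix Populations x genes intensity matrix (non-negative).
#' @param threshold Detection threshold in the same units (default 47).
#' @return Logical matrix of the same shape.
#' @export
binarize_expression <- function(matrix, threshold = 47) {
  stopifnot(threshold > 0)
  if (any(matrix < 0)) stop("negative expression intensities", call. = FALSE)
  matrix >= threshold
}

#' Is a gene expressed in an assay cell type?
#'
#' A cell type may be defined by several reference populations; the gene
#' counts as expressed in the cell type if at least one mapped population
#' expresses it. For pre-binarized human data, the lymphocyte composite uses
#' the stricter both-B-and-T rule via `require_all`.
#'
#' @param gene Gene id (column of `expressed`).
#' @param cell_type Assay cell type (name in `population_map`).
#' @param expressed Logical populations x genes matrix from
#'   [binarize_expression()].
#' @param population_map Named list: cell type -> character vector of
#'   reference populations.
#' @param require_all If `TRUE`, the gene must be expressed in every mapped
#'   population (the human "lymphocytes = both B and T" rule).
#' @return Logical scalar.
#' @export
gene_expressed_in_celltype <- function(gene, cell_type, expressed,
                                       population_map, require_all = FALSE) {
  pops <- population_map[[cell_type]]
  if (is.null(pops)) stop("cell type not covered by population map: ",
                          cell_type, call. = FALSE)
  if (!all(pops %in% rownames(expressed)))
    stop("population map names populations absent from the expression matrix",
         call. = FALSE)
  v <- expressed[pops, gene]
  if (require_all) all(v) else any(v)
}

#' Classify associations as cyto-cis or cyto-trans
#'
#' An association is cyto-cis iff the gene is expressed in the associated
#' cell type (per [gene_expressed_in_celltype()]); otherwise cyto-trans. The
#' full set of assay cell types expressing the gene is recorded for the
#' trans edge list. Genes absent from the expression matrix are flagged
#' unclassifiable and excluded from tallies.
#'
#' @param assoc data.frame with columns `gene` and `cell_type` (extra columns
#'   are preserved).
#' @param expressed Logical populations x genes matrix.
#' @param population_map Named list: cell type -> populations.
#' @param require_all Passed to [gene_expressed_in_celltype()] per cell type;
#'   either a single logical or a named logical vector by cell type (for the
#'   human lymphocyte composite).
#' @return data.frame of class `classified_associations` with added `mode`
#'   (`"cis"`, `"trans"` or `NA` for unclassifiable) and `expressed_in`
#'   (comma-separated assay cell types expressing the gene).
#' @export
classify_associations <- function(assoc, expressed, population_map,
                                  require_all = FALSE) {
  cts <- names(population_map)
  req <- if (length(require_all) == 1L)
    stats::setNames(rep(require_all, length(cts)), cts) else require_all
  mode <- rep(NA_character_, nrow(assoc))
  expr_in <- rep(NA_character_, nrow(assoc))
  for (i in seq_len(nrow(assoc))) {
    g <- assoc$gene[i]
    if (!(assoc$cell_type[i] %in% cts))
      stop("cell type not covered by population map: ", assoc$cell_type[i],
           call. = FALSE)
    if (!(g %in% colnames(expressed))) next  # unclassifiable
    in_ct <- vapply(cts, function(ct)
      gene_expressed_in_celltype(g, ct, expressed, population_map,
                                 require_all = isTRUE(req[[ct]])), logical(1))
    expr_in[i] <- paste(cts[in_ct], collapse = ",")
    mode[i] <- if (isTRUE(in_ct[[assoc$cell_type[i]]])) "cis" else "trans"
  }
  out <- cbind(assoc, data.frame(mode = mode, expressed_in = expr_in,
                                 stringsAsFactors = FALSE))
  class(out) <- c("classified_associations", "data.frame")
  out
}

#' Tally cyto-cis / cyto-trans associations
#'
#' Counts and percentages of cis and trans associations overall and per cell
#' type, distinct gene counts per mode, and the bipartite expressed-in ->
#' associated-with edge list for the trans associations.
#'
#' @param classified A `classified_associations` data.frame.
#' @return list of class `cyto_tally`: `n_cis`, `n_trans`, `n_unclassifiable`,
#'   `pct_cis`, `pct_trans` (percent of classifiable associations), `total`
#'   (classifiable), `genes_cis`, `genes_trans` (distinct gene counts),
#'   `by_cell_type` (data.frame), `trans_edges` (data.frame
#'   `source_cell_type`, `target_cell_type`, `gene`).
#' @export
tally_classifications <- function(classified) {
  cl <- classified[!is.na(classified$mode), , drop = FALSE]
  n_cis <- sum(cl$mode == "cis")
  n_trans <- sum(cl$mode == "trans")
  total <- n_cis + n_trans
  pct <- function(k) if (total == 0L) NA_real_ else 100 * k / total
  by_ct <- if (nrow(cl)) {
    tb <- table(cl$cell_type, factor(cl$mode, c("cis", "trans")))
    data.frame(cell_type = rownames(tb), n_cis = as.integer(tb[, "cis"]),
               n_trans = as.integer(tb[, "trans"]), row.names = NULL)
  } else data.frame(cell_type = character(0), n_cis = integer(0),
                    n_trans = integer(0))
  tr <- cl[cl$mode == "trans", , drop = FALSE]
  edges <- if (nrow(tr)) {
    do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      src <- strsplit(tr$expressed_in[i], ",", fixed = TRUE)[[1L]]
      src <- src[nzchar(src)]
      if (length(src) == 0L) return(NULL)
      data.frame(source_cell_type = src, target_cell_type = tr$cell_type[i],
                 gene = tr$gene[i], stringsAsFactors = FALSE)
    }))
  } else NULL
  if (is.null(edges))
    edges <- data.frame(source_cell_type = character(0),
                        target_cell_type = character(0), gene = character(0))
  structure(list(
    n_cis = n_cis, n_trans = n_trans,
    n_unclassifiable = sum(is.na(classified$mode)),
    pct_cis = pct(n_cis), pct_trans = pct(n_trans), total = total,
    genes_cis = length(unique(cl$gene[cl$mode == "cis"])),
    genes_trans = length(unique(cl$gene[cl$mode == "trans"])),
    by_cell_type = by_ct, trans_edges = edges), class = "cyto_tally")
}

#' @export
print.cyto_tally <- function(x, ...) {
  if (x$total == 0L) {
    cat("cyto_tally: no classifiable associations\n")
    return(invisible(x))
  }
  cat(sprintf("cyto_tally: %d associations: %d cyto-cis (%.1f%%, %d genes), %d cyto-trans (%.1f%%, %d genes)\n",
              x$total, x$n_cis, x$pct_cis, x$genes_cis, x$n_trans,
              x$pct_trans, x$genes_trans))
  if (x$n_unclassifiable > 0L)
    cat(sprintf("  %d unclassifiable (gene absent from expression reference)\n",
                x$n_unclassifiable))
  invisible(x)
}
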