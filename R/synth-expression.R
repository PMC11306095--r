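# Reference expression matrix and cell-type -> population map generator.

#' Generate a reference expression matrix and population map
#'
#' Emulates a sorted-population microarray compendium. Intensities come from a
#' two-component Gaussian mixture: a silent component (default mean 20 a.u.)
#' well below the 47 a.u. detection threshold and an expressed component
#' (default mean 200 a.u.) above the 120 a.u. confident-expression level.
#' Each assay cell type maps to one or more reference populations; the B-cell
#' and granulocyte subsets map to two populations each so that the
#' "expressed in at least one mapped subpopulation" rule is exercised.
#'
#' Planted truth is respected by construction: a cyto-cis QTL gene is expressed
#' in at least one population mapped to its target cell type; a cyto-trans QTL
#' gene is silent in every population mapped to its target cell type (silent
#' draws there are resampled below the detection threshold) and expressed in
#' at least one population mapped to a different cell type.
#'
#' @param truth A `truth_record`.
#' @param config A [panel_config()].
#' @return A list of class `expression_panel`: `matrix` (populations x genes
#'   intensity matrix), `population_map` (named list: cell type -> character
#'   vector of populations), `expressed` (the underlying boolean
#'   expressed-component indicator).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "truth_record"), inherits(config, "panel_config"))
  with_seed(stage_seed(config$seed, 5L), {
    cts <- cell_type_names(config$n_cell_types)
    pmap <- lapply(cts, function(ct)
      if (ct %in% c("B", "GN")) paste0(ct, ".", 1:2) else paste0(ct, ".1"))
    names(pmap) <- cts
    pops <- unlist(pmap, use.names = FALSE)
    genes <- sprintf("G%04d", seq_len(config$n_genes))

    expressed <- matrix(stats::runif(length(pops) * length(genes)) < 0.5,
                        length(pops), length(genes),
                        dimnames = list(pops, genes))
    for (i in seq_len(nrow(truth$qtl))) {
      q <- truth$qtl[i, ]
      own <- pmap[[q$cell_type]]
      if (q$mode == "cis") {
        if (!any(expressed[own, q$gene])) expressed[own[1L], q$gene] <- TRUE
      } else {
        expressed[own, q$gene] <- FALSE
        other <- setdiff(pops, own)
        if (!any(expressed[other, q$gene]))
          expressed[other[sample.int(length(other), 1L)], q$gene] <- TRUE
      }
    }

    m <- matrix(stats::rnorm(length(expressed),
                             ifelse(expressed, config$expr_expressed_mean,
                                    config$expr_silent_mean),
                             config$expr_sd),
                nrow(expressed), ncol(expressed), dimnames = dimnames(expressed))
    m[m < 0] <- 0
    # planted-mode consistency must hold exactly: silent draws for a planted
    # trans gene in its own cell type's populations stay below detection
    for (i in which(truth$qtl$mode == "trans")) {
      q <- truth$qtl[i, ]
      own <- pmap[[q$cell_type]]
      bad <- own[m[own, q$gene] >= 47]
      while (length(bad)) {
        m[bad, q$gene] <- pmax(0, stats::rnorm(length(bad),
                                               config$expr_silent_mean,
                                               config$expr_sd))
        bad <- bad[m[bad, q$gene] >= 47]
      }
    }
    structure(list(matrix = m, population_map = pmap, expressed = expressed),
              class = "expression_panel")
  })
}
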