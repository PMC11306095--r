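# One-call panel simulation plus plain-text serialization.

#' Simulate a complete synthetic panel
#'
#' Runs every generator in order — founders, truth planting, strain mosaics,
#' phenotypes, expression reference, conservation tracks — under seeds derived
#' deterministically from `config$seed`. Two calls with the same configuration
#' produce bit-identical panels.
#'
#' @param config A [panel_config()].
#' @return An object of class `cc_panel`: list with elements `config`,
#'   `founders`, `truth`, `mosaics`, `genotypes`, `phenotypes`, `expression`
#'   (an `expression_panel`), `conservation` and `immune_genes`.
#' @export
#' @examples
#' panel <- simulate_panel(panel_config(n_strains = 8, n_discovery = 5,
#'                                      n_loci = 30, n_genes = 6,
#'                                      n_cell_types = 3, seed = 7))
#' panel
simulate_panel <- function(config = panel_config()) {
  founders <- generate_founders(config)
  truth <- make_truth(founders, config)
  mosaics <- generate_strains(founders, config)
  pheno <- generate_phenotypes(mosaics, truth, config)
  expr <- generate_expression(truth, config)
  cons <- generate_conservation(truth, config)
  structure(list(config = config, founders = founders, truth = truth,
                 mosaics = mosaics, genotypes = mosaics$genotypes,
                 phenotypes = pheno, expression = expr, conservation = cons,
                 immune_genes = founders$immune_genes),
            class = "cc_panel")
}

#' @export
print.cc_panel <- function(x, ...) {
  cat("Synthetic CC-like panel\n")
  print(x$config)
  cat(sprintf("  planted QTL: %s\n",
              paste(sprintf("%s/%s(%s)", x$truth$qtl$gene,
                            x$truth$qtl$cell_type, x$truth$qtl$mode),
                    collapse = ", ")))
  invisible(x)
}

#' Write a panel to plain-text artifacts
#'
#' Serializes a simulated panel to the pipeline's on-disk dialect:
#' `genotypes.tsv` (locus annotation plus one allele column per founder and
#' strain), `phenotypes.tsv`, `expression.tsv` (population x gene),
#' `population_map.tsv`, `cds.bed`, `conserved_elements.bed` (0-based
#' half-open), `site_scores.bedgraph` and `truth.json`.
#'
#' @param panel A `cc_panel`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "cc_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  g <- panel$genotypes
  geno <- cbind(g$loci,
                as.data.frame(t(g$founders)),
                as.data.frame(t(g$strains)))
  utils::write.table(geno, p("genotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$phenotypes, p("phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- data.frame(population = rownames(panel$expression$matrix),
                     panel$expression$matrix, check.names = FALSE)
  utils::write.table(expr, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pm <- data.frame(cell_type = rep(names(panel$expression$population_map),
                                   lengths(panel$expression$population_map)),
                   population = unlist(panel$expression$population_map))
  utils::write.table(pm, p("population_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cons <- panel$conservation
  utils::write.table(cons$cds[, c("chrom", "start", "end", "gene")],
                     p("cds.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cons$elements[, c("chrom", "start", "end")],
                     p("conserved_elements.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cons$scores[, c("chrom", "start", "end", "score")],
                     p("site_scores.bedgraph"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(panel$immune_genes, p("immune_genes.txt"))
  truth <- panel$truth
  jsonlite::write_json(
    list(qtl = truth$qtl, trans_genes = truth$trans_genes,
         conservation_group_means = as.list(truth$conservation_group_means)),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(genotypes = p("genotypes.tsv"), phenotypes = p("phenotypes.tsv"),
             expression = p("expression.tsv"),
             population_map = p("population_map.tsv"), cds = p("cds.bed"),
             elements = p("conserved_elements.bed"),
             scores = p("site_scores.bedgraph"),
             immune_genes = p("immune_genes.txt"), truth = p("truth.json"))
  invisible(files)
}

#' Read a genotype table from the pipeline's TSV dialect
#'
#' @param path Path to a `genotypes.tsv` written by [write_panel()].
#' @param founder_prefix,strain_prefix Column-name prefixes distinguishing
#'   founder and strain allele columns.
#' @return A `cc_genotypes` object.
#' @export
read_genotypes <- function(path, founder_prefix = "F", strain_prefix = "S") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  ann <- c("locus", "chrom", "pos", "gene", "exonic")
  stopifnot(all(ann %in% names(d)))
  rest <- setdiff(names(d), ann)
  fcols <- rest[grepl(paste0("^", founder_prefix, "[0-9]+$"), rest)]
  scols <- rest[grepl(paste0("^", strain_prefix, "[0-9]+$"), rest)]
  loci <- d[, ann]
  fm <- t(as.matrix(d[, fcols, drop = FALSE]))
  colnames(fm) <- loci$locus
  sm <- if (length(scols)) {
    m <- t(as.matrix(d[, scols, drop = FALSE]))
    colnames(m) <- loci$locus
    m
  } else NULL
  new_cc_genotypes(loci, fm, sm)
}
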