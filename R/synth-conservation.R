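# Per-gene conservation-track generator (PhastCons-like).

#' Generate synthetic conservation tracks
#'
#' For every gene, emits a coding-sequence (CDS) interval set, a set of
#' conserved elements overlapping the CDS, and per-site conservation scores in
#' \[0, 1\] covering all element positions (all intervals 0-based half-open,
#' BED convention). Genes flagged cyto-trans in the truth record draw their
#' site scores from a Beta distribution with the lower planted group mean;
#' all other genes use the higher mean. A small configurable fraction of
#' genes receives no conserved element overlapping its CDS, so downstream
#' scoring must handle missing gene scores.
#'
#' @param truth A `truth_record` (supplies `trans_genes` and
#'   `conservation_group_means`).
#' @param config A [panel_config()].
#' @return An object of class `conservation_input`: list with data.frames
#'   `cds` (`chrom`, `start`, `end`, `gene`), `elements` (`chrom`, `start`,
#'   `end`) and `scores` (`chrom`, `start`, `end`, `score`; one row per site).
#' @export
generate_conservation <- function(truth, config) {
  stopifnot(inherits(truth, "truth_record"), inherits(config, "panel_config"))
  gm <- truth$conservation_group_means
  if (any(gm <= 0) || any(gm >= 1))
    stop("conservation group means must lie strictly inside (0, 1)",
         call. = FALSE)
  with_seed(stage_seed(config$seed, 6L), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    chrom <- paste0("chr", (seq_along(genes) - 1L) %% config$n_chromosomes + 1L)
    win <- (seq_along(genes) - 1L) * 10000L  # private window per gene

    cds_l <- vector("list", length(genes))
    el_l <- vector("list", length(genes))
    sc_l <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      w <- win[i]
      cds <- data.frame(chrom = chrom[i],
                        start = w + c(1000L, 2000L),
                        end = w + c(1000L + sample(300:500, 1L),
                                    2000L + sample(400:700, 1L)),
                        gene = genes[i], stringsAsFactors = FALSE)
      cds_l[[i]] <- cds
      if (stats::runif(1) < config$cons_missing_rate) {
        # element deliberately outside the CDS: gene has no scored CDS site
        el_l[[i]] <- data.frame(chrom = chrom[i], start = w + 100L,
                                end = w + 160L, stringsAsFactors = FALSE)
        pos <- seq.int(w + 100L, w + 159L)
      } else {
        n_el <- 1L + stats::rpois(1L, 2)
        starts <- sort(sample(seq.int(w + 900L, w + 2600L), n_el))
        lens <- sample(30:80, n_el, replace = TRUE)
        el_l[[i]] <- data.frame(chrom = chrom[i], start = starts,
                                end = starts + lens, stringsAsFactors = FALSE)
        pos <- unlist(Map(function(s, e) seq.int(s, e - 1L), starts,
                          starts + lens))
        pos <- unique(pos)
      }
      mu <- if (genes[i] %in% truth$trans_genes) gm[["trans"]] else gm[["cis"]]
      sc <- stats::rbeta(length(pos), mu * config$cons_kappa,
                         (1 - mu) * config$cons_kappa)
      sc_l[[i]] <- data.frame(chrom = chrom[i], start = pos, end = pos + 1L,
                              score = sc, stringsAsFactors = FALSE)
    }
    structure(list(cds = do.call(rbind, cds_l),
                   elements = do.call(rbind, el_l),
                   scores = do.call(rbind, sc_l)),
              class = "conservation_input")
  })
}
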