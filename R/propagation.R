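# Signal propagation across correlated traits: cluster validated genes by
# their LOD profiles, then associate whole clusters with cell types whose
# median LOD reaches at least 40% of the cluster's highest median.

#' Cluster genes by their LOD profiles across cell types
#'
#' Runs k-means for each candidate number of clusters (with multiple random
#' restarts under a fixed seed) and picks the k maximizing the mean
#' silhouette width (Euclidean distance).
#'
#' @param lod_matrix Numeric matrix, genes x cell types, of per-gene lead
#'   LOD scores (0 where a gene had no tested locus for a cell type).
#' @param k_range Integer vector of candidate cluster counts; silently
#'   truncated to `[2, n_genes - 1]`.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Random restarts per k.
#' @param standardize If `TRUE`, columns are scaled to unit variance before
#'   clustering. Default `FALSE` (raw LODs).
#' @return list with `labels` (named integer vector), `k` (chosen number of
#'   clusters) and `silhouette` (mean silhouette width per candidate k).
#' @export
cluster_genes <- function(lod_matrix, k_range = 2:8, seed = 1L, nstart = 10L,
                          standardize = FALSE) {
  stopifnot(is.matrix(lod_matrix), nrow(lod_matrix) >= 1L)
  n <- nrow(lod_matrix)
  if (n < 3L || nrow(unique(lod_matrix)) < 2L) {
    if (n >= 2L && nrow(unique(lod_matrix)) < 2L)
      warning("all LOD profiles identical: silhouette undefined, one cluster")
    labels <- rep(1L, n)
    names(labels) <- rownames(lod_matrix)
    return(list(labels = labels, k = 1L, silhouette = NULL))
  }
  X <- if (standardize) {
    sds <- apply(lod_matrix, 2L, stats::sd)
    sweep(lod_matrix, 2L, ifelse(sds > 0, sds, 1), "/")
  } else lod_matrix
  k_range <- sort(unique(pmin(pmax(as.integer(k_range), 2L), n - 1L)))
  k_range <- k_range[k_range <= nrow(unique(X))]
  if (length(k_range) == 0L) {
    labels <- rep(1L, n)
    names(labels) <- rownames(lod_matrix)
    return(list(labels = labels, k = 1L, silhouette = NULL))
  }
  D <- stats::dist(X)
  with_seed(seed, {
    sil <- rep(-Inf, length(k_range))
    fits <- vector("list", length(k_range))
    for (i in seq_along(k_range)) {
      fits[[i]] <- tryCatch(
        stats::kmeans(X, centers = k_range[i], nstart = nstart),
        error = function(e) NULL)  # duplicate sampled centers at extreme k
      if (is.null(fits[[i]])) next
      sil[i] <- mean(cluster::silhouette(fits[[i]]$cluster, D)[, "sil_width"])
    }
    if (all(!is.finite(sil))) {
      labels <- rep(1L, n)
      names(labels) <- rownames(lod_matrix)
      return(list(labels = labels, k = 1L, silhouette = NULL))
    }
    best <- which.max(sil)
    labels <- fits[[best]]$cluster
    names(labels) <- rownames(lod_matrix)
    list(labels = labels, k = k_range[best],
         silhouette = stats::setNames(sil, k_range))
  })
}

#' Propagate associations through LOD-profile clusters
#'
#' For each cluster, computes the median LOD per cell type over the cluster's
#' genes; the cluster is associated with every cell type whose median is at
#' least `threshold_fraction` of the cluster's highest median (comparison is
#' `>=`, so "at least 40%" includes exact equality). Every gene in the
#' cluster then gains an association with each such cell type. The final list
#' is the union of the validated input associations and the propagated ones,
#' deduplicated, each flagged by origin.
#'
#' @param labels Named integer vector of cluster labels (from
#'   [cluster_genes()]).
#' @param lod_matrix The same genes x cell types LOD matrix.
#' @param validated data.frame of validated associations (`gene`,
#'   `cell_type`, plus any extra columns kept as-is).
#' @param threshold_fraction Fraction of the top median required (default
#'   0.4).
#' @return list of class `propagation_result` with `associations`
#'   (data.frame `gene`, `cell_type`, `origin` in {validated, propagated}),
#'   `cluster_medians` (clusters x cell types), and `cluster_cell_types`
#'   (list: cluster -> associated cell types).
#' @export
propagate <- function(labels, lod_matrix, validated,
                      threshold_fraction = 0.4) {
  stopifnot(length(labels) == nrow(lod_matrix))
  cls <- sort(unique(labels))
  med <- t(vapply(cls, function(cl) {
    apply(lod_matrix[labels == cl, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(lod_matrix))))
  rownames(med) <- cls
  assoc_ct <- lapply(cls, function(cl) {
    m <- med[as.character(cl), ]
    colnames(lod_matrix)[m >= threshold_fraction * max(m)]
  })
  names(assoc_ct) <- cls

  prop <- do.call(rbind, lapply(cls, function(cl) {
    genes <- names(labels)[labels == cl]
    cts <- assoc_ct[[as.character(cl)]]
    if (length(genes) == 0L || length(cts) == 0L) return(NULL)
    expand.grid(gene = genes, cell_type = cts, stringsAsFactors = FALSE)
  }))
  base <- unique(validated[, c("gene", "cell_type")])
  base$origin <- "validated"
  if (!is.null(prop) && nrow(prop)) {
    key <- paste(prop$gene, prop$cell_type)
    new <- !(key %in% paste(base$gene, base$cell_type)) & !duplicated(key)
    prop <- prop[new, , drop = FALSE]
    if (nrow(prop)) {
      prop$origin <- rep("propagated", nrow(prop))
      out <- rbind(base, prop)
    } else out <- base
  } else out <- base
  rownames(out) <- NULL
  structure(list(associations = out, cluster_medians = med,
                 cluster_cell_types = assoc_ct, labels = labels),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  tb <- table(x$associations$origin)
  cat(sprintf("propagation_result: %d clusters; %d validated + %d propagated associations\n",
              nrow(x$cluster_medians),
              if ("validated" %in% names(tb)) tb[["validated"]] else 0L,
              if ("propagated" %in% names(tb)) tb[["propagated"]] else 0L))
  invisible(x)
}
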