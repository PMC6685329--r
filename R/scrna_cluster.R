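#' PCA embedding and graph-based clustering of single cells
#'
#' Normalizes (median-depth scaling + `log1p`), optionally selects highly
#' variable genes, computes a PCA embedding, builds a shared-nearest-
#' neighbour graph and partitions it by Leiden community detection
#' (modularity objective). A 3D t-SNE of the PCA space can be attached for
#' display; cluster assignment never depends on it. Deterministic given the
#' seed.
#'
#' @param counts A `counts_matrix` (QC-filtered; see [qc_filter()]).
#' @param n_pcs Number of principal components (default 30).
#' @param resolution Leiden resolution parameter.
#' @param n_clusters_hint If supplied, the resolution is tuned by bisection
#'   to yield this many clusters (best effort over `max_tune_iter` steps).
#' @param n_hvg Number of highly variable genes; `Inf` (or >= the gene
#'   count) uses the whole transcriptome.
#' @param k Nearest neighbours for the SNN graph.
#' @param tsne Compute the display-only 3D t-SNE embedding?
#' @param max_tune_iter Bisection steps when tuning to `n_clusters_hint`.
#' @param seed RNG seed.
#' @return A `cluster_result`: `cluster` (factor per cell), `n_clusters`,
#'   `pca` (cells x n_pcs), `tsne` (cells x 3 or NULL), `resolution`,
#'   `composition` (cluster x group counts, when the metadata has groups),
#'   `cell_ids`, `keep` (logical; all TRUE until contaminant removal),
#'   `contaminant_removed`.
#' @export
embed_and_cluster <- function(counts, n_pcs = 30L, resolution = 0.5,
                              n_clusters_hint = NULL, n_hvg = 2000L,
                              k = 15L, tsne = FALSE, max_tune_iter = 12L,
                              seed = NULL) {
  stopifnot(inherits(counts, "counts_matrix"))
  X <- counts$counts
  n_cells <- ncol(X)
  if (n_cells <= n_pcs) {
    stop_clonevasc("fewer cells (", n_cells, ") than principal components (", n_pcs, ")")
  }

  with_seed(seed, {
    norm <- normalize_counts(X)
    v <- hvg_dispersion(X)
    keep_g <- if (is.finite(n_hvg) && n_hvg < nrow(norm)) {
      order(v$z, decreasing = TRUE)[seq_len(n_hvg)]
    } else {
      which(v$var > 0)
    }
    keep_g <- keep_g[v$var[keep_g] > 0]
    Y <- Matrix::t(norm[keep_g, , drop = FALSE])

    pcs <- min(n_pcs, ncol(Y) - 1L, nrow(Y) - 1L)
    pca <- irlba::prcomp_irlba(Y, n = pcs, center = TRUE, scale. = TRUE)
    emb <- pca$x
    rownames(emb) <- colnames(X)

    g <- snn_graph(emb, k = k)

    cluster_at <- function(res) {
      comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                     resolution = res, n_iterations = 5L)
      factor(igraph::membership(comm))
    }

    if (is.null(n_clusters_hint)) {
      cl <- cluster_at(resolution)
      res_used <- resolution
    } else {
      lo <- 0.05; hi <- 6
      best <- NULL; best_gap <- Inf; res_used <- resolution
      for (it in seq_len(max_tune_iter)) {
        mid <- sqrt(lo * hi)
        cl_try <- cluster_at(mid)
        nk <- nlevels(cl_try)
        gap <- abs(nk - n_clusters_hint)
        if (gap < best_gap) {
          best <- cl_try; best_gap <- gap; res_used <- mid
        }
        if (nk == n_clusters_hint) break
        if (nk < n_clusters_hint) lo <- mid else hi <- mid
      }
      cl <- best
    }
    levels(cl) <- seq_len(nlevels(cl))

    tsne_emb <- NULL
    if (isTRUE(tsne)) {
      px <- min(30, max(1, floor((n_cells - 1) / 3) - 1))
      tsne_emb <- Rtsne::Rtsne(emb, dims = 3, pca = FALSE, perplexity = px,
                               check_duplicates = FALSE)$Y
      rownames(tsne_emb) <- colnames(X)
    }

    composition <- NULL
    if ("group" %in% names(counts$cells)) {
      composition <- table(cluster = cl, group = counts$cells$group)
    }

    structure(list(
      cluster = cl,
      n_clusters = nlevels(cl),
      pca = emb,
      tsne = tsne_emb,
      resolution = res_used,
      composition = composition,
      cell_ids = colnames(X),
      keep = rep(TRUE, n_cells),
      contaminant_removed = FALSE,
      removed_clusters = integer(0)
    ), class = "cluster_result")
  })
}

# Highly-variable-gene ranking by dispersion (variance / mean of
# depth-normalized counts), z-scored within 20 mean-expression bins so that
# abundance does not dominate the ranking.
hvg_dispersion <- function(X, n_bins = 20L) {
  depth <- Matrix::colSums(X)
  depth[depth == 0] <- 1
  cn <- X %*% Matrix::Diagonal(x = median(depth) / depth)
  mu <- Matrix::rowMeans(cn)
  sq <- cn
  sq@x <- sq@x^2
  v <- (Matrix::rowMeans(sq) - mu^2) * ncol(cn) / max(1, ncol(cn) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    i <- bins == b
    m <- mean(disp[i]); s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  list(z = z, var = v, mean = mu)
}

# Shared-nearest-neighbour graph with Jaccard edge weights, pruned at 1/15.
snn_graph <- function(emb, k = 15L, prune = 1 / 15) {
  n <- nrow(emb)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(emb, k = k)$nn.index
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1L),
    j = as.vector(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(A)
  snn <- methods::as(shared, "generalMatrix")
  snn@x <- snn@x / (2 * (k + 1L) - snn@x) # Jaccard on the union of neighbourhoods
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  igraph::graph_from_adjacency_matrix(snn, mode = "max", weighted = TRUE)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: %d clusters over %d cells (resolution %.3f)%s\n",
              x$n_clusters, sum(x$keep), x$resolution,
              if (x$contaminant_removed) "; contaminant cluster(s) removed" else ""))
  print(table(x$cluster))
  invisible(x)
}

#' Remove the haematopoietic contaminant cluster(s)
#'
#' Flags clusters whose mean expression of the positive haematopoietic
#' marker (Ptprc/CD45 by default) exceeds the global upper decile while
#' every negative endothelial marker (Pecam-1/CD31 and Kdr/VEGFR2 by
#' default) stays below its global lower quartile, and removes their cells.
#' Rare double-positive cells inside retained clusters (e.g. Ptprc+Pecam1+)
#' are kept and reported as a fraction of retained cells.
#'
#' @param result A `cluster_result` from [embed_and_cluster()].
#' @param counts The `counts_matrix` that was clustered.
#' @param positive Positive marker gene (flagging requires high expression).
#' @param negative Negative marker genes (flagging requires low expression
#'   of all of them).
#' @return The updated `cluster_result`: removed cells are dropped from
#'   `cluster`/`keep`, remaining clusters are renumbered consecutively, and
#'   `removed_clusters` (original labels), `contaminant_removed` and
#'   `double_positive_fraction` (per negative marker) are filled in.
#' @export
remove_contaminant_cluster <- function(result, counts,
                                       positive = "Ptprc",
                                       negative = c("Pecam1", "Kdr")) {
  stopifnot(inherits(result, "cluster_result"), inherits(counts, "counts_matrix"))
  X <- counts$counts
  for (gene in c(positive, negative)) {
    if (!gene %in% rownames(X)) {
      stop_clonevasc("marker gene `", gene, "` is absent from the count matrix")
    }
  }
  norm <- normalize_counts(X)
  pos <- norm[positive, ]
  hi <- quantile(pos, 0.9)
  cl <- result$cluster
  pos_mean <- tapply(pos, cl, mean)
  flagged <- pos_mean > hi
  for (gene in negative) {
    val <- norm[gene, ]
    lo <- quantile(val, 0.25)
    flagged <- flagged & tapply(val, cl, mean) < lo
  }
  removed_clusters <- as.integer(levels(cl)[flagged])

  keep_cell <- !(as.integer(as.character(cl)) %in% removed_clusters)
  out <- result
  out$keep <- result$keep & keep_cell
  new_cl <- droplevels(cl[keep_cell])
  # renumber consecutively, preserving order of original labels
  map <- setNames(seq_along(levels(new_cl)), levels(new_cl))
  out$cluster <- factor(unname(map[as.character(new_cl)]),
                        levels = seq_along(levels(new_cl)))
  out$cluster_map <- map
  out$cell_ids <- result$cell_ids[keep_cell]
  out$pca <- result$pca[keep_cell, , drop = FALSE]
  if (!is.null(result$tsne)) out$tsne <- result$tsne[keep_cell, , drop = FALSE]
  out$n_clusters <- nlevels(out$cluster)
  out$contaminant_removed <- TRUE
  out$removed_clusters <- removed_clusters
  if (!is.null(result$composition)) {
    grp <- counts$cells$group[keep_cell]
    out$composition <- table(cluster = out$cluster, group = grp)
  }

  raw_pos <- X[positive, keep_cell] > 0
  out$double_positive_fraction <- vapply(negative, function(gene) {
    mean(raw_pos & X[gene, keep_cell] > 0)
  }, numeric(1))
  out
}
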