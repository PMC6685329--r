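#' Per-cluster marker detection (one-vs-rest rank-sum tests)
#'
#' For every gene and every cluster, tests the cluster's cells against all
#' other retained cells with a Wilcoxon rank-sum test (normal approximation
#' with tie correction) on log-normalized expression, computes the log2
#' fold-change of mean expression, and adjusts p-values by
#' Benjamini-Hochberg within each cluster. A gene is flagged specific to a
#' cluster when it is a significant marker (adjusted p below `alpha`, log
#' fold-change above `lfc_threshold`) of exactly one cluster.
#'
#' @param result A `cluster_result`.
#' @param counts The `counts_matrix` the clustering was computed from.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param lfc_threshold Minimum log2 fold-change for a marker call.
#' @param min_cells Clusters with fewer cells have undefined markers and are
#'   skipped (recorded in the `skipped_clusters` attribute).
#' @return A `marker_table` data frame with columns `cluster`, `gene`,
#'   `log2_fc`, `statistic` (z), `p`, `p_adj`, `significant`, `specific`,
#'   sorted by cluster then decreasing effect size.
#' @export
cluster_markers <- function(result, counts, alpha = 0.05,
                            lfc_threshold = 0.25, min_cells = 3L) {
  stopifnot(inherits(result, "cluster_result"), inherits(counts, "counts_matrix"))
  if (result$n_clusters < 2L) stop_clonevasc("marker detection needs >= 2 clusters")
  idx <- match(result$cell_ids, colnames(counts$counts))
  if (anyNA(idx)) stop_clonevasc("`counts` does not contain the clustered cells")
  norm <- normalize_counts(counts$counts[, idx, drop = FALSE])
  cl <- result$cluster
  N <- ncol(norm); G <- nrow(norm)

  sizes <- table(cl)
  usable <- names(sizes)[sizes >= min_cells]
  skipped <- setdiff(levels(cl), usable)

  # Dense rank matrix (genes x cells) and per-gene tie terms.
  tn <- Matrix::t(norm) # cells x genes, fast column access
  ranks <- matrix(0, G, N)
  tie_term <- numeric(G)
  for (g in seq_len(G)) {
    x <- tn[, g]
    r <- rank(x)
    ranks[g, ] <- r
    tt <- table(x)
    tie_term[g] <- sum(tt^3 - tt)
  }

  IND <- sapply(usable, function(lv) as.numeric(cl == lv))
  R1 <- ranks %*% IND # G x K rank sums per cluster
  E <- expm1_means(norm, IND)

  out <- vector("list", length(usable))
  for (j in seq_along(usable)) {
    n1 <- sum(cl == usable[j]); n2 <- N - n1
    U <- R1[, j] - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- ifelse(sig2 > 0, (U - mu) / sqrt(sig2), 0)
    p <- 2 * pnorm(-abs(z))
    padj <- p.adjust(p, method = "BH")
    out[[j]] <- data.frame(
      cluster = usable[j],
      gene = rownames(norm),
      log2_fc = log2((E$inside[, j] + 1) / (E$outside[, j] + 1)),
      statistic = z,
      p = p,
      p_adj = padj,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  tab$significant <- tab$p_adj < alpha & tab$log2_fc > lfc_threshold
  n_sig <- tapply(tab$significant, tab$gene, sum)
  tab$specific <- tab$significant & n_sig[tab$gene] == 1L
  tab <- tab[order(tab$cluster, -tab$log2_fc), ]
  rownames(tab) <- NULL
  attr(tab, "skipped_clusters") <- skipped
  class(tab) <- c("marker_table", "data.frame")
  tab
}

expm1_means <- function(norm, IND) {
  ex <- norm
  ex@x <- expm1(ex@x)
  S <- as.matrix(ex %*% IND)          # G x K sums inside each cluster
  tot <- Matrix::rowSums(ex)
  n1 <- colSums(IND)
  inside <- sweep(S, 2, n1, "/")
  outside <- sweep(tot - S, 2, ncol(norm) - n1, "/")
  list(inside = inside, outside = outside)
}

#' Per-cluster group-composition test
#'
#' Tests each cluster for enrichment of one experimental group against the
#' global group ratio with a two-sided exact binomial test conditioned on
#' the cluster size. Clusters composed exclusively of one group are flagged,
#' as are clusters too small to be informative.
#'
#' @param result A `cluster_result` whose `composition` table is filled
#'   (i.e. the cell metadata carried a `group` column).
#' @param min_cells Clusters below this size are flagged `underpowered`.
#' @return Data frame with one row per cluster: `cluster`, `n`,
#'   `healthy_fraction`, `mi_fraction`, `p`, `enriched_group`, `exclusive`,
#'   `underpowered`.
#' @export
composition_test <- function(result, min_cells = 3L) {
  stopifnot(inherits(result, "cluster_result"))
  comp <- result$composition
  if (is.null(comp)) stop_clonevasc("no group labels: composition table is missing")
  comp <- as.matrix(comp)
  if (!all(c("healthy", "mi") %in% colnames(comp))) {
    stop_clonevasc("composition table must have `healthy` and `mi` groups")
  }
  p_global <- sum(comp[, "mi"]) / sum(comp)
  out <- lapply(rownames(comp), function(lv) {
    n <- sum(comp[lv, ])
    n_mi <- comp[lv, "mi"]
    p <- if (n > 0) binom.test(n_mi, n, p = p_global)$p.value else 1
    mi_frac <- if (n > 0) n_mi / n else NA_real_
    data.frame(
      cluster = lv, n = n,
      healthy_fraction = 1 - mi_frac,
      mi_fraction = mi_frac,
      p = p,
      enriched_group = if (n == 0 || p >= 0.05) "none" else
        if (mi_frac > p_global) "mi" else "healthy",
      exclusive = n > 0 && (n_mi == 0L || n_mi == n),
      underpowered = n < min_cells,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-cluster, per-group expression summary of one gene
#'
#' @param result A `cluster_result`.
#' @param counts The `counts_matrix` the clustering was computed from.
#' @param gene Gene name; an absent gene raises an error with nearest-name
#'   suggestions.
#' @return A `gene_query` list: `gene`, `by_cluster` (per-cluster mean
#'   log-normalized expression, detection fraction, and per-group means,
#'   sorted by decreasing mean), `by_group` (overall per-group summary).
#' @export
gene_query <- function(result, counts, gene) {
  stopifnot(inherits(result, "cluster_result"), inherits(counts, "counts_matrix"))
  X <- counts$counts
  if (!gene %in% rownames(X)) {
    sugg <- utils::head(agrep(gene, rownames(X), max.distance = 0.3,
                              ignore.case = TRUE, value = TRUE), 5L)
    stop_clonevasc("gene `", gene, "` not found",
                   if (length(sugg)) paste0("; did you mean: ",
                                            paste(sugg, collapse = ", "), "?") else "")
  }
  idx <- match(result$cell_ids, colnames(X))
  norm <- normalize_counts(X[, idx, drop = FALSE])
  val <- norm[gene, ]
  det <- X[gene, idx] > 0
  cl <- result$cluster
  grp <- counts$cells$group[idx]

  by_cluster <- data.frame(
    cluster = levels(cl),
    mean_expr = as.numeric(tapply(val, cl, mean)),
    detection_fraction = as.numeric(tapply(det, cl, mean)),
    stringsAsFactors = FALSE
  )
  if (!is.null(grp)) {
    for (g in unique(grp)) {
      by_cluster[[paste0("mean_", g)]] <-
        as.numeric(tapply(val * (grp == g), cl, sum) /
                   pmax(1, tapply(as.numeric(grp == g), cl, sum)))
    }
  }
  by_cluster <- by_cluster[order(-by_cluster$mean_expr), ]
  rownames(by_cluster) <- NULL

  by_group <- NULL
  if (!is.null(grp)) {
    by_group <- data.frame(
      group = sort(unique(grp)),
      mean_expr = as.numeric(tapply(val, grp, mean)[sort(unique(grp))]),
      detection_fraction = as.numeric(tapply(det, grp, mean)[sort(unique(grp))]),
      stringsAsFactors = FALSE
    )
  }
  structure(list(gene = gene, by_cluster = by_cluster, by_group = by_group),
            class = "gene_query")
}

#' @export
print.gene_query <- function(x, ...) {
  cat("Expression summary for", x$gene, "\n")
  print(utils::head(x$by_cluster, 10))
  if (!is.null(x$by_group)) print(x$by_group)
  invisible(x)
}
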