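#' Quality-control parameters for single-cell filtering
#'
#' @param min_genes_per_cell Cells with fewer detected genes than this are
#'   removed (strict `<`; a cell with exactly this many genes is retained).
#' @param max_mito_fraction Cells whose mitochondrial transcript fraction
#'   exceeds this are removed (strict `>`; a cell at exactly the threshold
#'   is retained).
#' @param mito_gene_rule Either a prefix string identifying mitochondrial
#'   genes (default `"mt-"`, mouse nomenclature) or an explicit character
#'   vector of gene names.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 400L,
                      max_mito_fraction = 0.20,
                      mito_gene_rule = "mt-") {
  if (min_genes_per_cell < 0) stop_clonevasc("`min_genes_per_cell` must be >= 0")
  check_probability(max_mito_fraction, "max_mito_fraction")
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_rule = mito_gene_rule),
            class = "qc_params")
}

mito_gene_index <- function(genes, rule) {
  if (length(rule) == 1L && !rule %in% genes) {
    which(startsWith(genes, rule))
  } else {
    which(genes %in% rule)
  }
}

#' Filter cells on detected-gene count and mitochondrial fraction
#'
#' Removes cells with a low gene count (fewer than `min_genes_per_cell`
#' detected genes) or a high mitochondrial transcript ratio (above
#' `max_mito_fraction`). Boundary semantics: both filters are strict, so a
#' cell with exactly 400 detected genes or exactly a 0.20 mitochondrial
#' fraction is retained. The returned object carries a QC report recording
#' the removal reason for every cell.
#'
#' @param counts A `counts_matrix`.
#' @param qc A [qc_params()] object.
#' @return The filtered `counts_matrix`, with a `qc_report` element: one row
#'   per input cell with `detected_genes`, `mito_fraction`, `removed` and
#'   `reason` (`"low_genes"`, `"high_mito"`, `"low_genes+high_mito"` or
#'   `""`), plus a `mito_filter_applied` attribute.
#' @export
qc_filter <- function(counts, qc = qc_params()) {
  stopifnot(inherits(counts, "counts_matrix"))
  X <- counts$counts
  detected <- Matrix::colSums(X > 0)
  total <- Matrix::colSums(X)
  mt <- mito_gene_index(rownames(X), qc$mito_gene_rule)
  mito_ok <- length(mt) > 0L
  if (!mito_ok) {
    warning("no mitochondrial genes identifiable under the mito_gene_rule; ",
            "mitochondrial filter skipped", call. = FALSE)
    mito_frac <- rep(NA_real_, ncol(X))
    high_mito <- rep(FALSE, ncol(X))
  } else {
    mito_frac <- ifelse(total > 0, Matrix::colSums(X[mt, , drop = FALSE]) / total, 0)
    high_mito <- mito_frac > qc$max_mito_fraction
  }
  low_genes <- detected < qc$min_genes_per_cell
  removed <- low_genes | high_mito
  reason <- rep("", ncol(X))
  reason[low_genes & !high_mito] <- "low_genes"
  reason[!low_genes & high_mito] <- "high_mito"
  reason[low_genes & high_mito] <- "low_genes+high_mito"

  report <- data.frame(
    cell_id = colnames(X),
    detected_genes = as.integer(detected),
    mito_fraction = mito_frac,
    removed = removed,
    reason = reason,
    stringsAsFactors = FALSE
  )
  attr(report, "mito_filter_applied") <- mito_ok
  attr(report, "qc_params") <- qc

  out <- counts
  keep <- !removed
  out$counts <- X[, keep, drop = FALSE]
  out$cells <- counts$cells[keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  out$qc_report <- report
  out
}

#' Depth-normalize and log-transform a count matrix
#'
#' Per-cell scaling to the median library size followed by `log1p`; the
#' standard variance-stabilizing transform for UMI data used throughout the
#' downstream analyses.
#'
#' @param counts A `counts_matrix` (or a dgCMatrix of raw counts).
#' @return A sparse matrix of log-normalized expression (genes x cells).
#' @export
normalize_counts <- function(counts) {
  X <- if (inherits(counts, "counts_matrix")) counts$counts else counts
  depth <- Matrix::colSums(X)
  depth[depth == 0] <- 1
  sf <- depth / median(depth)
  norm <- X %*% Matrix::Diagonal(x = 1 / sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(X)
  norm
}
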