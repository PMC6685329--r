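# Independent brute-force oracles and fixture builders.

# Flood-fill connected components of same-coloured labelled cells under
# 6-connectivity, written directly over a dense 3D array (independent of the
# graph-based implementation in the package). Returns an integer membership
# vector aligned with the labelled rows of `tissue`.
flood_fill_components <- function(tissue) {
  lab <- tissue[tissue$colour != "NONE", , drop = FALSE]
  n <- nrow(lab)
  if (n == 0L) return(integer(0))
  ox <- min(lab$x); oy <- min(lab$y); oz <- min(lab$z)
  dx <- max(lab$x) - ox + 1L; dy <- max(lab$y) - oy + 1L; dz <- max(lab$z) - oz + 1L
  idx_arr <- array(0L, dim = c(dx, dy, dz))
  idx_arr[cbind(lab$x - ox + 1L, lab$y - oy + 1L, lab$z - oz + 1L)] <- seq_len(n)
  comp <- integer(n)
  cur <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      p <- c(lab$x[i] - ox + 1L, lab$y[i] - oy + 1L, lab$z[i] - oz + 1L)
      for (r in seq_len(6L)) {
        q <- p + offsets[r, ]
        if (any(q < 1L) || q[1] > dx || q[2] > dy || q[3] > dz) next
        j <- idx_arr[q[1], q[2], q[3]]
        if (j != 0L && comp[j] == 0L && lab$colour[j] == lab$colour[i]) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# Random tissue on a small lattice: every site independently NONE or one of
# the four colours. Exercises the clone caller far from simulator geometry.
random_tissue <- function(nx, ny, nz, p_label = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L, z = seq_len(nz) - 1L)
  colour <- ifelse(runif(nrow(grid)) < p_label,
                   sample(CONFETTI_COLOURS, nrow(grid), replace = TRUE), "NONE")
  df <- data.frame(
    cell_id = seq_len(nrow(grid)),
    x = grid$x, y = grid$y, z = grid$z,
    colour = colour,
    vessel_id = 1L + (grid$y %/% 3L),
    edu = FALSE,
    region = "healthy",
    founder_id = NA_integer_,
    section_id = 1L,
    stringsAsFactors = FALSE
  )
  class(df) <- c("tissue_map", "data.frame")
  df
}

# Hand-built tissue map from explicit cell rows.
make_tissue <- function(x, y, z, colour, vessel_id = 1L, edu = FALSE,
                        section_id = 1L, founder_id = NA_integer_) {
  n <- length(x)
  df <- data.frame(
    cell_id = seq_len(n), x = x, y = y, z = z, colour = colour,
    vessel_id = rep_len(vessel_id, n), edu = rep_len(edu, n),
    region = rep_len("healthy", n), founder_id = rep_len(founder_id, n),
    section_id = rep_len(section_id, n), stringsAsFactors = FALSE
  )
  class(df) <- c("tissue_map", "data.frame")
  df
}

# Partition agreement identical up to relabelling.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    nrow(unique(data.frame(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Direct reference implementation of Benjamini-Hochberg (independent of
# p.adjust): q_i = min_{j >= i} p_(j) * m / j.
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Counts matrix with exact detected-gene counts and mitochondrial fractions:
# 500 non-mito genes plus one mito gene; cells detect 399/400/450/450 genes
# with mito fractions 0 / 0 / 0.25 / exactly 0.20.
qc_fixture <- function() {
  genes <- c(sprintf("G%03d", 1:500), "mt-Nd1")
  det <- c(399L, 400L, 450L, 450L)
  mat <- matrix(0, length(genes), 4, dimnames = list(genes, paste0("c", 1:4)))
  for (i in 1:4) mat[seq_len(det[i] - 1L), i] <- 2
  mat[det[1], 1] <- 2 # no mito counts: top up with one more plain gene
  mat[det[2], 2] <- 2
  mat["mt-Nd1", 3] <- sum(mat[, 3]) / 3 # m/(m + s) = 0.25
  mat["mt-Nd1", 4] <- sum(mat[, 4]) / 4 # m/(m + s) = 0.20 exactly
  make_counts(mat)
}

# Minimal hand-built counts_matrix.
make_counts <- function(mat, group = NULL, replicate = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("G%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%03d", seq_len(ncol(mat)))
  cells <- data.frame(cell_id = as.character(colnames(mat)),
                      stringsAsFactors = FALSE)
  if (!is.null(group)) cells$group <- group
  if (!is.null(replicate)) cells$replicate <- replicate
  structure(list(counts = methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix"),
                 genes = data.frame(gene = rownames(mat), stringsAsFactors = FALSE),
                 cells = cells),
            class = "counts_matrix")
}
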