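#' Call clones from a tissue map
#'
#' Partitions labelled cells into maximal connected monochromatic components.
#' A clone is two or more adjacent cells expressing the same fluorophore
#' (YFP, RFP, nGFP or mCFP); size-1 components are retained as singletons.
#' Unlabelled cells are untouched.
#'
#' @param tissue A `tissue_map` data frame (see [simulate_tissue()] /
#'   [read_tissue_csv()]).
#' @param adjacency `"6"` for the 6-connected integer-lattice neighbourhood
#'   (default), or `"metric"` for a Euclidean distance rule suitable for
#'   imported real segmentations.
#' @param metric_radius Maximum centre-to-centre distance for
#'   `adjacency = "metric"`.
#' @return A `clone_set`: list with `cells` (one row per labelled cell:
#'   `cell_id`, `component_id`, `colour`, `component_size`, `is_clone`,
#'   `vessel_id`, `section_id`), `clones` (one row per clone of size >= 2:
#'   `clone_id`, `colour`, `size`, `section_id`, `n_vessels`, and a
#'   `vessel_ids` list column), `n_clones`, `n_singletons`, and the adjacency
#'   rule used.
#' @examples
#' tissue <- simulate_tissue(tissue_preset("healthy"), sections = 1, seed = 1)
#' clones <- call_clones(tissue)
#' clones$n_clones
#' @export
call_clones <- function(tissue, adjacency = c("6", "metric"), metric_radius = 1.5) {
  adjacency <- match.arg(adjacency)
  validate_tissue_map(tissue)
  lab <- tissue[tissue$colour != "NONE", , drop = FALSE]

  if (nrow(lab) == 0L) {
    cells <- data.frame(cell_id = integer(0), component_id = integer(0),
                        colour = character(0), component_size = integer(0),
                        is_clone = logical(0), vessel_id = integer(0),
                        section_id = integer(0), stringsAsFactors = FALSE)
    return(structure(list(cells = cells, clones = empty_clone_frame(),
                          n_clones = 0L, n_singletons = 0L,
                          adjacency = adjacency),
                     class = "clone_set"))
  }

  comp <- if (adjacency == "6") {
    lattice_components(lab)
  } else {
    metric_components(lab, metric_radius)
  }

  sizes <- tabulate(comp)
  cells <- data.frame(
    cell_id = lab$cell_id,
    component_id = comp,
    colour = lab$colour,
    component_size = sizes[comp],
    is_clone = sizes[comp] >= 2L,
    vessel_id = lab$vessel_id,
    section_id = lab$section_id,
    stringsAsFactors = FALSE
  )

  clone_comp <- which(sizes >= 2L)
  if (length(clone_comp)) {
    idx <- cells$component_id %in% clone_comp
    sub <- cells[idx, , drop = FALSE]
    grp <- factor(sub$component_id, levels = clone_comp)
    clones <- data.frame(
      clone_id = seq_along(clone_comp),
      colour = tapply(sub$colour, grp, `[`, 1L),
      size = as.integer(sizes[clone_comp]),
      section_id = as.integer(tapply(sub$section_id, grp, `[`, 1L)),
      n_vessels = as.integer(tapply(sub$vessel_id, grp, function(v) length(unique(v)))),
      stringsAsFactors = FALSE
    )
    clones$vessel_ids <- unname(tapply(sub$vessel_id, grp, function(v) sort(unique(v))))
    # map component ids to clone ids on the per-cell table
    cells$clone_id <- NA_integer_
    cells$clone_id[idx] <- match(sub$component_id, clone_comp)
    rownames(clones) <- NULL
  } else {
    clones <- empty_clone_frame()
    cells$clone_id <- NA_integer_
  }

  structure(list(
    cells = cells,
    clones = clones,
    n_clones = nrow(clones),
    n_singletons = sum(sizes == 1L),
    adjacency = adjacency
  ), class = "clone_set")
}

empty_clone_frame <- function() {
  out <- data.frame(clone_id = integer(0), colour = character(0),
                    size = integer(0), section_id = integer(0),
                    n_vessels = integer(0), stringsAsFactors = FALSE)
  out$vessel_ids <- list()
  out
}

# Monochromatic connected components under 6-connectivity, via same-colour
# lattice-neighbour edges.
lattice_components <- function(lab) {
  n <- nrow(lab)
  key <- paste(lab$x, lab$y, lab$z, sep = ",")
  edges <- integer(0)
  offsets <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  for (off in offsets) {
    nk <- paste(lab$x + off[1], lab$y + off[2], lab$z + off[3], sep = ",")
    j <- match(nk, key)
    ok <- !is.na(j) & lab$colour == lab$colour[j]
    if (any(ok)) edges <- c(edges, rbind(which(ok), j[ok]))
  }
  components_from_edges(n, edges)
}

metric_components <- function(lab, radius) {
  n <- nrow(lab)
  pos <- cbind(lab$x, lab$y, lab$z)
  k <- min(n, 27L)
  nn <- FNN::get.knn(pos, k = k - 1L)
  ii <- rep(seq_len(n), each = k - 1L)
  jj <- as.vector(t(nn$nn.index))
  dd <- as.vector(t(nn$nn.dist))
  ok <- dd <= radius & lab$colour[ii] == lab$colour[jj]
  components_from_edges(n, as.vector(rbind(ii[ok], jj[ok])))
}

components_from_edges <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$membership)
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("Clone set: %d clones (size >= 2), %d singletons, adjacency = %s\n",
              x$n_clones, x$n_singletons, x$adjacency))
  if (x$n_clones > 0) {
    cat(sprintf("  mean clone size %.2f (SD %.2f); colours: %s\n",
                mean(x$clones$size), sd(x$clones$size),
                paste(names(table(x$clones$colour)),
                      table(x$clones$colour), sep = ":", collapse = " ")))
  }
  invisible(x)
}
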