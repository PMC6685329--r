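TISSUE_CSV_HEADER <- c("cell_id", "x", "y", "z", "colour", "vessel_id",
                       "edu", "region", "founder_id", "section_id")

#' Write / read a tissue map as CSV
#'
#' Fixed dialect: UTF-8, comma separated, mandatory header
#' `cell_id,x,y,z,colour,vessel_id,edu,region,founder_id,section_id`,
#' 0-based integer coordinates, booleans as 0/1, empty `founder_id` for
#' cells without ground truth, colours restricted to
#' YFP/RFP/nGFP/mCFP/NONE. The round trip is loss-free.
#'
#' @param tissue A `tissue_map` data frame.
#' @param path File path.
#' @return `write_tissue_csv` returns `path` invisibly; `read_tissue_csv`
#'   returns a validated `tissue_map`.
#' @export
write_tissue_csv <- function(tissue, path) {
  validate_tissue_map(tissue)
  out <- tissue[, TISSUE_CSV_HEADER]
  out$edu <- as.integer(out$edu)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_tissue_csv
#' @export
read_tissue_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(TISSUE_CSV_HEADER, names(df))
  if (length(missing)) {
    stop_clonevasc("tissue CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("cell_id", "x", "y", "z", "vessel_id", "founder_id", "section_id")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] != floor(df[[col]]))
    if (length(bad)) {
      stop_clonevasc("non-integer `", col, "` at data line(s): ",
                     paste(head(bad, 5L), collapse = ", "))
    }
    df[[col]] <- as.integer(df[[col]])
  }
  if (!all(df$edu %in% c(0L, 1L))) {
    stop_clonevasc("`edu` must be 0/1 at data line(s): ",
                   paste(head(which(!df$edu %in% c(0L, 1L)), 5L), collapse = ", "))
  }
  df$edu <- df$edu == 1L
  df <- df[, TISSUE_CSV_HEADER]
  class(df) <- c("tissue_map", "data.frame")
  validate_tissue_map(df)
  df
}

#' Write / read a count matrix as a MatrixMarket triplet directory
#'
#' 10x-style convention: `matrix.mtx` with genes as rows and cells as
#' columns, `genes.tsv` (one gene per line, with any extra gene metadata
#' columns), `cells.tsv` (cell id plus metadata columns, with header). The
#' round trip preserves counts and metadata exactly.
#'
#' @param counts A `counts_matrix`.
#' @param dir Directory (created if needed).
#' @return `write_counts_mtx` returns `dir` invisibly; `read_counts_mtx`
#'   returns a `counts_matrix`.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "counts_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts$counts, file.path(dir, "matrix.mtx"))
  write.table(counts$genes, file.path(dir, "genes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(counts$cells, file.path(dir, "cells.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  for (f in c("matrix.mtx", "genes.tsv", "cells.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop_clonevasc("`", f, "` not found in ", dir)
    }
  }
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m)) {
    stop_clonevasc("dimension mismatch: matrix has ", nrow(m), " genes but genes.tsv has ",
                   nrow(genes), " rows")
  }
  if (nrow(cells) != ncol(m)) {
    stop_clonevasc("dimension mismatch: matrix has ", ncol(m), " cells but cells.tsv has ",
                   nrow(cells), " rows")
  }
  dimnames(m) <- list(genes$gene,
                      if ("cell_id" %in% names(cells)) cells$cell_id else NULL)
  structure(list(counts = m, genes = genes, cells = cells),
            class = "counts_matrix")
}

#' Read a signature panel from YAML
#'
#' The panel file is a YAML list of gene symbols, optionally tagged with a
#' phase (`early`/`late`), e.g. `- gene: Snai1` / `  phase: early`, or plain
#' strings.
#'
#' @param path YAML file path.
#' @return Data frame with columns `gene` and `phase`.
#' @export
read_signature_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- raw$panel %||% raw
  rows <- lapply(entries, function(e) {
    if (is.character(e)) {
      data.frame(gene = e, phase = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = e$gene, phase = e$phase %||% NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$gene)) {
    stop_clonevasc("duplicate gene(s) in panel: ",
                   paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  }
  out
}

#' Load a shipped YAML tissue preset
#'
#' Reads one of the preset configuration files under
#' `inst/extdata/presets/` (`healthy.yaml`, `mi_border.yaml`) into a
#' [sim_tissue_params()] object. Equivalent to [tissue_preset()].
#'
#' @param path Path to a preset YAML file.
#' @return A `sim_tissue_params` object.
#' @export
read_tissue_preset <- function(path) {
  cfg <- yaml::read_yaml(path)
  cp <- unlist(cfg$colour_probs)[CONFETTI_COLOURS]
  cp <- cp / sum(cp)
  sim_tissue_params(
    recombination_efficiency = cfg$recombination_efficiency,
    colour_probs = cp,
    founder_density = cfg$founder_density,
    clone_size_mean = cfg$clone_size_mean,
    clone_size_sd = cfg$clone_size_sd,
    single_cell_fraction = cfg$single_cell_fraction,
    edu_window_fraction = cfg$edu_window_fraction,
    edu_background_rate = cfg$edu_background_rate,
    polychromatic_target = cfg$polychromatic_target,
    region = cfg$region,
    seed = cfg$seed
  )
}
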