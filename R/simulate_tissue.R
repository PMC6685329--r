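#' Simulate a Confetti-labelled endothelial tissue map
#'
#' Generates a 3D lattice tissue map of endothelial cells arranged along
#' vessel segments, with stochastic four-colour recombination, spatially
#' contiguous clonal expansion, EdU S-phase marking and ground-truth founder
#' identities. Sections are laid out as non-overlapping z-slabs; vessels are
#' parallel two-lane strips (an axis lane plus a lateral spill lane) spaced
#' at least two lattice steps apart so that cells on different vessels are
#' never adjacent under 6-connectivity.
#'
#' Each founding recombination event draws a fluorophore from
#' `colour_probs` and a clone size from the calibrated division law (size 1
#' with the derived per-founder singleton probability). Daughter cells occupy
#' a connected patch grown by a constrained random walk along the parent
#' vessel with lateral spill. With `merger_regime = "off"` founder patches
#' are separated by gaps of at least three columns, so distinct founders can
#' never touch and the number of monochromatic connected components equals
#' the number of founders exactly. With `merger_regime = "on"` paired
#' founders are planted at adjacent sites, so same-colour pairs merge into a
#' single apparent clone. Unlabelled eligible cells (those that did not
#' recombine at induction) are interspersed along vessels at a density set by
#' `recombination_efficiency`.
#'
#' @param params A [sim_tissue_params()] object.
#' @param sections Number of sections to simulate.
#' @param seed RNG seed (overrides `params$seed`); the output is
#'   deterministic given identical parameters and seed.
#' @return A `tissue_map` data frame with one row per cell and columns
#'   `cell_id`, `x`, `y`, `z` (0-based lattice coordinates), `colour`
#'   (YFP/RFP/nGFP/mCFP/NONE), `vessel_id`, `edu` (logical), `region`,
#'   `founder_id` (ground truth; `NA` for unlabelled cells), `section_id`.
#' @examples
#' tissue <- simulate_tissue(tissue_preset("healthy"), sections = 2, seed = 1)
#' table(tissue$colour)
#' @export
simulate_tissue <- function(params, sections = 30L, seed = NULL) {
  if (!inherits(params, "sim_tissue_params")) {
    stop_clonevasc("`params` must be created by sim_tissue_params()")
  }
  sections <- as.integer(sections)
  if (sections < 1L) stop_clonevasc("`sections` must be >= 1")
  seed <- seed %||% params$seed

  with_seed(seed, {
    xdim <- params$lattice_dims[["x"]]
    ydim <- params$lattice_dims[["y"]]
    zdim <- params$lattice_dims[["z"]]
    n_y_slots <- if (ydim >= 2L) (ydim - 2L) %/% 3L + 1L else 0L
    n_z_slots <- (zdim - 1L) %/% 2L + 1L
    n_slots <- n_y_slots * n_z_slots
    if (n_slots < 1L) stop_clonevasc("lattice too small: no vessel slots fit in the y/z dimensions")

    merger_on <- params$merger_regime == "on"
    pair_rate <- if (merger_on) params$merger_pair_rate else params$vessel_mix_rate
    eps <- params$recombination_efficiency

    out <- vector("list", sections)
    founder_counter <- 0L
    vessel_counter <- 0L

    for (s in seq_len(sections)) {
      zbase <- (s - 1L) * zdim
      # with eps = 0 no eligible cell recombines: no labelled founders exist
      n_f <- if (eps == 0) 0L else rpois(1L, params$founder_density)
      if (n_f == 0L) {
        out[[s]] <- empty_section_frame()
        next
      }

      colours <- sample(CONFETTI_COLOURS, n_f, replace = TRUE, prob = params$colour_probs)
      sizes <- draw_clone_sizes(n_f, params)
      founder_ids <- founder_counter + seq_len(n_f)
      founder_counter <- founder_counter + n_f

      # Pair a subset of founders onto shared vessels; drawing the pair count
      # directly keeps E[pairs] = n_f * pair_rate / 2 even at low rates.
      n_pairs <- min(rbinom(1L, n_f, pair_rate / 2), n_f %/% 2L)
      units <- list()
      if (n_pairs > 0L) {
        pp <- sample.int(n_f, 2L * n_pairs)
        units <- lapply(seq_len(n_pairs), function(i) pp[c(2L * i - 1L, 2L * i)])
      }
      singles <- setdiff(seq_len(n_f), if (n_pairs > 0L) unlist(units) else integer())
      units <- c(units, as.list(singles))
      n_units <- length(units)
      if (n_units > n_slots) {
        stop_clonevasc(sprintf(
          "section %d needs %d vessels but the %dx%dx%d slab only hosts %d; enlarge `lattice_dims`",
          s, n_units, xdim, ydim, zdim, n_slots))
      }
      slots <- sample.int(n_slots, n_units)

      sec_cells <- vector("list", n_units)
      free_x <- vector("list", n_units) # unlabelled-cell candidate sites per vessel
      for (u in seq_len(n_units)) {
        slot <- slots[u] - 1L
        y0 <- (slot %% n_y_slots) * 3L
        z0 <- zbase + (slot %/% n_y_slots) * 2L
        vessel_counter <- vessel_counter + 1L

        cursor <- 1L + sample.int(5L, 1L) - 1L
        vx <- integer(0); vlane <- integer(0); vfid <- integer(0)
        gap_cols <- integer(0)
        prev_max <- NA_integer_; prev_lane_at_max <- NA_integer_
        for (j in seq_along(units[[u]])) {
          f <- units[[u]][j]
          size <- sizes[f]
          adjacent_plant <- merger_on && j > 1L
          if (adjacent_plant) {
            x_start <- prev_max + 1L
            seed_lane <- prev_lane_at_max
          } else {
            if (j > 1L) {
              gap <- 2L + rpois(1L, 1.5)
              gap_cols <- c(gap_cols, (prev_max + 1L):(prev_max + gap))
              cursor <- prev_max + gap + 1L
            }
            x_start <- cursor
            seed_lane <- 1L
          }
          if (x_start + size - 1L > xdim) {
            stop_clonevasc(sprintf(
              "section %d: clone of %d cells does not fit on its vessel (x extent %d, slab x = %d); enlarge `lattice_dims`",
              s, size, x_start + size - 1L, xdim))
          }
          patch <- grow_patch(size, seed_lane)
          vx <- c(vx, x_start + patch$cx - 1L)
          vlane <- c(vlane, patch$lane)
          vfid <- c(vfid, rep.int(founder_ids[f], size))
          prev_max <- x_start + max(patch$cx) - 1L
          at_max <- patch$lane[patch$cx == max(patch$cx)]
          prev_lane_at_max <- at_max[sample.int(length(at_max), 1L)]
        }
        sec_cells[[u]] <- data.frame(
          x = vx, y = y0 + vlane - 1L, z = z0,
          colour = colours[match(vfid, founder_ids)],
          vessel_id = vessel_counter,
          founder_id = vfid,
          stringsAsFactors = FALSE
        )
        tail_cols <- if (prev_max + 2L <= xdim) {
          (prev_max + 2L):min(prev_max + 40L, xdim)
        } else integer(0)
        free_x[[u]] <- data.frame(
          x = c(gap_cols, tail_cols), y = y0, z = z0,
          vessel_id = vessel_counter
        )
      }

      labelled <- do.call(rbind, sec_cells)
      labelled$edu <- rbinom(nrow(labelled), 1L, params$edu_window_fraction) == 1L

      # Unlabelled eligible cells to make founders / eligible ~ recombination efficiency.
      n_unl <- if (eps >= 1) 0L else as.integer(round(n_f * (1 / eps - 1)))
      unl <- NULL
      if (n_unl > 0L) {
        pool <- do.call(rbind, free_x)
        if (nrow(pool) < n_unl) {
          stop_clonevasc(sprintf(
            "section %d: not enough free lattice sites for %d unlabelled cells; enlarge `lattice_dims`",
            s, n_unl))
        }
        pool <- pool[sample.int(nrow(pool), n_unl), , drop = FALSE]
        unl <- data.frame(
          x = pool$x, y = pool$y, z = pool$z,
          colour = "NONE", vessel_id = pool$vessel_id,
          founder_id = NA_integer_,
          edu = rbinom(n_unl, 1L, params$edu_background_rate) == 1L,
          stringsAsFactors = FALSE
        )
      }
      sec <- rbind(labelled, unl)
      sec$section_id <- s
      out[[s]] <- sec
    }

    tissue <- do.call(rbind, out)
    tissue$cell_id <- seq_len(nrow(tissue))
    tissue$region <- rep_len(params$region, nrow(tissue))
    # 0-based lattice coordinates in the public representation.
    tissue$x <- tissue$x - 1L
    tissue <- tissue[, c("cell_id", "x", "y", "z", "colour", "vessel_id",
                         "edu", "region", "founder_id", "section_id")]
    rownames(tissue) <- NULL
    class(tissue) <- c("tissue_map", "data.frame")
    attr(tissue, "sim_params") <- params
    tissue
  })
}

empty_section_frame <- function() {
  data.frame(x = integer(0), y = integer(0), z = integer(0),
             colour = character(0), vessel_id = integer(0),
             founder_id = integer(0), edu = logical(0),
             section_id = integer(0), stringsAsFactors = FALSE)
}

draw_clone_sizes <- function(n, params) {
  singleton <- rbinom(n, 1L, params$founder_singleton_prob) == 1L
  law <- params$division_count_law
  extra <- switch(law$family,
    point = rep.int(law$value, n),
    nbinom = rnbinom(n, size = law$size, mu = law$mu),
    poisson = rpois(n, law$lambda),
    stop_clonevasc("unknown division count law: ", law$family)
  )
  ifelse(singleton, 1L, 2L + as.integer(extra))
}

# Connected patch of `size` cells in a 2-lane strip (lane 1 = vessel axis,
# lane 2 = lateral spill), grown one uniformly chosen frontier site at a
# time, never extending left of the seed column. Returns 1-based local
# column offsets `cx` and lane indices.
grow_patch <- function(size, seed_lane = 1L) {
  cx <- integer(size); lane <- integer(size)
  cx[1] <- 1L; lane[1] <- seed_lane
  if (size == 1L) return(list(cx = cx, lane = lane))
  occ <- matrix(FALSE, 2L, size)
  occ[seed_lane, 1L] <- TRUE
  in_cand <- matrix(FALSE, 2L, size)
  cand <- integer(0) # keys: (col - 1) * 2 + lane
  push <- function(l, cl) {
    if (cl >= 1L && cl <= size && !occ[l, cl] && !in_cand[l, cl]) {
      in_cand[l, cl] <<- TRUE
      cand <<- c(cand, (cl - 1L) * 2L + l)
    }
  }
  push(seed_lane, 2L)
  push(3L - seed_lane, 1L)
  for (i in 2:size) {
    k <- cand[sample.int(length(cand), 1L)]
    cand <- cand[cand != k]
    cl <- (k - 1L) %/% 2L + 1L
    l <- k - (cl - 1L) * 2L
    in_cand[l, cl] <- FALSE
    occ[l, cl] <- TRUE
    cx[i] <- cl; lane[i] <- l
    push(l, cl - 1L); push(l, cl + 1L); push(3L - l, cl)
  }
  list(cx = cx, lane = lane)
}

#' Validate a tissue map
#'
#' Checks the tissue-map contract: required columns, unique cell ids, unique
#' lattice positions, a known colour vocabulary, and (when ground truth is
#' present) that all cells of a founder share one colour.
#'
#' @param tissue A `tissue_map` data frame.
#' @return `tissue`, invisibly; errors describe the offending cells.
#' @export
validate_tissue_map <- function(tissue) {
  required <- c("cell_id", "x", "y", "z", "colour", "vessel_id", "edu",
                "region", "section_id")
  missing <- setdiff(required, names(tissue))
  if (length(missing)) {
    stop_clonevasc("tissue map is missing columns: ", paste(missing, collapse = ", "))
  }
  dup_id <- tissue$cell_id[duplicated(tissue$cell_id)]
  if (length(dup_id)) {
    stop_clonevasc("duplicate cell_id values: ", paste(unique(dup_id), collapse = ", "))
  }
  bad_col <- setdiff(unique(tissue$colour), COLOUR_VOCAB)
  if (length(bad_col)) {
    stop_clonevasc("unknown colour token(s): ", paste(bad_col, collapse = ", "),
                   "; valid tokens are ", paste(COLOUR_VOCAB, collapse = ", "))
  }
  key <- paste(tissue$x, tissue$y, tissue$z, sep = ",")
  if (anyDuplicated(key)) {
    dup <- tissue$cell_id[key %in% key[duplicated(key)]]
    stop_clonevasc("cells share a lattice position: cell_id ",
                   paste(head(dup, 10L), collapse = ", "))
  }
  if ("founder_id" %in% names(tissue)) {
    lab <- tissue[!is.na(tissue$founder_id) & tissue$colour != "NONE", ]
    if (nrow(lab)) {
      n_col <- tapply(lab$colour, lab$founder_id, function(v) length(unique(v)))
      if (any(n_col > 1L)) {
        stop_clonevasc("founder(s) with mixed colours: ",
                       paste(names(n_col)[n_col > 1L], collapse = ", "))
      }
    }
  }
  invisible(tissue)
}
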