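#' Clonal statistics of a tissue map
#'
#' Computes the per-section and pooled clone statistics: clone-size moments,
#' per-colour clone sizes, fluorophore fractions among labelled cells,
#' founder events (clones + singletons) per section, the singleton cell
#' fraction, vessel clonality fractions, EdU indices, and a recovered
#' recombination efficiency (founder events / eligible cells, where eligible
#' cells are founder events plus unlabelled cells).
#'
#' @param clones A `clone_set` from [call_clones()], produced from `tissue`.
#' @param tissue The `tissue_map` the clones were called from.
#' @param min_labelled Minimum labelled cells for a vessel to be classified
#'   (passed to [classify_vessels()]).
#' @return A `clonal_stats` object: list with `summary` (pooled statistics),
#'   `per_section` (one row per section), `per_colour_sizes` (colour ->
#'   vector of clone sizes) and `colour_fractions`. When the tissue holds no
#'   labelled cells the statistics are `NA` and `summary$no_labelled_cells`
#'   is `TRUE`.
#' @export
clonal_stats <- function(clones, tissue, min_labelled = 2L) {
  if (!inherits(clones, "clone_set")) stop_clonevasc("`clones` must be a clone_set")
  validate_tissue_map(tissue)
  if (!all(clones$cells$cell_id %in% tissue$cell_id)) {
    stop_clonevasc("`clones` was not produced from this tissue map (unknown cell ids)")
  }

  lab <- tissue[tissue$colour != "NONE", , drop = FALSE]
  sections <- sort(unique(tissue$section_id))
  n_lab <- nrow(lab)

  if (n_lab == 0L) {
    return(structure(list(
      summary = list(no_labelled_cells = TRUE,
                     mean_clone_size = NA_real_, sd_clone_size = NA_real_,
                     n_clones = 0L, n_singletons = 0L, founder_events = 0L,
                     singleton_fraction = NA_real_,
                     edu_total_fraction = NA_real_,
                     edu_confetti_fraction = NA_real_,
                     monoclonal_vessel_fraction = NA_real_,
                     polychromatic_vessel_fraction = NA_real_,
                     recombination_efficiency_est = NA_real_,
                     founder_events_per_section = NA_real_),
      per_section = NULL, per_colour_sizes = list(),
      colour_fractions = setNames(rep(NA_real_, 4L), CONFETTI_COLOURS)
    ), class = "clonal_stats"))
  }

  cf <- table(factor(lab$colour, levels = CONFETTI_COLOURS))
  colour_fractions <- as.numeric(cf) / n_lab
  names(colour_fractions) <- CONFETTI_COLOURS

  sizes <- clones$clones$size
  per_colour_sizes <- split(sizes, factor(clones$clones$colour, levels = CONFETTI_COLOURS))

  vc <- classify_vessels(tissue, min_labelled = min_labelled)
  classified <- vc[vc$class != "unclassified", , drop = FALSE]
  mono_frac <- if (nrow(classified)) mean(classified$class == "monoclonal") else NA_real_

  cc <- clones$cells
  singleton_cells <- sum(!cc$is_clone)

  per_section <- do.call(rbind, lapply(sections, function(s) {
    ts <- tissue[tissue$section_id == s, , drop = FALSE]
    ls <- ts[ts$colour != "NONE", , drop = FALSE]
    cs <- cc[cc$section_id == s, , drop = FALSE]
    cls <- clones$clones[clones$clones$section_id == s, , drop = FALSE]
    vcs <- vc[vc$vessel_id %in% ts$vessel_id & vc$class != "unclassified", , drop = FALSE]
    n_clo <- nrow(cls)
    n_sin <- sum(cs$component_size == 1L)
    data.frame(
      section_id = s,
      n_cells = nrow(ts),
      n_labelled = nrow(ls),
      n_unlabelled = nrow(ts) - nrow(ls),
      n_clones = n_clo,
      n_singletons = n_sin,
      founder_events = n_clo + n_sin,
      mean_clone_size = if (n_clo) mean(cls$size) else NA_real_,
      singleton_fraction = if (nrow(ls)) n_sin / nrow(ls) else NA_real_,
      edu_total_fraction = if (nrow(ts)) mean(ts$edu) else NA_real_,
      edu_confetti_fraction = if (nrow(ls)) mean(ls$edu) else NA_real_,
      monoclonal_vessel_fraction = if (nrow(vcs)) mean(vcs$class == "monoclonal") else NA_real_,
      polychromatic_vessel_fraction = if (nrow(vcs)) mean(vcs$class == "polychromatic") else NA_real_,
      recombination_efficiency_est =
        (n_clo + n_sin) / (n_clo + n_sin + nrow(ts) - nrow(ls))
    )
  }))
  rownames(per_section) <- NULL

  summary <- list(
    no_labelled_cells = FALSE,
    mean_clone_size = if (length(sizes)) mean(sizes) else NA_real_,
    sd_clone_size = if (length(sizes) > 1L) sd(sizes) else NA_real_,
    n_clones = clones$n_clones,
    n_singletons = clones$n_singletons,
    founder_events = clones$n_clones + clones$n_singletons,
    founder_events_per_section = (clones$n_clones + clones$n_singletons) / length(sections),
    singleton_fraction = singleton_cells / n_lab,
    edu_total_fraction = mean(tissue$edu),
    edu_confetti_fraction = mean(lab$edu),
    monoclonal_vessel_fraction = mono_frac,
    polychromatic_vessel_fraction = if (is.na(mono_frac)) NA_real_ else 1 - mono_frac,
    recombination_efficiency_est =
      (clones$n_clones + clones$n_singletons) /
      (clones$n_clones + clones$n_singletons + sum(tissue$colour == "NONE"))
  )

  structure(list(summary = summary, per_section = per_section,
                 per_colour_sizes = per_colour_sizes,
                 colour_fractions = colour_fractions),
            class = "clonal_stats")
}

#' @export
print.clonal_stats <- function(x, ...) {
  s <- x$summary
  if (isTRUE(s$no_labelled_cells)) {
    cat("Clonal statistics: no labelled cells (statistics undefined)\n")
    return(invisible(x))
  }
  cat("Clonal statistics\n")
  cat(sprintf("  clones %d (mean size %.2f, SD %.2f); singletons %d\n",
              s$n_clones, s$mean_clone_size, s$sd_clone_size, s$n_singletons))
  cat(sprintf("  founder events/section %.1f; singleton cell fraction %.3f\n",
              s$founder_events_per_section, s$singleton_fraction))
  cat(sprintf("  colour fractions: %s\n",
              paste(names(x$colour_fractions),
                    sprintf("%.3f", x$colour_fractions), sep = "=", collapse = " ")))
  cat(sprintf("  monoclonal vessels %.3f; EdU+ | labelled %.3f; EdU+ | all %.4f\n",
              s$monoclonal_vessel_fraction, s$edu_confetti_fraction,
              s$edu_total_fraction))
  cat(sprintf("  recovered recombination efficiency %.3f\n",
              s$recombination_efficiency_est))
  invisible(x)
}

#' Classify vessels as monoclonal or polychromatic
#'
#' A vessel with at least `min_labelled` labelled cells is `monoclonal` when
#' all its labelled cells share one fluorophore and `polychromatic`
#' otherwise; vessels with fewer labelled cells are `unclassified` and are
#' excluded from clonality fractions (a vessel with a single labelled cell
#' cannot exhibit polyclonality).
#'
#' @param tissue A `tissue_map` data frame with a `vessel_id` column.
#' @param min_labelled Minimum labelled cells required for classification.
#' @return Data frame with one row per vessel: `vessel_id`, `n_labelled`,
#'   `n_colours`, `class`.
#' @export
classify_vessels <- function(tissue, min_labelled = 2L) {
  validate_tissue_map(tissue)
  lab <- tissue[tissue$colour != "NONE", , drop = FALSE]
  vessels <- sort(unique(tissue$vessel_id))
  if (!length(vessels)) {
    return(data.frame(vessel_id = integer(0), n_labelled = integer(0),
                      n_colours = integer(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  n_lab <- tabulate(match(lab$vessel_id, vessels), nbins = length(vessels))
  n_col <- vapply(split(lab$colour, factor(lab$vessel_id, levels = vessels)),
                  function(v) length(unique(v)), integer(1))
  cls <- ifelse(n_lab < min_labelled, "unclassified",
                ifelse(n_col == 1L, "monoclonal", "polychromatic"))
  data.frame(vessel_id = vessels, n_labelled = n_lab,
             n_colours = as.integer(n_col), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Compare a clonal statistic between two groups of sections
#'
#' Two-sample comparison of a per-section metric (e.g. `mean_clone_size`,
#' `edu_confetti_fraction`) between two groups, as used for healthy versus
#' infarct-border contrasts.
#'
#' @param stats_a,stats_b `clonal_stats` objects (their `per_section` tables
#'   are used) or data frames with one row per section.
#' @param metric Column name of the metric to compare.
#' @param method `"wilcox"` (Mann-Whitney, default), `"welch"` (Welch t), or
#'   `"permutation"` (difference of means, add-one permutation p-value).
#' @param n_resamples Permutations for `method = "permutation"`.
#' @param seed RNG seed for the permutation method.
#' @return List with per-group `n`, `mean`, `sd`, the difference of means
#'   (`effect`, group A minus group B), `method` and `p_value`.
#' @export
compare_groups <- function(stats_a, stats_b, metric,
                           method = c("wilcox", "welch", "permutation"),
                           n_resamples = 10000L, seed = NULL) {
  method <- match.arg(method)
  xa <- extract_metric(stats_a, metric)
  xb <- extract_metric(stats_b, metric)
  if (length(xa) < 2L || length(xb) < 2L) {
    stop_clonevasc("need >= 2 sections per group to compare `", metric, "`")
  }
  p <- switch(method,
    wilcox = suppressWarnings(wilcox.test(xa, xb))$p.value,
    welch = t.test(xa, xb)$p.value,
    permutation = with_seed(seed, {
      obs <- abs(mean(xa) - mean(xb))
      pool <- c(xa, xb)
      na <- length(xa)
      null <- replicate(n_resamples, {
        idx <- sample.int(length(pool), na)
        abs(mean(pool[idx]) - mean(pool[-idx]))
      })
      (1 + sum(null >= obs)) / (1 + n_resamples)
    })
  )
  list(metric = metric, method = method,
       n = c(a = length(xa), b = length(xb)),
       mean = c(a = mean(xa), b = mean(xb)),
       sd = c(a = sd(xa), b = sd(xb)),
       effect = mean(xa) - mean(xb),
       p_value = p)
}

extract_metric <- function(stats, metric) {
  df <- if (inherits(stats, "clonal_stats")) stats$per_section else stats
  if (is.null(df) || !is.data.frame(df)) {
    stop_clonevasc("group statistics must be a clonal_stats object or a per-section data frame")
  }
  if (!metric %in% names(df)) {
    stop_clonevasc("metric `", metric, "` is absent from the per-section table")
  }
  x <- df[[metric]]
  x[!is.na(x)]
}
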