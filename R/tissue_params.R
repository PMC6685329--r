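#' Parameters for the Confetti tissue simulator
#'
#' Builds and validates the parameter set consumed by [simulate_tissue()].
#' Defaults encode the healthy adult mouse heart: Cre-recombination in 46.6%
#' of eligible Pdgfb-lineage endothelial cells, the biased four-colour
#' fluorophore distribution (51.9/25.7/11.3/11.8% of reporter-expressing
#' cells, stored normalized), 72.3 founding recombination events per
#' 100 um wholemount section, mean clone size 4.0 (SD 2.1) among clones of
#' two or more cells, 54.6% of labelled cells present as undivided single
#' cells, a 28.5% EdU+ fraction among labelled cells, and 25.5% polychromatic
#' vessels among classifiable vessels.
#'
#' Three quantities are calibrated internally from the targets:
#'
#' * the per-founder non-division probability `s_f` is derived from the
#'   per-cell singleton fraction `single_cell_fraction` (`sigma`) and the
#'   clone-size mean `mu` as `s_f = sigma*mu/(1 - sigma + sigma*mu)`,
#'   because a clone of mean size `mu` contributes `mu` labelled cells while
#'   a singleton contributes one;
#' * the clone-size law for dividing founders is `S = 2 + X` with
#'   `X ~ NegBinom` moment-matched to `clone_size_mean`/`clone_size_sd`
#'   (Poisson when the target variance is not over-dispersed);
#' * the mixed-founder vessel seeding rate (probability that a founder event
#'   is planted as one of a pair sharing a vessel) is derived from
#'   `polychromatic_target` so that, in expectation, the fraction of
#'   classifiable vessels carrying two fluorophores matches the target.
#'
#' @param recombination_efficiency Probability an eligible endothelial cell
#'   recombines at induction (default 0.466).
#' @param colour_probs Named 4-vector of fluorophore probabilities
#'   (YFP, RFP, nGFP, mCFP); must sum to 1.
#' @param founder_density Expected founding recombination events per section.
#' @param clone_size_mean,clone_size_sd Target mean and SD of clone size
#'   (cells per clone) among clones of size >= 2.
#' @param single_cell_fraction Target fraction of labelled cells that remain
#'   undivided singletons.
#' @param edu_window_fraction Probability a labelled cell is EdU+ (S phase in
#'   the 1 h window before cull).
#' @param edu_background_rate EdU+ probability for unlabelled cells.
#' @param polychromatic_target Target fraction of classified vessels that are
#'   polychromatic; used to derive the mixed-founder seeding rate. Set to 0
#'   to disable mixed seeding.
#' @param vessel_mix_rate Optional explicit pair-seeding rate overriding the
#'   derivation from `polychromatic_target`.
#' @param merger_regime `"off"` (founders spatially separated; default) or
#'   `"on"` (paired founders planted at adjacent sites, so same-colour pairs
#'   merge into one apparent clone).
#' @param merger_pair_rate Pairing rate used when `merger_regime = "on"`.
#' @param lattice_dims Integer 3-vector: per-section slab dimensions in cells
#'   (x along vessels, y across vessel lanes, z across vessel planes).
#' @param section_thickness Physical section thickness in micrometres
#'   (metadata; sections are non-overlapping z-slabs).
#' @param region Region tag recorded for every cell.
#' @param seed Default RNG seed for [simulate_tissue()].
#' @return An object of class `sim_tissue_params`.
#' @seealso [tissue_preset()] for the shipped HEALTHY and MI-BORDER presets.
#' @export
sim_tissue_params <- function(recombination_efficiency = 0.466,
                              colour_probs = c(YFP = 0.519, RFP = 0.257,
                                               nGFP = 0.113, mCFP = 0.118) / 1.007,
                              founder_density = 72.3,
                              clone_size_mean = 4.0,
                              clone_size_sd = 2.1,
                              single_cell_fraction = 0.546,
                              edu_window_fraction = 0.285,
                              edu_background_rate = 9e-4,
                              polychromatic_target = 0.255,
                              vessel_mix_rate = NULL,
                              merger_regime = c("off", "on"),
                              merger_pair_rate = 0.25,
                              lattice_dims = c(x = 512L, y = 48L, z = 16L),
                              section_thickness = 100,
                              region = "healthy",
                              seed = NULL) {
  merger_regime <- match.arg(merger_regime)
  check_probability(recombination_efficiency, "recombination_efficiency")
  check_probability(single_cell_fraction, "single_cell_fraction")
  check_probability(edu_window_fraction, "edu_window_fraction")
  check_probability(edu_background_rate, "edu_background_rate")
  check_probability(merger_pair_rate, "merger_pair_rate")
  colour_probs <- check_colour_probs(colour_probs)
  if (founder_density <= 0) stop_clonevasc("`founder_density` must be positive")
  if (clone_size_mean < 2) stop_clonevasc("`clone_size_mean` must be >= 2 (clones have >= 2 cells)")
  if (clone_size_sd < 0) stop_clonevasc("`clone_size_sd` must be non-negative")
  lattice_dims <- as.integer(lattice_dims)
  if (length(lattice_dims) != 3L || any(lattice_dims < 1L)) {
    stop_clonevasc("`lattice_dims` must be 3 positive integers")
  }
  names(lattice_dims) <- c("x", "y", "z")

  # Per-founder non-division probability from the per-cell singleton target.
  sigma <- single_cell_fraction
  mu <- clone_size_mean
  s_f <- if (sigma == 0) 0 else sigma * mu / (1 - sigma + sigma * mu)

  # Moment-matched shifted size law for dividing founders: S = 2 + X.
  m <- clone_size_mean - 2
  v <- clone_size_sd^2
  division_count_law <- if (m <= 0) {
    list(family = "point", value = 0)
  } else if (v > m) {
    list(family = "nbinom", mu = m, size = m^2 / (v - m))
  } else {
    list(family = "poisson", lambda = m)
  }

  if (is.null(vessel_mix_rate)) {
    vessel_mix_rate <- derive_vessel_mix_rate(polychromatic_target, colour_probs, s_f)
  }
  check_probability(vessel_mix_rate, "vessel_mix_rate")

  structure(list(
    recombination_efficiency = recombination_efficiency,
    colour_probs = colour_probs,
    founder_density = founder_density,
    clone_size_mean = clone_size_mean,
    clone_size_sd = clone_size_sd,
    division_count_law = division_count_law,
    single_cell_fraction = single_cell_fraction,
    founder_singleton_prob = s_f,
    edu_window_fraction = edu_window_fraction,
    edu_background_rate = edu_background_rate,
    polychromatic_target = polychromatic_target,
    vessel_mix_rate = vessel_mix_rate,
    merger_regime = merger_regime,
    merger_pair_rate = merger_pair_rate,
    lattice_dims = lattice_dims,
    section_thickness = section_thickness,
    region = region,
    seed = seed
  ), class = "sim_tissue_params")
}

# Pair-seeding rate such that E[polychromatic | classified] = rho.
# Mixed vessels (2 founders) are always classifiable and polychromatic with
# probability 1 - sum(p^2); single-founder vessels are classifiable only when
# the founder divides (prob 1 - s_f) and are then monoclonal.
derive_vessel_mix_rate <- function(rho, colour_probs, s_f) {
  if (rho <= 0) return(0)
  collision <- sum(colour_probs^2)
  if (rho >= 1 - collision) {
    stop_clonevasc(sprintf(
      "`polychromatic_target` (%.3f) is not attainable: two independent founders share a colour with probability %.3f, so at most %.3f of mixed vessels are polychromatic",
      rho, collision, 1 - collision))
  }
  r <- rho * (1 - s_f) / ((1 - collision) - rho) # v_mix / v_single
  2 * r / (1 + 2 * r)
}

#' Shipped tissue-simulation presets
#'
#' `"healthy"`: uninjured adult mouse left ventricle at 21 days after
#' tamoxifen induction. `"mi"`: the infarct border zone at 7 days after
#' coronary ligation (injury at day 14 post-induction), with larger,
#' over-dispersed clones (mean 10.3, SD 10.6), fewer polychromatic vessels
#' (9.3%), a higher undivided-cell fraction (63.4%) and a much higher EdU+
#' fraction among labelled cells (58.5%).
#'
#' @param name `"healthy"` or `"mi"`.
#' @param ... Overrides passed on to [sim_tissue_params()].
#' @return A `sim_tissue_params` object.
#' @export
tissue_preset <- function(name = c("healthy", "mi"), ...) {
  name <- match.arg(name)
  defaults <- if (name == "healthy") {
    list()
  } else {
    list(
      colour_probs = c(YFP = 0.529, RFP = 0.188, nGFP = 0.265, mCFP = 0.088) / 1.07,
      founder_density = 67.3,
      clone_size_mean = 10.3,
      clone_size_sd = 10.6,
      single_cell_fraction = 0.634,
      edu_window_fraction = 0.585,
      edu_background_rate = 0.019,
      polychromatic_target = 0.093,
      region = "border"
    )
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_tissue_params, args)
}

#' @export
print.sim_tissue_params <- function(x, ...) {
  cat("Confetti tissue simulation parameters\n")
  cat(sprintf("  recombination efficiency : %.3f\n", x$recombination_efficiency))
  cat(sprintf("  colour probs (Y/R/nG/mC) : %s\n",
              paste(sprintf("%.3f", x$colour_probs), collapse = " ")))
  cat(sprintf("  founder density / section: %.1f\n", x$founder_density))
  cat(sprintf("  clone size target        : %.1f (SD %.1f)\n",
              x$clone_size_mean, x$clone_size_sd))
  cat(sprintf("  singleton cell fraction  : %.3f (per-founder prob %.3f)\n",
              x$single_cell_fraction, x$founder_singleton_prob))
  cat(sprintf("  EdU+ | labelled          : %.3f\n", x$edu_window_fraction))
  cat(sprintf("  vessel mix rate          : %.4f (polychromatic target %.3f)\n",
              x$vessel_mix_rate, x$polychromatic_target))
  cat(sprintf("  merger regime            : %s\n", x$merger_regime))
  cat(sprintf("  region                   : %s\n", x$region))
  invisible(x)
}
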