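test_that("zero recombination efficiency yields a tissue with no labelled cells", {
  p <- sim_tissue_params(recombination_efficiency = 0, founder_density = 20)
  tissue <- simulate_tissue(p, sections = 3, seed = 1)
  expect_equal(sum(tissue$colour != "NONE"), 0)
})

test_that("output satisfies the tissue-map contract and is seed-deterministic", {
  p <- tissue_preset("healthy")
  a <- simulate_tissue(p, sections = 4, seed = 11)
  b <- simulate_tissue(p, sections = 4, seed = 11)
  expect_identical(a, b)
  c <- simulate_tissue(p, sections = 4, seed = 12)
  expect_false(identical(a, c))
  expect_silent(validate_tissue_map(a))
  expect_identical(names(a), c("cell_id", "x", "y", "z", "colour", "vessel_id",
                               "edu", "region", "founder_id", "section_id"))
})

test_that("founder ground truth matches monochromatic components exactly (no-merger regime)", {
  for (preset in c("healthy", "mi")) {
    tissue <- simulate_tissue(tissue_preset(preset), sections = 5, seed = 21)
    lab <- tissue[tissue$colour != "NONE", ]
    comp <- flood_fill_components(tissue)
    expect_equal(length(unique(comp)), length(unique(lab$founder_id)))
    # each component is exactly one founder
    expect_true(same_partition(comp, lab$founder_id))
  }
})

test_that("merger regime plants touching founder pairs that fuse when monochromatic", {
  p <- sim_tissue_params(colour_probs = c(YFP = 1, RFP = 0, nGFP = 0, mCFP = 0),
                         merger_regime = "on", merger_pair_rate = 0.8,
                         founder_density = 40, polychromatic_target = 0)
  tissue <- simulate_tissue(p, sections = 4, seed = 31)
  lab <- tissue[tissue$colour != "NONE", ]
  expect_true(all(lab$colour == "YFP"))
  comp <- flood_fill_components(tissue)
  n_founders <- length(unique(lab$founder_id))
  n_components <- length(unique(comp))
  expect_gt(n_founders, n_components)
})

test_that("labelled colour fractions converge to colour_probs (law of large numbers)", {
  p <- tissue_preset("healthy")
  tissue <- simulate_tissue(p, sections = 40, seed = 41)
  lab <- tissue[tissue$colour != "NONE", ]
  # colour is founder-level; use founders as the effective sample size
  n_f <- length(unique(lab$founder_id))
  frac <- table(factor(lab$colour, levels = CONFETTI_COLOURS)) / nrow(lab)
  for (k in seq_along(CONFETTI_COLOURS)) {
    pk <- p$colour_probs[k]
    se <- sqrt(pk * (1 - pk) / n_f)
    # clone-size weighting inflates the variance ~ E[S^2]/E[S]^2; allow 4x
    expect_lt(abs(frac[k] - pk), 8 * se)
  }
})

test_that("healthy preset clone sizes recover the target mean over many sections", {
  tissue <- simulate_tissue(tissue_preset("healthy"), sections = 30, seed = 51)
  lab <- tissue[tissue$colour != "NONE", ]
  sizes <- table(lab$founder_id)
  sizes <- sizes[sizes >= 2]
  se <- 2.1 / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 4.0), 4 * se)
})

test_that("a slab too small for the requested founders raises a capacity error", {
  p <- sim_tissue_params(founder_density = 400,
                         lattice_dims = c(x = 64L, y = 9L, z = 4L))
  expect_error(simulate_tissue(p, sections = 1, seed = 1), "enlarge")
})

test_that("EdU marking matches the configured rates", {
  p <- sim_tissue_params(edu_window_fraction = 1, edu_background_rate = 0)
  tissue <- simulate_tissue(p, sections = 3, seed = 61)
  lab <- tissue$colour != "NONE"
  expect_true(all(tissue$edu[lab]))
  expect_false(any(tissue$edu[!lab]))
})
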