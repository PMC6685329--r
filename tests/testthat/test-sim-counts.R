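small_counts_params <- function(...) {
  sim_counts_params(n_cells = c(healthy = 250L, mi = 300L), n_genes = 600L, ...)
}

test_that("count simulation is deterministic given the seed", {
  p <- small_counts_params()
  a <- simulate_counts(p, seed = 3)
  b <- simulate_counts(p, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cells, b$cells)
  expect_false(identical(simulate_counts(p, seed = 4)$counts, a$counts))
})

test_that("the MI-only archetype contains no healthy cells", {
  cm <- simulate_counts(small_counts_params(), seed = 5)
  stalk <- cm$cells[cm$cells$archetype == "stalk", ]
  expect_gt(nrow(stalk), 0)
  expect_true(all(stalk$group == "mi"))
})

test_that("conflicting marker fold-changes across archetypes are rejected", {
  arch <- default_archetypes()
  arch$homeostatic$fold <- 4 # Plvap & Bgn live in other archetypes at fold 8
  arch$homeostatic$markers <- c(arch$homeostatic$markers, "Plvap")
  expect_error(sim_counts_params(archetypes = arch), "conflicting fold-changes")
})

test_that("per-gene moments follow the negative-binomial law under a flat configuration", {
  arch <- list(only = list(markers = c("Pecam1"), fold = 1, abundance = 1, mi_share = 0.5))
  p <- sim_counts_params(
    n_cells = c(healthy = 1000L, mi = 1000L), n_genes = 400L,
    archetypes = arch, depth = c(healthy = 1500, mi = 1500), depth_sdlog = 0,
    dispersion = 2, mito_mean = 0, mito_tail_fraction = 0,
    lowdepth_cell_fraction = 0, contaminant_fraction = 0,
    rare_double_positive_fraction = 0, program_genes = 0,
    endmt_latent_sdlog = 0, endmt_replicate_sdlog = 0, ec_core_fold = 1
  )
  cm <- simulate_counts(p, seed = 9)
  X <- cm$counts
  mu <- Matrix::rowMeans(X)
  v <- apply(as.matrix(X), 1, var)
  # restrict to reasonably expressed genes where moment checks are stable
  keep <- mu > 0.5 & !startsWith(rownames(X), "mt-")
  expected_var <- mu[keep] + mu[keep]^2 / 2
  # variance-of-variance for NB makes per-gene checks noisy; test in aggregate
  ratio <- v[keep] / expected_var
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  expect_gt(cor(v[keep], expected_var), 0.9)
})

test_that("mitochondrial fractions carry a tail beyond the QC threshold", {
  cm <- simulate_counts(small_counts_params(), seed = 11)
  X <- cm$counts
  mt <- startsWith(rownames(X), "mt-")
  frac <- Matrix::colSums(X[mt, ]) / Matrix::colSums(X)
  expect_gt(mean(frac > 0.20), 0.02)
  expect_equal(as.numeric(cor(frac, cm$cells$mito_fraction_true)), 1, tolerance = 0.1)
})

test_that("contaminant cells express Ptprc but not the endothelial programme", {
  cm <- simulate_counts(small_counts_params(contaminant_fraction = 0.1), seed = 13)
  X <- cm$counts
  contam <- cm$cells$archetype == "contaminant"
  expect_gt(mean(X["Ptprc", contam] > 0), 0.9)
  expect_lt(mean(X["Ptprc", !contam] > 0), 0.02)
  expect_lt(mean(X["Pecam1", contam] > 0), 0.2)
  expect_gt(mean(X["Pecam1", !contam] > 0), 0.95)
})
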