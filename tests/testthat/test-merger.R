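test_that("colour collision probability is sum(p^k) with the uniform special cases", {
  u <- c(YFP = 0.25, RFP = 0.25, nGFP = 0.25, mCFP = 0.25)
  expect_equal(colour_collision_probability(1, u), 1)
  expect_equal(colour_collision_probability(2, u), 0.25)
  for (k in 1:6) {
    expect_equal(colour_collision_probability(k, u), 4^(1 - k))
  }
  p <- tissue_preset("healthy")$colour_probs
  expect_equal(colour_collision_probability(2, p), sum(p^2))
  # strictly decreasing in k for a non-degenerate vector
  vals <- vapply(1:6, colour_collision_probability, numeric(1), colour_probs = p)
  expect_true(all(diff(vals) < 0))
  expect_error(colour_collision_probability(0, u), ">= 1")
  expect_error(colour_collision_probability(2, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("collision probability agrees with a Monte-Carlo draw of founder pairs", {
  p <- tissue_preset("healthy")$colour_probs
  set.seed(123)
  n <- 1e6
  a <- sample.int(4, n, replace = TRUE, prob = p)
  b <- sample.int(4, n, replace = TRUE, prob = p)
  mc <- mean(a == b)
  expect_equal(colour_collision_probability(2, p), mc, tolerance = 3 / sqrt(n) / mc)
})

test_that("merger test validates its inputs", {
  mono <- data.frame(colour = rep("YFP", 10), size = 2:11)
  expect_error(merger_test(mono), "monochromatic")
  expect_error(merger_test(data.frame(colour = "YFP", size = 2)), "at least 2")
})

test_that("constant clone sizes give a degenerate statistic with p = 1", {
  df <- data.frame(colour = rep(c("YFP", "RFP"), each = 10), size = 2L)
  out <- merger_test(df, n_resamples = 200, seed = 1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$p_kruskal, 1)
})

test_that("merger test is invariant to colour relabelling and ignores geometry", {
  set.seed(5)
  probs <- tissue_preset("healthy")$colour_probs
  df <- data.frame(colour = sample(names(probs), 120, TRUE, probs),
                   size = 2L + rnbinom(120, size = 1.7, mu = 2))
  a <- merger_test(df, colour_fractions = probs, n_resamples = 500, seed = 9)
  relabel <- c(YFP = "mCFP", RFP = "nGFP", nGFP = "RFP", mCFP = "YFP")
  df2 <- transform(df, colour = unname(relabel[colour]))
  probs2 <- setNames(probs, unname(relabel[names(probs)]))
  b <- merger_test(df2, colour_fractions = probs2, n_resamples = 500, seed = 9)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)

  # global translation of the tissue leaves the called clones, and hence the
  # test, unchanged
  tissue <- simulate_tissue(tissue_preset("mi"), sections = 4, seed = 13)
  shifted <- tissue
  shifted$x <- shifted$x + 50L
  shifted$y <- shifted$y + 7L
  ca <- call_clones(tissue)$clones
  cb <- call_clones(shifted)$clones
  expect_equal(ca$size, cb$size)
  expect_equal(ca$colour, cb$colour)
})

test_that("expansion-regime sizes leave the trend test at its nominal level", {
  # spot check at modest replication; the full calibration lives in the
  # acceptance suite
  set.seed(31)
  probs <- tissue_preset("healthy")$colour_probs
  rej <- replicate(60, {
    df <- data.frame(colour = sample(names(probs), 150, TRUE, probs),
                     size = 2L + rnbinom(150, size = 1.7, mu = 2))
    merger_test(df, colour_fractions = probs, n_resamples = 400)$p_value <= 0.05
  })
  expect_lt(mean(rej), 0.2)
})
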