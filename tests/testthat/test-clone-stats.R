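test_that("direct-count example: one 4-cell YFP clone plus one RFP singleton", {
  tissue <- make_tissue(x = c(0L, 1L, 2L, 3L, 10L), y = 0L, z = 0L,
                        colour = c(rep("YFP", 4), "RFP"),
                        vessel_id = c(rep(1L, 4), 2L))
  cs <- call_clones(tissue)
  st <- clonal_stats(cs, tissue)
  expect_equal(st$summary$mean_clone_size, 4)
  expect_equal(st$summary$founder_events, 2L)
  expect_equal(st$summary$singleton_fraction, 0.2)
  expect_equal(unname(st$colour_fractions[c("YFP", "RFP")]), c(0.8, 0.2))
  expect_equal(sum(st$colour_fractions), 1)
})

test_that("EdU indices follow the marked cells", {
  tissue <- make_tissue(x = c(0L, 1L, 4L, 6L), y = 0L, z = 0L,
                        colour = c("YFP", "YFP", "RFP", "NONE"),
                        edu = c(TRUE, TRUE, TRUE, FALSE))
  st <- clonal_stats(call_clones(tissue), tissue)
  expect_equal(st$summary$edu_confetti_fraction, 1)
  expect_equal(st$summary$edu_total_fraction, 0.75)
})

test_that("tissues without labelled cells give flagged absent statistics, not zeros", {
  tissue <- make_tissue(x = c(0L, 2L), y = 0L, z = 0L, colour = "NONE")
  st <- clonal_stats(call_clones(tissue), tissue)
  expect_true(st$summary$no_labelled_cells)
  expect_true(is.na(st$summary$mean_clone_size))
  expect_true(is.na(st$summary$singleton_fraction))
})

test_that("vessel classification follows the colour count above the threshold", {
  tissue <- make_tissue(
    x = c(0L, 2L, 4L, 6L, 8L,   0L, 2L, 4L, 6L,   0L,    0L, 2L),
    y = c(rep(0L, 5),           rep(3L, 4),        6L,    9L, 9L),
    z = 0L,
    colour = c(rep("RFP", 5), c("YFP", "YFP", "YFP", "mCFP"), "YFP", "NONE", "NONE"),
    vessel_id = c(rep(1L, 5), rep(2L, 4), 3L, 4L, 4L)
  )
  vc <- classify_vessels(tissue, min_labelled = 2L)
  expect_equal(vc$class[vc$vessel_id == 1], "monoclonal")
  expect_equal(vc$class[vc$vessel_id == 2], "polychromatic")
  expect_equal(vc$class[vc$vessel_id == 3], "unclassified")
  expect_equal(vc$class[vc$vessel_id == 4], "unclassified")

  st <- clonal_stats(call_clones(tissue), tissue)
  expect_equal(st$summary$monoclonal_vessel_fraction +
                 st$summary$polychromatic_vessel_fraction, 1)
})

test_that("per-section accounting sums to the pooled totals", {
  tissue <- simulate_tissue(tissue_preset("healthy"), sections = 6, seed = 77)
  cs <- call_clones(tissue)
  st <- clonal_stats(cs, tissue)
  ps <- st$per_section
  expect_equal(sum(ps$n_clones), st$summary$n_clones)
  expect_equal(sum(ps$n_singletons), st$summary$n_singletons)
  expect_equal(sum(ps$founder_events), st$summary$founder_events)
  expect_equal(sum(ps$n_labelled) - sum(ps$n_clones > 0) * 0, # plain conservation
               sum(tissue$colour != "NONE"))
  expect_equal(st$summary$founder_events_per_section,
               mean(ps$founder_events))
})

test_that("group comparison: identical groups give p = 1 under permutation", {
  df <- data.frame(section_id = 1:5, mean_clone_size = c(3, 4, 5, 4, 3))
  out <- compare_groups(df, df, "mean_clone_size", method = "permutation",
                        n_resamples = 500, seed = 1)
  expect_equal(out$effect, 0)
  expect_equal(out$p_value, 1)
  expect_error(compare_groups(df, df, "not_a_metric"), "absent")
  expect_error(compare_groups(df[1, , drop = FALSE], df, "mean_clone_size"), ">= 2")
})

test_that("healthy and infarct-border presets separate on clone size", {
  a <- simulate_tissue(tissue_preset("healthy"), sections = 15, seed = 5)
  b <- simulate_tissue(tissue_preset("mi"), sections = 15, seed = 6)
  sa <- clonal_stats(call_clones(a), a)
  sb <- clonal_stats(call_clones(b), b)
  cmp <- compare_groups(sa, sb, "mean_clone_size")
  expect_lt(cmp$p_value, 0.001)
  expect_lt(cmp$effect, 0)
})
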