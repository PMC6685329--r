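three_state_counts <- function(n = 600L, seed = 37) {
  # C shares its second marker set with B: those genes cannot be specific
  arch <- list(
    A = list(markers = sprintf("Amark%02d", 1:6), fold = 8, abundance = 1 / 3, mi_share = 0.5),
    B = list(markers = c(sprintf("Bmark%02d", 1:6), "Shared1", "Shared2"),
             fold = 8, abundance = 1 / 3, mi_share = 0.5),
    C = list(markers = c(sprintf("Cmark%02d", 1:6), "Shared1", "Shared2"),
             fold = 8, abundance = 1 / 3, mi_share = 0.5)
  )
  p <- sim_counts_params(n_cells = c(healthy = n %/% 2, mi = n - n %/% 2),
                         n_genes = 500L, archetypes = arch,
                         contaminant_fraction = 0, lowdepth_cell_fraction = 0,
                         mito_tail_fraction = 0, program_genes = 0,
                         endmt_latent_sdlog = 0, endmt_replicate_sdlog = 0)
  simulate_counts(p, seed = seed)
}

test_that("planted markers are recovered as significant, top-ranked and correctly specific", {
  cm <- three_state_counts()
  res <- embed_and_cluster(cm, n_pcs = 20, n_clusters_hint = 3, seed = 8)
  expect_equal(res$n_clusters, 3L)
  mk <- cluster_markers(res, cm)

  truth <- cm$cells$archetype
  for (arch_name in c("A", "B", "C")) {
    lv <- names(which.max(table(res$cluster[truth == arch_name])))
    top <- mk$gene[mk$cluster == lv][1:6]
    planted <- switch(arch_name,
                      A = sprintf("Amark%02d", 1:6),
                      B = c(sprintf("Bmark%02d", 1:6), "Shared1", "Shared2"),
                      C = c(sprintf("Cmark%02d", 1:6), "Shared1", "Shared2"))
    expect_gt(length(intersect(top, planted)), 3)
    sub <- mk[mk$cluster == lv & mk$gene %in% planted, ]
    expect_true(all(sub$p_adj < 0.01))
    expect_true(all(sub$significant))
  }

  # shared markers are significant in two clusters, hence not specific
  shared <- mk[mk$gene %in% c("Shared1", "Shared2") & mk$significant, ]
  expect_gt(nrow(shared), 2)
  expect_true(all(!shared$specific))
  # unshared planted markers of A are specific to A's cluster
  a_rows <- mk[mk$gene %in% sprintf("Amark%02d", 1:6) & mk$significant, ]
  expect_true(all(a_rows$specific))
})

test_that("a gene with an identical distribution everywhere is not flagged", {
  cm <- three_state_counts(n = 400L)
  res <- embed_and_cluster(cm, n_pcs = 20, n_clusters_hint = 3, seed = 9)
  mk <- cluster_markers(res, cm)
  # Pecam1 is elevated identically in every archetype
  expect_true(all(!mk$significant[mk$gene == "Pecam1"]))
})

test_that("the BH step is monotone and matches an independent reference", {
  cm <- three_state_counts(n = 400L)
  res <- embed_and_cluster(cm, n_pcs = 20, n_clusters_hint = 3, seed = 10)
  mk <- cluster_markers(res, cm)
  for (lv in unique(mk$cluster)) {
    sub <- mk[mk$cluster == lv, ]
    expect_true(all(sub$p_adj >= sub$p))
    expect_equal(sub$p_adj, ref_bh(sub$p))
    o <- order(sub$p)
    expect_true(!is.unsorted(sub$p_adj[o]))
  }
  # and on random p-vectors
  set.seed(1)
  for (i in 1:5) {
    pv <- runif(200)
    expect_equal(p.adjust(pv, "BH"), ref_bh(pv))
  }
})

test_that("composition testing: null calibration, exclusivity and underpowered flags", {
  # null: clusters drawn at the global ratio give approximately uniform p
  set.seed(101)
  ps <- replicate(300, {
    n <- sample(50:200, 1)
    n_mi <- rbinom(1, n, 0.55)
    comp <- matrix(c(n - n_mi, 500, n_mi, 611), 2, 2,
                   dimnames = list(cluster = c("1", "2"), group = c("healthy", "mi")))
    fake <- structure(list(composition = as.table(comp)), class = "cluster_result")
    composition_test(fake)$p[1]
  })
  expect_gt(mean(ps <= 0.05), 0.005)
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(mean(ps > 0.5), 0.3)

  comp <- matrix(c(0, 300, 80, 320), 2, 2,
                 dimnames = list(cluster = c("1", "2"), group = c("healthy", "mi")))
  fake <- structure(list(composition = as.table(comp)), class = "cluster_result")
  out <- composition_test(fake)
  expect_true(out$exclusive[out$cluster == "1"])
  expect_false(out$exclusive[out$cluster == "2"])

  tiny <- matrix(c(0, 300, 1, 320), 2, 2,
                 dimnames = list(cluster = c("1", "2"), group = c("healthy", "mi")))
  fake2 <- structure(list(composition = as.table(tiny)), class = "cluster_result")
  out2 <- composition_test(fake2)
  expect_equal(out2$p[out2$cluster == "1"], 1)
  expect_true(out2$underpowered[out2$cluster == "1"])

  expect_error(composition_test(structure(list(composition = NULL),
                                          class = "cluster_result")),
               "group labels")
})

test_that("gene queries rank the planted cluster first and reject absent genes", {
  cm <- three_state_counts(n = 400L)
  res <- embed_and_cluster(cm, n_pcs = 20, n_clusters_hint = 3, seed = 11)
  gq <- gene_query(res, cm, "Amark01")
  truth <- cm$cells$archetype
  a_cluster <- names(which.max(table(res$cluster[truth == "A"])))
  expect_equal(gq$by_cluster$cluster[1], a_cluster)
  expect_error(gene_query(res, cm, "Amork01"), "did you mean")

  # an all-zero gene summarizes to zero everywhere
  cm2 <- cm
  cm2$counts["Amark01", ] <- 0
  gq0 <- gene_query(res, cm2, "Amark01")
  expect_true(all(gq0$by_cluster$mean_expr == 0))
  expect_true(all(gq0$by_cluster$detection_fraction == 0))
})
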