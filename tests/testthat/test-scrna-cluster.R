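two_state_counts <- function(n = 500L, seed = 23) {
  arch <- list(
    A = list(markers = sprintf("Amark%02d", 1:10), fold = 8, abundance = 0.5, mi_share = 0.5),
    B = list(markers = sprintf("Bmark%02d", 1:10), fold = 8, abundance = 0.5, mi_share = 0.5)
  )
  p <- sim_counts_params(
    n_cells = c(healthy = n %/% 2, mi = n - n %/% 2), n_genes = 500L,
    archetypes = arch, contaminant_fraction = 0, lowdepth_cell_fraction = 0,
    mito_tail_fraction = 0, program_genes = 0,
    endmt_latent_sdlog = 0, endmt_replicate_sdlog = 0
  )
  simulate_counts(p, seed = seed)
}

test_that("two archetypes with disjoint markers are recovered almost perfectly", {
  cm <- two_state_counts()
  res <- embed_and_cluster(cm, n_pcs = 20, n_clusters_hint = 2, seed = 1)
  expect_equal(res$n_clusters, 2L)
  ari <- mclust::adjustedRandIndex(res$cluster, cm$cells$archetype)
  expect_gt(ari, 0.95)
})

test_that("a single homogeneous archetype yields one cluster at the default resolution", {
  arch <- list(only = list(markers = "Pecam1", fold = 1, abundance = 1, mi_share = 0.5))
  p <- sim_counts_params(n_cells = c(healthy = 150L, mi = 150L), n_genes = 500L,
                         archetypes = arch, contaminant_fraction = 0,
                         lowdepth_cell_fraction = 0, mito_tail_fraction = 0,
                         program_genes = 0, endmt_latent_sdlog = 0,
                         endmt_replicate_sdlog = 0)
  cm <- simulate_counts(p, seed = 29)
  res <- embed_and_cluster(cm, n_pcs = 20, seed = 2)
  expect_equal(res$n_clusters, 1L)
})

test_that("clustering is deterministic given the seed and invariant to gene order", {
  cm <- two_state_counts(n = 300L)
  a <- embed_and_cluster(cm, n_pcs = 15, n_clusters_hint = 2, seed = 3)
  b <- embed_and_cluster(cm, n_pcs = 15, n_clusters_hint = 2, seed = 3)
  expect_identical(a$cluster, b$cluster)

  perm <- sample(nrow(cm$counts))
  cm2 <- cm
  cm2$counts <- cm$counts[perm, ]
  cm2$genes <- cm$genes[perm, , drop = FALSE]
  c2 <- embed_and_cluster(cm2, n_pcs = 15, n_clusters_hint = 2, seed = 3)
  expect_true(same_partition(a$cluster, c2$cluster))
})

test_that("duplicated cells land in the same cluster as their originals", {
  cm <- two_state_counts(n = 250L)
  dup <- cm
  dup$counts <- cbind(cm$counts, cm$counts)
  colnames(dup$counts) <- c(colnames(cm$counts), paste0(colnames(cm$counts), "_dup"))
  dup$cells <- rbind(cm$cells, transform(cm$cells, cell_id = paste0(cell_id, "_dup")))
  res <- embed_and_cluster(dup, n_pcs = 15, n_clusters_hint = 2, seed = 4)
  n <- ncol(cm$counts)
  agree <- mean(res$cluster[seq_len(n)] == res$cluster[n + seq_len(n)])
  expect_gt(agree, 0.99)
})

test_that("clustering refuses fewer cells than components", {
  cm <- two_state_counts(n = 40L)
  expect_error(embed_and_cluster(cm, n_pcs = 50), "fewer cells")
})

test_that("contaminant removal flags the Ptprc+ Pecam1- Kdr- cluster and only it", {
  p <- sim_counts_params(n_cells = c(healthy = 300L, mi = 350L), n_genes = 600L,
                         contaminant_fraction = 0.05)
  cm <- simulate_counts(p, seed = 31)
  q <- qc_filter(cm)
  res <- embed_and_cluster(q, n_clusters_hint = 11, seed = 5)
  out <- remove_contaminant_cluster(res, q)
  expect_true(out$contaminant_removed)
  expect_gt(length(out$removed_clusters), 0)
  truth <- q$cells$archetype[match(out$cell_ids, q$cells$cell_id)]
  expect_equal(sum(truth == "contaminant"), 0)
  # no endothelial cells are lost with the contaminant flag
  expect_gt(length(out$cell_ids) / sum(q$cells$archetype != "contaminant"), 0.98)
})

test_that("no contaminant population means nothing is removed", {
  cm <- two_state_counts(n = 300L)
  res <- embed_and_cluster(cm, n_pcs = 15, n_clusters_hint = 2, seed = 6)
  out <- remove_contaminant_cluster(res, cm)
  expect_equal(length(out$removed_clusters), 0)
  expect_equal(length(out$cell_ids), ncol(cm$counts))
})

test_that("contaminant removal requires the marker genes to be present", {
  cm <- two_state_counts(n = 300L)
  res <- embed_and_cluster(cm, n_pcs = 15, seed = 7)
  expect_error(remove_contaminant_cluster(res, cm, positive = "NotAGene"),
               "NotAGene")
})
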