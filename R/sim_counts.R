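#' Default endothelial-state archetypes
#'
#' Ten transcriptional archetypes of cardiac endothelial cells, each defined
#' by a marker-gene set (seeded from the per-cluster top differentially
#' expressed genes of the reference atlas: homeostatic, interferon,
#' cardiomyocyte-marker-bearing, killer-cell-lectin-receptor, Notch,
#' Plvap+/remodelling, stalk-cell, extracellular-matrix, serpin, and
#' proliferative states), a marker fold-change, an overall abundance and the
#' expected fraction of the archetype's cells drawn from the
#' myocardial-infarction group. The stalk-cell archetype (7) is exclusive to
#' the MI group. `Plvap` is planted in archetypes 6, 7 and 8, matching its
#' reported enrichment; `Bgn` is shared between archetypes 6 and 8, so
#' neither can claim it as specific.
#'
#' @param fold Marker fold-change applied to each archetype's markers.
#' @return A named list of archetype definitions.
#' @export
default_archetypes <- function(fold = 8) {
  mk <- function(markers, abundance, mi_share) {
    list(markers = markers, fold = fold, abundance = abundance, mi_share = mi_share)
  }
  list(
    homeostatic   = mk(c("Arhgap18", "Adm", "Hspb1", "Cd36"), 0.16, 0.45),
    interferon    = mk(c("Ifit1", "Ifit2", "Ifit3", "Ifit3b", "Usp18", "Cxcl10"), 0.08, 0.70),
    cardiomyocyte = mk(c("Myl2", "Mb", "Myl3", "Tnnt2", "Tnni3", "Actc1"), 0.09, 0.80),
    klr           = mk(c("Klra3", "Klra9", "Klra10"), 0.06, 0.45),
    notch         = mk(c("Dll4", "Notch1", "Hey1", "Jag1", "Gja4"), 0.12, 0.45),
    plvap_remod   = mk(c("Plvap", "Lrg1", "Rbp1", "Bgn", "Vwf"), 0.11, 0.75),
    stalk         = mk(c("Ackr1", "Ehd4", "Tmem176a", "Tmem252", "Tmem176b", "Selp",
                         "Plvap"), 0.08, 1.00),
    ecm           = mk(c("Fbln2", "Anxa2", "Col5a2", "Emilin1", "Hmcn1", "Bgn",
                         "Mgp", "Plvap"), 0.10, 0.65),
    serpin        = mk(c("Serpina1b", "Serpina1d", "Serpina1e"), 0.08, 0.45),
    proliferative = mk(c("Mki67", "Top2a", "Cenpf", "Cks2", "Birc5", "Cenpa",
                         "Ube2c", "Cdc20"), 0.12, 0.70)
  )
}

MITO_GENES <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Co3", "Atp6", "Atp8",
                              "Cytb", "Nd3", "Nd4", "Nd4l", "Nd5", "Nd6"))
EC_CORE_GENES <- c("Pecam1", "Kdr", "Cdh5", "Cldn5", "Egfl7", "Pdgfb")
CONTAMINANT_GENES <- c("Ptprc", "Lyz2", "Coro1a", "Laptm5", "Cd52")

#' Parameters for the single-cell count simulator
#'
#' Defines a gene x cell negative-binomial UMI generator with archetype
#' structure, a haematopoietic (Ptprc+ Pecam1- Kdr-) contaminant population,
#' per-cell mitochondrial fractions with a tail beyond the 20% QC threshold,
#' a low-depth cell fraction falling under the 400-detected-genes QC
#' threshold, rare Ptprc+Pecam1+ double-positive cells in the MI group, a
#' correlated endothelial-to-mesenchymal (EndMT) expression program with
#' per-cell and per-replicate variability, and optional group-level
#' differential expression.
#'
#' @param n_cells Named integer vector `c(healthy = ..., mi = ...)`.
#' @param n_genes Total number of genes (named biology genes plus filler).
#' @param archetypes Archetype list as from [default_archetypes()].
#' @param depth Named expected UMI depth per group.
#' @param depth_sdlog Log-normal spread of per-cell depth.
#' @param dispersion Negative-binomial size parameter (must be > 0).
#' @param mito_mean Mean mitochondrial fraction of ordinary cells.
#' @param mito_tail_fraction Fraction of cells drawn from the high-mito tail.
#' @param mito_tail_mean Mean mitochondrial fraction in the tail (beyond 0.20).
#' @param lowdepth_cell_fraction Fraction of cells with strongly reduced
#'   depth (falling under the detected-gene QC threshold).
#' @param lowdepth_scale Depth multiplier for low-depth cells.
#' @param contaminant_fraction Fraction of cells that are haematopoietic
#'   contaminants.
#' @param rare_double_positive_fraction Fraction of MI endothelial cells that
#'   additionally express Ptprc (default 0.0029).
#' @param group_de_genes Optional named vector of fold-changes applied to MI
#'   cells (gene-level group effects independent of archetype).
#' @param endmt_genes Genes of the correlated EndMT program (defaults to the
#'   shipped panel).
#' @param endmt_latent_sdlog Per-cell log-normal SD of the EndMT program.
#' @param endmt_replicate_sdlog Per-replicate (animal) log-normal SD of the
#'   EndMT program.
#' @param n_replicates Named number of biological replicates per group.
#' @param program_genes Number of additional genes mildly modulated per
#'   archetype (a broad transcriptome "program" on top of the discrete
#'   markers, as real cell states carry; 0 disables).
#' @param program_sdlog Log-normal SD of the program modulation.
#' @param ec_core_fold Fold-change of pan-endothelial genes in EC cells.
#' @param contaminant_fold Fold-change of haematopoietic genes in
#'   contaminant cells (and of Ptprc in double-positive cells).
#' @param seed Default RNG seed for [simulate_counts()].
#' @return An object of class `sim_counts_params`.
#' @export
sim_counts_params <- function(n_cells = c(healthy = 3200L, mi = 3950L),
                              n_genes = 2000L,
                              archetypes = default_archetypes(),
                              depth = c(healthy = 2230, mi = 5040),
                              depth_sdlog = 0.25,
                              dispersion = 2,
                              mito_mean = 0.05,
                              mito_tail_fraction = 0.06,
                              mito_tail_mean = 0.35,
                              lowdepth_cell_fraction = 0.04,
                              lowdepth_scale = 0.07,
                              contaminant_fraction = 0.03,
                              rare_double_positive_fraction = 0.0029,
                              group_de_genes = NULL,
                              endmt_genes = endmt_panel()$gene,
                              endmt_latent_sdlog = 0.6,
                              endmt_replicate_sdlog = 0.4,
                              n_replicates = c(healthy = 3L, mi = 4L),
                              program_genes = 400L,
                              program_sdlog = 0.5,
                              ec_core_fold = 6,
                              contaminant_fold = 8,
                              seed = NULL) {
  if (!all(c("healthy", "mi") %in% names(n_cells))) {
    stop_clonevasc("`n_cells` must be named c(healthy = ..., mi = ...)")
  }
  if (dispersion <= 0) stop_clonevasc("`dispersion` must be > 0")
  if (any(depth <= 0)) stop_clonevasc("`depth` must be positive")
  for (nm in c("mito_mean", "mito_tail_fraction", "lowdepth_cell_fraction",
               "contaminant_fraction", "rare_double_positive_fraction")) {
    check_probability(get(nm), nm)
  }
  if (mito_tail_mean <= 0 || mito_tail_mean >= 1) {
    stop_clonevasc("`mito_tail_mean` must be in (0, 1)")
  }
  shares <- vapply(archetypes, function(a) a$mi_share, numeric(1))
  if (any(shares < 0 | shares > 1)) {
    stop_clonevasc("archetype `mi_share` values must be probabilities")
  }
  # A marker named by two archetypes must carry one fold-change.
  folds <- list()
  for (nm in names(archetypes)) {
    a <- archetypes[[nm]]
    for (g in a$markers) {
      if (!is.null(folds[[g]]) && folds[[g]] != a$fold) {
        stop_clonevasc("marker `", g, "` is assigned conflicting fold-changes across archetypes")
      }
      folds[[g]] <- a$fold
    }
  }
  all_markers <- unique(unlist(lapply(archetypes, `[[`, "markers")))
  named <- unique(c(all_markers, EC_CORE_GENES, CONTAMINANT_GENES, MITO_GENES,
                    endmt_genes, names(group_de_genes), "Pdpn"))
  if (n_genes < length(named) + 10L) {
    stop_clonevasc("`n_genes` too small to host the ", length(named), " named genes")
  }
  structure(list(
    n_cells = n_cells, n_genes = as.integer(n_genes), archetypes = archetypes,
    depth = depth, depth_sdlog = depth_sdlog, dispersion = dispersion,
    mito_mean = mito_mean, mito_tail_fraction = mito_tail_fraction,
    mito_tail_mean = mito_tail_mean,
    lowdepth_cell_fraction = lowdepth_cell_fraction,
    lowdepth_scale = lowdepth_scale,
    contaminant_fraction = contaminant_fraction,
    rare_double_positive_fraction = rare_double_positive_fraction,
    group_de_genes = group_de_genes,
    endmt_genes = endmt_genes,
    endmt_latent_sdlog = endmt_latent_sdlog,
    endmt_replicate_sdlog = endmt_replicate_sdlog,
    n_replicates = n_replicates,
    program_genes = as.integer(program_genes),
    program_sdlog = program_sdlog,
    ec_core_fold = ec_core_fold, contaminant_fold = contaminant_fold,
    seed = seed
  ), class = "sim_counts_params")
}

#' Simulate a single-cell UMI count matrix
#'
#' Draws a sparse gene x cell negative-binomial UMI matrix under the
#' archetype model of [sim_counts_params()]. Marker genes are elevated by
#' their archetype's fold-change; pan-endothelial genes (Pecam1, Kdr, Cdh5,
#' Cldn5, Egfl7, Pdgfb) are elevated in all endothelial cells; contaminant
#' cells express haematopoietic genes (Ptprc and friends) and leave the
#' endothelial genes at background. Per-cell metadata records the group,
#' replicate, true archetype, true mitochondrial fraction and the low-depth
#' and double-positive flags. Deterministic given the seed.
#'
#' @param params A [sim_counts_params()] object.
#' @param seed RNG seed (overrides `params$seed`).
#' @return A `counts_matrix`: list with `counts` (dgCMatrix, genes x cells),
#'   `genes` (data frame), `cells` (per-cell metadata data frame).
#' @export
simulate_counts <- function(params, seed = NULL) {
  if (!inherits(params, "sim_counts_params")) {
    stop_clonevasc("`params` must be created by sim_counts_params()")
  }
  seed <- seed %||% params$seed

  with_seed(seed, {
    G <- params$n_genes
    arch <- params$archetypes
    all_markers <- unique(unlist(lapply(arch, `[[`, "markers")))
    named <- unique(c(all_markers, EC_CORE_GENES, CONTAMINANT_GENES,
                      params$endmt_genes, names(params$group_de_genes), "Pdpn"))
    named <- setdiff(named, MITO_GENES)
    filler <- sprintf("Gene%04d", seq_len(G - length(named) - length(MITO_GENES)))
    genes <- c(named, MITO_GENES, filler)
    mt_idx <- match(MITO_GENES, genes)

    # Base relative abundance of non-mito genes (mito handled separately).
    # Biology genes get controlled moderate baselines so that fold-changes
    # translate into a reproducible detection signal.
    base_rel <- rlnorm(G, meanlog = 0, sdlog = 1.1)
    biology <- match(unique(c(all_markers, EC_CORE_GENES, params$endmt_genes,
                              names(params$group_de_genes))), genes)
    biology <- biology[!is.na(biology)]
    base_rel[biology] <- rlnorm(length(biology), meanlog = log(0.7), sdlog = 0.4)
    # pan-endothelial genes are abundant housekeeping-level transcripts:
    # detected in essentially every endothelial cell
    ec_idx <- match(EC_CORE_GENES, genes)
    base_rel[ec_idx] <- rlnorm(length(ec_idx), meanlog = log(2), sdlog = 0.25)
    cont_idx <- match(CONTAMINANT_GENES, genes)
    base_rel[cont_idx] <- rlnorm(length(cont_idx), meanlog = 0, sdlog = 0.3)
    base_rel[mt_idx] <- 0
    pi_mt <- rlnorm(length(mt_idx), 0, 0.5)
    pi_mt <- pi_mt / sum(pi_mt)

    # Cells.
    groups <- rep(c("healthy", "mi"), times = params$n_cells[c("healthy", "mi")])
    N <- length(groups)
    reps <- unlist(lapply(c("healthy", "mi"), function(g) {
      n <- params$n_cells[[g]]
      k <- params$n_replicates[[g]]
      paste0(g, "_rep", sample(rep_len(seq_len(k), n)))
    }))
    abundance <- vapply(arch, `[[`, numeric(1), "abundance")
    mi_share <- vapply(arch, `[[`, numeric(1), "mi_share")
    w_h <- abundance * (1 - mi_share)
    w_m <- abundance * mi_share
    archetype <- character(N)
    archetype[groups == "healthy"] <-
      sample(names(arch), sum(groups == "healthy"), replace = TRUE,
             prob = if (sum(w_h) > 0) w_h else rep(1, length(arch)))
    archetype[groups == "mi"] <-
      sample(names(arch), sum(groups == "mi"), replace = TRUE, prob = w_m)
    contaminant <- rbinom(N, 1L, params$contaminant_fraction) == 1L
    archetype[contaminant] <- "contaminant"
    double_pos <- !contaminant & groups == "mi" &
      rbinom(N, 1L, params$rare_double_positive_fraction) == 1L

    depth <- rlnorm(N, meanlog = log(params$depth[groups]) - params$depth_sdlog^2 / 2,
                    sdlog = params$depth_sdlog)
    lowdepth <- rbinom(N, 1L, params$lowdepth_cell_fraction) == 1L
    depth[lowdepth] <- depth[lowdepth] * params$lowdepth_scale

    tail_cell <- rbinom(N, 1L, params$mito_tail_fraction) == 1L
    mito <- numeric(N)
    mm <- params$mito_mean
    if (mm > 0) {
      mito[!tail_cell] <- stats::rbeta(sum(!tail_cell), mm * 40, (1 - mm) * 40)
    }
    tm <- params$mito_tail_mean
    mito[tail_cell] <- stats::rbeta(sum(tail_cell), tm * 20, (1 - tm) * 20)

    # Multiplier vectors per archetype (plus contaminant profile).
    # Endothelial cells express haematopoietic and lymphatic genes at near
    # zero; contaminants express the haematopoietic programme and leave the
    # endothelial genes at near zero.
    pdpn_idx <- match("Pdpn", genes)
    mult <- list()
    for (nm in names(arch)) {
      v <- rep(1, G)
      v[match(arch[[nm]]$markers, genes)] <- arch[[nm]]$fold
      v[match(EC_CORE_GENES, genes)] <- params$ec_core_fold
      v[cont_idx] <- 0.001
      v[pdpn_idx] <- 0.01
      if (params$program_genes > 0L) {
        prog <- sample.int(G, min(params$program_genes, G))
        v[prog] <- v[prog] * rlnorm(length(prog), 0, params$program_sdlog)
      }
      mult[[nm]] <- v
    }
    v <- rep(1, G)
    v[cont_idx] <- params$contaminant_fold
    v[match(EC_CORE_GENES, genes)] <- 0.02
    mult[["contaminant"]] <- v

    de_idx <- match(names(params$group_de_genes), genes)
    panel_idx <- match(intersect(params$endmt_genes, genes), genes)
    ptprc_idx <- match("Ptprc", genes)

    rep_levels <- unique(reps)
    rep_effect <- setNames(rlnorm(length(rep_levels), 0, params$endmt_replicate_sdlog),
                           rep_levels)
    cell_latent <- rlnorm(N, 0, params$endmt_latent_sdlog)

    # Draw counts cell by cell; assemble sparse triplets in blocks.
    ii <- vector("list", N); xx <- vector("list", N)
    nnz <- integer(N)
    disp <- params$dispersion
    for (i in seq_len(N)) {
      p <- base_rel * mult[[archetype[i]]]
      if (!contaminant[i]) {
        if (groups[i] == "mi" && length(de_idx)) {
          p[de_idx] <- p[de_idx] * params$group_de_genes
        }
        if (length(panel_idx)) {
          p[panel_idx] <- p[panel_idx] * cell_latent[i] * rep_effect[[reps[i]]]
        }
        # double positives express Ptprc at the haematopoietic level
        if (double_pos[i]) p[ptprc_idx] <- base_rel[ptprc_idx] * params$contaminant_fold
      }
      mu <- p * (depth[i] * (1 - mito[i]) / sum(p))
      mu[mt_idx] <- pi_mt * depth[i] * mito[i]
      cnt <- rnbinom(G, size = disp, mu = mu)
      nz <- which(cnt > 0L)
      ii[[i]] <- nz
      xx[[i]] <- cnt[nz]
      nnz[i] <- length(nz)
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(ii), j = rep.int(seq_len(N), nnz), x = unlist(xx),
      dims = c(G, N), dimnames = list(genes, paste0("cell", seq_len(N)))
    )

    cells <- data.frame(
      cell_id = colnames(counts),
      group = groups,
      replicate = reps,
      archetype = archetype,
      mito_fraction_true = mito,
      lowdepth = lowdepth,
      double_positive = double_pos,
      stringsAsFactors = FALSE
    )
    structure(list(counts = counts,
                   genes = data.frame(gene = genes, stringsAsFactors = FALSE),
                   cells = cells,
                   params = params),
              class = "counts_matrix")
  })
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("UMI count matrix: %d genes x %d cells (%.1f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  if ("group" %in% names(x$cells)) print(table(x$cells$group))
  invisible(x)
}

#' Reconstructed endothelial-to-mesenchymal transition marker panel
#'
#' A panel of canonical early (transcription-factor) and late
#' (mesenchymal-product) EndMT markers used for module scoring. The panel is
#' a reconstruction assembled from the EndMT genes named in the reference
#' analysis (Icam1, Vcam1, Vim, Fn1, Smtn) plus the canonical EndMT
#' programme, and is shipped as a YAML file in `inst/extdata`.
#'
#' @return Data frame with columns `gene` and `phase` (`early`/`late`).
#' @export
endmt_panel <- function() {
  path <- system.file("extdata", "endmt_panel_reconstructed.yaml",
                      package = "clonevasc")
  if (nzchar(path)) return(read_signature_panel(path))
  # fallback while the package is loaded without installed extdata
  data.frame(
    gene = c("Snai1", "Snai2", "Twist1", "Zeb1", "Zeb2", "Cdh2",
             "Icam1", "Vcam1", "Vim", "Fn1", "Smtn", "S100a4", "Acta2",
             "Tagln", "Col1a1", "Col3a1", "Serpine1", "Postn"),
    phase = c(rep("early", 6), rep("late", 12)),
    stringsAsFactors = FALSE
  )
}
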