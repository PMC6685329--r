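#' Probability that k independent founders share one fluorophore
#'
#' Analytic null for apparent-clone inflation by merger: the probability that
#' `k` adjacent but independent founders all drew the same colour is
#' `sum_c p_c^k`. For uniform probabilities this equals `4^(1-k)`.
#'
#' @param k Number of independent founders (>= 1).
#' @param colour_probs Valid 4-colour probability vector.
#' @return The collision probability.
#' @examples
#' colour_collision_probability(2, rep(0.25, 4)) # 0.25
#' @export
colour_collision_probability <- function(k, colour_probs) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop_clonevasc("`k` must be a single integer >= 1")
  }
  colour_probs <- check_colour_probs(colour_probs)
  sum(colour_probs^k)
}

#' Merger-versus-expansion inference on called clones
#'
#' Under pure clonal expansion, clone size is independent of fluorophore
#' identity. Under merger (independent founders adjacent by chance, fusing
#' when they share a colour), common colours collide more often, so expected
#' clone size increases with a colour's frequency. The test statistic is the
#' Spearman association between clone size and the frequency of the clone's
#' colour; its one-sided permutation p-value (colour labels permuted over
#' clones, add-one rule) is the primary `p_value`. A Kruskal-Wallis test of
#' clone size across colours -- the direct analogue of asking whether clone
#' size differs between fluorophores -- is computed alongside
#' (`p_kruskal`, also by permutation).
#'
#' @param clones A `clone_set` from [call_clones()] (or a data frame with
#'   `colour` and `size` columns).
#' @param colour_fractions Optional named colour frequencies; defaults to
#'   the labelled-cell colour fractions implied by the clones themselves.
#' @param n_resamples Number of label permutations (>= 1000 recommended).
#' @param seed RNG seed.
#' @return A `merger_test` result: `statistic` (observed Spearman rho),
#'   `kruskal_statistic`, `p_value`, `p_kruskal`, `n_resamples`, `n_clones`,
#'   and `expected_size_by_colour_under_merger` (Monte-Carlo expectation of
#'   apparent clone size per colour under a matched merger alternative).
#' @export
merger_test <- function(clones, colour_fractions = NULL,
                        n_resamples = 1000L, seed = NULL) {
  df <- if (inherits(clones, "clone_set")) clones$clones else clones
  if (!is.data.frame(df) || !all(c("colour", "size") %in% names(df))) {
    stop_clonevasc("`clones` must be a clone_set or a data frame with `colour` and `size`")
  }
  n <- nrow(df)
  if (n < 2L) stop_clonevasc("merger test needs at least 2 clones")
  colours_present <- unique(df$colour)
  if (length(colours_present) < 2L) {
    stop_clonevasc("merger test undefined for monochromatic clone sets")
  }
  if (n_resamples < 1L) stop_clonevasc("`n_resamples` must be >= 1")

  if (is.null(colour_fractions)) {
    # size-weighted: frequency of each colour among labelled clone cells
    tot <- tapply(df$size, df$colour, sum)
    colour_fractions <- as.numeric(tot) / sum(df$size)
    names(colour_fractions) <- names(tot)
  }
  freq <- colour_fractions[df$colour]
  if (anyNA(freq)) stop_clonevasc("`colour_fractions` is missing a colour present in the clones")

  with_seed(seed, {
    rs <- rank(df$size)
    rf <- rank(freq)
    rho_obs <- if (var(rs) == 0 || var(rf) == 0) 0 else cor(rs, rf)

    grp <- factor(df$colour)
    k <- nlevels(grp)
    ng <- as.numeric(table(grp))
    # Kruskal-Wallis with tie correction
    tie_term <- {
      tt <- table(df$size)
      sum(tt^3 - tt)
    }
    C <- 1 - tie_term / (n^3 - n)
    kw_of <- function(rank_vec_matrix) {
      # rank_vec_matrix: n x B matrix of (permuted) ranks
      Rg <- rowsum(rank_vec_matrix, grp)         # k x B group rank sums
      h <- 12 / (n * (n + 1)) * colSums(Rg^2 / ng) - 3 * (n + 1)
      if (C > 0) h / C else h * 0
    }
    kw_obs <- kw_of(matrix(rs, ncol = 1L))[1L]

    # Permuting colour labels over clones is equivalent to permuting sizes
    # against fixed labels.
    B <- as.integer(n_resamples)
    perm_idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
    S <- matrix(rs[perm_idx], nrow = n, ncol = B)
    rf_c <- rf - mean(rf)
    trend_obs <- sum(rs * rf_c)
    trend_null <- colSums(S * rf_c)
    p_trend <- (1 + sum(trend_null >= trend_obs)) / (1 + B)
    kw_null <- kw_of(S)
    p_kw <- (1 + sum(kw_null >= kw_obs)) / (1 + B)

    structure(list(
      statistic = rho_obs,
      kruskal_statistic = kw_obs,
      p_value = p_trend,
      p_kruskal = p_kw,
      null_law = "permutation",
      n_resamples = B,
      n_clones = n,
      colour_fractions = colour_fractions,
      expected_size_by_colour_under_merger =
        merger_expected_sizes(colour_fractions, mean(df$size))
    ), class = "merger_test")
  })
}

#' @export
print.merger_test <- function(x, ...) {
  cat("Merger-versus-expansion test\n")
  cat(sprintf("  %d clones; trend rho = %.3f, one-sided permutation p = %.4g\n",
              x$n_clones, x$statistic, x$p_value))
  cat(sprintf("  Kruskal-Wallis H = %.3f, permutation p = %.4g (%d resamples)\n",
              x$kruskal_statistic, x$p_kruskal, x$n_resamples))
  invisible(x)
}

# Expected apparent clone size per colour under the merger alternative:
# with pairing rate q, a founder is planted adjacent to a second independent
# founder with probability q; the pair fuses into one apparent clone when
# the colours collide. E[size | colour c] = mu * (1 + q * p_c).
merger_expected_sizes <- function(colour_fractions, mean_size, pair_rate = 0.5) {
  mean_size * (1 + pair_rate * colour_fractions)
}
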