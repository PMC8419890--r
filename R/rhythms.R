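#' One-way ANOVA across time bins
#'
#' Fixed-effects one-way F test of equality of means across Zeitgeber-time
#' bins, the first stage of the rhythm screen.
#'
#' @param values Numeric vector of observations.
#' @param bins Time-bin labels, one per observation (coerced to factor).
#' @return The F-test p-value. An all-constant series returns `p = 1` with a
#'   warning; a non-flat series with zero within-bin variance returns `p = 0`.
#' @export
anova_across_times <- function(values, bins) {
  bins <- factor(bins)
  if (nlevels(bins) < 2L) stop("need at least 2 time bins")
  if (any(tabulate(bins) == 0L)) stop("empty time bin")
  if (length(values) != length(bins)) stop("values/bins length mismatch")
  if (length(values) - nlevels(bins) < 1L)
    stop("no residual degrees of freedom (need replicates)")
  if (max(values) == min(values)) {
    warning("all values identical; returning p = 1")
    return(1)
  }
  p <- stats::oneway.test(values ~ bins, var.equal = TRUE)$p.value
  if (!is.finite(p)) p <- 0   # non-flat profile with zero within-bin variance
  p
}

# ---- umbrella (rise-then-fall) rank test ---------------------------------

# circular bin index in 1..k
circ_bin <- function(x, k) ((x - 1L) %% k) + 1L

# For each candidate peak bin j, a k x k weight matrix W with W[a, b] = 1
# meaning "add U_{ab}" to the statistic, where U_{ab} counts pairs
# (x in bin a, y in bin b) with x < y (ties 0.5). The profile is taken to
# rise over floor(k/2) steps up to the peak and fall over the rest: rising
# ordered pairs (a before b) contribute U_{ab}, falling ordered pairs
# contribute U_{ba}.
umbrella_weights <- function(k) {
  r <- k %/% 2L
  lapply(seq_len(k), function(j) {
    W <- matrix(0, k, k)
    rising <- circ_bin(seq(j - r, j), k)
    falling <- circ_bin(seq(j, j + (k - r - 1L)), k)
    for (i in seq_len(length(rising) - 1L))
      for (h in seq(i + 1L, length(rising)))
        W[rising[i], rising[h]] <- W[rising[i], rising[h]] + 1
    if (length(falling) > 1L)
      for (i in seq_len(length(falling) - 1L))
        for (h in seq(i + 1L, length(falling)))
          W[falling[h], falling[i]] <- W[falling[h], falling[i]] + 1
    W
  })
}

# pairwise "less than" matrix with 0.5 for ties
comparison_matrix <- function(values) {
  outer(values, values, "<") + 0.5 * outer(values, values, "==")
}

# S_j for all candidate peaks given observations, bin indicator matrix G and
# the weight list; U = t(G) C G aggregates pair counts between bins
umbrella_S <- function(values, G, W_list) {
  C <- comparison_matrix(values)
  U <- crossprod(G, C %*% G)
  vapply(W_list, function(W) sum(W * U), numeric(1))
}

# number of distinct assignments of n = sum(sizes) observations to bins
multinom_count <- function(sizes) {
  n <- sum(sizes)
  out <- 1
  rem <- n
  for (s in sizes) {
    out <- out * choose(rem, s)
    rem <- rem - s
  }
  out
}

# enumerate every distinct assignment of the observations to bins of the
# given sizes and return the matrix of S_j values (arrangements x k)
enumerate_umbrella_S <- function(values, sizes, W_list) {
  n <- length(values)
  k <- length(sizes)
  C <- comparison_matrix(values)
  total <- multinom_count(sizes)
  out <- matrix(NA_real_, total, k)
  row <- 0L
  labels <- integer(n)
  recurse <- function(bin, remaining) {
    if (bin > k) {
      G <- matrix(0, n, k)
      G[cbind(seq_len(n), labels)] <- 1
      U <- crossprod(G, C %*% G)
      row <<- row + 1L
      out[row, ] <<- vapply(W_list, function(W) sum(W * U), numeric(1))
      return(invisible(NULL))
    }
    if (length(remaining) == sizes[bin]) {
      labels[remaining] <<- bin
      recurse(bin + 1L, integer(0))
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[bin])
    for (cidx in seq_len(ncol(picks))) {
      sel <- picks[, cidx]
      labels[sel] <<- bin
      recurse(bin + 1L, setdiff(remaining, sel))
    }
    invisible(NULL)
  }
  recurse(1L, seq_len(n))
  out
}

#' Monte-Carlo null distribution of the umbrella statistic
#'
#' Samples the permutation null of the umbrella rank statistic for one
#' candidate peak position under a continuous (tie-free) exchangeable series:
#' observations are replaced by a uniformly random permutation of distinct
#' ranks. The null depends only on the bin-size vector and the peak position,
#' so one table is shared across genes measured under the same design.
#'
#' @param sizes Integer vector of per-bin replicate counts, in bin order.
#' @param peak Candidate peak bin index.
#' @param n_perm Number of permutation draws.
#' @param seed Integer seed for the draws.
#' @return Sorted numeric vector of `n_perm` null statistics.
#' @export
umbrella_null <- function(sizes, peak = 1L, n_perm = 20000L, seed = 1L) {
  k <- length(sizes)
  n <- sum(sizes)
  W <- umbrella_weights(k)[[peak]]
  G <- matrix(0, n, k)
  G[cbind(seq_len(n), rep(seq_len(k), sizes))] <- 1
  set.seed(seed)
  draws <- vapply(seq_len(n_perm), function(i) {
    y <- sample.int(n)
    C <- comparison_matrix(y)
    sum(W * crossprod(G, C %*% G))
  }, numeric(1))
  sort(draws)
}

# count of null values >= s; both grids are multiples of 0.5 so the -0.25
# offset makes findInterval exact
count_ge <- function(sorted_null, s) {
  length(sorted_null) - findInterval(s - 0.25, sorted_null)
}

#' Rank-based umbrella test for rise-then-fall rhythmicity
#'
#' Tests an independent-samples time-bin design against umbrella (monotone
#' rise to a peak bin, then fall) alternatives at every circular peak
#' position, in the spirit of rank-based rhythm detection for arbitrary
#' waveforms (Mack-Wolfe family). For each candidate peak bin j the statistic
#' sums, over ordered rising pairs (a, b), the count of pairs with
#' x_a < x_b, and over falling pairs the reversed count (ties contribute 0.5).
#' Per-peak p-values come from exhaustive enumeration of all distinct
#' assignments when their number is at most `enum_limit`, otherwise from
#' `n_perm` seeded permutations (with a 1/(n_perm+1) floor); the combined
#' p-value is Bonferroni-corrected over the k candidate peaks:
#' `p = min(1, k * min_j p_j)`.
#'
#' Only comparisons between observations enter the statistic, so any strictly
#' monotone transform of the values leaves the result unchanged.
#'
#' @param values Numeric observations.
#' @param bins Time-bin labels, one per observation; at least 3 bins, none
#'   empty.
#' @param mode `"auto"` (exact when feasible), `"exact"` or `"montecarlo"`.
#' @param n_perm Permutation count for Monte-Carlo mode.
#' @param seed Seed for Monte-Carlo mode.
#' @param enum_limit Maximum number of arrangements enumerated exactly.
#' @param null_dists Optional precomputed list of sorted null vectors (one per
#'   candidate peak, as from [umbrella_null()]) to reuse across many series.
#' @return List with `S_peak`, `peak_index` (candidate bin maximizing the
#'   evidence), `p_rain` (combined p-value), `p_per_peak`, `S_per_peak`,
#'   `bin_levels`, and `mode` used.
#' @export
umbrella_rank_test <- function(values, bins,
                               mode = c("auto", "exact", "montecarlo"),
                               n_perm = 20000L, seed = 1L,
                               enum_limit = 200000, null_dists = NULL) {
  mode <- match.arg(mode)
  if (!is.factor(bins)) bins <- factor(bins)   # keep declared (empty) levels
  k <- nlevels(bins)
  if (k < 3L) stop("umbrella test needs at least 3 time bins")
  sizes <- tabulate(bins, nbins = k)
  if (any(sizes == 0L)) stop("empty time bin")
  if (length(values) != length(bins)) stop("values/bins length mismatch")
  n <- length(values)

  W_list <- umbrella_weights(k)
  G <- matrix(0, n, k)
  G[cbind(seq_len(n), as.integer(bins))] <- 1
  S_obs <- umbrella_S(values, G, W_list)

  total <- multinom_count(sizes)
  if (mode == "auto") mode <- if (total <= enum_limit) "exact" else "montecarlo"

  if (mode == "exact") {
    if (total > enum_limit)
      stop("design has ", format(total), " arrangements, above enum_limit")
    S_all <- enumerate_umbrella_S(values, sizes, W_list)
    p <- vapply(seq_len(k), function(j) mean(S_all[, j] >= S_obs[j]),
                numeric(1))
  } else {
    if (is.null(null_dists)) {
      equal_sizes <- length(unique(sizes)) == 1L
      if (equal_sizes) {
        shared <- umbrella_null(sizes, peak = 1L, n_perm = n_perm, seed = seed)
        null_dists <- rep(list(shared), k)
      } else {
        null_dists <- lapply(seq_len(k), function(j)
          umbrella_null(sizes, peak = j, n_perm = n_perm, seed = seed + j))
      }
    }
    p <- vapply(seq_len(k), function(j) {
      nd <- null_dists[[j]]
      (1 + count_ge(nd, S_obs[j])) / (length(nd) + 1)
    }, numeric(1))
  }

  best <- which(p == min(p))
  if (length(best) > 1L) best <- best[which.max(S_obs[best])]
  list(S_peak = S_obs[best],
       peak_index = best,
       p_rain = min(1, k * min(p)),
       p_per_peak = p,
       S_per_peak = S_obs,
       bin_levels = levels(bins),
       mode = mode)
}

#' Detect rhythmic genes by ANOVA screening plus umbrella rank test
#'
#' Two-stage per-gene screen on a merged log2 matrix: (1) one-way ANOVA
#' across Zeitgeber-time bins with Benjamini-Hochberg adjustment over all
#' genes; (2) the umbrella rank test applied to the genes passing
#' `q_anova <= alpha1`, with BH adjustment within that family. A gene is
#' called rhythmic when `q_rain <= alpha2`. The peak phase `peak_zt` is the
#' ZT bin with the largest mean expression.
#'
#' @param m `expr_matrix` (log2).
#' @param meta Metadata data frame (`sample_id`, `group`, `zt`, ...).
#' @param group Group whose samples are analysed (e.g. `"young"`).
#' @param alpha1 FDR threshold of the ANOVA screen.
#' @param alpha2 FDR threshold of the umbrella stage.
#' @param n_perm,seed,enum_limit Settings passed to [umbrella_rank_test()];
#'   the permutation null table is computed once and shared across genes.
#' @param two_stage `FALSE` applies the umbrella test to all genes (single
#'   family).
#' @return Data frame with one row per gene: `gene_id`, `p_anova`, `q_anova`,
#'   `S_peak`, `peak_index`, `p_rain`, `q_rain`, `peak_zt`, `is_rhythmic`.
#'   Genes not reaching the umbrella stage carry `NA` in its columns and
#'   `is_rhythmic = FALSE`.
#' @export
detect_rhythmic <- function(m, meta, group, alpha1 = 0.05, alpha2 = 0.05,
                            n_perm = 20000L, seed = 1L, enum_limit = 200000,
                            two_stage = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!group %in% meta$group) stop("group '", group, "' absent from metadata")
  sel <- meta[meta$group == group & meta$sample_id %in% sample_ids(m), ,
              drop = FALSE]
  if (nrow(sel) == 0L) stop("no samples for group '", group, "'")
  v <- m$values[, sel$sample_id, drop = FALSE]
  bins <- factor(sel$zt)
  k <- nlevels(bins)
  if (k < 3L) stop("need at least 3 distinct ZT bins; found ", k)
  sizes <- tabulate(bins, nbins = k)
  zts <- as.numeric(levels(bins))

  p_anova <- apply(v, 1, function(y)
    suppressWarnings(anova_across_times(y, bins)))
  q_anova <- stats::p.adjust(p_anova, method = "BH")
  cand <- if (two_stage) which(q_anova <= alpha1) else seq_len(nrow(v))

  res <- data.frame(gene_id = rownames(v), p_anova = p_anova,
                    q_anova = q_anova, S_peak = NA_real_,
                    peak_index = NA_integer_, p_rain = NA_real_,
                    q_rain = NA_real_, peak_zt = NA_real_,
                    is_rhythmic = FALSE, row.names = NULL)

  bin_means <- t(apply(v, 1, function(y) tapply(y, bins, mean)))
  res$peak_zt <- zts[apply(bin_means, 1, which.max)]

  if (length(cand) > 0L) {
    total <- multinom_count(sizes)
    null_dists <- NULL
    if (total > enum_limit) {
      if (length(unique(sizes)) == 1L) {
        shared <- umbrella_null(sizes, peak = 1L, n_perm = n_perm, seed = seed)
        null_dists <- rep(list(shared), k)
      } else {
        null_dists <- lapply(seq_len(k), function(j)
          umbrella_null(sizes, peak = j, n_perm = n_perm, seed = seed + j))
      }
    }
    for (g in cand) {
      ut <- umbrella_rank_test(v[g, ], bins, mode = "auto", n_perm = n_perm,
                               seed = seed, enum_limit = enum_limit,
                               null_dists = null_dists)
      res$S_peak[g] <- ut$S_peak
      res$peak_index[g] <- ut$peak_index
      res$p_rain[g] <- ut$p_rain
    }
    res$q_rain[cand] <- stats::p.adjust(res$p_rain[cand], method = "BH")
    res$is_rhythmic <- !is.na(res$q_rain) & res$q_rain <= alpha2
  }
  res
}
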