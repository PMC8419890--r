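#' Filter genes with predominantly low microarray intensity
#'
#' Removes genes whose intensity falls below the pooled low-intensity
#' threshold in strictly more than `max_frac` of the samples. The threshold is
#' the `quantile` quantile (default 30%) of the intensity values of all genes
#' in all samples, pooled. A gene sitting below the threshold in exactly
#' 2/3 of the samples is retained: the inequality is strict.
#'
#' The threshold is a property of the full dataset: the value actually applied
#' is recorded in the `intensity_threshold` attribute of the result, and
#' re-filtering an already-filtered matrix reuses that recorded cutoff rather
#' than recomputing the quantile on the reduced gene set, so the filter is
#' idempotent.
#'
#' @param m An `expr_matrix` on the `raw_intensity` scale.
#' @param quantile Pooled quantile defining "low" intensity.
#' @param max_frac A gene is dropped when below threshold in strictly more
#'   than this fraction of samples.
#' @param threshold Optional explicit intensity cutoff overriding the pooled
#'   quantile.
#' @return Filtered `expr_matrix` with attributes `removed_genes` (character
#'   vector) and `intensity_threshold` (numeric cutoff applied).
#' @export
filter_low_intensity <- function(m, quantile = 0.30, max_frac = 2 / 3,
                                 threshold = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "raw_intensity")
    stop("filter_low_intensity expects a raw_intensity matrix")
  v <- m$values
  if (!is.numeric(v) || anyNA(v)) stop("intensity matrix must be numeric with no missing values")
  if (is.null(threshold)) threshold <- attr(m, "intensity_threshold")
  if (is.null(threshold))
    threshold <- stats::quantile(as.vector(v), probs = quantile, names = FALSE)
  frac_low <- rowMeans(v < threshold)
  drop <- frac_low > max_frac
  if (all(drop)) stop("intensity filter removed every gene")
  out <- em_update(m, v[!drop, , drop = FALSE])
  attr(out, "removed_genes") <- rownames(v)[drop]
  attr(out, "intensity_threshold") <- threshold
  out
}

#' Filter genes with low total read count
#'
#' Removes genes whose read count summed across all samples is below
#' `min_total` (default 100).
#'
#' @param m An `expr_matrix` on the `raw_count` scale.
#' @param min_total Minimum summed count to retain a gene; a gene with total
#'   exactly `min_total` is retained.
#' @return Filtered `expr_matrix` with attribute `removed_genes`.
#' @export
filter_low_counts <- function(m, min_total = 100) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "raw_count")
    stop("filter_low_counts expects a raw_count matrix")
  v <- m$values
  if (any(v < 0)) stop("counts must be non-negative")
  drop <- rowSums(v) < min_total
  if (all(drop)) stop("count filter removed every gene")
  out <- em_update(m, v[!drop, , drop = FALSE])
  attr(out, "removed_genes") <- rownames(v)[drop]
  out
}

#' Log2 transform and equalize per-sample medians
#'
#' Log2-transforms the matrix (counts are offset by `offset`, default +1,
#' before the log; intensities must be strictly positive) and shifts each
#' sample so that its median equals the grand median of the per-sample
#' medians. Afterwards all per-sample medians coincide.
#'
#' @param m An `expr_matrix` on a raw scale, or already `log2` (then only the
#'   median equalization is applied).
#' @param offset Pseudo-count added to raw counts before log2.
#' @return An `expr_matrix` on the `log2` scale with equal sample medians.
#' @export
log2_global_median_normalize <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (m$scale == "raw_count") {
    v <- log2(v + offset)
  } else if (m$scale == "raw_intensity") {
    if (any(v <= 0)) stop("intensities must be strictly positive for log2")
    v <- log2(v)
  }
  med <- apply(v, 2, stats::median)
  target <- stats::median(med)
  v <- sweep(v, 2, med - target, "-")
  em_update(m, v, scale = "log2")
}

#' Median-center genes within platform
#'
#' Subtracts, for every gene, its median computed within each platform, so
#' that each gene's within-platform median is zero. Removes gene-specific
#' platform baselines prior to cross-platform merging.
#'
#' @param m An `expr_matrix` on the `log2` scale.
#' @param platform Optional character/factor of per-sample platform labels
#'   (length `ncol(m)`). Default: all samples form one platform.
#' @return Median-centered `expr_matrix`.
#' @export
median_center <- function(m, platform = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("median_center expects a log2 matrix")
  v <- m$values
  if (is.null(platform)) platform <- rep("all", ncol(v))
  if (length(platform) != ncol(v))
    stop("'platform' must have one label per sample")
  for (p in unique(platform)) {
    idx <- platform == p
    if (!any(idx)) stop("platform with no samples")
    med <- apply(v[, idx, drop = FALSE], 1, stats::median)
    v[, idx] <- v[, idx, drop = FALSE] - med
  }
  em_update(m, v)
}

#' Merge two platforms on their common genes
#'
#' Restricts both matrices to the intersection of their gene sets (sorted
#' order) and concatenates their sample columns into one merged matrix.
#'
#' @param a,b `expr_matrix` objects on the `log2` scale with disjoint sample
#'   identifiers.
#' @return An `expr_matrix` with `platform = "merged"`; the per-sample
#'   platform of origin is recorded in the `sample_platform` attribute.
#' @export
merge_common_genes <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  if (a$scale != "log2" || b$scale != "log2")
    stop("both matrices must be log2-scaled before merging")
  common <- sort(intersect(gene_ids(a), gene_ids(b)))
  if (length(common) == 0L) stop("no common genes between the two platforms")
  dup <- intersect(sample_ids(a), sample_ids(b))
  if (length(dup) > 0L)
    stop("duplicate sample identifiers across inputs: ",
         paste(dup, collapse = ", "))
  v <- cbind(a$values[common, , drop = FALSE], b$values[common, , drop = FALSE])
  out <- expr_matrix(v, scale = "log2", platform = "merged")
  attr(out, "sample_platform") <- stats::setNames(
    c(rep(a$platform, ncol(a$values)), rep(b$platform, ncol(b$values))),
    colnames(v))
  out
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical distribution: the target is the
#' vector of row means of the column-sorted matrix, and each sample's values
#' are replaced by the target values at their within-sample ranks. Tied values
#' receive the mean of the target values over the tied rank span.
#'
#' @param m An `expr_matrix` (typically merged log2) without missing values.
#' @return Quantile-normalized `expr_matrix` (attributes preserved).
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (anyNA(v)) stop("quantile normalization requires a complete matrix")
  target <- rowMeans(apply(v, 2, sort))
  out <- v
  for (j in seq_len(ncol(v))) {
    o <- order(v[, j])
    span <- cumsum(!duplicated(v[o, j]))   # tie-group id in sorted order
    out[o, j] <- stats::ave(target, span)
  }
  res <- em_update(m, out)
  attr(res, "sample_platform") <- attr(m, "sample_platform")
  res
}

#' Empirical-Bayes batch correction (location/scale model)
#'
#' Removes additive and multiplicative batch effects from a log2 expression
#' matrix by the parametric empirical-Bayes procedure: each gene is
#' standardized against a batch-free least-squares fit (optionally including a
#' biological covariate whose effect is preserved), per-batch location and
#' scale estimates are shrunk towards method-of-moments hyperpriors (normal
#' prior on additive effects, inverse-gamma on multiplicative effects) by
#' iterative posterior updates, and the adjusted values are back-transformed.
#'
#' @param m An `expr_matrix` on the `log2` scale.
#' @param batch Per-sample batch labels (length `ncol(m)`); at least two
#'   samples per batch. With a single batch the matrix is returned unchanged.
#' @param group Optional per-sample biological covariate protected during
#'   correction (e.g. disease group).
#' @param eb Use empirical-Bayes shrinkage (default). `FALSE` applies the raw
#'   per-batch location/scale estimates.
#' @param tol,maxit Convergence tolerance and iteration cap for the posterior
#'   updates.
#' @return Batch-corrected `expr_matrix` (attributes preserved).
#' @export
batch_correct <- function(m, batch, group = NULL, eb = TRUE,
                          tol = 1e-6, maxit = 200) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("batch_correct expects a log2 matrix")
  v <- m$values
  n <- ncol(v)
  if (length(batch) != n) stop("'batch' must have one label per sample")
  batch <- factor(batch)
  nb <- table(batch)
  if (nlevels(batch) == 1L) return(m)
  if (any(nb < 2L))
    stop("each batch needs at least 2 samples; offending batch: ",
         paste(names(nb)[nb < 2], collapse = ", "))

  bmat <- stats::model.matrix(~ batch - 1)
  X <- bmat
  if (!is.null(group)) {
    if (length(group) != n) stop("'group' must have one label per sample")
    group <- factor(group)
    if (nlevels(group) > 1L) {
      gmat <- stats::model.matrix(~ group)[, -1, drop = FALSE]
      X <- cbind(bmat, gmat)
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with the covariate; cannot separate effects")

  beta <- solve(crossprod(X), crossprod(X, t(v)))        # p x G
  nbvec <- as.numeric(nb)
  grand_mean <- crossprod(nbvec / n, beta[seq_len(nlevels(batch)), , drop = FALSE])
  resid <- v - t(X %*% beta)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled <= 0))
    stop("gene(s) with zero pooled variance; cannot standardize")

  stand_mean <- matrix(grand_mean, nrow(v), n)
  if (ncol(X) > nlevels(batch)) {
    Xcov <- X[, -seq_len(nlevels(batch)), drop = FALSE]
    stand_mean <- stand_mean +
      t(Xcov %*% beta[-seq_len(nlevels(batch)), , drop = FALSE])
  }
  z <- (v - stand_mean) / sqrt(var_pooled)

  adj <- z
  for (b in levels(batch)) {
    idx <- batch == b
    zb <- z[, idx, drop = FALSE]
    nb_i <- sum(idx)
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1, stats::var)
    if (all(delta_hat == 0))
      stop("batch '", b, "' has zero within-batch variance for all genes")
    if (eb && isTRUE(stats::var(gamma_hat) > 0) &&
        isTRUE(stats::var(delta_hat) > 0)) {
      gbar <- mean(gamma_hat)
      t2 <- stats::var(gamma_hat)
      dm <- mean(delta_hat)
      s2 <- stats::var(delta_hat)
      aprior <- (2 * s2 + dm^2) / s2
      bprior <- (dm * s2 + dm^3) / s2
      g_old <- gamma_hat
      d_old <- delta_hat
      for (it in seq_len(maxit)) {
        g_new <- (nb_i * t2 * gamma_hat + d_old * gbar) / (nb_i * t2 + d_old)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + bprior) / (nb_i / 2 + aprior - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
        g_old <- g_new
        d_old <- d_new
        if (change < tol) break
      }
      gamma_star <- g_old
      delta_star <- d_old
    } else {
      gamma_star <- gamma_hat
      delta_star <- delta_hat
    }
    adj[, idx] <- (zb - gamma_star) / sqrt(pmax(delta_star, 1e-12))
  }
  out <- adj * sqrt(var_pooled) + stand_mean
  res <- em_update(m, out)
  attr(res, "sample_platform") <- attr(m, "sample_platform")
  res
}

#' Full dual-platform preprocessing cascade
#'
#' Applies, in order: the low-intensity filter to the array matrix and the
#' low-count filter to the RNA-seq matrix; log2 transformation with
#' global-median normalization per platform; gene-wise median centering
#' within platform; merging on common genes; quantile normalization; and
#' empirical-Bayes batch correction between platforms with the disease group
#' protected. Stage-wise gene/sample counts are logged to stderr.
#'
#' @param array_m `expr_matrix`, `raw_intensity` scale.
#' @param seq_m `expr_matrix`, `raw_count` scale.
#' @param meta Data frame with columns `sample_id`, `group`, `zt`,
#'   `platform`, `mouse_id` covering every sample in both matrices.
#' @param intensity_quantile,count_min Filter settings (see
#'   [filter_low_intensity()], [filter_low_counts()]).
#' @param verbose Log stage counts to stderr.
#' @return Merged, normalized, batch-corrected `expr_matrix` with attributes
#'   `sample_platform` and `stage_log` (data frame of per-stage counts).
#' @export
run_preprocess <- function(array_m, seq_m, meta,
                           intensity_quantile = 0.30, count_min = 100,
                           verbose = TRUE) {
  stopifnot(inherits(array_m, "expr_matrix"), inherits(seq_m, "expr_matrix"))
  check_meta(meta, c(sample_ids(array_m), sample_ids(seq_m)))

  log_df <- data.frame(stage = character(), genes = integer(),
                       samples = integer())
  note <- function(stage, em) {
    log_df <<- rbind(log_df, data.frame(stage = stage, genes = nrow(em$values),
                                        samples = ncol(em$values)))
    if (verbose)
      message(sprintf("[preprocess] stage=%s genes=%d samples=%d",
                      stage, nrow(em$values), ncol(em$values)))
  }
  note("input_array", array_m)
  note("input_seq", seq_m)

  a <- filter_low_intensity(array_m, quantile = intensity_quantile)
  note("filter_intensity", a)
  s <- filter_low_counts(seq_m, min_total = count_min)
  note("filter_counts", s)

  a <- log2_global_median_normalize(a)
  s <- log2_global_median_normalize(s)
  a <- median_center(a)
  s <- median_center(s)

  merged <- merge_common_genes(a, s)
  note("merge", merged)
  if (nrow(merged$values) == 0L) stop("no genes survive the merge")

  merged <- quantile_normalize(merged)
  note("quantile_normalize", merged)

  pl <- attr(merged, "sample_platform")
  grp <- meta$group[match(colnames(merged$values), meta$sample_id)]
  merged <- batch_correct(merged, batch = pl, group = grp)
  note("batch_correct", merged)

  attr(merged, "stage_log") <- log_df
  merged
}

# internal: sanity-check a metadata frame against sample ids
check_meta <- function(meta, ids) {
  need <- c("sample_id", "group", "zt", "platform", "mouse_id")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(ids, meta$sample_id)
  if (length(unknown) > 0L)
    stop("samples absent from metadata: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  invisible(TRUE)
}
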