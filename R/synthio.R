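#' Configuration for the synthetic dual-platform circadian dataset
#'
#' Bundles and validates all parameters of the expression simulator. The
#' defaults emulate a dual-platform kidney profiling design: three groups
#' (young, nephritic, remission), six Zeitgeber times at 4 h spacing over
#' 24 h, two platforms (microarray intensities and RNA-seq counts) with a set
#' of paired samples at ZT0/ZT12 measured on both, rhythmic genes whose
#' amplitude is dampened in disease and partially restored in remission.
#'
#' Each rhythmic gene g has a log2 mean profile
#' `mu(g, group, t) = b_g + A_g * damp(group) * cos(2*pi*(t - phi_g)/24)`.
#' Remission interpolates linearly between the nephritic and young states:
#' `damp_rem = damp_neph + c_g * (1 - damp_neph)` with per-gene correction
#' fraction `c_g`.
#'
#' @param n_genes Number of genes.
#' @param frac_rhythmic Proportion of rhythmic genes in `[0, 1]`.
#' @param zt_grid Zeitgeber times in hours, strictly increasing in `[0, 24)`.
#' @param n_reps Replicate mice per ZT per group per platform.
#' @param baseline_mean,baseline_sd Gene baseline `b_g` distribution (log2).
#' @param amplitude_log_mean,amplitude_log_sd Rhythmic amplitude `A_g` is
#'   `2^N(amplitude_log_mean, amplitude_log_sd)` (log2 units).
#' @param damp_nephritic Amplitude damping factor of the nephritic group in
#'   `[0, 1]` (young is 1).
#' @param correction_fraction Per-gene planted correction fraction `c_g` in
#'   `[0, 1]`: a scalar (recycled), a vector of length `n_genes`, or `NULL`
#'   to draw each `c_g` from `{0, 1}` with probability 1/2.
#' @param platform_shift_sd SD of the gene-wise additive platform offsets
#'   (log2); independent offsets are drawn for the array and seq platforms.
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (`variance = mu + dispersion * mu^2`).
#' @param noise_sd_array Gaussian noise SD of array log2 intensities.
#' @param noise_sd_seq SD of the extra log2-scale lognormal noise on the
#'   expected count.
#' @param n_paired Number of paired ZT0/ZT12 mice measured on both platforms.
#' @param seed Integer seed; drives a hierarchical per-gene stream so adding
#'   genes does not reshuffle existing ones.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, frac_rhythmic = 0.2,
                       zt_grid = c(0, 4, 8, 12, 16, 20), n_reps = 3,
                       baseline_mean = 7, baseline_sd = 1.5,
                       amplitude_log_mean = 0, amplitude_log_sd = 0.25,
                       damp_nephritic = 0.3, correction_fraction = NULL,
                       platform_shift_sd = 1.0, nb_dispersion = 0.05,
                       noise_sd_array = 0.3, noise_sd_seq = 0.2,
                       n_paired = 15, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_reps < 1) stop("n_reps must be positive")
  if (frac_rhythmic < 0 || frac_rhythmic > 1)
    stop("frac_rhythmic must lie in [0, 1]")
  if (damp_nephritic < 0 || damp_nephritic > 1)
    stop("damp_nephritic must lie in [0, 1]")
  if (any(zt_grid < 0 | zt_grid >= 24)) stop("zt_grid must lie in [0, 24)")
  if (is.unsorted(zt_grid, strictly = TRUE))
    stop("zt_grid must be strictly increasing")
  if (length(zt_grid) < 3L) stop("need at least 3 Zeitgeber times")
  sds <- c(baseline_sd, amplitude_log_sd, platform_shift_sd,
           noise_sd_array, noise_sd_seq)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (!is.null(correction_fraction)) {
    if (!length(correction_fraction) %in% c(1L, n_genes))
      stop("correction_fraction must be a scalar or length n_genes")
    if (any(correction_fraction < 0 | correction_fraction > 1))
      stop("correction_fraction must lie in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes),
                 frac_rhythmic = frac_rhythmic, zt_grid = zt_grid,
                 n_reps = as.integer(n_reps), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 amplitude_log_mean = amplitude_log_mean,
                 amplitude_log_sd = amplitude_log_sd,
                 damp_nephritic = damp_nephritic,
                 correction_fraction = correction_fraction,
                 platform_shift_sd = platform_shift_sd,
                 nb_dispersion = nb_dispersion,
                 noise_sd_array = noise_sd_array,
                 noise_sd_seq = noise_sd_seq,
                 n_paired = as.integer(n_paired), seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-gene substream seed, kept inside 32-bit integer range
gene_seed <- function(seed, g, salt = 0L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(g) * 69621 +
                as.numeric(salt) * 16807) %% 2147483647)
}

# sample sheet implied by a sim_config: one row per measurement
sim_sample_sheet <- function(config) {
  groups <- c("young", "nephritic", "remission")
  rows <- list()
  for (grp in groups)
    for (pl in c("array", "seq"))
      for (zt in config$zt_grid)
        for (r in seq_len(config$n_reps)) {
          mouse <- sprintf("%s_zt%02d_%s_m%d", substr(grp, 1, 3), zt, pl, r)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste0(mouse, "_", pl), group = grp, zt = zt,
            platform = pl, mouse_id = mouse)
        }
  # paired mice at ZT0/ZT12 measured on both platforms
  if (config$n_paired > 0L) {
    for (i in seq_len(config$n_paired)) {
      grp <- groups[((i - 1L) %% 2L) + 1L]      # alternate young/nephritic
      zt <- c(0, 12)[((i - 1L) %/% 2L) %% 2L + 1L]
      if (!zt %in% config$zt_grid) zt <- config$zt_grid[1]
      mouse <- sprintf("%s_zt%02d_paired_m%d", substr(grp, 1, 3), zt, i)
      for (pl in c("array", "seq"))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(mouse, "_", pl), group = grp, zt = zt,
          platform = pl, mouse_id = mouse)
    }
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  meta
}

#' Generate a synthetic dual-platform circadian expression dataset
#'
#' Simulates microarray intensities and RNA-seq counts for the design encoded
#' in a [sim_config()], together with the planted ground truth. Array values
#' are the log2 mean profile plus a gene-wise array offset plus Gaussian
#' noise, exponentiated back to the intensity scale. Counts are drawn from a
#' negative binomial whose mean is `2^(mu + seq offset + lognormal noise)`.
#' One global seed drives a hierarchical per-gene stream, so outputs are
#' reproducible and extending `n_genes` leaves existing genes untouched.
#'
#' @param config A [sim_config()].
#' @return List with elements `array` (`expr_matrix`, `raw_intensity`),
#'   `seq` (`expr_matrix`, `raw_count`), `meta` (sample sheet:
#'   `sample_id`, `group`, `zt`, `platform`, `mouse_id`) and `truth`
#'   (per-gene data frame: `gene_id`, `is_rhythmic`, `baseline`,
#'   `amplitude`, `acrophase`, `damp_young`, `damp_nephritic`,
#'   `damp_remission`, `correction`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  meta <- sim_sample_sheet(config)
  a_idx <- which(meta$platform == "array")
  s_idx <- which(meta$platform == "seq")
  damp_of <- function(grp, damp_rem) {
    out <- numeric(length(grp))
    out[grp == "young"] <- 1
    out[grp == "nephritic"] <- config$damp_nephritic
    out[grp == "remission"] <- damp_rem
    out
  }

  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  arr <- matrix(NA_real_, config$n_genes, length(a_idx),
                dimnames = list(gene_ids, meta$sample_id[a_idx]))
  cnt <- matrix(NA_real_, config$n_genes, length(s_idx),
                dimnames = list(gene_ids, meta$sample_id[s_idx]))
  truth <- data.frame(gene_id = gene_ids, is_rhythmic = FALSE,
                      baseline = NA_real_, amplitude = 0, acrophase = 0,
                      damp_young = 1, damp_nephritic = config$damp_nephritic,
                      damp_remission = NA_real_, correction = NA_real_)

  for (g in seq_len(config$n_genes)) {
    set.seed(gene_seed(config$seed, g))
    b <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
    rhythmic <- stats::runif(1) < config$frac_rhythmic
    A <- if (rhythmic) 2^stats::rnorm(1, config$amplitude_log_mean,
                                      config$amplitude_log_sd) else 0
    phi <- stats::runif(1, 0, 24)
    cg <- if (!rhythmic) NA_real_
          else if (is.null(config$correction_fraction)) sample(c(0, 1), 1)
          else if (length(config$correction_fraction) == 1L)
            config$correction_fraction
          else config$correction_fraction[g]
    damp_rem <- if (rhythmic)
      config$damp_nephritic + cg * (1 - config$damp_nephritic) else 1
    shift_arr <- stats::rnorm(1, 0, config$platform_shift_sd)
    shift_seq <- stats::rnorm(1, 0, config$platform_shift_sd)

    mu <- function(rows, shift) {
      b + A * damp_of(meta$group[rows], damp_rem) *
        cos(2 * pi * (meta$zt[rows] - phi) / 24) + shift
    }
    mu_a <- mu(a_idx, shift_arr)
    arr[g, ] <- 2^(mu_a + stats::rnorm(length(a_idx), 0,
                                       config$noise_sd_array))
    mu_s <- mu(s_idx, shift_seq) +
      stats::rnorm(length(s_idx), 0, config$noise_sd_seq)
    cnt[g, ] <- stats::rnbinom(length(s_idx), mu = 2^mu_s,
                               size = 1 / config$nb_dispersion)

    truth$is_rhythmic[g] <- rhythmic
    truth$baseline[g] <- b
    truth$amplitude[g] <- A
    truth$acrophase[g] <- phi
    truth$damp_remission[g] <- damp_rem
    truth$correction[g] <- cg
  }

  list(array = expr_matrix(arr, scale = "raw_intensity", platform = "array"),
       seq = expr_matrix(cnt, scale = "raw_count", platform = "seq"),
       meta = meta, truth = truth)
}

#' Generate synthetic physiological time series
#'
#' Simulates per-mouse analyte measurements following group-specific cosinor
#' curves with Gaussian noise: `value = mesor + amplitude *
#' cos(2*pi*(zt - acrophase)/24) + N(0, noise_sd)`.
#'
#' @param analytes Data frame with columns `analyte`, `group`, `mesor`,
#'   `amplitude`, `acrophase`, `noise_sd` (one row per analyte x group).
#' @param n_mice Mice per group.
#' @param zt_grid Sampling times in hours.
#' @param seed Integer seed.
#' @param period Rhythm period in hours.
#' @return Data frame with columns `mouse_id`, `group`, `zt`, `analyte`,
#'   `value`.
#' @export
generate_physiology <- function(analytes, n_mice = 6,
                                zt_grid = c(0, 4, 8, 12, 16, 20),
                                seed = 1L, period = 24) {
  need <- c("analyte", "group", "mesor", "amplitude", "acrophase", "noise_sd")
  miss <- setdiff(need, names(analytes))
  if (length(miss) > 0L)
    stop("analyte table missing column(s): ", paste(miss, collapse = ", "))
  if (any(analytes$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (n_mice < 1) stop("n_mice must be positive")
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(analytes)), function(i) {
    spec <- analytes[i, ]
    grid <- expand.grid(mouse = seq_len(n_mice), zt = zt_grid)
    value <- spec$mesor + spec$amplitude *
      cos(2 * pi * (grid$zt - spec$acrophase) / period) +
      stats::rnorm(nrow(grid), 0, spec$noise_sd)
    data.frame(mouse_id = sprintf("%s_m%d", substr(spec$group, 1, 3),
                                  grid$mouse),
               group = spec$group, zt = grid$zt, analyte = spec$analyte,
               value = value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic blood-pressure traces with planted dipper classes
#'
#' Simulates longitudinal systolic/diastolic readings for mice of known
#' dipper class. Each reading is the class's phase mean (rest phase = lights
#' on, ZT0-ZT12; active phase = dark, ZT12-ZT24) plus Gaussian noise;
#' diastolic pressure is systolic minus the pulse pressure.
#'
#' @param n_per_class Mice per class.
#' @param class_means Named list mapping class name to
#'   `c(active = <mmHg>, rest = <mmHg>)` systolic means. Defaults plant a
#'   dipper, a non-dipper and a reverse-dipper class.
#' @param noise_sd Reading noise SD in mmHg.
#' @param zt_grid Reading times in hours (default every 4 h).
#' @param pulse_pressure Systolic minus diastolic, mmHg (> 0).
#' @param seed Integer seed.
#' @return Data frame of readings: `mouse_id`, `class_planted`, `zt`, `sbp`,
#'   `dbp`.
#' @export
generate_bp_traces <- function(n_per_class = 5,
                               class_means = list(
                                 dipper = c(active = 125, rest = 105),
                                 nondipper = c(active = 120, rest = 115),
                                 reverse = c(active = 110, rest = 122)),
                               noise_sd = 3,
                               zt_grid = c(0, 4, 8, 12, 16, 20),
                               pulse_pressure = 30, seed = 1L) {
  if (pulse_pressure <= 0)
    stop("pulse_pressure must be positive (systolic must exceed diastolic)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  bad <- vapply(class_means, function(m) any(m - pulse_pressure <= 0),
                logical(1))
  if (any(bad))
    stop("class mean(s) imply systolic <= diastolic: ",
         paste(names(class_means)[bad], collapse = ", "))
  set.seed(as.integer(seed))
  rows <- list()
  for (cl in names(class_means)) {
    m <- class_means[[cl]]
    for (i in seq_len(n_per_class)) {
      phase_mean <- ifelse(zt_grid >= 12, m[["active"]], m[["rest"]])
      sbp <- phase_mean + stats::rnorm(length(zt_grid), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sprintf("%s_m%d", cl, i), class_planted = cl,
        zt = zt_grid, sbp = sbp, dbp = sbp - pulse_pressure)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
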