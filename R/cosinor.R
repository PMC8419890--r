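#' Single-component cosinor fit
#'
#' Least-squares fit of `y = M + beta * cos(2*pi*t/tau) + gamma * sin(2*pi*t/tau)`
#' with known period `tau`. The rhythm parameters follow from the linearized
#' coefficients: amplitude `A = sqrt(beta^2 + gamma^2)` and acrophase
#' `phi = (tau / 2*pi) * atan2(gamma, beta) mod tau`, i.e. the time of the
#' fitted peak in hours after lights-on.
#'
#' @param t Sampling times in hours.
#' @param y Observed values.
#' @param period Rhythm period `tau` in hours (default 24).
#' @return Object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `acrophase` (hours in `[0, period)`), `period`, `beta`, `gamma`,
#'   `p_zero_amplitude`, `n`, `residual_sd`, and flags
#'   `acrophase_undefined` (amplitude numerically zero) and `perfect_fit`
#'   (zero residual).
#' @export
#' @examples
#' t <- c(0, 4, 8, 12, 16, 20)
#' fit <- fit_cosinor(t, 5 + 2 * cos(2 * pi * t / 24))
#' c(fit$mesor, fit$amplitude, fit$acrophase)
fit_cosinor <- function(t, y, period = 24) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4L) stop("cosinor fit needs at least 4 observations")
  if (period <= 0) stop("period must be positive")
  if (length(unique(round((t %% period) / period, 10))) < 3L)
    stop("design is rank deficient: need >= 3 distinct times modulo the period")

  omega <- 2 * pi / period
  X <- cbind(1, cos(omega * t), sin(omega * t))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  mesor <- unname(cf[1])
  beta <- unname(cf[2])
  gamma <- unname(cf[3])
  amplitude <- sqrt(beta^2 + gamma^2)
  undef <- amplitude < 1e-10 * (abs(mesor) + 1)
  acrophase <- if (undef) 0 else ((period / (2 * pi)) * atan2(gamma, beta)) %% period

  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  flat <- ss_tot <= 1e-20 * n * (abs(mesor) + 1)^2
  perfect <- !flat && ss_res <= 1e-12 * max(ss_tot, 1)
  p <- if (flat) {
    1
  } else if (perfect) {
    0
  } else {
    f <- ((ss_tot - ss_res) / 2) / (ss_res / (n - 3))
    stats::pf(f, 2, n - 3, lower.tail = FALSE)
  }
  structure(list(mesor = mesor, amplitude = amplitude, acrophase = acrophase,
                 period = period, beta = beta, gamma = gamma,
                 p_zero_amplitude = p, n = n,
                 residual_sd = sqrt(ss_res / max(n - 3, 1)),
                 acrophase_undefined = undef, perfect_fit = perfect),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %g h): MESOR %.4g, amplitude %.4g, acrophase %.2f h%s, p(zero amplitude) %.3g, n = %d\n",
    x$period, x$mesor, x$amplitude, x$acrophase,
    if (x$acrophase_undefined) " [undefined]" else "", x$p_zero_amplitude, x$n))
  invisible(x)
}

#' Zero-amplitude F test for a cosinor fit
#'
#' Tests `A = 0` by comparing the cosinor model to the intercept-only model:
#' `F = ((SS_total - SS_resid)/2) / (SS_resid/(n-3))` referred to
#' `F(2, n-3)`. A perfect (zero-residual) fit returns `p = 0`.
#'
#' @param t Sampling times in hours.
#' @param y Observed values.
#' @param period Rhythm period in hours.
#' @return p-value.
#' @export
zero_amplitude_test <- function(t, y, period = 24) {
  fit_cosinor(t, y, period = period)$p_zero_amplitude
}

#' Pooled cosinor fits per analyte and group
#'
#' Fits a population-mean cosinor to all observations of each
#' (analyte, group) combination in a long physiology table, pooling mice
#' within group.
#'
#' @param table Data frame with columns `group`, `zt`, `analyte`, `value`.
#' @param analyte Optional analyte name(s) to restrict to.
#' @param group Optional group name(s) to restrict to.
#' @param period Rhythm period in hours.
#' @return Data frame with one row per (analyte, group): `mesor`,
#'   `amplitude`, `acrophase`, `p_zero_amplitude`, `n`,
#'   `acrophase_undefined`.
#' @export
fit_group_cosinor <- function(table, analyte = NULL, group = NULL,
                              period = 24) {
  need <- c("group", "zt", "analyte", "value")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("physiology table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(analyte)) {
    if (!all(analyte %in% table$analyte))
      stop("analyte(s) not found: ",
           paste(setdiff(analyte, table$analyte), collapse = ", "))
    table <- table[table$analyte %in% analyte, , drop = FALSE]
  }
  if (!is.null(group)) {
    if (!all(group %in% table$group))
      stop("group(s) not found: ",
           paste(setdiff(group, table$group), collapse = ", "))
    table <- table[table$group %in% group, , drop = FALSE]
  }
  combos <- unique(table[, c("analyte", "group")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- table[table$analyte == combos$analyte[i] &
                   table$group == combos$group[i], , drop = FALSE]
    if (length(unique(sub$zt)) < 4L)
      stop("fewer than 4 distinct ZTs for ", combos$analyte[i], "/",
           combos$group[i])
    fit <- fit_cosinor(sub$zt, sub$value, period = period)
    data.frame(analyte = combos$analyte[i], group = combos$group[i],
               mesor = fit$mesor, amplitude = fit$amplitude,
               acrophase = fit$acrophase,
               p_zero_amplitude = fit$p_zero_amplitude, n = fit$n,
               acrophase_undefined = fit$acrophase_undefined)
  })
  do.call(rbind, rows)
}
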