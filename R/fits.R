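# Measurement extraction: exponential relaxation fits, half-decay times,
# Boltzmann activation-curve fits, percent changes.

#' Fit a single exponential to a relaxing trace segment
#'
#' Least-squares fit of `y(t) = A * exp(-(t - t0) / tau) + C` with `t0` the
#' first time point of the segment.  Starting values come from the plateau
#' estimate (mean of the final 5% of samples) and a log-linear regression;
#' refinement uses Levenberg-Marquardt.  This is the tail-current /
#' fluorescence-deactivation time-constant measurement.
#'
#' @param time,value Numeric vectors (>= 20 samples).
#' @param direction `"decay"` (default) requires a decaying segment,
#'   `"rise"` a rising one (used for activation kinetics), `"auto"` accepts
#'   either.  A segment whose start and end differ by less than 5x the
#'   sample-noise estimate is rejected with a "no decay" error.
#' @return An object of class `exp_fit`: list with `tau` (s), `A`, `C`,
#'   `rms`, `window`, `fitted`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' f <- fit_single_exponential(t, 5 * exp(-t / 0.3) + 1)
#' f$tau
fit_single_exponential <- function(time, value,
                                   direction = c("decay", "rise", "auto")) {
  direction <- match.arg(direction)
  if (length(time) != length(value))
    stop("'time' and 'value' must have equal length", call. = FALSE)
  if (length(time) < 20L)
    stop("need at least 20 samples to fit", call. = FALSE)
  # robust sample-noise estimate from first differences, and a span estimate
  # from averaged leading/trailing levels so the decay test is about the
  # relaxation, not about two individual noisy samples
  noise <- stats::sd(diff(value)) / sqrt(2)
  n <- length(value)
  n1 <- max(3L, ceiling(0.01 * n))
  n2 <- max(3L, ceiling(0.05 * n))
  lead <- mean(value[seq_len(n1)])
  plateau_est <- mean(value[(n - n2 + 1L):n])
  span <- lead - plateau_est
  if (abs(span) <= 5 * noise * sqrt(1 / n1 + 1 / n2))
    stop("no decay: segment start and end are indistinguishable from noise",
         call. = FALSE)
  if (direction == "decay" && span <= 0)
    stop("no decay: segment rises; use direction = 'rise' for activation fits",
         call. = FALSE)
  if (direction == "rise" && span >= 0)
    stop("segment decays; use direction = 'decay'", call. = FALSE)

  t0 <- time[1L]
  tt <- time - t0
  C0 <- mean(value[tt >= stats::quantile(tt, 0.95)])
  A0 <- value[1L] - C0
  # log-linear tau start on the well-resolved part of the relaxation
  z <- (value - C0) / A0
  ok <- which(z > 0.1)
  tau0 <- if (length(ok) > 5L) {
    fitl <- stats::lm.fit(cbind(1, tt[ok]), log(z[ok]))
    sl <- fitl$coefficients[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else max(tt) / 3
  } else max(tt) / 3
  rng_t <- diff(range(tt))
  tau0 <- min(max(tau0, rng_t / 1e4), 100 * rng_t)

  # Levenberg-Marquardt on the residual function; a few tau starts, keep the
  # lowest SSE (near-exact data converge to machine-level residuals)
  resid_fun <- function(par) value - (par[1] + par[2] * exp(-tt / par[3]))
  fit <- NULL
  for (tau_start in unique(c(tau0, rng_t / 3, rng_t / 10, rng_t / 30))) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = c(C0, A0, tau_start), fn = resid_fun,
                         lower = c(-Inf, -Inf, rng_t / 1e6),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(cand) && all(is.finite(cand$par)) &&
        (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  if (is.null(fit))
    stop("exponential fit did not converge from any starting point",
         call. = FALSE)
  cf <- fit$par
  res <- resid_fun(cf)
  out <- list(tau = cf[3], A = cf[2], C = cf[1], rms = sqrt(mean(res^2)),
              window = c(time[1L], time[n]), fitted = value - res,
              iterations = fit$niter)
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("single-exponential fit: tau = %.6g s, A = %.4g, C = %.4g, RMS = %.3g\n",
              x$tau, x$A, x$C, x$rms))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau = object$tau, A = object$A, C = object$C)
}

#' @export
predict.exp_fit <- function(object, time, ...) {
  object$C + object$A * exp(-(time - object$window[1L]) / object$tau)
}

#' Half-decay time of a tail segment
#'
#' Time from segment start at which the signal first crosses halfway between
#' its initial value and its plateau (mean of the final 5% of samples), with
#' linear interpolation between samples.  Offset-invariant; used where a
#' single-exponential fit is not applicable.
#'
#' @param time,value Numeric vectors describing a decaying segment.
#' @return Half-decay time in seconds (relative to segment start).
#' @export
half_decay_time <- function(time, value) {
  if (length(time) != length(value) || length(time) < 10L)
    stop("need matching time/value vectors with >= 10 samples", call. = FALSE)
  plateau <- mean(value[time >= stats::quantile(time, 0.95)])
  start <- value[1L]
  if (start <= plateau)
    stop("segment does not decay toward a lower plateau", call. = FALSE)
  target <- (start + plateau) / 2
  below <- which(value <= target)
  below <- below[below > 1L]
  if (!length(below))
    stop("signal never crosses its half-decay level", call. = FALSE)
  i <- below[1L]
  frac <- (value[i - 1L] - target) / (value[i - 1L] - value[i])
  (time[i - 1L] + frac * (time[i] - time[i - 1L])) - time[1L]
}

#' Fit a Boltzmann activation curve
#'
#' Least-squares fit of
#' `y(V) = min + (max - min) / (1 + exp(-(V - V_half) / k))` with all four
#' parameters free (the minimum is not pinned to zero because simulated F(V)
#' has a nonzero floor).  Fits whose span is negative (decreasing data) or
#' whose slope factor is pinned at its bound are flagged rather than failed.
#'
#' @param V Test voltages (mV), >= 5 points spanning the transition.
#' @param y Responses (normalized conductance or fluorescence).
#' @return An object of class `boltzmann_fit`: `V_half` (mV), `k` (mV),
#'   `ymax`, `ymin`, `rms`, `flagged`, `reason`.
#' @export
#' @examples
#' V <- seq(-140, 80, by = 20)
#' y <- 1 / (1 + exp(-(V + 20) / 12))
#' fit_boltzmann(V, y)$V_half
fit_boltzmann <- function(V, y) {
  if (length(V) != length(y) || length(V) < 5L)
    stop("need >= 5 (V, y) points", call. = FALSE)
  ord <- order(V)
  V <- V[ord]; y <- y[ord]
  rng <- range(y)
  increasing <- stats::cor(V, y) >= 0
  k_lo <- 1e-3
  # Levenberg-Marquardt on the residual function over a small grid of
  # starting points (midpoint x slope scale x orientation); lowest SSE wins
  resid_fun <- function(par)
    y - (par[1] + (par[2] - par[1]) / (1 + exp(-(V - par[3]) / par[4])))
  vh_grid <- unname(stats::quantile(V, c(0.3, 0.5, 0.7)))
  fit <- NULL
  for (vh0 in vh_grid) for (k0 in c(8, 25)) for (up in c(increasing,
                                                         !increasing)) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = c(if (up) rng[1] else rng[2], if (up) rng[2] else rng[1],
                vh0, k0),
        fn = resid_fun,
        lower = c(-Inf, -Inf, min(V) - 200, k_lo),
        upper = c(Inf, Inf, max(V) + 200, 500),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(cand) && all(is.finite(cand$par)) &&
        (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  if (is.null(fit))
    stop("Boltzmann fit did not converge from any starting point",
         call. = FALSE)
  cf <- fit$par
  flagged <- FALSE; reason <- ""
  if (cf[2] < cf[1]) {
    flagged <- TRUE; reason <- "negative span (decreasing data)"
  } else if (cf[4] <= 2 * k_lo || cf[4] >= 499) {
    flagged <- TRUE; reason <- "slope factor pinned at bound"
  }
  out <- list(V_half = cf[3], k = cf[4], ymax = cf[2], ymin = cf[1],
              rms = sqrt(mean(resid_fun(cf)^2)),
              flagged = flagged, reason = reason)
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.4g mV, k = %.4g mV, range [%.4g, %.4g]%s\n",
              x$V_half, x$k, x$ymin, x$ymax,
              if (x$flagged) paste0("  [flagged: ", x$reason, "]") else ""))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(V_half = object$V_half, k = object$k,
    ymax = object$ymax, ymin = object$ymin)
}

#' @export
predict.boltzmann_fit <- function(object, V, ...) {
  object$ymin + (object$ymax - object$ymin) /
    (1 + exp(-(V - object$V_half) / object$k))
}

#' Percent change between paired control and drug measurements
#'
#' `100 * (drug - control) / control`, the convention used for all drug-effect
#' statistics (amplitudes, time constants).
#'
#' @param control,drug Numeric (vectorized); `control` must be nonzero.
#' @return Percent change(s).
#' @export
#' @examples
#' percent_change(1, 4.63)  # +363
percent_change <- function(control, drug) {
  if (any(control == 0)) stop("control value is zero", call. = FALSE)
  100 * (drug - control) / control
}
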