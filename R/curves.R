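# Isochronal G(V) / F(V) activation curves.

# Index of the last sample lying inside segment k of a trace's protocol
# (the isochronal measurement point: one sample before the boundary, since
# the boundary sample already carries the next segment's voltage).
iso_index <- function(trace, k) {
  pr <- attr(trace, "protocol")
  t_end <- segment_start(pr, k) + pr$segments$duration_s[k]
  which.min(abs(trace$time_s - (t_end - pr$dt_s)))
}

#' Isochronal conductance- and fluorescence-voltage curves
#'
#' Runs the activation-family protocols, measures current and fluorescence at
#' the final sample of each 2 s test pulse (isochronal, no driving-force
#' correction), normalizes each curve to its maximum over the family, and
#' fits a Boltzmann function to both.
#'
#' @param params A `kcnq_params` object.
#' @param family List of protocols from [activation_family()].
#' @param perturbation Optional [drug_perturbation()].
#' @return A list of class `gv_fv_curves`: data frames `g` and `f` with
#'   columns `V` and `value`, plus `g_fit` and `f_fit` ([fit_boltzmann()]
#'   results).
#' @export
#' @examples
#' cv <- gv_fv_curves(default_params(), activation_family(dt_s = 5e-3))
#' cv$g_fit$V_half - cv$f_fit$V_half  # F(V) lies left of G(V)
gv_fv_curves <- function(params, family = activation_family(),
                         perturbation = NULL) {
  V <- vapply(family, function(pr) pr$segments$voltage_mV[2L], 0)
  g <- f <- numeric(length(family))
  for (i in seq_along(family)) {
    tr <- simulate_trace(params, family[[i]], perturbation = perturbation,
                         fluor = "raw", keep_states = FALSE)
    idx <- iso_index(tr, 2L)
    g[i] <- tr$current[idx]
    f[i] <- tr$fluorescence[idx]
  }
  g <- g / max(g)
  f <- f / max(f)
  out <- list(g = data.frame(V = V, value = g),
              f = data.frame(V = V, value = f),
              g_fit = fit_boltzmann(V, g),
              f_fit = fit_boltzmann(V, f))
  class(out) <- "gv_fv_curves"
  out
}

#' @export
print.gv_fv_curves <- function(x, ...) {
  cat(sprintf("G(V): V1/2 = %.4g mV, k = %.4g mV\n",
              x$g_fit$V_half, x$g_fit$k))
  cat(sprintf("F(V): V1/2 = %.4g mV, k = %.4g mV\n",
              x$f_fit$V_half, x$f_fit$k))
  invisible(x)
}

#' @export
plot.gv_fv_curves <- function(x, ...) {
  vv <- seq(min(x$g$V), max(x$g$V), length.out = 200)
  graphics::plot(x$g$V, x$g$value, pch = 16, xlab = "V (mV)",
                 ylab = "normalized response", ylim = range(x$g$value, x$f$value),
                 ...)
  graphics::points(x$f$V, x$f$value, pch = 1)
  graphics::lines(vv, predict(x$g_fit, vv))
  graphics::lines(vv, predict(x$f_fit, vv), lty = 2)
  graphics::legend("topleft", c("G(V)", "F(V)"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
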