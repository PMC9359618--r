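# Piecewise-constant command-voltage protocols.

#' Define a voltage protocol
#'
#' A protocol is a holding voltage (used to pre-equilibrate the model) plus an
#' ordered list of piecewise-constant segments, sampled on a uniform grid.
#' Segment durations must be integer multiples of the sample interval.
#'
#' @param segments Data frame (or list coercible to one) with columns
#'   `duration_s` (> 0) and `voltage_mV`.
#' @param hold_mV Holding voltage (mV); the simulation starts from the
#'   steady state at this voltage.
#' @param dt_s Sample interval (s); must be smaller than the shortest segment.
#' @param name Optional protocol name.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(segments, hold_mV = -80, dt_s = 1e-3,
                             name = "custom") {
  segments <- as.data.frame(segments)
  if (!all(c("duration_s", "voltage_mV") %in% names(segments)))
    stop("'segments' needs columns duration_s and voltage_mV", call. = FALSE)
  if (nrow(segments) < 1L) stop("need at least one segment", call. = FALSE)
  if (any(!is.finite(segments$duration_s)) || any(segments$duration_s <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (any(!is.finite(segments$voltage_mV)))
    stop("segment voltages must be finite", call. = FALSE)
  if (!is.finite(dt_s) || dt_s <= 0 || dt_s >= min(segments$duration_s))
    stop("'dt_s' must be positive and smaller than the shortest segment",
         call. = FALSE)
  n_steps <- segments$duration_s / dt_s
  if (any(abs(n_steps - round(n_steps)) > 1e-6))
    stop("segment durations must be integer multiples of dt_s", call. = FALSE)
  out <- list(name = name, hold_mV = hold_mV, dt_s = dt_s,
              segments = segments[, c("duration_s", "voltage_mV")])
  class(out) <- "voltage_protocol"
  out
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("voltage protocol '%s': hold %g mV, dt = %g ms\n",
              x$name, x$hold_mV, 1000 * x$dt_s))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  segment %d: %g mV for %g s\n", i,
                x$segments$voltage_mV[i], x$segments$duration_s[i]))
  invisible(x)
}

#' Standard two-pulse deactivation protocol
#'
#' Hold at -80 mV, record a short baseline at the holding voltage, depolarize
#' to +20 mV for 2 s, then repolarize to -120 mV for 2 s to elicit the tail.
#' This is the protocol used for all deactivation time-constant measurements.
#'
#' @param pre_s Duration of the recorded baseline segment at the holding
#'   voltage (s).  It provides the noise estimate used to weight fitting.
#' @param dt_s Sample interval (s).
#' @return A `voltage_protocol` with segments (-80, +20, -120) mV.
#' @export
two_pulse_protocol <- function(pre_s = 0.2, dt_s = 1e-3) {
  voltage_protocol(
    data.frame(duration_s = c(pre_s, 2, 2), voltage_mV = c(-80, 20, -120)),
    hold_mV = -80, dt_s = dt_s, name = "two_pulse"
  )
}

#' Activation-curve protocol family
#'
#' Twelve protocols stepping from -140 to +80 mV in 20-mV increments for 2 s,
#' each followed by a 2 s tail pulse at -120 mV, from a -80 mV hold.  Used to
#' construct isochronal G(V) and F(V) curves.
#'
#' @param v_test Test voltages (mV).
#' @param pre_s,dt_s As in [two_pulse_protocol()].
#' @return A list of `voltage_protocol` objects, one per test voltage.
#' @export
activation_family <- function(v_test = seq(-140, 80, by = 20),
                              pre_s = 0.2, dt_s = 1e-3) {
  lapply(v_test, function(v) {
    voltage_protocol(
      data.frame(duration_s = c(pre_s, 2, 2), voltage_mV = c(-80, v, -120)),
      hold_mV = -80, dt_s = dt_s, name = sprintf("act_%+d_mV", as.integer(v))
    )
  })
}

# start time of segment k (0-based from first recorded sample)
segment_start <- function(protocol, k) {
  if (k == 1L) 0 else sum(protocol$segments$duration_s[seq_len(k - 1L)])
}
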