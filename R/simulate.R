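# Deterministic simulation of voltage-clamp-fluorometry observables.

# Matrix exponential of a small dense generator.
mat_exp <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE)))
}

# Propagate occupancies through piecewise-constant generators.
# Q_list[[k]] acts over durations[k]; samples every dt starting at t = 0
# (which carries p0).  Exact per step: p_{n+1} = p_n %*% expm(Q dt).
propagate_piecewise <- function(Q_list, durations, p0, dt) {
  n_steps <- round(durations / dt)
  if (any(abs(n_steps * dt - durations) > 1e-9 * pmax(durations, dt)))
    stop("segment durations must be integer multiples of dt", call. = FALSE)
  n_tot <- sum(n_steps) + 1L
  occ <- matrix(NA_real_, n_tot, length(p0))
  occ[1L, ] <- p0
  row <- 1L
  p <- p0
  for (k in seq_along(Q_list)) {
    P <- mat_exp(Q_list[[k]] * dt)
    for (s in seq_len(n_steps[k])) {
      p <- as.numeric(p %*% P)
      row <- row + 1L
      occ[row, ] <- p
    }
  }
  drift <- max(abs(rowSums(occ) - 1))
  if (drift > 1e-6)
    stop(sprintf("internal error: occupancy drift %.3g exceeds 1e-6", drift),
         call. = FALSE)
  list(time = seq(0, by = dt, length.out = n_tot), occ = occ, drift = drift)
}

#' Simulate a voltage-clamp-fluorometry recording
#'
#' Propagates the master equation of the 12-state model through a
#' piecewise-constant voltage protocol by exact matrix-exponential stepping,
#' starting from the steady state at the holding voltage, and derives the two
#' experimental observables: macroscopic current
#' `I(t) = Gmax * P_open(t) * (V(t) - E_K)` and the fluorescence signal
#' reporting voltage-sensor displacement (see [fluor_weights()]).
#'
#' Command voltage is right-continuous: the sample at a segment boundary
#' carries the new segment's voltage (occupancies are continuous).
#'
#' @param params A `kcnq_params` object.
#' @param protocol A `voltage_protocol`.
#' @param perturbation Optional [drug_perturbation()] applied to `params`
#'   before simulating; `NULL` and the identity perturbation give bit-identical
#'   results.
#' @param fluor `"normalized"` (min-max over this trace, the usual dF/F
#'   display convention) or `"raw"` (unnormalized weighted occupancy).  For
#'   paired control/drug display pass the control trace's scale via
#'   `fluor_scale` so drug-induced amplitude changes remain visible.
#' @param fluor_scale Optional `c(min, max)` used instead of this trace's own
#'   range when `fluor = "normalized"`.
#' @param keep_states If `TRUE` (default) the 12 occupancy series are kept as
#'   columns `p_C0 .. p_OA`.
#' @return A data frame of class `kcnq_trace` with columns `time_s`,
#'   `voltage_mV`, `current`, `fluorescence` (and occupancies), plus
#'   attributes `protocol`, `fluor_scale` and `drift`.
#' @export
#' @examples
#' tr <- simulate_trace(default_params(), two_pulse_protocol(dt_s = 5e-3))
#' range(tr$current)
simulate_trace <- function(params, protocol, perturbation = NULL,
                           fluor = c("normalized", "raw"),
                           fluor_scale = NULL, keep_states = TRUE) {
  fluor <- match.arg(fluor)
  if (!inherits(protocol, "voltage_protocol"))
    stop("'protocol' must be a voltage_protocol", call. = FALSE)
  if (!is.null(perturbation))
    params <- apply_perturbation(params, perturbation)
  validate_params(params)

  volts <- protocol$segments$voltage_mV
  durs <- protocol$segments$duration_s
  Q_list <- lapply(volts, function(v) build_rate_matrix(params, v))
  p0 <- steady_state(build_rate_matrix(params, protocol$hold_mV))
  prop <- propagate_piecewise(Q_list, durs, p0, protocol$dt_s)

  # right-continuous command voltage per sample
  n_steps <- round(durs / protocol$dt_s)
  v_t <- c(rep(volts, times = n_steps), volts[length(volts)])
  v_t <- c(volts[1L], v_t)[seq_along(prop$time)]
  # sample at a boundary belongs to the segment that starts there
  bounds <- cumsum(n_steps)
  if (length(bounds) > 1L)
    for (k in seq_len(length(bounds) - 1L)) v_t[bounds[k] + 1L] <- volts[k + 1L]

  p_open <- rowSums(prop$occ[, c(.iO, .iOA), drop = FALSE])
  current <- params$Gmax * p_open * (v_t - params$E_K)
  f_raw <- as.numeric(prop$occ %*% fluor_weights(params))
  if (fluor == "normalized") {
    sc <- if (is.null(fluor_scale)) range(f_raw) else fluor_scale
    if (diff(sc) <= 0) sc <- c(0, 1)
    f_out <- (f_raw - sc[1]) / (sc[2] - sc[1])
  } else {
    sc <- NULL
    f_out <- f_raw
  }

  out <- data.frame(time_s = prop$time, voltage_mV = v_t,
                    current = current, fluorescence = f_out)
  if (keep_states) {
    occ <- as.data.frame(prop$occ)
    names(occ) <- paste0("p_", state_names())
    out <- cbind(out, occ)
  }
  attr(out, "protocol") <- protocol
  attr(out, "fluor_scale") <- if (fluor == "normalized") sc else NULL
  attr(out, "fluor_raw_range") <- range(f_raw)
  attr(out, "drift") <- prop$drift
  class(out) <- c("kcnq_trace", "data.frame")
  out
}

#' @export
print.kcnq_trace <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat(sprintf("kcnq_trace: %d samples, %.3g s%s\n", nrow(x),
              max(x$time_s),
              if (!is.null(pr)) sprintf(", protocol '%s'", pr$name) else ""))
  cat(sprintf("  current range [%.4g, %.4g], fluorescence range [%.4g, %.4g]\n",
              min(x$current), max(x$current),
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' @export
plot.kcnq_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_s, x$voltage_mV, type = "s", xlab = "",
                 ylab = "V (mV)", ...)
  graphics::plot(x$time_s, x$current, type = "l", xlab = "",
                 ylab = "current (a.u.)", ...)
  graphics::plot(x$time_s, x$fluorescence, type = "l", xlab = "time (s)",
                 ylab = "fluorescence", ...)
  invisible(x)
}

#' Extract a time window from a trace
#'
#' @param trace A `kcnq_trace` (or any data frame with `time_s`).
#' @param from,to Window bounds in seconds (inclusive).
#' @return The subset of rows with `from <= time_s <= to`.
#' @export
trace_segment <- function(trace, from, to) {
  sel <- trace$time_s >= from - 1e-12 & trace$time_s <= to + 1e-12
  if (!any(sel)) stop("empty trace window", call. = FALSE)
  trace[sel, , drop = FALSE]
}

#' Write / read trace files
#'
#' Tab-delimited text with a header row; columns `time_s`, `voltage_mV`,
#' `current`, `fluorescence` and optionally the 12 occupancy columns, in that
#' fixed order.  Values carry 12 significant digits, so write/read round
#' trips are stable.
#'
#' @param trace A `kcnq_trace` or compatible data frame.
#' @param path File path.
#' @param states Include occupancy columns if present.
#' @export
write_trace <- function(trace, path, states = FALSE) {
  cols <- c("time_s", "voltage_mV", "current", "fluorescence")
  if (states) cols <- c(cols, intersect(paste0("p_", state_names()),
                                        names(trace)))
  df <- as.data.frame(trace)[, cols, drop = FALSE]
  txt <- vapply(df, function(col) sprintf("%.12g", col), character(nrow(df)))
  if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1L)
  con <- file(path, "wb")  # binary mode: fixed "\n" on every platform
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"),
               apply(txt, 1L, paste, collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("time_s", "voltage_mV", "current", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(df) <- c("kcnq_trace", "data.frame")
  df
}
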