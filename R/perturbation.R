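# Drug perturbations: multiplicative scalings of rate classes, their
# calibration, and the six-metric drug-effect summary.

#' Define a drug perturbation
#'
#' A named set of multiplicative scalings of rate classes and conductance:
#' `s_pore_open` on the base pore opening rate `ko0`, `s_pore_close` on the
#' closing rate `kc0`, `s_vsd_deact` on the backward rate `beta0` of the main
#' (independent resting <-> intermediate) voltage-sensor transition — applied
#' consistently in both tiers through the detailed-balance split — and
#' `s_conductance` on `Gmax`.  The identity perturbation has all factors 1.
#'
#' @param name Perturbation name.
#' @param s_pore_open,s_pore_close,s_vsd_deact,s_conductance Non-negative
#'   finite multipliers.
#' @return An object of class `drug_perturbation`.
#' @export
drug_perturbation <- function(name = "custom", s_pore_open = 1,
                              s_pore_close = 1, s_vsd_deact = 1,
                              s_conductance = 1) {
  s <- c(s_pore_open = s_pore_open, s_pore_close = s_pore_close,
         s_vsd_deact = s_vsd_deact, s_conductance = s_conductance)
  if (any(!is.finite(s)) || any(s < 0))
    stop("perturbation multipliers must be finite and >= 0", call. = FALSE)
  out <- c(list(name = name), as.list(s))
  class(out) <- "drug_perturbation"
  out
}

#' @export
print.drug_perturbation <- function(x, ...) {
  cat(sprintf(
    "perturbation '%s': pore open x%.4g, pore close x%.4g, VSD deact x%.4g, conductance x%.4g\n",
    x$name, x$s_pore_open, x$s_pore_close, x$s_vsd_deact, x$s_conductance))
  invisible(x)
}

#' The identity (no-drug) perturbation
#' @return A `drug_perturbation` with all multipliers 1.
#' @export
identity_perturbation <- function() drug_perturbation("identity")

is_identity <- function(p) {
  all(abs(c(p$s_pore_open, p$s_pore_close, p$s_vsd_deact,
            p$s_conductance) - 1) == 0)
}

#' R-L3 perturbation preset (voltage-sensor mechanism)
#'
#' Slows the backward rate of the main voltage-sensor transition by 240%
#' (rate scaled by 1/3.4, i.e. its time constant increased 240%) and scales
#' conductance by 1.24 (+24% amplitude).
#'
#' @param s_vsd_deact,s_conductance Override the preset factors.
#' @return A `drug_perturbation`.
#' @export
rl3_perturbation <- function(s_vsd_deact = 1 / 3.4, s_conductance = 1.24) {
  drug_perturbation("RL3", s_vsd_deact = s_vsd_deact,
                    s_conductance = s_conductance)
}

#' ML277 perturbation preset (pore mechanism)
#'
#' Slows pore opening and closing by one common factor `f_pore` (no
#' asymmetry), with an optional conductance increase.  If `f_pore` is not
#' supplied it is calibrated with [calibrate_pore_slowing()] so the current
#' deactivation time constant increases by `target_dtau_pct`.
#'
#' @param params Baseline parameters (used only when calibrating).
#' @param f_pore Common slowing factor (> 0); multipliers are `1 / f_pore`.
#' @param s_conductance Conductance multiplier.
#' @param target_dtau_pct Calibration target for the percent increase of the
#'   current tail time constant.
#' @param dt_s Sample interval used during calibration.
#' @return A `drug_perturbation`.
#' @export
ml277_perturbation <- function(params = default_params(), f_pore = NULL,
                               s_conductance = 1.95, target_dtau_pct = 363,
                               dt_s = 1e-3) {
  if (is.null(f_pore))
    f_pore <- calibrate_pore_slowing(params, target_dtau_pct, dt_s = dt_s)
  drug_perturbation("ML277", s_pore_open = 1 / f_pore,
                    s_pore_close = 1 / f_pore,
                    s_conductance = s_conductance)
}

#' Apply a perturbation to a parameter set
#'
#' Returns a copy of `params` with `ko0`, `kc0`, `beta0` and `Gmax` scaled by
#' the perturbation's multipliers.  Because the scalings act on base rates,
#' microscopic reversibility of every cycle is preserved
#' ([thermodynamic_consistency()] still passes).
#'
#' @param params A `kcnq_params` object.
#' @param perturbation A `drug_perturbation`.
#' @return A `kcnq_params` object.
#' @export
apply_perturbation <- function(params, perturbation) {
  if (!inherits(perturbation, "drug_perturbation"))
    stop("'perturbation' must be a drug_perturbation", call. = FALSE)
  if (is_identity(perturbation)) return(params)
  q <- params
  q$ko0 <- q$ko0 * perturbation$s_pore_open
  q$kc0 <- q$kc0 * perturbation$s_pore_close
  q$beta0 <- q$beta0 * perturbation$s_vsd_deact
  q$Gmax <- q$Gmax * perturbation$s_conductance
  validate_params(q)
  q
}

# --- tail / activation fits on a three-segment protocol trace -------------

# skip after a voltage step before fitting, to jump over the instantaneous
# ohmic transient (s)
TAIL_SKIP_S <- 0.010

# fit the relaxation of `channel` during segment k of a pre/test/tail trace;
# "auto" because the signed tail current is inward (V < E_K) and relaxes
# upward toward zero while its magnitude decays
segment_relaxation_fit <- function(trace, k, channel,
                                   direction = "auto") {
  pr <- attr(trace, "protocol")
  t0 <- segment_start(pr, k)
  t1 <- t0 + pr$segments$duration_s[k]
  seg <- trace_segment(trace, t0 + TAIL_SKIP_S, t1)
  fit_single_exponential(seg$time_s, seg[[channel]], direction = direction)
}

#' Summarize the effect of a perturbation on the model's observables
#'
#' Simulates the two-pulse protocol and the activation family for control and
#' perturbed parameters and extracts the six drug-effect metrics reported for
#' KCNQ1 activators: percent change in end-pulse current at +20 mV
#' (`dI_pct`), in the current (`dtau_I_pct`) and fluorescence
#' (`dtau_F_pct`) deactivation time constants at -120 mV
#' (single-exponential tail fits starting 10 ms after repolarization), in
#' the fluorescence activation time constant at +20 mV (`dtau_Fact_pct`),
#' and the shifts of the G(V) and F(V) Boltzmann midpoints (`dV_G`, `dV_F`,
#' mV, drug minus control).
#'
#' @param params Baseline `kcnq_params`.
#' @param perturbation A `drug_perturbation`.
#' @param dt_s Sample interval (s).
#' @param family Optional pre-built activation family (protocols).
#' @return An object of class `drug_effect_summary` containing the six
#'   metrics, the underlying control/drug values, and the perturbation.
#' @export
#' @examples
#' \donttest{
#' drug_effect_summary(default_params(), rl3_perturbation(), dt_s = 2e-3)
#' }
drug_effect_summary <- function(params, perturbation, dt_s = 1e-3,
                                family = NULL) {
  proto <- two_pulse_protocol(dt_s = dt_s)
  if (is.null(family)) family <- activation_family(dt_s = dt_s)

  ctrl <- simulate_trace(params, proto, fluor = "raw")
  drug <- simulate_trace(params, proto, perturbation = perturbation,
                         fluor = "raw")
  iso <- iso_index(ctrl, 2L)

  m_ctrl <- list(
    I_end = ctrl$current[iso],
    tau_I = segment_relaxation_fit(ctrl, 3L, "current")$tau,
    tau_F = segment_relaxation_fit(ctrl, 3L, "fluorescence")$tau,
    tau_Fact = segment_relaxation_fit(ctrl, 2L, "fluorescence",
                                      direction = "rise")$tau)
  m_drug <- list(
    I_end = drug$current[iso],
    tau_I = segment_relaxation_fit(drug, 3L, "current")$tau,
    tau_F = segment_relaxation_fit(drug, 3L, "fluorescence")$tau,
    tau_Fact = segment_relaxation_fit(drug, 2L, "fluorescence",
                                      direction = "rise")$tau)

  cv_ctrl <- gv_fv_curves(params, family)
  cv_drug <- gv_fv_curves(params, family, perturbation = perturbation)

  out <- list(
    dI_pct = percent_change(m_ctrl$I_end, m_drug$I_end),
    dtau_I_pct = percent_change(m_ctrl$tau_I, m_drug$tau_I),
    dtau_F_pct = percent_change(m_ctrl$tau_F, m_drug$tau_F),
    dtau_Fact_pct = percent_change(m_ctrl$tau_Fact, m_drug$tau_Fact),
    dV_G = cv_drug$g_fit$V_half - cv_ctrl$g_fit$V_half,
    dV_F = cv_drug$f_fit$V_half - cv_ctrl$f_fit$V_half,
    control = m_ctrl, drug = m_drug,
    control_curves = cv_ctrl, drug_curves = cv_drug,
    perturbation = perturbation)
  class(out) <- "drug_effect_summary"
  out
}

#' @export
print.drug_effect_summary <- function(x, ...) {
  cat(sprintf("drug effect summary ('%s')\n", x$perturbation$name))
  cat(sprintf("  dI        = %+7.1f %%   (end-pulse current, +20 mV)\n", x$dI_pct))
  cat(sprintf("  dtau_I    = %+7.1f %%   (current tail tau, -120 mV: %.4g -> %.4g s)\n",
              x$dtau_I_pct, x$control$tau_I, x$drug$tau_I))
  cat(sprintf("  dtau_F    = %+7.1f %%   (fluorescence tail tau: %.4g -> %.4g s)\n",
              x$dtau_F_pct, x$control$tau_F, x$drug$tau_F))
  cat(sprintf("  dtau_Fact = %+7.1f %%   (fluorescence activation tau, +20 mV)\n",
              x$dtau_Fact_pct))
  cat(sprintf("  dV1/2(G)  = %+7.2f mV,  dV1/2(F) = %+7.2f mV\n", x$dV_G, x$dV_F))
  invisible(x)
}

# percent change of the current tail tau for a common pore slowing factor f
.dtau_I_for_f <- function(params, f, proto, tau_ctrl) {
  pert <- drug_perturbation("pore_slow", s_pore_open = 1 / f,
                            s_pore_close = 1 / f)
  tr <- simulate_trace(params, proto, perturbation = pert, fluor = "raw",
                       keep_states = FALSE)
  percent_change(tau_ctrl, segment_relaxation_fit(tr, 3L, "current")$tau)
}

#' Calibrate a common pore-slowing factor to a tail-slowing target
#'
#' Finds the factor `f_pore` such that scaling both pore opening and closing
#' rates by `1 / f_pore` increases the current deactivation time constant at
#' -120 mV (two-pulse protocol, single-exponential tail fit) by
#' `target_pct` percent.  The map `f_pore -> dtau_I` is monotone; the root is
#' bracketed on `[1, 1000]` and refined by bisection in `log(f)`.
#'
#' @param params Baseline `kcnq_params`.
#' @param target_pct Target percent increase (> -100).
#' @param tol Relative tolerance on the achieved percent change (default
#'   0.5%).
#' @param f_range Search interval for `f_pore`.
#' @param dt_s Sample interval (s).
#' @return The calibrated scalar `f_pore`.
#' @export
calibrate_pore_slowing <- function(params, target_pct, tol = 5e-3,
                                   f_range = c(1, 1000), dt_s = 1e-3) {
  if (!is.finite(target_pct) || target_pct <= -100)
    stop("'target_pct' must be a finite percent > -100", call. = FALSE)
  proto <- two_pulse_protocol(dt_s = dt_s)
  ctrl <- simulate_trace(params, proto, fluor = "raw", keep_states = FALSE)
  tau_ctrl <- segment_relaxation_fit(ctrl, 3L, "current")$tau
  g <- function(f) .dtau_I_for_f(params, f, proto, tau_ctrl) - target_pct
  if (abs(target_pct) < 1e-9) return(1)
  lo <- f_range[1]; hi <- f_range[2]
  g_lo <- g(lo)
  if (abs(g_lo + target_pct - target_pct) < .Machine$double.eps) g_lo <- -target_pct
  if (g_lo > 0 && target_pct > 0)
    stop("target already exceeded at f_pore = ", lo, call. = FALSE)
  g_hi <- g(hi)
  if (g_hi < 0)
    stop("target percent change unreachable within f_pore <= ", hi,
         call. = FALSE)
  # bisection on log f
  for (iter in 1:60) {
    mid <- exp((log(lo) + log(hi)) / 2)
    g_mid <- g(mid)
    if (abs(g_mid) <= tol * abs(target_pct)) return(mid)
    if (g_mid > 0) hi <- mid else lo <- mid
    if (log(hi / lo) < 1e-10) break
  }
  exp((log(lo) + log(hi)) / 2)
}
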