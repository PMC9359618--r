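# Model parameters for the 12-state allosteric gating scheme.

#' Names of the numeric fields of a parameter set, in canonical order
#' @keywords internal
param_fields <- c(
  "alpha0", "z_alpha", "beta0", "z_beta",
  "theta0", "z_theta", "eta0", "z_eta",
  "ko0", "kc0", "L", "D", "x_split",
  "Gmax", "E_K", "w_I", "w_A", "VT"
)

#' Construct a parameter set for the 12-state KCNQ1 gating model
#'
#' The scheme has four identical voltage-sensing domains (VSDs), each moving
#' resting -> intermediate with voltage-dependent rates `alpha(V)` /
#' `beta(V)`, followed by a concerted transition of all four VSDs to the
#' activated configuration with rates `theta(V)` / `eta(V)`.  The pore opens
#' from every VSD configuration; each VSD in the intermediate state multiplies
#' the opening rate by the allosteric factor `L`, and the concerted-activated
#' configuration contributes a further factor `D`.  Rates follow single-barrier
#' voltage dependence, e.g. `alpha(V) = alpha0 * exp(z_alpha * V / VT)` and
#' `beta(V) = beta0 * exp(-z_beta * V / VT)`.
#'
#' Within the open tier the allosteric bias is split between speeding VSD
#' forward rates (factor `L^x_split`) and slowing VSD backward rates (factor
#' `L^(x_split - 1)`), which enforces microscopic reversibility for any
#' `x_split` in \[0, 1\]; the concerted step is treated analogously with `D`.
#'
#' @param alpha0,z_alpha Base rate (1/s) and effective charge of the forward
#'   independent VSD step (resting -> intermediate).
#' @param beta0,z_beta Base rate (1/s) and effective charge of the backward
#'   independent VSD step (the main voltage-sensor deactivation transition).
#' @param theta0,z_theta Base rate (1/s) and charge of the concerted
#'   intermediate -> activated step.
#' @param eta0,z_eta Base rate (1/s) and charge of the concerted return step.
#' @param ko0 Base pore opening rate (1/s) from the all-resting configuration.
#' @param kc0 Pore closing rate (1/s).
#' @param L Allosteric factor (>= 1) per VSD in the intermediate state.
#' @param D Additional allosteric factor (>= 1) for the concerted-activated
#'   configuration.
#' @param x_split Detailed-balance split in \[0, 1\]: how much of `L` (and `D`)
#'   speeds open-tier VSD forward rates versus slowing backward rates.
#' @param Gmax Maximal conductance (arbitrary units).
#' @param E_K Potassium reversal potential (mV).
#' @param w_I,w_A Fluorescence weight per VSD in the intermediate /
#'   activated state (dimensionless, `0 <= w_I <= w_A <= 1`).
#' @param VT Thermal voltage scale of the rate laws (mV).
#'
#' @return An object of class `kcnq_params` (a named list of numeric scalars).
#' @seealso [default_params()] for the calibrated baseline set,
#'   [build_rate_matrix()], [simulate_trace()].
#' @export
#' @examples
#' p <- default_params()
#' p$beta0
kcnq_params <- function(alpha0, z_alpha, beta0, z_beta,
                        theta0, z_theta, eta0, z_eta,
                        ko0, kc0, L, D, x_split = 0.5,
                        Gmax = 1, E_K = -105, w_I = 0.5, w_A = 1,
                        VT = 25.4) {
  p <- list(alpha0 = alpha0, z_alpha = z_alpha, beta0 = beta0, z_beta = z_beta,
            theta0 = theta0, z_theta = z_theta, eta0 = eta0, z_eta = z_eta,
            ko0 = ko0, kc0 = kc0, L = L, D = D, x_split = x_split,
            Gmax = Gmax, E_K = E_K, w_I = w_I, w_A = w_A, VT = VT)
  p <- lapply(p, as.numeric)
  class(p) <- "kcnq_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of rates, the allosteric bounds `L >= 1`, `D >= 1`,
#' the fluorescence weight ordering and the `x_split` range.  The offending
#' field is named in the error message.
#'
#' @param p A `kcnq_params` object (or named list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  for (f in param_fields) {
    v <- p[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  for (f in c("alpha0", "beta0", "theta0", "eta0", "ko0", "kc0", "Gmax", "VT"))
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0", call. = FALSE)
  if (p$L < 1) stop("parameter 'L' must be >= 1", call. = FALSE)
  if (p$D < 1) stop("parameter 'D' must be >= 1", call. = FALSE)
  if (p$x_split < 0 || p$x_split > 1)
    stop("parameter 'x_split' must lie in [0, 1]", call. = FALSE)
  if (p$w_I < 0) stop("parameter 'w_I' must be >= 0", call. = FALSE)
  if (p$w_A < p$w_I)
    stop("parameter 'w_A' must be >= w_I", call. = FALSE)
  invisible(p)
}

#' Calibrated baseline parameter set
#'
#' Default parameters of the 12-state model, calibrated once against the
#' qualitative behaviour of pseudo-wild-type KCNQ1 expressed in Xenopus
#' oocytes: slow sigmoidal current activation at +20 mV (time constant of
#' order hundreds of ms), a mono-exponential tail current at -120 mV, and an
#' F(V) curve hyperpolarized relative to G(V).  The same values are shipped in
#' `inst/extdata/default_params.cfg`.
#'
#' @return A `kcnq_params` object.
#' @export
default_params <- function() {
  kcnq_params(
    alpha0  = 7.9,    z_alpha = 1.55,
    beta0   = 1.0,    z_beta  = 0.55,
    theta0  = 6.0,    z_theta = 0.30,
    eta0    = 0.0314, z_eta   = 2.00,
    ko0     = 0.206,  kc0     = 36,
    L       = 3,      D       = 6,
    x_split = 0.1,
    Gmax    = 1,      E_K     = -105,
    w_I     = 0.8,    w_A     = 1,
    VT      = 25.4
  )
}

#' @export
print.kcnq_params <- function(x, ...) {
  cat("12-state KCNQ1 gating model parameters\n")
  cat(sprintf("  VSD step 1:  alpha0 = %g/s (z = %g),  beta0 = %g/s (z = %g)\n",
              x$alpha0, x$z_alpha, x$beta0, x$z_beta))
  cat(sprintf("  VSD step 2:  theta0 = %g/s (z = %g),  eta0 = %g/s (z = %g)\n",
              x$theta0, x$z_theta, x$eta0, x$z_eta))
  cat(sprintf("  Pore:        ko0 = %g/s, kc0 = %g/s,  L = %g, D = %g, x_split = %g\n",
              x$ko0, x$kc0, x$L, x$D, x$x_split))
  cat(sprintf("  Observables: Gmax = %g, E_K = %g mV, w_I = %g, w_A = %g, VT = %g mV\n",
              x$Gmax, x$E_K, x$w_I, x$w_A, x$VT))
  invisible(x)
}

#' Read / write parameter files
#'
#' Flat `key = value` text files whose keys are exactly the field names of
#' [kcnq_params()].  Values are written with 12 significant digits, so a
#' write/read round trip is lossless at that precision.  Lines starting with
#' `#` are comments.
#'
#' @param path File path.
#' @return `read_params()` returns a `kcnq_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  missing <- setdiff(param_fields, keys)
  if (length(missing))
    stop("parameter file missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- as.list(vals[match(param_fields, keys)])
  names(p) <- param_fields
  class(p) <- "kcnq_params"
  validate_params(p)
  p
}

#' @param p A `kcnq_params` object.
#' @param comment Optional character vector of comment lines written at the
#'   top of the file (prefixed with `#`).
#' @rdname read_params
#' @export
write_params <- function(p, path, comment = NULL) {
  validate_params(p)
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines, sprintf("%s = %s", param_fields,
                            vapply(p[param_fields], fmt_num, "")))
  writeLines(lines, path)
  invisible(path)
}

# 12-significant-digit formatting shared by all text writers
fmt_num <- function(x) sprintf("%.12g", x)
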