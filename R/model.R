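# Rate-matrix construction, detailed-balance checking and steady states.

#' State labels of the 12-state scheme
#'
#' Closed tier `C0..C4` (index = number of VSDs in the intermediate state),
#' `CA` (all four VSDs concerted-activated), then the corresponding open tier
#' `O0..O4`, `OA`.  This ordering fixes the row/column convention of every
#' rate matrix produced by the package.
#'
#' @return Character vector of length 12.
#' @export
state_names <- function() {
  c(paste0("C", 0:4), "CA", paste0("O", 0:4), "OA")
}

# index helpers (1-based into state_names())
.iC <- 1:5; .iCA <- 6L; .iO <- 7:11; .iOA <- 12L

#' Build the voltage-dependent rate matrix (generator)
#'
#' Evaluates all transition rates of the 12-state scheme at a single command
#' voltage and assembles the master-equation generator: off-diagonal entry
#' `(i, j)` is the rate of the `i -> j` transition (1/s), diagonal entries are
#' minus the row sums, and entries between non-adjacent states are exactly
#' zero.
#'
#' Closed-tier VSD transitions: `Cj -> Cj+1` at `(4 - j) * alpha(V)`,
#' `Cj+1 -> Cj` at `(j + 1) * beta(V)`, `C4 <-> CA` at `theta(V)` / `eta(V)`.
#' Pore transitions: `Cj -> Oj` at `ko0 * L^j` (`CA -> OA` at
#' `ko0 * L^4 * D`), all closings at `kc0`.  Open-tier VSD transitions carry
#' the detailed-balance split: forward rates are multiplied by `L^x_split`
#' (`D^x_split` for the concerted step) and backward rates by
#' `L^(x_split - 1)` (`D^(x_split - 1)`).
#'
#' @param params A `kcnq_params` object.
#' @param V Command voltage (mV), a single finite number.
#' @return A 12 x 12 numeric matrix with `dimnames` from [state_names()].
#' @export
#' @examples
#' Q <- build_rate_matrix(default_params(), -80)
#' max(abs(rowSums(Q)))  # conservation: ~1e-15
build_rate_matrix <- function(params, V) {
  validate_params(params)
  if (length(V) != 1L || !is.finite(V))
    stop("'V' must be a single finite voltage in mV", call. = FALSE)
  p <- params
  a  <- p$alpha0 * exp( p$z_alpha * V / p$VT)
  b  <- p$beta0  * exp(-p$z_beta  * V / p$VT)
  th <- p$theta0 * exp( p$z_theta * V / p$VT)
  et <- p$eta0   * exp(-p$z_eta   * V / p$VT)
  Lf <- p$L ^ p$x_split          # open-tier VSD forward factor
  Lb <- p$L ^ (p$x_split - 1)    # open-tier VSD backward factor
  Df <- p$D ^ p$x_split
  Db <- p$D ^ (p$x_split - 1)

  Q <- matrix(0, 12, 12, dimnames = list(state_names(), state_names()))
  for (j in 0:3) {
    # closed tier, independent VSD steps
    Q[.iC[j + 1], .iC[j + 2]] <- (4 - j) * a
    Q[.iC[j + 2], .iC[j + 1]] <- (j + 1) * b
    # open tier, with allosteric split
    Q[.iO[j + 1], .iO[j + 2]] <- (4 - j) * a * Lf
    Q[.iO[j + 2], .iO[j + 1]] <- (j + 1) * b * Lb
  }
  Q[.iC[5], .iCA] <- th;      Q[.iCA, .iC[5]] <- et
  Q[.iO[5], .iOA] <- th * Df; Q[.iOA, .iO[5]] <- et * Db
  for (j in 0:4) {
    Q[.iC[j + 1], .iO[j + 1]] <- p$ko0 * p$L ^ j
    Q[.iO[j + 1], .iC[j + 1]] <- p$kc0
  }
  Q[.iCA, .iOA] <- p$ko0 * p$L ^ 4 * p$D
  Q[.iOA, .iCA] <- p$kc0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Check microscopic reversibility of the gating cycles
#'
#' For each of the four-state cycles `(Cj, Cj+1, Oj+1, Oj)` (j = 0..3) and
#' the concerted cycle `(C4, CA, OA, O4)`, computes the ratio of the
#' clockwise to the counter-clockwise product of transition rates.  Detailed
#' balance requires every ratio to equal 1; the split rule built into
#' [build_rate_matrix()] guarantees this for any valid parameter set.
#'
#' @param x Either a `kcnq_params` object (the matrix is built at voltage
#'   `V`) or a 12 x 12 rate matrix, e.g. one deliberately tampered with.
#' @param V Voltage (mV) at which to evaluate rates when `x` is a parameter
#'   set.  The loop ratios of the native scheme are voltage independent.
#' @param tol Relative tolerance on `|ratio - 1|` for a loop to pass.
#' @return A data frame with one row per cycle: `loop`, `ratio`, `pass`;
#'   attribute `pass` gives the overall verdict.
#' @export
thermodynamic_consistency <- function(x, V = -80, tol = 1e-10) {
  Q <- if (is.matrix(x)) x else build_rate_matrix(x, V)
  if (!all(dim(Q) == c(12L, 12L)))
    stop("'x' must be a kcnq_params object or a 12 x 12 rate matrix",
         call. = FALSE)
  cyc <- lapply(0:3, function(j)
    c(.iC[j + 1], .iC[j + 2], .iO[j + 2], .iO[j + 1]))
  cyc <- c(cyc, list(c(.iC[5], .iCA, .iOA, .iO[5])))
  labels <- c(sprintf("C%d-C%d-O%d-O%d", 0:3, 1:4, 1:4, 0:3), "C4-CA-OA-O4")
  ratio <- vapply(cyc, function(s) {
    fwd <- Q[s[1], s[2]] * Q[s[2], s[3]] * Q[s[3], s[4]] * Q[s[4], s[1]]
    bwd <- Q[s[1], s[4]] * Q[s[4], s[3]] * Q[s[3], s[2]] * Q[s[2], s[1]]
    fwd / bwd
  }, 0)
  out <- data.frame(loop = labels, ratio = ratio,
                    pass = abs(ratio - 1) <= tol)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Stationary distribution of a generator
#'
#' Solves `p Q = 0`, `sum(p) = 1` by least squares on the augmented system.
#'
#' @param Q A square generator matrix (rows sum to zero).
#' @param max_kappa Condition-number threshold beyond which the generator is
#'   rejected as ill-conditioned.
#' @return Numeric occupancy vector (non-negative, sums to 1).
#' @export
steady_state <- function(Q, max_kappa = 1e12) {
  n <- nrow(Q)
  if (is.null(n) || n != ncol(Q)) stop("'Q' must be square", call. = FALSE)
  A <- rbind(t(Q), rep(1, n))
  kap <- kappa(A, exact = FALSE)
  if (!is.finite(kap) || kap > max_kappa)
    stop(sprintf("generator is ill-conditioned (condition estimate %.3g)", kap),
         call. = FALSE)
  p <- qr.solve(A, c(rep(0, n), 1))
  if (min(p) < -1e-10)
    stop("steady-state solve produced a significantly negative occupancy",
         call. = FALSE)
  p[p < 0] <- 0
  p <- p / sum(p)
  names(p) <- rownames(Q)
  p
}

#' Total open probability of an occupancy vector
#' @param p Length-12 occupancy vector in the [state_names()] order.
#' @return Scalar open probability (sum over the open tier).
#' @keywords internal
open_probability <- function(p) sum(p[c(.iO, .iOA)])

#' Fluorescence weights of the 12 states
#'
#' Per-channel fluorescence signal: each VSD in the intermediate state
#' contributes `w_I / 4`, the concerted-activated configuration contributes
#' `w_A`.  Pore state does not affect the optical signal.
#'
#' @keywords internal
fluor_weights <- function(params) {
  w <- c((0:4) * params$w_I / 4, params$w_A)
  c(w, w)
}
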