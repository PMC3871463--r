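#' Physical constants used throughout the package
#'
#' Returns the gas constant, Faraday constant, elementary charge and the
#' absolute temperature at which slope factors are converted to equivalent
#' gating charges.  At the default temperature (295 K) the thermal voltage
#' `RT/F` evaluates to about 25.4 mV.
#'
#' @param T_K absolute temperature in kelvin (default 295).
#' @return A list with elements `R` (J mol^-1 K^-1), `F` (C mol^-1),
#'   `e0` (C), `T` (K) and the derived `vt_mV` = RT/F in millivolts.
#' @export
#' @examples
#' constants()$vt_mV  # ~25.42 mV
constants <- function(T_K = 295) {
  stopifnot(is.numeric(T_K), length(T_K) == 1L, is.finite(T_K), T_K > 0)
  R <- 8.31446261815324
  Fd <- 96485.33212
  list(R = R, F = Fd, e0 = 1.6e-19, T = T_K, vt_mV = 1000 * R * T_K / Fd)
}

#' Single Boltzmann activation component
#'
#' @param V_mid half-activation voltage (mV).
#' @param k slope factor (mV); positive `k` gives a curve increasing with
#'   depolarization.
#' @return An object of class `boltzmann_component`.
#' @export
boltzmann_component <- function(V_mid, k) {
  stopifnot(is.numeric(V_mid), length(V_mid) == 1L, is.finite(V_mid))
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k == 0) stop("slope factor k must be non-zero", call. = FALSE)
  structure(list(V_mid = V_mid, k = k), class = "boltzmann_component")
}

#' Two-component Boltzmann activation law
#'
#' Weighted sum of two Boltzmann sigmoids,
#' `A * B1(V) + (1 - A) * B2(V)`, the standard description of an
#' activation curve governed by two distinct voltage-dependent
#' transitions.
#'
#' @param A weight of the first component, in \[0, 1\].
#' @param c1,c2 objects from [boltzmann_component()].
#' @return An object of class `two_boltzmann`.
#' @export
two_boltzmann <- function(A, c1, c2) {
  stopifnot(inherits(c1, "boltzmann_component"),
            inherits(c2, "boltzmann_component"))
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A))
  if (A < 0 || A > 1) {
    stop("component weight A must lie in [0, 1]", call. = FALSE)
  }
  structure(list(A = A, c1 = c1, c2 = c2), class = "two_boltzmann")
}

#' Voltage-dependent relaxation rate law
#'
#' Minimal Eyring-type parameterization of the forward and backward rates
#' of a two-state transition: `alpha(V) = a0 * exp(za*F*V/RT)` and
#' `beta(V) = b0 * exp(-zb*F*V/RT)`.
#'
#' @param a0,b0 forward/backward rate at 0 mV (ms^-1), strictly positive.
#' @param za,zb equivalent charge moved in each direction (e0 units),
#'   non-negative.
#' @return An object of class `rate_law`.
#' @export
rate_law <- function(a0, za, b0, zb) {
  stopifnot(is.numeric(a0), is.numeric(b0), is.numeric(za), is.numeric(zb))
  if (a0 <= 0 || b0 <= 0) stop("rates a0, b0 must be positive", call. = FALSE)
  if (za < 0 || zb < 0) stop("charges za, zb must be >= 0", call. = FALSE)
  structure(list(a0 = a0, za = za, b0 = b0, zb = zb), class = "rate_law")
}

#' Open-pore permeation law
#'
#' Parametric description of the single open channel's current-voltage
#' relation: a chord conductance that moves sigmoidally between a
#' depolarized limit `g_plus` and a hyperpolarized limit `g_minus`,
#' `gamma(V) = g_plus + (g_minus - g_plus) / (1 + exp(V / V_s))`, so that
#' `i_sc(V) = gamma(V) * V / 1000` (pA) vanishes at 0 mV as required in
#' symmetrical solutions.
#'
#' @param g_plus limiting chord conductance at depolarized voltages (pS).
#' @param g_minus limiting chord conductance at hyperpolarized voltages (pS).
#' @param V_s transition steepness (mV).
#' @return An object of class `permeation_law`.
#' @export
permeation_law <- function(g_plus, g_minus, V_s = 60) {
  stopifnot(is.numeric(g_plus), is.numeric(g_minus), is.numeric(V_s))
  if (g_plus <= 0 || g_minus <= 0) {
    stop("limiting conductances must be positive", call. = FALSE)
  }
  if (V_s == 0) stop("V_s must be non-zero", call. = FALSE)
  structure(list(g_plus = g_plus, g_minus = g_minus, V_s = V_s),
            class = "permeation_law")
}

#' Full channel model
#'
#' Aggregates the equilibrium open-probability law, the relaxation
#' kinetics, the open-pore permeation law, the channel count and the
#' open-channel noise ratio into the object consumed by the synthetic
#' generator and by the prediction helpers.
#'
#' @param po_law a [two_boltzmann()] law for the equilibrium open
#'   probability.
#' @param rates a [rate_law()] describing relaxation kinetics.
#' @param perm a [permeation_law()].
#' @param N channel count (non-negative integer).
#' @param sigma_o_over_i open-channel noise ratio sigma_o / i_sc
#'   (dimensionless, >= 0; ~0.1 for CNGA1 at +100 mV).
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(po_law, rates, perm, N, sigma_o_over_i = 0) {
  stopifnot(inherits(po_law, "two_boltzmann"), inherits(rates, "rate_law"),
            inherits(perm, "permeation_law"))
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N), N >= 0)
  if (abs(N - round(N)) > 1e-8) stop("N must be an integer", call. = FALSE)
  stopifnot(is.numeric(sigma_o_over_i), sigma_o_over_i >= 0)
  structure(list(po_law = po_law, rate_law = rates, perm = perm,
                 N = as.integer(round(N)),
                 sigma_o_over_i = sigma_o_over_i),
            class = "channel_model")
}

#' Evaluate a single Boltzmann component
#'
#' `1 / (1 + exp((V_mid - V) / k))`: 0.5 at `V = V_mid`, monotone
#' increasing in `V` for positive `k`.
#'
#' @param V membrane voltage(s), mV; must be finite.
#' @param c a [boltzmann_component()].
#' @return Open fraction(s) in (0, 1).
#' @export
eval_boltzmann <- function(V, c) {
  stopifnot(inherits(c, "boltzmann_component"))
  if (!is.numeric(V) || any(!is.finite(V))) {
    stop("V must be finite numeric", call. = FALSE)
  }
  1 / (1 + exp((c$V_mid - V) / c$k))
}

#' Evaluate a two-component Boltzmann law
#'
#' @param V membrane voltage(s), mV.
#' @param tb a [two_boltzmann()] law.
#' @return Values in \[0, 1\]; reduces to a single component when the
#'   weight is 0 or 1.
#' @export
eval_two_boltzmann <- function(V, tb) {
  stopifnot(inherits(tb, "two_boltzmann"))
  tb$A * eval_boltzmann(V, tb$c1) + (1 - tb$A) * eval_boltzmann(V, tb$c2)
}

#' Equivalent gating charge from a Boltzmann slope factor
#'
#' `z = RT / (k F)` with the slope factor `k` given in mV.
#'
#' @param k slope factor (mV), strictly positive.
#' @param T_K temperature (K).
#' @return Equivalent charge in e0 units.
#' @export
charge_from_slope <- function(k, T_K = 295) {
  if (!is.numeric(k) || any(k <= 0)) {
    stop("slope factor k must be positive", call. = FALSE)
  }
  constants(T_K)$vt_mV / k
}

#' Boltzmann slope factor from an equivalent charge
#'
#' Inverse of [charge_from_slope()]: `k = RT / (z F)` in mV.
#'
#' @param z equivalent charge (e0 units), strictly positive.
#' @param T_K temperature (K).
#' @return Slope factor in mV.
#' @export
slope_from_charge <- function(z, T_K = 295) {
  if (!is.numeric(z) || any(z <= 0)) {
    stop("charge z must be positive", call. = FALSE)
  }
  constants(T_K)$vt_mV / z
}

#' Relaxation rates, time constant and equilibrium open probability
#'
#' Evaluates `alpha(V)`, `beta(V)`, `tau(V) = 1/(alpha+beta)` and the
#' rate-implied equilibrium `po_eq = alpha/(alpha+beta)`.  `po_eq` is
#' algebraically a single Boltzmann with total charge `za + zb` and
#' midpoint `(RT/((za+zb)F)) * log(b0/a0)`.
#'
#' @param V membrane voltage(s), mV.
#' @param r a [rate_law()].
#' @param T_K temperature (K).
#' @return A data.frame with columns `V`, `alpha` (ms^-1), `beta`
#'   (ms^-1), `tau` (ms) and `po_eq`.
#' @export
relaxation <- function(V, r, T_K = 295) {
  stopifnot(inherits(r, "rate_law"))
  if (!is.numeric(V) || any(!is.finite(V))) {
    stop("V must be finite numeric", call. = FALSE)
  }
  vt <- constants(T_K)$vt_mV
  alpha <- r$a0 * exp(r$za * V / vt)
  beta <- r$b0 * exp(-r$zb * V / vt)
  data.frame(V = V, alpha = alpha, beta = beta,
             tau = 1 / (alpha + beta), po_eq = alpha / (alpha + beta))
}

#' Open-pore single-channel current
#'
#' `i_sc(V) = gamma(V) * V / 1000` pA, with the sigmoidal chord
#' conductance of [permeation_law()].  Zero at 0 mV (symmetrical
#' solutions) and strictly increasing in V.
#'
#' @param V membrane voltage(s), mV.
#' @param p a [permeation_law()].
#' @return Single-channel current(s) in pA.
#' @export
open_pore_current <- function(V, p) {
  stopifnot(inherits(p, "permeation_law"))
  if (!is.numeric(V) || any(!is.finite(V))) {
    stop("V must be finite numeric", call. = FALSE)
  }
  chord_conductance(V, p) * V / 1000
}

#' Chord conductance of the open pore
#'
#' @inheritParams open_pore_current
#' @return Chord conductance(s) in pS.
#' @export
chord_conductance <- function(V, p) {
  stopifnot(inherits(p, "permeation_law"))
  p$g_plus + (p$g_minus - p$g_plus) / (1 + exp(V / p$V_s))
}
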