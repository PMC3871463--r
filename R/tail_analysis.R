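#' Voltage-indexed curve table
#'
#' Common container for derived curves (normalized tails, conductance
#' ratios, open-pore ratios, time constants): one value per voltage with
#' an optional per-point uncertainty and patch count.
#'
#' @param V voltage grid (mV), strictly increasing.
#' @param value curve values.
#' @param sem per-point uncertainty (NA when single-patch).
#' @param n number of patches pooled per point.
#' @param label one of `"G_ratio"`, `"Po_ratio"`, `"tail_norm"`,
#'   `"gamma_ratio"`, `"isc_ratio"`, `"tau"`, `"tail_raw"`.
#' @param anchor normalization anchor voltage (mV) for ratio labels.
#' @return A data.frame of class `curve_table` with columns `V_mV`,
#'   `value`, `sem`, `n`.
#' @export
curve_table <- function(V, value, sem = NA_real_, n = 1L,
                        label = "tail_raw", anchor = NA_real_) {
  stopifnot(is.numeric(V), is.numeric(value), length(V) == length(value))
  if (is.unsorted(V, strictly = TRUE)) {
    stop("voltage grid must be strictly increasing", call. = FALSE)
  }
  df <- data.frame(V_mV = V, value = value, sem = sem, n = n)
  structure(df, class = c("curve_table", "data.frame"),
            label = label, anchor = anchor)
}

curve_label <- function(x) attr(x, "label")

# value at (or nearest within tol of) a given voltage
curve_value_at <- function(curve, V, tol = 1e-6) {
  i <- which(abs(curve$V_mV - V) < tol)
  if (length(i) != 1L) {
    stop("anchor voltage ", V, " mV absent from the curve grid",
         call. = FALSE)
  }
  curve$value[i]
}

# samples (1-based indices) of a time window [t0, t1) within a sweep
window_index <- function(dt, np, t0, t1) {
  idx <- which((seq_len(np) - 1L) * dt >= t0 & (seq_len(np) - 1L) * dt < t1)
  if (length(idx) == 0L) {
    stop("time window [", t0, ", ", t1, ") ms selects no samples",
         call. = FALSE)
  }
  idx
}

#' Isochronal tail-current amplitudes
#'
#' Reads every sweep's tail amplitude at the same latency after tail
#' onset (the common final epoch), optionally averaged over a short
#' window; the paired background recording, when present, is subtracted
#' at the same samples.  The resulting amplitude-vs-prepulse-voltage
#' relation reports the open probability reached at each prepulse.
#'
#' @param rec a [sweep_set()] recorded with a tail protocol (the varying
#'   prepulse epoch followed by a common tail epoch).
#' @param t_iso latency after tail onset (ms, default 0.5 — past the
#'   capacitive blanking window, early in the decay).
#' @param avg_window averaging window centered on `t_iso` (ms, default
#'   0.1; 0 reads a single sample).
#' @param mode `"point"` (isochronal read, default), `"peak"` (extremum
#'   of |I| over the tail past `t_iso`), or `"extrapolate"` (fit a single
#'   exponential over the tail past `t_iso` and back-extrapolate to the
#'   jump, removing the bias a fast-relaxing tail otherwise imposes on
#'   the inferred Po ratio).
#' @return A [curve_table()] (label `tail_raw`) of tail amplitude (pA)
#'   versus prepulse voltage.
#' @export
isochronal_tails <- function(rec, t_iso = 0.5, avg_window = 0.1,
                             mode = c("point", "peak", "extrapolate")) {
  stopifnot(inherits(rec, "sweep_set"))
  mode <- match.arg(mode)
  prot <- rec$protocol
  if (is.null(prot)) stop("recording carries no protocol", call. = FALSE)
  eb <- epoch_bounds(prot)
  ne <- nrow(eb)
  onset <- eb$start[ne]; t_end <- eb$end[ne]
  if (t_iso < 0 || onset + t_iso >= t_end) {
    stop("t_iso = ", t_iso, " ms lies outside the tail epoch", call. = FALSE)
  }
  np <- ncol(rec$traces)
  if (mode == "point") {
    half <- max(avg_window / 2, rec$dt / 2)
    idx <- window_index(rec$dt, np, onset + t_iso - half, onset + t_iso + half)
  } else {
    idx <- window_index(rec$dt, np, onset + t_iso, t_end)
  }
  traces <- rec$traces
  if (!is.null(rec$seal)) traces <- traces - rec$seal$traces
  amp <- if (mode == "point") {
    rowMeans(traces[, idx, drop = FALSE])
  } else if (mode == "peak") {
    apply(traces[, idx, drop = FALSE], 1L, function(x) x[which.max(abs(x))])
  } else {
    tt <- (idx - 1L) * rec$dt - onset
    apply(traces[, idx, drop = FALSE], 1L, function(x) {
      co <- fit_single_exp(tt, x)
      if (is.null(co)) NA_real_ else co$I0 + co$Iss
    })
  }
  V <- prot$sweep_levels
  o <- order(V)
  curve_table(V[o], amp[o], label = "tail_raw")
}

#' Normalize a tail-current curve
#'
#' `"minsub"`: `(I_t - I_min) / (I_anchor - I_min)` — 0 at the minimum,
#' 1 at the anchor voltage (the form used for two-component Boltzmann
#' fits).  `"plain"`: `I_t / I_anchor` — 1 at the anchor.
#'
#' @param tails a [curve_table()] of raw tail amplitudes.
#' @param mode `"minsub"` or `"plain"`.
#' @param anchor anchor voltage (mV, default +200).
#' @return A [curve_table()] labelled `tail_norm` (minsub) or `Po_ratio`
#'   (plain).
#' @export
normalize_tails <- function(tails, mode = c("minsub", "plain"),
                            anchor = 200) {
  stopifnot(inherits(tails, "curve_table"))
  mode <- match.arg(mode)
  y_anchor <- curve_value_at(tails, anchor)
  if (mode == "minsub") {
    # least-activated baseline: the extreme farthest from the anchor, so
    # inward (negative) tail currents normalize the same way as outward
    lo <- min(tails$value, na.rm = TRUE); hi <- max(tails$value, na.rm = TRUE)
    y_min <- if (abs(y_anchor - lo) >= abs(y_anchor - hi)) lo else hi
    denom <- y_anchor - y_min
    if (denom == 0) stop("degenerate normalization: flat curve", call. = FALSE)
    curve_table(tails$V_mV, (tails$value - y_min) / denom,
                sem = tails$sem / abs(denom), n = tails$n,
                label = "tail_norm", anchor = anchor)
  } else {
    if (y_anchor == 0) stop("anchor value is zero", call. = FALSE)
    curve_table(tails$V_mV, tails$value / y_anchor,
                sem = tails$sem / abs(y_anchor), n = tails$n,
                label = "Po_ratio", anchor = anchor)
  }
}

#' Fractional steady conductance G/G_anchor
#'
#' Chord conductance from the steady portion of each prepulse,
#' `G(V) = mean steady I / V` (the V = 0 sweep is dropped), normalized at
#' the anchor voltage.  G reflects both the open probability and the
#' open-pore conductance; dividing by the tail-derived Po ratio isolates
#' the latter (see [gamma_ratio()]).
#'
#' @param rec a [sweep_set()] recorded with a tail protocol.
#' @param window length (ms) of the steady window at the end of the
#'   prepulse epoch.
#' @param anchor anchor voltage (mV, default +200).
#' @return A [curve_table()] labelled `G_ratio`.
#' @export
steady_conductance <- function(rec, window = 10, anchor = 200) {
  stopifnot(inherits(rec, "sweep_set"))
  prot <- rec$protocol
  if (is.null(prot)) stop("recording carries no protocol", call. = FALSE)
  ve <- prot$varying_epoch
  if (is.na(ve)) stop("protocol has no varying epoch", call. = FALSE)
  eb <- epoch_bounds(prot)
  if (window <= 0 || window > prot$epochs$duration[ve]) {
    stop("steady window overruns the prepulse epoch", call. = FALSE)
  }
  idx <- window_index(rec$dt, ncol(rec$traces),
                      eb$end[ve] - window, eb$end[ve])
  traces <- rec$traces
  if (!is.null(rec$seal)) traces <- traces - rec$seal$traces
  I <- rowMeans(traces[, idx, drop = FALSE])
  V <- prot$sweep_levels
  keep <- V != 0
  G <- I[keep] / V[keep]
  V <- V[keep]
  o <- order(V)
  ct <- curve_table(V[o], G[o], label = "G_ratio", anchor = anchor)
  g_anchor <- curve_value_at(ct, anchor)
  if (g_anchor == 0) stop("anchor conductance is zero", call. = FALSE)
  ct$value <- ct$value / g_anchor
  ct
}

#' Open-pore conductance ratio from G and Po curves
#'
#' Pointwise quotient `gamma_sc/gamma_anchor = (G/G_anchor) /
#' (Po/Po_anchor)`: the open-pore rectification left after removing the
#' gating contribution.  Points where the Po ratio falls below `floor`
#' are masked (NA) rather than divided, to avoid noise amplification.
#'
#' @param G a `G_ratio` [curve_table()].
#' @param Po a `Po_ratio` (or `tail_norm`) [curve_table()] on the same
#'   voltage grid.
#' @param floor masking floor on the Po ratio (default 0.01).
#' @return A [curve_table()] labelled `gamma_ratio`.
#' @export
gamma_ratio <- function(G, Po, floor = 0.01) {
  stopifnot(inherits(G, "curve_table"), inherits(Po, "curve_table"))
  if (nrow(G) != nrow(Po) || any(abs(G$V_mV - Po$V_mV) > 1e-6)) {
    stop("G and Po voltage grids differ", call. = FALSE)
  }
  val <- ifelse(is.na(Po$value) | Po$value < floor, NA_real_,
                G$value / Po$value)
  curve_table(G$V_mV, val, label = "gamma_ratio", anchor = attr(G, "anchor"))
}

# single-exponential tail fit y(t) = I0 exp(-t/tau) + Iss, t from onset
fit_single_exp <- function(t, y) {
  iss0 <- mean(y[t >= stats::quantile(t, 0.8)])
  i00 <- y[1] - iss0
  d <- y - iss0
  # crude tau from the early decay (down to 1/5 of the jump) only, so the
  # estimate is not polluted by late-segment channel noise
  early_end <- which(abs(d) < 0.2 * abs(i00))[1]
  tau0 <- NA_real_
  if (!is.na(early_end) && early_end > 4L) {
    ok <- seq_len(early_end - 1L)
    ok <- ok[sign(d[ok]) == sign(i00) & abs(d[ok]) > 0]
    if (length(ok) > 3L) {
      tau0 <- -1 / stats::coef(stats::lm(log(abs(d[ok])) ~ t[ok]))[[2]]
    }
  }
  span <- diff(range(t))
  starts <- unique(c(if (is.finite(tau0) && tau0 > 0) tau0,
                     span / 200, span / 30, span / 5))
  fit <- NULL; best_rss <- Inf
  for (tau_s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ I0 * exp(-t / tau) + Iss,
                        start = list(I0 = i00, tau = tau_s, Iss = iss0),
                        lower = c(-Inf, 1e-4, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (rss < best_rss) { fit <- f; best_rss <- rss }
    }
  }
  # flat trace (no relaxation at this voltage): amplitude ~ 0, tau undefined
  if (is.null(fit)) return(list(I0 = 0, tau = NA_real_, Iss = mean(y)))
  co <- as.list(stats::coef(fit))
  if (abs(co$I0) < 3 * stats::sd(stats::resid(fit)) / sqrt(length(y))) {
    return(list(I0 = 0, tau = NA_real_, Iss = mean(y)))
  }
  co
}

#' Instantaneous I-V relation and deactivation kinetics
#'
#' For each test voltage, the post-blank tail is fitted with a single
#' exponential `I(t) = I0 exp(-t/tau) + Iss` and back-extrapolated to the
#' jump (`I0 + Iss`), yielding the instantaneous (open-pore) I-V relation
#' normalized at the anchor voltage, together with the deactivation time
#' constant per voltage.  Per-point fit failures are flagged (NA), never
#' fatal.
#'
#' @param rec a [sweep_set()] from an instantaneous-IV protocol (fixed
#'   depolarizing prepulse, varying final test epoch).
#' @param blank capacitive blanking window after the jump (ms).
#' @param anchor anchor voltage (mV, default +200).
#' @return A list with `iv` (a [curve_table()] labelled `isc_ratio`) and
#'   `tau` (a [curve_table()] labelled `tau`, ms).
#' @export
instantaneous_iv <- function(rec, blank = 0.3, anchor = 200) {
  stopifnot(inherits(rec, "sweep_set"))
  prot <- rec$protocol
  if (is.null(prot)) stop("recording carries no protocol", call. = FALSE)
  eb <- epoch_bounds(prot)
  ne <- nrow(eb)
  onset <- eb$start[ne]
  np <- ncol(rec$traces)
  idx <- window_index(rec$dt, np, onset + blank, eb$end[ne])
  tt <- (idx - 1L) * rec$dt - onset
  traces <- rec$traces
  if (!is.null(rec$seal)) traces <- traces - rec$seal$traces
  ns <- nrow(traces)
  inst <- tau <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    co <- fit_single_exp(tt, traces[s, idx])
    if (!is.null(co)) {
      inst[s] <- co$I0 + co$Iss
      tau[s] <- co$tau
    }
  }
  V <- prot$sweep_levels
  o <- order(V)
  iv <- curve_table(V[o], inst[o], label = "isc_ratio", anchor = anchor)
  ref <- curve_value_at(iv, anchor)
  if (is.na(ref) || ref == 0) {
    stop("anchor instantaneous current unavailable", call. = FALSE)
  }
  iv$value <- iv$value / ref
  list(iv = iv, tau = curve_table(V[o], tau[o], label = "tau"))
}

#' Fit a two-component Boltzmann activation curve
#'
#' Weighted least-squares fit of
#' `y(V) = A / (1 + exp((Vmid1 - V)/k1)) + (1 - A) / (1 + exp((Vmid2 - V)/k2))`
#' to a normalized tail curve, with multi-start initialization.  Slope
#' factors are converted to equivalent gating charges `z_i = RT/(k_i F)`.
#' Components are ordered so that component 1 has the smaller midpoint.
#' Near-degenerate two-component fits (a single transition) are flagged
#' through the parameter covariance rather than reported as spurious
#' second charges.
#'
#' @param curve a [curve_table()], typically from
#'   `normalize_tails(..., "minsub")`; at least 8 points.
#' @param init optional named list of starting values
#'   (`A, V_mid1, k1, V_mid2, k2`) tried in addition to the built-in grid.
#' @param T_K temperature (K) for the charge conversion.
#' @return An object of class `boltzmann2_fit`: fitted `A`, `V_mid1`,
#'   `k1`, `V_mid2`, `k2`, derived `z1`, `z2`, standard errors, residual
#'   standard deviation `sigma`, `converged` and `degenerate` flags.
#' @export
fit_two_boltzmann <- function(curve, init = NULL, T_K = 295) {
  stopifnot(inherits(curve, "curve_table"))
  keep <- is.finite(curve$value)
  V <- curve$V_mV[keep]; y <- curve$value[keep]
  if (length(V) < 8L) stop("need at least 8 points", call. = FALSE)
  w <- if (all(is.finite(curve$sem[keep])) && any(curve$n[keep] > 1L) &&
           all(curve$sem[keep] > 0)) {
    1 / curve$sem[keep]^2
  } else {
    rep(1, length(V))
  }
  starts <- list()
  for (A0 in c(0.3, 0.5, 0.7)) {
    for (k0 in c(12, 25)) {
      starts[[length(starts) + 1L]] <-
        list(A = A0, V_mid1 = stats::quantile(V, 0.25)[[1]], k1 = k0,
             V_mid2 = stats::quantile(V, 0.75)[[1]], k2 = k0)
    }
  }
  if (!is.null(init)) starts <- c(list(init), starts)
  model_fn <- function(p, Vv) {
    p[["A"]] / (1 + exp((p[["V_mid1"]] - Vv) / p[["k1"]])) +
      (1 - p[["A"]]) / (1 + exp((p[["V_mid2"]] - Vv) / p[["k2"]]))
  }
  resid_fn <- function(p) sqrt(w) * (y - model_fn(p, V))
  lo <- c(A = 0, V_mid1 = -500, k1 = 0.5, V_mid2 = -500, k2 = 0.5)
  hi <- c(A = 1, V_mid1 = 500, k1 = 400, V_mid2 = 500, k2 = 400)
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(st), fn = resid_fn,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:3) {
      rss <- sum(fit$fvec^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) {
    stop("two-component Boltzmann fit failed from every start (best RSS ",
         format(best_rss), ")", call. = FALSE)
  }
  co <- as.list(best$par)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) {
                   stats::setNames(rep(NA_real_, 5), names(best$par))
                 })
  # order components by midpoint
  if (co$V_mid2 < co$V_mid1) {
    co <- list(A = 1 - co$A, V_mid1 = co$V_mid2, k1 = co$k2,
               V_mid2 = co$V_mid1, k2 = co$k1)
    se <- se[c("A", "V_mid2", "k2", "V_mid1", "k1")]
    names(se) <- c("A", "V_mid1", "k1", "V_mid2", "k2")
  }
  z1 <- charge_from_slope(co$k1, T_K)
  z2 <- charge_from_slope(co$k2, T_K)
  rel_se <- abs(se / unlist(co))
  degenerate <- any(!is.finite(se)) || any(rel_se[-1] > 5, na.rm = TRUE) ||
    co$A < 1e-3 || co$A > 1 - 1e-3
  structure(list(
    A = co$A, V_mid1 = co$V_mid1, k1 = co$k1,
    V_mid2 = co$V_mid2, k2 = co$k2,
    z1 = z1, z2 = z2,
    se = se,
    z_se = c(z1 = z1 * se[["k1"]] / co$k1, z2 = z2 * se[["k2"]] / co$k2),
    sigma = sqrt(best_rss / max(length(V) - 5L, 1L)), rss = best_rss,
    converged = TRUE, degenerate = degenerate,
    T_K = T_K, fit = best), class = "boltzmann2_fit")
}

#' @export
print.boltzmann2_fit <- function(x, ...) {
  cat("Two-component Boltzmann fit\n")
  cat(sprintf("  A      = %.4f (se %.4f)\n", x$A, x$se[["A"]]))
  cat(sprintf("  V_mid1 = %8.2f mV, k1 = %6.2f mV, z1 = %.3f\n",
              x$V_mid1, x$k1, x$z1))
  cat(sprintf("  V_mid2 = %8.2f mV, k2 = %6.2f mV, z2 = %.3f\n",
              x$V_mid2, x$k2, x$z2))
  cat(sprintf("  residual sigma = %.4g%s\n", x$sigma,
              if (x$degenerate) "  [component degeneracy flagged]" else ""))
  invisible(x)
}

#' Predict from a two-component Boltzmann fit or law
#'
#' @param object a `boltzmann2_fit`.
#' @param V voltages (mV).
#' @param ... unused.
#' @return Fitted curve values.
#' @export
predict.boltzmann2_fit <- function(object, V, ...) {
  tb <- two_boltzmann(object$A,
                      boltzmann_component(object$V_mid1, object$k1),
                      boltzmann_component(object$V_mid2, object$k2))
  eval_two_boltzmann(V, tb)
}

#' Double-exponential activation fit
#'
#' Fits `I(t) = c + a_f exp(-t/tau_f) + a_s exp(-t/tau_s)` to an
#' activation time course at one voltage, enforcing `tau_f < tau_s`.
#' When the two time constants are separated by less than a factor 3 an
#' identifiability flag is raised; when the second amplitude is
#' negligible the trace is flagged as effectively single-exponential.
#'
#' @param y current trace (pA) over the activation epoch.
#' @param dt sampling interval (ms); or supply `t` directly.
#' @param t optional time vector (ms) overriding `dt`.
#' @param n_exp 1 or 2 exponentials.
#' @return A list: `tau_f`, `tau_s`, `amp_f`, `amp_s`, `c`, `converged`,
#'   `flag_identifiability`, `flag_single`.
#' @export
fit_activation <- function(y, dt = NULL, t = NULL, n_exp = 2) {
  if (is.null(t)) {
    stopifnot(!is.null(dt))
    t <- (seq_along(y) - 1L) * dt
  }
  stopifnot(length(t) == length(y), n_exp %in% c(1, 2))
  c0 <- mean(y[t >= stats::quantile(t, 0.9)])
  a0 <- y[1] - c0
  T_span <- diff(range(t))
  if (n_exp == 1) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c0p + a1 * exp(-t / tau1),
                        start = list(c0p = c0, a1 = a0, tau1 = T_span / 5),
                        lower = c(-Inf, -Inf, 1e-5),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(converged = FALSE))
    co <- as.list(stats::coef(fit))
    return(list(tau_f = co$tau1, tau_s = NA_real_, amp_f = co$a1,
                amp_s = NA_real_, c = co$c0p, converged = TRUE,
                flag_identifiability = FALSE, flag_single = TRUE))
  }
  best <- NULL; best_rss <- Inf
  for (tf0 in T_span * c(0.005, 0.02, 0.08)) {
    for (ratio in c(5, 20)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ c0p + af * exp(-t / tf) + as_ * exp(-t / ts),
          start = list(c0p = c0, af = a0 / 2, tf = tf0,
                       as_ = a0 / 2, ts = tf0 * ratio),
          lower = c(-Inf, -Inf, 1e-5, -Inf, 1e-5),
          control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (rss < best_rss) { best <- fit; best_rss <- rss }
      }
    }
  }
  if (is.null(best)) return(list(converged = FALSE))
  co <- as.list(stats::coef(best))
  if (co$tf > co$ts) {
    co <- list(c0p = co$c0p, af = co$as_, tf = co$ts, as_ = co$af, ts = co$tf)
  }
  total_amp <- abs(co$af) + abs(co$as_)
  list(tau_f = co$tf, tau_s = co$ts, amp_f = co$af, amp_s = co$as_,
       c = co$c0p, converged = TRUE,
       flag_identifiability = co$ts / co$tf < 3,
       flag_single = abs(co$as_) < 0.02 * total_amp ||
         abs(co$af) < 0.02 * total_amp)
}

#' Bell-shaped fit of the slow activation time constant
#'
#' Fits `tau(V) = 1 / (alpha(V) + beta(V))` with
#' `alpha = a0 exp((z/2) V F/RT)`, `beta = b0 exp(-(z/2) V F/RT)` (the
#' equivalent charge split symmetrically), returning the total equivalent
#' charge `z_eq` carried by the transition.
#'
#' @param V voltages (mV), at least 5.
#' @param tau measured time constants (ms).
#' @param T_K temperature (K).
#' @return A list: `a0`, `b0`, `z_eq` (e0 units), `se` (named), `converged`.
#' @export
fit_tau_bell <- function(V, tau, T_K = 295) {
  keep <- is.finite(V) & is.finite(tau) & tau > 0
  V <- V[keep]; tau <- tau[keep]
  if (length(V) < 5L) stop("bell fit needs at least 5 voltages", call. = FALSE)
  vt <- constants(T_K)$vt_mV
  ly <- log(tau)
  best <- NULL; best_rss <- Inf
  for (z0 in c(0.3, 0.6, 1, 1.5)) {
    r_hi <- 1 / tau[which.max(V)] * exp(-z0 / 2 * max(V) / vt)
    r_lo <- 1 / tau[which.min(V)] * exp(z0 / 2 * min(V) / vt)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ly ~ -log(a0 * exp(z / 2 * V / vt) + b0 * exp(-z / 2 * V / vt)),
        start = list(a0 = max(r_hi, 1e-6), b0 = max(r_lo, 1e-6), z = z0),
        lower = c(1e-9, 1e-9, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) return(list(converged = FALSE))
  co <- as.list(stats::coef(best))
  se <- tryCatch(sqrt(diag(stats::vcov(best))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("a0", "b0", "z_eq")
  list(a0 = co$a0, b0 = co$b0, z_eq = co$z, se = se, converged = TRUE)
}
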