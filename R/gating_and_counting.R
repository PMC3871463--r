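#' Channel count from a macroscopic current
#'
#' `N = I / (gamma * V * Po)` with `I` in pA, `V` in mV, `gamma` in pS
#' (so the single-channel current is `gamma * V / 1000` pA).  With the
#' measured CNGA1 values (gamma = 30 pS, Po = 0.8 at +60 mV) a 1 nA
#' current at +60 mV corresponds to ~0.7e3 channels and a 10 nA current
#' at +10 mV to ~4.2e4.
#'
#' @param I macroscopic current (pA).
#' @param V membrane voltage (mV), non-zero.
#' @param gamma single-channel conductance (pS), positive.
#' @param Po open probability, in (0, 1].
#' @return An object of class `count_result` with `N_est` and the echoed
#'   inputs.
#' @export
count_channels <- function(I, V, gamma, Po) {
  if (any(V == 0)) stop("V must be non-zero", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be positive", call. = FALSE)
  if (any(Po <= 0) || any(Po > 1)) {
    stop("Po must lie in (0, 1]", call. = FALSE)
  }
  N <- 1000 * I / (gamma * V * Po)
  structure(list(N_est = N, I_pA = I, V_mV = V, gamma_pS = gamma,
                 Po = Po, alpha = NA_real_, method = "direct"),
            class = "count_result")
}

#' Residual-current ratio under channel block
#'
#' Ratio `I_blocked / I_control` at the same voltage, the factor entering
#' the blocker-corrected counting formula.  (This quantity is sometimes
#' loosely called the "fractional blockage"; arithmetically it is the
#' residual fraction — the corrected count requires it to multiply the
#' denominator.)
#'
#' @param I_control current without blocker (pA), non-zero.
#' @param I_blocked current with blocker (pA), same sign as `I_control`.
#' @return The residual ratio alpha in \[0, 1\].
#' @export
block_fraction <- function(I_control, I_blocked) {
  if (any(I_control == 0)) stop("I_control must be non-zero", call. = FALSE)
  if (any(I_blocked * I_control < 0)) {
    stop("I_blocked and I_control have opposite signs", call. = FALSE)
  }
  I_blocked / I_control
}

#' Channel count with blocker correction
#'
#' `N = I / (gamma * V * Po * alpha)`: the direct count divided by the
#' residual-current ratio `alpha` measured for the blocker (e.g. 0.48 for
#' extracellular TEACl on the Na+ current), recovering the count the
#' unblocked current would have given.
#'
#' @inheritParams count_channels
#' @param alpha residual-current ratio from [block_fraction()], in (0, 1].
#' @return An object of class `count_result`.
#' @export
count_channels_blocked <- function(I, V, gamma, Po, alpha) {
  if (any(alpha <= 0) || any(alpha > 1)) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  res <- count_channels(I, V, gamma, Po)
  res$N_est <- res$N_est / alpha
  res$alpha <- alpha
  res$method <- "blocked"
  res
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("Channel count (%s): N = %.3g\n", x$method, x$N_est))
  cat(sprintf("  I = %g pA at %g mV; gamma = %g pS, Po = %g%s\n",
              x$I_pA, x$V_mV, x$gamma_pS, x$Po,
              if (!is.na(x$alpha)) sprintf(", alpha = %g", x$alpha) else ""))
  invisible(x)
}

#' Integrate off-gating charge per sweep
#'
#' Baseline-subtracted trapezoidal time integral of the gating current
#' over the off window, per sweep; 1 pA * ms = 1 fC.  `Q_norm` is taken
#' against the reference voltage's charge (by default the sweep with the
#' largest |Q|).  For a two-state sensor the Q(V) relation is the
#' sensor's activation Boltzmann.
#'
#' @param rec a [sweep_set()] of gating currents.
#' @param window `c(t0, t1)` ms from sweep start spanning the off-gating
#'   transient.
#' @param baseline `c(t0, t1)` ms of a quiescent segment used as the
#'   zero-current baseline.
#' @param ref_V reference voltage for normalization (mV); default: sweep
#'   with the largest |Q|.
#' @return A data.frame of class `charge_curve`: `V_mV`, `Q_fC`, `Q_norm`.
#' @export
integrate_off_charge <- function(rec, window, baseline, ref_V = NULL) {
  stopifnot(inherits(rec, "sweep_set"))
  np <- ncol(rec$traces)
  dur <- (np - 1L) * rec$dt
  if (window[1] < 0 || window[2] > dur + rec$dt) {
    stop("integration window lies outside the sweep", call. = FALSE)
  }
  wi <- window_index(rec$dt, np, window[1], window[2])
  bi <- window_index(rec$dt, np, baseline[1], baseline[2])
  tt <- (wi - 1L) * rec$dt
  ns <- nrow(rec$traces)
  Q <- numeric(ns)
  for (s in seq_len(ns)) {
    base <- mean(rec$traces[s, bi])
    Q[s] <- pracma::trapz(tt, rec$traces[s, wi] - base)  # pA*ms = fC
  }
  prot <- rec$protocol
  V <- if (!is.null(prot) && !is.null(prot$sweep_levels)) {
    prot$sweep_levels
  } else {
    seq_len(ns)
  }
  o <- order(V)
  V <- V[o]; Q <- Q[o]
  ref <- if (is.null(ref_V)) V[which.max(abs(Q))] else ref_V
  qref <- Q[which.min(abs(V - ref))]
  if (qref == 0) stop("reference charge is zero", call. = FALSE)
  structure(data.frame(V_mV = V, Q_fC = Q, Q_norm = Q / qref),
            class = c("charge_curve", "data.frame"), ref_V = ref)
}

#' Peak gating current of an exponentially relaxing sensor
#'
#' For a saturating step, `z` elementary charges per channel moving with
#' time constant `tau` across `N` channels give a peak gating current of
#' `z e0 N / tau` (e0 = 1.6e-19 C): e.g. z = 2, N = 3e4, tau = 1 ms
#' yields 9.6 pA.
#'
#' @param z equivalent charge per channel (e0 units), >= 0.
#' @param N channel count, >= 0.
#' @param tau relaxation time constant (ms), > 0.
#' @return Peak gating current (pA).
#' @export
peak_gating_current <- function(z, N, tau) {
  stopifnot(all(z >= 0), all(N >= 0), all(tau > 0))
  z * constants()$e0 * N / tau * 1e15   # C/ms -> pA
}

#' Gating-current detectability map
#'
#' Signal-to-noise ratio of the off-gating peak over a grid of equivalent
#' charge and relaxation time constant, for a patch of `N` channels and a
#' given background r.m.s., classified as `low` (S/N below the first
#' threshold), `mid`, or `high` (above the second).  The analytic variant
#' uses the exponential peak `z e0 N / tau`; the simulated variant
#' measures the maximum of a seeded noisy simulation.
#'
#' @param z_grid equivalent charges (e0 units).
#' @param tau_grid time constants (ms).
#' @param N channel count (default 3e4, a giant excised patch).
#' @param rms background r.m.s. (pA, default 1 at 10 kHz).
#' @param thresholds two class thresholds (default `c(4, 6)`).
#' @param method `"analytic"` (default) or `"simulated"`.
#' @param seed seed for the simulated variant.
#' @return A data.frame of class `detectability_map`: `z`, `tau_ms`,
#'   `snr`, `class` (factor low/mid/high).
#' @export
detectability_map <- function(z_grid, tau_grid, N = 3e4, rms = 1,
                              thresholds = c(4, 6),
                              method = c("analytic", "simulated"),
                              seed = 1) {
  stopifnot(length(z_grid) > 0, length(tau_grid) > 0, rms > 0,
            length(thresholds) == 2, thresholds[1] <= thresholds[2])
  method <- match.arg(method)
  grid <- expand.grid(z = z_grid, tau_ms = tau_grid)
  if (method == "analytic") {
    grid$snr <- peak_gating_current(grid$z, N, grid$tau_ms) / rms
  } else {
    # saturating off-step: the full sensor population relaxes with tau,
    # I_g(t) = z e0 N / tau * exp(-t/tau), plus band-limited seal noise
    dt <- 0.02; fs <- 1 / dt; fc <- 10
    snr <- numeric(nrow(grid))
    set.seed(seed)
    for (i in seq_len(nrow(grid))) {
      tau <- grid$tau_ms[i]
      tt <- seq(0, 10 * tau, by = dt)
      ig <- peak_gating_current(grid$z[i], N, tau) * exp(-tt / tau)
      tr <- ig + seal_noise_trace(length(tt), rms, fc, fs)
      co <- bessel4_lowpass(fc, fs)
      tr <- as.numeric(signal::filter(co$b, co$a, tr))
      snr[i] <- max(abs(tr)) / rms
    }
    grid$snr <- snr
  }
  grid$class <- cut(grid$snr, breaks = c(-Inf, thresholds, Inf),
                    labels = c("low", "mid", "high"), right = FALSE)
  structure(grid, class = c("detectability_map", "data.frame"),
            N = N, rms = rms, thresholds = thresholds, method = method)
}
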