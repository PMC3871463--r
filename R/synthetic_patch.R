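#' Seal-noise specification
#'
#' @param seal_rms background (pipette seal) current noise, pA r.m.s. at
#'   the recording bandwidth (default 1 pA at 10 kHz, typical for a giant
#'   excised patch).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(seal_rms = 1) {
  stopifnot(is.numeric(seal_rms), length(seal_rms) == 1L, seal_rms >= 0)
  structure(list(seal_rms = seal_rms), class = "noise_spec")
}

#' Two-state voltage-sensor specification
#'
#' @param z equivalent charge moved per channel between the resting and
#'   activated sensor state (e0 units, >= 0).
#' @param N number of channels in the patch (>= 0).
#' @param tau0_ms relaxation time constant of the sensor (ms).  By
#'   default the sensor relaxes exponentially with this voltage-independent
#'   time constant toward a Boltzmann equilibrium of charge `z` centred at
#'   `V_half` — the form used for predicted-gating-current calculations.
#' @param V_half midpoint (mV) of the sensor's activation Boltzmann.
#' @param tau_law optional [rate_law()] overriding the constant-tau
#'   kinetics: equilibrium and time constant are then both taken from the
#'   law, with `z` still scaling the moved charge.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(z, N, tau0_ms = 1, V_half = 0, tau_law = NULL) {
  stopifnot(is.numeric(z), z >= 0, is.numeric(N), N >= 0,
            is.numeric(tau0_ms), tau0_ms > 0)
  if (!is.null(tau_law)) stopifnot(inherits(tau_law, "rate_law"))
  structure(list(z = z, N = N, tau0_ms = tau0_ms, V_half = V_half,
                 tau_law = tau_law), class = "sensor_spec")
}

# equilibrium activated fraction and time constant of the sensor at V
sensor_state_laws <- function(sensor, V) {
  if (!is.null(sensor$tau_law)) {
    rr <- relaxation(V, sensor$tau_law)
    list(x_inf = rr$po_eq, tau = rr$tau)
  } else {
    bc <- boltzmann_component(sensor$V_half,
                              slope_from_charge(max(sensor$z, 1e-6)))
    list(x_inf = eval_boltzmann(V, bc), tau = rep(sensor$tau0_ms, length(V)))
  }
}

# Deterministic per-sweep seed streams from one master seed.
sweep_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# White Gaussian noise whose post-filter r.m.s. equals `rms`.
seal_noise_trace <- function(n, rms, filter_khz, fs) {
  if (rms == 0) return(numeric(n))
  if (is.null(filter_khz) || is.na(filter_khz)) {
    return(stats::rnorm(n, sd = rms))
  }
  stats::rnorm(n, sd = rms / filter_noise_gain(filter_khz, fs))
}

# Per-epoch gating targets for one sweep: po_inf from the equilibrium
# (two-Boltzmann) law, tau from the rate law.
epoch_gating <- function(model, levels) {
  po <- eval_two_boltzmann(levels, model$po_law)
  tau <- relaxation(levels, model$rate_law)$tau
  list(po = po, tau = tau)
}

#' Simulate macroscopic patch currents
#'
#' N independent two-state channels.  Within each constant-voltage epoch
#' the open-channel count follows the exact per-channel two-state
#' propagator (binomial updates with stay/open probabilities
#' `p_oo = po + (1-po) e^{-dt/tau}`, `p_co = po (1 - e^{-dt/tau})`), so at
#' steady state the mean current is `N i_sc Po` and its variance obeys the
#' binomial law `sigma^2 = i_sc I - I^2/N` exactly at any N.  The
#' equilibrium open probability follows the model's two-component
#' Boltzmann law; the relaxation time constant follows its rate law.
#' Filtered Gaussian seal noise is added, and a paired agonist-free
#' recording (seal noise only) is attached as `$seal` for background
#' subtraction.
#'
#' @param model a [channel_model()] with `N >= 1` (use N = 0 for a pure
#'   seal recording).
#' @param prot a [voltage_protocol()].
#' @param noise a [noise_spec()].
#' @param seed integer master seed; per-sweep streams are split from it so
#'   results are independent of sweep order.
#' @param dt sampling interval (ms; default 0.02, i.e. 50 kHz).
#' @param filter_khz low-pass cutoff applied to the simulated traces
#'   (default 10 kHz); `NULL` disables filtering.
#' @param with_seal attach the paired background recording (default TRUE).
#' @return A [sweep_set()]; `meta$n_open` holds the hidden open-channel
#'   count paths (sweeps x samples) for oracle checks.
#' @export
simulate_macroscopic <- function(model, prot, noise, seed,
                                 dt = 0.02, filter_khz = 10,
                                 with_seal = TRUE) {
  stopifnot(inherits(model, "channel_model"),
            inherits(prot, "voltage_protocol"),
            inherits(noise, "noise_spec"))
  volts <- command_waveform(prot, dt)
  ns <- nrow(volts); np <- ncol(volts)
  counts <- round(prot$epochs$duration / dt)
  fs <- 1 / dt
  seeds <- sweep_seeds(seed, 2L * ns)
  traces <- matrix(0, ns, np)
  nopen <- matrix(0L, ns, np)
  N <- model$N
  for (s in seq_len(ns)) {
    set.seed(seeds[s])
    lev <- prot$epochs$level
    if (!is.na(prot$varying_epoch)) lev[prot$varying_epoch] <- prot$sweep_levels[s]
    g <- epoch_gating(model, lev)
    isc <- open_pore_current(lev, model$perm)
    if (N > 0) {
      n_op <- stats::rbinom(1L, N, eval_two_boltzmann(prot$holding, model$po_law))
      pos <- 1L
      for (e in seq_along(counts)) {
        ne <- counts[e]
        if (ne == 0L) next
        decay <- exp(-dt / g$tau[e])
        p_oo <- g$po[e] + (1 - g$po[e]) * decay
        p_co <- g$po[e] * (1 - decay)
        path <- integer(ne)
        for (i in seq_len(ne)) {
          n_op <- stats::rbinom(1L, n_op, p_oo) +
            stats::rbinom(1L, N - n_op, p_co)
          path[i] <- n_op
        }
        nopen[s, pos:(pos + ne - 1L)] <- path
        traces[s, pos:(pos + ne - 1L)] <- path * isc[e]
        pos <- pos + ne
      }
    }
    traces[s, ] <- traces[s, ] +
      seal_noise_trace(np, noise$seal_rms, filter_khz, fs)
  }
  rec <- sweep_set(traces, dt, prot,
                   filter_khz = if (is.null(filter_khz)) NA_real_ else filter_khz,
                   meta = list(seed = seed, kind = "macroscopic",
                               N = N, n_open = nopen))
  if (!is.null(filter_khz)) rec <- lowpass(rec, filter_khz)
  if (with_seal) {
    seal_traces <- matrix(0, ns, np)
    for (s in seq_len(ns)) {
      set.seed(seeds[ns + s])
      seal_traces[s, ] <- seal_noise_trace(np, noise$seal_rms, filter_khz, fs)
    }
    seal <- sweep_set(seal_traces, dt, prot,
                      filter_khz = if (is.null(filter_khz)) NA_real_
                                   else filter_khz,
                      meta = list(seed = seed, kind = "seal"))
    if (!is.null(filter_khz)) seal <- lowpass(seal, filter_khz)
    rec$seal <- seal
  }
  rec
}

#' Simulate single-channel recordings
#'
#' Exact event-driven stochastic simulation of one or two independent
#' two-state channels: within each constant-voltage epoch, dwell times are
#' drawn from the exponential laws with rates `alpha(V)` (closed -> open)
#' and `beta(V)` (open -> closed) given by the model's rate law.  Open
#' channels may carry extra Gaussian open-channel noise
#' `sigma_o = sigma_o_over_i * |i_sc|`.
#'
#' @inheritParams simulate_macroscopic
#' @param model a [channel_model()] with `N` in \{1, 2\}.
#' @return A list with `rec` (a [sweep_set()]) and `state_path`, a list
#'   (one per sweep) of data.frames `channel`, `t_start`, `duration`,
#'   `state` (0 closed / 1 open) giving every dwell.
#' @export
simulate_single_channel <- function(model, prot, noise, seed,
                                    dt = 0.02, filter_khz = 10) {
  stopifnot(inherits(model, "channel_model"), model$N %in% c(1L, 2L))
  volts <- command_waveform(prot, dt)
  ns <- nrow(volts); np <- ncol(volts)
  counts <- round(prot$epochs$duration / dt)
  bounds_end <- cumsum(prot$epochs$duration)
  bounds_start <- c(0, bounds_end[-length(bounds_end)])
  fs <- 1 / dt
  seeds <- sweep_seeds(seed, ns)
  traces <- matrix(0, ns, np)
  paths <- vector("list", ns)
  tt <- (seq_len(np) - 1L) * dt
  for (s in seq_len(ns)) {
    set.seed(seeds[s])
    lev <- prot$epochs$level
    if (!is.na(prot$varying_epoch)) lev[prot$varying_epoch] <- prot$sweep_levels[s]
    rr <- relaxation(lev, model$rate_law)
    isc <- open_pore_current(lev, model$perm)
    dwells <- list()
    occupancy <- matrix(0L, model$N, np)
    for (ch in seq_len(model$N)) {
      state <- as.integer(stats::runif(1) <
                            relaxation(prot$holding, model$rate_law)$po_eq)
      for (e in seq_along(counts)) {
        t_now <- bounds_start[e]
        while (t_now < bounds_end[e]) {
          rate <- if (state == 1L) rr$beta[e] else rr$alpha[e]
          dur <- stats::rexp(1, rate)
          t_end <- min(t_now + dur, bounds_end[e])
          dwells[[length(dwells) + 1L]] <-
            c(ch, t_now, t_end - t_now, state, e)
          i0 <- floor(t_now / dt) + 1L
          i1 <- min(ceiling(t_end / dt), np)
          if (state == 1L && i0 <= i1) {
            idx <- i0:i1
            idx <- idx[tt[idx] >= t_now & tt[idx] < t_end]
            occupancy[ch, idx] <- 1L
          }
          if (t_now + dur < bounds_end[e]) state <- 1L - state
          t_now <- t_end
        }
      }
    }
    n_open <- colSums(occupancy)
    epoch_of <- rep(seq_along(counts), times = counts)
    cur <- n_open * isc[epoch_of]
    if (model$sigma_o_over_i > 0) {
      sig_o <- model$sigma_o_over_i * abs(isc[epoch_of])
      cur <- cur + stats::rnorm(np, sd = sqrt(pmax(n_open, 0)) * sig_o)
    }
    cur <- cur + seal_noise_trace(np, noise$seal_rms, filter_khz, fs)
    traces[s, ] <- cur
    dw <- do.call(rbind, dwells)
    paths[[s]] <- data.frame(channel = dw[, 1], t_start = dw[, 2],
                             duration = dw[, 3], state = dw[, 4],
                             epoch = dw[, 5])
  }
  rec <- sweep_set(traces, dt, prot,
                   filter_khz = if (is.null(filter_khz)) NA_real_ else filter_khz,
                   meta = list(seed = seed, kind = "single_channel"))
  if (!is.null(filter_khz)) rec <- lowpass(rec, filter_khz)
  list(rec = rec, state_path = paths)
}

#' Simulate gating currents of a two-state voltage sensor
#'
#' Deterministic ensemble gating current
#' `I_g(t) = z e0 N dx/dt`, where `x(t)` is the activated-sensor fraction
#' relaxing exponentially toward its voltage-dependent equilibrium within
#' each epoch, plus filtered seal noise.  On- and off-charges are equal
#' and opposite; a saturating step moves `z e0 N` coulombs in total.
#'
#' @param sensor a [sensor_spec()].
#' @inheritParams simulate_macroscopic
#' @param rc optional list `list(R_MOhm =, C_pF =)` adding a linear RC
#'   leak/capacitive artifact (off by default; used to exercise P/-4).
#' @return A [sweep_set()]; `meta$ig_ideal` holds the noise-free gating
#'   current (pA) for oracle checks.
#' @export
simulate_gating_currents <- function(sensor, prot, noise, seed,
                                     dt = 0.02, filter_khz = 10,
                                     rc = NULL) {
  stopifnot(inherits(sensor, "sensor_spec"),
            inherits(prot, "voltage_protocol"),
            inherits(noise, "noise_spec"))
  counts <- round(prot$epochs$duration / dt)
  np <- sum(counts)
  ns <- n_sweeps(prot)
  fs <- 1 / dt
  seeds <- sweep_seeds(seed, ns)
  traces <- matrix(0, ns, np)
  ideal <- matrix(0, ns, np)
  e0 <- constants()$e0
  for (s in seq_len(ns)) {
    lev <- prot$epochs$level
    if (!is.na(prot$varying_epoch)) lev[prot$varying_epoch] <- prot$sweep_levels[s]
    rr <- sensor_state_laws(sensor, lev)
    x <- sensor_state_laws(sensor, prot$holding)$x_inf
    pos <- 1L
    for (e in seq_along(counts)) {
      ne <- counts[e]
      if (ne == 0L) next
      t_loc <- (seq_len(ne) - 1L) * dt
      xe <- rr$x_inf[e] + (x - rr$x_inf[e]) * exp(-t_loc / rr$tau[e])
      # dx/dt in 1/ms; z e0 N dx/dt in C/ms = 1e15 pA
      ig <- sensor$z * e0 * sensor$N * (rr$x_inf[e] - xe) / rr$tau[e] * 1e15
      ideal[s, pos:(pos + ne - 1L)] <- ig
      x <- rr$x_inf[e] + (x - rr$x_inf[e]) * exp(-ne * dt / rr$tau[e])
      pos <- pos + ne
    }
    set.seed(seeds[s])
    tr <- ideal[s, ] + seal_noise_trace(np, noise$seal_rms, filter_khz, fs)
    if (!is.null(rc)) {
      volts <- command_waveform(prot, dt)[s, ]
      tr <- tr + rc_response(volts, dt, rc$R_MOhm, rc$C_pF)
    }
    traces[s, ] <- tr
  }
  rec <- sweep_set(traces, dt, prot,
                   filter_khz = if (is.null(filter_khz)) NA_real_ else filter_khz,
                   meta = list(seed = seed, kind = "gating",
                               z = sensor$z, N = sensor$N, ig_ideal = ideal))
  if (!is.null(filter_khz)) rec <- lowpass(rec, filter_khz)
  rec
}

# Linear RC membrane response to a commanded voltage waveform:
# I = V/R + C dV/dt.  V in mV, R in MOhm -> V/R in nA = 1e3 pA;
# C in pF, dV/dt in mV/ms -> C dV/dt in fA*1e3 = pA... (pF * mV/ms = fC/ms
# * 1e-3 = 1e-15 C / 1e-3 s = 1e-12 A = pA).
rc_response <- function(volts, dt, R_MOhm, C_pF) {
  i_leak <- volts / R_MOhm * 1000          # mV / MOhm = nA -> pA
  dv <- c(0, diff(volts)) / dt             # mV/ms
  i_cap <- C_pF * dv                       # pA
  i_leak + i_cap
}

#' Response of a purely linear (RC) membrane to a protocol
#'
#' Convenience generator used to validate P/-4 subtraction: a resistor
#' plus linear capacitor patch with no channels.
#'
#' @param prot a [voltage_protocol()].
#' @param dt sampling interval (ms).
#' @param R_MOhm leak resistance (MOhm).
#' @param C_pF linear membrane capacitance (pF).
#' @return A [sweep_set()] of the linear response (pA), unfiltered.
#' @export
linear_rc_response <- function(prot, dt, R_MOhm, C_pF) {
  volts <- command_waveform(prot, dt)
  traces <- t(apply(volts, 1L, rc_response, dt = dt,
                    R_MOhm = R_MOhm, C_pF = C_pF))
  if (n_sweeps(prot) == 1L) traces <- matrix(traces, nrow = 1L)
  sweep_set(traces, dt, prot, meta = list(kind = "linear_rc"))
}
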