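# Shared fixture builders; everything is generated in code at test time.

vt295 <- cngrectify::constants(295)$vt_mV

# the wild-type two-component activation law (z1 = 1.71 at -93.64 mV,
# z2 = 1.07 at +130.73 mV, weight 0.6)
wt_po_law <- function(A = 0.6) {
  two_boltzmann(A,
                boltzmann_component(-93.64, slope_from_charge(1.71)),
                boltzmann_component(130.73, slope_from_charge(1.07)))
}

# single-component law written as the degenerate two-component object
one_po_law <- function(V_mid, k) {
  two_boltzmann(1, boltzmann_component(V_mid, k),
                boltzmann_component(V_mid, k))
}

# fast-gating ohmic model: correlation time ~ tau ms so that short steady
# segments carry many independent samples for moment checks
fast_gate_model <- function(N = 1e4, g = 30, V_mid = 0, k = 25,
                            rate0 = 10, sigma_o = 0) {
  channel_model(one_po_law(V_mid, k),
                rate_law(rate0, 0.05, rate0, 0.05),
                permeation_law(g, g), N = N, sigma_o_over_i = sigma_o)
}

# single constant-voltage step preceded by a short holding epoch
step_protocol <- function(V, dur, hold = 0, hold_dur = 5) {
  voltage_protocol(hold, data.frame(level = c(hold, V),
                                    duration = c(hold_dur, dur)))
}

# multi-voltage "protocol" as one varying epoch (one long step per sweep)
grid_protocol <- function(levels, dur, hold = 0, hold_dur = 5) {
  voltage_protocol(hold, data.frame(level = c(hold, NA),
                                    duration = c(hold_dur, dur)),
                   sweep_levels = levels)
}

# deterministic (noise-free ensemble mean) tail sweeps for a model: the
# analytic relaxation of N channels, used as an oracle input for fitters
deterministic_tails <- function(model, prot, dt = 0.02) {
  volts <- command_waveform(prot, dt)
  counts <- round(prot$epochs$duration / dt)
  traces <- matrix(0, nrow(volts), ncol(volts))
  for (s in seq_len(nrow(volts))) {
    lev <- prot$epochs$level
    if (!is.na(prot$varying_epoch)) lev[prot$varying_epoch] <- prot$sweep_levels[s]
    po_inf <- eval_two_boltzmann(lev, model$po_law)
    tau <- relaxation(lev, model$rate_law)$tau
    isc <- open_pore_current(lev, model$perm)
    po <- eval_two_boltzmann(prot$holding, model$po_law)
    pos <- 1L
    for (e in seq_along(counts)) {
      tt <- (seq_len(counts[e]) - 1L) * dt
      p <- po_inf[e] + (po - po_inf[e]) * exp(-tt / tau[e])
      traces[s, pos:(pos + counts[e] - 1L)] <- model$N * isc[e] * p
      po <- po_inf[e] + (po - po_inf[e]) * exp(-counts[e] * dt / tau[e])
      pos <- pos + counts[e]
    }
  }
  sweep_set(traces, dt, prot, meta = list(kind = "deterministic"))
}

# sample indices of a [t0, t1) window, mirroring the package's indexing
window_index_for_test <- function(rec, window) {
  tt <- (seq_len(ncol(rec$traces)) - 1L) * rec$dt
  which(tt >= window[1] & tt < window[2])
}
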