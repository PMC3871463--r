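test_that("isochronal tails are flat for voltage-independent gating and monotone otherwise", {
  prot <- build_tail_protocol(0, -100, 200, 20, 40, -200, 5, hold_dur = 5)
  # voltage-independent Po (very shallow law pinned open)
  flat <- channel_model(one_po_law(-2000, 100), rate_law(5, 0.05, 0.05, 0.05),
                        permeation_law(30, 30), N = 1e4)
  rec <- simulate_macroscopic(flat, prot, noise_spec(1), seed = 8)
  tails <- isochronal_tails(rec)
  expect_lt(diff(range(tails$value)) / abs(mean(tails$value)), 0.02)
  # monotone Po preset: tail amplitude tracks prepulse Po
  m <- load_preset("cs_like")
  rec2 <- simulate_macroscopic(m, prot, noise_spec(1), seed = 9)
  tails2 <- isochronal_tails(rec2)
  rho <- cor(tails2$V_mV, abs(tails2$value), method = "spearman")
  expect_gt(rho, 0.95)
  expect_error(isochronal_tails(rec2, t_iso = -1), "tail epoch")
  expect_error(isochronal_tails(rec2, t_iso = 100), "tail epoch")
})

test_that("tail normalization: anchoring, plain mode, affine invariance", {
  ct <- curve_table(seq(-100, 200, by = 20), c(3, 2, 4:17) * 1.7 + 2)
  ns <- normalize_tails(ct, "minsub")
  expect_equal(min(ns$value), 0)
  expect_equal(ns$value[ns$V_mV == 200], 1)
  const <- curve_table(seq(-100, 200, by = 20), rep(4.2, 16))
  expect_equal(normalize_tails(const, "plain")$value, rep(1, 16))
  # minsub output is invariant under gain/offset of the raw amplitudes
  set.seed(3)
  for (i in 1:10) {
    g <- runif(1, 0.1, 50) * sample(c(-1, 1), 1); o <- runif(1, -100, 100)
    tr <- curve_table(ct$V_mV, g * ct$value + o)
    ref <- normalize_tails(ct, "minsub")$value
    got <- normalize_tails(tr, "minsub")$value
    if (g < 0) {
      # sign flip moves the minimum; only positive gains preserve minsub
      next
    }
    expect_equal(got, ref, tolerance = 1e-12)
  }
  bad <- curve_table(seq(-100, 180, by = 20), 1:15)
  expect_error(normalize_tails(bad), "anchor")
})

test_that("two-component presets show the activation plateau in normalized tails", {
  m <- load_preset("wt_dma")
  prot <- build_tail_protocol(0, -180, 200, 20, 60, -200, 5, hold_dur = 5)
  rec <- simulate_macroscopic(m, prot, noise_spec(1), seed = 12)
  norm <- normalize_tails(isochronal_tails(rec, t_iso = 0.2,
                                           mode = "extrapolate"), "minsub")
  slope <- diff(norm$value) / diff(norm$V_mV)
  mid <- which(norm$V_mV[-1] > -50 & norm$V_mV[-1] <= 50)
  expect_lt(min(abs(slope[mid])), 0.1 * max(abs(slope)))
})

test_that("steady conductance: flat for ohmic pores, rectifying for Cs- and EA-like", {
  prot <- build_tail_protocol(0, -200, 200, 40, 40, -200, 5, hold_dur = 5)
  flat <- channel_model(one_po_law(-2000, 100), rate_law(5, 0.05, 5, 0.05),
                        permeation_law(30, 30), N = 1e4)
  G <- steady_conductance(simulate_macroscopic(flat, prot, noise_spec(1),
                                               seed = 21))
  expect_lt(max(abs(G$value - 1)), 0.03)
  cs <- steady_conductance(simulate_macroscopic(load_preset("cs_like"), prot,
                                                noise_spec(1), seed = 22))
  expect_gt(cs$value[cs$V_mV == -200], 1)
  ea <- steady_conductance(simulate_macroscopic(load_preset("ea_like"), prot,
                                                noise_spec(1), seed = 23))
  expect_equal(ea$value[ea$V_mV == 200], 1)
  expect_lt(ea$value[ea$V_mV == -200], 0.5)
  rec <- simulate_macroscopic(flat, prot, noise_spec(1), seed = 24)
  expect_error(steady_conductance(rec, window = 100), "overruns")
})

test_that("gamma ratio: identity quotient, masking, grid mismatch", {
  V <- seq(-100, 200, by = 50)
  a <- curve_table(V, c(0.2, 0.4, 0.6, 0.8, 0.9, 0.95, 1), label = "G_ratio")
  expect_equal(gamma_ratio(a, a)$value, rep(1, 7))
  po <- curve_table(V, c(0, 0.005, 0.6, 0.8, 0.9, 0.95, 1))
  gr <- gamma_ratio(a, po)
  expect_true(all(is.na(gr$value[1:2])))
  expect_false(anyNA(gr$value[3:7]))
  b <- curve_table(V + 10, a$value)
  expect_error(gamma_ratio(a, b), "grids differ")
})

test_that("full-pipeline decomposition recovers the generator's gamma and Po laws", {
  # Cs-like preset, N = 1e4: gamma- and Po-ratio within 10% everywhere
  m <- load_preset("cs_like")
  prot <- build_tail_protocol(0, -100, 200, 20, 100, -200, 5)
  rec <- simulate_macroscopic(m, prot, noise_spec(1), seed = 42)
  po <- normalize_tails(isochronal_tails(rec, t_iso = 0.2,
                                         mode = "extrapolate"), "plain")
  po_truth <- eval_two_boltzmann(po$V_mV, m$po_law) /
    eval_two_boltzmann(200, m$po_law)
  expect_lt(max(abs(po$value / po_truth - 1)), 0.1)
  G <- steady_conductance(rec)
  pog <- po[po$V_mV != 0, ]
  gr <- gamma_ratio(G, curve_table(pog$V_mV, pog$value, label = "Po_ratio"))
  g_truth <- chord_conductance(gr$V_mV, m$perm) / chord_conductance(200, m$perm)
  expect_lt(max(abs(gr$value / g_truth - 1), na.rm = TRUE), 0.1)
  # rectification bookkeeping: |I(-200)| > |I(+200)| even though Po rises
  # with depolarization (the inward rectification is carried by gamma_sc)
  rec2 <- simulate_macroscopic(m, grid_protocol(c(-200, 200), 50),
                               noise_spec(1), seed = 43, with_seal = FALSE)
  idx <- which((seq_len(ncol(rec2$traces)) - 1) * rec2$dt >= 35)
  I <- rowMeans(rec2$traces[, idx])
  expect_gt(abs(I[1]), abs(I[2]))
  expect_gt(eval_two_boltzmann(200, m$po_law),
            eval_two_boltzmann(-200, m$po_law))
})

test_that("instantaneous I-V: exact recovery on noiseless tails, round trip on Cs-like", {
  m <- load_preset("cs_like")
  prot <- build_instantaneous_iv_protocol(0, 200, 60, -200, 200, 40, 20,
                                          hold_dur = 2)
  det <- deterministic_tails(m, prot)
  res <- instantaneous_iv(det, blank = 0.1)
  tau_truth <- relaxation(res$tau$V_mV, m$rate_law)$tau
  # relaxation amplitude vanishes near the anchor and at 0 mV (no current)
  keep <- res$tau$V_mV <= 100 & res$tau$V_mV != 0
  expect_lt(max(abs(res$tau$value[keep] / tau_truth[keep] - 1)), 0.02)
  iv_truth <- open_pore_current(res$iv$V_mV, m$perm) /
    open_pore_current(200, m$perm)
  expect_lt(max(abs(res$iv$value[keep] - iv_truth[keep])), 0.02)
  # stochastic round trip at N = 1e4 with seal noise
  rec <- simulate_macroscopic(m, prot, noise_spec(1), seed = 7)
  res2 <- instantaneous_iv(rec, blank = 0.3)
  keep2 <- abs(res2$iv$V_mV) >= 40
  expect_lt(max(abs(res2$iv$value[keep2] /
                      iv_truth[match(res2$iv$V_mV[keep2], res$iv$V_mV)] - 1)),
            0.1)
  # deactivation faster at hyperpolarized potentials (Rb-like range)
  neg <- res2$tau$V_mV <= -80
  expect_gt(cor(res2$tau$V_mV[neg], res2$tau$value[neg],
                method = "spearman"), 0.8)
})

test_that("two-component Boltzmann fit recovers the generating parameters", {
  V <- seq(-180, 200, by = 20)
  tb <- wt_po_law()
  y_min <- eval_two_boltzmann(-180, tb)   # upstream minsub behaviour
  y <- (eval_two_boltzmann(V, tb) - 0) / 1
  curve <- curve_table(V, y, label = "tail_norm")
  fit <- fit_two_boltzmann(curve)
  expect_equal(fit$A, 0.6, tolerance = 1e-3)
  expect_equal(fit$V_mid1, -93.64, tolerance = 1e-3)
  expect_equal(fit$V_mid2, 130.73, tolerance = 1e-3)
  expect_equal(fit$z1, 1.71, tolerance = 1e-3)
  expect_equal(fit$z2, 1.07, tolerance = 1e-3)
  expect_false(fit$degenerate)
  # charge/slope consistency
  expect_equal(fit$z1, charge_from_slope(fit$k1), tolerance = 1e-9)
})

test_that("fit error shrinks monotonically as noise decreases", {
  V <- seq(-180, 200, by = 20)
  truth <- eval_two_boltzmann(V, wt_po_law())
  err <- sapply(c(0.05, 0.01, 0.002), function(s) {
    set.seed(101)
    y <- truth + rnorm(length(V), sd = s)
    f <- fit_two_boltzmann(curve_table(V, y))
    abs(f$z1 - 1.71) / 1.71 + abs(f$z2 - 1.07) / 1.07
  })
  expect_true(all(diff(err) < 0))
})

test_that("noisy replicate fits recover both gating charges within 15%", {
  V <- seq(-180, 200, by = 20)
  truth <- eval_two_boltzmann(V, wt_po_law())
  set.seed(55)
  reps <- replicate(6, truth + rnorm(length(V), sd = 0.03))
  curve <- curve_table(V, rowMeans(reps),
                       sem = apply(reps, 1, sd) / sqrt(6), n = 6)
  fit <- fit_two_boltzmann(curve)
  expect_lt(abs(fit$z1 - 1.71) / 1.71, 0.15)
  expect_lt(abs(fit$z2 - 1.07) / 1.07, 0.15)
})

test_that("single-component data raise the degeneracy flag instead of a spurious z2", {
  V <- seq(-180, 200, by = 20)
  y <- eval_boltzmann(V, boltzmann_component(-20, 20))
  fit <- fit_two_boltzmann(curve_table(V, y))
  expect_true(fit$degenerate)
})

test_that("activation fits: biexponential recovery, single-exp and separation flags", {
  tt <- seq(0, 15, by = 0.02)
  y <- 10 - 4 * exp(-tt / 0.08) - 6 * exp(-tt / 1.5)
  fit <- fit_activation(y, t = tt)
  expect_true(fit$converged)
  expect_equal(fit$tau_f, 0.08, tolerance = 0.01)
  expect_equal(fit$tau_s, 1.5, tolerance = 0.01)
  expect_false(fit$flag_identifiability)
  y1 <- 10 - 6 * exp(-tt / 1.2)
  f1 <- fit_activation(y1, t = tt)
  expect_true(f1$flag_single)
  y2 <- 10 - 4 * exp(-tt / 0.8) - 4 * exp(-tt / 1.6)
  f2 <- fit_activation(y2, t = tt)
  expect_true(f2$flag_identifiability)
})

test_that("bell-shaped tau(V) fit recovers the 0.88-charge transition", {
  V <- seq(-180, 200, by = 20)
  r <- rate_law(0.35, 0.44, 0.35, 0.44)
  tau <- relaxation(V, r)$tau
  fit <- fit_tau_bell(V, tau)
  expect_equal(fit$z_eq, 0.88, tolerance = 1e-6)
  # at measurement-scale scatter the charge comes back within 10%
  set.seed(77)
  tau_n <- tau * exp(rnorm(length(V), sd = 0.07))
  fit_n <- fit_tau_bell(V, tau_n)
  expect_lt(abs(fit_n$z_eq - 0.88) / 0.88, 0.1)
})
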