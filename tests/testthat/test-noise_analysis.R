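test_that("variance-to-mean matches i_sc(1-Po) and is robust to seal noise", {
  # fast-gating model so short stationary segments hold many independent
  # samples; unfiltered so the binomial law applies without attenuation
  V <- c(-150, -100, -50, 50, 100, 150)
  m <- fast_gate_model(N = 1e4, V_mid = 50, k = 60, rate0 = 10)
  prot <- grid_protocol(V, 400)
  rec <- simulate_macroscopic(m, prot, noise_spec(1), seed = 61,
                              filter_khz = NULL)
  nt <- variance_to_mean(rec, window = c(50, 405))
  pred <- open_pore_current(nt$V_mV, m$perm) *
    (1 - eval_two_boltzmann(nt$V_mV, m$po_law))
  expect_lt(max(abs(nt$ratio / pred - 1)), 0.1)
  # tripling the background leaves the subtracted ratio unchanged
  rec3 <- simulate_macroscopic(m, prot, noise_spec(3), seed = 61,
                               filter_khz = NULL)
  nt3 <- variance_to_mean(rec3, window = c(50, 405))
  expect_lt(max(abs(nt3$ratio / pred - 1)), 0.1)
})

test_that("saturated gating leaves no excess noise", {
  m <- fast_gate_model(N = 1e4, V_mid = -2000, k = 50, rate0 = 10)  # Po ~ 1
  rec <- simulate_macroscopic(m, grid_protocol(c(-100, 100), 200),
                              noise_spec(1), seed = 62, filter_khz = NULL)
  nt <- variance_to_mean(rec, window = c(30, 205))
  expect_lt(max(abs(nt$ratio)), 0.02)
})

test_that("measured ratio agrees with the brute-force hidden-path oracle", {
  m <- fast_gate_model(N = 1e4, V_mid = 50, k = 60, rate0 = 10)
  prot <- grid_protocol(c(-100, 60, 140), 400)
  rec <- simulate_macroscopic(m, prot, noise_spec(0), seed = 63,
                              filter_khz = NULL, with_seal = TRUE)
  nt <- variance_to_mean(rec, window = c(50, 405))
  idx <- window_index_for_test(rec, c(50, 405))
  lev <- sort(prot$sweep_levels)
  for (i in seq_along(lev)) {
    s <- which(prot$sweep_levels == lev[i])
    isc <- open_pore_current(lev[i], m$perm)
    path <- rec$meta$n_open[s, idx] * isc
    oracle <- var(path) / mean(path)
    expect_equal(nt$ratio[i], oracle, tolerance = 0.02)
  }
})

test_that("predicted ratio curve: closed forms and round trip", {
  m <- fast_gate_model(N = 1e4, V_mid = -2000, k = 50)   # Po ~ 1
  expect_lt(max(abs(predicted_ratio(m, seq(-200, 200, 50))$value)), 1e-8)
  # Po = 0.5 ohmic 30 pS: ratio = 0.5 * i_sc; 2.4 pA at +160 mV
  m2 <- fast_gate_model(N = 1e4, V_mid = 0, k = 1e9)   # Po = 0.5 at all V
  pr <- predicted_ratio(m2, c(-160, 160))
  expect_equal(pr$value[pr$V_mV == 160], 2.4, tolerance = 1e-6)
  expect_equal(pr$value[pr$V_mV == -160], -2.4, tolerance = 1e-6)
})

test_that("absolute Po from noise: limits, error, simulation recovery", {
  expect_equal(absolute_po_from_noise(0, 2)$Po, 1)
  expect_equal(absolute_po_from_noise(2, 2)$Po, 0)
  expect_error(absolute_po_from_noise(1, 0), "non-zero")
  expect_true(absolute_po_from_noise(-0.5, 2)$out_of_range)
  # generator truth Po = 0.8 recovered within 0.05
  m <- fast_gate_model(N = 1e4, V_mid = 60 - 25 * log(4), k = 25, rate0 = 10)
  V <- 60
  expect_equal(eval_two_boltzmann(V, m$po_law), 0.8, tolerance = 1e-9)
  rec <- simulate_macroscopic(m, step_protocol(V, 600), noise_spec(1),
                              seed = 64, filter_khz = NULL)
  nt <- variance_to_mean(rec, window = c(60, 605))
  po_est <- absolute_po_from_noise(nt$ratio, open_pore_current(V, m$perm))
  expect_lt(abs(po_est$Po - 0.8), 0.05)
})

test_that("open-channel noise inflation: closed forms, bound, monotonicity", {
  expect_equal(open_noise_inflation(0, 0.7), 0)
  expect_equal(open_noise_inflation(0.5, 0.5), sqrt(1.5) - 1,
               tolerance = 1e-12)
  expect_lte(open_noise_inflation(0.5, 0.5), 0.25)
  expect_equal(open_noise_inflation(0.1, 0.5), 0.00995049383620780,
               tolerance = 1e-12)
  r <- seq(0, 1, by = 0.05); p <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(open_noise_inflation(r, 0.5)) > 0))
  expect_true(all(diff(open_noise_inflation(0.3, p)) > 0))
  expect_error(open_noise_inflation(0.1, 1), "undefined")
})

test_that("amplitude histogram + mixture fit count the channels in a patch", {
  perm <- permeation_law(30, 30)
  po <- one_po_law(60, 25)                 # Po = 0.5 at +60 mV
  # dwells ~5 ms: openings well resolved at 10 kHz, so level-transition
  # ramp samples are a negligible fraction of the record
  rates <- rate_law(0.2, 0.05, 0.2, 0.05)
  prot <- step_protocol(60, 400, hold_dur = 1)
  # two channels, well-separated levels (i_sc = 1.8 pA, seal 0.25 pA rms)
  m2 <- channel_model(po, rates, perm, N = 2)
  sim2 <- simulate_single_channel(m2, prot, noise_spec(0.25), seed = 71)
  fit2 <- fit_gaussian_mixture(sim2$rec)
  expect_equal(fit2$n_components, 3L)
  expect_equal(fit2$channel_count, 2L)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)
  # one channel at Po ~ 0.5
  m1 <- channel_model(po, rates, perm, N = 1)
  sim1 <- simulate_single_channel(m1, prot, noise_spec(0.25), seed = 72)
  fit1 <- fit_gaussian_mixture(sim1$rec)
  expect_equal(fit1$channel_count, 1L)
  # channel-free patch: a single (closed) component
  m0 <- fast_gate_model(N = 0)
  rec0 <- simulate_macroscopic(m0, prot, noise_spec(0.25), seed = 73,
                               with_seal = FALSE)
  fit0 <- fit_gaussian_mixture(rec0)
  expect_equal(fit0$channel_count, 0L)
  expect_error(fit_gaussian_mixture(numeric(0)), "empty")
  expect_error(amplitude_histogram(sweep_set(matrix(1, 1, 1), 0.02)),
               "bin_width")
})

test_that("two-channel counting succeeds in at least 95% of seeded runs", {
  perm <- permeation_law(30, 30)
  m2 <- channel_model(one_po_law(60, 25), rate_law(0.2, 0.05, 0.2, 0.05),
                      perm, N = 2)
  prot <- step_protocol(60, 250, hold_dur = 1)
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_single_channel(m2, prot, noise_spec(0.25), seed = 200 + s)
    fit <- fit_gaussian_mixture(sim$rec, max_points = 4000)
    if (fit$channel_count == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("DMA-like noise grows super-linearly with |V| at hyperpolarized voltages", {
  m <- load_preset("dma_like")
  pred <- predicted_ratio(m, c(-200, -100))
  # |sigma^2/I| growth outpaces the |V| growth (open-pore rectification,
  # with Po remaining low in this range)
  expect_gt(abs(pred$value[1]) / abs(pred$value[2]), 2)
  expect_lt(eval_two_boltzmann(-100, m$po_law), 0.3)
  rec <- simulate_macroscopic(m, grid_protocol(c(-200, -100), 400),
                              noise_spec(1), seed = 75, filter_khz = NULL)
  nt <- variance_to_mean(rec, window = c(50, 405))
  expect_gt(abs(nt$ratio[nt$V_mV == -200]) / abs(nt$ratio[nt$V_mV == -100]), 2)
})
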