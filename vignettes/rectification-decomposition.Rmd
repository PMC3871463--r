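---
title: "Decomposing CNG-channel rectification: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing CNG-channel rectification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cngrectify)
```

# The scientific problem

A macroscopic current–voltage relation from a patch of N identical
channels factorizes as

$$ I(V) = N \, i_{sc}(V) \, P_o(V), \qquad i_{sc}(V) = \gamma_{sc}(V)\,V, $$

so rectification (|I| differing at ±V) can be produced by the open pore
(voltage-dependent single-channel conductance $\gamma_{sc}$), by gating
(voltage-dependent open probability $P_o$), or by both in opposite
directions. In CNGA1 channels the permeant ion decides which factor
dominates: large alkali cations (Rb⁺, Cs⁺) rectify inwardly through
$\gamma_{sc}$ while $P_o$ *increases* with depolarization; organic
cations (MA⁺, DMA⁺, EA⁺) rectify outwardly through $P_o$ while
$\gamma_{sc}$ falls with depolarization. This package implements the
measurement chain that separates the two factors and the synthetic
recordings needed to validate every stage.

# Models

## Equilibrium gating

$P_o(V)$ is a weighted sum of two Boltzmann sigmoids,

$$ P_o(V) = A\,B_1(V) + (1-A)\,B_2(V), \qquad
   B_i(V) = \frac{1}{1+e^{(V_{mid,i}-V)/k_i}}, $$

the standard description when two distinct charge systems underlie
activation (a single transition is the degenerate case $A \in \{0,1\}$).
Slope factors are stored in mV and converted to equivalent charges as
$z_i = RT/(k_i F)$ at $T = 295$ K ($RT/F \approx 25.42$ mV); all
RT/F arithmetic converts to volts internally.

## Kinetics

Relaxation follows a minimal Eyring form
$\alpha(V) = a_0 e^{z_a FV/RT}$, $\beta(V) = b_0 e^{-z_b FV/RT}$, giving
$\tau(V) = 1/(\alpha+\beta)$ — bell-shaped whenever $z_a + z_b > 0$ —
and a rate-implied equilibrium that is algebraically a single Boltzmann
of charge $z_a + z_b$. The bell fit of measured activation time
constants (`fit_tau_bell`) splits the equivalent charge 50/50 between
the forward and backward rates; the data constrain only the total
$z_{eq}$, so the split is a convention, not an inference.

Because the two-component equilibrium law has no published kinetic
scheme attached, the macroscopic generator treats the channel as a
single *effective* two-state gate whose equilibrium follows the
two-component law and whose time constant follows the rate law. This
keeps the binomial variance law $\sigma^2 = i_{sc} I - I^2/N$ exact at
every N (the property all the noise analysis rests on) at the cost of
not reproducing multi-exponential macroscopic relaxations. The
double-exponential activation fitter is validated against analytic
biexponential traces instead.

## Open pore

$\gamma_{sc}(V)$ is a sigmoid chord conductance,
$\gamma(V) = g_+ + (g_- - g_+)/(1 + e^{V/V_s})$, so $i_{sc}(0) = 0$ in
symmetrical solutions and the hyperpolarized/depolarized limits are set
directly by the preset. This is an artifact parameterization: presets
are calibrated to the qualitative conductance ratios of each permeant
ion (about 3× at −200 vs +200 mV for Rb⁺-like, 4× for Cs⁺-like, a
mild decrease with depolarization for the organic cations), not fitted
to any published trace. The form's transition is pinned at 0 mV, which
is why stronger statements (e.g. conductance halving *within* the
−200…−100 mV range) are outside its reach.

## Voltage sensor

Gating currents use a two-state sensor: activated fraction $x(t)$
relaxing exponentially toward a Boltzmann equilibrium of charge $z$
centred at $V_{half}$, with $I_g = z e_0 N\,dx/dt$
($e_0 = 1.6\times10^{-19}$ C). By default the relaxation time constant
is a voltage-independent parameter $\tau_0$ (default 1 ms), matching how
predicted gating currents are customarily simulated; tying $\tau$ to a
symmetric Eyring law of the same $z$ would collapse it by orders of
magnitude at ±200 mV and invalidate the S/N analysis the map is built
for. A `rate_law` override is available when voltage-dependent sensor
kinetics are wanted.

# Estimators and their parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `t_iso` (isochronal latency) | 0.5 | ms | past the capacitive blank, early in the tail decay |
| `avg_window` | 0.1 | ms | averages a few samples without biasing the read |
| tail mode | `point` | — | `peak` and `extrapolate` (exponential back-extrapolation to the jump) are provided because the published measurement latency is marked only graphically; extrapolation removes the $e^{-t_{iso}/\tau}$ compression when deactivation is fast |
| normalization anchor | +200 | mV | the subscript convention of the ratio curves; configurable for protocols without +200 |
| `floor` (Po masking) | 0.01 | — | quotient points with Po ratio below it are masked, not divided |
| steady window | 10 | ms | end of the prepulse epoch, past activation |
| `blank` (instantaneous IV) | 0.3 | ms | excludes the capacitive/filter transient after the jump |
| filter | 4-pole Bessel, 10 | kHz | patch-amplifier emulation; −3 dB at the cutoff |
| seal noise | 1 | pA r.m.s. | at the 10 kHz bandwidth; generated white at 50 kHz and scaled by the filter's equivalent-noise-bandwidth gain so the quoted figure refers to the stated bandwidth |
| mixture selection | BIC over 1–4 comps | — | samples are thinned to ≤5000 quasi-independent points first; BIC over strongly autocorrelated samples buys spurious components |
| S/N thresholds | 4, 6 | — | class boundaries of the detectability map |

Weighted Boltzmann fits use per-point SEM weights only when the curve
pools more than one patch; otherwise the fit is unweighted. The
two-component fit is run from a small grid of starts (weights 0.3/0.5/0.7,
slopes 12/25 mV, midpoints at the voltage quartiles) with the
Levenberg–Marquardt optimizer called directly (`nls.lm`), because the
`nls` model wrapper refuses the singular gradients that legitimately
arise when the data contain only one component; such fits converge to a
boundary weight and are flagged `degenerate` via the parameter
covariance instead of reporting a spurious second charge. Components
are ordered by midpoint (smaller = component 1).

Background subtraction in the noise analysis is performed on variances
(quadrature), which is exact for independent sources; a `mode = "rms"`
switch reproduces the literal r.m.s. difference some legends quote. The
open-channel noise bound uses
$\sigma_{tot}^2 = \sigma^2 + \sigma_e^2$ with
$\sigma_e^2 = N P_o \sigma_o^2$ — the only decomposition in which N and
$i_{sc}$ cancel to leave the two quoted control parameters
($\sigma_o/i_{sc}$ and $P_o$) and which reproduces the ≤25% bound at
$\sigma_o/i_{sc} = 0.5$, $P_o = 0.5$.

# What the generator emulates — and what it does not

Emulated: 50 kHz sampling; 10 kHz 4-pole Bessel filtering; binomial
(exact per-channel two-state propagator) gating noise at any N;
event-driven single-channel dwells with exponential statistics;
Gaussian open-channel noise $\sigma_o = r\,i_{sc}$; ~1 pA seal noise
with paired agonist-free background sweeps; deterministic ensemble
gating currents with conserved on/off charge; an optional linear RC
artifact solely to exercise P/−4 subtraction; per-sweep random streams
split from one master seed (bit-identical reruns, sweep-order
independence).

Not emulated: proton block and its pH dependence; flicker and
subconductance states (the known source of residual discrepancy between
measured and predicted noise in Cs⁺); rundown, series-resistance and
liquid-junction artifacts; capacitive transients beyond the linear RC
option; multi-exponential macroscopic kinetics. Passing round-trip
tests therefore demonstrates that the estimators are unbiased under the
model's assumptions — not that real recordings satisfy those
assumptions.

# Numerical choices

- Epochs are half-open `[start, end)` with t = 0 at sweep start; epoch
  durations should be multiples of the sampling interval (builders
  produce them; hand-built protocols are rounded to the grid).
- The Bessel filter is designed from the analog prototype poles (roots
  of the reversed Bessel polynomial, scaled to −3 dB at unit frequency)
  via the bilinear transform with cutoff prewarping; DC gain is exactly 1.
- Charge integration is trapezoidal at native dt in fC (pA·ms). A
  discontinuous-onset exponential sampled at 50 kHz carries an intrinsic
  half-sample ambiguity of $dt/(2\tau)$ (~1% at τ = 1 ms), common to
  any digitized measurement of the same waveform; conservation
  statements compare like with like.
- Exponential tail fits are multi-start; a trace whose fitted amplitude
  is within noise of zero is reported as flat (amplitude 0, τ = NA)
  rather than failing the sweep.
- The detectability map's default S/N uses the analytic peak
  $z e_0 N/\tau$; the `simulated` variant measures the noisy filtered
  maximum, which is biased upward by a few noise s.d. — the map
  documents the estimator, tests bound the bias.

# Problem sizes

The validation suite simulates patches of $10^3$–$10^5$ channels,
steady segments of 100–600 ms per voltage, single-channel records of
0.25–4 s, 100-seed channel-counting repetitions and 50-seed charge
integrations; these sizes give the moment estimators standard errors a
factor ≥2 below the tolerances being asserted while keeping the whole
suite under a minute of simulation per module.

# Known limitations

- The tail-derived $P_o$ ratio is exact only as $t_{iso}/\tau \to 0$;
  the `extrapolate` mode removes the bias under the single-exponential
  assumption but inherits its failure modes (flagged per point).
- The preset component weight A = 0.6 is a free choice: no published
  value exists for any fitted curve. All recovery statements are
  conditional on the preset, not on the biology.
- Gaussian-mixture channel counting assumes resolvable, equidistant,
  equal-noise levels; unresolved flicker (fast gating relative to the
  filter) biases it downward, which is the physically expected failure.
- `read_atf` supports the package's documented tab-separated dialect
  (version line, count line, optional records, titles, data), not every
  ATF file in the wild; binary ABF is out of scope.
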