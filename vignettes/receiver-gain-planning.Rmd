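---
title: "Receiver-gain calibration and SNR-optimal acquisition planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receiver-gain calibration and SNR-optimal acquisition planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgplan)
```

## The model

The amplitude of an NMR signal recorded through a receive chain factors as

$$\mathrm{Signal} = A \cdot f(RG) \cdot \sin\alpha \cdot P \cdot C,$$

with $A$ a hardware coefficient independent of the other factors, $f(RG)$
the gain function of the receiver (equal to $RG$ for a linear receiver),
$\alpha$ the excitation flip angle, $P$ the nuclear polarization (a
fraction), and $C$ the spin concentration in mol/L. The noise, by
contrast, is *not* a simple function of the gain: receivers distribute
amplification over several stages, and the internal level plan that
allocates gain across them can switch configuration at a particular gain
setting, changing the output noise floor discontinuously. The SNR as a
function of $RG$ is therefore an empirical curve, measured once per
system with a reference sample at known $(\alpha_{ref}, P_{ref},
C_{ref})$, and transferred to any other conditions through the ratios

$$SNR(RG) = SNR_{ref}(RG)\cdot
  \frac{\sin\alpha}{\sin\alpha_{ref}}\cdot
  \frac{P}{P_{ref}}\cdot \frac{C}{C_{ref}}.$$

Planning an acquisition is then the constrained maximization

$$SNR(RG,\alpha)\to\max,\qquad \mathrm{Signal}\le S_m,\qquad
  0<\alpha\le\alpha_m\le 90^\circ,$$

where $S_m$ is the largest FID amplitude the digitizer records faithfully
(the receiver range threshold RRT, or a safety fraction of it) and
$\alpha_m$ caps the flip angle — essential in hyperpolarized experiments,
where each pulse consumes polarization by $\cos\alpha$ and the
magnetization cannot be regenerated.

The package realizes the maximization on a grid: SNR and FID-amplitude
maps over $(RG, \alpha)$, an overflow mask, and the argmax of the masked
SNR. A Karush–Kuhn–Tucker treatment of the same program is possible but
was deliberately not implemented: the grid is exhaustive over the actual
(discrete) hardware settings, trivially robust to the empirical,
non-smooth $SNR_{ref}(RG)$, and is verified in the test suite against an
independently coded brute-force scan.

### Two calibrated channels

The overflow constraint acts on the *FID amplitude* — the time-domain
signal the ADC digitizes — while SNR is quantified on *spectral
integrals*. These two scales are related but not identical (the FID
maximum depends on linewidth and off-resonance, the integral does not),
so the calibration curve carries both: `signal_integral` (and the derived
per-point SNR) for the objective, and `fid_max` for the constraint. Both
are fitted with through-origin slopes versus $RG\times C$; the zero
intercept encodes zero signal at zero gain. The closed-form *clipping
product* $k = \max(\sin\alpha\cdot RG)$ and the flip-angle limit
$\arcsin(\min(1, k/RG))$ use the FID channel only.

### Reference polarization is stored, not recomputed

For thermally polarized references the spin-1/2 Boltzmann form
$P=\tanh(h\nu/2k_BT)$ is available (`thermal_polarization()`, default
298 K), but a curve's $P_{ref}$ is always an explicit stored value: the
temperature of a particular calibration is an experimental fact, not
something to re-derive silently. The $\tanh$ form is used for every
registered nucleus, including the spin-1 deuteron — at the ~$10^{-5}$
polarizations involved it is linear in $\gamma B/T$ to better than
$10^{-6}$ relative (a tested property), and only polarization *ratios*
enter the planning equations.

## Quantification choices

* **SNR convention**: peak integral ÷ noise RMS, matching
  integration-based quantification; the peak-amplitude convention is
  available as an option (`snr_of(..., convention = "amplitude")`).
* **No apodization, ever**: windowing alters both signal and noise and
  would bias the calibration. Zero filling is allowed; integrals are
  normalized by bin width so they are invariant to it (tested to 1%).
* **Noise region**: RMS of the real part after a linear detrend, over
  either a user-given interval or the contiguous window (default 10% of
  the spectrum, configurable) of minimal standard deviation among windows
  disjoint from declared peak regions. The integration limits and window
  width used by a given spectrometer vendor's tools are generally
  undocumented; here they are explicit parameters.
* **Baseline**: a zero-order offset (median of the real part) is removed
  before integration; the linear detrend applies only within the noise
  window. Anything stronger would interact with the no-apodization rule.
* **Clipping is per quadrature channel**: the two ADCs digitize real and
  imaginary parts independently, so a sample clips when either $|Re|$ or
  $|Im|$ reaches the ceiling; the boundary counts as clipped. The
  magnitude-FID plateau near RRT seen on instruments then emerges rather
  than being imposed.
* **RRT estimation**: a clipped channel shows runs of samples pinned at
  its maximum; runs of ≥ 4 samples within 0.1% (relative) of the
  per-channel maximum are taken as plateau and their median is the RRT
  estimate. Unclipped records are ignored; purely unclipped input is an
  error, since the ceiling is simply not visible in it.

## Calibration-curve numerics

* **Interpolation** of $SNR_{ref}$ between measured gains is
  piecewise-linear, exact at the knots, and never extrapolates.
* **Discontinuity handling**: adjacent gains where SNR falls by more than
  a threshold (default 10%) are flagged as a level-plan switch. Because
  the switch is a hardware step and not a smooth feature, interpolation
  refuses to bridge the flagged segment: queries inside it snap to the
  nearer measured knot. The default planning grid includes the measured
  knots so that a tie inside a snapped segment resolves to the measured
  gain itself.
* **Tie-breaking** at equal SNR prefers lower RG, then lower $\alpha$:
  the lower gain keeps the recorded signal far from the ceiling at no
  sensitivity cost.
* **Gains in dB** (benchtop consoles) convert with the amplitude
  convention $RG_{lin} = 10^{\mathrm{dB}/20}$; curves always store linear
  gains plus an annotation of the original unit.
* **Averaged acquisitions** are stored per scan (signal and FID maximum
  divided by the number of averages) so curves from different averaging
  are comparable; per-point SNR is kept as the *measured* ratio, since
  dividing only the numerator would change its meaning.
* **Default grids**: $\alpha$ from 0.1° to $\alpha_m$ in 0.1° steps; RG
  on the receiver's discrete settable list when provided, otherwise 400
  log-spaced points (plus the knots) across the calibrated range —
  log-spacing mirrors the roughly geometric spacing of settable hardware
  gains.

## What the simulator emulates — and what it does not

`noise_model()` composes an input-referred term (amplified with the
signal) and an output floor, with a multiplicative penalty on the floor
above a switching gain:

$$\sigma(RG) = \sqrt{(\sigma_{in} f(RG))^2 +
  (\sigma_{out}\,\mathrm{penalty}(RG))^2}.$$

The implied SNR $\propto f(RG)/\sigma(RG)$ reproduces, by parameter
choice, the three shapes seen across real systems: asymptotic saturation,
dip-and-recover, and monotone growth. Three presets ship:

* `"saturating"` ($\sigma_{in}=1,\ \sigma_{out}=12$): SNR plateaus
  around RG 30 — a proton-channel shape.
* `"dip"` ($\sigma_{in}=1,\ \sigma_{out}=5$, switch at RG 18, penalty
  5.7022): SNR plateaus by RG 10–18, loses 40% of its value between
  RG 18 and 20.2, and recovers to just below the pre-switch maximum at
  RG 101. The penalty is the closed-form solution of
  $SNR(20.2)=0.6\,SNR(18)$ for this $\sigma$ pair; the other parameters
  place the plateau and the near-equality of RG 18 and RG 101 where
  X-nucleus channels of 7–9.4 T systems show them.
* `"monotone"` ($\sigma_{in}=1,\ \sigma_{out}=36$): SNR still rising at
  the maximum gain, with declining rate — a higher-frequency-path shape.

These are *qualitative* stand-ins chosen once: measured hardware curves
are system-, frequency- and hardware-revision-specific, and no preset
claims to reproduce any particular instrument's numbers. FIDs are
single-resonance decaying exponentials with circular complex Gaussian
noise (independent per channel and sample) and hard per-channel limiting
at ±RRT. Not modeled: multi-peak spectra, $B_1$ inhomogeneity,
radiation damping, receiver phase drift, DNP buildup and transfer
physics, and signal compression *below* the ceiling (real receivers
distort somewhat before clipping outright). Passing tests therefore
demonstrate the correctness of the calibration/planning machinery on the
stated receiver model, not the behavior of any physical spectrometer.

In the hyperpolarized series generator, polarization before shot $n$ is
$P_n = P_0 e^{-t_n/T_1}\prod_{m<n}\cos\alpha_m$, repetition times can be
jittered uniformly within a range (consoles insert variable compilation
delays), and per-shot integrals receive Gaussian noise at the gain's
$\sigma$. `normalize_series()` rescales alternating-gain shots by the
*calibrated* signal ratio — by default factor-only, matching the
experimental practice; the $\cos\alpha$ consumption correction is opt-in
(`correct_flip = TRUE`), in which case the fitted monoexponential
estimates $T_1$ itself rather than the effective decay. The fit is
`nls()` seeded by a log-linear regression, with a Wald 95% interval on
the decay time.

## Problem sizes in the shipped tests

The test suite and acceptance script run entirely from code-generated
data: 4096–16384-point FIDs for spectral tests, 14-gain sweeps for the
dip scenario, 100-replicate sweeps (1024 points) for slope-recovery
statistics, 50-replicate 46-shot series for $T_1$ coverage, and 1000
randomized planning fixtures for overflow safety — sizes chosen so the
whole suite completes in well under a minute while keeping the
statistical assertions comfortably powered.

## Known limitations

* The relation between the integral and FID-max slopes depends on
  lineshape and off-resonance; it is carried as data (two measured
  channels), never derived from a formula.
* Interpolation inside a flagged discontinuity segment is a convention
  (snap to nearer knot); the true SNR between two gains that straddle a
  level-plan switch is unknowable without measuring there.
* The planner treats the calibration as exact; it does not propagate
  measurement uncertainty into the plan. With a noisy calibration, gains
  whose SNR differs by less than the calibration error are effectively
  tied — the lower-RG tie-break is then the safe choice.
* dB-gain receivers that re-scale signals internally (automatic
  RG-compensation) violate the through-origin linear model; for such
  systems the curve remains usable empirically, but the fitted slopes and
  the clipping product lose their closed-form meaning.
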