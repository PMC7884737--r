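---
title: "Models and numerical choices in hemowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in hemowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowave)
```

hemowave analyses invasive aortic pressure--flow recordings of the kind
acquired in large-animal stent-graft experiments: a catheter pressure in
the ascending aorta, an aortic flow or velocity signal, an ECG for beat
gating, and scalar B-mode diameters of the target segment. This
vignette documents the models, the tunable parameters and their
defaults, the synthetic data the package validates itself against, and
the numerical choices a maintainer would want spelled out.

## The analysis chain

**Beat gating and ensemble averaging.** Beats begin at the R-wave peak.
The detector smooths the ECG with a 10 ms moving average, integrates
the squared derivative over 20 ms, thresholds adaptively at 25% of the
global maximum with a 200 ms refractory period, and refines each
candidate to the local ECG maximum. It is designed for clean laboratory
signals, not ambulatory ECG. Eight consecutive beats (configurable) are
cut from R peak to R peak, linearly resampled to the median RR length
-- the literature is generally silent on how unequal beat lengths are
harmonised, and linear interpolation at 1000 Hz introduces errors far
below measurement noise -- and averaged pointwise, attenuating
uncorrelated noise by about $1/\sqrt{8}$.

**Input impedance.** The averaged beat is treated as one period of a
periodic signal. With pressure in dyn/cm$^2$ and flow in cm$^3$/s, the
harmonic impedance is $Z(k) = \hat P(k) / \hat Q(k)$. $Z_0$, the
modulus at DC, equals mean pressure over mean flow (total LV
afterload). The characteristic impedance $Z_c$ is taken as the
unweighted arithmetic mean of $|Z|$ over all harmonics of the beat
fundamental lying in the closed band 1--10 Hz. A continuous-frequency
average is not available from a single periodic beat, so the
harmonic-mean-of-moduli reading is implemented; whether one instead
interpolates a modulus curve across the band is a genuinely open
convention, and the band edges are arguments (`f_lo`, `f_hi`).
Harmonics whose flow coefficient falls below $10^{-6}$ of the
fundamental's are masked rather than divided through.

**Wave separation.** With the diastolic offset removed
($\tilde p = P - \min P$) and a given $Z_c$,
$$P_f = \tfrac{1}{2}(\tilde p + Z_c Q), \qquad
  P_b = \tfrac{1}{2}(\tilde p - Z_c Q),$$
which reconstructs $\tilde p$ and $Q$ exactly. Reflection magnitude
and index use peak-trough amplitudes: $RM = |P_b|/|P_f|$,
$RI = RM/(1+RM)$. Published tables sometimes reference the forward
wave to the absolute pressure level instead of the diastolic baseline;
`separate_waves()` therefore also reports `pf_peak_abs_mmhg`, but RM
and RI always use amplitudes. Removing the offset before separation
matters: a constant baseline is not travelling wave energy, and RM is
invariant to it by construction.

**Wave intensity.** $WI = (dP/dt)(dU/dt)$ from crude sample-to-sample
forward differences at the recording rate (default 1000 Hz), no
smoothing. The raw-increment form $dP\,dU$ is available
(`raw_increments = TRUE`; values scale by $f_s^2$), but the
time-normalised form is the default because the conventional units
mmHg·m/s$^3$ are only dimensionally consistent with derivatives. W1 is
the maximum over the first 40% of ejection, W2 the maximum from 60% of
ejection to 50 ms past its end, and NW the minimum between the W1 and
W2 peak times. These windows translate the phase descriptions "early
systole", "end of ejection" and "mid systole" into something
computable; the fractions are arguments, and the ejection window itself
comes from flow thresholds (onset at 5% of peak flow, end at the first
downward zero-crossing or fall below 2% after the peak -- both
overridable, both chosen to tolerate baseline noise). NW is reported
as the trough *value* of the trace, not an area under the negative
lobe, matching the peak-extraction convention used for W1 and W2.

**Stiffness indices.** From scalar diameters and the ascending
pressures measured during imaging:
$$\beta = \frac{\ln(\mathrm{SBP}/\mathrm{DBP})}{(D_{max}-D_{min})/D_{min}},
  \qquad
  \mathrm{PWV} = \sqrt{\frac{A_d\,\mathrm{PP}}{\rho\,\Delta A}},$$
with circular cross-sections ($A = \pi(D/2)^2$; B-mode yields a single
diameter, so no ellipse correction is attempted), PP converted to Pa
and $\rho = 1060$ kg/m$^3$ by default. $\beta = 0$ when SBP = DBP
(zero log-ratio is well defined); only inverted pressures or
$D_{max} \le D_{min}$ are errors. Aggregation across subjects must be
mean-of-individual-values, never formula-of-means -- `build_report()`
works per subject for exactly this reason.

**Statistics.** `wilcoxon_paired()` drops zero differences, mid-ranks
ties, takes $T = \min(W^+, W^-)$ and by default uses the asymptotic
normal approximation *without* continuity correction:
$z = (T - n(n+1)/4)/\sqrt{n(n+1)(2n+1)/24}$, two-sided. For $n = 7$
uniformly signed changes this yields $p = 0.018$, the convention common
in small invasive studies; the exact sign-flip enumeration
(`method = "exact"`) gives $2/2^7 \approx 0.016$ and is preferable on
first principles, but the asymptotic form is the default so results
line up with that reporting tradition. `pearson_correlation()` reports
the $t$-based $p$ on $n-2$ df both one-sided (tail matching the sign of
$r$; listed first because directional correlations at $n = 7$ are
typically reported that way) and two-sided.

## The synthetic generator

`generate_recording()` implements a lossless uniform tube with
characteristic impedance $Z_c$ and one discrete reflection site:
per beat the forward flow is a half-sine over the ejection window,
forward pressure is $Z_c Q_f$ (1 mmHg = 1333.22 dyn/cm$^2$, applied by
one conversion utility), and the backward wave is
$\Gamma P_f(t - 2\tau)$ -- or, in reverberant mode, the geometric train
$\sum_{k\ge1} \Gamma^k P_f(t - k\,2\tau)$ truncated when a term drops
below $10^{-6}$ of the first, far beneath any noise floor. Measured
pressure adds the diastolic level and optional white noise; measured
flow is $(P_f - P_b)/Z_c$ plus noise; velocity is flow over the probe
area; the ECG is a 20 ms triangular R complex at each beat onset
(enough for the gating detector without modelling a full PQRST).
RR jitter perturbs beat periods, not within-beat shape, so ensemble
averaging is exercised meaningfully.

Defaults are fixed once, as a plausible large-animal baseline: 120 bpm,
diastolic 90 mmHg, $Z_c = 65$ dyn·s·cm$^{-5}$, peak flow 350 mL/s
(cardiac output $\approx 4.7$ L/min), ejection 35% of the cycle, probe
area 3.1 cm$^2$ (a ~2 cm aorta), $\Gamma = 0.2$ (a modest healthy-state
reflection), and $2\tau = 60$ ms -- a reflection site ~12 cm downstream
at ~4 m/s wave speed. The half-sine is a stand-in, not a claim of
fidelity to any species' flow profile: the properties the pipeline is
tested on (conservation, separation identities, $Z_c$ flatness without
reflection, NW monotonicity in $\Gamma$) are shape-independent, which
is why a closed-form wave was chosen. What the generator does *not*
emulate: multi-branch reflection networks, viscoelastic wall damping,
frequency-dependent $Z_c$, catheter dynamics, baseline drift. Passing
its recovery tests therefore validates the numerics of the chain, not
the physiological interpretation of any real recording.

## Numerical behaviour worth knowing

**$Z_c$ band-average bias.** For a single reflection the input
impedance modulus oscillates around $Z_c$ with frequency period
$1/2\tau$; averaging five harmonics (2--10 Hz at 120 bpm) leaves a
residual oscillatory bias whose sign and size depend on $2\tau$. At the
default 60 ms delay the estimate runs ~9% low at $\Gamma = 0.2$; near
$2\tau = 90$ ms the harmonic phases sit in quadrature, the nulls
average out, and recovery is within ~4% up to $\Gamma = 0.4$. The
recovery tests use that quadrature delay; the estimation-error
monotonicity in $\Gamma$ is tested at the default. This bias is a
property of the band-average definition itself, not of the
implementation, and it is one reason $Z_c$ from 1--10 Hz averaging
should be read as a convention-laden index rather than a tube constant.

**NW timing.** For a half-sine forward wave,
$WI \propto \dot Q_f(t)^2 - \Gamma^2 \dot Q_f(t-2\tau)^2$, whose
minimum is anchored where $\dot Q_f$ vanishes -- mid-ejection -- with
only a $\Gamma^2$-order correction that drifts with the echo delay
(~1 ms per 15 ms of delay at $\Gamma = 0.4$). NW timing is therefore a
mid-systolic marker here, not a transit-time estimator.

**Degenerate inputs.** Division hazards are errors, never infinities:
zero mean flow (Z0 undefined), no usable harmonic in the $Z_c$ band,
$Z_c \le 0$, $D_{max} = D_{min}$, zero pulse pressure, zero-variance
correlations, all-zero paired differences. Non-finite samples are
rejected on read unless linear interpolation is explicitly requested
(the repair count is logged). Exact ties in $|{\rm differences}|$ get
mid-ranks with no variance correction, matching the convention the
asymptotic formula reproduces.

**Problem sizes.** The validation suite runs on 9--12 beat records at
1000 Hz (~6,000 samples), 30--40 Monte Carlo seeds for the averaging
property and 2,000 null replicates for the test-size check -- small
enough to re-run habitually, large enough that the stochastic checks
have comfortable margins.

## Worked example

```{r example, eval = FALSE}
sim <- generate_recording(synthetic_config(gamma = 0.2,
                                           round_trip_delay_s = 0.09))
m <- analyze_record(sim$record,
                    diameters = diameter_measurement(19.7, 18.4))
m[c("pp_mmhg", "zc_dyn_s_cm5", "rm", "ri", "w1_mmhg_m_s3",
    "nw_mmhg_m_s3", "beta", "pwv_m_s")]
attr(m, "stages")$wave_intensity
```

## Known limitations

Single-tube, single-reflection world; no windkessel afterload, no
viscoelasticity. The R-peak detector assumes a dominant, impulse-like
QRS. Flow/velocity interconversion requires a user-supplied probe
area -- measured flowmeter and velocity channels are never silently
reconciled. The asymptotic signed-rank default is a reporting
convention, deliberately chosen over the exact test for comparability
with the small-cohort literature it mirrors; at $n = 7$ the two can
disagree in the second decimal of $p$.
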