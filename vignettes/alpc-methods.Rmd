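---
title: "Estimating multiple steady-state response latencies by phase coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multiple steady-state response latencies by phase coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpc)
```

## The problem

Auditory steady-state responses (ASSRs) are EEG oscillations phase-locked
to periodicities in a sound. When a multi-tone complex with carriers
$f_1, \dots, f_I$ drives a nonlinearity of order $R$, the response contains
combination products at $|\sum_i a_i f_i|$ for integer coefficients with
$\sum_i |a_i| \le R$ (same parity as $R$ for a homogeneous $x^R$ system).
Different stages of the auditory pathway behave as different nonlinear
subsystems with different conduction delays, so the recorded channel is a
*mixture*

$$y(t) = \sum_{m=1}^{M} \xi_m \sum_r \psi_{mr}\, x_m^r(t - \tau_m) + \varepsilon(t),$$

and the scientific quantity of interest is the set of latencies
$\tau_1, \dots, \tau_M$.

A steady-state component carries its latency only through its phase. If
$N$ components share one latency $\tau$, their measured phases
$\alpha_i$ and initial phases $\varphi_i$ satisfy
$\alpha_i + \tau\omega_i = 2\pi n_i + \varphi_i + \epsilon_i$ with unknown
integers $n_i$. The package estimates $\tau$ by minimizing the **mean
phase error** (MPE),

$$\mathrm{MPE}(\tau) = \frac{1}{N}\sum_{i=1}^{N}
  \bigl|e^{j(\alpha_i + \tau\omega_i)} - e^{j\varphi_i}\bigr| \in [0, 2],$$

which sidesteps the $2\pi$ wrap-around entirely: no cycle counts are
needed during the search, and they are recovered afterwards from the
optimum. At the optimum the absolute phase lags
$2\pi n_i + \varphi_i - \alpha_i$ fall on a line through the origin whose
slope $d_\phi$ obeys the classical apparent-latency (group-delay) rule
$\tau = d_\phi / 2\pi$; the package asserts this consistency on every
estimate.

## Zero-phase stimuli and time compensation

For a multi-cosine stimulus with all initial phases zero, *every*
distortion product again has zero initial phase, so $\varphi_i \equiv 0$
and no knowledge of the nonlinearity is needed. Analysis windows never
start at stimulus onset (the first 300 ms are contaminated by transient
evoked potentials), and an ongoing window starting at $\Delta_t$ yields a
*pseudo-latency* $\tau_p = \tau_e - \Delta_t$, possibly negative; the true
latency is restored by time compensation, $\tau_e = \tau_p + \Delta_t$.
For zero-phase *sine* carriers only the even-order pure-difference
products keep a common initial phase; in the carrier waveform's own
reference that phase is $\pi/2$, which `predict_initial_phase()` produces
(and cross-checks against a numeric synthesis oracle in the tests).

## Sequential forward selection

With several subsystems the candidate components do not share one
latency. `sfs_select()` grows a subset greedily from a start frequency
(or pair): at each step the candidate whose inclusion yields the smallest
re-optimized MPE is tried, and committed only while

1. the increase of the *summed* phase-error length
   ($n_\text{new}\,\mathrm{MPE}_\text{new} - n_\text{old}\,\mathrm{MPE}_\text{old}$,
   i.e. the residual chord contributed by the newcomer) stays below 0.1;
2. the MPE stays below 0.5;
3. (pair start) the latency moves by less than 5 ms.

Criterion 1 is deliberately formulated on the summed error rather than on
the mean. A component from a foreign subsystem whose latency offset is
nearly an integer number of its periods contributes only a small residual
chord — in the worked two-subsystem example, 98 Hz with a 30-ms latency
offset sits within 0.6 ms of three full periods, contributing a chord of
just 0.37. A mean-based increase threshold of 0.1 could then never fire
once nine components are selected ($0.37/10 < 0.1$), and the selection
would absorb the foreign component; the summed-error form terminates
exactly where it should. The criterion is tested *before* committing, so
the offending frequency is never added. `extract_all_latencies()` then
removes the selected subset and repeats on the remainder (subsequent
passes start from the two highest-LCI candidates), yielding disjoint
subsets, one latency each.

## The MSPC baseline

The parametric alternative assumes a system order $R$, enumerates all
order-$R$ products of the stimulus, compensates initial phases by the
linear rule $\varphi = \sum_i a_i \varphi^{in}_i$, and minimizes the MPE
over the *whole* retained set — no subset selection. With one true
latency this coincides with the nonparametric estimate; with a mixture it
is biased. On the worked examples the lumped cost is nearly bistable:
for the order-3 lumping of the second example the two basins sit at
51.0 ms (MPE 0.647) and 21.0 ms (MPE 0.678) with exact phases. Reported
single-draw values in that situation are noise-realization dependent —
which is precisely the methodological point of the baseline comparison.

Because this baseline cannot shed components, its component screen
matters. An LCI-only screen at the 95% point retains about one spurious
random-phase product per twenty tested, enough to tip the near-degenerate
basins. The simulation driver therefore requires components to pass
*both* the latency-consistency screen and the neighboring-SNR F-test
(`snr_alpha = 0.01`), mirroring the analysis pipeline in which a
component must be a significant ASSR before any latency is estimated;
`mspc_estimate()` defaults to the LCI-only screen.

## Significance statistics

* **LCI** (latency consistency index): resultant length of a component's
  phases over $K$ commensurate epochs; threshold $\sqrt{3/K}$
  (approximately the 95% point of the null; $0.05$ at $K = 1200$).
* **Neighboring SNR**: target-bin power over the mean of the $N$ bins
  within ±0.5 Hz; the null ratio is $F(2, 2N)$-distributed, giving
  thresholds of 5.318 dB ($\alpha = .05$) and 7.492 dB ($\alpha = .01$)
  at $N = 12$ (12-s trials, 1/12-Hz bins).
* **PLV**: resultant length over time of the phase difference between the
  ±2 Hz band around a target frequency (analytic-signal phase, 10% edge
  trim) and the reference oscillator $2\pi f t$. Computed within-epoch;
  thresholds 0/0.4/0.6/0.8 drive epoch exclusion.

Both thresholds are verified by Monte-Carlo null calibration in the test
suite.

## The simulator as a stated world

`synthesize()` evaluates the polynomial mixture analytically on the
sampling grid (delays introduce no start-up transient), and calibrates
white Gaussian noise against the *measured* mean-square power of the
clean mixture, so a requested SNR is realized to within 0.1 dB. Defaults
are 1000 Hz sampling and 100-s duration: long commensurate windows give
near-exact phase estimates at 5 dB SNR, which is what makes the
worked-example recoveries sharp. For *noise-free* runs (the gain-sweep
experiment) a 2-s window is used — phases are exact at any commensurate
length, so nothing is lost.

What a green simulation test establishes: correct enumeration,
phase bookkeeping, cost minimization, selection and screening under
additive white noise on a mixture of homogeneous polynomial subsystems.
What it does not establish: robustness to pink background EEG,
inter-trial latency jitter, or amplitude nonstationarity; the EEG
pipeline test plants the same mixture into pink noise across 61 channels
and recovers latencies within 2 ms, but real recordings remain outside
what synthetic checks can certify.

Candidate detection for the nonparametric route scans integer-frequency
bins and keeps those passing both the SNR F-test (α = 0.01) and the LCI
threshold; both tests are part of the published analysis and their joint
false-positive rate is negligible at the scan sizes used here.

## The overlapping-output limit

When two subsystems share all outputs, only mixed phases are observable.
For relative gain $\xi$ on the shorter-latency subsystem the estimated
latency interpolates between the true pair; at $\xi = 1$ equal-magnitude
phasor averaging gives exactly the midpoint (17.5 ms for 15/20 ms).
Normalizing the noise-free estimates over the published 15-point gain
grid and fitting $f(x) = a/(1 + e^{-bx})$ in $x = \ln\xi$ gives
$a \approx 1.00$ and $|b| \approx 1.19$. Numerically, $\xi \to \infty$
drives the estimate to the latency of the *gained* subsystem, so $b$ is
negative for $\tau_1 < \tau_2$; published accounts of this law have the
limit written the other way around, and only $|b|$ is meaningful here.

## Numerical choices

* Latency search: 0.1-ms grid over the prior (default 0–100 ms, a
  physiological prior for auditory latencies), then golden-section
  refinement to $10^{-3}$ ms around every near-optimal grid minimum.
  The MPE is periodic in the reciprocal of the frequency gcd; ties are
  broken toward the smallest latency and flagged, as is a prior wider
  than one period.
* Phase extraction: discrete Fourier projection onto
  $\cos(2\pi f t)$ with the time origin at the window start; windows must
  span whole numbers of every component period (enforced, not assumed).
* Filtering: 10th-order Butterworth high-pass (1 Hz) as five biquads plus
  a Q = 35 notch (50 Hz), applied forward-backward with odd-symmetric
  padding of $3/f_c$ seconds; implemented in-package because no DSP
  library is available, and validated against analytic magnitude
  responses.
* Trial rejection: per-channel peak-to-peak range within each trial;
  indicators are the mean and variance across channels ("across
  channels" resolving the ambiguity of the published description);
  outliers beyond $Q_3 + 1.5\,\mathrm{IQR}$ are excluded worst-first,
  capped at 5% of trials.
* Distortion sets: a frequency generated by several coefficient vectors
  records them all; order labels are per vector, and callers filter
  (e.g. interaction tables list a frequency at its lowest generating
  order). The default enumeration returns the homogeneous order-$R$
  output set; `parity = NA` gives the cumulative set, which is the
  monotone one.

## Known limitations

* Latencies are attached to frequency subsets, not to anatomical
  sources; overlapping-output mixtures yield a gain-weighted compromise
  latency by construction.
* The SFS is greedy; it inherits the usual suboptimality of forward
  selection and depends on the start component when noise is high.
* The neighboring-SNR estimator is biased upward by +1 in expectation;
  as in the published analysis, no correction is applied.
* Instantaneous-phase (time-resolved) latency tracking is out of scope.
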