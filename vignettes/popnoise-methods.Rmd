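---
title: "Methods: population coding and noise-correlation analysis with popnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population coding and noise-correlation analysis with popnoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popnoise)
```

## The analysis problem

`popnoise` analyses trial-structured extracellular recordings from primary
visual cortex (V1) under a drifting-grating protocol: 12 motion directions
(0°–330° in 30° steps) plus an interleaved blank gray screen, presented in
pseudorandom order within each of several sweeps, 1 s per trial, with units
recorded simultaneously on a 1×32 linear probe. The scientific questions it
serves are population-coding ones: how selective are single units
(orientation tuning, OSI), how reliable are they (ROC-based SNR, Fano
factor), how much variability is *shared* between units (noise correlation
r~sc~, covariance, multi-unit Fano factor), how much stimulus information
the population carries (bias-corrected mutual information), and whether
fast-spiking (putative inhibitory) units decorrelate the network during
evoked activity. A synthetic-recording generator with young / aged /
metformin-treated presets lets the whole chain be exercised end-to-end and
validated against analytic oracles at desk scale.

## Data model

One `pn_recording` is one animal/session: a protocol, a unit table
(identifier, probe channel, depth, group tag, mean waveform) and a 3-way
integer count array condition × sweep × unit. Counts are canonical: every
statistic in the package consumes per-trial spike counts; spike times are
optional and used only to build sub-trial bins for the ROC analysis.
Bundles on disk are plain text (`protocol.json`, `units.tsv`, `trials.tsv`,
optional `spike_times.tsv`) and round-trip bit-exactly. Only blank-condition
trials carry spontaneous activity; inter-trial gray periods are not
modelled.

## Tuning model

Condition-mean rates are fitted with a double von Mises curve
$$f(x) = A\left[\frac{e^{k_1\cos(x-\theta_1)}}{2\pi I_0(k_1)} +
\frac{e^{k_2\cos(x-\theta_2)}}{2\pi I_0(k_2)}\right] + \mu,$$
with the null direction hard-constrained to $\theta_2 = \theta_1 + 180°$.
The constraint removes a label-swapping degeneracy that the usual "differ
by π" phrasing leaves open. As commonly printed, the two von Mises terms
are density-normalised and can never reach tens of spikes/s, so a single
multiplicative amplitude $A$ (Hz) is part of the model. The fit is plain
least squares (Nelder–Mead on log-transformed positive parameters),
multi-started from the observed argmax direction and ±one direction step;
the best restart wins, so the achieved residual is monotone in the number
of starts. Goodness of fit is the coefficient of determination $R^2$
between fitted and observed condition means — bounded above by 1 and the
standard selection statistic for tuning curves. Only units with gof
strictly greater than 0.6 contribute OSI values.

Degenerate inputs: exactly flat rate vectors return the flat fit
($k_1=k_2=0$, gof 0 by convention, OSI 0); if every restart fails the fit
is flagged with gof $-\infty$ and is excluded by any threshold.

OSI is reported as a fraction,
$\mathrm{OSI} = (R_{\mathrm{opt}} - R_{\mathrm{orth}})/(R_{\mathrm{opt}} +
R_{\mathrm{orth}})$, where $R_{\mathrm{opt}}$ averages the fitted curve at
$\theta_1$ and $\theta_2$ and $R_{\mathrm{orth}}$ averages it at
$\theta_1 \pm 90°$. Evaluating on the fitted curve (rather than raw
condition means) is the default because the orthogonal directions need not
coincide with measured conditions; a raw-response variant is exposed.
Preferred orientation is $\theta_1 \bmod 180°$, and the pairwise ΔPO is the
circular distance on the orientation half-circle, in [0°, 90°].

## Single-unit reliability

**ROC-based SNR.** Evoked response bins (optimal condition, defined by the
raw argmax of condition means so SNR never depends on fit success) are
compared with spontaneous bins (blank trials). A threshold sweep over all
observed values yields the ROC curve; the SNR is the trapezoidal area under
it, which equals the Mann–Whitney U statistic over $nm$ with ties counted
one half — 0.5 is chance, 1.0 perfect separation. The paper-style
procedure leaves the bin width unstated; the default is 0.1 s within the
1 s stimulus, pooled over the condition's sweeps (~100 bins per
distribution at 10 sweeps), exposed as `roc_bin_s`. Without spike times
the code falls back to one bin per trial.

**Fano factor.** Per grating condition, the across-sweep variance-to-mean
ratio with the unbiased (n−1) variance — at 10 sweeps the biased form
would understate FF by 10% — averaged over conditions with non-zero mean
(an optimal-condition-only mode is exposed). The MUA Fano factor applies
the same computation to counts summed across all simultaneously recorded
units per trial; under independent Poisson spiking it stays near 1, so any
excess is shared variability.

## Pairwise and population noise

Within each condition, trial counts are standardised,
$z = (R_{\mathrm{trial}} - E(R))/\sigma$, using the population-form
(divide-by-n) SD to match the expectation-operator definitions; zero-SD
conditions are dropped jointly for both pair members. Noise correlation is
the Pearson correlation of the pooled z vectors — pooling spans all 12
grating conditions (standard practice; maximises trials), and spontaneous
r~sc~ uses the blank condition alone through the same machinery.
Covariance is computed on raw counts pooled across grating conditions with
the population-form identity $\mathrm{cov} = E(N_1N_2) - E(N_1)E(N_2)$,
exactly as printed; note this mixes signal and noise covariance — the
package reproduces the printed definition rather than silently switching
to residuals.

Binned relations (r~sc~ against pair firing rate, probe distance, or ΔPO)
use half-open bins with the conventional edges (0–50 by 10 spikes/s,
0–300 by 50 µm, 0–90 by 30°); out-of-range pairs go to an explicitly
reported overflow bin. The pair firing rate is the arithmetic mean of the
two units' evoked rates (geometric-mean alternative exposed). Pair
distance is |Δdepth| — contacts are collinear on a linear probe.

The decorrelation index of an FS–RS pair is
$\min(0,\; r_{sc}^{\mathrm{evoked}} - r_{sc}^{\mathrm{spont}})$: positive
differences mean no decorrelation and are assigned zero; more negative
values mean stronger inhibition-mediated decorrelation.

## Mutual information

The plugin estimator uses empirical probabilities,
$MI = H(R) - H(R|S)$ in bits with $0\log 0 = 0$. Population responses are
discretised per unit into approximately equipopulated bins (default 2) and
joined into tuple symbols; with sizes ≤ 6 and 2 bins the symbol space
(≤ 64) stays well below the 130-trial budget of the default protocol. The
Panzeri–Treves correction subtracts
$[\sum_s(\tilde R_s - 1) - (\tilde R - 1)]/(2N\ln 2)$ bits, with occupied
response bins counted naively by default; an optional mode estimates the
underlying bin count by inverting the expected-occupancy relation
$r_{\mathrm{obs}} = R(1-(1-1/R)^N)$ (the cited procedure is not printed
anywhere, so this is the package's documented stand-in). The corrected
value may be slightly negative — that is expected behaviour, not an error.
MI versus population size draws seeded random unit subsets per size and
reports mean ± SEM; blank trials enter as a 13th stimulus by default, and
stimulus probabilities are empirical (uniform under the balanced
protocol). Subset count, bin count and blank inclusion are all parameters
because none is stated in the source analysis style.

## Waveform classification

Three features are measured on the mean waveform: trough-to-peak duration,
|peak|/|trough| amplitude ratio, and the signed slope 0.5 ms after the
trough. A unit is FS iff duration < 0.26 ms, ratio > 0.8 and the end slope
is negative — all boundaries strict. The "−0.05" printed alongside the
negative-slope criterion is read as an exemplar value, not a threshold; the
conservative sign rule is the default and a numeric threshold is exposed.
Because a 30 kHz grid quantises the duration to ~0.033 ms — coarser than
the 0.26 ms boundary is stated to — waveforms are cubic-spline upsampled
(default ×30, ~1 µs) before the extrema are located, the standard practice
in waveform-based cell typing. This is why boundary-location by bisection
recovers the switch points to ~0.001 of the stated values rather than to
one raw sample.

## The synthetic generator: what it emulates and what it does not

Each simulated trial draws one shared gain $g \sim N(1, \sigma_g)$
(truncated at 0, separate SDs for evoked and blank epochs); unit $i$ then
fires Poisson with mean $\lambda_i(c)\,T\,(1 + c_i(g-1))$, where
$\lambda_i$ is the double von Mises tuning rate and the coupling $c_i$ is
1 for RS units and an epoch-specific value for FS units. This
doubly-stochastic construction is the minimal model that yields jointly
controllable Fano factors above 1 and positive noise correlations, with
closed forms used as oracles: $FF = 1 + \lambda T \sigma_g^2$ and
$r_{sc} = c_ac_b\lambda_a\lambda_b\sigma_g^2 / \sqrt{v_a v_b}$ with
$v_i = \lambda_i + c_i^2\lambda_i^2\sigma_g^2$ (gain truncation is ignored
in the oracle; its bias is negligible for $\sigma_g \le 0.3$).

Presets state the simulated world once: `young` (23 units, 16% FS,
baseline 5 Hz, amplitude 20 Hz, concentration 3, $\sigma_g = 0.15$,
FS coupling 0.3 evoked / 1 spontaneous), `aged` (28 units, 14% FS,
baseline 10 Hz, concentration 1.5, $\sigma_g = 0.3$, FS coupling 1/1 — no
decorrelation), `met` (21 units, 12% FS, baseline 2.5 Hz, amplitude 16 Hz,
concentration 3, $\sigma_g = 0.15$, FS coupling 0.25/1). Unit counts per
animal and FS fractions sit in the reported ranges; baselines and
amplitudes place spontaneous/peak rates in the reported few-to-twenty
spikes/s regime; the remaining magnitudes were chosen once so that every
group contrast has the reported *direction* (aged > young for noise
metrics, aged < young for selectivity and information, met restoring
young-like noise with a lower baseline). No preset value was calibrated
against printed medians — the source recordings are not public, so
magnitude agreement is out of reach by construction, and a green
directional test establishes sign reproduction only.

The generator does not emulate: temporal spike-train structure within
trials beyond uniform placement (so ISI statistics are uninformative),
rate adaptation across sweeps, distance- or ΔPO-dependent correlation
structure (implanted correlations are uniform across pairs — the binned
relations are flat by construction in synthetic data), eye movements, or
any biophysics.

## Group statistics

Metrics are pooled across animals within a group (as in the source
analysis; a mixed-model treatment of animal nesting is out of scope and
the pooling limitation is acknowledged). Before testing, a single
non-iterated 3σ pass removes values outside mean ± 3 SD per metric per
group. Two-sided Mann–Whitney U tests use exact enumeration of the
permutation null for max(n, m) ≤ 8 (ties handled exactly) and the
tie-corrected normal approximation with continuity correction otherwise;
effect sizes are Cliff's delta (which equals 2·AUC − 1, an identity the
test suite asserts across modules) and Cohen's d. Binned r~sc~ and MI
curves are compared with an additive two-way ANOVA (group + bin, Type II
sums of squares for unbalanced cells); the interaction is off by default
because the source analysis style does not state one, and a flag enables
it. Zero-residual designs are flagged degenerate rather than reporting an
infinite F silently. No multiple-testing correction is applied by default.

## Numerical choices and degenerate inputs

- ROC thresholds sweep all distinct observed values with a strictly-greater
  rule; endpoints (0,0) and (1,1) are always included, making trapezoidal
  AUC identical to the half-tie U statistic.
- Quantile binning merges degenerate edges and reports the achieved bin
  count; constant units collapse to a single symbol.
- `fano_factor` errors when all conditions have zero mean; zero-variance
  conditions are dropped from z-scoring (jointly for a pair).
- All simulation and subset sampling goes through an RNG-state-preserving
  seed wrapper, so library calls never disturb the caller's RNG stream;
  pipeline stages derive their seeds from the master seed by fixed
  offsets, so any stage can be re-run in isolation.

## Known limitations

- Pair statistics at the protocol's native 10 sweeps are noisy; recovery
  of implanted correlations to ±0.05 needs a few hundred pooled trials
  (the validation suite uses 30 sweeps).
- Covariance as printed mixes signal and noise covariance; interpret the
  covariance tables accordingly.
- The decorrelation clamp at zero puts group *medians* at the boundary
  whenever fewer than half of FS–RS pairs decorrelate; group contrasts on
  this index should use means, as the pipeline's directional checks do.
- MI values depend on the quantisation (bins per unit) and subset counts;
  they are comparable within a run, not absolute channel capacities.
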