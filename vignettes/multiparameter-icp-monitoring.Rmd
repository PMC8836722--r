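---
title: "Multiparameter ICP trend analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparameter ICP trend analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icptrend)
```

This vignette is the package's account of its science: what each index
measures and under which conventions it is computed, what the synthetic-data
generator does and does not emulate, and the reasoning behind the choices
that were genuinely open.

## The data model

The unit of analysis is a uniformly sampled *trend* recording
(`trend_series`): mean ICP, mean arterial pressure (MAP) and the ICP pulse
amplitude (AMP), typically exported by a bedside monitor at one sample every
3 seconds over about 3 days of postoperative monitoring. AMP — the
cardiac-cycle excursion of the ICP waveform — cannot be recovered from a
3-second trend, so it is taken as an input channel, exactly as monitors
export it, not extracted from a beat-resolved waveform.

Artifact-affected samples are *flagged* invalid rather than deleted. This
keeps the sampling grid uniform, so segmentation stays index arithmetic and
no pressure value is ever interpolated across a gap.

## The indices and their conventions

All indices are computed per segment (1 h by default, `segment_trend()`),
then aggregated per patient (`patient_indices()`).

**Mean ICP and CPP.** Arithmetic means over valid samples; CPP is computed
as mean(MAP) − mean(ICP) over the *same* valid samples, so the identity
CPP = mean MAP − mean ICP holds to machine precision by construction. A
segment with under `min_valid_fraction` (default 0.5) valid samples yields a
missing value — never zero. The 0.5 default is an explicit, configurable
convention; trend archives carry no ground truth about how much artifact is
tolerable.

**PRx.** The pressure reactivity index is the moving Pearson correlation of
(MAP, ICP) sample pairs: 5-minute windows advanced in 1-minute steps, the
segment value being the mean of the window correlations. The windowing
follows the established neuromonitoring convention; because the input is
already a multi-second trend, the correlation is taken on the 3-second
samples directly, with no 10-second re-averaging. Both window and step are
arguments, and `window_s = 3600` recovers the alternative one-correlation-
per-hour reading.

**RAP.** The compensatory reserve index applies the same machinery to
(AMP, ICP) with a 4-minute window — the conventional correlation over ~40
multi-second averages. RAP ≈ 0 indicates good reserve, ≈ 1 the steep zone
of the pressure–volume curve, < 0 exhausted compensation.

Two rules apply to every correlation window. A window with fewer than
`min_window_valid` (default 0.75) valid samples is skipped. A window in
which either channel has zero variance is also skipped rather than scored
0: zero would assert "no reactivity" from no information. If no window
qualifies, the segment index is missing. Numerically, the windowed engine
centres each channel on its segment mean and uses running sums; the unit
tests hold it to 1 part in 10⁹ against a naive per-window `cor()`
implementation, and the zero-variance guard is relative (a window is
"constant" when its centred sum of squares is below 10⁻¹⁰ of its scale).

**DICP.** The pressure-time dose above a threshold (20 mmHg by default, the
recommended treatment threshold in hypertensive intracerebral hemorrhage)
integrates max(0, ICP − threshold) over valid runs, in mmHg × h. Each
valid sample contributes its clipped excess over its own 3-second interval;
algebraically this equals a trapezoidal rule within each run of consecutive
valid samples plus a half-interval extension at each run end. The
convention was chosen because it makes three properties exact rather than
approximate: a constant 25 mmHg hour contributes exactly 5 mmHg × h, the
dose is exactly additive over any partition at sample boundaries, and runs
broken by artifacts are integrated separately with no bridging. At patient
level DICP is the *monitoring-period total*, not an hourly mean — a dose
accumulates, which is why multi-day recordings land in the hundreds of
mmHg × h.

**CPPopt.** Hourly segments are binned by mean CPP (5 mmHg bins, ≥ 2
segments per bin, ≥ 4 bins), PRx is averaged per bin, and a quadratic is
fitted to (bin centre, mean PRx). The vertex abscissa is returned only when
the parabola opens upward *and* the vertex lies inside the observed CPP
range; otherwise the estimate is refused with a reason code. A monotone
PRx–CPP relation therefore yields "undefined", not an extrapolated optimum.
The fit is PRx against *CPP*: that is what the optimal-perfusion-pressure
literature prescribes, and a reactivity-versus-perfusion curve is the only
reading under which a "optimal CPP" vertex is meaningful.

## The synthetic-data generator

No patient-level recordings are distributable, so the generator
(`simulate_patient()`) provides the study conditions for every test. It is
deliberately the *minimal* structure under which all five indices are
independently steerable:

- MAP = baseline + slow wave + white noise. The slow wave is a sinusoid in
  the Lundberg-B band (default amplitude 3 mmHg, period 60 s — vasomotor
  waves of ~1/min are the canonical carrier of reactivity information).
- ICP = baseline + `reactivity_gain` × (MAP slow wave) + an independent
  B-wave (default 1.5 mmHg, 90 s) + white noise. The gain is the handle on
  PRx: its sign fixes the sign of the MAP–ICP correlation, and gain 0 with
  independent noise yields PRx near 0.
- AMP = `amp_baseline` · exp(`elastance_coeff` · (ICP − baseline)) + noise
  while ICP is below `icp_critical`, then declining linearly with the
  matched slope above it, floored at 0. The exponential branch reproduces
  the steep-zone behaviour (amplitude grows with ICP, RAP → 1); operating
  above the critical point reproduces exhausted compensation (amplitude
  falls, RAP < 0).
- A fixed fraction of samples (default 2%) is flagged invalid at random
  positions.

Default noise SDs (ICP 1.5, MAP 2, AMP 0.3 mmHg) are of the order seen in
3-second trend exports; they matter only through the signal-to-noise ratio
of the slow waves, which the calibration below accounts for explicitly.

`simulate_cohort()` builds a two-group cohort. Per patient it draws target
values of mean ICP, CPP, PRx and RAP from the group's distributions — the
defaults are the published group means/SDs of a 53-patient hypertensive
intracerebral hemorrhage cohort (good prognosis n = 27, GOS IV–V; poor
n = 26, GOS I–III) — and then *inverts* the window-correlation formula to
find the gain and elastance that produce them: with slow-wave variance
S = A²/2, MAP window variance P = S + σ²_MAP and non-coupled ICP variance
Q = B²/2 + σ²_ICP, the gain solving r = gS/√(P(g²S + Q)) is

g(r) = sign(r) · √( r²PQ / (S(S − r²P)) ),

and the (linearised) elastance for a RAP target is
σ_AMP · r / (a₀ σ_ICP √(1 − r²)). Targets are truncated to the achievable
range (|PRx| ≤ 0.65 under the default signal-to-noise ratio, RAP in
[−0.8, 0.9]); the critical turning point is placed 25 mmHg above each
patient's baseline so the calibrated steep-zone regime stays in force. DICP
is deliberately *not* calibrated: it emerges from the drawn ICP level
relative to the 20 mmHg threshold. The source study reports only medians
and IQRs for the dose, so its dispersion is a free choice of the generator
and no claim is made that the simulated dose distribution matches the
study's.

All randomness flows from one master seed; per-patient seeds are drawn once
from it, so a cohort is reproducible element for element.

**What the generator does not emulate:** treatment feedback (dehydration
therapy, repeat surgery) on ICP; beat-level waveforms; non-sinusoidal or
intermittent B-wave trains; plateau (Lundberg-A) waves; structured artifact
(drift, flushes) beyond random dropouts; and any DICP dispersion matching.
Passing tests on this generator show that the index engine and the
statistical layer recover what was put in — they are not evidence about
real recordings.

## The statistical layer

The group-comparison tests mirror the fixed assignments of the study design
this layout reproduces: pooled (equal-variance) two-sample t for age,
hematoma volume, mean ICP, PRx, RAP and CPP; Mann–Whitney U for GCS and
DICP; uncorrected Pearson chi-square for sex. Normality is a stated
assumption, not re-tested per run. The pooled (not Welch) t and the
uncorrected (not Yates) chi-square are deliberate: they are the forms under
which the published table's statistics are exactly reproducible from its
printed summaries, which the acceptance checks verify. `pooled_t()` accepts
either raw samples or printed summaries and gives identical results on a
sample and on its own summaries.

`mann_whitney()` reports U1 = #{x > y} + ties/2, U2 = n₁n₂ − U1 and
min(U1, U2) — the convention under which published tables print U — with a
tie-corrected normal approximation and continuity correction for the p
value, adequate at these group sizes (the suite cross-checks against both
`wilcox.test()` and exact enumeration).

ROC analysis orients every index by an *explicit* direction flag (higher
mean ICP, PRx, RAP and DICP predict poor outcome; lower CPP does).
Directions are never auto-flipped: auto-flipping would silently convert an
anti-predictive index into an apparently predictive one; a mis-specified
direction instead surfaces as AUC < 0.5 with a logged message. The
trapezoidal AUC equals the normalised Mann–Whitney statistic (ties counted
half) to 10⁻¹², an identity the suite asserts on random instances. AUC
confidence intervals offer DeLong (default) and Hanley–McNeil. The DeLong
interval is built on the logit scale and back-transformed: at these group
sizes and at AUCs near 1 the untransformed Wald form measurably undercovers
(≈ 89% at nominal 95% in the suite's own 26-vs-27 normal-scores
simulation), while the logit form holds ≈ 95%; for degenerate AUC (0 or 1)
it falls back to the truncated Wald interval, so a perfect separation at
small n reports an upper bound capped at 1.

For the type-I-error property of the comparison layer, the suite checks
each index comparison separately — each stays non-significant at α = 0.05
in ≥ 90% of null-cohort seeds. A family-wise "no test significant" reading
would be unattainable by construction at the nominal level with five
approximately independent tests (expected family-wise rate ≈ 23%), and
per-comparison calibration is the property the individual tests actually
promise.

## Problem sizes and determinism

The Monte-Carlo test conditions are: 6 h of trend data per patient for
cohort-level checks (100 master seeds for the calibrated-separation and
null-calibration properties), 2 h per recording for the reactivity-gain
recovery sweep (5 gains × 20 seeds), 500 replicates for DeLong coverage,
and 100 random 1200-sample segments for oracle equivalence at 10⁻⁹
relative tolerance. These sizes are the package's chosen simulation design;
all are driven by fixed seeds and reproduce exactly.

## Known limitations

- The sinusoidal slow-wave model gives correlation windows an
  almost-periodic structure; real B-wave trains are intermittent, which
  makes real PRx/RAP noisier than the simulated ones at equal gain.
- The AMP decline branch is anchored to the amplitude the exponential
  relation reaches at the critical point. When a configuration puts the
  baseline far above `icp_critical` that anchor becomes small and the
  clipped amplitude floor dominates; the exhausted-compensation regime is
  meaningful for moderate excursions (up to ~10 mmHg) above the turning
  point.
- The PRx/RAP calibration inverts a stationary-variance approximation;
  measured patient means track the targets but are not exact, so calibrated
  cohorts reproduce group *separations*, not the published statistics
  digit for digit.
- CPPopt on 1-h bins needs a CPP range actually visited by the patient;
  recordings with tightly controlled CPP will (correctly) return
  "insufficient bins" rather than an optimum.
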