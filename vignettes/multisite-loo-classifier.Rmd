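---
title: "Multisite leave-one-out connectivity classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisite leave-one-out connectivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcloo)
```

## The problem

Resting-state functional connectivity summarizes the coupling between brain
regions as the correlation of their slow BOLD fluctuations. Given a lattice of
$R$ gray-matter regions of interest, each subject contributes a symmetric
$R \times R$ matrix of Fisher-transformed Pearson correlations; each unordered
region pair is a *connection*, and a whole-brain 7266-region lattice has
$\binom{7266}{2} = 26{,}393{,}745$ of them. The question this package
addresses is whether such mass-univariate connectivity, pooled across many
acquisition sites with heterogeneous scanners and protocols, can classify a
single held-out subject as autism or control — and how accuracy depends on
which connections are used, on site, on scan length, and on symptom severity.

## The classifier

For each left-out subject $s$ and each connection $c$:

1. **Dual-group GLM.** On the remaining subjects, the connection values $x$
   are regressed separately within the autism and control groups on an
   intercept, age, age$^2$, a gender indicator, and two handedness indicators
   (left, ambidextrous; right-handed is the reference). Rank-deficient
   columns (for instance a single-gender group) are dropped and contribute
   zero to predictions; a group smaller than its retained column count + 1
   falls back to the group mean.
2. **Prediction.** Each fit is evaluated at the left-out subject's
   covariates, giving $\hat x_{aut}$ and $\hat x_{ctl}$.
3. **Site mean offset.** Both estimates are shifted by
   $\bar x_{site(s)}^{(-s)} - \bar x_{\neg site(s)}$, the difference between
   the subject's site mean for that connection (excluding the subject) and
   the mean over all other sites.
4. **F-weighted score.**
   $\mathrm{score}_c = (|x - \hat x_{ctl}| - |x - \hat x_{aut}|)\, F_c$ with
   $F_c = t_c^2$ from the pooled two-sample $t$ between the remaining groups
   ($df = n_1 + n_2 - 2$). Proximity to the autism estimate is positive.
5. **Aggregation.** Scores are averaged over the connections incident to
   each ROI (within the active connection subset; ROIs with none contribute
   0) and the $R$ per-ROI averages are summed into the classification score:
   positive predicts autism, negative control.

Strict leave-one-out discipline holds throughout: the left-out subject's
connectivity enters only as the $x$ in step 4 — never the fits, the $F$
statistics, the selection p-values, or the site means. Connection subsets are
re-selected for every left-out subject (`select_connections()`, two-tailed
$p < \alpha$ with $\alpha \in \{10^{-2},10^{-3},10^{-4},10^{-5}\}$ by
convention), or taken as strength-by-distance bins (0.05 Fisher-z by 5 mm,
half-open floor intervals, negative strengths indexing negative bins) with
reference strengths from an independent cohort.

Scores are thresholded at 0, or at the Youden-optimal point of the ROC curve
("optimizing the area under the curve" can only coherently mean the optimal
operating point, since a threshold does not change the AUC; ties break toward
the smaller threshold). Significance of an accuracy is the exact binomial
tail $P(X \ge k \mid n, 1/2)$; `binomial_critical_count()` inverts it
(509/964 at $\alpha = 0.05$, 531/964 at $\alpha = 0.001$).

Two design points were genuinely open and are resolved as follows. The order
of the "difference of absolute differences" is forced to
$|x-\hat x_{ctl}| - |x-\hat x_{aut}|$ by the stated sign convention (negative
= control). Site is handled as the post-hoc mean offset of step 3 rather
than a GLM column, following the operational description of the method; the
alternative reading (site as covariate) is *not* equivalent — see
"Limitations" below. The weighting $F = t^2$ is the unadjusted two-sample
statistic; a covariate-adjusted alternative would change the weights but not
the architecture. Under p-value subsets, per-ROI averages divide by the
number of incident *selected* connections rather than $R-1$; the
all-connections case needs no such rule.

## Preprocessing layer

Time-series cleaning mirrors standard resting-state practice: linear detrend
plus an ideal FFT-domain bandpass (0.001–0.1 Hz); nuisance regression of CSF,
white-matter, soft-tissue and six motion time courses (least squares with an
intercept; dependent regressors dropped with a warning); motion scrubbing at
a threshold of 0.2 mm on framewise displacement and DVARS with a one-frame
guard band on each side and concatenation of survivors.

Numerical choices worth knowing:

* The bandpass is implemented as an exact orthogonal projection: detrend,
  ideal frequency mask, then removal of the band-limited image of the linear
  ramp. Ramps are annihilated exactly and the filter is idempotent to
  machine precision; in-band RMS gain is ~1 and stopband RMS gain ~0.02 at
  the test frequencies.
* Framewise displacement is the root-mean-square of the six frame-to-frame
  parameter differences, rotations converted to arc length at a 50 mm
  radius; FD of the first frame is 0 by definition. The L1 ("power")
  convention is available via `variant = "power"`.
* DVARS is the RMS temporal derivative over channels divided by the global
  SD of the series, so the single 0.2 threshold remains meaningful on
  normalized data; the divisor is a documented knob (`scale`). How the
  original mm threshold maps onto DVARS units is under-specified in the
  literature this follows; the normalization is our documented choice.
* Fisher z uses correlations clipped at $|r| = 1 - 10^{-7}$ so duplicate
  time courses stay finite.

## The synthetic cohort generator

No public generative model exists for multisite connectivity cohorts, so the
generator is a stand-in built to exercise exactly the structure the
classifier assumes:

$$x_{s,c} = \mathrm{baseline}_c + \beta_{age}\,age_s + \beta_{age^2}\,age_s^2
  + \mathrm{site}_{site(s),c} + \mathrm{sev}_s\,\delta\,[c \in A]
  + \varepsilon_{s,c} + m_{s,c},$$

with affected set $A$ of size `round(effect_fraction * C)`, site offsets
drawn once per (site, connection) from $N(0, \sigma_{site}^2)$, latent
severity $|N(1, 0.3^2)|$ for autism and 0 for controls,
$\varepsilon \sim N(0, \sigma_e^2)$, and measurement noise
$m \sim N(0, 1/(T_{ret}-3))$ — the asymptotic sampling variance of a
Fisher-z correlation from $T_{ret}$ retained volumes. Generating matrices
at the Fisher-z level with this exact sampling noise (rather than simulating
full BOLD series per subject) keeps cohorts cheap while preserving the one
property that matters downstream: connectivity precision grows with scan
length. `simulate_timeseries()` exists separately to validate the
connectivity module against known correlation structure at small $R$.

Defaults describe a mid-sized multisite study: $R = 100$ lattice ROIs
(4950 connections), 5 sites of 24 subjects (12/12 per diagnosis), 150
volumes at TR 2 s, ages uniform on 6–60 years, 85% male, handedness
(0.894, 0.099, 0.007), $\delta = 0.5$ on 2% of connections,
$\sigma_{site} = 0.1$, $\sigma_e = 0.2$, weak common age trends. Behavioral
scores are linear in severity plus noise, with intercepts, slopes and
residual SDs anchored to published cohort summaries (controls ~21 vs autism
~92 on SRS, 112 vs 105 verbal IQ, 105 vs 75 Vineland, ADI-R only measured in
autism); motion spikes occur 1.5x more often in autism, producing the usual
group difference in retained volumes. All randomness flows from one seed.

What the generator does **not** emulate: scanner physics, susceptibility
artifact, realistic BOLD spectra, spatially structured (distance- or
network-dependent) effects, or site differences in age/gender composition.
Passing recovery tests on these cohorts therefore shows the pipeline is
correct and well calibrated under its own assumptions, not that comparable
accuracy is attainable on real consortium data.

## Verification strategy and problem sizes

Every vectorized computation has an independent oracle in the test suite:
the streaming classifier is checked connection-by-connection against
`loo_scores_reference()` (a deliberately naive reimplementation; agreement
~1e-14 on R = 10–12, n = 24–36 cohorts), fits against explicit
normal-equations solutions, binomial boundaries against a log-space tail
summation, bin assignment against brute-force histograms, the ROC threshold
against an exhaustive midpoint scan. Cohort-level checks run at $R = 100$,
$n = 120$, 5–6 sites — about 1.5 s per full leave-one-out pass — with 10–20
seeds per stochastic property.

## Limitations

The mean-offset site adjustment is *approximate* harmonization, and the
package's calibration experiments quantify two consequences that follow from
its algebra:

* **No exact site-shift invariance.** Adding a constant to every value of
  one site propagates into the pooled GLM coefficients (by
  $k\,(X^TX)^{-1}X^T 1_{site}$), into the two-sample $t$/$F$ statistics, and
  into the "all other sites" means of other sites' offsets. Only fitting and
  testing on site-centered data would cancel a site shift exactly, and that
  is a different method from the one implemented here. Score changes under a
  0.5 z site shift are order-1 relative, not machine-zero.
* **Anti-conservatism under genuine site structure.** With per-site offsets
  present, removing the left-out subject from its site-by-group cell
  perturbs its own group's mean by $-u(1-w_S)/(n_g-1)$ (where $u$ is the
  site-vs-rest offset contrast and $w_S$ the site's weight), while the
  adjusted estimates are mis-centered by about $-w_S u$; the product gives
  every subject a small systematically *correct* score shift. Empirically,
  null ($\delta = 0$) cohorts classify at ~56% rather than 50% with
  $\sigma_{site} = 0.1$, and at ~50% when $\sigma_{site} = 0$ or with a
  single site. The same mechanism adds site-level accuracy noise that can
  mask the scan-length effect in small site sets. Users comparing against
  chance should calibrate against permuted labels rather than the nominal
  binomial null when site structure is strong.

Other limitations: the classifier is a fixed weighted average, not a learned
model; image-space preprocessing (realignment, normalization, segmentation)
is consumed as given; no spatial smoothing or global-signal regression is
performed anywhere; and the multiple-comparison display floor for per-ROI
accuracy maps uses a conservative Bonferroni-style inversion of the exact
binomial tail, documented in `per_roi_accuracy()`.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1, out = "runs/demo")
res <- run_pipeline(cfg)
res$evaluation          # accuracy/sensitivity/specificity per subset rule
res$site_accuracy       # per-site accuracy and mean volumes
res$behavior            # score-behavior correlations with BH flags
```

The run directory contains the phenotype table, ROI centroids, ground-truth
connection list, per-rule score tables, evaluation summaries and a manifest
with md5 hashes of every artifact; rerunning with the same seed reproduces
them byte for byte.
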