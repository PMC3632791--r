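---
title: "Methods: task, observer model, psychometrics and lesion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task, observer model, psychometrics and lesion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacdisp)
```

This vignette documents the modelling assumptions, default parameters and
numerical choices behind `sacdisp`. It is the methods companion to the
`analysis/` drivers and the README.

## 1. Task design

Subjects fixate, a target appears 12–16° away (fixation and target
eccentricities drawn from {6, 8}° on opposite sides of the midline), and the
target is displaced during the saccade. In **STEP** the displaced target is
present when the eyes land; in **BLANK** it reappears only after a 250 ms
gap, which restores displacement sensitivity. Displacements follow three
interleaved 1-up-1-down staircases per condition and direction:

- STEP: step size 3°, starting at −7, 0, +7° (lattice resolution 1°, since
  the three starts are mutually offset by multiples of 1° under ±3° moves);
- BLANK: step size 1.5°, starts −3.5, 0, +3.5° (resolution 0.5°).

`staircase_lattice()` exposes the reachable level sets; `schedule_session()`
interleaves the staircases in randomised order within blocks. Internally
displacements are coded forward-positive (in the saccade direction), so the
same machinery serves both directions.

## 2. The observer model

All synthetic behaviour comes from a linear corollary-discharge (CD)
observer. For a trial with stimulus amplitude $A$ and displacement $D$:

$$S = g\,|A| + \varepsilon_m, \qquad
  \hat S = g_{cd}\,(g\,|A| + \lambda\,\varepsilon_m) + \varepsilon_{cd},$$
$$\hat D = D + (\hat S - S), \qquad
  \text{report forward} \iff w\,\hat D + \varepsilon_{dec} \ge 0 ,$$

with $\varepsilon_m \sim N(0, \sigma_m^2)$,
$\varepsilon_{cd} \sim N(0, \sigma_{cd}^2)$, and decision noise
$\varepsilon_{dec}$ whose SD is condition-dependent (large in STEP, small in
BLANK — this is what implements saccadic suppression of displacement and its
release by blanking). A lapse parameter maps a random fraction of trials to
a coin flip.

Two parameters carry the lesion hypotheses:

- **CD gain** $g_{cd} < 1$: the internal movement estimate is hypometric,
  so $\hat S - S < 0$ on average and a physically stationary target appears
  to have jumped *backward*; the fitted point of subjective stationarity
  (PSS) shifts *forward* and BLANK thresholds rise.
- **CD coupling** $\lambda = 0$: the motor error never reaches the monitor,
  so a self-generated undershoot ($\varepsilon_m < 0$) yields
  $\hat S - S > 0$ and is misread as a forward target jump. This predicts a
  positive correlation between binned saccadic hypometria and
  forward-report probability — error misattribution — without necessarily
  moving the PSS.

### Default parameters

| parameter | control | thalamic preset | rationale |
|---|---|---|---|
| `motor_gain` | 0.92 | 0.92 | normal saccades undershoot by ~5–10 % |
| `motor_sd` (deg) | 1.0 | 1.0 | typical landing scatter at 12–16° |
| `cd_gain` | 1.0 | 0.9 | intact vs hypometric internal monitor |
| `cd_sd` (deg) | 0.3 | 0.6 | lesion adds monitoring noise |
| `cd_coupling` | 1 | 0 | intact vs uncoupled error copy |
| `decision_sd_step` (deg) | 1.8 | 1.8 | BLANK/STEP threshold ratio ≈ 0.2–0.5 in controls |
| `decision_sd_blank` (deg) | 0.4 | 0.4 | control BLANK thresholds ≈ 0.3–0.5° |
| `lapse` | 0 | 0 | see §5 |

These are *study conditions*, fixed before any acceptance outcome was
inspected; they were chosen so that control fits land in the empirically
typical range (BLANK threshold a few tenths of a degree, STEP above 1°,
relative threshold well below 1) and the thalamic preset produces a forward
PSS shift of roughly 1° — the size reported for thalamic patients.

### Realism and limitations

The model is linear and Gaussian: no compression of perceived amplitude, no
adaptation across trials, no dependence of motor noise on amplitude, and the
staircase-driven stimulus stream is treated as exchangeable. Eye traces (§3)
have a stereotyped velocity profile with additive white position noise;
there are no microsaccades, drifts, blinks or corrective saccades. These
simplifications are deliberate — each acceptance check isolates one
mechanism — but numbers should not be read as subject-level predictions.

## 3. Eye traces and oculomotor processing

`generate_eye_trace()` builds 500 Hz position traces with a raised-cosine
velocity profile and a main-sequence duration $T = 2.2A + 21$ ms. Ground
truth is exposed in two forms, because "onset" is ambiguous for a smooth
profile: the *movement* onset/offset (between which the position change
equals the executed amplitude exactly) and the analytic *30 °/s threshold
crossings* (what a velocity-criterion detector can recover, to ±1 sample).
The gaze-contingent displacement trigger fires one 110 Hz display frame
after the onset threshold crossing; `trigger_check()` verifies it precedes
the saccade midpoint.

`filter_trace()` low-passes position at 60 Hz with a Butterworth filter and
`signal::filtfilt` for zero phase. `filtfilt` assumes zero-padded ends,
which creates edge transients on traces that start at a non-zero position;
we therefore pad by odd reflection (up to 50 samples) before filtering and
trim afterwards. Velocity is the central difference of filtered position.
`detect_saccade()` marks supra-threshold runs of ≥ 6 ms, takes the
largest-amplitude run as the principal saccade (flagging multiples), and
measures amplitude between 50 ms pre/post fixation medians.

## 4. Psychometrics

`fit_cumulative_gaussian()` maximises the Bernoulli likelihood of

$$P(\text{forward}\mid d) = \frac{\text{lapse}}{2} +
  (1-\text{lapse})\,\Phi\!\left(\frac{d-\text{pss}}{\text{jnd}}\right)$$

over (pss, log jnd) with `optim(method = "L-BFGS-B")`, five dispersed
starts, jnd bounded in [0.01, 50] and probabilities clamped at $10^{-12}$.
Separable data (all backward levels below all forward levels) are flagged
from the data themselves rather than from the optimiser, whose plateau
behaviour is unreliable.

The percent-correct curve folds the fit,
$PC(|d|) = (F(|d|) + 1 - F(-|d|))/2$, and `threshold_75()` finds the 75 %
crossing by `uniroot` (tolerance $10^{-6}$). For pss = 0 and no lapse this
reduces to $0.6745 \cdot \text{jnd}$:

```{r}
threshold_75(list(pss = 0, jnd = 1, lapse = 0))
```

**Decision — thresholds from the fitted curve, not staircase reversals.**
Reversal averages estimate the ~50 % point of the up-down rule and waste
the non-reversal trials; fitting all trials and reading the 75 % point off
the folded curve is both more efficient and the definition used for every
reported threshold here.

## 5. Deficit profiles

Per subject and direction: the relative threshold BLANK/STEP (blanking
benefit), the left–right BLANK threshold asymmetry, and the 8-bin
error-attribution correlation (trials sorted by hypometria error into eight
equal-count bins — remainders go to the lowest-error bins — then Pearson
correlation between bin mean error and bin forward rate; constant reports
are flagged degenerate with p = 1). `cohort_profiles()` builds control
norms and flags values beyond 1.96 control SDs: upper one-sided for
relative thresholds (a deficit is a *missing* blanking benefit), two-sided
for asymmetry, strict inequality at the boundary.

**Decision — lapse policy.** The generative lapse default is 0 and the fits
also fix lapse = 0. With ≤ 144 trials per cell a free lapse trades off
against jnd and inflates threshold variance; simulated observers have no
attentional lapses, so fixing the parameter is the unbiased choice. The
fitting code accepts a nonzero lapse for sensitivity analyses.

## 6. Lesion cohorts and lesion-symptom mapping

`generate_lesion_cohort()` plants a 2 mm-radius critical region at a fixed
thalamic-like coordinate on a 32³ mm grid and draws ellipsoidal lesions
(radii 2–4 voxels, centres scattered with SD 3 mm around the region), so
that some patients overlap it and some do not; masks round-trip through
NIfTI (`RNifti`, sform code 2).

`vlsm_map()` tests each voxel lesioned in at least 2 (and fewer than all)
patients with the **Liebermeister quasi-exact test**: the one-sided p-value
is the upper hypergeometric tail of the (a+1, b, c, d+1)-augmented table,

```r
phyper(a, a + 1 + c, b + d + 1, a + 1 + b, lower.tail = FALSE)
```

which equals the uniform-prior Bayesian probability that the impairment
rate among lesioned patients is at most that among spared patients,
$\int \mathrm{dbeta}(y; b{+}1, d{+}1)\, \mathrm{pbeta}(y; a{+}1, c{+}1)\,dy$.
The test suite verifies this identity exhaustively for all tables with
$n \le 12$ (max discrepancy ~$10^{-15}$) and that Liebermeister is never
larger than Fisher's one-sided p. The balanced table (1,1,1,1) gives
exactly 0.5:

```{r}
liebermeister_test(1, 1, 1, 1)$p
```

**Decision — sidedness.** Maps are one-sided (lesion → impairment): the
anatomical hypothesis is directional and the Bayesian reading is only exact
one-sided. A two-sided p is available as $2\min(p_1, 1-p_1)$ capped at 1,
exact here because the posterior is continuous so the two directions are
complementary.

z-maps use $z = \Phi^{-1}(1-p)$; the peak voxel breaks ties by lesion
count, then index order. `subtraction_map()` contrasts impaired and spared
overlap percentages with a ±15 % display threshold; `power_map()` reports
each voxel's best-case (relabeling) minimum p, i.e. where the cohort could
in principle detect anything at α = 0.05; `label_association()` runs a
1-df chi-square (no continuity correction) per atlas label against the
deficit label, on the package's synthetic four-nucleus parcellation.

## 7. Workflow shape and problem sizes

The repository is an analysis workflow: the reusable machinery lives in the
package, and the study itself is the numbered drivers in `analysis/`
(simulate → oculomotor QC → fits → profiles → VLSM → report), each writing
plain files to `results/` so stages can be rerun independently. The
end-to-end path is also callable as `run_pipeline()`.

Typical sizes and costs (single core): a 144-trial session simulates in
~0.1 s; a 2000-trial psychometric fit takes ~0.6 s; a 22-subject cohort
(12 672 trials) runs through all six drivers in under two minutes; a 32³
VLSM map computes in ~0.03 s because the Liebermeister tail is a single
vectorised `phyper` call over the distinct voxel tables. The full test
suite runs in ~1.5 minutes.
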