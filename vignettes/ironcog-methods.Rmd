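---
title: "Methods: modelling blood-brain-behavior chains in an iron biofortification trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling blood-brain-behavior chains in an iron biofortification trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironcog)
```

# The scientific problem

Iron deficiency, with or without anemia, impairs cognition, and two
physiological channels are plausible: dopaminergic signalling (tracked by
serum ferritin, sFt) and oxygen transport (tracked by hemoglobin, Hb). A
randomized feeding trial that provides an iron-biofortified staple grain to
one arm and a conventional variety to the other, with blood biomarkers, EEG,
and a cognitive battery measured at baseline (BL) and endline (EL), yields
exactly the data needed to ask whether **change in brain activity mediates
the effect of change in iron status on change in behavior**, with change in
Hb moderating the ferritin paths.

`ironcog` implements that analysis chain end to end:

1. **Iron status** — Cook body iron, anemia/ID/IDA/IDNA classification,
   prevalence tables.
2. **Difference-in-differences (DiD)** — per-variable 2 (group) x 2
   (assessment) contrasts.
3. **Plausibility regressions** — change scores on biomarker changes under a
   constrained model space with AIC selection.
4. **Composite scores** — sign-aligned Z change composites for attention and
   memory, behavioral and EEG.
5. **Moderated mediation** — two-equation path model with bootstrap
   intervals and falsification alternatives.
6. **Synthetic cohorts** — a seeded generator that runs the mediation model
   forward, so every stage is testable without subject-level trial data
   (which are not publicly deposited).

# Data model

All stages consume a long *cohort table*: one row per
(subject, assessment, variable) with `group` (`CPM` comparison /
`BPM` biofortified pearl millet), `sex`, and `age`. `validate_cohort()`
enforces the schema; `read_cohort()`/`write_cohort()` move it through
comma-separated UTF-8 text.

# Iron status

Body iron (mg/kg) uses the Cook log-ratio of soluble transferrin receptor
(sTfR, converted ug/mL -> ug/L) to ferritin:

$$\mathrm{BI} = -\frac{\log_{10}(\mathrm{sTfR}\times 1000/\mathrm{sFt}) - 2.8229}{0.1207}.$$

Because the index is nonlinear, it is always computed per subject; the index
of a group-mean panel is not the group mean of the index (Jensen's
inequality), which is why the package never aggregates before transforming.

Cutoffs (all strict inequalities): anemia Hb < 13 g/dL for males aged
15–16 y, < 12 g/dL otherwise (source tables print "ug/dL" once, an obvious
unit slip for g/dL); iron deficiency sFt < 15 ng/mL by default — the value
under which the baseline characteristics table is internally consistent
(IDA + IDNA counts decompose the sFt < 15 row exactly) — with the screening
definition of 20 ng/mL available via `sft_cutoff`; inflammation AGP > 1.0 g/L
or CRP > 5.0 mg/L, where CRP is compared in the units of the input column.
Printed prevalence percentages round half away from zero.

# Difference-in-differences

`fit_did()` fits `value ~ group * assessment` by OLS with dummy coding and
reference levels **BPM** and **BL**, chosen because they reproduce the
published Condition / Assessment / Differences columns:

* condition = CPM(BL) − BPM(BL),
* assessment = BPM(EL) − BPM(BL),
* DiD = [CPM(EL) − CPM(BL)] − [BPM(EL) − BPM(BL)].

Both assessments of a subject enter as observations; the saturated model
reconstructs cell means exactly, and confidence intervals use the pooled
residual variance with t quantiles (the published tables do not state
whether pooled or per-cell variances were used; pooled is the regression
default and is documented here as our choice). No multiplicity correction is
applied across variables, matching the source analysis. Baseline group
comparisons use a 2 x 2 (group x sex) ANOVA with type-II sums of squares
(cells are unbalanced) and chi-squared tests of association without
continuity correction.

`did_table()` also reports the *normalized change difference*: per-variable
Z-transformed, sign-aligned change, averaged per group, reported as
mean(BPM) − mean(CPM) so that positive values mean the biofortified arm
improved more.

The printed contrast tables ship as data (`did_printed_cells()`); three rows
carry an `erratum` note because their printed Condition or Assessment entry
cannot be reproduced from their own printed cells within one printed unit
(a duplicated cell, and two sign slips whose interval centres identify the
intended value). Consistency checks run on the remaining rows, and the
erratum set is frozen by a test so it cannot silently grow.

# Plausibility regressions

For each outcome's change score, candidate predictors are the biomarker
changes {Hb, sFt, sTfR, BdFe} with one hard constraint: body iron is derived
from ferritin and sTfR, so it may never share a model with either
(`enumerate_allowable()`: 10 of 16 subsets survive). Candidates are the null
model, each maximal allowable set ({Hb, sFt, sTfR} and {Hb, BdFe}), and a
backward-stepwise fit from each maximal set (drop the least significant term
with p >= 0.05, refit, repeat; the direction — backward — and the per-term
0.05 threshold are our documented choices where the source only says
"stepwise" and "statistically significant"). Age and sex may enter as
covariates under the same retain-if-significant rule. A model is accepted if
it strictly beats the null on AIC, has the lowest AIC among candidates
(ties: fewer parameters), and explains at least 10% of the variance;
otherwise the outcome is reported as having no acceptable model. The AIC is
the Gaussian OLS form `n log(RSS/n) + 2(k+1)`.

A note on verification design: the equivalence of this selection with an
exhaustive search over all allowable subsets is checked on simulated data
with clearly active (|t| ~ 5) and clearly inactive predictors. Near the
retention threshold (|t| ~ 2) the p-value rule and AIC legitimately
disagree — AIC's implied one-parameter threshold is p ~ 0.157 — so
borderline-signal test beds measure that policy difference, not
implementation error.

# Composite scores

Change scores (EL − BL) are Z-transformed over the pooled cohort (both
arms) and sign-aligned so positive always means improvement: reaction times
and N1 amplitudes are negated (faster responses, larger-magnitude negative
N1), sensitivity, capacity change, P3 and band power are kept, sTfR is
negated among the biomarkers. Composites are plain arithmetic means of their
components (no factor weighting): behavioral capture (go/no-go RT, 2-cue
RT), selection (spatial-cue RT, incongruent-flanker RT), memory (face-task
RT and sensitivity, recognition capacity change), and EEG counterparts built
from the N1/P3 amplitudes of the corresponding conditions, plus gamma power
for the memory family. The exact condition-to-composite mapping is a
convention the source does not enumerate; it is configurable
(`default_composite_map()`) and recorded in the emitted sign-map manifest.
A subject missing some components of a composite receives the mean of the
available ones, with a warning.

Because Z-scoring re-centres and re-scales, injecting an improvement for a
subset of subjects must raise that subset's average Z change — the audit the
tests apply — but an individual with an extreme baseline score can move
slightly the other way purely through the inflated scale; the audit is
therefore on the group mean, not each subject.

# Moderated mediation

With X = Z change in sFt, W = Z change in Hb, M an EEG composite and Y the
matching behavioral composite, two OLS equations are fitted:

$$M = a_0 + a_1 X + a_2 W + a_3 XW + \varepsilon_M$$
$$Y = b_0 + c_1 X + c_2 W + c_3 XW + b_M M + \varepsilon_Y$$

Moderation sits on the two X paths only; the M -> Y path is unmoderated.
Effects: direct = $c_1$ and indirect = $a_1 b_M$, both at W = 0 (the mean of
the Z-scored moderator, matching single-number published effect estimates);
index of moderated mediation = $a_3 b_M$; and the conditional indirect
effect $(a_1 + a_3 w) b_M$ is reported at w = −1, 0, +1.

Confidence intervals come from nonparametric case resampling: subjects are
resampled with replacement, both equations refitted, and 2.5/97.5
percentiles taken (5000 replicates by default, seeded). Percentile rather
than bias-corrected intervals are the simplest form consistent with the
asymmetric intervals a product of coefficients requires. If more than 1% of
replicates are rank deficient the bootstrap aborts with a diagnostic.

Falsification alternatives: a *direct-only* model (Y ~ X, no mediator or
moderator) and a *scrambled* model, operationalized as the cyclic role
rotation (outcome -> predictor role, predictor -> mediator role,
mediator -> outcome role, moderator unchanged) refitted with the same
machinery — the source's phrase "rearranging the order of the effects" is
ambiguous, and the rotation is the documented choice. Selection criteria:
(a) every component equation's overall F significant; (b) every component
R² >= 0.10; (c) every non-intercept parameter significant; (d) the chosen
model must have a lower total AIC (sum of the two equations) than every
two-equation alternative and a lower outcome-equation AIC than the
direct-only model, whose single equation shares the same response.
Non-significant moderation terms can be pruned and refitted
(`prune_mediation()`); the structural X and M paths are never silently
removed — criterion (c) judges them instead.

**A structural caveat the package's own simulations exposed.** For jointly
Gaussian data, the true chain and its rotation factor the same joint
density up to one marginal: $p(M\mid X)\,p(Y\mid X,M) = p(X,M,Y)/p(X)$
while the rotation gives $p(X,M,Y)/p(Y)$. After standardization those
marginals match, so *without moderation the summed AICs of the true and
scrambled systems are asymptotically identical*; only the interaction
terms — which the rotation cannot re-express — separate them, and at n = 74
with moderate moderation the scrambled model loses on AIC in roughly
three-quarters of cohorts rather than nearly all. The acceptance suite
reports that rate as measured; AIC comparison against a role-rotated
alternative is intrinsically weak evidence, and the component-R² criterion
(b) — which the scrambled model's first equation fails robustly — carries
most of the falsification weight in practice.

Identifiability of degenerate cases: with *no* disturbance anywhere, a
mediator that is an exact linear function of X (and W) is collinear with
the outcome design, and the fit correctly errors. Noiseless-recovery tests
therefore give the mediator variation of its own through the moderator main
path and use the pruned outcome equation Y ~ X + M, under which the exact
indirect effect is recovered to machine precision.

# The synthetic cohort generator

`simulate_cohort()` emulates the study design: 33 CPM and 41 BPM subjects
aged 12–16, baseline Hb/sFt/sTfR drawn per group from normals truncated at
zero with means from the published baseline table and SDs recovered from
the printed standard errors (SE x sqrt(n)); CRP/AGP at low-inflammation
values (1.0 mg/L and 0.6 g/L) since no moments are printed. Ferritin change
means are the published per-group endline-minus-baseline cells (+1.55 CPM,
+5.26 BPM ng/mL) with SD 8 ng/mL (consistent with the width of the
published assessment-contrast intervals); hemoglobin changes (−0.07/+0.32
g/dL, SD 1) correlate 0.3 with ferritin changes so moderation is exercised
on correlated predictors; sTfR drifts follow the published cells.

The structural chain runs the mediation model *forward on the raw change
scale* — `latent_EEG = a0 + a1 d_sft + a2 d_hb + a3 d_sft d_hb + noise`,
then the behavioral latent with the mediator path `b_m` — one latent
EEG/behavior pair per composite family (capture, selection, memory), which
is why downstream parameter recovery is a meaningful end-to-end test.
Default paths (`default_paths()`) put the ferritin path near half a latent
SD per SD of ferritin change with positive moderation on both ferritin
paths, the model form the published analysis selected. Latents map to the
individual task/ERP variables with unit loadings, a per-variable native
scale, indicator noise (0.3 latent SD), and a generation-time sign flip for
reaction times and N1 amplitudes so that larger latent improvement lowers
RT and deepens N1 — the mirror image of the analysis sign map.

Two honesty notes. First, to keep endline biomarkers positive the ferritin
change is truncated just above −baseline, which lifts the realized change
mean for low-ferritin subjects; the generator's tests compare against the
truncated-normal expectation rather than the nominal mean. Second, the
generator does **not** emulate dropout or missingness, trial-level RT
distributions, covariance among task variables beyond the shared latent
(the source gives none), or EEG artifacts; passing tests therefore
demonstrate correctness of the estimation machinery under the declared
generative model, not robustness to those real-data features.

Trial-level epochs (`simulate_erp_epochs()`) are plumbing for the feature
extractors: Gaussian bumps at 150 ms (N1-like, SD 25 ms) and 400 ms
(P3-like, SD 60 ms), 10 Hz and 40 Hz sinusoids, white noise, sampled at
250 Hz over −200…800 ms. Note the 250 Hz grid anchored at −200 ms brackets
150 ms at ±2 ms rather than sampling it exactly.

# ERP feature summarization

Component amplitudes are **mean** (not peak) amplitudes in a window after
mean-baseline correction over −200–0 ms — robust for small samples; default
windows N1 80–180 ms and P3 300–500 ms, both configurable since the source
does not fix them. Band power uses a Welch periodogram — Hann window, 1 s
segments, 50% overlap, per-segment mean removal (so DC offsets drop out) —
scaled so the density integrates to the signal variance; bands default to
alpha 8–12 Hz and gamma 30–45 Hz. The periodogram is implemented directly
on `stats::fft()` with `signal::hanning()` windows. Load slopes are exact
least-squares slopes of a feature against load level, and the composite-face
contrast is the double difference
(aligned: different − same) − (misaligned: different − same).

# Problem sizes and tolerances

The simulation suites use: 500 cohorts of n = 74 for indirect-effect
recovery (bias tolerance 0.02) and percentile-bootstrap coverage
(500 replicates per cohort, acceptance band 0.90–0.98); 1000 cohorts for
the type-I rate of the bootstrap interval (bound 7%); 500 cohorts for the
falsification comparison; 100 random datasets for oracle equivalence of
every least-squares stage at 1e−10; and 200 trials for stepwise-vs-
exhaustive agreement. Exact arithmetic checks (printed-table reproduction,
enumeration, Z audits) run at machine precision or one printed unit, as
appropriate.

# Known limitations

* The mediation model is estimated by OLS path analysis; no latent-variable
  or multilevel estimation, and mediation on observational change scores is
  at best weak causal evidence.
* The scrambled-model AIC comparison is structurally weak (see above).
* Composite membership for EEG conditions is a declared convention.
* The generator's truncation and loading choices are defaults, not
  estimates; real assay and task covariance structures are unknown.
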