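---
title: "Models and methods behind fearcond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fearcond}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearcond)
```

`fearcond` implements the full analysis chain from trial-level differential
fear-conditioning data to the prospective prediction of emotional distress:
task-schedule construction, data reduction into learning indices, profile
clustering, diathesis–stress regressions, and growth mixture modelling of
weekly coping trajectories. This vignette documents the models, the
numerical choices, and the places where a design decision was genuinely
open, so that a user can judge what a passing test suite does and does not
establish.

## The task grammar

Each of the three task days starts with differential fear acquisition: 8
presentations of a threat cue (CS+) and 8 of a safety cue (CS−), with six
of the eight CS+ presentations followed by the aversive outcome — a 75%
reinforcement rate. The day then continues with extinction (12 + 12
unreinforced trials), avoidance (6 + 6 trials without response cost
followed by 6 + 6 with a one-point cost), or generalization (two trials of
each of CS+, CS−, and four intermediate-size stimuli GS1–GS4). Expectancy
and distress are rated on 0–10 integer scales.

The stimulus order is fixed across participants, emulating a trial order
randomized once before a study begins. To make that order reproducible
independently of R's session RNG, schedules are drawn from a dedicated
Lehmer generator (`state' = 16807 · state mod 2³¹−1`) under a constrained
shuffle (at most three consecutive presentations of the same stimulus).
Which six CS+ presentations are reinforced is not fixed by the constants
above; we always reinforce the first two presentations (so early learning
is possible for every learner) and place the remaining four by the seeded
shuffle. One schedule is generated per day from the same stream; whether a
real study would re-randomize per day is unknowable from the published
constants, so the package exposes a single seeded procedure for all three.

Counterbalancing is deterministic and cyclic: participant id `i` receives
task order `(i − 1) mod 6` out of the six permutations and shape-role
mapping `((i − 1) div 6) mod 2`, which balances both factors exactly over
any block of 12 consecutive ids.

## The synthetic cohort generator

The generator is a minimal Rescorla–Wagner / logistic / similarity-gradient
stack. It is *not* a model fitted to human data; it was chosen because each
latent parameter has an analytic limit and a monotone link to exactly the
index that is supposed to measure it, which is what makes recovery testing
meaningful.

* **Expectancy.** Associative strength `V ∈ [0, 1]` updates as
  `V ← V + α (λ − V)` with `λ = 1` when the outcome is delivered. The CS+
  uses `alpha_plus` (acquisition, avoidance) or `beta_ext` (extinction).
  The CS− starts at `v0 + (1 − alpha_minus)(1 − v0)` and decays toward 0
  at rate `alpha_minus`: a *safety-learning deficit* is a slow decay from
  an inflated start, not excitatory learning, so CS− responding varies
  independently of CS+ acquisition. A rating is
  `round(clamp(10 V + ε, 0, 10))` with participant noise `ε ~ N(0, eps_sd²)`.
* **Distress.** `round(clamp(10 · gamma_distress · V + ε))` — distress is
  expectancy passed through a participant-specific gain, which lets the
  primary and secondary indices dissociate.
* **Avoidance.** Press probability `plogis(pi_avoid + 4 V − kappa_cost ·
  cost)`; given a press the latency is uniform on 0–2 s.
* **Generalization.** First-trial values follow a Gaussian gradient over
  the ordinal size continuum,
  `V(rank) = v_minus + (v_plus − v_minus) exp(−((5 − rank)/sigma_gen)²)`,
  anchored at the day's post-acquisition strengths.

**Population choices.** Learning rates are Beta-distributed with a
deliberate slow tail: `beta_ext ~ Beta(1.2, 4)` because extinction within a
single 24-trial session is typically incomplete and the whole-phase index
only discriminates below rates of about 0.25; and 12% of the population is
drawn as an *unengaged* subpopulation with both learning rates from
`Beta(1, 8)`, which is what the nonlearner exclusion rule exists to catch
in unsupervised online studies. Under these defaults roughly 6–9% of a
cohort fails differential responding per day and the rank correlation
between each latent and its index exceeds 0.7 at n = 200. These values were
fixed once, before the downstream analyses were run against them.

**Questionnaires.** A Part-2/3 outcome on the Z scale is
`stability · Z(baseline) + Σ w_j Z(index_j) + failure · failed_c +
nle · Z(NLE) + interactions + noise`, mapped onto the instrument range by
rounding and clamping. Planted weights therefore act on the cohort's own
Z-scored indices, so ordinary least squares recovers them without
circularity. The clamping step makes the effective weight vary slightly
between cohorts (about 1.2× the nominal sampling error), which is why the
recovery tests are phrased across seeds rather than on a single draw.
Default planted effects mirror a safety-learning-deficit pattern (CS−
acquisition predicting stress, depression and self-generalization;
CS+ avoidance predicting anxiety); they can be removed or replaced through
`cohort_params()`. Stressors are independent of the latents by default;
coupling (e.g. avoidance propensity with threat acquisition) is opt-in.

**Weekly trajectories.** Participants with disappointing failed exams
follow one of three latent quadratic classes over ten weekly
impact-of-event measurements — persistent impact (30, −0.4, 0.02),
adjustment (26, −2.8, 0.14), early disengagement (18, −4.2, 0.30) — with
random intercepts (sd 4) and slopes (sd 0.5) and residual sd 3, clamped to
the 0–45 sum range. Class membership is mildly coupled to avoidance
propensity and distress gain by default, emulating the finding that
persistent-impact trajectories go with more avoidance and stronger distress
acquisition. The failure rate (0.40) together with Part-2 participation
(0.88) puts the follow-up subsample near 230 of 655, the order of magnitude
of the study the structure emulates.

What the generator does **not** emulate: human learning-curve shapes beyond
monotone links, response-time structure, item-level questionnaire data,
missingness mechanisms other than independent dropout, and any dependence
of dropout on symptoms. Passing recovery tests therefore establishes that
the pipeline measures what the generative model encodes — not that the
indices are valid measures of human learning.

## Data reduction: exclusion and the thirteen indices

A participant is retained for a day's phase-specific indices iff the mean
US-expectancy over the *final three* CS+ acquisition presentations of that
day strictly exceeds the CS− counterpart. "Higher" is read literally, so
ties exclude. Exclusions are day-specific; the day-1 acquisition indices
are always computed.

The seven primary indices are the day-1 acquisition means (CS+ and CS−),
two reverse-scored extinction declines, the no-cost avoidance counts (CS+
and CS−), and the range-corrected generalization ratio; the six secondary
indices repeat acquisition/extinction/generalization on the distress
channel and add the cost-phase CS+ avoidance count.

Numerical conventions worth knowing:

* **Midway bracketing.** The group midway point is the average of the group
  CS+ means on extinction trials 1 and 12; the bracket is the *first*
  consecutive pair `(t, t+1)` with `mean_t ≥ midpoint ≥ mean_{t+1}`. A flat
  or immediately sub-midpoint curve brackets `(1, 2)`; a curve that never
  crosses downward brackets the pair whose average is closest to the
  midpoint, earliest on ties. The group means are computed over retained
  participants of the extinction day (configurable), and the distress
  early-extinction index reuses the expectancy-based midway.
* **Reverse scoring.** Both extinction indices are `later − first`, so a
  decreasing curve scores negative and "higher = less extinction".
* **Latency boundary.** A press at exactly 2.0 s counts as avoided ("in
  the first 2 s" read inclusively).
* **Range-corrected GEN** is `ΣGS / max(all six first-trial ratings)`,
  in `[0, 4]`, undefined (missing, flagged) when the maximum is 0. The
  abandoned preregistered variant `(ΣGS − 4·CS−)/(CS+ − CS−)` is exposed
  behind `gen_variant = "prereg"` for sensitivity analyses; it explodes
  when CS+ responding is low or CS− responding high, which is exactly why
  it was abandoned, and it is not validated against any reference values.
* **Z-scaling** uses the sample sd (n − 1) over available cases per index,
  after exclusions. With fewer than two values or zero spread the raw
  values are retained with a warning.

## Manipulation checks and correlations

The 2×2 within-subject ANOVA (Stimulus × first/last trial) is computed from
per-participant difference scores, which is exact for two-level factors and
sidesteps sphericity corrections the design cannot violate; partial η² for
a single-df within effect reduces to `F / (F + n − 1)`. The six-stimulus
generalization check is a classical one-way within-subject decomposition
with η² = SS_stimulus / SS_total. Correlations switch from Pearson to
Spearman when either variable fails a Shapiro–Wilk gate at α = 0.05 — the
gate is a documented convention, since no specific normality test is
canonical for this switch. All p-values are two-sided and deliberately
uncorrected for multiplicity (the analyses are exploratory by design); the
regression ledger keeps raw p-values so Benjamini–Hochberg can be layered
on afterwards.

## Profile clustering

k-means (Hartigan–Wong via `stats::kmeans`, squared Euclidean, 50 restarts
at the chosen k, 300-iteration cap) runs over the Z-scored indices of a
channel, with listwise deletion over the chosen subset. The cluster number
is selected by the gap statistic with a uniform reference over each
feature's observed range — the simpler of the two classical reference
choices — using `gap(k) = E*[log W_k] − log W_k`, spread
`s_k = sd · √(1 + 1/B)`, and the standard "first k with gap(k) ≥
gap(k+1) − s(k+1)" rule, with B = 100 reference draws by default. Three
variants are exposed: the preregistered five indices (extinction,
avoidance, generalization), all seven primary indices, and the secondary
channel. A table with no variation at all returns k = 1 trivially.

## Hierarchical prediction models

Every prediction model is ordinary least squares with classical standard
errors, fitted as a hierarchy: baseline covariate only, plus main effects,
plus interactions. Outcome and baseline are Z-scored over the model's
complete cases; indices enter as cohort Z-scores; the binary failure
indicator is centred (a documented choice — an uncentred indicator changes
only the main-effect parameterization); life-event counts are Z-scored.
Interaction terms are products of these standardized components, and main
effects are always retained alongside their interactions. The self-
generalization scale has no Part-1 administration, so its models use the
baseline anxiety (GAD-7) score as covariate — a package convention, made
explicit in the `hier_fit` object. Rank deficiency raises an error naming
the collinear terms rather than silently dropping them.

`run_paper_grid()` enumerates the full family — each index alone, each
index × failure, each index × life-event count/burden, and all 21 pairwise
index × index products — one model per cell, and collects the focal term
per cell into a tidy ledger.

## Growth mixture models

The trajectory module is self-contained maximum likelihood: for participant
`i` in class `k`, `y_i = X_i β_k + Z_i b_i + e_i` with `b_i ~ N(0, Ψ)` and
`e_i ~ N(0, σ² I)`. Class-specific fixed coefficients; `Ψ` and `σ²` shared
across classes (the common default in latent-class growth software; the
source analyses do not state theirs). Effects structures: none (latent
class growth analysis), random intercept, or random intercept + linear
slope. The quadratic term is never random — whether the reference analyses
randomized it is unstated, and a random quadratic at n ≈ 216 with ten
waves is fragile.

Estimation is EM over class responsibilities and random-effect posterior
moments, grouped by observed-week pattern so balanced data cost one matrix
factorization per iteration. The update for `β_k` is the responsibility-
weighted least squares on `y_i − Z_i E[b_i]`, and `σ²`/`Ψ` use the full
conditional second moments, so the observed-data log-likelihood is
provably nondecreasing; the implementation asserts this on every iteration
(`monotone_ok`). Convergence is a relative log-likelihood change below
1e−6 with a 500-iteration cap. Multi-start (100 by default) perturbs a
K-quantile split of the individual OLS intercepts; the first start is the
unperturbed split. Starts whose smallest class responsibility collapses are
discarded and the best remaining log-likelihood wins. A residual variance
pinned at the 1e−12 floor sets a `sigma_floor` flag (noise-free data).
Time is coded 0..9 over the ten weekly measurements; the logarithmic shape
uses `log(t + 1)` so week 0 is finite. Free parameters are
`(K − 1) + K·p + {0, 1, 3} + 1`, and `BIC = −2 logL + p·log(n_subjects)`.
Model selection takes the lowest BIC among converged fits, ties to fewer
parameters. The bootstrapped likelihood-ratio test is deliberately not
implemented. The K = 1 fit is cross-checked against `lme4` maximum
likelihood in the test suite; `lme4` is never used in the estimation path.

Classes are relabelled by descending fixed intercept and participants
assigned by highest posterior probability, exact ties to the lower class
index. Class–index association uses one-way ANOVA per index, switching to
Kruskal–Wallis (with rank η² `(H − k + 1)/(n − k)`) when pooled
within-class residuals fail the Shapiro–Wilk gate; post-hoc pairwise
comparisons use Bonferroni-adjusted p-values and match the omnibus method.

## Problem sizes and reproducibility

The package's own validation runs at deliberately chosen scales: recovery
correlations at n = 200, regression recovery at n = 600 across four seeds,
type-I calibration over four null cohorts of 250, gap-statistic selection
over 20 seeds at n = 120 with B = 20, and mixture recovery at n = 216 with
ten weeks, classes `K ≤ 4` and six random starts. These sizes keep every
property measurable with comfortable margins while remaining quick enough
to run routinely; `n_starts = 100` and `B = 100` remain the analysis
defaults. All randomness in a pipeline run flows from the single
`pipeline_config()` seed; schedules additionally carry their own Lehmer
stream so the trial order is stable across R versions and sessions.

## Known limitations

* The generator's monotone-link design means recovery tests validate the
  pipeline's arithmetic and inference, not the psychometric validity of
  the indices on human data.
* Avoidance-day expectancy dynamics treat an avoided outcome as a
  non-reinforced trial; competing theoretical accounts (e.g. protection
  from extinction) are not modelled.
* The shared-variance mixture can prefer extra classes when the true
  random-effect structure is heavier-tailed than normal; BIC selection
  inherits the usual sensitivity to n.
* Listwise deletion is used throughout (clustering subsets, regression
  models); no imputation machinery is provided.
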