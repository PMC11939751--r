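---
title: "Bayesian rule sets for ordinal survey data: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian rule sets for ordinal survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brsurvey)
```

## The problem

Survey research on job satisfaction routinely asks which *combinations* of
conditions — sleep quality, autonomy, working hours, health — distinguish
highly satisfied respondents, not which variables matter marginally.
Regression answers the marginal question; this package answers the
combinatorial one with an OR-of-ANDs **rule set classifier**: a small
collection of rules such as

> IF health is medium-or-high AND autonomy is high AND work time is low
> THEN predict high job satisfaction,

where a respondent is predicted positive when *any* rule fires. The
package implements the full analysis around that model for CGSS-style
resident-survey extracts (18 variables: ordinal ratings on 1–4/1–5/1–10
scales, continuous hours/minutes/income, 0/1 indicators), together with a
synthetic-survey generator so every stage can be exercised and verified
without access to the restricted survey file.

## Model

Let $S$ be the prepared data (binary features plus a binary outcome) and
$A = \{a_1,\dots,a_M\}$ a candidate rule set, each rule a conjunction of at
most $L$ binary literals. The posterior over rule sets is

$$p(A \mid S) \propto \pi(A)\, p(S \mid A).$$

**Prior.** $\pi(A)$ penalizes size and length: a Poisson distribution with
mean $\lambda$ on the number of rules and a probability vector over rule
lengths $1..L$,

$$\log \pi(A) = \log \mathrm{Pois}(|A|;\lambda) + \sum_{a \in A} \log w_{|a|}.$$

Defaults: $\lambda = 3$ (the analysis is designed to report 2–3 rules) and
uniform $w$. Note $\mathrm{Pois}(2;3) = \mathrm{Pois}(3;3)$, so the default
prior is indifferent between two and three rules — a consequence visible in
the bootstrap analysis below.

**Likelihood.** Rows are split into the covered stratum (some rule fires)
and the uncovered stratum. Each stratum's positive rate gets a conjugate
Beta prior and is marginalized, giving a Beta-Binomial in the confusion
counts:

$$\log p(S \mid A) =
  \log \frac{B(\mathrm{TP}+\alpha_+,\ \mathrm{FP}+\beta_+)}{B(\alpha_+,\beta_+)}
+ \log \frac{B(\mathrm{FN}+\alpha_-,\ \mathrm{TN}+\beta_-)}{B(\alpha_-,\beta_-)}.$$

Defaults $\alpha_+ = 100, \beta_+ = 1$ (covered rows expected positive) and
$\alpha_- = 1, \beta_- = 100$ (uncovered rows expected negative). The
orientation matters: the Beta prior sits on each stratum's *positive* rate.
With the strata transposed the model rewards covering noise and the
property test "perfect separation beats any single-bit corruption" fails —
that test is in the suite precisely to pin the orientation.

**Search.** The posterior is discrete and multimodal; `brs_fit()` runs
independent annealed Metropolis chains (default 10 × 10,000 iterations;
geometric temperature 1.0 → 0.01; add/remove/replace moves with
probabilities 0.4/0.4/0.2) over subsets of a mined candidate pool. Two
details make the search work at pool sizes in the thousands:

* **Guided proposals.** An add (or the add half of a replace) samples a
  currently uncovered positive row and proposes uniformly among pool rules
  covering it, falling back to a uniform pool draw. Uniform proposals
  essentially never find a specific good rule among 5000 candidates within
  realistic budgets.
* **Greedy polish.** Each chain ends with a vectorized hill-climb — best
  single add, remove, or one-for-one swap until no move improves the
  posterior — so every chain reports a local mode. On study-sized problems
  the polished 3-chain × 500-iteration configuration reproduces the
  10-chain × 3000-iteration MAP exactly, which is how the bootstrap stage
  stays affordable.

## Pipeline

**Preparation** (`prepare_survey()`). Reverse-code autonomy, sleep quality
and job satisfaction so higher = more; drop variables with more than 10%
missing values (5% in the robustness variant) and then delete incomplete
rows listwise; remove rows reporting more than 84 h of weekly work (84
exactly is kept); dichotomize the outcome at mean + 1 SD (strictly above =
high); discretize ordinal variables by rating levels (level $\ell$ of $k$
maps to grade $\lceil 3\ell/k \rceil$) and continuous ones at their type-7
empirical terciles; expand each 3-grade variable into the four overlapping
binaries *low*, *low-or-med*, *med-or-high*, *high* plus a `NOT_`
complement for each. Two cutpoints give three bins; the "four categories"
are the overlapping binary features, which is the only reading under which
nested threshold rules like "not (low or med)" are expressible. Over three
bins every complement duplicates a base feature column-wise
(`NOT_low = med_or_high`, `NOT_low_or_med = high`), so mining
deduplicates content-identical columns and rule identity is canonical.

**Mining** (`mine_candidates()`). All conjunctions of ≤ 3 literals covering
at least ⌈5% · n⌉ rows, excluding contradictions (a feature with its
complement — support zero anyway) and conjunctions extensionally equal to
one of their sub-rules (a literal implied by another, ubiquitous with
nested categories). Pools above 5000 are screened by information gain
toward the positive class. Support is counted over all rows ("appear in at
least 5% of the data"); a class-conditional option exists in the config.

**Stability** (`bootstrap_stability()`). B bootstrap resamples (default
100; the packaged study conditions use 50), re-mine and re-fit on each;
a rule's *prevalence* is the fraction of resamples whose MAP set contains
it (identity = exact canonical literal set); its coverage is split into
true-positive (positive sign) and false-positive (negative sign)
contributions, evaluated in-bag by default (out-of-bag optional), with
2.5th/97.5th percentile intervals of the signed coverage. Rules at or
above 5% prevalence form the aggregated rule set.

**Causal extension.** The core variable splits the sample at mean + 1 SD
into high/low groups; a logistic propensity model over the controls feeds
either greedy nearest-neighbour/caliper/radius matching (caliper default
0.2 SD of the logit of the score) or inverse-probability weights
$1/p$ and $1/(1-p)$ with a 99th-percentile extreme-weight flag. Fitted
rules become 0/1 indicator columns; three least-squares regressions (the
mediator on treatment + controls + rules; the outcome on treatment +
mediator + controls; the outcome on all of them) decompose each rule's
association into an indirect effect (mediator-path coefficient × the
mediator's outcome coefficient, delta-method SE) and a direct effect.
Identical indicators are merged, a cross-validated LASSO
(`lambda.1se`) filters weak rules, and VIFs are reported — in that order.
Ungrouped analyses simply omit the treatment term.

**Baselines.** LASSO over up-to-third-order interaction products with an
OLS refit on the selected support (plain 5%-level t-tests, no multiplicity
correction — a documented caveat, mirroring the enumeration style of the
comparison it reproduces); CART rule extraction (each path to a positive
leaf is a rule) at a complexity matched to the aggregated rule set; and
random-forest impurity importance, normalized to sum to one.

## The synthetic generator as study conditions

`default_survey_spec()` fixes the 18 variables with their original codings
and ranges (work time 0–84 h/week, sleep 6–12 h, age 18–65, income ≥ 0
log-normal with mean near 79k and a heavy right tail, sleep quality
concentrated at "Good"). Continuous marginals match the published
descriptives. For the most skewed ordinal items (health, the two
work-family conflict items, fairness, trust) the generator moderates the
skew so that **every overlapping category keeps roughly ≥ 10% mass**. This
is a deliberate design principle, not a calibration detail: a category
with 2–5% mass yields features that can never clear the 5% support
threshold and literals so close to vacuous that planted-truth recovery is
ill-posed (any ≥ 95%-prevalent literal substitutes freely). A generator
meant to *test* rule recovery must keep its planted literals identifiable.

Rules are planted on the discretized categories, so the ground truth is
expressible in the mined feature space. Rows satisfying any planted rule
draw a high outcome with probability $1 - \text{noise}$, all others with
probability $\text{noise}$; the outcome is then emitted as an ordinal
rating whose mean + 1 SD cutoff isolates the top level, so the pipeline's
dichotomization reproduces the generator's labels. With a `target_support`
the generator forces rule support by conditional resampling (and breaks
accidental satisfaction elsewhere, preferring literals not shared with the
row's own rule); without one, support follows the independent marginals —
the two headline rules land near 9–12%. Missingness is MCAR (the pipeline
only filters on missing *fractions*, so MCAR suffices to test the filter);
work-time outliers are drawn uniformly on (85, 168).

What the generator does **not** emulate: survey weights, household
clustering, and any inter-variable dependence beyond what the planted
rules induce. Passing tests therefore demonstrate correctness of the
machinery under independence plus planted structure, not performance on
the dependence patterns of real survey data.

## What the bootstrap shows under the study conditions

At n = 1000, 10% noise, B = 50 (five different master seeds), the two
planted rules are recovered with prevalence 0.80–1.00 while every other
rule stays below 0.3 — a wide margin that cleanly identifies the
planted structure. The aggregated set at the 5% prevalence threshold is
nevertheless usually *not exactly* the planted pair: per-resample MAP sets
genuinely include a third rule, or swap the weakly identifying
sleep-quality literal (marginal prevalence 0.83), in a minority of
resamples, and those variants accumulate 6–16% prevalence. This is a
property of the model under the default prior — the Poisson($\lambda=3$)
prior charges nothing for a third rule — and of bootstrap noise, not of
the search: re-running resamples at 6× the iteration budget reproduces the
same MAP sets. Consumers of the aggregated set should read prevalence as
the primary evidence and treat the sub-0.2 tail as bootstrap variants; the
causal extension's LASSO filter is the packaged remedy for pruning them.

## Numerical and degenerate-input choices

* Quantiles are type-7 (linear interpolation) everywhere; tercile bins use
  left-closed comparisons (≤ lower cutpoint = bottom). Degenerate
  cutpoints (heavy ties) warn and collapse the middle bin.
* A zero-variance outcome dichotomizes to all zeros with a warning; a
  zero-variance treatment variable is an error (both groups are required).
* Mining order is deterministic: by length, then decreasing gain, then
  rule string; fits and bootstraps are reproducible from a single seed
  (per-resample chain seeds are drawn from the master seed).
* Perfect separation in the propensity model fails loudly, naming the
  covariate with the largest coefficient.
* Empty rule sets are legal throughout (they predict all-negative);
  an empty candidate pool is an error with guidance.
* Problem sizes in the packaged analyses — n = 1000 respondents, 50
  bootstrap resamples with 3 chains × 500 iterations each, n = 5000/2000
  for the propensity and mediation recovery checks — are the package's
  validation conditions; the heavier 10 × 10,000 configuration remains the
  default for one-shot fits.

## Known limitations

* Bootstrap prevalence uses exact literal-set identity; near-duplicate
  rules are not merged at the stability stage (by design — merging is the
  causal stage's LASSO filter's job), so aggregated sets carry a variant
  tail under label noise.
* The mediation decomposition is associational; no identification
  assumptions are checked, and sensitivity analysis for unmeasured
  confounding is out of scope.
* The interaction screen's significance flags are uncorrected for
  multiplicity, matching the comparison it mirrors.
* Ordinal grade maps are fixed (contiguous thirds of the level range);
  survey items whose substantive "low/medium/high" boundaries differ need
  a custom spec.
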