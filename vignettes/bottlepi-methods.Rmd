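---
title: "Methods: bottleneck history, pooled diversity and evolutionary response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottleneck history, pooled diversity and evolutionary response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottlepi)
```

## What the package models

`bottlepi` implements, end to end, an analysis that asks which of two
quantities better predicts the adaptive capacity of replicated
experimental-evolution lines: the *expected* inbreeding coefficient implied
by each line's population-bottleneck history, or the *realised* genomic
variation measured as nucleotide diversity from pooled sequencing. The
setting it emulates is a large Drosophila experiment: lines founded from a
mass-bred base pass through 2, 3 or 5 generations at a census size of 4
(two breeding pairs), are flushed back to ~200 individuals, are sequenced
as pools of 15 males, and are then reared for ten generations on a
line-specific stressful medium while productivity, dry body mass,
extinction, and before/after egg-to-adult viability are scored.

Because the original raw data are not redistributed, the package ships a
synthetic-cohort generator whose defaults encode that study design, so
every downstream stage (diversity estimation, response slopes, predictor
comparison) is runnable and testable at desk scale.

## Inbreeding theory

Two closed forms anchor everything.

**Expected inbreeding.** For lines propagated by separate-sex breeding
pairs, identity by descent obeys the two-generation-memory recursion

$$F_t = F_{t-1} + \frac{1 - 2F_{t-1} + F_{t-2}}{2N_e}, \qquad
F_0 = F_{-1} = 0,$$

implemented in `expected_inbreeding(ne, n_steps)`. With $N_e = 4$ this
yields 0.125, 0.219 (exactly 7/32) and 0.381 (exactly 195/512) after 1, 2
and 4 steps. The package adopts the convention that the *first* pairing
draws unrelated parents from the mass-bred base, so a design with $g$
bottleneck generations corresponds to $g - 1$ recursion steps
(`design_f_steps()`); designs with 2, 3 and 5 bottleneck generations
therefore carry expected F of 0.125, 0.219 and 0.381. The opposite
convention is available through `first_pairing_unrelated = FALSE`.

`expected_inbreeding()` also exposes the monoecious (random-selfing)
one-generation form $F_t = F_{t-1} + (1 - F_{t-1}) / (2N_e)$, whose
complement $(1 - 1/(2N_e))^t$ is exactly the decay of gene diversity under
binomial Wright–Fisher drift (`expected_het_retention()`). The two forms
agree at one step and then diverge slowly (0.219 vs 0.234 at two steps;
0.381 vs 0.414 at four). This distinction matters for calibration: an
allele-frequency simulator *cannot* realise the breeding-pair recursion —
its gene-diversity decay is the geometric form by construction — so the
simulator is validated against the geometric oracle, while the
breeding-pair values are the ones used as the "expected F" predictor in
the headline comparison, and `validate_against_theory()` prints both side
by side.

**Effective size.** `harmonic_ne()` implements
$N_e = t \,/\, \sum_i 1/N_i$ over a fluctuating census trajectory. For the
trajectories `[1000, 4 x g, 200]` with $g = 2, 3, 5$ the harmonic means are
7.9, 6.6 and 5.6: *decreasing* with more bottleneck generations. Published
reports sometimes attach these values to labels in the opposite order;
`check_ne_labels()` compares a reported set against the computation and
flags an apparent transposition. The package keys every value to the
census trajectory, never to a label.

## The synthetic cohort

### Founder pool

`founder_pool()` draws locus frequencies i.i.d. from a truncated
Beta(0.5, 0.5) on [0.05, 0.95] — a U-shaped spectrum resembling a large
neutral population, truncated because the pooled caller would not report
sites far below 10% frequency anyway. The base population's true spectrum
is unknown; the law is a modelling choice and fully configurable. Loci are
placed on chromosomes 2, 3, 4 and X (weights 0.38/0.40/0.02/0.20, roughly
proportional to chromosome sizes); the X fraction exists so the autosome
filter downstream is exercised, and male hemizygosity is deliberately not
modelled since X sites never reach the diversity estimate.

The default locus count (25,000) is set so that, after drift and
filtering, per-line SNP counts land in the low tens of thousands, the
range reported for pooled GBS of such lines.

### Linkage blocks

Loci are grouped into `n_blocks = 8` contiguous blocks that share one
genealogy during the bottleneck phase. This is the coarsest realistic
model of linkage in a Drosophila pedigree over 2–5 generations: there are
five major chromosome arms, males are achiasmate (no recombination), and
females contribute of the order of one crossover per arm per meiosis, so a
line's genome segregates as a handful of founder segments rather than as
tens of thousands of independent loci. The block structure is what gives
replicate lines of the same design realistic line-level spread in retained
diversity; with fully independent loci, every line of a group would retain
almost exactly the group mean and the measured-diversity predictor would
collapse onto group membership.

### Drift and realised breeders

`simulate_drift()` propagates each block's founder gene copies by
multinomial resampling: the founding sample (2 gene copies per
contributing adult, drawn from the base) is the first bottleneck
generation, each later bottleneck generation resamples the copy counts,
and the flush resamples $2 \times 200$ copies. With equal contribution at
the census size the expected retained gene diversity is exactly
$\prod_i (1 - 1/(2N_i))$ over post-founder generations
(`expected_line_retention()`), and `validate_against_theory()` confirms the
simulator against this oracle to Monte-Carlo precision.

Real breeding-pair lines do not drift at the idealised census size:
adults die during the pairing windows and reproductive success is
unequal, so realised $N_e$ varies line to line — an acknowledged feature
of such experiments, and a key reason expected F predicts outcomes
imperfectly. `generate_cohort()` therefore draws, per line and bottleneck
generation, the number of actually contributing adults as census minus
binomial failures (`breeders$fail_prob = 0.10` per adult, floored at one
pair) and passes these to `simulate_drift()`. The idealised
equal-contribution process remains the default contract of
`simulate_drift()` itself, keeping the closed-form oracle exact; the
breeder-failure layer lives in the cohort generator and can be switched
off (`breeders = list(fail_prob = 0)`).

Outbred control lines skip the bottleneck phase and drift per locus for 5
generations at size 200 (the window during which the staggered inbred
lines are brought to their target levels), retaining ≈98.8% of founder
diversity.

### Pooled reads

`simulate_pool_reads()` emulates pooled GBS: 30 gene copies (15 males)
sampled binomially from the line frequency, per-site depth from a
negative binomial (mean 60, size 2 — mode near 30, long right tail into
the mid-hundreds), clipped at 600, and a binomial variant count given
depth. The finite-depth estimator bias is analytic,
$E[\hat p(1-\hat p)] = q(1-q)(1 - 1/c)$ at depth $c$, and is verified by
simulation; it is shared across groups as long as the coverage
distributions match, which the Kolmogorov–Smirnov diagnostic
(`coverage_ks_diagnostic()`) checks. Read-depth equalisation across
libraries is represented by giving every line the same depth law rather
than by resampling reads, since the pipeline starts at variant tables.

### Phenotypes

Per-generation trait means follow
`baseline + beta * retention * g + noise`, with retention the line's
realised gene diversity relative to the founder pool — the generator's
ground truth for "adaptive capacity scales with standing variation".
Defaults: productivity baseline 1.5 flies·female⁻¹·day⁻¹ with
`beta = 0.08` and noise SD 0.16; dry body mass baseline 0.30 mg with
`beta = 0.003` mg and noise SD 0.006. The noise SDs were chosen so that
default cohorts yield diversity–slope coefficients of determination of
the magnitude reported for such experiments (R² in the 0.2–0.3 range);
they are per-generation-mean SDs on the trait scale.

Adult output per generation is normal around `199 + 34 * retention`
(SD 12, plus a line effect of SD 5), and a line is extinct at the first of
generations 1–9 where fewer than 200 adults can be collected — the
experiment's operational rule. These constants were calibrated once so
that a default 132-line cohort loses roughly 35–50 inbred lines, with
extinction concentrated at low diversity, matching the scale of loss the
emulated study reports.

Baseline viability is assayed per line on a benign medium and at four
acetic-acid doses (1, 2.5, 5, 10 mL/L) with 5 vials × 15 eggs each; the
line's stress medium is the dose bringing survival closest to 50%
(`select_stress_level()`, ties toward the lower dose, restricted to the
two doses actually used in the long experiment; outbred lines all run at
2.5 mL/L). Dose response is exponential in dose with a line-specific
sensitivity. After ten generations, survivors are re-assayed (10 vials ×
15 eggs): true stress viability gains `-0.05 + 0.20 * retention`, while
benign viability shifts by a retention-*independent* −0.03. That
asymmetry is deliberate: it encodes the observed decoupling in which
diversity predicts the evolutionary gain under selection but not the
correlated change in the benign environment. A retention-dependent benign
cost would induce a diversity–benign association that the emulated data
do not show; group-level benign declines are real in that study but are
the business of the (out-of-scope) per-generation GLMM contrasts, not of
this generator.

## Diversity estimation

`filter_variants()` applies the pooled-calling retention rules exactly:
autosomes {2, 3, 4}, coverage in [10, 600], variant count ≥ 1, and
variant-allele frequency ≥ 10% — the *called* allele frequency, matching
the caller's parameter semantics, not the folded minor-allele frequency
(π = p(1−p) is symmetric, so only the filter is affected).
`remove_cross_sample_monomorphic()` then drops loci fixed for the
non-reference allele (frequency exactly 1) in *every* line where they
appear post-filter; loci absent from some lines are judged on the lines
where present. Whether the original analysis applied this exclusion
before or after the per-line filters is not documented; the package
applies it after, and the order can be changed by composing the verbs
directly. π for a line sums over that line's own variant loci (absent
loci contribute nothing); `nucleotide_diversity()` also reports the
per-SNP mean as a diagnostic, but all downstream analysis uses the sum.
`relative_pi()` scales by the outbred mean so the outbred group is 1 by
construction. Positions are 1-based and locus identity is
(chromosome, position) throughout.

## Response and comparison

Evolutionary response per line is the unweighted OLS slope of
per-generation trait means on generation index (`response_slopes()`),
computed only from ≥ 3 observed generations; shorter series are returned
with the exclusion reason rather than silently dropped, and the pipeline
computes slopes only for lines that completed the experiment, since
slopes from the 1–2 generations an extinct line survived are not
response estimates. Viability change is `v10 − v0` on the proportion
scale with the variance-sum-law standard error
`sqrt(var10/n10 + var0/n0)` (`viability_delta()`).

The headline inference (`compare_predictors()`) takes the eligible lines
(non-extinct, with a diversity estimate), fits `response ~ π` and
`response ~ F` per response measure, and nests both in the combined model
`response ~ π + F` (the encompassing model). Each predictor's added value
is the Wald test of dropping it from the combined model, computed as the
partial F on (1, n−3) df — algebraically the squared coefficient t for a
single linear restriction in OLS, an identity the tests assert to 1e-8
and cross-check against an independent Wald-test implementation.
Diversity contrasts (outbred vs each level; extinct vs survived) use
Welch's t, Holm-adjusted (the standard reading of "sequential
Bonferroni"), with the family size settable above the number of
contrasts performed. All p-values are two-sided and α = 0.05 wherever a
threshold is applied.

## Numerical and design choices

* Recursion arithmetic is plain double precision; rounding (3 decimals
  for F, 1 for Ne) happens only at report time.
* Effectively infinite Ne (≥ 1e9) returns an all-zero F trajectory rather
  than accumulating 1e-10-scale dust.
* Drift frequencies are clamped to [0, 1] against floating-point spill
  from the block matrix product.
* `select_stress_level()` rounds the |viability − 0.5| distance to 9
  decimals before ordering so exact ties break toward the lower dose
  rather than by floating-point accident.
* Collinear predictors in `ols_fit()`/`encompassing_test()` raise a
  singular-design error: with π ≡ F the comparison is unidentifiable and
  no output is preferable to an arbitrary one.
* K-S p-values are asymptotic (two-sample effective size
  `n1 n2 / (n1 + n2)`); coverage vectors are heavily tied, which the
  asymptotic ECDF treatment handles by right-continuity.
* Every random quantity in a cohort derives from a per-line seed drawn
  once under the master seed, so cohorts are byte-reproducible and
  insensitive to consumption order.

Validation problem sizes are package choices made for desk-scale
precision: simulator calibration uses 1000 replicate lines per design at
300 loci (the oracle is an expectation, so the locus count affects only
Monte-Carlo error); the estimator-bias check uses 60,000 sites per depth;
the null calibration of the encompassing test uses 2000 replicates at
n = 87; pattern-reproduction checks use 20 full default cohorts.

## What passing tests do and do not show

The generator is neutral Wright–Fisher plus measurement layers. It
reproduces the *structure* of the emulated study — group ordering of
diversity, line-level heterogeneity within groups, diversity-coupled
response slopes, extinction enriched at low diversity, and the
stress/benign decoupling — and the package's tests assert those patterns
over replicate cohorts. It does not reproduce the study's real-data test
statistics, which depend on its unpublished raw measurements. Known
departures from real data: group-mean diversity declines at the full
neutral rate (real bottlenecked lines often retain more, via balancing
selection and associative overdominance, mechanisms not modelled); there
is no mutation, migration, selection during drift, or purging; trait
noise is Gaussian on the trait scale; and productivity's adult-output
process is modelled separately from the productivity trait series rather
than derived from it. Within those limits, a passing suite shows the
pipeline's statistics do what they claim on data whose generating truth
is known — not that the biological conclusions of any particular real
dataset are correct.
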