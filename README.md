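# bottlepi

Does the *history* of a population bottleneck or the *genomic variation it
actually left behind* better predict how well a population can adapt?
`bottlepi` is an R package for answering that question in replicated
experimental-evolution designs: inbred lines created by a known number of
bottleneck generations, genotyped as pooled samples, then selected in a
stressful environment while fitness traits and extinctions are scored.
It is written for evolutionary and conservation geneticists who want the
whole chain — bottleneck theory, pooled-sequencing diversity estimation,
response quantification, and the predictor comparison — as small,
pipeable, tested functions, together with a synthetic-cohort generator
that emulates such a study so every stage can be exercised without any
raw data.

## The quantities at the core

**Expected inbreeding** of a line propagated by breeding pairs at
effective size $N_e$ follows the two-generation recursion

$$F_t = F_{t-1} + \frac{1 - 2F_{t-1} + F_{t-2}}{2N_e},\qquad F_0=F_{-1}=0 ,$$

giving F = 0.125, 0.219, 0.381 for designs with 2, 3, 5 generations at
census size 4 (the first pairing draws unrelated parents, so steps =
generations − 1). The **effective size** of a fluctuating census
trajectory is its harmonic mean $N_e = t / \sum_i 1/N_i$.

**Nucleotide diversity** of a pooled sample is
$\pi = \sum_{\text{variant loci}} p\,(1-p)$ over autosomal variants
passing the pooled-calling filters (coverage 10–600, count ≥ 1, variant
frequency ≥ 10%), with loci fixed non-reference in every sample removed,
and is reported relative to the outbred-line mean.

**Evolutionary response** per line is the OLS slope of per-generation
trait means on generation (and, for viability, the before/after change
with variance-sum-law SE). The headline comparison nests the two
single-predictor models in the **encompassing model**
`response ~ π + F`; each predictor's added explanatory value is the Wald
(partial-F) test of dropping it, on (1, n−3) df.

## Worked example

```r
library(bottlepi)

theory_table(digits = TRUE)
#> # A tibble: 3 × 7
#>   design n_bottleneck_gens f_steps expected_f harmonic_ne wf_het_retention
#> 1 Low                    2       1      0.125         7.9            0.764
#> 2 Medium                 3       2      0.219         6.6            0.668
#> 3 High                   5       4      0.381         5.6            0.512
```

Expected F rises, and harmonic-mean Ne falls, with more bottleneck
generations; `wf_het_retention` is the fraction of gene diversity drift
is expected to leave. `check_ne_labels()` flags reported Ne sets whose
labels are transposed relative to this computation.

A full synthetic study — 132 lines (42/40/40 inbred at 2/3/5 bottleneck
generations plus 10 outbred), pooled read tables, ten generations of
traits, viability assays, extinctions — and its complete analysis:

```r
res <- run_pipeline(seed = 1)
res
#> <pipeline_result> seed 1, config 622dcc26
#>   132 lines, 50 extinct, 82 eligible for comparison
#> Predictor comparison over 82 eligible lines
#> # A tibble: 8 × 7
#>   response           predictor r_squared f_statistic p_value partial_f partial_p
#> 1 slope_productivity pi          0.325       38.5    2.31e-8    8.61     0.00437
#> 2 slope_productivity expected…   0.256       27.5    1.26e-6    0.496    0.483
#> 3 slope_body_mass    pi          0.305       35.1    7.41e-8    5.29     0.0241
#> 4 slope_body_mass    expected…   0.259       27.9    1.06e-6    0.0187   0.892
#> 5 viability_benign   pi          0.00717      0.578  4.49e-1    1.69     0.198
#> 6 viability_benign   expected…   0.00114      0.0912 7.63e-1    1.20     0.276
#> 7 viability_stress   pi          0.196       19.5    3.14e-5    9.71     0.00256
#> 8 viability_stress   expected…   0.125       11.4    1.13e-3    2.51     0.117
```

Read the table row-wise: for productivity slopes, π explains 32% of
between-line variance and survives the encompassing test
(partial-F = 8.6, p = 0.004), while expected F adds nothing once π is in
the model (partial-F = 0.5, p = 0.48); the same asymmetry holds for body
mass and for the viability gain on the stress medium, and *neither*
predictor explains the benign-medium change — the trade-off signature.
The Welch contrasts below the models show every inbred group less
diverse than the outbred lines and extinct lines less diverse than
survivors (t = −4.95, Holm-adjusted p = 2.5e-6). Per-line tables live in
`res$diversity`, `res$slopes`, `res$viability_changes`;
`ggplot2::autoplot(res$comparison)` draws the scatter panels and
`plot_diversity_groups()` / `plot_extinction_diversity()` the boxplots.

Every stage is also a standalone verb on plain data frames —
`filter_variants()`, `remove_cross_sample_monomorphic()`,
`nucleotide_diversity()`, `relative_pi()`, `response_slopes()`,
`viability_change()`, `encompassing_test()` — so user-supplied variant
tables (TSV, or minimal VCF via `read_variant_vcf()`) and trait tables in
the same schemas drop straight in. A thin command-line wrapper with
`theory` / `simulate` / `diversity` / `respond` / `compare` / `run-all`
subcommands is installed at `inst/cli/bottlepi.R`.

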