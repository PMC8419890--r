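# circarenal

Circadian rhythm analysis of kidney expression data profiled on mixed
microarray and RNA-seq platforms, with companion tools for physiological
rhythmometry and blood-pressure dipping phenotypes.

## The problem

Kidney function is under strong circadian control: electrolyte excretion,
aldosterone, and blood pressure all oscillate over the 24 h light/dark cycle,
driven in part by rhythmic transcription in the kidney itself. In chronic
inflammatory kidney disease (the motivating setting is lupus nephritis in the
NZB/W F1 mouse model) these renal rhythms dampen, blood pressure can stop
dipping at rest or even reverse, and successful remission-induction therapy
partially restores the normal pattern. Quantifying this requires a pipeline
that can

1. merge expression data collected on two platforms (microarray intensities
   and RNA-seq counts) into one comparable log2 matrix,
2. call per-gene rhythmicity from a small number of Zeitgeber times (ZT0,
   4, 8, 12, 16, 20; ZT0 = lights on) with few replicates per time,
3. fit cosinor models to physiological series (MESOR, amplitude, acrophase),
4. score how far disease-disrupted day/night contrasts return toward the
   healthy state under remission, and
5. classify nocturnal blood-pressure dipping per animal.

`circarenal` implements all five stages plus a synthetic-data generator that
plants known rhythms, platform effects, correction fractions and dipper
classes, so every stage can be validated against ground truth.

## Methods at the core

**Preprocessing.** Microarray genes in the pooled lowest 30% intensity
quantile in strictly more than 2/3 of samples are removed; RNA-seq genes with
total count < 100 are removed. Each platform is log2-transformed and shifted
to a common global median, then gene-wise median-centered within platform.
Common genes are merged, quantile-normalized, and batch-corrected between
platforms with a parametric empirical-Bayes location/scale model (normal
prior on additive batch effects, inverse-gamma on multiplicative ones,
method-of-moments hyperpriors, iterative posterior shrinkage), protecting the
disease group as a covariate.

**Rhythm detection.** A two-stage per-gene screen: one-way ANOVA across ZT
bins with Benjamini–Hochberg adjustment, followed — for genes with
q ≤ α₁ — by a rank-based umbrella test against rise-then-fall alternatives
at every circular peak position (Mack–Wolfe family). For candidate peak j the
statistic is

S_j = Σ_{(a,b) rising} U_{ab} + Σ_{(a,b) falling} U_{ba},

where U_{ab} counts pairs (x ∈ bin a, y ∈ bin b) with x < y (ties 0.5).
Per-peak p-values come from exhaustive enumeration of all distinct
bin assignments when feasible, otherwise from seeded permutations of a shared
null table; the combined p is Bonferroni-corrected over the k candidate
peaks. A gene is rhythmic when the BH-adjusted umbrella q ≤ α₂; its peak
phase is the ZT bin with maximal mean.

**Cosinor rhythmometry.** Least-squares fit of
y = M + β·cos(2πt/τ) + γ·sin(2πt/τ) with known period τ (default 24 h);
amplitude A = √(β²+γ²), acrophase φ = (τ/2π)·atan2(γ, β) mod τ, and a
zero-amplitude F test on (2, n−3) degrees of freedom.

**Remission correction.** Panel entry requires |Δ_young| ≥ log2(1.25) with
BH-adjusted Welch q < 0.05 and |Δ_young − Δ_neph| ≥ log2(1.25), where Δ is
the mean log2(ZT0) − mean log2(ZT12) contrast per group. The correction
fraction c = (Δ_rem − Δ_neph)/(Δ_young − Δ_neph); a gene is corrected when
c ≥ 0.5 (boundary inclusive).

**Dipping.** Per mouse, d = (mean active-phase SBP − mean rest-phase SBP) /
mean active-phase SBP; dipper if d ≥ 0.10, non-dipper if 0 ≤ d < 0.10,
reverse if d < 0. For mice the active phase is the dark phase (ZT12–24).

## Worked example

```r
library(circarenal)

cfg    <- sim_config(n_genes = 500, seed = 42)
sim    <- generate_expression(cfg)
merged <- run_preprocess(sim$array, sim$seq, sim$meta)
#> [preprocess] stage=filter_intensity genes=371 samples=69
#> [preprocess] stage=merge genes=371 samples=138
#> [preprocess] stage=batch_correct genes=371 samples=138

res_y <- detect_rhythmic(merged, sim$meta, "young",     seed = 42)
res_n <- detect_rhythmic(merged, sim$meta, "nephritic", seed = 42)
sum(res_y$is_rhythmic); sum(res_n$is_rhythmic)
#> [1] 72
#> [1] 37
```

72 genes are called rhythmic in young kidneys but only 37 in nephritic ones —
the planted disease damping (amplitude factor 0.3) suppresses most calls.
Comparing the two sets:

```r
cmp <- compare_rhythmic_sets(res_y, res_n)
length(cmp$shared); cmp$n_union; cmp$concordance
#> [1] 37
#> [1] 72
#> same_time within_4h off_cycle
#>        22        14         1
```

All 37 nephritic calls are shared with the young set, and 36 of them peak
within 4 h of their young-kidney phase. The remission-correction panel and
its classifier:

```r
panel <- select_correction_panel(merged, sim$meta)
rec   <- classify_correction(panel, merged, sim$meta)
nrow(rec); sum(rec$corrected)
#> [1] 58
#> [1] 35
```

58 genes show a robust young-kidney day/night contrast that is lost in
disease; 35 of them recover at least half of it in remission (the generator
plants correction fractions of 0 or 1 with equal probability). Physiology and
blood pressure:

```r
fit_group_cosinor(generate_physiology(default_analytes(), seed = 42))
#>       analyte     group mesor amplitude acrophase p_zero_amplitude
#> 1    urine_na     young 100.5     26.84      16.5         5.39e-13
#> 2    urine_na nephritic  95.1      6.81      15.4         4.88e-03
#> 3 aldosterone     young 302.9    121.96      12.0         1.36e-14
#> 4 aldosterone nephritic 510.0     12.54      19.6         3.67e-01

table(classify_dipper(generate_bp_traces(n_per_class = 3, seed = 42))$status)
#> dipper non-dipper    reverse
#>      3          3          3
```

Urinary sodium peaks late in the active phase (planted acrophase 16 h,
recovered 16.5 h) with the nephritic amplitude collapsed; aldosterone is
elevated and arrhythmic in disease; all nine planted dipper phenotypes are
recovered exactly.

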