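# pairedimpute

Simulation framework for studying how missing-value imputation distorts the
intra-subject correlation structure of **multi-biospecimen metabolomics
studies** — and what that distortion does to the validity of downstream
significance tests.

## The problem

Metabolomics studies increasingly measure the same metabolites in two
biospecimens (plasma and serum, lung tissue and serum, ...) from the same
subjects. For each metabolite this gives two abundance vectors across
subjects whose Pearson correlation — the *between-biospecimen correlation*
— is what a bivariate MANOVA of group differences (e.g. cancer vs control)
leverages for power. Mass-spectrometry data are plagued by missing values
concentrated below the detection limit; imputing them is routine, but
imputation can flatten the between-biospecimen correlation toward zero and
thereby change which metabolites test significant.

`pairedimpute` quantifies this with known ground truth. It

1. **simulates** paired-biospecimen studies (`generate_paired_study()`):
   per metabolite a true correlation *r* drawn from a rescaled-beta profile
   (presets `"high"`: range [-0.2, 0.98], mode 0.5; `"low"`: [-0.3, 0.3],
   mode 0), log-normal abundances, and an exact count of truly differential
   metabolites shifted in both biospecimens;
2. **masks** cells with left-censoring-weighted missingness
   (`induce_missingness()`): exactly round(p% · M · N) cells drawn from at
   or below each metabolite's scheduled q-th percentile
   (p ∈ {1, 5, 10, 20, 30, 40, 50, 60} paired with
   q ∈ {2, 10, 20, 40, 50, 60, 70, 80});
3. **imputes** under two strategies — each biospecimen matrix **separately**
   or both **combined** into one stacked 2M × N matrix — with five methods:
   half-minimum (HM), k-nearest neighbours (KNN), iterative random forest
   (RF, missForest-style over `ranger`), bootstrap-EM multivariate normal
   (EMB, compiled EM core), and quantile-regression imputation of
   left-censored data (QRILC);
4. **evaluates** against the complete data (`correlation_records()`,
   `manova_calls()`, `validity_metrics()`): per-metabolite correlation bias
   r_imputed − r_true, and the sensitivity / specificity / accuracy of
   Hotelling-T² MANOVA calls (T² = (n₁n₂/n) d′S⁻¹d,
   F = (n−3)/(2(n−2)) · T² on (2, n−3) df; raw p < 0.05) relative to the
   calls made on the complete data.

`run_study()` executes the full factorial (profiles × levels × methods ×
approaches × replicates) reproducibly from one master seed;
`summarize_results()` condenses it. The numbered scripts under `analysis/`
walk the whole experiment: `01_simulate.R` (write the synthetic studies),
`02_run_grid.R` (the factorial), `03_summarize.R` (tables),
`04_figures.R` (scatter and box plots).

## Worked example

```r
library(pairedimpute)

# a GCTOF-like paired study: 48 cancer vs 31 control subjects,
# 176 metabolites, high between-biospecimen correlation
st <- generate_paired_study(group_design(48, 31, de_fraction = 0.23,
                                         effect_size = 1),
                            correlation_profile("high"), 176, seed = 1)
st
#> paired_study: 176 metabolites x 79 subjects (raw scale)
#>   groups: case=48, control=31
#>   missing cells: A=0, B=0
#>   true differential metabolites: 40

# mask 20% of each biospecimen matrix (left-censoring-weighted), log-transform
mask_A <- induce_missingness(st$A, p = 20, seed = 2)
mask_B <- induce_missingness(st$B, p = 20, seed = 3)
masked   <- log_transform_study(mask_study(st, mask_A, mask_B))
complete <- log_transform_study(st)

# impute with random forest under both approaches
s <- imputer_settings(rf_trees = 50, seed = 4)
rf_sep  <- impute_study(masked, "RF", "separate", s)
rf_comb <- impute_study(masked, "RF", "combined", s)

# correlation preservation
bias_summary(correlation_records(complete, rf_sep, mask_A, mask_B))
#>     n n_undefined  mean_bias mean_abs_bias   sd_bias mean_r_true mean_r_imputed
#> 1 176           0 -0.1407041      0.150005 0.1055725   0.4863865      0.3456824

# validity of MANOVA calls vs the complete data
truth <- manova_calls(complete)
validity_metrics(truth$call, manova_calls(rf_sep)$call)
#> validity_metrics: sens 0.911, spec 0.947, acc 0.938 (TP 41 FP 7 TN 124 FN 4)
validity_metrics(truth$call, manova_calls(rf_comb)$call)
#> validity_metrics: sens 0.867, spec 0.947, acc 0.926 (TP 39 FP 7 TN 124 FN 6)
```

Reading the numbers: at 20% missingness the mean between-biospecimen
correlation drops from 0.49 in the true data to 0.35 after RF imputation
(mean bias −0.14 — the characteristic attenuation toward zero), yet 93–94%
of the MANOVA significance calls still agree with the complete-data
analysis. Attenuation grows sharply with the missingness rate and with the
underlying correlation level; the vignette
(`vignettes/paired-biospecimen-imputation.Rmd`) details the models, the
method parameters, and what the simulation does and does not emulate.

User-supplied data are accepted as two metabolite × subject TSVs plus a
group-label file via `read_paired_study()`.

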