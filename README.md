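# swiron

Regional brain iron analysis from susceptibility-weighted imaging (SWI)
phase images, aimed at the progression of Alzheimer's disease (AD).

Excess iron deposition is a putative factor in AD pathogenesis, and the SWI
phase signal is sensitive to tissue iron. `swiron` implements a complete,
testable pipeline for asking three questions of a phase-imaging cohort with
NC / MCI / AD diagnoses (normal control, mild cognitive impairment, AD):

1. **Which brain regions carry diagnostic signal?** Atlas-based regional
   mean phase is converted to an iron content score
   `X = -b̄·π/4096` (radians; raw phase `b ∈ [-4096, 4095]`, more negative
   phase = more iron), and disease-predictive regions are selected by
   Lasso / Adaptive Lasso regression of an ordinal diagnosis code
   (NC = 0, MCI = 1, AD = 2):
   `min_w Σᵢ (yᵢ − wᵀxᵢ)² + λ‖w‖₁`, the adaptive variant penalising
   `Σⱼ |wⱼ|/|β̂ⱼ|` with preliminary least-squares weights `β̂`.
2. **How discriminative are they?** Repeated stratified 62/7 train/test
   splits score three-class accuracy for four classifier families
   (AdaBoost with 100 rounds at learning rate 0.1; a linear max-margin SVM
   with C = 1; a depth-4 decision tree; depth-5 gradient-boosted trees with
   a softmax multiclass objective), with region selection redone inside each
   training split so test subjects never leak into selection.
3. **Do the selected regions share genetic factors?** Each candidate gene's
   *presence frequency* is the dot product `Σₛ wₛ Zₛ` between the number of
   selected regions falling in each coarse anatomical structure (`wₛ`) and
   the gene's normalized expression Z-score per structure (`Zₛ`), using a
   packaged 21-gene × 18-structure Z-score table in the style of the Allen
   Human Brain Atlas microarray export.

A synthetic cohort generator emulates a 69-subject study
(24 NC / 21 MCI / 24 AD) with known ground-truth effect regions, so every
stage runs and is tested without any clinical data download.

## Worked example

```r
library(swiron)

spec   <- cohort_spec(seed = 42)          # 24 NC / 21 MCI / 24 AD, 16 regions,
cohort <- generate_cohort(spec)           # true effects in regions 2, 7, 11

features <- build_feature_matrix(cohort$volumes, cohort$atlas)
#> Regional iron feature matrix: 69 subjects x 16 regions (atlas: synthetic)

set.seed(42)
select_regions(features, cohort$labels$class, variant = "lasso")
#> Region selection (lasso): lambda = 0.3062, 5 region(s) selected
#>    2, 4, 7, 8, 11
```

All three true effect regions (2, 7, 11) are recovered, plus two false
positives at this seed. Their discriminative power, with selection redone
per split:

```r
plan <- evaluation_plan(n_repeats = 10, seed = 42,
                        classifiers = c("linear_svm", "decision_tree"))
run_evaluation(features, cohort$labels$class, plan)
#> Three-class accuracy over 10 repeats (lasso selection, 62/7 split):
#>    linear_svm decision_tree
#>             1             1
```

(Perfect accuracy reflects the default generator's strong effect sizes, not
a claim about real SWI data.) Gene association from the packaged fixtures:

```r
z <- load_zscore_table()                            # 21 genes x 18 structures
w <- compute_structure_weights(load_region_list())  # counts of 20 regions
head(rank_genes(z, w), 3)
#>   rank  gene symbol frequency
#> 1    1   CLU    CLU     15.01
#> 2    2 MEF2C  MEF2C     14.54
#> 3    3  MART   MAPT     12.24
```

CLU, MEF2C and MAPT (printed "MART" in the source table, kept verbatim)
carry the three largest presence frequencies: the genes whose expression is
most concentrated in the AD-predictive territory.

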