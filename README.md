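# glycoprof

Quantification and concordance analysis of whole-serum N-glycan
HILIC-UHPLC chromatograms.

Serum N-glycans — oligosaccharides enzymatically released from serum
glycoproteins, fluorescently labelled with 2-aminobenzamide (2-AB) and
separated by hydrophilic-interaction UHPLC — are widely studied disease
biomarkers. Before any biological comparison, the raw fluorescence traces
must be turned into a matched peak-area matrix: every sample's peaks
detected, integrated, mapped onto a common set of glycan peaks, and
expressed on the instrument-independent glucose-unit (GU) scale. This
package implements that pipeline for laboratories profiling serum
glycans, together with the statistics used to ask a methodological
question that matters for multi-centre biomarker studies: do different
blood-collection tubes and processing protocols change an individual's
glycan profile, or is the within-person signal stable enough that tube
type can be ignored?

## What the pipeline does

1. **Normalization** — each trace is scaled to unit total (trapezoidal)
   area; downstream percent-area statistics are scale-free.
2. **Alignment** — traces are rigidly shifted so every sample's
   global-maximum apex meets the median apex time.
3. **Peak calling** — local-polynomial Gaussian-kernel regression
   (plug-in bandwidth) estimates the smoothed signal f̂ and its
   derivatives; apexes are down-going zero crossings of f̂′ with
   f̂″ < 0, troughs the up-going crossings, and sub-prominence wiggles
   are discarded.
4. **Perpendicular-drop integration** — the area of each peak is the
   trapezoidal integral of the raw trace between vertical cuts at its
   flanking troughs, so contiguous peaks partition the signal exactly.
5. **GU calibration** — a monotone piecewise-cubic map from retention
   time to glucose units is fitted through the apexes of a 2-AB glucose
   homopolymer ladder.
6. **Cross-sample matching** — pooled apex times are clustered
   (average-linkage, cut at a time tolerance), groups present in ≥ 50%
   of samples are kept, and a sample's missing peaks are imputed from
   its own time offsets at neighbouring matched groups, then
   re-integrated, yielding a complete samples × peaks matrix of percent
   areas.
7. **Concordance statistics** — per-peak geometric means and log-normal
   CVs (`CV = √(exp(s²) − 1)` with `s` the SD of log areas, both pooled
   and as the mean of within-patient CVs); pairwise Pearson correlation
   of percent-area profiles; complete-linkage clustering and classical
   MDS (principal coordinate analysis) on the distance `d = 1 − |r|`;
   and a per-peak blocked ANOVA of log areas on tube type with patient
   as the blocking factor, Bonferroni-corrected.

A synthetic chromatogram generator (`simulate_dataset()`) emulates the
study design — per-patient profiles drawn log-normally around a
canonical 42-peak whole-serum template, small tube-level perturbations,
retention-time jitter, baseline drift, detector noise — and emits exact
ground truth, so the entire pipeline is testable without instrument
data.

## Worked example

```r
library(glycoprof)

cfg <- simulation_config(n_patients = 4, seed = 2026)  # 4 patients x 3 tubes
ds  <- simulate_dataset(cfg)
res <- run_pipeline(ds$chromatograms, ds$sheet, ds$ladder)

res$matrix
#> <peak_matrix> 12 samples x 42 peak groups (16 neutral); 3 imputed cells

head(res$summary[, c("group","gu","geo_mean_pct","cv_pct","mean_cv_pct","p_bonferroni")])
#>    group    gu geo_mean_pct cv_pct mean_cv_pct p_bonferroni
#> P1     1 5.894        0.193 38.313      21.839            1
#> P2     2 5.986        1.744 34.232       2.242            1
#> P3     3 6.194        0.754 16.597       4.877            1
#> P4     4 6.322        0.463 11.874       8.830            1
#> P5     5 6.615        0.160 25.463      23.806            1
#> P6     6 6.754        1.460 12.047       2.671            1

r <- res$concordance$r
r["A1", "A2"]; r["A1", "B1"]
#> [1] 0.9996      # same patient, different tubes
#> [1] 0.9781      # different patients

split(names(cutree(res$concordance$hclust, k = 4)),
      cutree(res$concordance$hclust, k = 4))
#> $`1`: "A1" "A2" "A3"   $`2`: "B1" "B2" "B3"
#> $`3`: "C1" "C2" "C3"   $`4`: "D1" "D2" "D3"
```

The matrix recovers all 42 template peaks on the GU grid (5.89–12.50).
Repeat tubes from one individual correlate at r ≈ 0.9996 while profiles
from different individuals sit near 0.98, so cutting the 1 − |r|
complete-linkage tree at four clusters reassembles the four patients
exactly — the concordance pattern that justifies treating tube type as
a negligible source of variation. `cv_pct` is the CV across all samples
(dominated by inter-individual spread); `mean_cv_pct` is the mean
within-patient CV across tubes, an order of magnitude smaller for the
major peaks. The Bonferroni-corrected blocked-ANOVA p-values show no
tube effect on any peak. Small peaks (< 0.5% of area) carry visibly
higher CVs — their integration is noise-limited.

A thin command-line front end is included:

```sh
Rscript inst/cli/glycoprof.R simulate --out data --seed 3
Rscript inst/cli/glycoprof.R stats --in data --out results_dir
```

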