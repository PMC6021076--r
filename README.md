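# mircluster

Cluster-level analysis of circulating miRNA qPCR panels, for researchers
studying pregnancy outcomes (and anyone else whose miRNAs of interest
sit in genomic clusters). Many placental miRNAs are organised in large
chromosomal clusters — the imprinted c14mc locus at 14q32, c19mc at
19q13.41, and the miR-17/92 family on 13q31.3/Xq26.2 — and circulate in
maternal plasma. `mircluster` asks whether such clusters behave as
co-regulated units and whether their *coordination*, not just their
level, differs between term and preterm (PTB) deliveries.

## What it computes

Starting from a raw cycle-threshold (CT) matrix, miRBase-style GFF3
annotations, and a sample metadata table:

1. **Preprocess** — hemolysis QC (miR-451a vs miR-23a-3p ΔCT), censoring
   of unamplified reactions (CT > 50 by default), global-mean −ΔCT
   normalisation (−ΔCT<sub>sm</sub> = mean CT<sub>s·</sub> −
   CT<sub>sm</sub>), and a detection-prevalence filter (≥ 30 of 42
   samples by default).
2. **Cluster assignment** — single-linkage chaining of miRNAs within
   10 kb on a chromosome, plus named family pooling across chromosomes
   and cytoband labelling (c14mc, c19mc, …).
3. **Correlation structure** — cluster-ordered Pearson matrices per
   group; the Jennrich χ² test of correlation-matrix equality,

   χ² = ½ tr(Z²) − diag(Z)ᵀ S⁻¹ diag(Z),  Z = √c · R̄⁻¹(R₁ − R₂),
   S = I + R̄ ∘ R̄⁻¹,  df = p(p−1)/2;

   and two-group ANOVA on within-/between-cluster coefficient sets
   (F ≡ pooled t², df = (1, k₁+k₂−2)).
4. **Factor analysis** — minimum-residual EFA with Horn's parallel
   analysis and BIC for the dimension, oblimin rotation for an oblique
   simple structure, and row-mean cluster scores.
5. **Outcome models** — matched-pair mixed regressions
   `outcome ~ score + BMI + gravida + history of PTB + fetal sex +
   (1 | pair)` for gestational age, birth weight, head circumference
   (linear) and PTB status (logistic), plus per-miRNA t-tests and
   miRNA–outcome correlation tables.
6. **Synthetic cohorts** — a seeded generator with recorded ground truth
   (latent factors, loadings, outcome effects) emulating the 21 + 21
   matched design, used by the test suite for calibration and
   parameter-recovery experiments.

## Worked example

```r
library(mircluster)

sim  <- simulate_cohort(default_sim_config(seed = 1))
expr <- detection_filter(normalize_global_mean(sim$ct), min_samples = 30)
cmap <- name_clusters(assign_clusters(sim$annotations, max_gap = 10000),
                      sim$locus_labels)
cmap
#> cluster_map: 3 cluster(s), 60 unclustered miRNA(s)
#>   c14mc            33 members
#>   c19mc            15 members
#>   miR-17/92        10 members

cmp <- compare_groups(expr, cmap, sim$metadata,
                      regions = c("c14mc", "c19mc", "miR-17/92"))
cmp$anova[, c("regionA","regionB","F","df2","p_value",
              "mean_r_term","mean_r_ptb")]
#>     regionA   regionB      F  df2   p_value mean_r_term mean_r_ptb
#> 1     c14mc     c14mc   52.2 1054  9.71e-13       0.724     0.6814
#> 2     c19mc     c19mc  164.6  180  3.56e-27       0.757     0.8710
#> 3 miR-17/92 miR-17/92   65.3   70  1.28e-11       0.674     0.8219
#> 4     c14mc     c19mc 2067.1  922 1.05e-237      -0.288    -0.6683
#> 5     c14mc miR-17/92  190.3  592  9.67e-38       0.214     0.0611
#> 6     c19mc miR-17/92   59.1  250  3.45e-13      -0.315    -0.1840
```

Reading the table: within-cluster coordination of c14mc is weaker in PTB
(mean r 0.72 → 0.68) while c19mc tightens (0.76 → 0.87), and the
negative coupling between c14mc and c19mc is much stronger in PTB
(−0.29 → −0.67) — the generator's configured group differences,
recovered by the analysis. `cmp$jennrich` carries the matrix-equality
tests per region (regions wider than the group size are reported as
numerically untestable rather than approximated).

```r
sc  <- cluster_scores(expr, cmap, c("c14mc", "c19mc", "miR-17/92"))
fit <- fit_mixed_outcome(sc, sim$metadata, "gestational_age_birth")
fit[, c("cluster","estimate","std_err","z","ci95_low","ci95_high")]
#>     cluster estimate std_err      z ci95_low ci95_high
#> 1     c14mc    0.877   0.853  1.028   -0.794     2.548
#> 2     c19mc   -0.394   0.521 -0.755   -1.416     0.628
#> 3 miR-17/92    0.587   0.642  0.914   -0.671     1.845
```

Each row is one matched-pair mixed model: weeks of gestation per unit
cluster score (mean −ΔCT of the cluster's members), adjusted for BMI,
gravida, history of PTB and fetal sex, with a random intercept per pair.

A command-line wrapper covers the same stages
(`inst/cli/mircluster simulate | qc | normalize | cluster | comatrix |
factors | model | all`).

## Reproducibility script

`scripts/acceptance.R` regenerates the default simulated cohort from a
seed, writes it to disk, and runs every pipeline stage end to end
(normalisation → clustering → group comparison → factor analysis →
outcome models), writing its summary JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/mircluster-methods.Rmd`) describes the
statistical models, the numerical safeguards (nearest-positive-definite
repair, condition-number limits, deterministic rotation starts), what
the synthetic generator does and does not emulate, and known
limitations of the design at n = 42.
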