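---
title: "Cluster-level analysis of circulating miRNA qPCR panels: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-level analysis of circulating miRNA qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircluster)
```

## The problem

Many placentally expressed microRNAs sit in large genomic clusters — the
imprinted c14mc locus at 14q32, the c19mc locus at 19q13.41, and the
miR-17/92 family with paralogous loci on 13q31.3 and Xq26.2 — and are
released into the maternal circulation during pregnancy. Because members
of a cluster share promoters and regulatory context, their plasma levels
should move together, and disturbances of pregnancy may show up not as a
shift of any one miRNA but as a change in the *coordination* of whole
clusters. `mircluster` implements that idea as a pipeline: from a raw
qPCR cycle-threshold (CT) matrix to cluster-ordered correlation
structure, its comparison between term and preterm (PTB) deliveries, a
factor-analytic check that the latent structure really is genomic, and
matched-pair regressions of birth outcomes on cluster-level expression
scores.

## Preprocessing model

**Censoring.** A reaction that never crosses the detection threshold is
*unamplified*; by convention exports mark these with CT values above the
cycle limit, so any CT strictly greater than `unamplified_ct` (default
50; most panels stop at 40) or an empty cell is treated as missing in
every downstream statistic. No imputation is done anywhere.

**Global-mean normalisation.** For sample $s$ with amplified CTs
$\mathrm{CT}_{s m}$, expression is
$-\Delta\mathrm{CT}_{sm} = \overline{\mathrm{CT}}_{s\cdot} - \mathrm{CT}_{sm}$,
the sample's mean CT over its *amplified* miRNAs minus the miRNA's CT
(one qPCR cycle ~ one doubling, so this is log2-scale expression
relative to the sample's global level; higher = more expressed). Two
consequences are worth keeping in mind:

* each sample's non-missing $-\Delta$CT values average to exactly zero
  (tested to 1e-9), and adding a constant to one sample's CTs changes
  nothing — the normalisation absorbs global efficiency or input
  differences;
* the per-sample centring couples all miRNAs weakly: every correlation
  acquires a small common-mode component. This is intrinsic to
  global-mean $-\Delta$CT analysis, not an artifact of this
  implementation, and it is why the synthetic generator carries a
  background panel (below).

The pipeline normalises first (global mean over *all* amplified miRNAs)
and then applies the detection filter, keeping only miRNAs observed in
at least `min_detected` samples (default 30, matched to a 42-sample
cohort; a fraction mode covers other sizes). A
`renormalize_after_filter` flag exposes the alternative ordering.

**Hemolysis QC.** Red blood cells are rich in miR-451a while miR-23a-3p
is comparatively stable in plasma, so
$\Delta = \mathrm{CT}(\text{miR-23a-3p}) - \mathrm{CT}(\text{miR-451a})$
rises in hemolysed samples. The conventional reading flags $\Delta > 7$
cycles and marks 5–7 as borderline. Samples are flagged, never dropped
automatically — the analyst decides.

## Genomic clustering

Clusters are formed per chromosome by single-linkage chaining: sort by
start, and start a new cluster whenever the gap from the previous
member's end to the next member's start exceeds `max_gap` (default
10 kb; overlaps count as gap 0). Chains of one miRNA are reported as
unclustered and excluded from cluster-level statistics. miRNAs sharing a
named family label (the miR-17/92 paralogs) are pooled into one family
cluster regardless of chromosome, taking precedence over genomic
chaining; the family map is an explicit two-column table because
paralogy is knowledge, not something coordinates reveal. Cytoband-style
names (c14mc for the 14q32 run, c19mc for 19q13.41) come from a
user-supplied span table so the package is genome-build-agnostic. The
chaining is property-tested against a brute-force union-find oracle and
is monotone: growing `max_gap` never increases the number of chains.

## Correlation structure and its comparison

For each group (term, PTB) the package builds the Pearson correlation
matrix of $-\Delta$CTs over pairwise-complete observations, ordered by
cluster and genomic position; entries with fewer than `min_pairs`
(default 10) complete pairs are set missing. Two complementary
comparisons are run:

* **Jennrich test.** A $\chi^2$ test of the equality of two correlation
  matrices from independent samples: with
  $\bar R = (n_1 R_1 + n_2 R_2)/(n_1+n_2)$, $c = n_1 n_2/(n_1+n_2)$,
  $Z = \sqrt{c}\,\bar R^{-1}(R_1 - R_2)$ and
  $S = I + \bar R \circ \bar R^{-1}$,
  $\chi^2 = \tfrac12\,\mathrm{tr}(Z^2) - \mathrm{diag}(Z)^\top S^{-1}\mathrm{diag}(Z)$
  on $p(p-1)/2$ degrees of freedom. The statistic is exactly zero at
  equality and its null distribution is Monte-Carlo calibrated in the
  test suite (empirical type-I error at $\alpha = 0.05$ within
  [0.03, 0.08] at $p=4$, $n=60$ per group). The test needs invertible
  matrices: pairwise-complete inputs with eigenvalues below 1e-8 are
  repaired to the nearest positive-definite correlation matrix
  (`Matrix::nearPD`, recorded in the output), and a pooled matrix with
  condition number above 1e10 raises an error with the condition number
  rather than returning noise. In a 21 + 21 design this makes the
  33-member c14mc block untestable by Jennrich ($p > n$);
  `compare_groups()` records the failure for that region and carries
  on — the ANOVA comparison below does not share the restriction.
* **ANOVA on coefficient sets.** Following the convention that the
  coefficient sets are approximately normal, the within-cluster
  (upper-triangle, $k(k-1)/2$ values) or between-cluster ($k_A k_B$
  values) coefficients of the two groups are compared by two-group
  one-way ANOVA: $F$ with df $(1,\;k_1+k_2-2)$, identically the squared
  pooled t statistic (property-tested). Group means are reported on the
  r scale; a Fisher-z option is available since correlations are
  bounded. Note the coefficients within a set share the same samples and
  are not independent, so these p-values are descriptive of the printed
  convention rather than strictly calibrated — a caveat inherited from
  the method itself. No multiplicity correction is applied to the six
  standard comparisons; a Bonferroni column is emitted alongside.

## Factor analysis

The claim "miRNAs group by genomic location, not expression level" is
checked with exploratory factor analysis on the correlation matrix:

* **Retention** by Horn's parallel analysis: observed eigenvalues are
  compared with the mean (or an upper quantile) of eigenvalues from
  `n_sim` simulated uncorrelated datasets of the same dimensions; the
  suggestion is the leading run of observed values above their
  reference.
* **Fitting** by minimum residual (minres/ULS): uniquenesses
  $\psi$ are optimised (L-BFGS-B with the analytic gradient
  $-2\sum_{i>k}\lambda_i v_{ji}^2$) so that the rank-$k$ eigenapproximation
  of $R - \mathrm{diag}(\psi)$ minimises the squared off-diagonal
  residuals. On an exact one-factor matrix the loadings are recovered to
  machine precision (tested).
* **Rotation** to an oblique simple structure by the oblimin criterion
  via gradient projection, with several deterministic starts because the
  identity start can be a saddle for symmetric patterns; factor signs
  are fixed by making each factor's largest-magnitude loading positive,
  so runs are reproducible.
* **Model comparison** by an approximate Bartlett-corrected
  likelihood-ratio $\chi^2$ with $\mathrm{BIC} = \chi^2 - df\,\log n$.
  The dimension choice takes the parallel-analysis count and lets BIC
  move it to a neighbouring count only when the BIC is actually
  defensible, i.e. when there are more observations than variables; with
  $p \ge n$ the BIC column is reported but does not arbitrate.

Since `psych` and `GPArotation` are not dependencies, the minres
objective, the oblimin gradient-projection rotation and parallel
analysis are implemented in the package from the published algorithms
and validated against closed forms in the test suite.

Cluster *scores* — the variables carried into outcome models — are
deliberately humbler: the per-sample arithmetic mean of the non-missing
$-\Delta$CTs of a cluster's members. Row means tolerate sporadically
undetected miRNAs without imputation and are trivially interpretable;
no Bartlett/Thurstone factor-score estimator is offered.

## Outcome models

Each cluster score enters its own matched-pair mixed model (clusters one
per model, mirroring the reporting convention):
`outcome ~ score + bmi + gravida + history_ptb + fetal_sex + (1 | pair_id)`,
linear (`lme4::lmer`, REML) for gestational age, birth weight and head
circumference, logistic (`glmer`) for PTB status. Inference on the score
term uses the Wald z with a normal 95% CI. A singular pair variance is
retained and noted; only a hard failure falls back to fixed effects with
a `degraded` flag, and separation in the logistic model surfaces as a
recorded warning note rather than a silent divergence. A term-only
ordinary regression (`term_only_regression()`) asks whether a
cluster–outcome association survives adjustment for gestational age and
birth weight within term deliveries, reported as the usual
$(R^2, F(df_1, df_2), p)$ tuple.

Per-miRNA screens use the pooled-variance Student t-test by default
(Welch by flag); the accompanying global comparison of total expression
is computed on per-sample mean raw CT, because the per-sample mean
$-\Delta$CT is identically zero by construction and cannot carry a
global signal. Outcome correlations are Pearson with unadjusted
0.05/0.01 flags as conventionally printed, plus Benjamini–Hochberg
q-values for honesty.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` draws a matched case-control cohort of 21 term and
21 PTB deliveries with a 118-assay panel: three one-factor clusters
(33 c14mc-like, 15 c19mc-like, 10 miR-17/92-like members, the family
split across chr13/chrX) plus 60 unclustered background miRNAs.

Key design choices, with reasons:

* **Background miRNAs are not optional.** The global mean is taken over
  the whole panel. If the panel contained only the three clusters, the
  per-sample centring would impose one linear constraint across the
  three cluster levels and collapse them to two effective dimensions —
  no analysis could ever recover three factors. Real panels detect far
  more miRNAs than these clusters; 60 factor-free background assays
  (marginal sd 0.9, matching the clustered miRNAs) restore that
  property.
* **Group structure.** Within-cluster coordination is a loading problem:
  PTB multiplies c14mc loadings by 0.7 (weaker coordination) and c19mc
  by 1.1 (stronger). Between-cluster coordination is a latent
  correlation problem: the c14mc–c19mc factor correlation is −0.3 in
  term and −0.7 in PTB, with the miR-17/92 couplings (+0.2/+0.4, −0.2)
  completing the matrix. The two mechanisms are configured independently
  so each is separately testable.
* **Labels are the recruitment design.** A case-control study samples
  deliveries by outcome; the generator does the same, giving the groups
  gestational-age baselines 38.6 ± 0.7 (term) and 35.3 ± 2.4 weeks (PTB)
  and adding a group-independent cluster-score effect. Two tempting
  alternatives were measured and rejected: rejecting whole draws on a
  37-week threshold selects on the cluster scores themselves and erases
  the configured between-group coupling difference, while truncating
  only the gestational-age residual makes the expected outcome nonlinear
  in the score and biases the regression slope to less than half its
  value. With design-based labels both the correlation structure and the
  regression estimand are exact; gestational age falls on the label's
  side of 37 weeks for roughly 90% of samples, and the metadata
  validator treats the label as authoritative, warning on the remainder.
  (The emulated cohort's published summary rows are themselves mutually
  inconsistent — an overall sd of 1.6 weeks cannot arise from those
  group means and sds — so the generator matches the group rows and its
  overall sd is ~2.3 weeks.)
* **Outcome scale.** Effects are defined per unit of the *centred*
  cluster score — the observable the models actually regress on. Since
  $-\Delta$CT is only defined relative to the sample's global mean, an
  "uncentred" effect would not be estimable by any analysis of the data.
  `outcome_on = "factor"` exposes the latent-scale alternative for
  attenuation studies. Birth weight (160 g/week, sd 250 g) and head
  circumference (0.3 cm/week, sd 1.1 cm) follow gestational age, and by
  default c19mc has a direct −0.9 cm/unit effect on head circumference
  independent of gestational age, so the term-only regression has
  something real to find.
* **Censoring.** Per-miRNA baseline CTs are drawn N(36, 6) against a
  cutoff of 50, so a small tail of assays is partially or wholly
  unamplified — enough to exercise the missing-data paths and the
  30-of-42 detection rule without dominating the data.

What the generator does *not* emulate: amplification curves, plate and
batch effects, hemolysis chemistry (QC fixtures are constructed directly
as CT patterns), matching on covariates (pairs are formed in order;
the simulated covariates are exchangeable so this is equivalent), and
any causal pathway from outcomes back to miRNA expression. A green test
on this cohort therefore establishes that the statistics recover the
configured structure at the design's size — not that real plasma data
behave this way.

## Numerical choices

* Pairwise-complete correlation matrices that fail an eigenvalue floor
  of 1e-8 are nearest-PD repaired before inversion; every consumer
  records whether repair happened.
* Jennrich inputs with condition number above 1e10 error out with
  diagnostics; `compare_groups()` downgrades that to a per-region note.
* The minres optimiser bounds uniquenesses to [1e-3, 1] and starts from
  1 − SMC; non-convergence is an error carrying the optimiser code, not
  a silent result.
* All simulation and resampling take explicit seeds; nothing reads
  global RNG state without restoring it (`withr::with_seed`).
* Ties in the chaining sort are broken by (chromosome, start, end, id),
  making cluster output order-independent (tested).

## Known limitations

* The ANOVA on correlation coefficients inherits the independence caveat
  noted above; its p-values reproduce the field's convention.
* With 21 samples per group, Jennrich is limited to regions with fewer
  than ~20 members; larger blocks are reported as untestable rather than
  approximated.
* At this design size, Horn retention of the smallest (10-member)
  cluster's factor is marginal under the default coupling: in repeated
  simulation about 83% of cohorts retain all three factors (and when
  three are retained, over 95% of miRNAs load on their generating
  cluster's factor essentially always). Retention — not alignment — is
  the binding constraint, which is worth knowing before designing a
  similar study at n = 42. The package reports the eigenvalue/threshold
  table so the marginality is visible case by case.
* The logistic PTB model is included for completeness; with labels tied
  to recruitment rather than a data threshold, its effect in the default
  synthetic world is weak.
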