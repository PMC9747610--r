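---
title: "Methods: pre-vaccination endotypes and antibody response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-vaccination endotypes and antibody response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vaxendo analyzes a multi-study compendium of blood transcriptomes collected
around vaccination, together with antibody titers. This vignette documents
the statistical procedures, their assumptions, the parameters that matter,
the numerical conventions adopted where a choice was genuinely open, and
what the bundled synthetic-data generator does and does not emulate.

## The compendium model

All methods operate on log2-scale expression values indexed by gene symbol
and sample, with per-sample metadata (participant, study, platform, sample
type, vaccine, day relative to vaccination). Day −7 and day 0 are the only
days treated as pre-vaccination, everywhere. Gene symbols are matched
case-sensitively with no alias resolution; the loader rejects missing values
by default (optional per-gene-median imputation), because every downstream
stage assumes a complete matrix.

## Normalization and batch correction

Within each study, quantile normalization replaces each sample's sorted
values by the across-sample mean of order statistics (ties receive the mean
of their tied ranks — the standard convention, which makes the map
well-defined); single-sample studies are left unchanged. Across studies, a
per-gene ordinary least squares model with categorical study, sample-type
and platform effects is estimated **on pre-vaccination samples only** and
the fitted batch component is subtracted from every time point, so
vaccine-induced changes are never absorbed into the batch estimate. The
pre-vaccination-only window is deliberately not configurable.

Because each study is typically run on one platform with one sample type,
the design is rank deficient. Columns are added greedily in the order
intercept → study → sample type → platform, keeping only columns that
increase the design rank; thus platform (then sample type) columns are
dropped first when confounded, the finer study factor absorbs the shared
variance, and the dropped columns are recorded in the model object. The
alternative (dropping study first) would leave between-study differences
uncorrected whenever platforms coincide, which is the common case.

Subtracting per-study means has a known limitation: when endotype
composition differs between studies, part of the biological signal is
removed along with the batch effect. This is inherent to mean-subtraction
correction, is visible in the simulator at large endotype effects with small
studies, and is why the endotype-recovery validation (below) is run with
batch effects disabled while batch-effect removal is validated separately.

## PVCA

Variance attribution works on principal components of the sample-by-sample
covariance of gene-standardized expression. The smallest PC set reaching a
cumulative-variance threshold (default 0.60, a common PVCA convention;
reported in the result) is retained. Per PC, all requested factors are
fitted **jointly** as random intercepts by REML (lme4); if the fit fails, a
one-way method-of-moments estimator per factor is used instead. Negative
components are truncated at zero. Each retained PC's normalized components
are weighted by that PC's share of **total** variance, and the residual is
reported as the remainder: the discarded tail PCs — which are mostly noise —
therefore count toward `resid`. (Normalizing weights over retained PCs only
would systematically under-count the residual, because the top PCs are
structure-rich by construction.) Factors with as many levels as samples are
unidentifiable and dropped with a warning; single-level factors contribute
zero.

Metadata encoding follows fixed rules: age is binned into 10-year intervals;
days above 20 are collapsed into one `">=20"` level (days up to 20 stay
distinct), a convention flagged in the output because "censoring at 20 days"
admits more than one reading; missing values become an explicit `"missing"`
level. Bootstrap confidence intervals (percentile, 95%) resample
*participants* with all their samples, respecting repeated measures; the
bootstrap unit is a package choice since sample-level resampling would
understate uncertainty for longitudinal designs. Production runs use a few
thousand replicates; the tests use 50 to keep runtimes short.

## SLEA

Expression is gene-standardized (centered and scaled per gene across all
samples) before scoring, so the null distribution of a random gene set's
mean is comparable across sets; this convention is declared rather than
inherited, and it implies that per-sample z-scores do depend (through the
standardization) on the full sample collection. For a set with `m` genes
found in the matrix, the observed statistic in sample `s` is the mean
standardized expression of its genes; the null is the empirical distribution
of means of random `m`-gene sets drawn without replacement from all genes.
One shared block of draws per distinct `m` serves all sets of that size —
this costs O(perms × genes) instead of O(perms × genes × sets) and removes
set-to-set Monte-Carlo noise at equal size. `z = (obs − null_mean)/null_sd`,
defined as 0 when the null sd is 0 (degenerate samples, or a set spanning
the whole universe). Defaults: 1000 permutations, explicit seed, sets kept
only at effective size ≥ 5 (the floor is configurable; very small sets give
unstable nulls). An exact mode enumerates all subsets for validation on tiny
universes, where the sampled null must agree with the closed-form
finite-population mean and sd.

Superset scores are unweighted means of member-set z-scores over the seven
canonical groups (T cells, NK cells, B cells, monocytes/DCs, inflammation,
E2F/MYC, ISGs). Because GMT files cannot carry the grouping, it travels in a
two-column sidecar table (`supersets.tsv`).

## Endotype discovery

Pre-vaccination samples are clustered on their SLEA column vectors with
Euclidean distance and complete linkage; the dendrogram is cut at the
requested k. The Gap statistic compares `log W_k` (within-cluster pairwise
dispersion, squared Euclidean, `Σ_r D_r / 2n_r`) against reference datasets
drawn uniformly over each feature's observed range — the simpler of the two
reference schemes in the original proposal, chosen for determinism — and
selects the smallest k with `Gap(k) ≥ Gap(k+1) − se(k+1)`. All-identical
inputs short-circuit to k = 1 with a warning. With real batch residue the
gap curve can keep improving past the biological k; the recovery validation
therefore isolates clustering from batch structure.

The three clusters are ranked by their mean inflammatory SLEA score — by
default the mean over the four hallmark inflammatory sets
(HALLMARK_INFLAMMATORY_RESPONSE, HALLMARK_COMPLEMENT,
HALLMARK_IL6_JAK_STAT3_SIGNALING, HALLMARK_TNFA_SIGNALING_VIA_NFKB) — and
labeled `inflam.lo` / `inflam.mid` / `inflam.hi`. Labels depend only on
scores, never on cluster ids. Tertile annotations use type-7 empirical
quantiles at 1/3 and 2/3 with ties to the lower bin. Participant-level
consensus is the majority label across a participant's pre-vaccination
samples, ties broken by the mean score.

Temporal stability is a one-way random-effects variance ratio: for each gene
set, the between-participant variance over eligible samples (day −7, day 0,
or day ≥ 70) divided by total variance, method-of-moments, truncated to
[0, 1]; the aggregate is the mean over sets. This variance-ratio definition
is a declared stand-in for trait-stability metrics defined elsewhere in the
literature; it equals 1 when participants are internally constant and ≈ 0
for exchangeable samples.

## Antibody response

Per strain, fold change = titer at the in-window day nearest 28 (± 2 d; tie
toward the later day) over the pre-vaccination titer (day 0 preferred,
day −7 fallback — the baseline day is otherwise unspecified, so the closest
day to vaccination wins). MFC is the maximum over strains; participants
without a qualifying strain are omitted with a log message, never silently.
Titers must be positive; any detection-limit flooring belongs upstream and
explicit. Vaccine scaling z-scores `log2(MFC)` within vaccine (zero-variance
vaccines score 0 with a warning). Responder classes use per-study type-7
percentiles: high ⇔ MFC ≥ p70, low ⇔ MFC ≤ p30, strictly between ⇒
moderate; if the two thresholds coincide (all MFCs equal) everyone is
moderate, since there is no information to rank. Because the class
boundaries are percentile-based, they are invariant to any monotone
transform of MFC.

## Response classifier and signature scoring

The supervised task is high vs low (moderate excluded). One pre-vaccination
sample per participant enters (day 0 preferred). Features are the top genes
by variance across pre-vaccination samples of participants with response
data (default 500; ties broken lexicographically for determinism). The
random forest is evaluated by outer stratified 10-fold cross-validation
(stratified by class only; study/vaccine stratification is not attempted and
the report records this). Within each training fold the per-split feature
count is selected from {√p, p/10, p/3} by the forest's **out-of-bag** auROC:
OOB error is itself a fold-free cross-validation estimate for bagged
ensembles, and using it instead of a nested 10-fold loop cuts the number of
forest fits about five-fold without an optimistic bias, since the outer
evaluation loop is untouched. Trees default to 500. All metrics (auROC,
accuracy, PPV, NPV, sensitivity, specificity, Brier) are computed on the
pooled out-of-fold predicted probabilities; per-vaccine auROCs are computed
on the out-of-fold subsets. Significance comes from permuting labels against
the pooled out-of-fold probabilities, `p = (1 + #{auROC_perm ≥ obs}) /
(n_perm + 1)`; re-running the full cross-validation per permutation would be
quadratically more expensive for the same null. Importances (impurity-based)
are min-max scaled to [0, 100] and thresholds are strict (`> t`).

Signature scores are arithmetic means on the log2 scale (equivalent to
geometric means of raw intensities): mean of present up genes minus mean of
present down genes, an empty side contributing 0; a signature with no gene
in the matrix is an error naming the missing symbols.

## Etiology metascore

`score = mean(HK3, TNIP1, GPAA1, CTSB) − mean(IFI27, JUP, LAX1)` on
batch-corrected log2 expression; `score ≥ 0` ⇒ bacterial-like. The score is
linear with weights +1/4 and −1/3 and invariant to adding a common constant
to all seven genes. All seven markers must be present — the published
weights assume the complete panel, so partial scoring is refused.

## Kinetics

Per participant and superset, delta = post score − pre score (day 0
preferred, day −7 fallback). Post days are binned at centers 1, 3, 7, 14
(tolerance ±1 for the first two, ±2 for the others) plus an open `21+` bin;
a day is assigned to the nearest center, ties toward the later bin, and
multiple samples in a bin resolve to the day nearest the center (tie →
later). Between-endotype comparisons use the two-sided Wilcoxon rank-sum
test — exact for combined n ≤ 25 without ties, exact by enumeration for
n ≤ 10 with ties, otherwise normal approximation with continuity and tie
correction — with effect size defined as the difference of group medians
(means would be equally defensible; medians are robust to the heavy-tailed
deltas the generator produces) and Benjamini–Hochberg correction across the
entire superset × bin × pair table.

## The synthetic-data generator

The generator is an additive Gaussian model on the log2 scale, matching the
linear batch-subtraction assumptions of the correction stage:
`expression = baseline(gene) + endotype shift + kinetic induction + study +
platform + sample-type effects + noise`. Each participant carries one
endotype for all samples. `inflam.hi` raises the inflammation, ISG and
monocyte/DC modules by `delta`; `inflam.lo` raises the T/NK/B/E2F-MYC
modules by `delta`; `inflam.mid` applies `delta/2` to both groups. Default
conditions: three studies of thirty participants, 1000 genes with seven
40-gene modules, `delta = 1` log2 units, noise sd 0.25, study batch sd 0.5,
platform and sample-type sds 0.25 — effect sizes a transcriptomics
practitioner would call moderate and clearly resolvable, chosen once. Each
study gets exactly one platform and one sample type, mirroring the real
confounding and making the aliasing logic testable. Post-vaccination
kinetics add per-superset, per-day mean inductions (defaults: early
inflammation/monocyte/ISG induction at days 1–3, a B-cell bump at day 7);
the day ≤ 3 inflammation induction is multiplied by an attenuation factor
(default 0.5) in `inflam.hi` participants, emulating blunted inflammatory
responses in already-inflamed individuals. Titers are log-normal at day 0;
the day-28 log2 titer adds `max(0, titer_beta · endotype_score + noise)`
with scores 0/0.5/1 for lo/mid/hi (defaults `titer_beta = 1.5`, noise sd 1).
Independent RNG streams per component (baseline, assignment, batch, noise,
titers) derive from one master seed, so changing the number of strains never
perturbs the expression draws, and a fixed seed reproduces outputs
byte-identically.

What the generator does **not** emulate: count-level RNA-seq noise,
probe-level artifacts, gene–gene correlation beyond module structure,
titer censoring at detection limits, age/sex-linked expression, and
missingness. Tests passing on this generator therefore demonstrate the
pipeline's correctness under its stated model, not robustness to every
property of real compendia.

## Validation conditions and problem sizes

The recovery experiments use fixed, documented conditions: endotype
recovery runs at `delta = 1`, noise 0.25, 90 participants over 20 seeds,
with batch/platform/sample-type sds set to 0 so that clustering is tested in
isolation (batch-effect removal has its own validation, and mean-subtraction
correction under unbalanced endotype composition would otherwise entangle
the two — see above). PVCA recovery uses 200 genes and 120 day-0
participants with effect sds solved so the planted day-0 fractions are study
0.3, endotype 0.2, residual 0.5 (`batch_sd² = 0.15`, `delta²/6 = 0.10`,
`noise² = 0.25`). Classifier calibration uses 300 participants and 600
genes: a null (`titer_beta = 0`) and a strong planted effect
(`titer_beta = 2`, titer noise 0.25), with 300 trees; the permutation test's
empirical type-I error is estimated over 1000 null datasets of 40 samples
with 99 permutations each, enough replicates that the binomial noise of the
estimate is small against the margin being checked. The full-pipeline
determinism check runs two identical configurations on a 60-participant
compendium and compares output file hashes.

## Known limitations

* Mean-subtraction batch correction removes real signal when biological
  composition is confounded with study; only a shared-participant or
  reference-based design could separate them.
* The Gap statistic's one-standard-error rule is sensitive to substructure
  (including batch residue) and can choose k above the biological number of
  groups; endotype labeling deliberately operates on the k = 3 cut.
* PVCA fractions are method-of-attribution, not causal decompositions;
  REML truncation at zero biases small fractions upward slightly.
* The OOB-based `mtry` tuning assumes the forest's OOB auROC ranks
  hyperparameters like an inner cross-validation would; for very small
  classes this ranking gets noisy.
* The temporal-stability metric is a variance ratio over eligible days; it
  is not guaranteed to match other published stability indices numerically.
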