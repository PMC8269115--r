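---
title: "Models and methods: histone-signature subtyping and driver screening in liposarcoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: histone-signature subtyping and driver screening in liposarcoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipodriver)
library(dplyr)
```

# The scientific problem

Well-differentiated (WDLPS) and dedifferentiated (DDLPS) liposarcoma share
the hallmark 12q13-15 amplification (MDM2, CDK4) but differ sharply in
aggressiveness. A recurring observation in DDLPS cohorts is that a subset
of tumors massively over-expresses the replication-dependent (canonical)
histone genes (RD-HIST) clustered at 6p22.2 — genes normally transcribed
only during S-phase — and that this histone-high state tracks with
proliferation and genomic instability. `lipodriver` implements the
integrated analysis that (a) calls somatic copy-number amplification and
point-mutation candidates from paired tumor/normal exome coverage, (b)
scores RD-HIST expression and splits DDLPS into histone-high (`HIST+DD`)
and histone-low (`HIST-DD`) subgroups, and (c) screens transcription
factors for the combination of RD-HIST co-expression and tumor-specific
focal amplification that nominates an HMGA2-like upstream driver.

Because the patient-level data behind such studies are typically not
deposited, every stage is paired with a synthetic cohort generator that
plants known parameters, so the pipeline's claims are validated by
parameter recovery rather than by re-processing inaccessible data.

# Module by module

## Copy number from paired coverage

Per-bin copies are anchored at diploid autosomes by median-of-ratios:

$$\widehat{c}_i \;=\; 2\,\frac{t_i/\mathrm{med}(t)}{n_i/\mathrm{med}(n)},$$

with medians over autosomal bins and zero-normal bins masked rather than
zeroed. No purity or ploidy correction is applied; sex chromosomes are
excluded from the medians.

Segmentation is a recursive change-point carve in the
circular-binary-segmentation style: within the current window the
contiguous arc whose mean contrasts most with the rest — statistic
$S(i,j)=\lvert \bar{x}_{\mathrm{in}}-\bar{x}_{\mathrm{out}}\rvert
\sqrt{n_{\mathrm{in}} n_{\mathrm{out}}/n}$ — is accepted if a permutation
test (default 1000 within-window shuffles of the bins, reference
distribution the max arc statistic of each shuffle) gives p < 0.01, then
the arc and its flanks are carved recursively; arcs and nonempty flanks
keep at least `min_bins = 3` bins. We initially evaluated a plain binary
split (best single flank split by mean difference, permutation-tested) and
found it analytically and empirically under-powered for short interior
amplicons: a 3–5-bin event inside a 60-bin chromosome yields shuffle-null
p-values of 0.05–0.3 because permutations re-cluster the same extreme bin
values at window edges. The segment-vs-rest arc statistic is the standard
remedy and is what the field's segmentation tools use. The statistic's
$\sqrt{n_{\mathrm{in}}n_{\mathrm{out}}/n}$ scaling keeps its null variance
constant across arc sizes, so the permutation comparison is exact; ties in
the arc scan break to the leftmost arc, making segmentation deterministic
given the permutation seed.

"Focal amplification" is defined as extra copies $>2$ (the ">two-copy"
rule) on a segment no longer than 20 Mb. The length cap is a documented
package default — focality has no universal definition — and both the
threshold and cap are exposed. SCNA burden counts segments with
$\lvert c-2\rvert \ge 1$ supported by $\ge 3$ bins.

The copy-number/expression correlation is computed gene-level: per gene,
the mean copies of overlapping segments (averaged over the sample group)
against the mean log2 normalized expression, Pearson with a two-sided
t-based p. With fewer than 3 genes, or zero variance on either axis, it
raises an error instead of returning NaN.

## Somatic candidates

Each site's (ref, alt) × (tumor, normal) table is tested with a two-tailed
Fisher's exact test implemented from the hypergeometric mass: the p-value
is the sum of probabilities of all tables with the observed margins whose
probability is at most that of the observed table, with an absolute
1e-12 slack for float ties; a zero margin returns p = 1 by convention.
Candidates are ranked by raw p (ties broken by chromosome, then position,
so the ranking is a stable total order) — no multiple-testing correction
enters the ranking, though BH q-values are reported. The pass filters
(p < 0.01, tumor alt ≥ 4, normal alt ≤ 1) are package decisions: the read
support thresholds replace the manual inspection a human analyst would
apply. The normal-alt cap trades a few percent of sensitivity (true sites
whose matched normal happens to show ≥ 2 error reads) for high precision.

## Expression statistics

Counts are normalized by median-of-ratios size factors (genes with any
zero excluded from the median; factors rescaled to geometric mean 1, which
makes normalization exactly idempotent). Differential expression is a
two-sided Wilcoxon rank-sum test on log2(normalized + 1) — exact
enumeration when both groups have ≤ 10 samples and the data are untied,
normal approximation with tie correction otherwise — with BH adjustment
and a +1-pseudocount log2 fold change. This is deliberately a rank-based
stage (results carry a `wilcoxon` method tag), not a negative-binomial
GLM: the package does not claim to reproduce shrinkage-based estimators,
and no single DE significance cutoff is asserted; counts at several
cutoffs are reported instead (`glance()`).

Gene-set over-representation is an upper-tail hypergeometric test against
a flat gene universe (no ontology DAG handling); gene-set expression
shifts are Wilcoxon tests on per-sample mean set scores with Bonferroni
correction across sets.

The embedding primitive z-scores genes on log2 values (zero-variance
genes dropped with a warning), takes principal components from the sample
covariance, fixes each component's sign so its largest-magnitude loading
is positive (plots and downstream labels are reproducible), and clusters
samples with Ward linkage on Euclidean distances. Ward/Euclidean is a
package choice — hierarchical clustering of signature genes rarely states
its linkage — and is exposed as an argument.

## Histone scoring and subtyping

A sample's RD-HIST score is its mean log2(normalized + 1) over the
catalog (66 genes over families H1:6, H2A:16, H2B:18, H3:15, H4:11 by
default; the shipped catalog ids are synthetic placeholders matching the
simulator, and real analyses supply their own GMT). The overall score is
exactly the size-weighted mean of family scores. DD tumors are classified
by a k = 2 Ward cut on the catalog genes restricted to DD samples, the
higher-mean cluster labelled `HIST+DD`; this rule makes labels
deterministic. WD samples are never classified — the signature is treated
as DD-internal — but `flag_wd_high_histone()` reports WD samples scoring
above the HIST+ minimum (the sub-clone question) without relabelling
anything.

The averaged gene-set fold change uses per-gene
$(\bar{x}_B + 1)/(\bar{x}_A + 1)$ with a detection filter (mean
normalized count ≥ 1 by default) whose surviving subset size is always
reported; this is how a 66-gene catalog can honestly yield a fold change
over, say, 53 detected genes.

## The driver screen

The cascade mirrors a driver-prioritization funnel: (1) expressed TFs
(mean normalized count ≥ 1 across tumors — the expression rule behind
published "percent expressed" figures is rarely stated, so the threshold
is exposed); (2) co-expressed TFs, requiring Pearson R above 0.6 against
*each* of the five family mean profiles, computed on DD samples only by
default. Correlating against family aggregates rather than all 66
individual genes is the central interpretive decision: single-gene
profiles at moderate depth are noise-dominated, and the per-gene strict
mode remains available (`family_mode = "per_gene"`); (3) amplified TFs,
whose gene interval is overlapped by a passing focal amplification in at
least one DD sample and whose mean DD extra copies exceed the WD mean
("DD-specific" in the sense of amplitude, since the HMGA2-like interval
is amplified in both subtypes, just more strongly in DD). Passers are
ranked by maximum DD extra copies, then minimum family correlation, then
gene id. Funnel counts are emitted at every stage with the one-decimal
percentage formatter (68 of 1988 prints as "68 (3.4%)").

# The synthetic cohort generator

The generator is first-class, tested code. Its defaults are the study
conditions the analysis is designed for, and they are fixed once:

* **Samples**: 11 WD, 8 HIST−DD, 5 HIST+DD, 3 normals.
* **Genome**: four 60-Mb chromosomes binned at 1 Mb. A 12-Mb broad
  amplicon ("12q13-15-like") carried by every tumor, planted as three
  sub-segments with independent lognormal amplitudes around the group
  mean (11.8 copies WD, 15.5 DD; real amplicons are internally
  heterogeneous, and a perfectly uniform amplicon would make gene-level
  CN variation degenerate); a 5-Mb driver-TF segment just distal to it,
  near-diploid in WD/HIST− (mean extra 0.5) and amplified to a mean of
  18 copies in HIST+ tumors; a diploid 2-Mb histone cluster
  ("6p22.2-like") of 66 genes; and random 3–8-bin passenger gains/losses
  at rates 1 / 2.5 / 4 per tumor for WD / HIST− / HIST+ (gain extra
  copies lognormal around 4, sdlog 0.35 — comfortably above the 2-copy
  call threshold, as focal sarcoma gains typically are — so recovery
  metrics measure the caller, not threshold-straddling events).
* **Coverage**: tumor bins Poisson(depth × c/2), normal Poisson(depth),
  depth 150 — a typical tumor-exome coverage.
* **Expression**: gene baselines are a 85%/15% expressed/silent mixture
  (the expressed fraction echoes what TF expression surveys report).
  Copy-number-coupled genes follow a power-law dosage response,
  $\log_2 x = b + s\,(\log_2 c - 1)$ with dosage exponent $s = 1$
  (proportional dosage). We deliberately do not make log-expression
  linear in copies: exponentiating a 16-copy amplification's lognormal
  dispersion produces a continuum of intermediate histone states that
  real HIST+/HIST− cohorts do not show, and proportional dosage is the
  field's default expectation. Histone genes follow the realized driver-TF
  log-expression through `beta_tf_hist` (default 1); under
  `passenger_decouple` (default) all other genes in amplified intervals
  stay at baseline, emulating the low passenger CN-expression
  correlations attributed to epigenetic silencing. Counts are
  Poisson-lognormal (log-normal biological noise SD 0.3, lognormal
  library factors sdlog 0.15) — a simpler noise model than a dispersed
  negative binomial, adequate for recovery testing.
* **Somatic sites**: per tumor Poisson(14.1) (WD) or Poisson(23.5) (DD)
  true sites, tumor alt fraction Beta(6, 14) (mean 0.3), normal error
  0.002, plus 150 error-only decoy sites.
* **Phenotypes**: mitotic index $= 3 + 7a + N(0, 2.5)$ per 10 HPF and
  Ki67 $= 5 + 14a + N(0,6)$ % (clipped to [0, 100]), with $a$ the true
  histone activity; normals get near-zero baselines. The noise
  magnitudes are package defaults — no published value exists for them.

Seeding uses one master seed split into named substreams per generator,
so adding a generator never perturbs another's draws, and one seed yields
a bit-identical cohort.

What the generator does *not* emulate: read-level data, sequence content,
GC/mappability bias, tumor purity and subclonality, allele-specific copy
number, batch effects, and single-cell structure. Recovery results
therefore demonstrate the pipeline's correctness and calibration under
its stated model, not performance on raw sequencing data.

# Numerical choices and degenerate inputs

* Fisher tail rule: absolute 1e-12 slack; zero margins give p = 1.
* Wilcoxon: mid-ranks with tie-corrected variance on the approximate
  path; the exact path is only used for untied data.
* Segmentation ties: leftmost arc; masked bins excluded from means;
  empty chromosomes skipped with a warning.
* Zero-variance vectors: correlations are returned as flagged undefined
  (screen) or raise errors (CN-expression correlation), never silent 0s.
* PCA sign: largest-|loading| positive per component.
* All intervals are 0-based half-open except site positions (1-based,
  VCF-style); every interval writer embeds a `#coords=` header.

# Problem sizes used for validation

The shipped validation runs use 1200-gene, 27-sample cohorts (60 TFs),
20 seeded cohorts for copy-number and subtype recovery, 50 seeded screens
for driver recovery plus 50 under the β = 0 null, a 10,000-gene null for
DE type-I error, the exhaustive 2×2 sweep with margins ≤ 30 for the
Fisher oracle, and exhaustive permutation enumeration for group sizes up
to 8 for the Wilcoxon oracle. These sizes are the package's validation
design; all thresholds the tests assert (sensitivity ≥ 0.95, FDP ≤ 0.05,
RMSE ≤ 0.5 copies, label accuracy ≥ 95%, rank-1 rate ≥ 90%, null pass
rate ≤ 10%, type-I ≤ 6%) are computed fresh at test time.

# Known limitations

* Absolute copies assume a diploid, pure tumor; purity/ploidy inference
  is out of scope, as is allele-specific copy number.
* The DE stage is rank-based; shrinkage estimators will differ,
  particularly at low counts.
* The screen establishes co-occurrence (co-expression + amplification),
  not causality; knockdown-style validation is outside the package.
* Gene sets are flat; no GO DAG propagation.
* The simulator's clean subgroup structure makes subtype recovery an
  upper bound on real-data performance.
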