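---
title: "Methods: stratifying large-cell neuroendocrine lung carcinomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying large-cell neuroendocrine lung carcinomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `lcnectype`, the
choices made where the design was genuinely open, and what the synthetic
cohorts used for validation do and do not emulate.

## The biological problem

Pulmonary large-cell neuroendocrine carcinomas (LCNEC) sit between
adenocarcinoma-like and small-cell-like lung cancers. Genomically they
divide into two mutually exclusive arms: tumors with bi-allelic
*STK11*/*KEAP1* inactivation (type I) and tumors with bi-allelic *RB1*
inactivation (type II). Transcriptionally, type I tumors express the
neuroendocrine program (high *ASCL1*, *DLL3*, *CHGA*, *SYP*, *NCAM1*; low
NOTCH pathway activity), whereas type II tumors show the reverse pattern.
The package provides each analysis stage needed to recover this structure
from cohort-scale mutation, copy-number and expression data.

## Significantly mutated genes

The background model assumes somatic mutations fall uniformly over a
callable coding territory `G` (default 3e7 bases), so a gene of coding
length `L_g` expects `lambda_g = N_total L_g / G` mutations when the
cohort carries `N_total` somatic calls. Two per-gene signals are tested:

* **burden** — the upper Poisson tail of the non-synonymous count at rate
  `lambda_g f_ns`, with `f_ns = 0.75` the expected non-synonymous fraction
  of random coding mutations (configurable; no per-trinucleotide
  opportunity model is attempted);
* **ratio** — the upper binomial tail of the gene's non-synonymous count
  among all its mutations at the cohort-wide non-synonymous fraction.

The two signals are combined through Fisher's statistic
`T = -2(log p_burden + log p_ratio)`. A chi-squared(4) reference would be
miscalibrated twice over: both tails are discrete, and both depend on the
same observed non-synonymous count. We therefore compute the p-value of
`T` by *complete enumeration* of its null distribution (total count
Poisson, non-synonymous count binomial given the total), which is cheap
because the support is small. The reported default is the mid-P version of
that enumerated tail — half weight on the observed statistic — which makes
the null distribution of p-values uniform on average; the strictly
conservative tail is available via `combination = "exact"`. On simulated
uniform-null cohorts of 1,000 genes the fraction of genes with
`p_combined < 0.05` sits within the binomial noise band around 0.05, and
replicate cohorts essentially never produce a Benjamini-Hochberg call at
Q < 0.01.

Damaging-mutation enrichment (splice-site, nonsense, frameshift) is an
upper binomial tail at the cohort damaging fraction, and hotspot
clustering resamples positions uniformly along the gene, using the maximum
per-position recurrence as statistic with an add-one Monte Carlo p-value.
Both are gated to genes mutated in more than 10% of samples. Genes without
expression support (abundance > 1 in fewer than 35/60 of samples) are
removed *before* the BH correction, since non-expressed genes accumulate
excess background mutations.

## Purity, ploidy and cancer cell fractions

For a segment with tumor/normal ratio `r` in a specimen of purity `rho`
and tumor ploidy `psi`, the implied tumor copy number is

    c(r) = (r (rho psi + 2 (1 - rho)) - 2 (1 - rho)) / rho.

`fit_purity_ploidy()` scores every `(rho, psi)` on a grid (purity
0.10-1.00 by 0.01; ploidy 1.5-5.5 by 0.05) by the segment-length-weighted
mean squared distance of `c(r_i)` to the nearest non-negative integer.
Solutions related by `c -> a c + m` (integer shifts and scalings of the
copy-number profile) score identically on clean data; the fitter
enumerates that family analytically around the grid argmin and takes the
lowest-ploidy member within 1.5x of the best score, breaking remaining
ties toward higher purity. A homozygously deleted segment anchors the
profile absolutely (a negative shifted copy number is impossible), which
is why the synthetic genomes always include one.

The expected allelic fraction of a clonal mutation of multiplicity `m` on
total copy `c_t` is `AF_exp = m rho / (c_t rho + 2 (1 - rho))`; the cancer
cell fraction is the quotient `CCF = AF_obs / AF_exp(m)` with `m` chosen
in `[1, c_t]` to bring `AF_exp` closest to the observed fraction (no
allele-specific copy numbers are required). Estimates above 1.5 are capped
and flagged rather than silently truncated to 1.

Clonal/subclonal status uses the *sample-level* distribution of CCFs: a
two-component mixture with a clonal point mass at CCF 1 and a subclonal
component uniform on (0, 1), binomial read-count likelihoods, and a
mixing weight fitted by EM. A mutation is called clonal or subclonal only
when its posterior component probability exceeds 0.90. We initially
implemented a per-mutation grid posterior with a uniform CCF prior
(retained as `classify_clonality()` / `method = "grid"`), but its
boundary behavior is poor: at depth 100 a true-clonal mutation with
moderate expected fraction is confidently mis-called subclonal 1.5-5% of
the time while almost never reaching a confident clonal call, so in a
cohort that is ~93% clonal the confident calls are badly contaminated.
The mixture uses the information the sample as a whole carries about the
clonal fraction and does not have this failure mode.

Subclonal enrichment per sample is an upper binomial tail of the
subclonal-call count against the 0.10 false-assignment rate implied by
the decision band, at alpha 0.01.

## Mutational signatures

Single-base substitutions with flanking context are collapsed to the
pyrimidine-reference strand and counted into the conventional 96 channels
(substitution-major, then 5' and 3' base, alphabetically). Signatures are
extracted by non-negative matrix factorization minimizing generalized
Kullback-Leibler divergence with multiplicative updates (tolerance 1e-8
relative KL change, at most 10,000 iterations, epsilon 1e-12 guards).
Each of the 50 default restarts yields `k` column-stochastic signatures;
the pooled restart solutions are clustered by cosine similarity into `k`
consensus signatures (medoids), whose mean within-cluster cosine is the
reproducibility score. Exposures are then refit against the consensus
signatures with the signature matrix frozen, which preserves per-sample
totals. `k` is user-supplied; `scan_signature_k()` reports reconstruction
error and reproducibility over candidate ranks without choosing one, and
the KL trace of every restart is retained so monotone convergence can be
verified. Cases with fewer than 30 variants (configurable) are excluded
before extraction, since their spectra are too sparse to constrain the
factorization.

## Expression subtyping

Raw counts are upper-quartile normalized (each sample's 75th percentile
of nonzero counts scaled to the cohort mean of those percentiles). The
grand median of the normalized matrix defines the low/high expression
threshold used for marker profiling. Clustering genes must exceed
quantile thresholds of both `log2(mean)` and `log2(variance)` on the
normalized scale — the quantile pairs used by the five comparison
experiments ship as `clustering_presets()`; filtering happens after
normalization. Before clustering, values are `log2(x + 1)` transformed
and median-centered by gene.

Consensus clustering draws 250 subsamples of 80% of the samples without
replacement (both configurable), clusters each by PAM on a Spearman
correlation distance (or average-linkage hierarchical clustering on a
Pearson distance), and records the co-clustering frequency of co-sampled
pairs. Final labels cut an average-linkage tree of one minus the
consensus matrix; the area under the consensus CDF is reported per `k`.
Cluster merging (e.g. collapsing two classes judged redundant on review)
is an explicit, logged operation rather than a silent relabeling.

Cluster separation between two classes is tested against a single
multivariate Gaussian null whose diagonal covariance (in principal
components) carries the sample eigenvalue spectrum floored at a
MAD-based background noise variance; each simulated dataset is scored by
its best 2-means cluster index. Because the observed index is computed
for the *given* labels while the null re-optimizes, the test is
deliberately conservative: arbitrary (non-clustering-derived) labels can
only push the p-value toward 1, and even clustering-derived labels carry
an extra conservatism from the null's re-inflated sample spectrum. We
treat it as a guard against over-interpreting weak splits, not as a
calibrated p-value.

The subtype classifier is ClaNC-style: per gene and class a t-like score
`(class mean - overall mean) / (pooled within-class SD + s0)` with `s0`
the median pooled SD; classes greedily claim their top genes by absolute
score with every gene active in at most one class; prediction is nearest
centroid in the standardized space. Permutation differential expression
follows the SAM construction: `d = (mean2 - mean1)/(s + s0)` with `s0`
chosen from the percentiles of `s` to stabilize the spread of `d` across
`s`-bins (falling back to the 5th percentile when the criterion is flat),
a label-permutation null, and q-values from the ratio of expected to
observed exceedances, monotonized. Gene-set enrichment of the resulting
lists is a hypergeometric upper tail over user-supplied sets.

## Genotype-subtype association

Driver status per sample and gene combines somatic hits (non-synonymous
mutations, disrupting rearrangements) with second-hit evidence (a second
mutation, loss of heterozygosity) and homozygous deletions: a homozygous
deletion alone is bi-allelic, two independent hits are bi-allelic, a
single hit is mono-allelic, and LOH without any somatic hit is recorded
as no alteration (it only corroborates a hit). Mutual exclusivity of the
*STK11*/*KEAP1* and *RB1* arms is a two-sided Fisher exact test on the
collapsed 2x2 table, with the two-sided p defined by probability
ordering; an r x c Monte Carlo version samples margin-preserving tables.
Subtype labels follow the driver rule (type I: *STK11*/*KEAP1* without
*RB1*; type II: the reverse; both altered is ambiguous). Exclusivity and
typing can count any alteration or bi-allelic events only; the validation
workflow uses bi-allelic mode because the subgroups are defined by
bi-allelic inactivation and because at realistic mutation rates (~8.6
non-synonymous/Mb) random passenger hits in a 2-3 kb driver occur in ~3%
of samples and would otherwise blur the planted architecture.

Neuroendocrine profiling calls each marker high when it strictly exceeds
the global threshold; the per-sample profile string combines the ASCL1
and DLL3 states with a majority-vote NOTCH state over *NOTCH1*, *NOTCH2*,
*HES1* and *REST*.

## The synthetic cohorts

`simulate_cohort()` emulates the statistical structure the analyses
assume, with defaults chosen once to match the cohort this methodology
was developed for:

* purity uniform on 0.4-0.9 (median ~0.6); integer copy-number states
  drawn per segment with weights giving a length-weighted ploidy of ~2.75,
  plus one homozygous deletion per genome; segment ratios get Gaussian
  noise (SD 0.02);
* 8.6 non-synonymous mutations per Mb over a 30 Mb territory, 25%
  synonymous, ~7.5% small indels; 7% of mutations subclonal with CCF
  uniform on 0.2-0.5; mutations on gained segments predate the gain with
  probability 0.35 (multiplicity 2) — only clonal mutations can, since
  subclones arise after the clonal copy-number state is fixed; read
  counts are binomial at depth 100;
* trinucleotide channels drawn from a two-profile mixture (a C>A-heavy
  tobacco-like profile at weight 0.51 and a C>T-heavy background at
  0.49), set so the cohort C:G>A:T fraction is ~0.387; the two synthetic
  profiles are constructed to have cosine similarity < 0.1 so that
  factorization recovery is identifiable — they are not measured
  reference signatures;
* genotype classes type I (37%), type II (42%) and other (21%), with
  class-defining drivers planted as bi-allelic events (LOH or a second
  mutation) and *TP53* altered in 92% of samples; expression classes
  matched to genotype, with 50 marker genes per class shifted by 2
  noise-SDs on the log2 scale and the neuroendocrine marker panel planted
  at ~4x the global median (high state) or well below it (low state).

A single root seed drives every component through deterministically
derived sub-streams, so adding a component never perturbs the others and
identical seeds give byte-identical cohorts.

What the simulations do **not** emulate: realistic chromosome structure
and gene-level copy-number events, covariate structure in mutation rates
(replication timing, expression level), allele-specific copy number,
subclonal copy-number changes, batch effects and library-size artifacts
in expression, and inter-gene correlation beyond the planted classes.
Passing recovery tests therefore demonstrates the estimators are correct
under their stated models, not that real cohorts satisfy those models.

## Validation scale and numerical choices

The validation suite exercises: 20 tumors x ~200 mutations for CCF
recovery; 15-20 samples for purity/ploidy recovery; 20 null cohorts of
1,000 genes for mutated-gene calibration; 50 samples x ~500 mutations and
50 restarts for signature recovery; 60 samples and 250 resamples for
consensus clustering; 100 held-out samples for the classifier; 20
replicates at 200 permutations for differential-expression calibration;
and complete enumeration of all small contingency tables for the Fisher
test. These sizes make the whole suite run in minutes while leaving the
statistical checks well-powered.

Numerical conventions worth knowing: discrete-test p-values use exact
tails (with the enumerated mid-P combination for the mutated-gene test);
the CCF cap is 1.5 with a flag; thresholds are strict inequalities (a
marker exactly at the global median is "low"; a BH q exactly at the
threshold is not significant); Fisher two-sided p uses probability
ordering with a 1e-7 relative tolerance for ties; the NMF adds 1e-12
inside multiplicative updates to avoid division by zero; and consensus
matrices put 1 on the diagonal by convention.
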