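---
title: "Detecting homologous recombination deficiency from the CpG deamination fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homologous recombination deficiency from the CpG deamination fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamHRD)
```

## The problem

Homologous recombination deficiency (HRD) predicts response to PARP
inhibitors and platinum chemotherapy. The established genomic readout is a
copy-number "scar" score, HRDsum = LOH + LST + TAI, computed from
allele-specific copy-number segments. Scar scores have a well-known
weakness: at low tumor purity the allele-specific copy-number signal is
diluted by normal cells and the score collapses, so HR-deficient tumors in
impure clinical samples are missed.

`deamHRD` implements an alternative readout based solely on the somatic
single-base-substitution (SBS) spectrum. Spontaneous deamination of
5-methylcytosine at CpG dinucleotides produces C>T transitions at CpG
sites in every tumor at a roughly clock-like rate. HR-deficient tumors
accumulate many additional mutations spread broadly over the other
mutation types, which *dilutes* the CpG C>T share of the spectrum. The
biomarker is therefore

$$
f_{deam} = 100 \times
\frac{\#\{\mathrm{C{>}T\ at\ CpG}\}}{\#\{\mathrm{all\ SBS}\}} \quad [\%],
$$

where the numerator counts the four channels `A[C>T]G`, `C[C>T]G`,
`G[C>T]G`, `T[C>T]G` of the standard 96 trinucleotide mutation types.
**Low** f_deam predicts HRD. Because every detected mutation contributes
equally and mutation detection does not depend on the mutation type, the
expected value of f_deam is unchanged when purity drops — only its
sampling noise grows as the effective mutation count shrinks.

## Mutation catalogs

SBS calls (MAF-like TSV, or VCF plus a reference FASTA for context
lookup) are normalized to the pyrimidine strand: a purine-referenced
substitution is reverse-complemented together with its flanking bases, so
`G>A` in context `C_T` becomes `C>T` in context `A_G`. The canonical
channel order is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G; then
5' base A,C,G,T; then 3' base A,C,G,T). Signature matrices in the COSMIC
layout are matched by row label, so their file order is irrelevant.

Records that are not single-base substitutions are skipped and counted;
soft-masked (lowercase) bases are uppercased; records containing `N` are
skipped with a warning rather than failing a whole cohort. TMB is defined
as the number of SBS in the sequenced region, i.e. the catalog total. No
VAF or depth filter is applied by default (thresholds are exposed in
`build_catalogs()`), since the analysis is meant to run on already-filtered
somatic calls.

**The NA rule.** The standard error of f_deam is approximately
$\sqrt{f(1-f)/\mathrm{TMB}}$ — it decreases with the inverse square root
of the TMB. Below `min_tmb = 10` mutations the estimate is dominated by
noise and is reported as `NA`, a value, not an error; downstream rank
statistics exclude NA samples pairwise and report the exclusion count.

## Ground-truth HR classification

Benchmarking a biomarker needs a label independent of the biomarker.
Tumors are classified by the *cause* of HRD from gene-level inputs:
deleterious BRCA1/2 alteration (H1a), deleterious alteration in another
HR-pathway gene (H1b), BRCA1/2 VUS (H2a), other-HR VUS (H2b), none (H3);
a tumor receives the highest applicable class. Deleterious classes carry
a biallelic/monoallelic suffix; `allelic = unknown` is treated as
monoallelic (conservative). The benchmark positives, H1a\*, are tumors
with a biallelic deleterious BRCA1/2 alteration *or* BRCA1 promoter
hypermethylation; negatives are H3 tumors without hypermethylation; all
other classes are excluded with the reason recorded. A tumor with a
monoallelic H1a and a biallelic H1b alteration keeps class H1a (class
precedence is strict); the suffix then comes from the H1a alteration.
Absent methylation data are treated as negative for classification but
recorded as unknown, so cohorts without methylation arrays can still be
benchmarked.

The shipped HR gene list is a deliberately marked placeholder of
well-known HR genes; real analyses should supply the full panel used by
their pipeline via `hr_gene_list(path)`.

## Scar scores

The package implements the published scar-score definitions directly on
allele-specific segments (`cn_major >= cn_minor >= 0`, 1-based inclusive coordinates):

* **LOH** — segments with `cn_minor = 0`, `cn_major > 0`, length
  strictly greater than 15 Mb, not spanning a whole chromosome.
* **LST** — per chromosome arm, segments shorter than 3 Mb are removed
  and identical adjacent states merged, iterated to a fixed point; then
  each adjacent pair with differing allele-specific state and both
  segments at least 10 Mb counts one transition.
* **TAI** — allele-imbalanced segments reaching a telomere, not spanning
  the whole chromosome and not crossing the centromere. "Crossing" means
  spanning the entire centromere interval (the segment reaches the other
  arm); a telomeric segment that merely ends inside the centromere stays
  on its arm. No minimum TAI length is applied by default.

All thresholds are arguments ("Mb" is exactly 1e6 bp; length is
`end − start + 1`). Sex chromosomes are excluded by default. No ploidy
correction of LOH is applied; a future flag may add it. Overlapping
segments are a validation error, since they indicate an upstream
segmentation problem rather than a scoring choice.

## The purity dilution model

The reference experiment dilutes high-purity tumors *in silico*: a tumor
of source purity $q$ is brought to target purity $p \le q$ by combining a
fraction $p/q$ of tumor reads with $1 - p/q$ of matched-normal reads.
This package replaces BAM-level read mixing with its exact variant-level
equivalent, the central modeling abstraction:

* a somatic variant with VAF $v$ at purity $q$ has expected VAF
  $v \cdot p/q$ in the mixture (normal reads carry no somatic allele);
* depth is Poisson around `mean_depth` (negative binomial optional);
  the alt count is Binomial(depth, expected VAF);
* the variant is *detected* when it has at least `min_alt_reads = 3` alt
  reads and observed VAF at least `min_vaf = 0.02`.

The detection defaults were chosen so that, at the default depth of 100×,
detection collapses near 5% purity but is nearly complete at 10% —
mirroring how limited sequencing coverage bounds mutation calling. No
sequencing-error false positives are modeled by default. Because
detection never looks at the mutation type, diluting a catalog is
channel-blind thinning and f_deam is unbiased under dilution (this is
tested, not assumed).

Copy-number attenuation uses the observed major-allele fraction of a
segment with allele copies $(a, b)$ at purity $p$:

$$ m = \frac{p\,a + (1-p)}{p\,(a+b) + 2(1-p)}, $$

plus Gaussian noise with sd `noise_sd_at_unit_depth / sqrt(mean_depth)`
(default 0.5, i.e. 0.05 at 100×). A segment is re-called to its integer
allele state only when $|m - 1/2|$ exceeds the calling threshold
(default 0.08); otherwise it is indistinguishable from balanced diploid
and collapses to (1,1). The threshold sits below the deviation of every
non-diploid state at full purity (the smallest, for (2,1), is 1/6), so
at $p = 1$ with zero noise all states are recovered exactly; as purity
falls, states cross into the diploid band in order of their imbalance —
(2,1)-like states near 30–40% purity, LOH states near 15–20% — which
reproduces the characteristic stepwise degradation of HRDsum at 40%, 20%
and 10% purity while f_deam stays put.

## Biomarker evaluation

ROC curves, AUC and the paired DeLong test are delegated to `pROC` after
orienting each score by its stated direction (f_deam: lower predicts
HRD-positive; HRDsum: higher predicts positive). Two independent oracles
guard this machinery in the test suite: a brute-force pairwise
concordance AUC, and a stratified paired bootstrap for the AUC
difference. Cutpoints are optimized by exhaustive search over the
midpoints of adjacent distinct scores (plus one candidate outside each
extreme), maximizing balanced accuracy; ties are broken toward higher
sensitivity, the convention that favors not missing HRD patients. At a
fixed cutpoint, the f_deam call is strictly-below (`< 13.1`) and the
HRDsum call is at-or-above (`>= 42`), matching the clinical convention
for genomic instability scores; the boundary inclusion is configurable
since published cutpoints rarely state it.

Channel-wise differential analysis normalizes each catalog by its TMB,
compares each of the 96 channels by a two-sided Wilcoxon rank-sum test
(exact when the combined n is at most 50 and untied, normal approximation
with continuity correction otherwise), and applies Benjamini–Hochberg
correction across the 96 tests with significance at FDR 5%. Cohen's
kappa quantifies the agreement of the two binary calls; a constant rater
yields kappa 0 by the marginal-product definition.

`signature_cgtg_fraction()` reports the probability mass a signature
places on the four f_deam channels — the quantity that explains where
f_deam cannot work: signatures of mismatch-repair deficiency and POLE
dysfunction are themselves rich in CpG C>T, confounding the biomarker in
the corresponding tumor types. The package does not redistribute the
COSMIC signature matrix; `read_signature_matrix()` reads the official
file when the user supplies it, and records should note the genome build
of the matrix, as the CG>TG content differs slightly between builds.

## The synthetic cohort generator

The generator produces labeled cohorts with the statistical structure the
analysis assumes, so every stage runs without external data:

* **Spectra.** Each class draws channels multinomially from a profile
  putting a configurable mass on the four CpG C>T channels (uniform
  elsewhere). Defaults: 8% for HR-deficient (flat, SBS3-like) and 25%
  for HR-proficient (CpG-enriched, SBS1-like) — echoing the direction
  and approximate magnitude of the ovarian-cancer contrast without
  claiming to reproduce its exact distributions.
* **TMB.** Log-normal with meanlog log(60) and sdlog 0.5, typical of
  exome-scale ovarian tumors; over 90% of samples exceed the NA floor of
  10 mutations.
* **VAF.** Beta(8, 12), mean 0.4 — clonal heterozygous variants at
  source purity 0.8.
* **Scars.** A target HRDsum is drawn per sample from a truncated normal
  (positives: mean 55, sd 15; negatives: mean 20, sd 12; the clinical
  cutpoint being 42) and split over LOH/LST/TAI by a symmetric
  multinomial; `plant_scar_genome()` then constructs a segment profile
  over a fixed 22-autosome synthetic genome containing *exactly* those
  qualifying events and nothing else. Unit layouts use short buffer
  segments (4–5 Mb: large enough to survive LST smoothing, too small to
  act as LST flanks) so units never interact; the planted counts are the
  generator's ground truth and are verified exactly by the tests. If an
  extreme draw exceeds the genome's capacity the achievable number is
  planted and recorded, which slightly compresses the far upper tail of
  the HRDsum distribution.
* **Causes.** Positives receive a biallelic deleterious BRCA1/2
  alteration (70%) or BRCA1 promoter hypermethylation (30%), so the
  cause-of-HRD classifier and benchmark labeling run end to end.

What the generator does **not** emulate: real per-cancer-type spectra,
subclonality (all variants are clonal at their stated VAF), sequence-level
mutation placement, correlated noise between neighboring segments, and
purity heterogeneity within a cohort. Passing tests therefore demonstrate
the internal consistency and the qualitative purity behavior of the
method, not clinical performance on real tumors.

## Numerical choices and degenerate inputs

* Empty record sets give all-zero catalogs; TMB 0 gives f_deam `NA`.
* All-tied score vectors are reported as degenerate cutpoints with
  balanced accuracy 0.5.
* Identical score vectors short-circuit the DeLong test to p = 1 (the
  covariance matrix is singular there).
* Balanced (1,1) segments have observed fraction exactly 1/2 at any
  purity, hence never generate spurious scar signal.
* Seeds control every stochastic step; identical configuration and seed
  reproduce cohorts, dilutions and reports bitwise.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 20 + 20
(purity experiments, matching the reference design of the dilution
study) and 100 + 100 samples (evaluation statistics), TMB around 60,
500 replicates for error-law checks, 200 replicate dilutions for
thinning invariance, and 20 replicate cohorts for the purity-degradation
contrast — sizes at which every quantity of interest is stable to well
under its test tolerance.

## Limitations

The HR gene list is a placeholder; the purity model abstracts read
mixing at the variant level and cannot reproduce coverage-driven
artifacts of real BAM subsampling; no ploidy correction is applied to
LOH; TAI has no minimum-length filter; and the COSMIC signature
composition analysis requires the user-supplied official matrix.
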