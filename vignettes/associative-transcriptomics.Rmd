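---
title: "Methods: Associative Transcriptomics for allopolyploid panels"
author: "polyAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Associative Transcriptomics for allopolyploid panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

polyAT implements an Associative Transcriptomics (AT) workflow for
allopolyploid crops: transcriptome SNP markers and transcript abundance
(gene expression markers, GEMs) are scored across an inbred diversity panel
and both are tested for association with trait variation. This vignette is
the package's account of the statistical machinery, the choices behind it,
and what the bundled simulator does and does not establish.

## 1. Polyploid SNP calling

Input is a per-accession pileup summary: for every CDS-model position, the
count of quality-passing reads and the per-base counts (base-quality
filtering is assumed to have happened upstream in the aligner's
meta-analysis; the package does not model per-base qualities).

Per accession and site, `call_base()` applies the platform rules:

* depth must be *in excess of* 10 reads (`depth >= 11`; the
  `min_depth_exclusive` parameter is exclusive by construction);
* a base contributes to the call only if its within-accession frequency is
  at least the noise threshold `noise_freq = 0.2`;
* exactly one contributing base gives a resolved call; exactly two give the
  two-base IUPAC code — the *hemi-SNP* allele state created when reads
  cross-map from a homoeologue fixed for another base; three or more give a
  missing call. Two-base codes are the declared alphabet: a three-base
  mixture is not representable and, in inbred material, is read as noise
  rather than as a top-two call.

Sites are then kept when the missing fraction is strictly below 0.25, the
number of distinct non-missing call states is at most 3, and the site is
polymorphic. Call states are alleles in their own right here — the panel is
doubled-haploid/inbred, so `A` and `R` at one site are two fixed alleles of
the marker, and both count toward the three-allele limit. The minor allele
frequency is the frequency of the second most frequent state; association
and LD apply a strict MAF > 0.01 floor, while the marker set itself retains
all polymorphic sites.

Simple SNPs (resolved bases only) are assigned with confidence to the
genome of their host CDS model. A hemi-SNP's polymorphism may sit in either
homoeologue, so it is genome-assigned only when direct linkage-map evidence
(a set of site ids from a mapping population) places it; otherwise it is
rendered pale downstream and drawn at both homoeologous positions
("shadows").

## 2. Expression quantification

RPKM is `count / ((length/1000) * (total_mapped/1e6))`, with the
whole-reference mapped-read total as denominator. GEM analysis keeps models
whose panel mean RPKM (zeros included, no trimming — the simplest reading
of a panel mean) is strictly above 0.4.

## 3. Structure, kinship, LD

Call states are encoded per marker as alternate-allele dosages: most
frequent state 0, alternate 1, and, for three-state markers of the form
{A, G, R}, 0.5 for the IUPAC union code (it is the heterozygous-looking
mixture of the two resolved alleles). A three-state marker whose third
state is *not* the union of the other two has no position on a single
alternate-allele axis and is masked at that state.

* **Distances/dendrogram**: JC69, `d = -(3/4) log(1 - (4/3) p)` with `p`
  the mismatch proportion over shared non-missing call states; saturated
  pairs (`p >= 0.75`) are flagged `Inf`. Trees are average-linkage (UPGMA)
  by default — the reference platform names no linkage — with
  neighbor-joining selectable.
* **Q matrix**: a light PCA-to-simplex estimator stands in for a full
  admixture likelihood tool. Dosages are mean-imputed (preserves allele
  frequency) and column-centered; the top `k-1` principal coordinates are
  taken; `k` archetypal accessions are the most extreme member of each
  k-means cluster; every accession is projected onto the simplex spanned by
  the archetypes by constrained least squares (active-set enumeration —
  exact for the small `k` of interest). `k = "auto"` uses the largest
  eigengap among the first 10 eigenvalues; this is a surrogate for the
  reference tool's likelihood-based choice and is not expected to match it
  in hard cases. A weak eigengap (adjacent eigenvalue ratio below 1.3)
  triggers a no-structure warning.
* **Kinship**: `K = GGᵀ/m` on standardized, mean-imputed dosages, rescaled
  to unit mean diagonal; symmetric PSD by construction.
* **LD**: markers restricted to genome-assigned sites with MAF > 0.01, one
  site drawn at random (seeded, default 1) per CDS model because sites
  within a model are tightly linked; pairwise r² is the squared Pearson
  correlation of dosages, pairwise-complete. In inbred material composite
  dosage correlation equals haplotype r², so no haplotype EM is needed.
  Only within-chromosome pairs enter the per-chromosome and genome means.

## 4. Association

`fit_null_mlm()` fits `y = Xβ + g + e`, `g ~ N(0, σ²_g K)`,
`e ~ N(0, σ²_e I)` by REML. `X` is the intercept plus `k-1` admixture
columns (one dropped: Q rows sum to 1). K is eigendecomposed once and the
restricted likelihood profiled over `δ = σ²_e/σ²_g` on a log10 grid over
[1e-5, 1e5] (step 0.1) refined by golden-section search; a boundary optimum
warns. The pseudo-heritability is `h² = σ²_g/(σ²_g+σ²_e) = 1/(1+δ)`.

`snp_association()` reuses those components for every marker (P3D/EMMAX):
in the rotated, whitened basis each marker's effect is a weighted
least-squares slope after residualizing on X, with a Wald t-test on
`n - rank(X) - 1` degrees of freedom (no finite-sample Satterthwaite).
With `K = NULL` and no Q this reduces *exactly* to per-marker OLS, which
the test suite asserts to 1e-8. Markers with missing calls are tested on
their observed subset against the null covariance restricted to those
accessions (Cholesky factors cached per missingness pattern). Exact
per-marker REML is available behind `per_marker_reml = TRUE` and agrees
with P3D on complete data to within the grid tolerance; it exists for
checking, not routine use. P-values are handled on the log scale
throughout, so `-log10 P` is exact far beyond double underflow.

`gem_association()` is a fixed-effect OLS of trait on RPKM plus Q per
model, vectorized by Frisch–Waugh residualization. The reported intercept
is `mean(y) - slope * mean(RPKM)` — the marginal prediction line used by
take-one-out — rather than the raw regression constant, which would need
the covariates of a new accession to predict. Genomic control is applied to
GEM scans by default (`λ = median(χ²)/qchisq(0.5, 1)`; adjustment only when
`λ > 1`, so deflated scans are untouched); for SNP scans it is off by
default and available behind a flag, matching the toolchain convention of
correcting the regression-based scan only.

Bonferroni lines use the number of markers actually tested after filtering;
the 5% FDR line is the largest Benjamini–Hochberg-passing p-value, `Inf`
when none passes.

## 5. Take-one-out validation

Each phenotyped accession is dropped in turn; the association scan is rerun
on the remainder; markers above that round's Bonferroni line are selected;
the left-out trait is predicted as the unweighted mean over selected
markers of (SNPs) the allelic-effect value for the left-out call state,
with the training mean as fallback for unseen/missing states, or (GEMs)
`intercept + slope × RPKM`. The unweighted mean is deliberately simple:
peak markers are strongly collinear and a multiple-regression combiner adds
variance without adding information at these panel sizes.

Predictive power is the R² (with intercept) of predicted against observed
values over rounds in which at least one marker was selected. Rounds with
no selected marker predict the training mean and are flagged but excluded
from the R² regression: the per-round training mean is `(S − y_i)/(n−1)`,
mechanically anti-correlated with the held-out value, and including such
rounds would manufacture R² ≈ 1 on pure-noise traits.

Kinship and the Q matrix are genotype-only panel covariates: they are
estimated once and subset per round. The leave-one-out guarantee — enforced
by a poisoning test — is that the left-out accession's *trait* value never
influences fitting or selection; its genotype/expression necessarily enters
its own prediction. The default is full reselection per round; `fast` mode
fixes the selection from the full-panel scan (a mild selection leak, kept
for interactive use and shown on simulations to agree with full mode within
R² ± 0.05).

## 6. The synthetic panel

`simulate_panel()` generates the study conditions end to end; all defaults
are fixed once:

| parameter | default | why |
|---|---|---|
| `n_accessions` | 383 | the reference panel size |
| `models_per_genome`, `sites_per_model` | 190, 4 | ~1 500 candidate sites: enough markers for structure, kinship and scans while keeping a full pipeline run in seconds |
| `k`, `fst` | 2, 0.1 | two admixed subpopulations at moderate differentiation, the structure reported for such panels |
| `admix_shape` | 0.25 | U-shaped admixture: mostly near-pure accessions with a mixed minority |
| `linkage_within` | 0.85 | sites within a CDS model share a latent genealogy — transcriptome SNPs in one gene are tightly linked, the very reason LD analysis samples one SNP per model |
| `depth_mean`, `error_rate` | 50 reads, 0.005 | typical mRNA-seq coverage after quality filtering |
| `cross_mapping_rate` | 0.3 | homoeologous read contamination well above the 0.2 noise threshold, so hemi-alleles call as codes |
| `homoeo_div` | 0.5 | probability the homoeologous site is fixed for another base at a candidate SNP position |
| `discriminating_frac` | 0.2 | fraction of models whose reads map uniquely; their polymorphisms surface as simple SNPs (the platform's minority), the rest mostly as hemi-SNPs |
| `h2` | 0.794 | the erucic-acid-like heritability of the default architecture |
| `major_fracs` | 0.30, 0.20 on A8, C3 | two major seed-oil-style loci |
| `expression_frac`, slope sign | 0.15, negative | one expression-mediated gene on C2: low expression raises the trait |
| `n_polygenic` | 150 | small-effect background bringing the genetic fraction up to `h2` |
| `linkage_frac` | 0.3 | fraction of sites with direct linkage-map evidence |

Mechanisms worth spelling out:

* **Genotypes** are Balding–Nichols: ancestral frequencies Uniform(0.05,
  0.95), Beta-drifted per subpopulation at the given Fst, one allele drawn
  per accession from its admixture-weighted frequency (inbred: homozygous).
* **Hemi-SNPs** arise mechanically: Poisson depth, a binomial
  `cross_mapping_rate` fraction of reads carrying the homoeologue's base,
  uniform sequencing errors. With rate 0 the called marker set contains no
  ambiguity codes beyond the error floor; raising the rate raises the
  hemi-SNP fraction monotonically (saturating once every retained site is
  hemi). A side effect of binomial sampling at depth ~50 straddling the
  0.2 threshold is that common polymorphic sites in cross-mapped models
  often accumulate four call states and are removed by the allele-count
  filter — which is why the simulated causal loci are placed in
  discriminating models, mirroring the fact that the platform's causal
  peaks consist of genome-assignable markers.
* **The expression-variant gene**: its regulatory allele is the genotype at
  a scored site of a *neighbouring* C2 model. The causal gene itself
  carries no associated SNP (its association is purely through expression),
  but the variant is in LD with the flanking marker peak — the
  configuration in which an expression-mediated gene is discoverable at
  all, and without which no kinship-based REML could attribute that
  variance to genetics. Background expression is log-normal; 10% of models
  are near-silent (exercising the 0.4 RPKM floor); 30% have mild
  subpopulation-structured baselines (differential expression between crop
  types), which is what genomic control corrects in confounded GEM scans.
* **The trait** is `Σ effect × dosage + slope × causal RPKM` plus Gaussian
  noise variance-matched on the realized genetic values, so realized h²
  equals the target to within sampling error of the noise draw.

What the simulator does **not** emulate: read-level data and alignment,
base-quality variation, homoeologous exchange/CNV and presence–absence
variation, between-model LD along a chromosome (so simulated LD decays to
the null `1/(n-1)` level immediately outside a model, and the genome mean
r² is far below a real panel's), selection/bottleneck history, and
multi-tissue expression. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the stated statistical
structure, not performance on real mRNA-seq.

## 7. Numerical and design choices

* Strict inequalities throughout where the rules say "in excess of",
  "below", "> 0.01", "> 0.4": depth ≥ 11, missingness < 0.25, MAF > 0.01,
  mean RPKM > 0.4.
* Positions are 1-based within CDS models; the Manhattan x-axis is gene
  order (chromosome, order index), not base pairs.
* Missing call sentinel `N`; missing trait = empty CSV field; fixed
  4-decimal floats, scientific notation for p-values, so write→read→write
  is byte-stable.
* Ties in state frequencies (reference-state choice, MAF) resolve
  alphabetically via the deterministic table ordering.
* Degenerate inputs error early: constant traits, non-PSD K, monomorphic
  sites, all-missing columns, empty p-vectors.
* All randomness (k-means restarts, LD site sampling, every simulator
  stage) is seeded locally and restores the caller's RNG state; stage seeds
  are derived from the master seed by fixed offsets.
* Problem sizes in the test-suite and acceptance script — full 383-accession
  panels with ~1 500 candidate sites, 20 recovery seeds, ≥ 10 000 null
  marker tests, one full-mode take-one-out run — were chosen so the whole
  suite completes in minutes on a single CPU while keeping every check at
  the panel scale the defaults describe.

## 8. Known limitations

* The Q estimator is a PCA surrogate, not a likelihood admixture model;
  its `k = "auto"` eigengap can disagree with likelihood-based selection.
* P3D fixes variance components across markers; for markers of very large
  effect the exact per-marker REML test (provided behind a flag) is the
  reference.
* GRM-based h² of architectures dominated by a couple of major loci is
  estimated with substantial seed-to-seed spread at n = 383 and ~1 100
  markers; the acceptance check therefore evaluates the mean across seeds.
* The take-one-out R² depends on the combiner; the unweighted mean shrinks
  multi-marker predictions below the total variance the selected markers
  tag.
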