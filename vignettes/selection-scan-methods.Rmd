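---
title: "Methods: the three-statistic selection scan and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the three-statistic selection scan and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements,
the choices made where several defensible options existed, and what the
bundled synthetic-data generator does and does not establish about real
data.

## The analysis model

The package targets SNP-array genotypes: diploid, biallelic, with sample
sizes of tens per population and marker densities of roughly one SNP per
few kilobases.  Three families of statistics are computed.

**Windowed F_ST.**  For one comparison of two groups, the per-SNP estimator
is

\[ F_{ST} = 1 - \frac{p_1 q_1 + p_2 q_2}{2 \bar p \bar q}, \qquad
   \bar p = \tfrac{1}{2}(p_1 + p_2), \]

the loss of heterozygosity relative to the pooled frequency.  SNPs
monomorphic across both groups are excluded (the estimator is 0/0 there),
never recorded as zero.  Window means over a 200-kb grid stepping by 60 kb
are standardized to Z-scores (ZF_ST) with the *population* (divide-by-N)
standard deviation over all emitted windows of the comparison; a window is
called significant at ZF_ST ≥ 4.  Group frequencies pool the samples of a
group's member populations (allele-count weighted); pooling, rather than
averaging per-population frequencies, is the default because the group is
the unit of contrast.

**FLK.**  The kinship-corrected Lewontin–Krakauer statistic.  With a
population-frequency vector \(p\) at one SNP and a shared-drift kinship
matrix \(K\), the ancestral frequency is the generalized-least-squares
estimate \(p_0 = (1' K^{-1} p)/(1' K^{-1} 1)\) (one pass; the drift scale
\(p_0(1-p_0)\) cancels from the weights) and the statistic is

\[ T = (p - p_0 1)' \, [K\, p_0 (1 - p_0)]^{-1} \, (p - p_0 1), \]

approximately \(\chi^2_{k-1}\) for \(k\) populations under neutral drift.
SNPs whose estimated \(p_0\) is 0 or 1 carry no information and are
excluded.  \(K\) comes from Reynolds distances via a neighbour-joining
tree, rooted on an outgroup when one is available and at the midpoint
otherwise; \(K_{ij}\) is the branch length shared by the root-to-\(i\) and
root-to-\(j\) paths.  Negative NJ branch lengths (a numerical artefact of
NJ on noisy distances) are clamped to zero to keep \(K\) positive
semidefinite; the clamp count is reported.

This arm deliberately replaces the haplotype-cluster version of the test
with the single-SNP FLK plus the same window averaging, Z-standardization
and empirical chi-square scaling applied to window means.  The
cluster-based variant adds a fastPHASE-style hidden-Markov LD model whose
EM fits are a configuration of an external package rather than a statistic
with a closed definition; the kinship-aware differentiation test that both
share is what FLK contributes, and the arm is labelled `flk` in all
outputs so it cannot be mistaken for the cluster version.  Window p-values
come from a scaled chi-square fitted to the empirical window distribution
by moment matching (scale \(s = v/2m\), df \(k = 2m^2/v\) from the mean
\(m\) and variance \(v\) of window means): window means of correlated
per-SNP chi-squares are well approximated by a gamma family, and the
empirical fit absorbs the unknown effective number of independent SNPs per
window.  Significance is −log₁₀ p ≥ 3.

**Rsb.**  The cross-population ratio of integrated site-EHH.  Site-EHH at
distance \(d\) from a focal SNP is the probability that two haplotypes
drawn without replacement are identical over every SNP from the focal out
to \(d\) (the focal allele included; the curve starts at 1 at the focal by
convention).  The curve is truncated at the first point below
`ehh_cutoff`, at an inter-SNP gap above `ehh_max_gap`, or at the
chromosome end; iES is its trapezoidal integral over physical position,
both sides summed (units bp).  Per SNP,
\(\mathrm{Rsb} = \ln(\mathrm{iES}_1/\mathrm{iES}_2)\), median-centred
(robust to the long right tail a sweep itself creates) and scaled by the
population SD, then transformed to
\(P_{Rsb} = -\log_{10}[1 - 2(\Phi(|\mathrm{Rsb}|) - 0.5)]\) — the
two-sided normal significance; 3.29 maps to 3.0.  SNPs are called at
P_Rsb ≥ 3; a window inherits the maximum P_Rsb of its SNPs, a documented
choice where a per-window definition is not standard.  EHH is
allele-agnostic (site homozygosity, not core-allele EHH): that is what the
iES construction integrates, and it requires no ancestral-allele calls.

**f3/f4.**  \(f_3(A;B,C)\) is the mean over SNPs of
\((p_A-p_B)(p_A-p_C)\), with the finite-sample bias
\(p_A(1-p_A)/(c_A-1)\) (allele count \(c_A\)) subtracted by default —
without it a drifted-but-unadmixed target is biased positive; the
correction is a flag so the infinite-sample identity tests can switch it
off.  \(f_4(A,B;C,D)\) is the mean of \((p_A-p_B)(p_C-p_D)\).  Standard
errors are delete-one block jackknives over consecutive blocks of 500 SNPs
in genome order — physical blocks longer than the LD scale make the
deleted blocks effectively independent.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` / `window_step` | 200,000 / 60,000 | bp | window geometry matched to array densities where ~25 SNPs fall in a window; the 60-kb step trades resolution against multiplicity |
| `zfst_min` | 4 | Z | upper-tail cutoff on the genome-wide window distribution |
| `flk_logp_min`, `prsb_min` | 3 | −log₁₀ p | two-sided p = 0.001 |
| `maf_max_excl` | 0.01 | frequency | variants with MAF ≤ 1% removed (boundary removes: the filter keeps only MAF strictly above the threshold) |
| `sample_miss`, `variant_miss` | 0.10, 0.05 | rate | remove-at-or-above thresholds |
| `ehh_cutoff` | 0.05 | EHH | truncates the integral once haplotype identity is effectively lost; unstated in common practice between 0.05 and 0.10 |
| `ehh_max_gap` | 200,000 | bp | guards the integral against assay gaps |
| LD pruning | 50 SNPs / 5 / r² 0.5 | — | conventional PLINK-style configuration; recorded in the QC provenance, not treated as canonical |
| `block_snps` | 500 | SNPs | jackknife block length |
| `min_consensus_methods` | 2 | — | consensus requires two of the three arms |
| `min_snps` | 2 | SNPs/window | single-SNP windows are too noisy to report |

QC filters run in a fixed order — non-autosomal variants, then sample
missingness, then variant missingness, then MAF (on retained samples) —
mirroring the common tool default; the order is not universal, so the
report records per-stage removals to make any discrepancy with another
tool's joint behaviour diagnosable.  `apply_qc` is idempotent.

## Numerical and edge-case choices

* Standardization uses the divide-by-N SD everywhere (`standardize()`),
  and errors on zero variance rather than emitting NaNs; the FLK
  chi-square fit likewise refuses a zero-variance window distribution.
* A constant ln iES ratio (e.g. the two groups are the same data) is
  reported as all-zero Rsb scores rather than an error: there is no
  signal, not a failure.
* PCA mean-imputes missing calls per SNP before centring and scaling by
  \(\sqrt{p(1-p)}\); component signs are fixed by making each component's
  largest-magnitude score positive.  PCA here is descriptive plumbing, so
  the simplest missing-data convention wins.
* LD pruning removes the lower-MAF SNP of an offending pair (ties remove
  the later position), making the output order-deterministic.
* Merging two arrays drops strand-ambiguous A/T and C/G SNPs: strand
  cannot be verified from genotype data alone, and silently flipped sites
  corrupt every downstream frequency.  Counts of dropped sites are
  reported.
* Internal coordinates are 1-based inclusive throughout; BED conversion
  happens only at I/O boundaries.
* Haplotype statistics refuse missing data; phased input must be complete.
* Inbreeding F uses the allele-count-corrected expected homozygosity
  inside the per-individual estimator (the method-of-moments form) and is
  undefined for populations of one.

## The synthetic-data generator

`sim_config()` defines the reference scenario: four populations (labelled
E1, E2, E3, S after the fat-rump, western and southern long-fat-tail, and
thin-tail groups the scan design contrasts), Balding–Nichols drift
F = 0.05 each, 20 diploid samples per population, 20,000 evenly spaced
SNPs on one 50-Mb chromosome, and a hard sweep in E1 at 25 Mb with a
300-kb half-width and `founder_fraction = 0.05`; seed 20190109.

Frequencies are simulated directly (ancestral Uniform(0.05, 0.95), per
population Beta\((p(1-F)/F, (1-p)(1-F)/F)\)); an admixed target's
frequencies are the \(\theta\)-mixture of its sources'.  Haplotypes are
Li–Stephens-style mosaics of a 20-founder pool with per-bp switch rate
1e-5 (mean copied tract ~100 kb at the default SNP spacing), which gives
the geometric LD decay the Rsb arm needs.  A frequency-level simulator was
chosen over a coalescent one deliberately: it is orders of magnitude
faster, its drift parameters map one-to-one onto the quantities the
FST/FLK/f-statistic calibrations measure, and the copying layer supplies
LD where it matters.

The sweep is a recombination-escape tract model: each haplotype of the
swept population is swept with probability `1 − founder_fraction`; a swept
haplotype carries the founder-1 tract from the sweep centre outward to a
per-side escape distance drawn uniformly between half and the full
half-width.  Coverage is therefore complete over the inner half of the
interval and tapers linearly beyond it, so expected differentiation and
haplotype homozygosity peak at the centre — as in a real sweep, where
recombination during fixation erodes the swept haplotype with distance
from the selected site.  A spatially uniform overwrite of the whole
interval was rejected: it makes every fully interior window statistically
interchangeable, so no method could localize the centre better than the
interval width, which defeats the centre-recovery property the scan is
meant to have.

**What passing tests show, and what they do not.**  The generator has
independent drift across populations (a star phylogeny), evenly spaced
markers, no genotyping error, no missingness, perfect phasing, and a
single clean hard sweep.  Null calibrations and sweep-recovery rates on it
validate the statistical machinery — the estimators, the standardizations,
the chi-square scaling, the interval algebra — under the model's
assumptions.  They do not certify behaviour under ascertainment bias,
hierarchical population structure (where diagonal-drift FLK is
conservative or anticonservative depending on topology), soft or partial
sweeps, phasing error, or real LD landscapes.

## Calibration problem sizes

The packaged checks use: 100 seeds of a 2,000-window genome (≈48k SNPs,
four populations) for the FST and FLK null rates; 100 seeds of 2,000
phased SNPs in two populations for the per-SNP Rsb null rate; 100 seeded
runs of the full default sweep scenario for recovery rates; and 100
replicates of 5,000-SNP frequency datasets for the f4 null and the
jackknife-SE/replicate-SD comparison.  These sizes give binomial standard
errors comfortably below the margins being asserted while keeping the
whole suite to a few minutes.

## Known limitations

* The FLK arm is single-SNP-based; haplotype-cluster information is not
  used (see above).
* Rsb's window statistic (max P_Rsb) is a design choice; users wanting
  SNP-level calls should read the per-SNP table.
* The consensus region bound is the union of contributing method
  intervals, which is wide by construction; the covered-by-≥2 cores are
  recoverable by intersecting the per-method interval sets.
* `kinship_from_tree` assumes drift is tree-like; admixed populations
  violate this and inflate FLK at their SNPs.
* No genotype imputation, liftover, phasing or genotype calling; phased
  complete input is a precondition of the haplotype arm.
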