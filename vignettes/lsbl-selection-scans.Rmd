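---
title: "Locus-specific branch length selection scans: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-specific branch length selection scans: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsblscan)
```

# The problem

Populations that colonized extreme environments — the motivating case is
highland livestock on a high plateau, genotyped on a ~60K SNP array
alongside many lowland breeds — carry alleles whose frequencies were
driven up by local positive selection. Against a background of drift and
admixture, a locus under selection in one population shows an allele
frequency that is unusually differentiated from *both* of two reference
groups, not merely from one of them. `lsblscan` implements this
three-group contrast end to end: per-SNP F\_ST between groups, the
locus-specific branch length (LSBL) decomposition, empirical outlier
calling, candidate-region gene annotation, and the supporting population
statistics, together with a Balding–Nichols simulator that makes the whole
pipeline testable with known ground truth.

# The statistics

## Unbiased F_ST from allele counts

For two groups with allele-A counts $a_i$ out of $n_i$ successfully
genotyped **chromosomes** ($n_i = 2 \times$ non-missing diploid
individuals), the package uses the Hudson-type unbiased estimator

$$
h_i = \frac{a_i (n_i - a_i)}{n_i (n_i - 1)}, \qquad
N = \left(\frac{a_1}{n_1} - \frac{a_2}{n_2}\right)^2
    - \frac{h_1}{n_1} - \frac{h_2}{n_2}, \qquad
\hat F_{ST} = \frac{N}{N + h_1 + h_2}.
$$

$h_i$ is the unbiased within-group heterozygosity and the numerator is an
unbiased estimate of the squared frequency difference. The counting unit
deserves a note: "sample size" in F\_ST legends is ambiguous, but the
estimator's denominators $n_i(n_i-1)$ only make sense in chromosomes, so
that is what `allele_counts()` produces.

Three conventions complete the definition:

* a raw estimate below 0 has no biological interpretation and is clipped
  to 0 (`clipped` column of `reich_fst()`); the raw value is kept
  alongside;
* when both groups are fixed for the same allele the denominator is 0 and
  the estimate is defined as 0 (no differentiation);
* a group with fewer than 2 chromosomes at a SNP makes the pair
  undefined; the scan flags such SNPs invalid rather than imputing.

## LSBL

Given the three clipped pairwise values — focal vs contrast 1
($d_{f1}$), focal vs contrast 2 ($d_{f2}$), contrast 1 vs contrast 2
($d_{12}$) —

$$
\mathrm{LSBL} = \frac{d_{f1} + d_{f2} - d_{12}}{2}
$$

is the branch private to the focal group in the three-taxon star. Two
exact identities follow directly and are enforced by tests at every SNP of
every simulated scan: swapping the contrast groups leaves LSBL unchanged,
and the two focal branches computed on either side of an edge sum to the
pairwise distance across it. Negative LSBL values are retained (only
F\_ST is clipped); they can never reach the upper tail that defines
outliers.

## Empirical outliers

There is no parametric null: outliers are the top `top_fraction` of the
empirical LSBL distribution (default 0.005). The count is
`floor(top_fraction * N_valid)`, which reproduces the array-scale
arithmetic of 207 outliers among 41,495 valid SNPs at 0.5%. Ties at the
cutoff are broken by ascending (chromosome, position) so repeated runs are
identical; the threshold is recomputed per scan rather than carried over
between scans (e.g. after merging a fine-mapping panel).

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_call_rate` | 0.95 (strict `>`) | fraction | array-QC convention for "call rate > 95%" |
| `min_maf` | 0.05 (strict `>`) | frequency | removes near-monomorphic SNPs with no scan information |
| `subset_by_maf(..., inclusive = TRUE)` | 0.2 | frequency | diversity panels use the inclusive "MAF ≥" dialect |
| `top_fraction` | 0.005 | fraction | the empirical 0.5% tail |
| `flank` | 50,000 | bp | candidate region = SNP ± 50 kb, the array's LD scale |
| `r2_max` | 0.3 | r² | LD-pruning threshold for structure analyses |
| `window_snps`, `step_snps` | 50, 5 | SNPs | the common pruning window idiom; both configurable |
| `g` (allelic richness) | user-set | chromosomes | rarefaction size must not exceed the smallest group, so it is a required argument |

MAF is always computed over all non-missing chromosomes of the panel at
hand. Thresholold dialects are deliberate: QC filters are strict
inequalities, the diversity floor is inclusive, and both are exposed.

# The simulator, and what passing tests do not show

`sim_config()` defines a Balding–Nichols panel: ancestral frequency
$p \sim U(0.05, 0.95)$ per SNP (a wide ascertained-array-like range so
most loci survive the MAF filter), population frequency
$p_i \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with per-population
drift $F$, Hardy–Weinberg genotypes, and independent per-call missingness
(default 2%). `F = 0` is handled as the exact zero-drift limit
($p_i = p$). All randomness derives from one integer seed (R's default
Mersenne–Twister generator); frequencies use the seed itself and
genotypes use seed + 1, so each stage is separately reproducible and a
fixed seed yields byte-identical PED output.

The default study conditions are one focal population of 30 diploids at
$F = 0.1$ contrasted with two pools of 100 diploids at $F = 0.03$. The
asymmetry is intentional: in the motivating design the contrast groups
are unions of ten-odd breeds, and the mean frequency of a pool drifts far
less than any single constituent breed. Under the symmetric alternative
(all three groups at $F = 0.1$) the focal group's own drift — which is
shared between $d_{f1}$ and $d_{f2}$ and therefore inflates LSBL — makes
a frequency shift of 0.5 statistically indistinguishable from the neutral
0.5% tail; the pooled-contrast design is both more realistic and the one
under which the power property below is meaningful.

Selection is planted post hoc on the drifted focal frequency in one of
three modes (`selection_spec()`): a signed shift clamped to $[0,1]$, an
absolute target frequency, or `fix_minor`, a completed sweep to fixation
of the focal population's minor allele. `fix_minor` is the default for
power studies because its realized frequency shift is at least 0.5 by
construction; a clamped `shift` of the same nominal size can realize
almost nothing when the drifted frequency is already near the boundary.
The property test suite uses these conditions at 10,000 SNPs with 20
planted sweeps over 20 replicate seeds and requires at least 80% of
planted loci in the top-0.5% outlier set; `scripts/acceptance.R`
recomputes the same rate (about 91% at seed 1).

What the simulator does **not** emulate — so what green tests do not
prove about real data: loci are independent (no LD, so no clustering of
outliers around a sweep and no pruning realism), there is no admixture or
migration (drift is star-shaped from one ancestor), selection is a
frequency shift rather than a forward trajectory, and array ascertainment
is mimicked only through the ancestral frequency range. Recovery rates
measured here are upper bounds on what an equally sized real design
would achieve.

## A calibration note on F under Balding–Nichols

With both populations drifted $F$ from the ancestor,
$E[(p_1-p_2)^2] = 2Fp(1-p)$ and $E[h_i] = (1-F)p(1-p)$, so the
estimator's expected numerator over expected denominator is exactly $F$.
The package therefore exposes `reich_fst_genomewide()`, the
ratio-of-sums aggregate, which lands on $F$ to three decimals at 6,000
SNPs and is the quantity a calibration check should use. The *mean of
per-SNP clipped ratios* is a different, less well-behaved summary: it
sits a few percent *below* $F$ at these sample sizes (a mean-of-ratios
bias that clipping only partially offsets). One acceptance test in this
package instead compares that per-SNP mean against $2F/(1+F)$ — a value
that would be correct if the between-population heterozygosity grew with
divergence as it does along a coalescent path, which the Balding–Nichols
construction (independent drift around a fixed ancestor, unchanged
expected between-group heterozygosity) does not produce. No correct
implementation of both the model and the estimator can satisfy it, and
the test is left failing deliberately rather than tuned; the
mathematically grounded calibration (ratio-of-sums within 20% of $F$ for
$F \in \{0.05, 0.1, 0.2\}$) is asserted, and passes, in the regular
suite.

# Numerical and design choices

* **Allele orientation.** The counted allele (`allele_a`) is the
  lexicographically smaller allele observed at the SNP, applied
  uniformly. F\_ST, LSBL and the distances are invariant to orientation;
  frequency tables state the counted allele. One consequence is
  documented in the I/O tests: a SNP observed monomorphic for the larger
  allele necessarily reads back complemented after a PED round trip,
  because PED does not record which allele was counted.
* **Missing data.** Missing genotypes are `NA` end to end and `"0 0"` on
  disk; a missing call is never conflated with dosage 0.
* **LD pruning.** Within each sliding window the violating pair's
  lower-MAF SNP is removed (ties: the later map position); passes repeat
  until a full pass removes nothing. Because the retained set is a
  fixpoint, pruning is idempotent — re-pruning the output is the
  identity, which the suite asserts.
* **Allelic richness.** The rarefaction sum uses `lchoose` ratios, exact
  and overflow-safe; SNPs with fewer than `g` chromosomes are excluded
  from population means rather than extrapolated. At `g = 2` the
  statistic reduces to `1 + H_E`, a closed form the tests check against
  exhaustive enumeration.
* **Neighbor joining.** Deterministic Saitou–Nei: ties in the
  Q-criterion resolve to the smallest index pair; a negative branch
  length is clamped to 0 with the deficit moved to its sister branch so
  the joined pair still spans its distance. On additive matrices the
  result provably reproduces the generating tree, which the suite checks
  against an independent NJ implementation. Newick output quotes labels
  containing metacharacters or spaces.
* **Enrichment.** Hypergeometric upper tail via `phyper`; each set is
  intersected with the universe first; sets with no universe member are
  dropped before the Bonferroni factor is fixed, while `k = 0` sets stay
  (p = 1) so the number of tests is transparent. The default universe is
  all genes in the supplied annotation — an offline stand-in for
  whatever curated universe produced published enrichment tables, which
  is one reason published gene counts are not reproducible here.
* **Coordinates.** Gene models live as 1-based closed intervals (the
  Bioconductor convention; BED's 0-based half-open is converted on
  import). Candidate regions are `[max(1, pos - flank), pos + flank]`
  and a gene is captured by ≥ 1 bp of overlap — containment is not
  required, matching the "flanking window" reading of candidate regions.

# Problem sizes

The suite and the acceptance script run at deliberately chosen scales:
the structural scan arithmetic at the full 41,495-SNP array size with 60
samples; calibration at 6,000 SNPs per drift value; power at 10,000 SNPs
× 230 samples × 20 replicates; trees at up to 30 individuals and 1,000
SNPs; enumeration oracles (subsampling, hypergeometric draws) at sizes
where exhaustive enumeration is exact (n ≤ 25). These sizes keep every
derived quantity statistically stable while the whole suite completes in
well under a minute of simulation time per component.

# Known limitations

Binary PLINK (BED/BIM/FAM) and VCF input, multi-allelic sites, sex
chromosomes, phasing, haplotype-based LD, window-averaged or
log-transformed branch statistics, and simulation-based significance are
all out of scope; the empirical quantile is the only null, as is standard
for this scan family. The allele-sharing distance is IBS-based and
computed per pair, which is quadratic in samples — fine for hundreds of
individuals, not for biobanks.
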