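# lsblscan

Selection scans for structured populations from biallelic SNP array
genotypes. `lsblscan` is aimed at population geneticists asking which
loci drove local adaptation in one population — say, a highland livestock
population — relative to two reference groups, using the
locus-specific branch length (LSBL) statistic on top of unbiased per-SNP
F<sub>ST</sub>.

## The statistic

For each SNP, allele counts (*a*, *n*) per group (in chromosomes) feed
the Hudson-type unbiased F<sub>ST</sub> estimator

```
h_i = a_i (n_i − a_i) / (n_i (n_i − 1))
N   = (a_1/n_1 − a_2/n_2)² − h_1/n_1 − h_2/n_2
F_ST = N / (N + h_1 + h_2)        (negative values clipped to 0)
```

and the three pairwise values of a focal / contrast-1 / contrast-2 design
are decomposed into the branch private to the focal group:

```
LSBL = (d_f1 + d_f2 − d_12) / 2
```

SNPs in the top fraction (default 0.5%) of the empirical LSBL
distribution are outliers; the ±50 kb windows around them nominate
candidate genes, which can be tested for gene-set enrichment
(hypergeometric, Bonferroni-corrected).

Around this core the package provides PED/MAP I/O with call-rate/MAF QC
filters and panel merging, per-population diversity statistics
(H<sub>E</sub>, proportion of polymorphic markers, rarefaction allelic
richness), LD r² pruning, allele-sharing distances with
neighbor-joining trees (Newick output), and a Balding–Nichols genotype
simulator with planted selected loci so the whole pipeline can be
validated against known truth.

## Worked example

Simulate a panel with 10 planted sweeps in the focal population, filter,
scan, and compare calls against the truth table:

```r
library(lsblscan)

cfg <- sim_config(n_snps = 5000,
                  selected = selection_spec("Highland", 10, "fix_minor"),
                  seed = 42)
panel <- simulate_panel(cfg)
panel$genotypes
#> genotype_matrix: 230 samples x 5000 SNPs
#>   missing genotypes: 1.95%
#>   chromosomes: 1, 2, 3, ..., 18

g <- filter_snps(panel$genotypes)          # call rate > 0.95, MAF > 0.05
spec <- build_shared_spec(panel$assignment,
                          "Highland", "Lowland1", "Lowland2")
scan <- lsbl_scan(g, spec, top_fraction = 0.005)
scan
#> lsbl_scan: focal Highland vs Lowland1 / Lowland2
#>   4822 valid SNPs, 24 outliers at top 0.5%, cutoff 0.4087

head(scan$outliers$outliers, 5)
#>    snp_id chrom     pos      lsbl rank
#> 1 snp3147    12  445000 0.9457600    1
#> 2 snp1098     4 1320000 0.8674325    2
#> 3 snp1235     5  615000 0.8239489    3
#> 4 snp4598    17  750000 0.7364182    4
#> 5 snp4044    15  760000 0.7328042    5

planted <- panel$truth$snp_id[!is.na(panel$truth$selected_in)]
length(intersect(planted, scan$outliers$outliers$snp_id))
#> [1] 10
```

Reading: 178 of the 5,000 simulated SNPs failed QC (leaving 4,822 valid),
so the 0.5% tail holds `floor(0.005 × 4822) = 24` outliers, the weakest
of which has LSBL 0.41; all 10 planted sweeps rank inside the tail, led
by snp3147 with a focal-private branch of 0.95. Downstream,
`candidate_regions()` + `map_regions_to_genes()` turn outliers into
candidate gene sets and `gene_set_enrichment()` tests them against GMT
gene sets.

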