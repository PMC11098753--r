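# dpcseq

Downstream analysis of **DPC-seq** experiments — genome-wide mapping of
DNA–protein cross-links (DPCs). DPCs are bulky lesions in which a protein is
covalently bound to DNA; they block replication and transcription, and cells
remove them through global proteolysis-dependent pathways and, in actively
transcribed genes, through a transcription-coupled pathway that requires the
Cockayne syndrome protein CSB. DPC-seq sequences the DNA recovered from
KCl–SDS-precipitated protein–DNA complexes, so read coverage proxies DPC
density; comparing coverage across recovery times, genotypes and drugs
quantifies induction and repair gene by gene.

The package is aimed at analysts of damage-mapping sequencing data. It
implements:

* **Coverage**: per-gene fragment counts (half-open, any-overlap) normalized
  to reads per million per kilobase,
  `v_gs = c_gs / (T_s/10^6) / (L_g/10^3)`; metagene (scaled gene body +
  fixed flanks) and TSS-centered profiles, strand-oriented and
  RPM-normalized.
* **Repair statistics**: per-gene log2 fold changes with a pseudocount,
  two-sided t-tests on log coverage with Bonferroni correction
  (`p_adj = min(1, m·p)`), and direction-aware calls of genes whose repair
  is *transcription-dependent* (higher coverage under flavopiridol at 6 h)
  or *CSB-dependent* (higher coverage in CSB knockouts at 6 h).
* **Group tests**: paired two-sided Wilcoxon signed-rank tests across genes
  (exact by sign-assignment enumeration up to 25 nonzero pairs, normal
  approximation with tie/continuity corrections beyond).
* **Stratification**: quantile groups of accessibility or RNAPII occupancy,
  median-split occupancy × accessibility quadrants with set percentages,
  genomic-feature enrichment, and size-matched control sets.
* **Screen hits**: classification of CRISPRi screen sensitizers/suppressors
  from DrugZ-format tables at an FDR cutoff.
* **Simulation**: a seeded generator of synthetic genomes, formaldehyde DPC
  landscapes (more cross-links in inaccessible chromatin, an RNAPII
  cross-link peak at TSSs) with first-order repair kinetics
  `λ_g(t) = λ_g(0)·exp(−k_g t)`,
  `k_g = k_global·m + k_tc·r_g·[WT]·[no flavopiridol]`,
  `m = 1 − φ·[MG132]`, and sequencing fragments with per-gene ground-truth
  dependence labels.

See `vignettes/dpcseq-methods.Rmd` for the full model, parameter defaults
and design rationale.

## Worked example

Simulate a small experiment (500 genes, 5×10⁵ fragments per sample, three
replicates of WT ± flavopiridol and CSB⁻/⁻ at 0 h and 6 h recovery), build
the coverage matrix, and call transcription-dependent repair genes:

```r
library(dpcseq)

cfg <- simulation_config(n_genes = 500, depth_per_sample = 5e5)
sim <- simulate_dpcseq(cfg, seed = 42)
mat <- coverage_matrix(sim$fragments, sim$genes)

ss  <- sim$samplesheet
ids <- function(g, d, h) ss$sample_id[ss$genotype == g & ss$drug == d &
                                      ss$recovery_h == h]
calls <- compare_coverage(mat, ids("WT", "flavopiridol", 6),
                          ids("WT", "none", 6))
table(calls$call)
#>    dependent non_changing     excluded
#>           66          434            0
```

66 genes show significantly higher DPC coverage when transcription was
blocked during recovery — these undergo transcription-dependent repair. The
simulator's ground truth says how good the calls are:

```r
truth <- sim$truth$transcription_dependent
sum(calls$call == "dependent" & truth) / sum(truth)   # sensitivity: 0.868
mean(truth[calls$call == "dependent"])                # precision:   1.000
```

Called genes concentrate among highly transcribed, highly accessible genes:

```r
q <- quadrant_assign(sim$covariates)
quadrant_percentages(calls$gene_id[calls$call == "dependent"], q)
#>            quadrant  n percentage
#> 1   low_occ.low_acc  0        0.0
#> 2  low_occ.high_acc  0        0.0
#> 3  high_occ.low_acc  6        9.1
#> 4 high_occ.high_acc 60       90.9
```

90.9% of the called set sits in the high-occupancy/high-accessibility
quadrant. The paired Wilcoxon helper reproduces textbook exact results:

```r
wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
#> Wilcoxon signed rank: W = 15, n = 5, p = 0.0625 (exact)
```

`run_pipeline(cfg, seed, out_dir)` chains all stages (simulate → coverage →
compare → stratify) and writes every table as TSV plus a JSON run manifest;
outputs are byte-identical for a given config and seed.

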