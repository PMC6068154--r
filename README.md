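# phagerecomb

Recombination-intensity scanning for bacteriophage pan-genomes.

Phages recombine when two viruses co-infect the same bacterial cell, and the
imprint of that exchange is visible in metagenome-assembled genomes: pairs of
nearby polymorphic sites whose allele combinations cannot descend from a
single mutational tree. `phagerecomb` takes the per-gene multiple sequence
alignments of species-level viral groups (e.g. Roary orthologue exports),
quantifies recombination in every gene, finds the viral groups and genes
whose recombination intensity exceeds what their diversity and sampling depth
predict, and tests whether that intensity is associated with sample origin
and with the immune systems (restriction–modification, CRISPR) of the host
bacteria. A built-in cohort simulator with known recombination truth makes
every stage of the pipeline testable without any external data.

## The statistics at the core

For two biallelic sites, observing all four gametes (00, 01, 10, 11) among
the haplotypes is incompatible with a single tree under infinite-sites
mutation — at least one recombination event must have happened between them
(the **four-gamete test**). The **Hudson–Kaplan lower bound** R_m is the
maximum number of pairwise disjoint intervals bracketed by incompatible site
pairs; `phagerecomb` computes it per gene after filtering every column that
contains a gap, an N or an IUPAC ambiguity code, together with the
**nucleotide diversity**

    pi = (sum over sequence pairs of mismatch counts) / (C(n,2) * L)

on the same filtered columns. Group-level recombination intensity is
y = sum(R_m) / sum(L) over the group's genes, and intensity is judged against
the ordinary least squares fit

    y_i = b0 + b1 * x1_i + b2 * x2_i + e_i

where x1 is mean nucleotide diversity and x2 the number of individuals
(group level) or aligned sequences (gene level). Units whose residual
deviation exceeds a threshold — 0.009 by convention, or the empirical 90th
percentile — are flagged **recombination-intense**. Fisher's exact tests,
2×k chi-squared and one-sided Welch's t complete the association battery.

## Worked example

A four-haplotype gene with three segregating sites, every pair of which
shows all four gametes:

```r
library(phagerecomb)
mat <- rbind(s1 = c("A","A","A"), s2 = c("A","C","C"),
             s3 = c("C","A","C"), s4 = c("C","C","A"))
st <- gene_stats(alignment("toy_gene", "demo", mat))
st$rmin          # 2   -- two disjoint incompatible intervals
st$pi            # 0.6667
st$breakpoints   # intervals (1,2) and (2,3)
```

A synthetic cohort, scanned end to end with the top-decile threshold:

```r
cfg <- sim_config(n_groups = 50, seed = 7)
sim <- simulate_cohort(cfg)
grp <- cohort_group_stats(cohort_gene_stats(sim$cohort))
thr <- quantile(scan_groups(grp)$records$deviation, 0.9)
sc  <- scan_groups(grp, threshold = thr)
head(sc$records)
#>    unit_id      y     x1 x2 deviation flagged
#> 1 group042 0.0117 0.0594 20   0.00656    TRUE
#> 2 group039 0.0113 0.0581 22   0.00618    TRUE
#> 3 group019 0.0117 0.0499 29   0.00615    TRUE
#> 4 group028 0.0104 0.0652 15   0.00552    TRUE
#> 5 group031 0.0108 0.0532 22   0.00525    TRUE
#> 6 group002 0.0104 0.0441 26   0.00416   FALSE
```

Five groups are flagged, all of them among the cohort's six planted
recombination-hot groups (`sim$group_truth$hot`). `y` is R_m per nucleotide,
`x1` mean diversity, `x2` the number of individuals; `deviation` is the
residual from the fitted plane. The immunity association then reads, e.g.:

```r
test_immunity_association(sc$records, sim$immunity, sim$metadata,
                          system = "type2", cutoff = c(0.8, 0.7, 0.6))
```

which reports one Fisher test per cutoff (odds ratio < 1 = the inverse
association between recombination intensity and hosts dense in Type II
restriction endonucleases).

Real data enter through `read_cohort()` (a directory with one subdirectory
of per-gene FASTA alignments per viral group), `read_group_metadata()` and
`read_immunity()`; `run_scan()`/`run_associate()` write the full set of
result tables. `inst/cli/phagerecomb-cli.R` wraps the three stages as
`simulate` / `scan` / `associate` subcommands.

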