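---
title: "Detecting recombination-intense phage groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination-intense phage groups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phagerecomb` quantifies homologous recombination in phage pan-genomes and
flags the viral groups and genes where it is unusually intense. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, what the synthetic cohort generator does and does not
emulate, and the numerical and design choices made where more than one
defensible option existed.

## Per-gene statistics

**Column filtering.** Every alignment column containing any character
outside {A, C, G, T} in any sequence is removed before analysis. Gaps, `N`
and all IUPAC ambiguity codes are treated identically: ambiguous calls in
metagenome assemblies are unreliable, and the four-gamete argument needs
fully resolved haplotypes at both sites of a pair. Filtering is listwise
(a column is dropped for all sequences or none), so all statistics of one
gene share a single column space. The filtered length L — not the raw,
gapped length — is the denominator of R_m per nucleotide and of pi, because
R_m is only defined on the retained columns. This is a genuine convention
choice; the alternative (raw length) would shrink both y and the flagging
threshold's meaning on gappy alignments.

**Segregating sites and the four-gamete test.** Columns with exactly two
residues become binary sites (the first sequence's allele is coded 0 — an
arbitrary orientation; all downstream quantities are invariant to it).
Columns with three or more alleles are excluded from the recombination
analysis because the four-gamete argument is defined for biallelic sites
under infinite-sites mutation; they still count toward pi and L. A site
pair is incompatible when all four gametes 00, 01, 10, 11 occur, which
requires at least four haplotypes — genes with fewer than four sequences
therefore have R_m = 0 structurally, and are excluded from gene-level
regressions rather than entered as biological zeros.

**Hudson–Kaplan R_m.** Each incompatible pair brackets an interval that
must contain at least one breakpoint. R_m is the maximum number of pairwise
disjoint such intervals (intervals sharing only an endpoint count as
disjoint, because a breakpoint strictly between two sites cannot serve two
intervals that only touch). The implementation removes every interval that
contains another (it is implied), sorts survivors by right endpoint with
ties broken by left endpoint, and greedily selects each interval whose left
endpoint is at or beyond the last selected right endpoint. The greedy count
is provably the maximum; the fixed tie-break makes the *reported* set of
breakpoint intervals deterministic. Breakpoints are reported in raw-alignment
coordinates (1-based, at the flanking segregating sites) so they can be drawn
against the original gene. The test suite checks the count against two
independent oracles — a dynamic program over intervals sorted by right
endpoint, and exhaustive subset search when the interval set is small — on
1,000 random site matrices.

**Nucleotide diversity.** pi is the plain average pairwise difference per
site: the sum over unordered sequence pairs of mismatch counts, divided by
`choose(n, 2) * L`. No Jukes–Cantor multiple-hit correction and no
n/(n−1) finite-sample factor are applied; this is the simplest convention
and the one most comparable across genes of the same cohort, which is all
the downstream regression needs. Genes with fewer than two sequences or
zero filtered columns are marked unusable and excluded with a logged reason.

## Group aggregation and the regression scan

Group-level intensity is y = Σ R_m / Σ L over the group's genes with at
least four sequences, and the diversity covariate x1 is the unweighted mean
of pi over all usable genes (unweighted, matching the convention of
averaging per-gene diversity rather than pooling sites). x2 is the number
of individuals in the group. Detectable recombination grows mechanically
with both polymorphism (incompatible pairs need flanking variation) and
sample size (more haplotypes expose more gametes), so the scan fits

y = b0 + b1·x1 + b2·x2 + e

by ordinary least squares and ranks units by their raw residual. The
deviation used for flagging is the residual from the *full* fitted model,
not the vertical distance to the two-dimensional display line drawn at the
mean x2 — the display line is exactly that, a display device. A unit is
flagged when its deviation strictly exceeds the threshold. The group-level
default threshold is the conventional absolute 0.009; the selection logic
behind that constant is "approximately the top decile of deviations", and
`scripts/acceptance.R` flags at the empirical 90th percentile for that
reason (see *Limitations* for the scale gap on synthetic data). At the gene
level no absolute convention exists, so the default is percentile mode at
the 90th percentile. Fits require at least 4 points and a full-rank design;
degenerate designs raise an error rather than being silently pseudo-inverted.
No multiple-testing correction is applied: flagging is a ranking device, not
a per-unit hypothesis test.

## Association battery

Sample-origin enrichment and host-immunity associations are Fisher's exact
tests on 2×2 tables (flagged × attribute). Two-sided p-values use the
point-probability convention — the sum of probabilities of all tables with
the observed margins whose probability does not exceed the observed one
(within the customary 1e−7 relative slack) — which is the dominant
convention and matches enumeration exactly; sidedness is a logged
parameter, two-sided by default since a direction is not assumed a priori.
The reported odds ratio is the sample estimate ad/bc. Host-immunity
frequencies are categorized 1 (<20%), 2 (20–80%, boundaries inclusive) and
3 (>80%) for display, and the association test dichotomizes at "frequency
strictly above the cutoff", sweeping cutoffs 0.8/0.7/0.6 by default as a
robustness check. Functional-category enrichment of flagged genes against
the background pan-genome uses Pearson's 2×k chi-squared without continuity
correction (intended for large counts), and regional rate comparisons use
one-sided Welch's t with Welch–Satterthwaite degrees of freedom.

## The synthetic cohort generator

Each gene receives a random Kingman coalescent genealogy (uniform
pair-merging, exponential epoch durations at rate C(j,2)), a Poisson number
of infinite-sites mutations placed on branches with probability
proportional to branch length, and a Poisson number of crossovers applied
afterwards as template switches between extant tips (recipient's suffix
from a uniform breakpoint replaced by the donor's). This construction gives
two exact guarantees the tests lean on: with zero crossovers the data are
tree-compatible, so R_m = 0 for every gene and every seed; and each
crossover contributes exactly one breakpoint, so R_m never exceeds the
planted crossover count. Branch-length-weighted mutation placement matters:
placing mutations uniformly over branches would make expected diversity
scale like 1/a_n (the harmonic sum), confounding diversity with sample
size and defeating the covariate control the scan relies on.

Recombination-hot groups have their crossover mean multiplied by
`hot_multiplier`; metadata assigns each group one synthetic host species,
an oral/other origin, and immune-system frequencies. With association
strength s, hot groups' hosts exceed 80% Type II frequency with probability
(1−s)·q versus q for cold groups (q = `type2_high_rate`), planting an
inverse association; s = 0 is the exact null used for calibration.

Default parameters and rationale:

| parameter | default | rationale |
|---|---|---|
| `n_groups` | 211 | cohort size of a typical species-level human-virome study |
| `n_individuals_range` | 12–30 | the four-gamete test loses most of its power below roughly a dozen haplotypes (at n = 4 detected R_m is near zero and non-monotone in the true crossover count), so the default cohort emulates moderately sampled groups; real cohorts include groups down to 4 members, where flagging power is accordingly limited |
| `genes_per_group_range` | 20–40 | a desk-scale pan-genome (real phage pan-genomes often run larger); keeps default cohorts and Monte-Carlo checks at minutes on one CPU |
| `gene_length_range` | 300–900 bp | typical phage gene lengths |
| `mutations_per_gene_mean` | 120 | yields per-gene diversity around 0.02–0.06, the magnitude observed in recombination-analysed phage cohorts |
| `crossovers_per_gene_mean` | 5 (cold) | background recombination giving group y ≈ 0.004–0.006 |
| `hot_multiplier` | 5 | a planted effect strong enough to be detectable yet within the saturation regime of R_m |
| `hot_group_fraction` | 0.12 | roughly the flagged share in real cohorts (top decile plus) |
| `oral_fraction` | 0.75 | share of oral-origin groups in human-virome cohorts |
| `immunity_association_strength` | 0.9 | a strong planted inverse Type II association; set to 0 for the null |
| `type2_high_rate` | 0.5 | background share of host species dense in Type II endonucleases |

Reproducibility: one global seed drives the metadata layer and one derived
sub-seed per group, so cohorts are byte-identical across runs and groups
are independent streams.

**What the generator does not emulate.** No selection, codon structure,
indels (gap filtering is exercised by hand-built fixtures instead),
read-level errors or mis-assembly; donors are drawn from the sampled tips
rather than an external population, so repeated crossovers homogenize the
sample; host species are unique per group, whereas real cohorts share hosts
across groups. Passing tests therefore demonstrate the correctness of the
statistics and the scan's ability to recover planted signal under clean
polymorphism — not robustness to alignment error or assembly artefacts.

## Numerical choices and degenerate inputs

Character sorting uses radix order everywhere outputs are written, so
result files are byte-identical across locales. Floating-point output is
rendered with 8 significant digits. A deviation exactly equal to the
threshold is not flagged (strict inequality). Empty cohorts, groups with no
usable genes, and gene scans with fewer than four eligible genes are
skipped with logged reasons rather than errors, so one degenerate group
cannot abort a cohort run; truly malformed inputs (ragged FASTA, duplicate
ids, frequencies outside [0,1], rank-deficient designs) raise errors naming
the offending file, row or condition.

## Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen to finish in minutes on a
single CPU: 1,000 random site matrices (S ≤ 12) for the R_m oracle, 200
zero-crossover genes, 3 × 200 genes for the lower-bound/monotonicity check
(crossover means 0.5, 2, 8), 100 cohorts of 50 groups (5 hot) for
planted-outlier recovery, exhaustive Fisher enumeration over all 2×2 tables
with total ≤ 60, 500 metadata replicates for null calibration, and one
15-group end-to-end determinism run. The null-calibration check compares
the empirical rejection rate of the Type II association test against the
*exact attained size* of the level-0.05 Fisher test given each replicate's
margins (plus an upper bound at the nominal level): an exact conditional
test on discrete tables is conservative by construction, with attained size
near 0.03 at these margins, so "about 5%" is the wrong reference point and
matching the enumerated size is the meaningful calibration property.

## Limitations

R_m is a conservative lower bound — it detects a minority of true events,
saturates as crossovers accumulate (template switching between sampled tips
erases earlier evidence), and is blind to recombination between
near-identical sequences. Under the generator's defaults, flagged-group
deviations reach roughly 0.003–0.007, below the conventional absolute
threshold of 0.009 that real cohorts motivate (real recombination-intense
groups reach R_m per nucleotide of several hundredths, beyond the
generator's detection ceiling); this is why percentile-based flagging is
the right mode on synthetic data. The regression is linear in diversity and
sample size while true detectability is concave in both, so extreme-x1
units carry systematic residuals; the scan is a ranking heuristic, not an
inference procedure. Fisher tests on few flagged groups are coarse and
conservative. None of the association tests correct for phylogenetic
relatedness of viral groups or their hosts.
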