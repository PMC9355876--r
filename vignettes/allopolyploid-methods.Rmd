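---
title: "Methods: subgenome assignment, translocation detection and dominance statistics in allohexaploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allopolyploid subgenome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenomics)
```

## The problem

An allohexaploid genome (AACCDD) carries three homoeologous chromosome
sets descended from distinct diploid ancestors. Three recurring questions
drive the analyses in this package:

1. **Which chromosome belongs to which subgenome?** Answered by similarity
   to an A-like diploid reference: the C lineage is far more diverged from
   the A/D lineages than A and D are from each other, so ranking
   chromosomes by reference similarity separates the three tiers.
2. **Where has sequence moved between subgenomes?** Intergenomic
   translocations leave a read-depth signature: reads from a diploid
   relative of the donor subgenome pile up on the acceptor chromosome.
3. **Is one subgenome dominant?** Quantified by gene fractionation
   (presence/absence of conserved orthologs), relaxed purifying selection
   (Ka/Ks), and homoeolog expression bias in A–C–D triads.

Every analysis is exercised end to end on a synthetic allohexaploid built
by the package's own generator, which also emits machine-readable truth
tables so recovery can be scored exactly.

## Synthetic data model

`simulate_ancestors()` draws one random root genome and derives the A, C
and D ancestors by i.i.d. substitutions, uniform over the three
alternative bases (a Jukes–Cantor-style model with no indels; this keeps
fragment placements exact-length and mismatches countable). The default
divergences from the root are **A = 0.02, C = 0.15, D = 0.05** per site,
reproducing the field's divergence hierarchy ((A,D),C): the C lineage
split first, and the polyploid's A-like reference resembles A most, D at
an intermediate level and C least. Each subgenome also receives a
diagnostic 20-bp satellite motif overwritten at Poisson-placed positions
(50/Mb by default), the analogue of genome-specific tandem repeats used to
cross-check subgenome identity.

The default genome scale is 3 chromosomes × 1 Mb per subgenome. This is a
desk-scale stand-in for a multi-Gb genome chosen so that (a) every planted
rearrangement spans at least two depth windows at the scaled window
geometry and (b) the full study (five assignment seeds, two 5× read sets,
all statistics) runs in minutes on one CPU core. All problem sizes quoted
in this vignette are the package's own defaults, not external constraints.

`simulate_allohexaploid()` concatenates the three ancestors and applies a
rearrangement inventory in stage order (tetraploid events before hexaploid
events). The default set mirrors the canonical allohexaploid history at
generator scale: two D→C and four C→D translocations at the tetraploid
stage (one of them non-homoeologous), then one C→A translocation and one
large inversion on a C chromosome after hexaploidization. Translocations
use **copy semantics** — the destination interval is replaced by the source
ancestor segment, so the planted segment is exactly the donor sequence —
and the truth table records final coordinates of every event.

Expression triads, ortholog presence/absence and genotypes follow standard
models: negative-binomial counts with variance `mu + phi * mu^2`
(default `phi = 0.01`, mild extra-Poisson noise appropriate for the
single-library-per-organ design; TPM conversion assumes equal gene
lengths), independent Bernoulli gene loss per subgenome, and a
haplotype-copying chain in which the allele at a SNP copies its left
neighbour with probability `exp(-d / L)`, giving pairwise r² that decays
approximately as `exp(-2 d / L)`.

Every generator is a pure function of (configuration, seed); identical
inputs give byte-identical outputs.

## Subgenome assignment

The reference genome is split into 100-bp non-overlapping fragments
(`fragment_genome()`; trailing remainders are dropped and logged) and
placed on the polyploid with `map_fragments()`, an exact seed-and-verify
matcher: non-overlapping exact seeds of length
`min(31, floor(len / (max_mismatches + 1)))` are looked up in a sorted
k-mer index of the target and every candidate is verified by a full
Hamming comparison on both strands. By the pigeonhole principle at least
one seed of a placement with ≤ `max_mismatches` mismatches is exact, so
the search provably finds **all** best placements — the test suite checks
equivalence with an all-positions Hamming scan. `max_mismatches` defaults
to 5 per 100-bp fragment: tolerant of the A-lineage divergence regime
(~2–5%), while C-lineage loci (~15%) essentially never qualify, which is
what creates the three-tier similarity signal.

A fragment is *retained* when its best placement is unique
(`n_best_locations == 1`). Syntenic blocks are maximal runs of retained
placements on one target chromosome, orientation-consistent and monotone
in coordinate, with at most one missing or interrupting fragment tolerated
(`call_syntenic_blocks()`, threshold ≥ 5 fragments per block).

The similarity score of a target chromosome is

```
score = covered_bp × mean fragment identity / chromosome length
```

computed over retained placements (optionally restricted to block
members). Two design points deserve note, since "similarity" has no
canonical numeric definition:

* Normalizing by chromosome length makes the score insensitive to
  chromosome size.
* The default input is retained placements rather than block members.
  Under the i.i.d. substitution model the D subgenome wins the
  best-placement race only at scattered positions (each win is an
  independent small-probability event), so D-side wins almost never form
  five-fragment colinear runs; a block-restricted score would leave D
  indistinguishable from C. Retained placements preserve the ranking
  signal on all three tiers, and blocks remain available as a
  conservative filter for noisy real data.

Chromosomes are rank-sorted by score: top third → A, bottom third → C,
middle third → D, with deterministic tie-breaking (covered bp, then name).
An assignment is refused outright when every score is zero.
`validate_by_depth()` cross-checks the labels with ancestor read coverage,
and the satellite-motif densities provide a second independent check.

## Translocation detection by read depth

Reads simulated from the C (and D) ancestor at 5× coverage are placed with
the same matcher. `compute_depth()` accumulates per-base depth by direct
interval counting; the depth sum always equals the summed aligned lengths
of the placements supplied. For translocation calling the depth is built
from **all best placements** of each read, not unique placements only:
with copy semantics the donor content exists twice in the hexaploid, and a
unique-only rule would zero out exactly the signal being sought.
Identity profiling and assignment, by contrast, use unique placements.

`window_medians()` computes sliding-window median depth (even-count
windows take the mean of the central pair; the terminal truncated window
is flagged). The study-scale geometry is 1 Mb windows with 0.5 Mb steps;
generator-scale runs use 10 kb / 5 kb, preserving the 2:1 ratio.

`call_segments()` declares a window *donor-present* when its median depth
reaches `high_frac` (default **0.5**) of the donor's baseline — the median
of window medians on the donor's own (home) chromosomes. The 0.5 fraction
is this package's choice: under Poisson-like coverage at ≥ 5× the depth
on true donor segments concentrates near the baseline while cross-lineage
mapping contributes well under half of it, so 0.5 separates presence from
absence with a wide margin. Consecutive qualifying windows merge across at
most one gap window (symmetric with the block gap tolerance). The donor
chromosome of a segment — needed to separate homoeologous from
non-homoeologous exchanges — cannot be recovered from depth alone; when
placements carrying read-origin names are available the modal origin
chromosome is used, otherwise the class is reported as unknown.

`translocation_share()` and `summarize_pairs()` are exact arithmetic on
segment lengths; totals always partition the summed length.

## Fractionation, Ka/Ks and expression bias

**Fractionation.** `pav_counts()` counts conserved orthologs absent per
subgenome (unknown cells excluded, all-absent rows flagged).
`chisq_two_cell()` tests two counts against an expected split with
`chi2 = sum((obs − exp)² / exp)`, df = 1, no continuity correction (cell
counts in this setting are in the hundreds to tens of thousands, where the
correction is irrelevant). The expected ratio is an explicit parameter
defaulting to 1:1 — an equal-split expectation is an assumption, and
results should state the model used. Pairwise families are BH-adjusted.

**Ka/Ks.** `ng86_kaks()` implements the Nei–Gojobori (1986) counting
estimator: per-codon synonymous site fractions over the three alternative
bases (changes to stop codons count as nonsynonymous, so sites sum to 3
per codon), averaged over both sequences; pathway-averaged difference
counts for multi-substitution codons with equal weights, discarding orders
that pass through a stop whenever a stop-free order exists; Jukes–Cantor
correction `d = −¾ ln(1 − 4p/3)`, flagged saturated at `p ≥ 0.75`. Codons
containing gaps, N or a stop in either sequence are dropped pairwise.
Estimates with `Ks < 0.01` are excluded from summaries, and group
distributions are compared with two-tailed Wilcoxon rank-sum tests
(BH-adjusted). A counting estimator supports the ordinal comparison of
Ka/Ks distributions between subgenomes; it does not reproduce
maximum-likelihood branch-specific estimates, and no numerical equality
with such estimates is claimed.

**Expression bias.** Triad matrices concatenate the A, C and D homoeolog
expression vectors per organ, keep triads expressing at least one
homoeolog, and are log-transformed as `log10(TPM + 1)`. Clustering uses
`1 − Pearson` distance with average linkage; constant profiles, whose
correlation is undefined, are placed at the maximum distance 1. Fold
changes use a pseudocount of ε = 0.5 TPM, which bounds the fold change for
zero cells and keeps the measure antisymmetric. The per-pair bias test is
a one-tailed Fisher exact test on
`[[count_x, lib_x − count_x], [count_y, lib_y − count_y]]` — the gene's
share of its library against the other homoeolog's share — computed as an
exact hypergeometric tail. A homoeolog is called dominant in an organ when
it beats **both** others (BH-adjusted p < 0.05 within the organ family)
and both fold changes clear the |log2FC| > 0.5 gate. The triad-level
consensus applies the same rule to counts pooled across organs: the
planted (and biologically typical) bias is a consistent per-triad shift,
so pooling maximizes power for weakly expressed triads without inflating
the false-positive rate; on 1,000 simulated triads with a planted 20%
biased fraction at log2FC = 2 the recovered fraction is within ±0.01 and
every recovered direction is correct. The 2×2 construction and the
TPM-vs-counts choice for fold changes are parameterized because neither
has a single canonical form.

## Variant QC and association support

`filter_resequencing_snps()` applies six ordered hard-filter rules
(quality/QD/FS/MQ thresholds; biallelic; InDel proximity ≤ 5 bp;
depth-based genotype masking at 3× / ⅓ of the sample mean, which can
cascade into the MAF < 0.05 and missing-rate > 0.3 rules). Each removed
record is attributed to the *first* rule that removes it, so the report's
removals always sum to input − retained. A record missing a required
quality field fails the quality rule by convention. The GBS filter keeps
biallelic sites with MAF > 0.05, missingness < 20% and heterozygosity
< 10%.

The QC arithmetic helpers (`heterozygosity_rate()`, `accuracy_rate()`,
`anchoring_rate()`, `contig_stats()`, `bonferroni_neglog_threshold()`) are
exact rational arithmetic with rounding applied only at the final printed
precision (3, 3, 2 and 2 decimals respectively).

`ld_r2_decay()` computes composite LD — squared Pearson correlation of
genotype dosages, appropriate for unphased genotypes — within a 50-SNP
sliding window, bins pairs by physical distance, smooths the bin means
with monotone (isotonic, non-increasing) regression and reports the decay
distance where the smoothed curve crosses r² = 0.2 (linear interpolation
between bins). Defining the crossing on the smoothed curve makes the
distance insensitive to single noisy bins. The "effective number of SNPs"
in the association threshold is an explicit argument, since it has no
universal definition.

## A worked micro-example

```{r example}
model <- ancestor_model(n_chromosomes = 3, chrom_length = 1e5)
anc <- simulate_ancestors(model, seed = 1)
hex <- simulate_allohexaploid(anc, default_rearrangements(1e5))
pl <- map_fragments(fragment_genome(anc$root, 100), hex$genome, 5)
asg <- assign_subgenomes(pl, hex$genome)
table(predicted = asg$assignment,
      truth = hex$truth$subgenome_of_chromosome[names(asg$assignment)])
```

## What the synthetic validation does and does not show

The generator reproduces the *statistical structure* the analyses assume —
a divergence hierarchy, uniformly diverged lineages, clean copy-type
rearrangements, NB expression noise, exponential LD — under which the
pipeline's recovery can be scored exactly. It deliberately omits much of
what makes real polyploid genomes hard: repeat families and nested
transposons (the dominant fraction of real cereal genomes), indels and
structural read artifacts, GC and coverage biases, paralogy beyond strict
triads, population structure, and base-composition realism. Passing the
recovery tests therefore demonstrates that the *procedures are correct and
calibrated under their stated models*, not that real-data performance will
match; on real data the mapper can be bypassed entirely by supplying
externally produced placement tables, and the study-scale window and
threshold parameters apply.

## Degenerate inputs and numerical conventions

* All internal coordinates are 0-based half-open; VCF positions convert at
  the I/O boundary only.
* Ambiguity codes other than N are normalized to N (logged), and N never
  matches anything in the mapper.
* Chromosomes shorter than one fragment/window yield zero fragments or a
  single flagged truncated window, with warnings rather than errors.
* Ranking ties (similarity, modal identity) break deterministically.
* Undefined ratios (Ka/Ks with Ks = 0, precision with no predictions,
  correlation of constant vectors) are reported as NA or a documented
  fallback, never silently dropped.

## Known limitations

* The mapper is substitution-only (no gapped alignment); real-data use
  should import placements from a full aligner.
* Depth-based calling cannot see copy-neutral inversions, by design.
* The chi-squared expectation model and the Fisher 2×2 construction are
  assumptions exposed as parameters; conclusions should be read relative
  to the model actually used.
* Wilcoxon comparisons treat triads/gene pairs as independent
  observations, which understates within-genome correlation in real data.
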