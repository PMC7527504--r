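---
title: "Methods: statistics, algorithms and design choices in slocuspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics, algorithms and design choices in slocuspop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods
it implements, the parameters that matter, and the places where the
design was genuinely open and a choice had to be made.

## Scope and data model

The package analyses three kinds of input: aligned in-frame coding
nucleotide sequences (the `codon_aln` class, built on a plain `aln`
alignment), aligned amino-acid sequences, and diploid unphased
microsatellite genotypes (`genotype_table`). Alignments are assumed
pre-aligned and curated; the package performs no alignment itself.

Gap handling is global complete deletion: `strip_gap_columns()` removes
every column containing a gap in any sequence before any statistic is
computed, and records the retained column indices for traceability.
The one deliberate exception is the Poisson protein distance, where
ambiguous positions (`-`/`X`) are removed per sequence pair by default
(`deletion = "pairwise"`), because pairwise deletion is the convention
for distance-matrix phylogenetics and keeps short ambiguous stretches
from erasing whole columns across a large alignment; both behaviours
are flag-selectable in both places.

Lowercase input is uppercased silently; characters outside the declared
alphabet are an error rather than being masked, since silent masking
changes site counts. Reading frame defaults to 0 and there is no ORF
detection; internal stop codons are an error unless explicitly allowed.

## Diversity and divergence

Nucleotide diversity is the mean over all n(n−1)/2 sequence pairs of
the per-pair proportion of differing sites. The Jukes–Cantor correction
d = −(3/4)ln(1 − 4p/3) is applied *per pair* and then averaged — not to
the averaged p — matching the composition used by the standard
implementations of the Nei–Gojobori method; it is undefined at
p ≥ 3/4 and the package raises an error there rather than truncating.

Synonymous/non-synonymous accounting follows Nei & Gojobori (1986):

* **Sites.** Each codon position contributes (synonymous single-nt
  changes)/3 to the synonymous site count. Changes that would create a
  stop codon are excluded from both classes without renormalising, so a
  codon's site total is 3 minus one third of its stop-neighbour count.
  Site totals are computed per sequence and averaged (per pair for
  pairwise statistics).
* **Differences.** For a codon pair differing at d positions, all d!
  orderings of the changes are enumerated; orderings passing through a
  stop codon are discarded, and the synonymous/non-synonymous step
  counts are averaged over the remainder. If every ordering crosses a
  stop (possible for some 3-difference pairs), all orderings are used
  with a warning rather than failing. The test suite checks every one
  of the 61×61 sense-codon pairs against an independently written
  recursive enumerator.

π_S/π_A divide the pairwise difference sums by the pair-averaged site
counts; K_S/K_A do the same against each sequence of an explicit
comparator set. Divergence deliberately *requires* a comparator
(ancestral or outgroup alleles): an intra-sample "divergence" would
duplicate π, and the McDonald–Kreitman test in the same workflow needs
interspecific fixed differences anyway. A mean-pairwise intra-sample
mode can be had by passing focal sequences as the comparator.

Segregating mutations are classified synonymous/non-synonymous per
codon by pathway logic against the codon's majority (consensus) state,
with lexicographic tie-breaks; multi-hit codons therefore contribute
fractional class counts, which are rounded to integers by largest
remainder only where a report demands integers (mutation-count columns,
MK tables). The total mutation count η is Σ(distinct states − 1) over
sites, the definition consistent with infinite-sites counting.

## Neutrality tests

Tajima's D uses the 1989 variance coefficients. Both variance
coefficients vanish identically at n = 3, so D is reported only as
defined: S = 0, or any degenerate denominator, yields `NA` (never 0).
The partitioned statistics D_S and D_A plug the class-specific
segregating-mutation totals and class-specific mean pairwise difference
sums into the same formula — the only construction consistent with
reporting one D per site class from frequency-spectrum inputs; the
class totals are used unrounded there.

Fu & Li's D\* and F\* are the no-outgroup star variants with the
Simonsen et al. (1995) corrected coefficients. η_s counts mutations
carried by exactly one sequence (for a column where every state is a
singleton, one fewer than the state count, capped at the column's
mutation count). Both statistics validate against the neutral
coalescent null in the test suite: across 500 simulated samples
(n = 13, θ = 5) their means sit within ±0.2/±0.25 of zero.

The McDonald–Kreitman classification is per codon: variable within the
focal sample → polymorphic (even if also different from the outgroup —
the standard MK convention); monomorphic and different from the
outgroup's majority-rule consensus codon → fixed. Mutations are typed
by the same pathway averaging and the 2×2 table is tested two-sided by
Fisher's exact test (Williams-corrected G-test by flag). Mutations, not
sites, are counted when a position is hit repeatedly.

## Trees and networks

UPGMA is implemented directly (group-size-weighted average linkage,
node height = joining distance / 2) so that tie-breaking could be made
deterministic: among equidistant pairs the lexicographically smallest
pair of cluster labels joins first, and a cluster is labelled by its
smallest member. The implementation is cross-checked against
average-linkage `hclust` merge heights in the tests, is ultrametric to
1e-9 by construction, and reconstructs any tree whose cophenetic matrix
it is given. Bootstrap support resamples alignment columns with
replacement (500 replicates by default, seeded) and reports the
percentage of replicates containing each original clade.

The minimum spanning network is the union of all minimum spanning
trees over Hamming distances — an edge of weight w is kept iff its
endpoints are not connected by edges of weight < w − ε — with ε = 0 by
default and the ε-relaxation available for display purposes. Identical
sequences collapse to one node carrying their multiplicity.

Median-joining proceeds in two phases. Candidate median vectors are
generated from MSN-connected triplets as per-site majority consensus
(when all three states differ, the central node's state is kept),
iterating so medians of medians can arise. Candidates are then admitted
greedily, each only while it strictly reduces the weight of the minimum
spanning tree over the current node set. The greedy admission is what
guarantees the invariant that median vectors never increase the
spanning cost — a naive "add every locally improving median" rule
violates it, because every median node must itself be spanned. Medians
left dangling (degree ≤ 1) are pruned. The exported edge set keeps the
minimum-spanning links among the observed haplotypes alongside the
extended network's links, so the observed backbone remains inspectable
as a subgraph; the reported `total_mutation_length` is the spanning-
tree weight of the final network, the quantity reported as the
"shortest tree" mutation count in network software.

The rho statistic is the mean shortest-path mutation count from a
designated ancestral node to a set of descendants (the network
generalisation of mean tip distance; path ties are irrelevant because
only the count enters). Ages are rho/μ with μ = 10⁻³ mutations per
year by default — the rate conventionally used for GSI S-alleles; note
that with μ expressed in mutations/year, converting mutational units to
years is division by μ (equivalently multiplication by 1/μ = 1000
years per mutation).

## SSR diversity and linkage disequilibrium

He defaults to Nei's unbiased estimator (2n/(2n−1))(1 − Σp²) and PD to
1 − Σ(genotype frequency)² over observed unordered genotype classes —
the defaults of the population-genetics tools this report format comes
from; the plain 1 − Σp² estimator is a flag.

Rare alleles (sample frequency strictly below 5% by default) are
masked from LD analysis by setting carrier calls to missing — a single
pass; frequencies are deliberately not recomputed afterwards, so a
borderline allele cannot cascade into masking further alleles.

Because genotypes are unphased, LD uses Weir's composite measure. In
dosage form: with X the 0/1/2 copy count of allele a and Y that of
allele b at another locus, r is the Pearson correlation of X and Y —
i.e. the composite disequilibrium Δ_ab normalised by the observed
dosage variances (p(1−p) + D_HW per locus). Under Hardy–Weinberg
proportions this reduces to Δ²/(p_a(1−p_a)p_b(1−p_b)); under complete
coupling it correctly yields r² = 1, which the HWE-denominator formula
does not. For biallelic data it equals the squared Pearson correlation
of allele indicators, which the tests verify.

Significance defaults to a seeded permutation of one locus's genotypes
across individuals (1000 permutations by default), because the target
sample sizes (a couple dozen accessions) are too small for the
asymptotic χ² (available by flag). Two numerical choices matter here:

* **Mid-P.** Dosage correlations are heavily tied, and the standard
  (1 + #{≥})/(B+1) estimator is visibly conservative — its null
  distribution fails a uniformity check. Ties between permuted and
  observed |r| therefore count one half.
* **Effective test count.** The locus-pair P is the Bonferroni-adjusted
  minimum allele-pair P, with the multiplier (k−1)(l−1) — the rank of
  the allele-dosage cross-correlation system — not the raw k·l allele-
  pair count: for two biallelic loci all four allele-pair |r| values
  are identical and raw Bonferroni would quarter the type-I rate.

With these choices the empirical false-positive rate at α = 0.05 on
independent simulated loci sits at the nominal level (the acceptance
script measures it), and both the locus-level and allele-pair-level
percentage summaries are emitted, since report conventions differ on
which unit to count.

## Simulators: what they emulate, and what they do not

`sim_neutral_sample()` is a standard neutral coalescent under infinite
sites: exponential coalescence times at rate k(k−1)/2, Poisson(θ/2 per
lineage) mutations, each mutation a unique site with a single derived
state and no back-mutation — exactly the null under which Tajima's and
Fu & Li's statistics are calibrated, and deliberately nothing more (no
recombination, no demography, no selection). Defaults in tests mirror
the scale of the motivating data: n = 13 sequences per allele class
and a few hundred variable sites (θ = 5 over 600 nt for the nulls).

`sim_codon_sample()` evolves codons along the genealogy by proposing
random single-nucleotide changes, rejecting stops, and accepting
non-synonymous proposals with probability min(1, ω). The ω filter acts
on acceptance rather than rates, which makes the realised dN/dS ratio
approximately ω *by construction* — adequate for recovery tests and
partition-purity checks, but not a full codon substitution model (no
transition/transversion bias, no codon frequencies, no site-to-site ω
variation). Ratio recovery is assessed on pooled estimates
(mean π_A over replicates / mean π_S over replicates): a per-replicate
ratio is upward-biased by noise in its denominator at realistic
mutation counts.

`sim_ssr_genotypes()` draws two alleles per individual per locus under
HWE; designated biallelic locus pairs are generated from two-locus
haplotype frequencies with normalised association D′ (infeasible D′
errors out with the feasible bound). There is no stepwise mutation
model and no genotyping error.

Consequently, passing tests demonstrate correctness of the statistics
under their own model assumptions — they cannot certify behaviour on
real data with recombination, gene conversion, balancing selection at
the S-locus, or genotyping artefacts.

## Determinism and degenerate inputs

Every stochastic operation takes an explicit seed and is reproducible
bit-exactly; two runs with identical config and inputs produce
byte-identical output files. Statistics that are undefined (no
polymorphism for D, no mutations for D*/F*, a zero denominator in any
ratio) are reported as `NA`/empty in output tables, never as 0.
Report tables round the π/K family to 3 decimals and ratios and D
statistics to 2, matching the conventional printed precision. Problem
sizes used by the validation runs (500 coalescent replicates; 20 codon
replicates of 500 codons; 400 LD datasets of 50 individuals with 200
permutations) were chosen as the smallest giving stable Monte-Carlo
means relative to the tolerances being checked.

## Known limitations

* The Nei–Gojobori method undercounts at high divergence even with the
  Jukes–Cantor correction; no maximum-likelihood dN/dS is provided.
* Median generation uses majority consensus only (no quasi-median
  expansion for three-way site conflicts), so on data with many
  three-state sites the network can be less resolved than exhaustive
  median-joining; the spanning-cost guarantee still holds.
* Fu & Li's outgroup variants (D, F) are not implemented — only the
  star statistics.
* The LD permutation test permutes whole genotypes, preserving each
  locus's Hardy–Weinberg departure; it tests association between loci,
  not within-locus structure.
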