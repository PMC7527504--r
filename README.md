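# slocuspop

Molecular-evolution and population-genetics toolkit for S-locus genes —
built around the analyses used to study the breakdown of gametophytic
self-incompatibility (GSI) in *Prunus*, where the pollen-side
determinant is the S-haplotype-specific F-box gene (SFB). The package
is equally usable for any curated set of aligned coding alleles plus
surrounding microsatellite genotypes.

## What it computes

**Codon-aware diversity and divergence.** For an in-frame coding
alignment: the segregating-site spectrum (polymorphic sites S,
singletons, parsimony-informative sites, total mutations η), nucleotide
diversity π (mean pairwise difference per site), and the
synonymous/non-synonymous decomposition via the approximate method of
Nei and Gojobori (1986): expected synonymous and non-synonymous site
counts per codon, pathway-averaged difference counts Nd/Ns for each
codon pair (stop-codon pathways excluded), giving π_S, π_A within a
sample and K_S, K_A against a designated comparator, each with the
Jukes–Cantor multiple-hit correction d = −(3/4)·ln(1 − 4p/3).

**Neutrality tests.** Tajima's D — total and partitioned into
synonymous and non-synonymous mutation classes — Fu & Li's D\* and F\*
(the no-outgroup star variants, Simonsen-corrected coefficients), and
the McDonald–Kreitman test contrasting fixed versus polymorphic
synonymous/non-synonymous changes with a two-sided Fisher exact test
(f_A/f_S vs P_A/P_S, neutrality index, G-test by flag).

**Trees and haplotype networks.** Poisson-corrected amino-acid
distances d = −ln(1 − p) with pairwise deletion of ambiguous sites,
UPGMA clustering with column-bootstrap support, ε-relaxed minimum
spanning networks (the union of all minimum spanning trees over Hamming
distances), median-joining networks (consensus median vectors admitted
while they shorten the spanning structure), and rho-statistic dating:
rho is the mean mutational distance from an ancestral node to its
descendants, converted to years as age = rho/μ (default
μ = 10⁻³ mutations/year).

**SSR diversity and linkage disequilibrium.** For diploid unphased
multiallelic genotypes: observed allele counts Ao, observed
heterozygosity Ho, Nei's unbiased expected heterozygosity
He = (2n/(2n−1))(1 − Σp²), power of discrimination
PD = 1 − Σ(genotype frequency)², rare-allele exclusion (frequency < 5%
by default), and a composite linkage-disequilibrium scan: squared
allele-dosage correlations r² per allele pair (Weir's composite
measure), seeded permutation significance, and locus-pair summaries.

**Simulators.** A neutral infinite-sites coalescent (for validating the
neutrality statistics against their sampling null), a codon-alignment
simulator with tunable dN/dS acceptance ratio ω plus an outgroup
branch, and an SSR genotype simulator under HWE with tunable two-locus
D′ — so every statistic in the package is testable without external
data.

## Worked example

```r
library(slocuspop)

# a 13-allele coding sample with omega = 0.5 and a diverged outgroup
sim <- sim_codon_sample(n = 13, theta = 30, L_codons = 200, omega = 0.5,
                        t_div = 0.1, seed = 11)

run_diversity(list(SFB = sim$focal), comparator = sim$outgroup)
#>   Class  N Poly.S Sing Par.Inf    pi  M Syn.M N.Syn.M   piS   piA piA.piS    KS   KA KA.KS
#> 1   SFB 13     62   27      37 0.033 65    27      38 0.052 0.029    0.55 0.068 0.07  1.02

run_neutrality(list(SFB = sim$focal), outgroup = sim$outgroup)
#>   Class fS fA PS PA fA.fS PA.PS   D_T   D_S   D_A D_star F_star
#> 1   SFB  3 13 27 38  4.33  1.41 -0.16 -0.52 -0.23  -0.32  -0.34

net <- median_joining_network(sim$focal$aln)
net
#> haplotype network: 16 nodes (4 median), 23 edges, spanning length 66

hap <- net$nodes$id[net$nodes$type == "observed"]
rho_age(net, hap[1], setdiff(hap, hap[1]))$age_years
#> [1] 21636.36
```

Reading the output: 62 of 600 sites segregate, and purifying pressure
on the non-synonymous class (ω = 0.5) shows up as π_A/π_S = 0.55 within
the sample, while the MK table contrasts the 3:13 fixed with the 27:38
polymorphic synonymous:non-synonymous split. The slightly negative
Tajima's D and Fu & Li statistics are within the neutral range. The
network dates the root haplotype at roughly 21,600 years before present
at μ = 10⁻³ mutations/year.

A command-line wrapper with `diversity`, `neutrality`, `network`,
`ssr` and `simulate` subcommands is installed under `inst/cli/`:

```sh
Rscript inst/cli/slocuspop.R diversity --in coding.fasta \
    --comparator ancestors.fasta --out results/
```

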