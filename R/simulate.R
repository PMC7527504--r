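## Coalescent and genotype simulators used to validate every statistic
## against its sampling distribution: neutral infinite-sites samples,
## codon alignments with a controlled non-synonymous/synonymous rate
## ratio (omega) plus a diverged outgroup, and diploid SSR genotypes
## under Hardy-Weinberg equilibrium with tunable two-locus association.

#' Simulate a neutral infinite-sites sequence sample
#'
#' Standard neutral coalescent (exponential waiting times at rate
#' k(k-1)/2 while k lineages remain); mutations fall on the genealogy
#' as a Poisson process with rate theta/2 per lineage per unit time,
#' each creating one new segregating site (one derived state, no
#' back-mutation) mapped onto a random monomorphic background sequence.
#'
#' @param n sample size (>= 2).
#' @param theta population mutation parameter per locus.
#' @param L sequence length in nucleotides; must accommodate the
#'   realised mutation count.
#' @param seed RNG seed (required).
#' @return a nucleotide \code{aln} with ids seq1..seqn; attribute
#'   \code{n_mutations} records the realised mutation count.
#' @export
sim_neutral_sample <- function(n, theta, L, seed) {
  if (n < 2L) stop("n >= 2 required")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  muts <- sim_genealogy_mutations(n, theta)
  S <- length(muts)
  if (S > L)
    stop("sequence length L = ", L, " cannot hold ", S,
         " segregating sites; increase L")
  bg <- sample(NUCS, L, replace = TRUE)
  m <- matrix(rep(bg, each = n), n, L)
  if (S > 0L) {
    pos <- sample.int(L, S)
    for (k in seq_len(S)) {
      derived <- sample(setdiff(NUCS, bg[pos[k]]), 1L)
      m[muts[[k]], pos[k]] <- derived
    }
  }
  rownames(m) <- paste0("seq", seq_len(n))
  out <- aln_from_matrix(m, "nucleotide")
  attr(out, "n_mutations") <- S
  out
}

# carrier-set representation of mutations on a neutral genealogy:
# returns a list, one element per mutation, of the tip indices below it
sim_genealogy_mutations <- function(n, theta) {
  lineages <- as.list(seq_len(n))
  muts <- list()
  k <- n
  while (k > 1L) {
    dt <- stats::rexp(1L, rate = k * (k - 1) / 2)
    nmut <- stats::rpois(1L, theta / 2 * k * dt)
    if (nmut > 0L) {
      hit <- sample.int(k, nmut, replace = TRUE)
      for (h in hit) muts[[length(muts) + 1L]] <- lineages[[h]]
    }
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages[[pair[1L]]] <- merged
    lineages[[pair[2L]]] <- NULL
    k <- k - 1L
  }
  muts
}

# explicit genealogy (topology + branch lengths) for sequence evolution
sim_genealogy_tree <- function(n) {
  parent <- integer(2L * n - 1L)
  blen <- numeric(2L * n - 1L)
  active <- seq_len(n)
  birth <- rep(0, 2L * n - 1L)
  t <- 0; nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    ch <- active[pair]
    parent[ch] <- nxt
    blen[ch] <- t - birth[ch]
    birth[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, blen = blen, root = 2L * n - 1L, n = n)
}

STOPFREE_CODONS <- setdiff(names(GENETIC_CODE_TABLE)[
  !grepl("N", names(GENETIC_CODE_TABLE))], STOP_CODONS)
STOPFREE_CODONS <- STOPFREE_CODONS[nchar(STOPFREE_CODONS) == 3L &
  !grepl("[^ACGT]", STOPFREE_CODONS)]

# evolve a codon sequence along a branch: n_prop proposed random
# single-nt changes; stops rejected; non-synonymous accepted with
# probability min(1, omega)
evolve_codons <- function(codons, n_prop, omega) {
  Lnt <- 3L * length(codons)
  for (k in seq_len(n_prop)) {
    site <- sample.int(Lnt, 1L)
    cidx <- (site - 1L) %/% 3L + 1L
    pos <- (site - 1L) %% 3L + 1L
    old <- codons[cidx]
    ch <- strsplit(old, "")[[1L]]
    ch[pos] <- sample(setdiff(NUCS, ch[pos]), 1L)
    new <- paste(ch, collapse = "")
    if (is_stop(new)) next
    if (GENETIC_CODE_TABLE[[new]] != GENETIC_CODE_TABLE[[old]] &&
        stats::runif(1L) > min(1, omega)) next
    codons[cidx] <- new
  }
  codons
}

#' Simulate a codon alignment with controlled omega plus an outgroup
#'
#' Mutations are proposed as random single-nucleotide changes along a
#' neutral coalescent genealogy (rate theta/2 per lineage) and along an
#' outgroup branch of expected \code{t_div} proposals per site;
#' synonymous proposals are always accepted, non-synonymous ones with
#' probability min(1, omega), and changes creating stop codons are
#' rejected.  Realised piA/piS and KA/KS therefore approximate omega.
#'
#' @param n focal sample size.
#' @param theta proposal parameter per locus on the genealogy.
#' @param L_codons alignment length in codons.
#' @param omega non-synonymous/synonymous acceptance ratio (>= 0).
#' @param t_div expected proposals per nucleotide site on the outgroup
#'   branch (0 for none).
#' @param seed RNG seed (required).
#' @return list with \code{focal} (a \code{codon_aln}) and
#'   \code{outgroup} (a one-sequence nucleotide \code{aln}, or NULL).
#' @export
sim_codon_sample <- function(n, theta, L_codons, omega, t_div = 0,
                             seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  tree <- sim_genealogy_tree(n)
  root_seq <- sample(STOPFREE_CODONS, L_codons, replace = TRUE)
  seqs <- vector("list", 2L * n - 1L)
  seqs[[tree$root]] <- root_seq
  # preorder: parents always have larger indices than children
  for (node in rev(seq_len(2L * n - 2L))) {
    p <- tree$parent[node]
    n_prop <- stats::rpois(1L, theta / 2 * tree$blen[node])
    seqs[[node]] <- evolve_codons(seqs[[p]], n_prop, omega)
  }
  m <- do.call(rbind, lapply(seq_len(n), function(i)
    strsplit(paste(seqs[[i]], collapse = ""), "")[[1L]]))
  rownames(m) <- paste0("seq", seq_len(n))
  focal <- codon_alignment(aln_from_matrix(m, "nucleotide"))
  outgroup <- NULL
  if (t_div > 0) {
    n_prop <- stats::rpois(1L, t_div * 3L * L_codons)
    og <- evolve_codons(root_seq, n_prop, omega)
    outgroup <- alignment("outgroup", paste(og, collapse = ""), "nucleotide")
  }
  list(focal = focal, outgroup = outgroup)
}

#' Simulate diploid SSR genotypes under HWE
#'
#' Each individual receives two alleles per locus drawn from the locus
#' allele-frequency vector.  For designated locus pairs, two-locus
#' haplotypes are drawn with normalised association D' and paired into
#' diploids, inducing the requested linkage disequilibrium (biallelic
#' loci only).
#'
#' @param n_ind number of individuals.
#' @param freqs named list of per-locus allele-frequency vectors (names
#'   are allele codes; frequencies sum to 1).
#' @param ld_pairs optional data.frame with columns \code{locus1},
#'   \code{locus2}, \code{d_prime} (biallelic loci, disjoint pairs).
#' @param seed RNG seed (required).
#' @return a \code{genotype_table}.
#' @export
sim_ssr_genotypes <- function(n_ind, freqs, ld_pairs = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  for (f in freqs)
    if (abs(sum(f) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  calls <- list()
  paired <- character(0L)
  if (!is.null(ld_pairs)) {
    for (r in seq_len(nrow(ld_pairs))) {
      l1 <- ld_pairs$locus1[r]; l2 <- ld_pairs$locus2[r]
      dp <- ld_pairs$d_prime[r]
      f1 <- freqs[[l1]]; f2 <- freqs[[l2]]
      if (length(f1) != 2L || length(f2) != 2L)
        stop("d_prime pairing requires biallelic loci")
      pA <- f1[1L]; pB <- f2[1L]
      Dmax <- if (dp >= 0) min(pA * (1 - pB), (1 - pA) * pB)
              else min(pA * pB, (1 - pA) * (1 - pB))
      D <- dp * Dmax
      h <- c(pA * pB + D, pA * (1 - pB) - D,
             (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D)
      if (any(h < -1e-12))
        stop("d_prime = ", dp, " infeasible; feasible |d_prime| <= 1")
      h <- pmax(h, 0); h <- h / sum(h)
      hap <- matrix(c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L), 4L, 2L, byrow = TRUE)
      draw <- hap[sample.int(4L, 2L * n_ind, replace = TRUE, prob = h), ]
      a1 <- matrix(names(f1)[draw[, 1L]], ncol = 2L)   # two gametes/ind
      a2 <- matrix(names(f2)[draw[, 2L]], ncol = 2L)
      calls[[l1]] <- a1
      calls[[l2]] <- a2
      paired <- c(paired, l1, l2)
    }
  }
  for (loc in setdiff(names(freqs), paired)) {
    f <- freqs[[loc]]
    calls[[loc]] <- matrix(sample(names(f), 2L * n_ind, replace = TRUE,
                                  prob = f), ncol = 2L)
  }
  calls <- calls[intersect(names(freqs), names(calls))]
  genotype_table(paste0("ind", seq_len(n_ind)), calls)
}

#' Tiny hand-countable worked-example datasets
#'
#' Deterministic fixtures with expected-output manifests: the
#' four-sequence site-spectrum example, the TTT/GTA codon-pathway pair,
#' the three-taxon UPGMA matrix, the four-haplotype network set and the
#' four-individual genotype table.
#'
#' @return named list; each element has \code{data} and
#'   \code{manifest} (expected values).
#' @export
fixture_worked_examples <- function() {
  list(
    spectrum = list(
      data = alignment(paste0("s", 1:4),
                       c("AAAA", "AAAA", "AGAA", "AGAT"), "nucleotide"),
      manifest = list(S = 2L, eta = 2L, singletons = 1L,
                      parsimony_informative = 1L)),
    codon_pair = list(
      data = c("TTT", "GTA"),
      manifest = list(Nd = 1.5, Ns = 0.5)),
    upgma3 = list(
      data = matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3L,
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
      manifest = list(newick = "((A:1,B:1):1,C:2);",
                      heights = c(1, 2))),
    haplotypes4 = list(
      data = alignment(paste0("h", 1:4),
                       c("AAA", "ATA", "AAT", "ATT"), "nucleotide"),
      manifest = list(n_nodes = 4L, spanning_length = 3L)),
    genotypes4 = list(
      data = genotype_table(paste0("i", 1:4), list(
        L1 = rbind(c("A", "B"), c("A", "B"), c("A", "A"), c("B", "B")))),
      manifest = list(Ao = 2L, Ho = 0.5, He_plain = 0.5, PD = 0.625)))
}
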