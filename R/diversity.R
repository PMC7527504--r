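## Polymorphism and divergence statistics: segregating-site spectrum,
## nucleotide diversity (with optional Jukes-Cantor multiple-hit
## correction), Nei-Gojobori (1986) synonymous/non-synonymous site and
## difference counting, and per-site-class diversity and divergence.

#' Jukes-Cantor distance from a proportion of differences
#'
#' d = -(3/4) ln(1 - 4p/3); undefined for p >= 3/4.
#'
#' @param p proportion of differing sites (vectorised).
#' @return corrected distance(s).
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75))
    stop("Jukes-Cantor correction undefined for p >= 3/4 (p = ",
         format(max(p)), ")")
  -0.75 * log(1 - 4 * p / 3)
}

#' Segregating-site spectrum of a nucleotide alignment
#'
#' Counts polymorphic sites (S), singleton sites (rarest variant carried
#' by exactly one sequence), parsimony-informative sites (>= 2 states
#' each at count >= 2) and the total mutation count eta (distinct states
#' minus one, summed over sites).  Columns are tallied over A/C/G/T;
#' N is ignored within a column.
#'
#' @param aln gap-stripped nucleotide \code{aln}, n >= 2.
#' @return list with \code{S}, \code{singletons},
#'   \code{parsimony_informative}, \code{eta}, \code{eta_singletons}
#'   (singleton mutations, for Fu & Li).
#' @export
site_spectrum <- function(aln) {
  if (length(aln) < 2L) stop("site spectrum requires n >= 2 sequences")
  m <- aln_matrix(aln)
  S <- sing <- pinf <- eta <- eta_s <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j][m[, j] %in% c("A", "C", "G", "T")])
    k <- length(tab)
    if (k < 2L) next
    S <- S + 1L
    eta <- eta + (k - 1L)
    n1 <- sum(tab == 1L)
    eta_s <- eta_s + min(n1, k - 1L)
    if (min(tab) == 1L) sing <- sing + 1L
    if (sum(tab >= 2L) >= 2L) pinf <- pinf + 1L
  }
  list(S = S, singletons = sing, parsimony_informative = pinf,
       eta = eta, eta_singletons = eta_s)
}

# pairwise difference proportions; positions with N in either sequence
# are dropped from that pair's comparison
pairwise_p <- function(m) {
  n <- nrow(m)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- diffs <- len <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    a <- m[idx[r, 1L], ]; b <- m[idx[r, 2L], ]
    ok <- a != "N" & b != "N"
    len[r] <- sum(ok)
    diffs[r] <- sum(a[ok] != b[ok])
    p[r] <- if (len[r] > 0) diffs[r] / len[r] else 0
  }
  list(p = p, diffs = diffs, len = len)
}

#' Nucleotide diversity (pi) per site
#'
#' Mean over all n(n-1)/2 sequence pairs of the per-pair proportion of
#' differing sites, optionally Jukes-Cantor corrected per pair before
#' averaging.
#'
#' @param aln gap-stripped nucleotide \code{aln}, n >= 2.
#' @param jc apply the Jukes-Cantor correction to each pairwise
#'   proportion.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(aln, jc = FALSE) {
  if (length(aln) < 2L) stop("pi requires n >= 2 sequences")
  pw <- pairwise_p(aln_matrix(aln))
  d <- if (jc) jukes_cantor(pw$p) else pw$p
  mean(d)
}

#' Mean number of pairwise differences (absolute)
#' @param aln gap-stripped nucleotide \code{aln}.
#' @return mean pairwise difference count (k-hat).
#' @export
mean_pairwise_differences <- function(aln) {
  mean(pairwise_p(aln_matrix(aln))$diffs)
}

## ---- Nei-Gojobori (1986) machinery -------------------------------------

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

is_stop <- function(codon) codon %in% STOP_CODONS

# all 9 single-nucleotide neighbours of a codon
codon_neighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1L]]
  out <- character(9L); k <- 0L
  for (pos in 1:3) for (nt in setdiff(NUCS, ch[pos])) {
    tmp <- ch; tmp[pos] <- nt
    k <- k + 1L; out[k] <- paste(tmp, collapse = "")
  }
  out
}

# fractional (syn, nonsyn) site counts of one codon; changes to stop
# codons are excluded from both classes (denominator stays 3 per position)
ng_codon_sites <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return(c(syn = NA_real_, nonsyn = NA_real_))
  if (is_stop(codon)) stop("stop codon has no defined site counts: ", codon)
  aa <- GENETIC_CODE_TABLE[[codon]]
  syn <- nonsyn <- 0
  for (nb in codon_neighbours(codon)) {
    if (is_stop(nb)) next
    if (GENETIC_CODE_TABLE[[nb]] == aa) syn <- syn + 1 else nonsyn <- nonsyn + 1
  }
  c(syn = syn / 3, nonsyn = nonsyn / 3)
}

#' Expected synonymous and non-synonymous site counts (Nei-Gojobori)
#'
#' Per codon, each of the three positions contributes the fraction of
#' its possible single-nucleotide changes that are synonymous; changes
#' creating a stop codon are excluded from both classes.  Counts are
#' summed per sequence and averaged across sequences.  Codons containing
#' N are skipped.
#'
#' @param codon_aln a \code{codon_aln}.
#' @return list with \code{syn_sites} and \code{nonsyn_sites}.
#' @export
ng_site_counts <- function(codon_aln) {
  per <- ng_sites_per_seq(codon_aln)
  list(syn_sites = mean(per[, "syn"]), nonsyn_sites = mean(per[, "nonsyn"]))
}

# per-sequence NG site totals (n x 2 matrix)
ng_sites_per_seq <- function(codon_aln) {
  cd <- codon_array(codon_aln)
  uniq <- unique(as.vector(cd))
  tab <- vapply(uniq, ng_codon_sites, numeric(2L))
  syn <- matrix(tab[1L, match(cd, uniq)], nrow(cd))
  nonsyn <- matrix(tab[2L, match(cd, uniq)], nrow(cd))
  cbind(syn = rowSums(syn, na.rm = TRUE), nonsyn = rowSums(nonsyn, na.rm = TRUE))
}

#' Pathway-averaged codon differences (Nei-Gojobori)
#'
#' Averages synonymous/non-synonymous step counts over all orderings of
#' the single-nucleotide changes separating two codons (1, 2 or 6
#' pathways), excluding pathways passing through a stop codon.  If every
#' pathway passes through a stop, all pathways are used with a warning.
#'
#' @param codon_a,codon_b three-letter codons, neither a stop.
#' @return named vector \code{c(Nd, Ns)}; \code{Nd + Ns} equals the
#'   number of differing positions.
#' @export
ng_codon_differences <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "")[[1L]]; b <- strsplit(codon_b, "")[[1L]]
  pos <- which(a != b)
  if (length(pos) == 0L) return(c(Nd = 0, Ns = 0))
  paths <- ng_enumerate_paths(a, b, pos, skip_stops = TRUE)
  if (nrow(paths) == 0L) {
    warning("all mutational pathways between ", codon_a, " and ", codon_b,
            " pass through stop codons; including them")
    paths <- ng_enumerate_paths(a, b, pos, skip_stops = FALSE)
  }
  c(Nd = mean(paths[, 1L]), Ns = mean(paths[, 2L]))
}

# enumerate orderings of positions; each row = (nonsyn steps, syn steps)
ng_enumerate_paths <- function(a, b, pos, skip_stops = TRUE) {
  orders <- perms(pos)
  out <- matrix(0, 0L, 2L)
  for (r in seq_len(nrow(orders))) {
    cur <- a; nd <- ns <- 0; ok <- TRUE
    for (p in orders[r, ]) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (skip_stops && is_stop(c2)) { ok <- FALSE; break }
      if (GENETIC_CODE_TABLE[[c1]] == GENETIC_CODE_TABLE[[c2]])
        ns <- ns + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) out <- rbind(out, c(nd, ns))
  }
  out
}

perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

# pairwise syn/nonsyn difference totals for one sequence pair of codons;
# codons with N in either sequence are skipped
ng_pair_differences <- function(codons_a, codons_b) {
  nd <- ns <- 0
  for (j in seq_along(codons_a)) {
    ca <- codons_a[j]; cb <- codons_b[j]
    if (ca == cb) next
    if (grepl("N", ca, fixed = TRUE) || grepl("N", cb, fixed = TRUE)) next
    d <- ng_codon_differences(ca, cb)
    nd <- nd + d[["Nd"]]; ns <- ns + d[["Ns"]]
  }
  c(Nd = nd, Ns = ns)
}

#' Synonymous and non-synonymous nucleotide diversity
#'
#' For every sequence pair, synonymous (Ns) and non-synonymous (Nd)
#' differences are summed over codons by Nei-Gojobori pathway averaging
#' and divided by the pair-averaged synonymous / non-synonymous site
#' counts; the per-pair proportions (optionally Jukes-Cantor corrected)
#' are then averaged.
#'
#' @param codon_aln a \code{codon_aln}, n >= 2.
#' @param jc apply the Jukes-Cantor correction per pair.
#' @return list with \code{pi_S} and \code{pi_A}.
#' @export
pi_syn_nonsyn <- function(codon_aln, jc = FALSE) {
  cd <- codon_array(codon_aln)
  if (nrow(cd) < 2L) stop("pi_S/pi_A require n >= 2 sequences")
  sites <- ng_sites_per_seq(codon_aln)
  n <- nrow(cd)
  pS <- pA <- numeric(0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- ng_pair_differences(cd[i, ], cd[j, ])
    ssites <- (sites[i, "syn"] + sites[j, "syn"]) / 2
    asites <- (sites[i, "nonsyn"] + sites[j, "nonsyn"]) / 2
    pS <- c(pS, d[["Ns"]] / ssites)
    pA <- c(pA, d[["Nd"]] / asites)
  }
  if (jc) { pS <- jukes_cantor(pS); pA <- jukes_cantor(pA) }
  list(pi_S = mean(pS), pi_A = mean(pA))
}

#' Synonymous and non-synonymous divergence against a comparator
#'
#' Mean over all (focal, comparator) sequence pairs of the per-site
#' synonymous (K_S) and non-synonymous (K_A) distances, Nei-Gojobori
#' counted and optionally Jukes-Cantor corrected per pair.
#'
#' @param codon_aln focal \code{codon_aln}.
#' @param comparator nucleotide \code{aln} of >= 1 outgroup/ancestral
#'   sequences aligned to the same columns.
#' @param jc apply the Jukes-Cantor correction.
#' @return list with \code{K_S} and \code{K_A}.
#' @export
ka_ks <- function(codon_aln, comparator, jc = TRUE) {
  if (length(comparator) < 1L) stop("comparator alignment is empty")
  if (aln_width(comparator) != aln_width(codon_aln$aln))
    stop("comparator must be aligned to the same columns")
  comp <- codon_alignment(comparator, codon_aln$frame_offset,
                          allow_stops = TRUE)
  cd_f <- codon_array(codon_aln); cd_o <- codon_array(comp)
  s_f <- ng_sites_per_seq(codon_aln); s_o <- ng_sites_per_seq(comp)
  KS <- KA <- numeric(0L)
  for (i in seq_len(nrow(cd_f))) for (j in seq_len(nrow(cd_o))) {
    d <- ng_pair_differences(cd_f[i, ], cd_o[j, ])
    ssites <- (s_f[i, "syn"] + s_o[j, "syn"]) / 2
    asites <- (s_f[i, "nonsyn"] + s_o[j, "nonsyn"]) / 2
    KS <- c(KS, d[["Ns"]] / ssites)
    KA <- c(KA, d[["Nd"]] / asites)
  }
  if (jc) { KS <- jukes_cantor(KS); KA <- jukes_cantor(KA) }
  list(K_S = mean(KS), K_A = mean(KA))
}

# fractional per-codon polymorphic mutation counts, classified syn/nonsyn:
# the most frequent codon (lexicographic tie-break) is the reference and
# every other distinct codon contributes its pathway-averaged Nd/Ns
codon_poly_fractions <- function(codon_col) {
  codon_col <- codon_col[!grepl("N", codon_col)]
  tab <- sort(table(codon_col), decreasing = TRUE)
  if (length(tab) < 2L) return(c(Nd = 0, Ns = 0))
  top <- max(tab)
  ref <- sort(names(tab)[tab == top])[1L]
  nd <- ns <- 0
  for (cdn in setdiff(names(tab), ref)) {
    d <- ng_codon_differences(ref, cdn)
    nd <- nd + d[["Nd"]]; ns <- ns + d[["Ns"]]
  }
  c(Nd = nd, Ns = ns)
}

# largest-remainder rounding of a fractional vector to integers summing
# to round(sum(x))
largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Synonymous / non-synonymous segregating mutation counts
#'
#' Classifies the mutations segregating in a codon alignment by
#' Nei-Gojobori pathway logic (consensus-referenced, fractional for
#' multi-hit codons).
#'
#' @param codon_aln a \code{codon_aln}.
#' @param integer_counts round the fractional class totals to integers
#'   by largest remainder (default TRUE).
#' @return list with \code{syn_mut} and \code{nonsyn_mut}.
#' @export
classify_segregating_mutations <- function(codon_aln, integer_counts = TRUE) {
  cd <- codon_array(codon_aln)
  frac <- c(Nd = 0, Ns = 0)
  for (j in seq_len(ncol(cd))) frac <- frac + codon_poly_fractions(cd[, j])
  if (integer_counts) {
    r <- largest_remainder(c(frac[["Ns"]], frac[["Nd"]]))
    list(syn_mut = r[1L], nonsyn_mut = r[2L])
  } else {
    list(syn_mut = frac[["Ns"]], nonsyn_mut = frac[["Nd"]])
  }
}

#' Full diversity summary of a coding alignment
#'
#' One row of the standard polymorphism/divergence report: sample size,
#' site spectrum, pi, synonymous and non-synonymous mutation counts,
#' pi_S/pi_A and (when a comparator is supplied) K_S/K_A.
#'
#' @param codon_aln focal \code{codon_aln}.
#' @param comparator optional comparator \code{aln} for divergence.
#' @param jc Jukes-Cantor correct pi, pi_S, pi_A, K_S, K_A.
#' @return list of statistics (ratios NA when a denominator is 0).
#' @export
diversity_summary <- function(codon_aln, comparator = NULL, jc = TRUE) {
  aln <- codon_aln$aln
  sp <- site_spectrum(aln)
  pi <- nucleotide_diversity(aln, jc = jc)
  cls <- classify_segregating_mutations(codon_aln)
  pp <- pi_syn_nonsyn(codon_aln, jc = jc)
  out <- list(n = length(aln), S = sp$S, singletons = sp$singletons,
              parsimony_informative = sp$parsimony_informative,
              pi = pi, eta = sp$eta,
              syn_mut = cls$syn_mut, nonsyn_mut = cls$nonsyn_mut,
              pi_S = pp$pi_S, pi_A = pp$pi_A,
              pi_A_pi_S = safe_ratio(pp$pi_A, pp$pi_S),
              K_S = NA_real_, K_A = NA_real_, K_A_K_S = NA_real_,
              jc_corrected = jc)
  if (!is.null(comparator)) {
    k <- ka_ks(codon_aln, comparator, jc = jc)
    out$K_S <- k$K_S; out$K_A <- k$K_A
    out$K_A_K_S <- safe_ratio(k$K_A, k$K_S)
  }
  out
}

safe_ratio <- function(num, den) if (!is.na(den) && den > 0) num / den else NA_real_
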