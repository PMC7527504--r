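## Frequency-spectrum neutrality tests (Tajima's D; Fu & Li's D* and F*,
## the no-outgroup "star" variants) and the McDonald-Kreitman
## polymorphism-versus-divergence test.

# Tajima (1989) variance coefficients
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from sample size, segregating-site count and mean pairwise
# differences; S may be fractional (site-class partitions)
tajima_D_stat <- function(n, S, k_hat) {
  if (S <= 0) return(NA_real_)
  cst <- tajima_constants(n)
  (k_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Standardised difference between the pairwise-diversity and the
#' segregating-site estimators of theta.  Undefined (NA) when there is
#' no polymorphism.
#'
#' @param aln gap-stripped nucleotide \code{aln}, n >= 2 (n >= 4
#'   recommended).
#' @return list with \code{n}, \code{S}, \code{k_hat}, \code{D} and
#'   \code{site_class = "all"}.
#' @export
tajima_D <- function(aln) {
  if (length(aln) < 2L) stop("Tajima's D requires n >= 2 sequences")
  sp <- site_spectrum(aln)
  k_hat <- mean_pairwise_differences(aln)
  list(n = length(aln), S = sp$S, k_hat = k_hat,
       D = tajima_D_stat(length(aln), sp$S, k_hat), site_class = "all")
}

#' Tajima's D partitioned into synonymous and non-synonymous classes
#'
#' Class-specific segregating-mutation totals (Nei-Gojobori pathway
#' classification, fractional for multi-hit codons) and class-specific
#' mean pairwise difference sums are plugged into the standard D
#' formula.  A class with no mutations yields NA.
#'
#' @param codon_aln a \code{codon_aln}.
#' @return list with elements \code{syn} and \code{nonsyn}, each shaped
#'   like \code{\link{tajima_D}} output.
#' @export
tajima_D_partitioned <- function(codon_aln) {
  cd <- codon_array(codon_aln)
  n <- nrow(cd)
  cls <- classify_segregating_mutations(codon_aln, integer_counts = FALSE)
  sumNd <- sumNs <- 0
  npair <- n * (n - 1) / 2
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- ng_pair_differences(cd[i, ], cd[j, ])
    sumNd <- sumNd + d[["Nd"]]; sumNs <- sumNs + d[["Ns"]]
  }
  k_syn <- sumNs / npair; k_nonsyn <- sumNd / npair
  list(
    syn = list(n = n, S = cls$syn_mut, k_hat = k_syn,
               D = tajima_D_stat(n, cls$syn_mut, k_syn),
               site_class = "synonymous"),
    nonsyn = list(n = n, S = cls$nonsyn_mut, k_hat = k_nonsyn,
                  D = tajima_D_stat(n, cls$nonsyn_mut, k_nonsyn),
                  site_class = "nonsynonymous"))
}

# Fu & Li (1993) star-variant coefficients with the Simonsen et al.
# (1995) corrections
fu_li_constants <- function(n) {
  i <- seq_len(n - 1L)
  an <- sum(1 / i); bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, cn = cn, dn = dn,
       uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu & Li's D* and F* (no outgroup)
#'
#' Singleton-based neutrality statistics: eta is the total mutation
#' count, eta_s the mutations carried by exactly one sequence.  Negative
#' values indicate an excess of singletons.  Undefined (NA) when
#' eta = 0.
#'
#' @param aln gap-stripped nucleotide \code{aln}, n >= 3.
#' @return list with \code{n}, \code{eta}, \code{eta_s}, \code{D_star},
#'   \code{F_star}.
#' @export
fu_li <- function(aln) {
  n <- length(aln)
  if (n < 3L) stop("Fu & Li's D*/F* require n >= 3 sequences")
  sp <- site_spectrum(aln)
  eta <- sp$eta; eta_s <- sp$eta_singletons
  if (eta == 0L)
    return(list(n = n, eta = 0L, eta_s = 0L,
                D_star = NA_real_, F_star = NA_real_))
  cst <- fu_li_constants(n)
  pi_hat <- mean_pairwise_differences(aln)
  D_star <- (n / (n - 1) * eta - cst$an * eta_s) /
    sqrt(cst$uD * eta + cst$vD * eta^2)
  F_star <- (pi_hat - (n - 1) / n * eta_s) /
    sqrt(cst$uF * eta + cst$vF * eta^2)
  list(n = n, eta = eta, eta_s = eta_s, D_star = D_star, F_star = F_star)
}

#' Assemble a McDonald-Kreitman 2x2 table from counts
#'
#' @param f_S,f_A fixed synonymous / non-synonymous differences.
#' @param P_S,P_A polymorphic synonymous / non-synonymous mutations.
#' @return list with the counts, \code{ratio_fixed} (f_A/f_S),
#'   \code{ratio_poly} (P_A/P_S), \code{neutrality_index}
#'   (ratio_poly/ratio_fixed) and \code{p_value} (two-sided Fisher
#'   exact); ratios are NA when a denominator is zero.
#' @export
mk_table <- function(f_S, f_A, P_S, P_A) {
  counts <- c(f_S = f_S, f_A = f_A, P_S = P_S, P_A = P_A)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("MK counts must be non-negative integers")
  ratio_fixed <- safe_ratio(f_A, f_S)
  ratio_poly <- safe_ratio(P_A, P_S)
  ni <- if (!is.na(ratio_fixed) && !is.na(ratio_poly) && ratio_fixed > 0)
    ratio_poly / ratio_fixed else NA_real_
  p <- if (sum(counts) > 0)
    stats::fisher.test(matrix(c(f_S, f_A, P_S, P_A), 2L))$p.value
  else NA_real_
  list(f_S = as.integer(f_S), f_A = as.integer(f_A),
       P_S = as.integer(P_S), P_A = as.integer(P_A),
       ratio_fixed = ratio_fixed, ratio_poly = ratio_poly,
       neutrality_index = ni, p_value = p)
}

#' McDonald-Kreitman test
#'
#' Contrasts fixed interspecific differences with intraspecific
#' polymorphism at synonymous and non-synonymous positions.  A codon is
#' polymorphic when variable within the focal sample (whatever the
#' outgroup shows); fixed when the focal sample is monomorphic and
#' differs from the outgroup consensus codon.  Mutations are typed by
#' Nei-Gojobori pathway averaging; fractional class totals are rounded
#' by largest remainder.
#'
#' @param codon_aln focal \code{codon_aln}, n >= 2.
#' @param outgroup nucleotide \code{aln} aligned to the same columns.
#' @param test \code{"fisher"} (default) or \code{"gtest"}.
#' @return an MK table as from \code{\link{mk_table}}, with the chosen
#'   test's p-value.
#' @export
mk_test <- function(codon_aln, outgroup, test = c("fisher", "gtest")) {
  test <- match.arg(test)
  if (missing(outgroup) || is.null(outgroup) || length(outgroup) < 1L)
    stop("the MK test requires an outgroup alignment")
  if (aln_width(outgroup) != aln_width(codon_aln$aln))
    stop("outgroup must be aligned to the same columns")
  og <- codon_alignment(outgroup, codon_aln$frame_offset, allow_stops = TRUE)
  cd <- codon_array(codon_aln); cdo <- codon_array(og)
  fix <- c(Nd = 0, Ns = 0); poly <- c(Nd = 0, Ns = 0)
  for (j in seq_len(ncol(cd))) {
    focal <- cd[, j][!grepl("N", cd[, j])]
    if (length(focal) == 0L) next
    if (length(unique(focal)) > 1L) {
      poly <- poly + codon_poly_fractions(cd[, j])
    } else {
      oc <- codon_consensus(cdo[, j])
      if (!is.na(oc) && oc != focal[1L] &&
          !grepl("N", oc, fixed = TRUE)) {
        d <- tryCatch(ng_codon_differences(focal[1L], oc),
                      error = function(e) c(Nd = NA_real_, Ns = NA_real_))
        if (!anyNA(d)) fix <- fix + d
      }
    }
  }
  rf <- largest_remainder(c(fix[["Ns"]], fix[["Nd"]]))
  rp <- largest_remainder(c(poly[["Ns"]], poly[["Nd"]]))
  out <- mk_table(rf[1L], rf[2L], rp[1L], rp[2L])
  if (test == "gtest") out$p_value <- g_test_2x2(out$f_S, out$f_A,
                                                 out$P_S, out$P_A)
  out
}

# majority-rule consensus codon of an outgroup column (lexicographic
# tie-break); NA when no usable codon
codon_consensus <- function(codons) {
  codons <- codons[!grepl("N", codons)]
  codons <- codons[!is_stop(codons)]
  if (length(codons) == 0L) return(NA_character_)
  tab <- sort(table(codons), decreasing = TRUE)
  sort(names(tab)[tab == max(tab)])[1L]
}

# likelihood-ratio G test on a 2x2 with Williams correction
g_test_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  g <- 2 * sum(ifelse(m > 0, m * log(m / e), 0))
  N <- sum(m)
  q <- 1 + (N / rowSums(m)[1] + N / rowSums(m)[2] - 1) *
    (N / colSums(m)[1] + N / colSums(m)[2] - 1) / (6 * N)
  stats::pchisq(g / q, df = 1L, lower.tail = FALSE)
}
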