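## Microsatellite (SSR) locus diversity and composite
## linkage-disequilibrium scanning for diploid unphased genotypes.

#' Construct a diploid genotype table
#'
#' @param individuals character vector of unique ids.
#' @param calls named list, one element per locus: a matrix/data.frame
#'   with 2 columns of allele codes (character), NA for missing; one
#'   row per individual.  Both alleles of a call are missing together.
#' @param map optional named numeric vector of map positions (cM).
#' @return a \code{genotype_table}.
#' @export
genotype_table <- function(individuals, calls, map = NULL) {
  individuals <- as.character(individuals)
  if (length(individuals) < 2L) stop("need >= 2 individuals")
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  if (length(calls) < 1L) stop("need >= 1 locus")
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop("loci must be named")
  calls <- lapply(calls, function(x) {
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop("each locus needs exactly 2 allele columns")
    if (nrow(x) != length(individuals))
      stop("calls must have one row per individual")
    x <- matrix(as.character(x), ncol = 2L)
    half <- xor(is.na(x[, 1L]), is.na(x[, 2L]))
    if (any(half)) stop("half-missing genotype call at row ",
                        which(half)[1L])
    x
  })
  structure(list(individuals = individuals, loci = names(calls),
                 calls = calls, map = map), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype table: %d individuals x %d loci\n",
              length(x$individuals), length(x$loci)))
  invisible(x)
}

#' Read a genotype table from delimited text
#'
#' Expected layout: header row with locus names (each name once per
#' allele column, so each locus spans two adjacent columns), first
#' column the individual id, then two allele columns per locus.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param missing token encoding a missing allele (default "NA").
#' @return a \code{genotype_table}.
#' @export
read_genotypes <- function(path, sep = "\t", missing = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0L))
  if (ncol(df) < 3L || (ncol(df) - 1L) %% 2L != 0L)
    stop("expected an id column plus two columns per locus in ", path)
  ids <- df[[1L]]
  loci <- unique(names(df)[-1L])
  calls <- list()
  for (k in seq_along(loci)) {
    cols <- 1L + c(2L * k - 1L, 2L * k)
    m <- as.matrix(df[, cols])
    m[m == missing] <- NA_character_
    calls[[loci[k]]] <- m
  }
  genotype_table(ids, calls)
}

#' Write a genotype table to delimited text
#' @param gt a \code{genotype_table}.
#' @param path output path.
#' @param sep field separator.
#' @param missing missing-allele token.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gt, path, sep = "\t", missing = "NA") {
  out <- data.frame(id = gt$individuals, stringsAsFactors = FALSE)
  for (loc in gt$loci) {
    m <- gt$calls[[loc]]
    m[is.na(m)] <- missing
    out[[paste0(loc, ".1")]] <- m[, 1L]
    out[[paste0(loc, ".2")]] <- m[, 2L]
  }
  names(out) <- c("id", rep(gt$loci, each = 2L))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus diversity statistics
#'
#' Ao = distinct alleles; Ho = fraction of genotyped individuals that
#' are heterozygous; He = expected heterozygosity, by default Nei's
#' unbiased estimator (2n/(2n-1)) (1 - sum p_i^2); PD = power of
#' discrimination, 1 - sum over observed (unordered) genotype classes of
#' the squared genotype frequency.
#'
#' @param gt a \code{genotype_table}.
#' @param locus locus name.
#' @param unbiased use the unbiased He (default); FALSE gives plain
#'   1 - sum p_i^2.
#' @return list with \code{Ao}, \code{Ho}, \code{He}, \code{PD},
#'   \code{n} (genotyped individuals).
#' @export
locus_diversity <- function(gt, locus, unbiased = TRUE) {
  m <- gt$calls[[locus]]
  if (is.null(m)) stop("unknown locus: ", locus)
  ok <- !is.na(m[, 1L])
  if (!any(ok)) stop("locus ", locus, " has no genotyped individuals")
  m <- m[ok, , drop = FALSE]
  n <- nrow(m)
  alleles <- c(m[, 1L], m[, 2L])
  p <- table(alleles) / (2 * n)
  Ao <- length(p)
  Ho <- mean(m[, 1L] != m[, 2L])
  He <- 1 - sum(p^2)
  if (unbiased) He <- He * (2 * n) / (2 * n - 1)
  geno <- apply(m, 1L, function(r) paste(sort(r), collapse = "/"))
  g <- table(geno) / n
  PD <- 1 - sum(g^2)
  list(Ao = Ao, Ho = Ho, He = He, PD = PD, n = n)
}

#' Locus diversity summary table
#'
#' One row per locus plus an Average row, matching the usual SSR
#' characterisation report (Ao, Ho, He, PD).
#'
#' @param gt a \code{genotype_table}.
#' @param unbiased passed to \code{\link{locus_diversity}}.
#' @return data.frame with columns Locus, Ao, Ho, He, PD.
#' @export
ssr_diversity_table <- function(gt, unbiased = TRUE) {
  rows <- lapply(gt$loci, function(l) {
    d <- locus_diversity(gt, l, unbiased = unbiased)
    data.frame(Locus = l, Ao = d$Ao, Ho = d$Ho, He = d$He, PD = d$PD)
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(Locus = "Average", Ao = mean(tab$Ao), Ho = mean(tab$Ho),
                    He = mean(tab$He), PD = mean(tab$PD))
  rbind(tab, avg)
}

# allele frequencies at one locus over non-missing calls
allele_freqs <- function(m) {
  ok <- !is.na(m[, 1L])
  a <- c(m[ok, 1L], m[ok, 2L])
  table(a) / length(a)
}

#' Remove rare alleles ahead of LD analysis
#'
#' Calls carrying an allele with sample frequency strictly below
#' \code{min_freq} are set to missing (single pass; frequencies are not
#' recomputed afterwards).  Loci left monomorphic are flagged in the
#' \code{monomorphic} attribute and warned about.
#'
#' @param gt a \code{genotype_table}.
#' @param min_freq frequency threshold (default 0.05); alleles at
#'   exactly \code{min_freq} are retained.
#' @return filtered \code{genotype_table}.
#' @export
rare_allele_filter <- function(gt, min_freq = 0.05) {
  mono <- character(0L)
  for (loc in gt$loci) {
    m <- gt$calls[[loc]]
    p <- allele_freqs(m)
    rare <- names(p)[p < min_freq]
    if (length(rare)) {
      hit <- m[, 1L] %in% rare | m[, 2L] %in% rare
      m[hit, ] <- NA_character_
      gt$calls[[loc]] <- m
    }
    left <- allele_freqs(m)
    if (length(left) < 2L) mono <- c(mono, loc)
  }
  if (length(mono))
    warning("monomorphic after rare-allele filtering (excluded from LD): ",
            paste(mono, collapse = ", "))
  attr(gt, "monomorphic") <- mono
  gt
}

# n x (alleles) dosage matrix for one locus (0/1/2 copies), NA rows for
# missing calls
dosage_matrix <- function(m) {
  p <- allele_freqs(m)
  al <- names(p)
  n <- nrow(m)
  X <- matrix(NA_real_, n, length(al), dimnames = list(NULL, al))
  ok <- !is.na(m[, 1L])
  for (k in seq_along(al))
    X[ok, k] <- (m[ok, 1L] == al[k]) + (m[ok, 2L] == al[k])
  X
}

#' Composite linkage-disequilibrium scan
#'
#' For every locus pair and every allele pair, the composite
#' (unphased-genotype) squared correlation r^2: the squared Pearson
#' correlation between the two alleles' diploid dosage vectors (Weir's
#' composite disequilibrium normalised by the observed dosage
#' variances, which reduces to Delta^2 / (p(1-p)q(1-q)) under
#' Hardy-Weinberg proportions).  Significance per allele pair comes
#' from a seeded permutation of individuals' genotypes at one locus
#' (default) or the chi-square approximation n r^2 ~ chi^2_1.
#' Locus-pair P = Bonferroni-adjusted minimum allele-pair P.
#'
#' @param gt a \code{genotype_table} (typically rare-allele filtered).
#' @param alpha significance level for the summaries (default 0.05).
#' @param n_perm permutations per locus pair (default 1000; < 100 warns).
#' @param seed RNG seed, required when \code{method = "permutation"}.
#' @param method \code{"permutation"} (default) or \code{"chisq"}.
#' @return an \code{ld_result}: list with \code{allele_pairs}
#'   (data.frame locus1, locus2, allele1, allele2, r2, p),
#'   \code{locus_pairs} (locus1, locus2, r2 frequency-weighted mean, p,
#'   significant), \code{pct_significant_locus_pairs},
#'   \code{pct_significant_allele_pairs}, \code{alpha}.
#' @export
ld_scan <- function(gt, alpha = 0.05, n_perm = 1000L, seed = NULL,
                    method = c("permutation", "chisq")) {
  method <- match.arg(method)
  if (method == "permutation") {
    if (is.null(seed)) stop("seed required for permutation testing")
    if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values")
    set.seed(seed)
  }
  keep <- setdiff(gt$loci, attr(gt, "monomorphic"))
  keep <- keep[vapply(keep, function(l)
    length(allele_freqs(gt$calls[[l]])) >= 2L, TRUE)]
  if (length(keep) < 2L) stop("need >= 2 polymorphic loci for LD")
  ap <- list(); lp <- list()
  for (i in seq_len(length(keep) - 1L)) for (j in (i + 1L):length(keep)) {
    l1 <- keep[i]; l2 <- keep[j]
    X <- dosage_matrix(gt$calls[[l1]])
    Y <- dosage_matrix(gt$calls[[l2]])
    ok <- stats::complete.cases(X) & stats::complete.cases(Y)
    X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
    vX <- apply(X, 2L, stats::var) > 0
    vY <- apply(Y, 2L, stats::var) > 0
    X <- X[, vX, drop = FALSE]; Y <- Y[, vY, drop = FALSE]
    if (ncol(X) == 0L || ncol(Y) == 0L || nrow(X) < 3L) next
    robs <- suppressWarnings(stats::cor(X, Y))
    robs[is.na(robs)] <- 0
    if (method == "permutation") {
      # mid-P over the permutation distribution: ties between permuted
      # and observed |r| (frequent with discrete dosages) count half,
      # keeping the null P close to uniform
      greater <- equal <- matrix(0, nrow(robs), ncol(robs))
      for (b in seq_len(n_perm)) {
        rp <- suppressWarnings(stats::cor(X, Y[sample.int(nrow(Y)), ,
                                               drop = FALSE]))
        rp[is.na(rp)] <- 0
        greater <- greater + (abs(rp) > abs(robs) + 1e-12)
        equal <- equal + (abs(abs(rp) - abs(robs)) <= 1e-12)
      }
      P <- (greater + 0.5 * equal + 0.5) / (n_perm + 1)
    } else {
      P <- stats::pchisq(nrow(X) * robs^2, df = 1L, lower.tail = FALSE)
    }
    r2 <- robs^2
    pa <- colMeans(X) / 2; pb <- colMeans(Y) / 2
    wt <- outer(pa, pb)
    ap[[length(ap) + 1L]] <- data.frame(
      locus1 = l1, locus2 = l2,
      allele1 = rep(rownames(r2), ncol(r2)),
      allele2 = rep(colnames(r2), each = nrow(r2)),
      r2 = as.vector(r2), p = as.vector(P), stringsAsFactors = FALSE)
    # effective independent tests: allele-pair correlations of a k x l
    # allele system have rank (k-1)(l-1); plain #pairs over-corrects
    # (for two biallelic loci all four |r| are identical)
    n_tests <- max(1L, (ncol(X) - 1L) * (ncol(Y) - 1L))
    lp[[length(lp) + 1L]] <- data.frame(
      locus1 = l1, locus2 = l2,
      r2 = sum(wt * r2) / sum(wt),
      p = min(1, min(P) * n_tests), stringsAsFactors = FALSE)
  }
  allele_pairs <- do.call(rbind, ap)
  locus_pairs <- do.call(rbind, lp)
  locus_pairs$significant <- locus_pairs$p < alpha
  structure(list(
    allele_pairs = allele_pairs, locus_pairs = locus_pairs,
    pct_significant_locus_pairs = 100 * mean(locus_pairs$significant),
    pct_significant_allele_pairs = 100 * mean(allele_pairs$p < alpha),
    alpha = alpha), class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf(
    "LD scan: %d locus pairs, %d allele pairs; %.1f%% locus pairs significant at alpha=%g\n",
    nrow(x$locus_pairs), nrow(x$allele_pairs),
    x$pct_significant_locus_pairs, x$alpha))
  invisible(x)
}

#' Export the locus-pair P-value matrix
#'
#' Writes a square locus-by-locus matrix of P values (diagonal 1) plus a
#' companion long-format table with significance stars.
#'
#' @param ld an \code{ld_result}.
#' @param path output TSV path for the matrix; the companion table goes
#'   to \code{paste0(path, ".pairs")}.
#' @return the matrix, invisibly.
#' @export
export_p_matrix <- function(ld, path) {
  loci <- unique(c(ld$locus_pairs$locus1, ld$locus_pairs$locus2))
  M <- matrix(1, length(loci), length(loci), dimnames = list(loci, loci))
  for (r in seq_len(nrow(ld$locus_pairs))) {
    p <- ld$locus_pairs$p[r]
    M[ld$locus_pairs$locus1[r], ld$locus_pairs$locus2[r]] <- p
    M[ld$locus_pairs$locus2[r], ld$locus_pairs$locus1[r]] <- p
  }
  utils::write.table(round(M, 6), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  comp <- ld$locus_pairs
  comp$star <- ifelse(comp$significant, "*", "")
  utils::write.table(comp, paste0(path, ".pairs"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(M)
}
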