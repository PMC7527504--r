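## Orchestration: one entry point per report table of the analysis
## (diversity, neutrality, tree + network + ages, SSR diversity + LD),
## each deterministic given its config and seed and emitting TSV.

round_col <- function(x, digits) ifelse(is.na(x), NA, round(x, digits))

#' Diversity report (one row per allele class)
#'
#' Runs the full polymorphism/divergence summary per coding alignment
#' and formats the standard column set: N, Poly.S, Sing, Par.Inf, pi, M,
#' Syn.M, N.Syn.M, piS, piA, piA/piS, KS, KA, KA/KS.  pi-family values
#' are rounded to 3 decimals, ratios to 2.
#'
#' @param groups named list of \code{codon_aln} objects (one per allele
#'   class).
#' @param comparator optional comparator \code{aln} for KA/KS.
#' @param jc Jukes-Cantor correct the pi/K family (default TRUE).
#' @param out optional TSV path.
#' @return data.frame, one row per class, input order.
#' @export
run_diversity <- function(groups, comparator = NULL, jc = TRUE, out = NULL) {
  rows <- list()
  for (nm in names(groups)) {
    ca <- groups[[nm]]
    if (length(ca$aln) < 2L) {
      warning("class ", nm, " has fewer than 2 sequences; skipped")
      next
    }
    s <- diversity_summary(ca, comparator = comparator, jc = jc)
    rows[[nm]] <- data.frame(
      Class = nm, N = s$n, Poly.S = s$S, Sing = s$singletons,
      Par.Inf = s$parsimony_informative, pi = round_col(s$pi, 3L),
      M = s$eta, Syn.M = s$syn_mut, N.Syn.M = s$nonsyn_mut,
      piS = round_col(s$pi_S, 3L), piA = round_col(s$pi_A, 3L),
      piA.piS = round_col(s$pi_A_pi_S, 2L),
      KS = round_col(s$K_S, 3L), KA = round_col(s$K_A, 3L),
      KA.KS = round_col(s$K_A_K_S, 2L))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  tab
}

#' Neutrality report (one row per allele class)
#'
#' McDonald-Kreitman counts and ratios plus Tajima's D (total and
#' partitioned) and Fu & Li's D*/F*.  MK columns are NA when no
#' outgroup is supplied; undefined statistics are NA, never 0.
#'
#' @param groups named list of \code{codon_aln} objects.
#' @param outgroup optional outgroup \code{aln} (enables MK).
#' @param out optional TSV path.
#' @return data.frame with columns Class, fS, fA, PS, PA, fA.fS, PA.PS,
#'   D_T, D_S, D_A, D_star, F_star.
#' @export
run_neutrality <- function(groups, outgroup = NULL, out = NULL) {
  rows <- list()
  for (nm in names(groups)) {
    ca <- groups[[nm]]
    td <- tajima_D(ca$aln)
    part <- tajima_D_partitioned(ca)
    fl <- if (length(ca$aln) >= 3L) fu_li(ca$aln)
          else list(D_star = NA_real_, F_star = NA_real_)
    mk <- if (!is.null(outgroup)) mk_test(ca, outgroup)
          else list(f_S = NA, f_A = NA, P_S = NA, P_A = NA,
                    ratio_fixed = NA_real_, ratio_poly = NA_real_)
    rows[[nm]] <- data.frame(
      Class = nm, fS = mk$f_S, fA = mk$f_A, PS = mk$P_S, PA = mk$P_A,
      fA.fS = round_col(mk$ratio_fixed, 2L),
      PA.PS = round_col(mk$ratio_poly, 2L),
      D_T = round_col(td$D, 2L), D_S = round_col(part$syn$D, 2L),
      D_A = round_col(part$nonsyn$D, 2L),
      D_star = round_col(fl$D_star, 2L),
      F_star = round_col(fl$F_star, 2L))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  tab
}

#' Tree, network and rho/age report
#'
#' Builds the bootstrap-annotated Poisson/UPGMA protein tree, the
#' median-joining network of the nucleotide haplotypes, and (when
#' ancestors are designated) a rho/age table at mutation rate \code{mu}.
#'
#' @param prot_aln protein \code{aln} for the tree.
#' @param nuc_aln nucleotide \code{aln} for the network.
#' @param ancestors optional named list: ancestor node id -> character
#'   vector of descendant node ids.
#' @param replicates bootstrap replicates (default 500).
#' @param epsilon network relaxation (default 0).
#' @param mu mutation rate, mutations per year (default 1e-3).
#' @param seed RNG seed for the bootstrap.
#' @param out_dir optional output directory (writes tree.nwk,
#'   network.tsv, network_nodes.tsv, network.graphml, ages.tsv).
#' @return list with \code{tree}, \code{network}, \code{ages}
#'   (data.frame or NULL).
#' @export
run_tree_network <- function(prot_aln, nuc_aln, ancestors = NULL,
                             replicates = 500L, epsilon = 0, mu = 1e-3,
                             seed = 1L, out_dir = NULL) {
  tree <- bootstrap_upgma(prot_aln, replicates = replicates, seed = seed)
  net <- median_joining_network(nuc_aln, epsilon = epsilon)
  ages <- NULL
  if (!is.null(ancestors)) {
    rows <- lapply(names(ancestors), function(a) {
      r <- rho_age(net, a, ancestors[[a]], mu = mu)
      data.frame(ancestor = a,
                 descendants = paste(r$descendants, collapse = ","),
                 rho = r$rho, mu = mu, age_years = r$age_years)
    })
    ages <- do.call(rbind, rows)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    write_network_tsv(net, file.path(out_dir, "network.tsv"),
                      file.path(out_dir, "network_nodes.tsv"))
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    if (!is.null(ages))
      utils::write.table(ages, file.path(out_dir, "ages.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  list(tree = tree, network = net, ages = ages)
}

#' SSR diversity and LD report
#'
#' Per-locus diversity table (with Average row) and, after rare-allele
#' filtering, the composite-LD locus-pair P matrix.
#'
#' @param gt a \code{genotype_table}.
#' @param min_allele_freq rare-allele threshold for LD (default 0.05).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed for the permutation test.
#' @param out_dir optional output directory (diversity.tsv,
#'   p_matrix.tsv).
#' @return list with \code{diversity} (data.frame) and \code{ld}
#'   (\code{ld_result} or NULL when too few polymorphic loci remain).
#' @export
run_ssr <- function(gt, min_allele_freq = 0.05, alpha = 0.05,
                    n_perm = 1000L, seed = 1L, out_dir = NULL) {
  div <- ssr_diversity_table(gt)
  filt <- rare_allele_filter(gt, min_freq = min_allele_freq)
  ld <- tryCatch(ld_scan(filt, alpha = alpha, n_perm = n_perm, seed = seed),
                 error = function(e) {
                   warning("LD scan skipped: ", conditionMessage(e))
                   NULL
                 })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    div_out <- div
    div_out[-1L] <- lapply(div_out[-1L], function(x) round(x, 2L))
    utils::write.table(div_out, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ld))
      export_p_matrix(ld, file.path(out_dir, "p_matrix.tsv"))
  }
  list(diversity = div, ld = ld)
}
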