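# Independent brute-force oracles used across the suite.  These are
# written from first principles and deliberately share no code with the
# package implementation.

GC <- Biostrings::GENETIC_CODE
STOPS <- names(GC)[GC == "*"]
CODONS61 <- setdiff(names(GC)[!grepl("[^ACGT]", names(GC))], STOPS)

# recursive enumeration of every mutational ordering between two codons,
# tracking syn/nonsyn steps and whether a stop is crossed
oracle_codon_paths <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  res <- list()
  recurse <- function(cur, remaining, nd, ns, through_stop) {
    if (length(remaining) == 0) {
      res[[length(res) + 1]] <<- c(nd = nd, ns = ns, stop = through_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- bv[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      hit_stop <- through_stop || c2 %in% STOPS
      step_syn <- GC[[c1]] == GC[[c2]]
      recurse(nxt, setdiff(remaining, p),
              nd + ifelse(step_syn, 0, 1), ns + ifelse(step_syn, 1, 0),
              hit_stop)
    }
  }
  pos <- which(av != bv)
  if (length(pos) == 0) return(matrix(c(0, 0, 0), 1,
                                      dimnames = list(NULL, c("nd", "ns", "stop"))))
  recurse(av, pos, 0, 0, FALSE)
  do.call(rbind, res)
}

oracle_ng_diff <- function(a, b) {
  paths <- oracle_codon_paths(a, b)
  ok <- paths[, "stop"] == 0
  if (any(ok)) paths <- paths[ok, , drop = FALSE]
  c(Nd = mean(paths[, "nd"]), Ns = mean(paths[, "ns"]))
}

# two-sided Fisher exact P by full hypergeometric enumeration over
# tables with the observed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)), 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# union of all minimum spanning trees by exhaustive enumeration of
# spanning edge subsets (feasible for <= 7 nodes)
oracle_mst_union <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf; trees <- list()
  for (comb in utils::combn(m, n - 1, simplify = FALSE)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs[comb, , drop = FALSE]))
    if (igraph::components(g)$no != 1) next
    w <- sum(d[pairs[comb, , drop = FALSE]])
    if (w < best - 1e-9) { best <- w; trees <- list(comb) }
    else if (abs(w - best) <= 1e-9) trees[[length(trees) + 1]] <- comb
  }
  edges <- unique(do.call(rbind, lapply(trees, function(comb)
    pairs[comb, , drop = FALSE])))
  list(edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
       weight = best)
}

# random in-frame stop-free codon alignment
random_codon_aln <- function(n, n_codons, seed) {
  set.seed(seed)
  m <- replicate(n, paste(sample(CODONS61, n_codons, replace = TRUE),
                          collapse = ""))
  codon_alignment(alignment(paste0("s", seq_len(n)), m))
}
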