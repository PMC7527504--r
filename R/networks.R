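## Minimum-spanning and median-joining haplotype networks on Hamming
## distances, rho-statistic dating, and network export.

hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# collapse identical sequences; representative id = first occurrence,
# members lists every sequence id carried by the node
collapse_haplotypes <- function(aln) {
  first <- !duplicated(aln$seq)
  hap_seq <- aln$seq[first]
  hap_id <- aln$id[first]
  members <- vapply(hap_seq, function(s)
    paste(aln$id[aln$seq == s], collapse = ","), "")
  mult <- vapply(hap_seq, function(s) sum(aln$seq == s), 0L)
  data.frame(id = hap_id, seq = hap_seq, multiplicity = as.integer(mult),
             members = unname(members), type = "observed",
             stringsAsFactors = FALSE)
}

# epsilon-relaxed minimum spanning network over a set of sequences:
# edge (u,v,w) is kept iff u and v are not connected by edges of weight
# < w - epsilon (epsilon = 0 gives the union of all MSTs)
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(data.frame(from = integer(), to = integer(),
                                weight = integer()))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    limit <- w[r] - epsilon
    sub <- pairs[w < limit - 1e-9, , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(sub))
      g <- igraph::add_edges(g, t(sub))
    comp <- igraph::components(g)$membership
    keep[r] <- comp[pairs[r, 1L]] != comp[pairs[r, 2L]]
  }
  data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
             weight = as.integer(w[keep]))
}

#' Minimum spanning network of haplotypes
#'
#' Identical sequences are collapsed into one node with multiplicity;
#' the network is the union of all minimum spanning trees over Hamming
#' distances, relaxed by \code{epsilon}: a link of weight w is kept when
#' its endpoints are not already connected by links of weight
#' < w - epsilon.
#'
#' @param haplotypes gap-stripped nucleotide \code{aln}.
#' @param epsilon relaxation (mutational units), default 0.
#' @return a \code{hap_network}: list with \code{nodes} (id, seq,
#'   multiplicity, members, type), \code{edges} (from, to, weight as
#'   node ids) and \code{total_mutation_length} (weight of a minimum
#'   spanning tree of the network).
#' @export
minimum_spanning_network <- function(haplotypes, epsilon = 0) {
  nodes <- collapse_haplotypes(haplotypes)
  d <- hamming_matrix(nodes$seq)
  ed <- msn_edges(d, epsilon)
  build_network(nodes, ed)
}

build_network <- function(nodes, ed) {
  edges <- data.frame(from = nodes$id[ed$from], to = nodes$id[ed$to],
                      weight = ed$weight, stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges), class = "hap_network")
  net$total_mutation_length <- spanning_length(net)
  net
}

# weight of a minimum spanning tree of the network graph
spanning_length <- function(net) {
  if (nrow(net$edges) == 0L) return(0L)
  g <- network_graph(net)
  as.integer(sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight))
}

network_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf(
    "haplotype network: %d nodes (%d median), %d edges, spanning length %d\n",
    nrow(x$nodes), sum(x$nodes$type == "median"), nrow(x$edges),
    x$total_mutation_length))
  invisible(x)
}

# majority-consensus median of three sequences; site ties (all three
# states distinct) keep the first sequence's state
median_vector <- function(s1, s2, s3) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  c3 <- strsplit(s3, "")[[1L]]
  out <- a
  for (k in seq_along(a)) {
    st <- c(a[k], b[k], c3[k])
    tab <- sort(table(st), decreasing = TRUE)
    out[k] <- if (max(tab) >= 2L) names(tab)[1L] else a[k]
  }
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Bandelt-style iteration: starting from the epsilon-relaxed minimum
#' spanning network, consensus (median) vectors of connected node
#' triplets are added whenever they shorten the connection (Steiner
#' improvement), the network is rebuilt, and unused medians are pruned;
#' iteration stops at a fixed point.  The exported edge set keeps the
#' minimum-spanning links among the observed haplotypes alongside the
#' links of the extended network, so the observed backbone remains a
#' subgraph.
#'
#' @param haplotypes gap-stripped nucleotide \code{aln}; variable sites
#'   must be A/C/G/T.
#' @param epsilon relaxation, default 0.
#' @param max_iter safety cap on median-addition rounds.
#' @return a \code{hap_network}; median nodes have
#'   \code{type = "median"} and multiplicity 0.
#' @export
median_joining_network <- function(haplotypes, epsilon = 0, max_iter = 25L) {
  m <- aln_matrix(haplotypes)
  variable <- apply(m, 2L, function(col) length(unique(col)) > 1L)
  if (any(!m[, variable, drop = FALSE] %in% c("A", "C", "G", "T")))
    stop("variable sites must be unambiguous A/C/G/T")
  obs <- collapse_haplotypes(haplotypes)
  # 1. generate candidate median vectors from connected triplets,
  #    iterating so medians of medians can arise
  pool_nodes <- obs
  candidates <- character(0L)
  for (iter in seq_len(max_iter)) {
    d <- hamming_matrix(pool_nodes$seq)
    ed <- msn_edges(d, epsilon)
    adj <- vector("list", nrow(pool_nodes))
    for (r in seq_len(nrow(ed))) {
      adj[[ed$from[r]]] <- c(adj[[ed$from[r]]], ed$to[r])
      adj[[ed$to[r]]] <- c(adj[[ed$to[r]]], ed$from[r])
    }
    added <- character(0L)
    for (v in seq_len(nrow(pool_nodes))) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      for (i in seq_len(length(nb) - 1L)) for (j in (i + 1L):length(nb)) {
        u <- nb[i]; w <- nb[j]
        med <- median_vector(pool_nodes$seq[v], pool_nodes$seq[u],
                             pool_nodes$seq[w])
        if (med %in% pool_nodes$seq || med %in% added) next
        star <- hd(med, pool_nodes$seq[v]) + hd(med, pool_nodes$seq[u]) +
          hd(med, pool_nodes$seq[w])
        if (star < d[u, v] + d[v, w]) added <- c(added, med)
      }
    }
    if (length(added) == 0L) break
    pool_nodes <- rbind(pool_nodes, data.frame(
      id = paste0("cand", length(candidates) + seq_along(added)),
      seq = added, multiplicity = 0L, members = "", type = "median",
      stringsAsFactors = FALSE))
    candidates <- c(candidates, added)
  }
  # 2. greedy admission: a median enters only while it strictly reduces
  #    the spanning-tree weight, so medians never increase cost
  mst_weight <- function(seqs) {
    d <- hamming_matrix(seqs)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
  }
  chosen <- character(0L)
  current <- mst_weight(obs$seq)
  pool <- setdiff(candidates, obs$seq)
  while (length(pool)) {
    gains <- vapply(pool, function(m)
      mst_weight(c(obs$seq, chosen, m)), 0)
    best <- which.min(gains)
    if (gains[best] >= current) break
    current <- gains[best]
    chosen <- c(chosen, pool[best])
    pool <- pool[-best]
  }
  nodes <- obs
  if (length(chosen))
    nodes <- rbind(nodes, data.frame(
      id = paste0("mv", seq_along(chosen)), seq = chosen,
      multiplicity = 0L, members = "", type = "median",
      stringsAsFactors = FALSE))
  # 3. prune medians left dangling in the final MSN
  repeat {
    d <- hamming_matrix(nodes$seq)
    ed <- msn_edges(d, epsilon)
    deg <- tabulate(c(ed$from, ed$to), nbins = nrow(nodes))
    drop <- which(nodes$type == "median" & deg <= 1L)
    if (length(drop) == 0L) break
    nodes <- nodes[-drop, , drop = FALSE]
  }
  # keep the observed-haplotype MSN backbone in the exported edge set
  net <- build_network(nodes, ed)
  obs_d <- hamming_matrix(obs$seq)
  obs_ed <- msn_edges(obs_d, epsilon)
  backbone <- data.frame(from = obs$id[obs_ed$from], to = obs$id[obs_ed$to],
                         weight = obs_ed$weight, stringsAsFactors = FALSE)
  all_e <- rbind(net$edges, backbone)
  key <- apply(all_e, 1L, function(r)
    paste(sort(c(r[["from"]], r[["to"]])), collapse = "\r"))
  net$edges <- all_e[!duplicated(key), , drop = FALSE]
  rownames(net$edges) <- NULL
  net$total_mutation_length <- spanning_length(net)
  net
}

hd <- function(s1, s2) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  sum(a != b)
}

#' Rho statistic and node age
#'
#' rho = mean shortest-path mutation count from an ancestral node to a
#' set of descendant nodes; the age in years is rho divided by the
#' mutation rate (mutations per year).
#'
#' @param net a \code{hap_network}.
#' @param ancestor node id.
#' @param descendants character vector of node ids.
#' @param mu mutation rate in mutations per year (default 1e-3).
#' @return list with \code{ancestor}, \code{descendants}, \code{rho},
#'   \code{mu}, \code{age_years}.
#' @export
rho_age <- function(net, ancestor, descendants, mu = 1e-3) {
  ids <- net$nodes$id
  missing_ids <- setdiff(c(ancestor, descendants), ids)
  if (length(missing_ids))
    stop("nodes not in network: ", paste(missing_ids, collapse = ", "),
         "; available: ", paste(ids, collapse = ", "))
  g <- network_graph(net)
  dist <- igraph::distances(g, v = ancestor, to = descendants,
                            weights = igraph::E(g)$weight)
  if (any(!is.finite(dist)))
    stop("descendant(s) unreachable from ", ancestor)
  rho <- mean(dist)
  list(ancestor = ancestor, descendants = descendants, rho = rho,
       mu = mu, age_years = rho / mu)
}

#' Write a haplotype network as TSV edge + node tables
#'
#' @param net a \code{hap_network}.
#' @param edge_path path for the edge list (source, target, weight).
#' @param node_path path for the node table (id, multiplicity, type,
#'   members).
#' @return \code{edge_path}, invisibly.
#' @export
write_network_tsv <- function(net, edge_path, node_path) {
  ed <- net$edges; names(ed) <- c("source", "target", "weight")
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes[, c("id", "multiplicity", "type", "members")],
                     node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}

#' Write a haplotype network as GraphML
#'
#' @param net a \code{hap_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(network_graph(net), path, format = "graphml")
  invisible(path)
}

#' Read a network edge list written by \code{write_network_tsv}
#'
#' @param edge_path edge TSV (source, target, weight).
#' @param node_path optional node TSV.
#' @return a \code{hap_network} (sequences absent).
#' @export
read_network_tsv <- function(edge_path, node_path = NULL) {
  ed <- utils::read.table(edge_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(ed) <- c("from", "to", "weight")
  nodes <- if (!is.null(node_path))
    utils::read.table(node_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(id = unique(c(ed$from, ed$to)), multiplicity = NA_integer_,
                  type = NA_character_, members = "",
                  stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = ed), class = "hap_network")
  net$total_mutation_length <- spanning_length(net)
  net
}
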