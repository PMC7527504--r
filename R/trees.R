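## Poisson-corrected protein distances and UPGMA clustering with
## bootstrap support.

#' Poisson-corrected amino-acid distance matrix
#'
#' d = -ln(1 - p) with p the proportion of differing residues per
#' sequence pair, in substitutions per site.  Ambiguous positions
#' (\code{-} or \code{X}) are removed per pair by default (pairwise
#' deletion); \code{deletion = "complete"} removes them globally first.
#'
#' @param prot_aln a protein \code{aln}.
#' @param deletion \code{"pairwise"} (default) or \code{"complete"}.
#' @return symmetric matrix with zero diagonal, labelled by sequence id.
#' @export
poisson_distance <- function(prot_aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (prot_aln$kind != "protein") stop("protein alignment required")
  m <- aln_matrix(prot_aln)
  if (deletion == "complete") {
    keep <- colSums(m == "-" | m == "X") == 0L
    if (!any(keep)) stop("no unambiguous columns left")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[i, ] != "X" & m[j, ] != "-" & m[j, ] != "X"
    if (!any(ok)) stop("no comparable sites between ", rownames(m)[i],
                       " and ", rownames(m)[j])
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    if (p >= 1) stop("Poisson distance undefined (p >= 1) between ",
                     rownames(m)[i], " and ", rownames(m)[j])
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

# UPGMA agglomeration.  Returns the merge history: per step the joined
# cluster member labels, the height, and the clade (sorted member set).
# Tie-break: the pair whose (sorted) representative labels are
# lexicographically smallest; a cluster is represented by its smallest
# member label.
upgma_merge <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("non-finite distances")
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2L) stop("UPGMA requires >= 2 labels")
  clusters <- lapply(labs, identity)          # member labels
  reps <- labs                                # representative = min label
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  newick <- labs
  dm <- d
  merges <- list()
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      dij <- dm[i, j]
      key <- paste(sort(c(reps[i], reps[j])), collapse = "\r")
      if (dij < best_d - 1e-12 ||
          (abs(dij - best_d) <= 1e-12 && !is.null(best_key) && key < best_key)) {
        best <- c(i, j); best_d <- dij; best_key <- key
      } else if (is.null(best)) {
        best <- c(i, j); best_d <- dij; best_key <- key
      }
    }
    i <- best[1L]; j <- best[2L]
    h <- best_d / 2
    bl_i <- h - heights[i]; bl_j <- h - heights[j]
    ord <- order(c(reps[i], reps[j]))
    parts <- c(sprintf("%s:%.17g", newick[i], bl_i),
               sprintf("%s:%.17g", newick[j], bl_j))[ord]
    k <- length(clusters) + 1L
    clusters[[k]] <- sort(c(clusters[[i]], clusters[[j]]))
    reps[k] <- min(reps[i], reps[j])
    sizes[k] <- sizes[i] + sizes[j]
    heights[k] <- h
    newick[k] <- paste0("(", parts[1L], ",", parts[2L], ")")
    merges[[length(merges) + 1L]] <-
      list(clade = clusters[[k]], height = h, node = k)
    # group-size-weighted average distances
    dm <- rbind(cbind(dm, 0), 0)
    for (m2 in active) {
      if (m2 == i || m2 == j) next
      dm[k, m2] <- dm[m2, k] <-
        (sizes[i] * dm[i, m2] + sizes[j] * dm[j, m2]) / (sizes[i] + sizes[j])
    }
    active <- c(setdiff(active, c(i, j)), k)
  }
  list(newick = newick[length(newick)], merges = merges,
       heights = heights, labels = labs)
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group agglomeration with arithmetic (group-size
#' weighted) average linkage; node height = joining distance / 2, so the
#' tree is ultrametric.  Ties are broken on the lexicographically
#' smallest pair of cluster labels for reproducibility.
#'
#' @param d symmetric distance matrix with labels as dimnames.
#' @return an \code{ape} \code{phylo} object (rooted, ultrametric), with
#'   attribute \code{clades}: the member-label set of each internal
#'   node, in merge order.
#' @export
upgma <- function(d) {
  res <- upgma_merge(d)
  tr <- ape::read.tree(text = paste0(res$newick, ";"))
  attr(tr, "clades") <- lapply(res$merges, `[[`, "clade")
  tr
}

#' UPGMA tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance UPGMA tree per replicate, and reports for each
#' internal node of the original tree the percentage of replicates
#' containing the same clade.
#'
#' @param prot_aln protein \code{aln} (>= 2 columns).
#' @param replicates bootstrap replicate count (default 500); 0 returns
#'   the tree without supports.
#' @param seed RNG seed (required when \code{replicates > 0}).
#' @param deletion ambiguity handling passed to
#'   \code{\link{poisson_distance}}.
#' @return a \code{phylo} tree whose \code{node.label} holds percentage
#'   supports (root label empty).
#' @export
bootstrap_upgma <- function(prot_aln, replicates = 500L, seed = NULL,
                            deletion = "pairwise") {
  d <- poisson_distance(prot_aln, deletion = deletion)
  res <- upgma_merge(d)
  tr <- ape::read.tree(text = paste0(res$newick, ";"))
  clades <- lapply(res$merges, `[[`, "clade")
  if (replicates > 0L) {
    if (is.null(seed)) stop("seed required for bootstrap resampling")
    set.seed(seed)
    keys <- vapply(clades, paste, "", collapse = "\r")
    counts <- setNames(numeric(length(keys)), keys)
    m <- aln_matrix(prot_aln)
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      ab <- aln_from_matrix(m[, cols, drop = FALSE], "protein")
      rb <- tryCatch(upgma_merge(poisson_distance(ab, deletion = deletion)),
                     error = function(e) NULL)
      if (is.null(rb)) next
      bk <- vapply(lapply(rb$merges, `[[`, "clade"), paste, "", collapse = "\r")
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
    support <- round(100 * counts / replicates, 1)
    # merge order is postorder of internal nodes as written in the
    # newick string; map clades to phylo node numbers by tip sets
    tr$node.label <- rep("", tr$Nnode)
    for (k in seq_along(clades)) {
      node <- match_clade_node(tr, clades[[k]])
      if (!is.na(node)) tr$node.label[node - length(tr$tip.label)] <-
          as.character(support[k])
    }
  }
  attr(tr, "clades") <- clades
  tr
}

# internal phylo node whose descendant tip set equals 'clade'
match_clade_node <- function(tr, clade) {
  ntip <- length(tr$tip.label)
  for (node in (ntip + 1L):(ntip + tr$Nnode)) {
    tips <- tr$tip.label[tip_descendants(tr, node)]
    if (length(tips) == length(clade) && setequal(tips, clade))
      return(node)
  }
  NA_integer_
}

tip_descendants <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tip_descendants, tr = tr))
}

#' Write a tree to Newick
#'
#' Supports (node labels) are preserved; branch lengths at 6 decimals.
#'
#' @param tree a \code{phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
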