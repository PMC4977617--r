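#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} is joined, with branch lengths
#' \eqn{v_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))} and \eqn{v_j = d_{ij} - v_i}.
#' Ties in Q are broken deterministically by the lexicographically smallest
#' pair of representative labels (the smallest leaf label in each subtree).
#' A negative branch length is clamped to zero and its deficit transferred to
#' the sister edge, so path lengths through the joined node are preserved.
#'
#' @param dm symmetric numeric matrix with labels as dimnames (e.g. from
#'   [genotypeDistance()] or [groupNeiDistance()]); must be complete and finite.
#' @return an unrooted \code{ape::phylo} tree.
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' neighborJoining(d)  # v_a = 1, v_b = 2, v_c = 3
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix must carry labels as dimnames")
  if (nrow(dm) < 3L) stop("need at least 3 labels")
  if (anyNA(dm) || any(!is.finite(dm)))
    stop("distance matrix has missing or infinite entries; impute or subset first")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  # active nodes: newick fragment + representative (minimal leaf) label
  frag <- quoteNewick(labels)
  rep_ <- labels
  d <- dm
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_[ij[1L]], rep_[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }   # clamp-and-transfer
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], vi, frag[j], vj)
    newrep <- min(rep_[i], rep_[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_ <- c(rep_[keep], newrep)
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  ape::read.tree(text = txt)
}

# Quote labels containing newick-reserved characters.
quoteNewick <- function(x) {
  bad <- grepl("[ ()\\[\\]:;,']", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Write a tree in newick format
#'
#' @param tree an \code{ape::phylo} tree.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bipartition a tree at its longest internal edge
#'
#' Cuts the tree at the longest internal (non-terminal) edge — or a supplied
#' edge index — and reports the two resulting leaf clusters, largest first.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param edge optional row index into \code{tree$edge}; default the longest
#'   internal edge (ties: first in edge order).
#' @return list(clusters = list of two character vectors, edge, length).
#' @export
clusterReport <- function(tree, edge = NULL) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > ntip)
  if (is.null(edge)) {
    if (!length(internal)) stop("tree has no internal edge")
    edge <- internal[which.max(tree$edge.length[internal])]
  }
  below <- tipsBelow(tree, tree$edge[edge, 2L])
  side1 <- tree$tip.label[below]
  side2 <- setdiff(tree$tip.label, side1)
  clusters <- list(side1, side2)[order(-c(length(side1), length(side2)))]
  list(clusters = clusters, edge = edge, length = tree$edge.length[edge])
}

# Tip indices in the clade below a node.
tipsBelow <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tipsBelow, tree = tree))
}
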