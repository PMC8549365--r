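# Rooted neighbour joining with non-negative branch clamping.
#
# Standard NJ agglomeration, modified so that no branch length is ever
# negative: whenever a branch estimate for one member of a joined pair comes
# out negative it is set to zero and the deficit moved to the sister branch,
# which preserves the tip-to-tip distance of the joined pair. The final join
# of the last two nodes is resolved into a root that splits the remaining
# distance equally, which is exact under the equal-branch-length assumption
# of the pairwise divergence estimates feeding the matrix.

#' Rooted neighbour joining with non-negative branches
#'
#' @param d symmetric numeric distance matrix (zero diagonal, non-negative
#'   entries, dimnames = tip labels), n >= 2.
#' @return a rooted binary tree of class \code{phylo} (package \pkg{ape})
#'   with non-negative branch lengths.
#' @export
rooted_nj <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) ct_error("invalid_matrix", "need at least two taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    ct_error("invalid_matrix", "distance matrix is not symmetric")
  if (any(d < 0)) ct_error("invalid_matrix", "negative distances")
  if (any(abs(diag(d)) > 1e-12)) ct_error("invalid_matrix", "non-zero diagonal")

  labels <- rownames(d)
  # active nodes are represented by their (parenthesised) newick fragments
  nwk <- labels
  active <- d
  while (nrow(active) > 2L) {
    m <- nrow(active)
    r <- rowSums(active)
    q <- (m - 2) * active - outer(r, r, `+`)
    diag(q) <- Inf
    # minimal Q; ties broken by lexicographic (row label, col label) order
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    lab <- cbind(rownames(active)[best[, 1]], rownames(active)[best[, 2]])
    ord <- order(lab[, 1], lab[, 2])
    i <- best[ord[1L], 1L]; j <- best[ord[1L], 2L]
    dij <- active[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    # clamp: preserve bi + bj = dij while forbidding negative lengths
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_d <- (active[i, ] + active[j, ] - dij) / 2
    new_d <- pmax(new_d, 0)[-c(i, j)]
    new_lab <- paste0("n", m)  # internal bookkeeping label, never emitted
    merged <- sprintf("(%s:%.17g,%s:%.17g)", nwk[i], bi, nwk[j], bj)
    keep <- setdiff(seq_len(m), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], new_d),
                    c(new_d, 0))
    rownames(active)[m - 1L] <- colnames(active)[m - 1L] <- new_lab
    nwk <- c(nwk[keep], merged)
  }
  d12 <- active[1L, 2L]
  tree <- ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                        nwk[1L], d12 / 2, nwk[2L], d12 / 2))
  if (length(tree$tip.label) > 2L) {
    # place the root at the midpoint of the longest tip-to-tip path: exact
    # under the clock assumption already made by the pairwise divergence
    # estimates (equal branch lengths to the MRCA), where the tree is
    # ultrametric and the midpoint is the true root; path lengths -- hence
    # patristic distances -- are unchanged by the re-rooting
    tree <- phangorn::midpoint(tree)
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Patristic distances between the tips of a tree
#'
#' Sums branch lengths along tip-to-tip paths.
#'
#' @param tree a \code{phylo} object.
#' @return symmetric numeric matrix over tip labels with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  as.matrix(stats::cophenetic(tree))
}

#' Write a tree as Newick
#'
#' @param tree a \code{phylo} object.
#' @param path file path.
#' @param digits significant digits for branch lengths (default 6).
#' @return \code{path}, invisibly.
#' @export
write_tree_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
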