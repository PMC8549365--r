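# Population-structure utilities: Lingoes correction, pairwise FST / PhiST,
# Mantel tests and minimum spanning networks.

#' Lingoes correction of a distance matrix
#'
#' Adds the smallest constant to all squared off-diagonal distances that
#' makes the matrix Euclidean-embeddable: if the Gower-centred matrix of
#' \code{-d^2/2} has smallest eigenvalue \code{-c < 0}, returns \code{d'}
#' with \code{d'^2 = d^2 + 2c} off-diagonal; otherwise returns \code{d}
#' unchanged.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param tol eigenvalue tolerance below which the matrix is already
#'   treated as Euclidean (default 1e-9, relative to the largest
#'   eigenvalue magnitude).
#' @return corrected distance matrix (same dimnames); attribute
#'   \code{lingoes_constant} carries the constant c applied (0 if none).
#' @export
lingoes_correct <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  G <- gower_center(d^2)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  cc <- -min(ev)
  if (cc <= tol * scale) {
    attr(d, "lingoes_constant") <- 0
    return(d)
  }
  d2 <- d^2 + 2 * cc
  diag(d2) <- 0
  out <- sqrt(d2)
  dimnames(out) <- dimnames(d)
  attr(out, "lingoes_constant") <- cc
  out
}

gower_center <- function(d2) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% d2 %*% J
}

#' Pairwise FST / PhiST between populations
#'
#' For every pair of populations, runs a two-level AMOVA and reports
#' \code{FST = sigma_among / (sigma_among + sigma_within)} with a p-value
#' from permuting reads between the two populations.
#'
#' In \code{"haplotype-frequency"} mode distances between distinct
#' haplotypes are set to 1 (conventional frequency-based FST); in
#' \code{"distance"} mode the supplied matrix is used, yielding PhiST.
#'
#' @param tab data frame with a population column, \code{haplotype_id} and
#'   \code{count}.
#' @param pop name of the population column.
#' @param d haplotype distance matrix; required in \code{"distance"} mode.
#' @param mode \code{"haplotype-frequency"} or \code{"distance"}.
#' @param n_perm permutations per pair (default 1000; 0 disables tests).
#' @param seed integer seed (required when \code{n_perm > 0}).
#' @return a list of class \code{fst_matrix}: \code{fst} and \code{p}
#'   (symmetric matrices over population labels), \code{mode}.
#' @export
pairwise_fst <- function(tab, pop, d = NULL,
                         mode = c("haplotype-frequency", "distance"),
                         n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c(pop, "haplotype_id", "count") %in% names(tab)))
  pops <- sort(unique(as.character(tab[[pop]])))
  if (length(pops) < 2L)
    ct_error("degenerate_design", "need at least two populations")
  haps <- sort(unique(tab$haplotype_id))
  if (mode == "haplotype-frequency") {
    d <- 1 - diag(length(haps))
    dimnames(d) <- list(haps, haps)
  } else if (is.null(d)) {
    ct_error("invalid_matrix", "mode 'distance' requires a distance matrix")
  }
  np <- length(pops)
  fst <- matrix(0, np, np, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  if (n_perm > 0) {
    if (is.null(seed)) ct_error("seed_required", "seed required for tests")
    set.seed(as.integer(seed))
  }
  for (i in seq_len(np - 1L)) {
    for (j in seq.int(i + 1L, np)) {
      sub <- tab[tab[[pop]] %in% pops[c(i, j)], , drop = FALSE]
      sub$._pop <- as.character(sub[[pop]])
      sizes <- tapply(sub$count, sub$._pop, sum)
      if (any(sizes < 2))
        ct_error("degenerate_design",
                 "each population needs at least two reads")
      prep <- amova_prep(sub, d, "._pop")
      obs <- amova_compute(prep$counts, prep$strata, prep$D2)
      stat <- obs$phi[1L]
      fst[i, j] <- fst[j, i] <- stat
      if (n_perm > 0) {
        exceed <- 0
        for (b in seq_len(n_perm)) {
          cts <- permute_reads(prep$counts)
          perm <- amova_compute(cts, prep$strata, prep$D2)
          if (perm$phi[1L] >= stat) exceed <- exceed + 1
        }
        pmat[i, j] <- pmat[j, i] <- (1 + exceed) / (n_perm + 1)
      }
    }
  }
  structure(list(fst = fst, p = pmat, mode = mode, n_perm = n_perm),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise %s (%s mode, %d permutations)\n",
              if (x$mode == "distance") "PhiST" else "FST",
              x$mode, x$n_perm))
  print(round(x$fst, digits))
  invisible(x)
}

#' Mantel test between two population-pair matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance from
#' permuting the row/column labels of the second matrix. For six or fewer
#' populations all permutations are enumerated exactly; otherwise
#' \code{n_perm} random permutations are drawn. The p-value is one-sided
#' (proportion of permutations with \code{r >= r_obs}, the identity
#' included).
#'
#' Non-significant entries of a differentiation matrix (e.g. FST with
#' permutation p > 0.05) can be zeroed (\code{"zero_nonsignificant"}) or
#' excluded pairwise from the correlation (\code{"exclude_nonsignificant"},
#' entries set to NA are dropped wherever they land under permutation).
#'
#' @param m1,m2 symmetric matrices with identical dimnames.
#' @param p2 optional matrix of p-values accompanying \code{m2}, used by the
#'   handling modes; entries with \code{p2 > alpha} are zeroed/excluded.
#' @param handling \code{"none"}, \code{"zero_nonsignificant"} or
#'   \code{"exclude_nonsignificant"}.
#' @param alpha significance cut-off used by the handling modes (0.05).
#' @param n_perm random permutations when exact enumeration is not used.
#' @param seed integer seed (required unless enumeration is exact).
#' @return list of class \code{mantel_test}: \code{r}, \code{p},
#'   \code{exact} (logical), \code{n_perm}, \code{handling}.
#' @export
mantel_test <- function(m1, m2, p2 = NULL,
                        handling = c("none", "zero_nonsignificant",
                                     "exclude_nonsignificant"),
                        alpha = 0.05, n_perm = 999, seed = NULL) {
  handling <- match.arg(handling)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  stopifnot(identical(dimnames(m1), dimnames(m2)))
  n <- nrow(m1)
  if (handling != "none") {
    if (is.null(p2)) ct_error("invalid_matrix",
                              "handling modes require the p-value matrix p2")
    ns <- !is.na(p2) & p2 > alpha
    if (handling == "zero_nonsignificant") {
      m2[ns] <- 0
      m2[m2 < 0] <- 0             # negative differentiation clamped to zero
    } else {
      m2[ns] <- NA_real_
    }
  }
  off <- upper.tri(m1)
  r_for_perm <- function(perm) {
    mp <- m2[perm, perm]
    x <- m1[off]; y <- mp[off]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  r_obs <- r_for_perm(seq_len(n))
  if (is.na(r_obs)) {
    x <- m1[off]; y <- m2[off]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      ct_error("too_few_entries",
               "fewer than 3 complete pairs after exclusion")
    ct_error("zero_variance", "correlation undefined: zero variance")
  }
  exact <- n <= 6L
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, r_for_perm, numeric(1))
    rs <- rs[!is.na(rs)]
    p <- mean(rs >= r_obs - 1e-12)
    B <- length(rs)
  } else {
    if (is.null(seed)) ct_error("seed_required", "seed required")
    set.seed(as.integer(seed))
    exceed <- 0; B <- n_perm
    for (b in seq_len(n_perm)) {
      rp <- r_for_perm(sample.int(n))
      if (!is.na(rp) && rp >= r_obs - 1e-12) exceed <- exceed + 1
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, exact = exact, n_perm = B,
                 handling = handling),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations%s)\n",
              x$r, x$p, x$handling, x$n_perm,
              if (x$exact) ", exact enumeration" else ""))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- as.integer(append(p, n, after = i))
  }
  out
}

#' Minimum spanning network over haplotypes
#'
#' Kruskal's algorithm with a deterministic tie-break: edges are sorted by
#' weight, then lexicographically by their endpoint labels. Node attributes
#' (per-population read counts) are attached for plotting-style export.
#'
#' @param d symmetric distance matrix over haplotypes; \code{Inf} entries
#'   are treated as absent edges.
#' @param node_attrs optional data frame of per-haplotype attributes
#'   (rownames = haplotype labels), e.g. per-population counts.
#' @return list of class \code{msn}: \code{edges} (data frame u, v, weight),
#'   \code{nodes} (the attribute table, with a \code{total} column when
#'   counts are supplied), \code{total_weight}.
#' @export
min_spanning_network <- function(d, node_attrs = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  keep <- is.finite(w)
  ij <- ij[keep, , drop = FALSE]; w <- w[keep]
  u <- labels[ij[, 1L]]; v <- labels[ij[, 2L]]
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  ord <- order(w, u, v)
  u <- u[ord]; v <- v[ord]; w <- w[ord]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sel <- logical(length(w))
  for (e in seq_along(w)) {
    ri <- find(match(u[e], labels)); rj <- find(match(v[e], labels))
    if (ri != rj) { parent[ri] <- rj; sel[e] <- TRUE }
  }
  if (sum(sel) != n - 1L)
    ct_error("disconnected",
             "distance graph is disconnected (infinite distances split it)")
  edges <- data.frame(u = u[sel], v = v[sel], weight = w[sel],
                      stringsAsFactors = FALSE)
  nodes <- NULL
  if (!is.null(node_attrs)) {
    nodes <- as.data.frame(node_attrs)
    nodes <- nodes[labels, , drop = FALSE]
    num <- vapply(nodes, is.numeric, logical(1))
    if (any(num)) nodes$total <- rowSums(nodes[, num, drop = FALSE])
  }
  structure(list(edges = edges, nodes = nodes,
                 total_weight = sum(edges$weight)),
            class = "msn")
}

#' @export
print.msn <- function(x, ...) {
  cat(sprintf("Minimum spanning network: %d nodes, %d edges, total weight %.4g\n",
              nrow(x$edges) + 1L, nrow(x$edges), x$total_weight))
  invisible(x)
}

#' Write a minimum spanning network to TSV files
#'
#' @param msn a \code{\link{min_spanning_network}} result.
#' @param edge_path,node_path output paths (node table skipped when absent).
#' @return \code{edge_path}, invisibly.
#' @export
write_msn <- function(msn, edge_path, node_path = NULL) {
  utils::write.table(msn$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path) && !is.null(msn$nodes)) {
    out <- cbind(haplotype_id = rownames(msn$nodes), msn$nodes)
    utils::write.table(out, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edge_path)
}
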