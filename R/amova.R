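# Distance-based hierarchical AMOVA with permutation tests.
#
# Every read is treated as an individual (one symbiont cell). Reads carrying
# the same haplotype are at distance zero, so all sums of squares can be
# computed from per-group haplotype count vectors and the haplotype-level
# squared-distance matrix:
#   SS within group g = (1/n_g) * sum_{i<j in g} d^2_ij
#                     = c_g' D2 c_g / (2 n_g),
# with c_g the haplotype counts of group g. Variance components are obtained
# by solving the expected-mean-square equations of the unbalanced nested
# random-effects design; the coefficient of sigma^2_j in E[MS_i] (levels
# numbered outermost = 1) is
#   c_ij = (A_ij - A_{i-1,j}) / df_i,
#   A_ij = sum over level-i groups G of
#          (sum over level-j units u in G of n_u^2) / n_G,
# with level 0 = the whole data set. Negative components are reported as-is.

# ---- internal core ---------------------------------------------------------

# tab: data.frame with stratum columns, haplotype_id, count
# d:   haplotype distance matrix (labels cover all haplotype_id in tab)
amova_prep <- function(tab, d, levels) {
  stopifnot(all(c(levels, "haplotype_id", "count") %in% names(tab)))
  haps <- rownames(d)
  if (is.null(haps)) ct_error("invalid_matrix", "distance matrix needs dimnames")
  miss <- setdiff(unique(tab$haplotype_id), haps)
  if (length(miss))
    ct_error("invalid_hierarchy", sprintf(
      "haplotypes absent from distance matrix: %s",
      paste(utils::head(miss, 5), collapse = ", ")))
  # check strict nesting: each inner label maps to exactly one outer label
  if (length(levels) > 1L) {
    for (l in seq.int(2L, length(levels))) {
      inner <- tab[[levels[l]]]
      outer_id <- interaction(tab[levels[seq_len(l - 1L)]], drop = TRUE)
      if (any(tapply(as.character(outer_id), inner,
                     function(z) length(unique(z))) > 1L))
        ct_error("invalid_hierarchy", sprintf(
          "stratum '%s' is not nested: some labels span several outer groups",
          levels[l]))
    }
  }
  # aggregate to finest units (unique stratum combinations)
  unit <- interaction(tab[levels], drop = TRUE, lex.order = TRUE)
  hap_f <- factor(tab$haplotype_id, levels = haps)
  counts <- matrix(0, nlevels(unit), length(haps),
                   dimnames = list(levels(unit), haps))
  idx <- cbind(as.integer(unit), as.integer(hap_f))
  for (r in seq_len(nrow(tab)))
    counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + tab$count[r]
  keep_h <- colSums(counts) > 0
  counts <- counts[, keep_h, drop = FALSE]
  strata <- unique(tab[order(unit), levels, drop = FALSE])
  strata <- as.data.frame(lapply(strata, as.character),
                          stringsAsFactors = FALSE)
  # relabel each stratum to its full path (outer labels prefixed) so that
  # labels are globally unique; subunit identity then survives permutation
  # of an outer level without accidental merging of same-named inner groups
  for (l in seq_along(levels))
    strata[[l]] <- as.character(interaction(strata[seq_len(l)], drop = TRUE,
                                            lex.order = TRUE))
  D2 <- as.matrix(d)[keep_h, keep_h, drop = FALSE]^2
  list(counts = counts, strata = strata, D2 = D2, levels = levels)
}

# SS within the groups defined by factor f over unit rows
ss_within_groups <- function(counts, D2, f) {
  M <- rowsum(counts, f)
  n <- rowSums(M)
  sum(rowSums((M %*% D2) * M) / (2 * n))
}

# full AMOVA table from a unit-level representation
amova_compute <- function(counts, strata, D2) {
  L <- ncol(strata)
  N <- sum(counts)
  grp <- vector("list", L)
  for (l in seq_len(L))
    grp[[l]] <- interaction(strata[seq_len(l)], drop = TRUE, lex.order = TRUE)
  G <- vapply(grp, nlevels, integer(1))
  unit_f <- grp[[L]]                    # finest grouping = one group per unit?
  # units are unique stratum combinations, so grp[[L]] has one level per row
  W <- numeric(L + 1L)                  # W[l+1] = SS within level-l grouping
  W[1L] <- ss_within_groups(counts, D2, factor(rep(1L, nrow(counts))))
  for (l in seq_len(L)) W[l + 1L] <- ss_within_groups(counts, D2, grp[[l]])
  ss_among <- -diff(W)                  # among level l within level l-1
  ss_error <- W[L + 1L]
  df_among <- diff(c(1L, G))
  df_error <- N - G[L]
  if (any(df_among <= 0L))
    ct_error("degenerate_design",
             "a hierarchical level has a single group (zero df)")
  # expected-mean-square coefficients
  sizes <- lapply(grp, function(f) {
    s <- rowsum(rowSums(counts), f)
    stats::setNames(s[, 1L], rownames(s))
  })
  A <- matrix(0, L + 1L, L)             # rows: level 0..L, cols: level j
  for (j in seq_len(L)) {
    n_u <- sizes[[j]]
    A[1L, j] <- sum(n_u^2) / N
    for (i in seq_len(j)) {
      # level-j groups nested in level-i groups: map via first unit of each
      parent <- tapply(as.character(grp[[i]]), grp[[j]], `[`, 1L)
      contrib <- rowsum(unname(n_u^2), unname(parent[names(n_u)]))
      A[i + 1L, j] <- sum(contrib[, 1L] / sizes[[i]][rownames(contrib)])
    }
  }
  cmat <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq.int(i, L))
    cmat[i, j] <- (A[i + 1L, j] - A[i, j]) / df_among[i]
  ms_among <- ss_among / df_among
  ms_error <- ss_error / df_error
  sigma <- numeric(L + 1L)              # components 1..L, then error
  sigma[L + 1L] <- ms_error
  for (i in rev(seq_len(L))) {
    sigma[i] <- (ms_among[i] - ms_error -
                   if (i < L) sum(cmat[i, seq.int(i + 1L, L)] *
                                    sigma[seq.int(i + 1L, L)]) else 0) / cmat[i, i]
  }
  sig_tot <- sum(sigma)
  # Phi for level l: sigma_l over (sigma_l + everything nested below it);
  # the within row carries the cumulative Phi (all among / total)
  phi <- numeric(L + 1L)
  for (l in seq_len(L)) phi[l] <- sigma[l] / sum(sigma[l:(L + 1L)])
  phi[L + 1L] <- sum(sigma[seq_len(L)]) / sig_tot
  list(df = c(df_among, df_error, N - 1L),
       SS = c(ss_among, ss_error, W[1L]),
       MS = c(ms_among, ms_error, W[1L] / (N - 1L)),
       sigma = sigma, percent = 100 * sigma / sig_tot, phi = phi,
       N = N, G = G)
}

# expand a haplotype count matrix subset to a vector of haplotype indices
expand_reads <- function(counts) rep(seq_len(ncol(counts)), colSums(counts))

# ---- permutation machinery -------------------------------------------------

# permute individuals (reads) among the unit rows of `counts`, within each
# block of `block` (NULL permutes globally), preserving unit sizes.
permute_reads <- function(counts, block = NULL) {
  K <- ncol(counts)
  out <- counts
  blocks <- if (is.null(block)) factor(rep(1L, nrow(counts))) else block
  for (b in levels(blocks)) {
    rows <- which(blocks == b)
    sub <- counts[rows, , drop = FALSE]
    pool <- unlist(lapply(seq_len(nrow(sub)),
                          function(i) rep(seq_len(K), sub[i, ])))
    pool <- sample(pool)
    sizes <- rowSums(sub)
    split_idx <- rep(seq_along(rows), sizes)
    for (i in seq_along(rows))
      out[rows[i], ] <- tabulate(pool[split_idx == i], nbins = K)
  }
  out
}

# permute whole innermost units (rows of `counts`, e.g. host samples) among
# the hierarchy's slots, within each block of `block`: the strata tree keeps
# its shape while unit contents move, the scheme used to test among-group
# components above the innermost level.
permute_units <- function(counts, block = NULL) {
  blocks <- if (is.null(block)) factor(rep(1L, nrow(counts))) else block
  idx <- seq_len(nrow(counts))
  for (b in levels(blocks)) {
    rows <- which(blocks == b)
    idx[rows] <- rows[sample.int(length(rows))]
  }
  counts[idx, , drop = FALSE]
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Distance-based AMOVA over a nested sampling hierarchy, treating each read
#' as an individual. Sums of squares are computed from squared inter-read
#' distances; variance components solve the expected-mean-square equations
#' of the unbalanced nested design; Phi-statistics are component ratios; and
#' significance is assessed by the standard nested permutation scheme:
#' whole lowest-level units (e.g. host samples) are permuted among the
#' groups of the tested level within the enclosing stratum, and the
#' innermost level permutes individual reads among units; the within row
#' reports the global test (reads permuted freely, cumulative Phi).
#'
#' Negative variance components are reported as-is, not truncated. For
#' distances that are not Euclidean-embeddable (e.g. tree-derived
#' distances), apply \code{\link{lingoes_correct}} first.
#'
#' @param tab data frame with one row per (stratum combination, haplotype):
#'   the stratum columns named in \code{levels}, plus \code{haplotype_id}
#'   and \code{count} (number of reads).
#' @param d haplotype distance matrix whose dimnames cover all haplotype
#'   ids in \code{tab}.
#' @param levels character vector of stratum column names, outermost first.
#' @param n_perm permutations per level (default 1000); 0 disables tests.
#' @param seed integer seed for the permutation stream (required when
#'   \code{n_perm > 0}).
#' @return an object of class \code{amova}: a list with \code{table} (one
#'   row per level plus within and total rows: Df, SS, MS, sigma, percent,
#'   phi, p_value), \code{levels}, \code{n_perm}, \code{seed}.
#' @export
amova <- function(tab, d, levels, n_perm = 1000, seed = NULL) {
  prep <- amova_prep(tab, d, levels)
  obs <- amova_compute(prep$counts, prep$strata, prep$D2)
  L <- length(levels)
  pvals <- rep(NA_real_, L + 1L)
  if (n_perm > 0) {
    if (is.null(seed)) ct_error("seed_required",
                                "a seed is required for permutation tests")
    set.seed(as.integer(seed))
    exceed <- numeric(L + 1L)
    blocks <- lapply(seq_len(L), function(l) {
      if (l == 1L) NULL
      else interaction(prep$strata[seq_len(l - 1L)], drop = TRUE,
                       lex.order = TRUE)
    })
    for (b in seq_len(n_perm)) {
      for (l in seq_len(L)) {
        cts <- if (l == L) permute_reads(prep$counts, blocks[[l]])
        else permute_units(prep$counts, blocks[[l]])
        perm <- amova_compute(cts, prep$strata, prep$D2)
        if (perm$sigma[l] >= obs$sigma[l]) exceed[l] <- exceed[l] + 1
      }
      # within row: cumulative Phi under global permutation of reads
      cts <- permute_reads(prep$counts)
      perm <- amova_compute(cts, prep$strata, prep$D2)
      if (perm$phi[L + 1L] >= obs$phi[L + 1L])
        exceed[L + 1L] <- exceed[L + 1L] + 1
    }
    pvals <- (1 + exceed) / (n_perm + 1)
  }
  rows <- c(sprintf("Among %s%s", levels,
                    c("", sprintf(" within %s", levels[-L])[seq_len(L - 1L)])),
            "Within", "Total")
  table <- data.frame(
    Df = obs$df,
    Sum.Sq = obs$SS,
    Mean.Sq = obs$MS,
    sigma = c(obs$sigma, sum(obs$sigma)),
    percent = c(obs$percent, 100),
    phi = c(obs$phi, NA),
    p.value = c(pvals, NA),
    row.names = rows)
  structure(list(table = table, levels = levels, n_perm = n_perm,
                 seed = seed, N = obs$N),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 4, ...) {
  cat(sprintf("Hierarchical AMOVA (%d reads; levels: %s; %d permutations)\n",
              x$N, paste(x$levels, collapse = " > "), x$n_perm))
  tab <- x$table
  tab$p.value <- ifelse(is.na(tab$p.value), "",
                        format.pval(tab$p.value, digits = 3))
  print(format(tab, digits = digits), ...)
  invisible(x)
}

#' @export
summary.amova <- function(object, ...) print(object, ...)
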