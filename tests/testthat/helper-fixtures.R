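# shared fixtures and independent oracles, all built in code

PRIMERS <- c(FWD = "ACGGTCTTAGGCTTACCGTACGT",
             REV = "TGCACCTAGGTTCAAGCCTTGAA")

rnd_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a catalog of K random spacers (ids 1..K) with a random 30 nt repeat
make_catalog <- function(K, spacer_len = 35, rep_len = 30) {
  spacer_catalog(stats::setNames(vapply(seq_len(K), function(i)
    rnd_dna(spacer_len), character(1)), seq_len(K)), rnd_dna(rep_len))
}

# clean amplicon: FWD + repeat + (spacer + repeat)* + revcomp(REV)
build_amplicon <- function(ids, catalog, primers = PRIMERS) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  body <- paste0(catalog$repeat_sequence,
                 paste(vapply(as.integer(ids), function(i)
                   paste0(catalog$spacers[[as.character(i)]],
                          catalog$repeat_sequence), character(1)),
                   collapse = ""))
  paste0(primers[["FWD"]], body, rc(primers[["REV"]]))
}

rc_chr <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# independent grid-search oracle for the OISL maximum: exhaustive 2-D grid
# in the (t, lambda) parametrisation (lambda = rho * (1 - exp(-t)), a
# bijection for t > 0), whose log-likelihood is a separable sum; resolution
# `res` on each axis
oisl_grid_oracle <- function(al, t_max = 5, res = 1e-4) {
  n_sh <- length(al$shared)
  n_int <- al$internal_unique_a + al$internal_unique_b
  k_sum <- al$leader_unique_a + al$leader_unique_b
  tg <- seq(res, t_max, by = res)
  p <- exp(-tg)
  class_ll <- 2 * n_sh * log(p) -
    (n_sh + n_int) * (log(p) + log1p(1 - p)) +
    if (n_int > 0) n_int * (log(p) + log1p(-p)) else 0
  t_hat <- tg[which.max(class_ll)]
  if (n_int == 0) t_hat <- 0          # boundary: maximum at p = 1
  lam_hat <- if (k_sum > 0) {
    lg <- seq(res, k_sum + 5, by = res)
    pois_ll <- -2 * lg + k_sum * log(lg)
    lg[which.max(pois_ll)]
  } else 0
  list(t_hat = t_hat, lambda_hat = lam_hat)
}

# exhaustive minimum spanning tree weight via Pruefer sequences (n <= 7)
brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2L) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pruefer <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    pq <- pruefer
    for (v in pq) {
      leaf <- which(degree == 1L)[1L]
      w <- w + d[leaf, v]
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    w <- w + d[last[1L], last[2L]]
    if (w < best) best <- w
  }
  best
}

# Heap's algorithm: all permutations of 1..n (independent of the package's
# internal enumeration)
heap_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  gen <- function(k) {
    if (k == 1L) { out[[length(out) + 1L]] <<- a; return(invisible()) }
    for (i in seq_len(k)) {
      gen(k - 1L)
      j <- if (k %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  gen(n)
  out
}

# random symmetric distance-like matrix (zero diagonal, labels)
rand_dist <- function(n, max = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.05, max)
  m <- m + t(m)
  dimnames(m) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  m
}
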