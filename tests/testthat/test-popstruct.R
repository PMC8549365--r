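test_that("lingoes correction leaves Euclidean matrices untouched", {
  # points on a line: 0, 1, 3
  m <- as.matrix(dist(c(0, 1, 3)))
  dimnames(m) <- list(1:3, 1:3)
  out <- lingoes_correct(m)
  expect_equal(unclass(out), unclass(m), ignore_attr = TRUE)
  expect_identical(attr(out, "lingoes_constant"), 0)
  # ultrametric distances are Euclidean
  set.seed(31)
  u <- as.matrix(stats::cophenetic(ape::rcoal(6)))
  out_u <- lingoes_correct(u)
  expect_identical(attr(out_u, "lingoes_constant"), 0)
})

test_that("lingoes output always passes the Euclidean eigen-check", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(4:9, 1)
    m <- rand_dist(n)^0.25             # strongly non-Euclidean shapes
    m[1, 2] <- m[2, 1] <- max(m) * 2   # triangle violations
    out <- lingoes_correct(m)
    ev <- eigen(crisprtype:::gower_center(out^2), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * max(abs(ev), 1))
    # original squared distances shifted by one constant off-diagonal
    cc <- attr(out, "lingoes_constant")
    off <- upper.tri(m)
    expect_equal(out[off]^2, m[off]^2 + 2 * cc, tolerance = 1e-12)
  }
})

test_that("minimum spanning network picks the chain over the shortcut", {
  dm <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ms <- min_spanning_network(dm)
  expect_identical(ms$edges$u, c("A", "B"))
  expect_identical(ms$edges$v, c("B", "C"))
  expect_equal(ms$total_weight, 2)
})

test_that("MST weight matches the exhaustive spanning-tree minimum", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    d <- rand_dist(n)
    ms <- min_spanning_network(d)
    expect_equal(ms$total_weight, brute_force_mst_weight(d),
                 tolerance = 1e-12)
    expect_identical(nrow(ms$edges), n - 1L)
  }
})

test_that("equal-weight ties resolve deterministically by endpoint labels", {
  n <- 5
  d <- matrix(1, n, n); diag(d) <- 0
  labs <- c("b", "a", "d", "c", "e")
  dimnames(d) <- list(labs, labs)
  ms1 <- min_spanning_network(d)
  ms2 <- min_spanning_network(d[rev(labs), rev(labs)])
  expect_identical(ms1$edges, ms2$edges)
  # all-ties star/chain: edges are the lexicographically first n-1 pairs
  expect_identical(ms1$edges$u, c("a", "a", "a", "a"))
  expect_identical(ms1$edges$v, c("b", "c", "d", "e"))
})

test_that("disconnected graphs (infinite cap) raise an error; attributes attach", {
  d <- matrix(Inf, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1
  dimnames(d) <- list(letters[1:4], letters[1:4])
  expect_error(min_spanning_network(d), class = "disconnected")
  d2 <- rand_dist(3)
  attrs <- data.frame(s1 = c(3, 0, 1), s2 = c(0, 2, 5),
                      row.names = rownames(d2))
  ms <- min_spanning_network(d2, attrs)
  expect_identical(ms$nodes$total, c(3, 2, 6))
})

test_that("mantel test on identical matrices gives r = 1 and the enumeration minimum", {
  set.seed(34)
  m <- rand_dist(5)
  mt <- mantel_test(m, m)
  expect_equal(mt$r, 1)
  expect_true(mt$exact)
  expect_equal(mt$p, 1 / factorial(5))
})

test_that("mantel (r, p) match a full-enumeration oracle on 4x4 matrices", {
  set.seed(35)
  for (rep in 1:10) {
    m1 <- rand_dist(4)
    m2 <- rand_dist(4)
    mt <- mantel_test(m1, m2)
    # independent oracle: Heap's algorithm enumeration
    off <- upper.tri(m1)
    rs <- vapply(heap_perms(4), function(p)
      stats::cor(m1[off], m2[p, p][off]), numeric(1))
    r_obs <- stats::cor(m1[off], m2[off])
    expect_equal(mt$r, r_obs)
    expect_equal(mt$p, mean(rs >= r_obs - 1e-12))
  }
})

test_that("mantel r agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(36)
  m1 <- rand_dist(7); m2 <- rand_dist(7)
  mt <- mantel_test(m1, m2, n_perm = 99, seed = 2)
  vg <- suppressWarnings(vegan::mantel(m1, m2, permutations = 0))
  expect_equal(mt$r, unname(vg$statistic))
  expect_false(mt$exact)
})

test_that("mantel handling modes zero or exclude non-significant entries", {
  set.seed(37)
  m1 <- rand_dist(5)
  m2 <- m1 + matrix(rnorm(25, 0, 0.01), 5); m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 0; dimnames(m2) <- dimnames(m1)
  p2 <- matrix(0.01, 5, 5); dimnames(p2) <- dimnames(m1)
  p2[1, 2] <- p2[2, 1] <- 0.5          # one non-significant pair
  m2[1, 3] <- m2[3, 1] <- -0.05        # one negative differentiation
  p2[1, 3] <- p2[3, 1] <- 0.01
  z <- mantel_test(m1, m2, p2 = p2, handling = "zero_nonsignificant")
  ex <- mantel_test(m1, m2, p2 = p2, handling = "exclude_nonsignificant")
  # oracle for the zero mode
  m2z <- m2; m2z[1, 2] <- m2z[2, 1] <- 0; m2z[m2z < 0] <- 0
  off <- upper.tri(m1)
  expect_equal(z$r, stats::cor(m1[off], m2z[off]))
  # oracle for the exclusion mode
  keep <- off & !(row(m1) == 1 & col(m1) == 2)
  expect_equal(ex$r, stats::cor(m1[keep], m2[keep]))
  # degenerate inputs fail loudly
  const <- m1 * 0; dimnames(const) <- dimnames(m1)
  expect_error(mantel_test(m1, const), class = "zero_variance")
  p_all <- matrix(1, 5, 5); dimnames(p_all) <- dimnames(m1)
  expect_error(mantel_test(m1, m2, p2 = p_all,
                           handling = "exclude_nonsignificant"),
               class = "too_few_entries")
})
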