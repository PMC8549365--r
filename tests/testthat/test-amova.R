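test_that("maximal structure: fixed distinct haplotypes give 100% among-population", {
  tab <- data.frame(pop = c("p1", "p2"), haplotype_id = c("h1", "h2"),
                    count = c(10, 10))
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("h1", "h2"),
                                                c("h1", "h2")))
  a <- amova(tab, d, "pop", n_perm = 99, seed = 1)
  expect_equal(a$table["Among pop", "percent"], 100)
  expect_equal(a$table["Among pop", "phi"], 1)
  expect_lte(a$table["Among pop", "p.value"], 0.01)
  expect_equal(sum(a$table$Df[1:2]), a$table["Total", "Df"])
})

test_that("balanced toy matches hand-solved expected-mean-square equations", {
  # 2 groups x 2 pops x 4 individuals on a line; squared Euclidean
  # distances decompose exactly as a nested ANOVA of the coordinates:
  #   x = (0,0,0,0, 2,2,2,2 | 10,10,10,10, 14,14,14,14)
  # SS_total = sum (x - mean)^2,   MS solved with n' = 4, n'' = 8 by hand:
  x <- c(rep(0, 4), rep(2, 4), rep(10, 4), rep(14, 4))
  ids <- sprintf("i%02d", seq_along(x))
  d <- as.matrix(dist(x)); dimnames(d) <- list(ids, ids)
  tab <- data.frame(grp = rep(c("g1", "g2"), each = 8),
                    pop = rep(c("a", "b", "c", "d"), each = 4),
                    haplotype_id = ids, count = 1)
  a <- amova(tab, d, c("grp", "pop"), n_perm = 0)
  # hand computation: group means 1 and 12, grand mean 6.5
  ss_grp <- 16 * 6.5^2 - 8 * 1^2 - 8 * 12^2 + 2 * 0 # via deviations below
  ss_grp <- 8 * (1 - 6.5)^2 + 8 * (12 - 6.5)^2        # = 484
  ss_pop <- 4 * ((0 - 1)^2 + (2 - 1)^2 + (10 - 12)^2 + (14 - 12)^2) # = 40
  ss_err <- 0
  expect_equal(a$table$Sum.Sq[1:3], c(ss_grp, ss_pop, ss_err))
  expect_equal(a$table$Df[1:3], c(1, 2, 12))
  # components: sigma_e = 0; sigma_pop = (MS_pop - MS_e)/4 = 5;
  # sigma_grp = (MS_grp - MS_pop)/8 = (484 - 20)/8 = 58
  expect_equal(a$table$sigma[1:3], c(58, 5, 0))
})

test_that("one-level AMOVA Phi equals pairwise FST", {
  set.seed(21)
  tab <- data.frame(pop = rep(c("p1", "p2"), each = 3),
                    haplotype_id = c("h1", "h2", "h3", "h1", "h3", "h4"),
                    count = c(8, 3, 2, 1, 6, 7))
  haps <- paste0("h", 1:4)
  d <- rand_dist(4); dimnames(d) <- list(haps, haps)
  a <- amova(tab, d, "pop", n_perm = 0)
  f <- pairwise_fst(tab, "pop", d = d, mode = "distance", n_perm = 0)
  expect_equal(f$fst["p1", "p2"], a$table["Among pop", "phi"])
})

test_that("pairwise FST matches the direct variance-component computation", {
  # printed toy counts pop1 {h1:8, h2:2}, pop2 {h1:2, h2:8}; 0/1 distances.
  # Direct two-level computation: N = 20, unequal pairs overall = 10*10,
  #   SS_total = (1/N) sum_{i<j} d2 = 100/20 = 5
  #   SS_within = sum_g (1/10) * 8*2 = 2 * 1.6 = 3.2;  SS_among = 1.8
  #   MS_w = 3.2/18; n' = (20 - 2*100/20)/1 = 10; sigma_a = (1.8 - MS_w)/10
  tab <- data.frame(pop = rep(c("p1", "p2"), each = 2),
                    haplotype_id = c("h1", "h2", "h1", "h2"),
                    count = c(8, 2, 2, 8))
  ms_w <- 3.2 / 18
  sigma_a <- (1.8 - ms_w) / 10
  fst_expected <- sigma_a / (sigma_a + ms_w)
  f <- pairwise_fst(tab, "pop", n_perm = 199, seed = 5)
  expect_equal(f$fst["p1", "p2"], fst_expected)
  # fixed alternative haplotypes: FST = 1
  tab2 <- data.frame(pop = c("p1", "p2"), haplotype_id = c("h1", "h2"),
                     count = c(9, 9))
  f2 <- pairwise_fst(tab2, "pop", n_perm = 99, seed = 5)
  expect_equal(f2$fst["p1", "p2"], 1)
  expect_lte(f2$p["p1", "p2"], 0.05)
  # identical frequencies: FST ~ 0 (can be negative), non-significant
  tab3 <- data.frame(pop = rep(c("p1", "p2"), each = 2),
                     haplotype_id = c("h1", "h2", "h1", "h2"),
                     count = c(50, 50, 50, 50))
  f3 <- pairwise_fst(tab3, "pop", n_perm = 99, seed = 5)
  expect_lte(f3$fst["p1", "p2"], 1e-10)
  expect_gt(f3$p["p1", "p2"], 0.05)
})

test_that("degenerate designs are rejected", {
  tab <- data.frame(pop = "p1", haplotype_id = c("h1", "h2"), count = c(3, 3))
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("h1", "h2"),
                                                c("h1", "h2")))
  expect_error(amova(tab, d, "pop", n_perm = 0),
               class = "degenerate_design")
  expect_error(pairwise_fst(tab, "pop", n_perm = 0),
               class = "degenerate_design")
})

test_that("negative variance components are reported, not truncated", {
  # two pops with identical composition: among component is typically < 0
  tab <- data.frame(pop = rep(c("p1", "p2"), each = 2),
                    haplotype_id = c("h1", "h2", "h1", "h2"),
                    count = c(10, 10, 10, 10))
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("h1", "h2"),
                                                c("h1", "h2")))
  a <- amova(tab, d, "pop", n_perm = 0)
  expect_lt(a$table["Among pop", "sigma"], 0)
  expect_equal(sum(a$table$percent[1:2]), 100, tolerance = 1e-8)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(22)
  n_perm <- 49L
  haps <- paste0("h", 1:6)
  pvals <- replicate(120, {
    # iid reads: every read draws its haplotype from one common frequency
    # vector, so populations are exchangeable under the null
    freq <- c(rgamma(6, 1)); freq <- freq / sum(freq)
    cnt <- stats::rmultinom(3, 40, freq)
    tab <- data.frame(pop = rep(c("p1", "p2", "p3"), each = 6),
                      haplotype_id = rep(haps, 3),
                      count = as.integer(cnt))
    tab <- tab[tab$count > 0, ]
    d <- rand_dist(6); dimnames(d) <- list(haps, haps)
    a <- amova(tab, d, "pop", n_perm = n_perm,
               seed = sample.int(1e6, 1))
    a$table["Among pop", "p.value"]
  })
  # under the null, (1 + exceed)/(B + 1) is uniform on {1/(B+1), ..., 1}
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("amova validates hierarchy nesting and haplotype coverage", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("h1", "h2"),
                                                c("h1", "h2")))
  bad <- data.frame(region = c("r1", "r2"), site = c("s1", "s1"),
                    haplotype_id = c("h1", "h2"), count = c(5, 5))
  expect_error(amova(bad, d, c("region", "site"), n_perm = 0),
               class = "invalid_hierarchy")
  miss <- data.frame(pop = c("p1", "p2"), haplotype_id = c("h1", "hX"),
                     count = c(5, 5))
  expect_error(amova(miss, d, "pop", n_perm = 0),
               class = "invalid_hierarchy")
})
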