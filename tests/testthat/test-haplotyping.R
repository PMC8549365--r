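test_that("map_spacers classifies constructed reads through the QC precedence", {
  set.seed(41)
  cat5 <- make_catalog(5)
  rd <- build_amplicon(c(1, 2), cat5)
  q <- map_spacers(rd, cat5, PRIMERS)
  expect_identical(q$category, "PASS")
  expect_identical(q$spacer_ids, c(1L, 2L))

  # missing trailing primer
  q2 <- map_spacers(substr(rd, 1, nchar(rd) - 23), cat5, PRIMERS)
  expect_identical(q2$category, "MISSING_PRIMER")

  # both primers but a 30 nt interior
  short <- paste0(PRIMERS[["FWD"]], substr(cat5$spacers[[1]], 1, 30),
                  rc_chr(PRIMERS[["REV"]]))
  expect_identical(map_spacers(short, cat5, PRIMERS)$category, "TOO_SHORT")

  # one spacer reversed between ordinary ones -> mixed orientation
  mix <- paste0(PRIMERS[["FWD"]], cat5$repeat_sequence,
                cat5$spacers[[1]], cat5$repeat_sequence,
                rc_chr(cat5$spacers[[2]]), cat5$repeat_sequence,
                cat5$spacers[[3]], cat5$repeat_sequence,
                rc_chr(PRIMERS[["REV"]]))
  expect_identical(map_spacers(mix, cat5, PRIMERS)$category,
                   "MIXED_ORIENTATION")

  # spacers out of catalog order
  miso <- build_amplicon(c(3, 1), cat5)
  expect_identical(map_spacers(miso, cat5, PRIMERS)$category, "MISORDERED")

  # an extra 40 nt inserted into one gap -> irregular spacing
  irr <- paste0(PRIMERS[["FWD"]], cat5$repeat_sequence,
                cat5$spacers[[1]], cat5$repeat_sequence, rnd_dna(40),
                cat5$spacers[[2]], cat5$repeat_sequence,
                rc_chr(PRIMERS[["REV"]]))
  expect_identical(map_spacers(irr, cat5, PRIMERS)$category,
                   "IRREGULAR_SPACING")
})

test_that("map_spacers is strand-invariant after orientation normalisation", {
  set.seed(42)
  cat5 <- make_catalog(5)
  rd <- build_amplicon(c(1, 3, 5), cat5)
  q_f <- map_spacers(rd, cat5, PRIMERS)
  q_r <- map_spacers(rc_chr(rd), cat5, PRIMERS)
  expect_identical(q_f$category, "PASS")
  expect_identical(q_r$category, "PASS")
  expect_identical(q_f$spacer_ids, q_r$spacer_ids)
})

test_that("raising max_edits never loses spacer hits", {
  set.seed(43)
  cat3 <- make_catalog(3)
  rd <- build_amplicon(c(1, 2, 3), cat3)
  # plant two substitutions inside spacer 2
  pos <- regexpr(cat3$spacers[[2]], rd, fixed = TRUE)
  mutated <- rd
  for (off in c(3, 9)) {
    at <- pos + off
    substr(mutated, at, at) <- setdiff(c("A", "C", "G", "T"),
                                       substr(mutated, at, at))[1]
  }
  n_hits <- vapply(0:5, function(k)
    nrow(map_spacers(mutated, cat3, PRIMERS, max_edits = k)$matches),
    integer(1))
  expect_true(all(diff(n_hits) >= 0))
  expect_lt(n_hits[1], n_hits[6])  # the mutated spacer needs edits > 0
})

test_that("call_haplotypes recovers exact counts at zero error", {
  set.seed(44)
  cat6 <- make_catalog(6)
  haps <- list(A = crispr_array(1:6), B = crispr_array(c(1, 3, 5)),
               C = crispr_array(c(1, 6)))
  reads <- c(replicate(12, build_amplicon(haps$A, cat6)),
             replicate(6, build_amplicon(haps$B, cat6)),
             replicate(2, build_amplicon(haps$C, cat6)))
  res <- call_haplotypes(list(s1 = sample(reads)), cat6, PRIMERS)
  expect_identical(sum(res$table$read_count), 20L)
  got <- stats::setNames(res$table$read_count, res$table$haplotype_id)
  expect_identical(got[["H1.2.3.4.5.6"]], 12L)
  expect_identical(got[["H1.3.5"]], 6L)
  expect_identical(got[["H1.6"]], 2L)
  # QC categories partition the library
  expect_identical(sum(res$qc$n), 20L)
})

test_that("call_haplotypes raises empty_sample when nothing passes", {
  set.seed(45)
  cat3 <- make_catalog(3)
  primerless <- replicate(5, paste0(cat3$repeat_sequence,
                                    cat3$spacers[[1]],
                                    cat3$repeat_sequence))
  expect_error(call_haplotypes(list(s1 = primerless), cat3, PRIMERS),
               class = "empty_sample")
})

test_that("discover_spacers rebuilds the catalog from error-free reads", {
  set.seed(46)
  cat5 <- make_catalog(5)
  reads <- c(replicate(4, build_amplicon(1:5, cat5)),
             replicate(4, build_amplicon(c(1, 3, 5), cat5)),
             replicate(2, rc_chr(build_amplicon(1:5, cat5))))
  disc <- discover_spacers(Biostrings::DNAStringSet(reads),
                           cat5$repeat_sequence)
  expect_identical(unname(disc$spacers), unname(cat5$spacers))
  expect_error(discover_spacers(Biostrings::DNAStringSet(rnd_dna(300)),
                                cat5$repeat_sequence),
               class = "no_repeat_found")
})

test_that("discover_spacers reaches a clean consensus at 1% substitution error", {
  set.seed(47)
  cat5 <- make_catalog(5)
  hier <- data.frame(s = "s1", haplotype_id = "H", count = 50)
  reads <- simulate_reads(hier, list(H = crispr_array(1:5)), cat5, PRIMERS,
                          sub_rate = 0.01, indel_rate = 0, seed = 48)
  disc <- discover_spacers(reads[[1]], cat5$repeat_sequence)
  expect_identical(length(disc), 5L)
  expect_setequal(unname(disc$spacers), unname(cat5$spacers))
})

test_that("putative new spacers are flagged, extracted and rediscovered", {
  set.seed(49)
  # truth catalog has 6 spacers; the working catalog lacks spacer 6
  full <- make_catalog(6)
  known <- spacer_catalog(full$spacers[1:5], full$repeat_sequence)
  reads <- replicate(6, build_amplicon(c(1, 2, 6, 3, 4), full))
  qcs <- lapply(reads, map_spacers, catalog = known, primers = PRIMERS)
  expect_true(all(vapply(qcs, `[[`, character(1), "category") ==
                    "IRREGULAR_SPACING"))
  for (i in seq_along(qcs)) qcs[[i]]$read_id <- i
  cand <- extract_putative_new_spacers(qcs, nchar(full$repeat_sequence))
  expect_identical(length(cand), 6L)
  # the candidate region contains the novel spacer verbatim
  expect_true(all(grepl(full$spacers[["6"]], as.character(cand),
                        fixed = TRUE)))
  re <- discover_spacers(cand, full$repeat_sequence,
                         existing_catalog = known)
  expect_identical(unname(re$spacers), full$spacers[["6"]])
  expect_identical(names(re$spacers), "6")  # ids continue after catalog
  # an empty flagged set yields an empty extraction
  expect_identical(length(extract_putative_new_spacers(list(), 30)), 0L)
})
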