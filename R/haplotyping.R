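# Haplotype calling from long-read CRISPR amplicons.
#
# Workflow: discover seed spacers by repeat-anchored extraction, map spacers
# and primers onto every read by approximate (Levenshtein) matching, assign
# each read a single QC category, and call haplotypes (ordered spacer-id
# arrays) from the reads that pass.

# all approximate occurrences of `pattern` in `subject`, each with its
# minimal edit distance <= max_edits; overlapping candidates resolved
# greedily by ascending edit distance then leftmost position. A single
# scan at max_edits first decides whether the pattern occurs at all; the
# per-distance refinement then stops as soon as every occurrence is
# resolved.
find_hits <- function(pattern, subject, max_edits) {
  if (!inherits(subject, "DNAString")) subject <- Biostrings::DNAString(subject)
  coarse <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = max_edits,
                                     with.indels = TRUE)
  if (length(coarse) == 0L)
    return(data.frame(start = integer(), end = integer(), dist = integer()))
  # number of distinct (non-overlapping) occurrence sites to resolve
  cs <- BiocGenerics::start(coarse); ce <- BiocGenerics::end(coarse)
  o <- order(cs)
  n_sites <- 0L; last_end <- -1L
  for (idx in o) {
    if (cs[idx] > last_end) { n_sites <- n_sites + 1L; last_end <- ce[idx] }
  }
  acc_s <- integer(); acc_e <- integer(); acc_d <- integer()
  for (k in 0:max_edits) {
    m <- if (k == max_edits) coarse
    else Biostrings::matchPattern(pattern, subject, max.mismatch = k,
                                  with.indels = TRUE)
    if (length(m)) {
      st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
      for (idx in order(st)) {
        s <- st[idx]; e <- en[idx]
        if (!length(acc_s) || all(e < acc_s | s > acc_e)) {
          acc_s <- c(acc_s, s); acc_e <- c(acc_e, e); acc_d <- c(acc_d, k)
        }
      }
    }
    if (length(acc_s) >= n_sites) break
  }
  o <- order(acc_s)
  data.frame(start = acc_s[o], end = acc_e[o], dist = acc_d[o])
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Discover seed spacers by repeat-anchored extraction
#'
#' Finds approximate occurrences of the conserved repeat on both strands of
#' each read, extracts the inter-repeat segments of plausible spacer length,
#' clusters them at an identity threshold, and returns consensus spacers
#' (the most frequent member sequence of each cluster) with fresh integer
#' ids assigned in order of average position along the reads (leader
#' first).
#'
#' When an existing catalog is supplied (re-discovery of putative new
#' spacers), clusters resembling a known spacer are discarded: an exact-
#' threshold match is the same spacer, and a near-threshold match is a
#' low-quality rediscovery; only clusters below \code{novel_max_identity}
#' to every known spacer are reported as new.
#'
#' @param reads a \code{DNAStringSet} (or anything coercible), or a path to
#'   a FASTQ/FASTA file.
#' @param repeat_seq the conserved repeat sequence (>= 20 nt).
#' @param max_repeat_edits edit distance tolerated on repeat hits (3).
#' @param min_len,max_len spacer length bounds (default 20 and 60 nt).
#' @param identity within-cluster identity threshold (0.85).
#' @param min_count minimum segments supporting a reported spacer (2).
#' @param existing_catalog optional \code{spacer_catalog} for re-discovery.
#' @param novel_max_identity clusters at or above this identity to an
#'   existing spacer are discarded as rediscoveries (0.5).
#' @return a \code{spacer_catalog} (ids 1..K, or continuing after the
#'   existing catalog's ids).
#' @export
discover_spacers <- function(reads, repeat_seq, max_repeat_edits = 3L,
                             min_len = 20L, max_len = 60L,
                             identity = 0.85, min_count = 2L,
                             existing_catalog = NULL,
                             novel_max_identity = 0.5) {
  reads <- as_dna_set(reads)
  ct_stopifnot_dna(repeat_seq, "repeat sequence")
  if (nchar(repeat_seq) < 20L)
    ct_error("invalid_catalog", "repeat sequence must be at least 20 nt")
  segs <- character(); ords <- numeric(); read_of <- integer()
  ord_max_by_read <- numeric(0)
  any_repeat <- FALSE
  rep_pat <- Biostrings::DNAString(repeat_seq)
  for (i in seq_along(reads)) {
    sq <- as.character(reads[[i]])
    hits_f <- find_hits(rep_pat, sq, max_repeat_edits)
    hits_r <- find_hits(rep_pat, revcomp(sq), max_repeat_edits)
    if (nrow(hits_r) > nrow(hits_f)) { sq <- revcomp(sq); hits_f <- hits_r }
    if (nrow(hits_f) == 0L) next
    any_repeat <- TRUE
    if (nrow(hits_f) < 2L) next
    for (g in seq_len(nrow(hits_f) - 1L)) {
      seg <- substr(sq, hits_f$end[g] + 1L, hits_f$start[g + 1L] - 1L)
      if (nchar(seg) >= min_len && nchar(seg) <= max_len &&
          !grepl("[^ACGT]", seg)) {
        segs <- c(segs, seg)
        ords <- c(ords, g)
        read_of <- c(read_of, i)
      }
    }
    ord_max_by_read[as.character(i)] <- nrow(hits_f) - 1L
  }
  if (!any_repeat)
    ct_error("no_repeat_found",
             sprintf("no read contains the repeat within %d edits",
                     max_repeat_edits))
  if (length(segs) == 0L)
    ct_error("no_repeat_found", "repeats found but no inter-repeat spacers")
  # greedy clustering seeded by the most abundant exact sequences
  uniq <- sort(table(segs), decreasing = TRUE)
  useq <- names(uniq)
  reps <- character(); members <- list()
  for (u in useq) {
    placed <- FALSE
    if (length(reps)) {
      dd <- utils::adist(u, reps)[1L, ]
      lim <- ceiling((1 - identity) * pmax(nchar(u), nchar(reps)))
      j <- which(dd <= lim)
      if (length(j)) {
        j <- j[1L]
        members[[j]] <- c(members[[j]], rep(u, uniq[[u]]))
        placed <- TRUE
      }
    }
    if (!placed) {
      reps <- c(reps, u)
      members[[length(reps)]] <- rep(u, uniq[[u]])
    }
  }
  size <- vapply(members, length, integer(1))
  keep <- size >= min_count
  reps <- reps[keep]; members <- members[keep]
  if (length(reps) == 0L)
    ct_error("no_repeat_found", "no spacer cluster reached min_count")
  # consensus = modal member sequence of the cluster
  consensus <- vapply(members, function(m) {
    tab <- sort(table(m), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  # order clusters leader-to-trailer: topological sort on the pairwise
  # within-read precedence counts, falling back to mean relative position
  # when the evidence is cyclic or absent
  seg_cluster <- integer(length(segs))
  for (j in seq_along(reps)) seg_cluster[segs %in% members[[j]]] <- j
  J <- length(reps)
  prec <- matrix(0L, J, J)
  for (rd in split(seq_along(segs), read_of)) {
    cl <- seg_cluster[rd][order(ords[rd])]
    if (length(cl) > 1L) {
      for (x in seq_len(length(cl) - 1L))
        for (y in seq.int(x + 1L, length(cl)))
          prec[cl[x], cl[y]] <- prec[cl[x], cl[y]] + 1L
    }
  }
  rel <- ords / ord_max_by_read[as.character(read_of)]
  rel_pos <- vapply(seq_len(J), function(j)
    mean(rel[seg_cluster == j]), numeric(1))
  edge <- prec > t(prec)
  ord_idx <- integer(0)
  remaining <- seq_len(J)
  while (length(remaining)) {
    indeg <- vapply(remaining, function(j)
      sum(edge[remaining, j]), integer(1))
    cand <- remaining[indeg == 0L]
    if (!length(cand)) cand <- remaining       # cycle: fall back
    nxt <- cand[which.min(rel_pos[cand])]
    ord_idx <- c(ord_idx, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  consensus <- consensus[ord_idx]
  next_id <- 1L
  if (!is.null(existing_catalog)) {
    known <- existing_catalog$spacers
    best_ident <- vapply(consensus, function(s) {
      1 - min(utils::adist(s, known)[1L, ] /
                pmax(nchar(s), nchar(known)))
    }, numeric(1))
    consensus <- consensus[best_ident < novel_max_identity]
    if (length(consensus) == 0L)
      ct_error("no_repeat_found",
               "all rediscovered spacers match the existing catalog")
    next_id <- max(spacer_ids(existing_catalog)) + 1L
  }
  ids <- seq.int(next_id, length.out = length(consensus))
  spacer_catalog(stats::setNames(consensus, ids), repeat_seq)
}

as_dna_set <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) "fastq" else "fasta"
    return(Biostrings::readDNAStringSet(x, format = fmt))
  }
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  if (inherits(x, "QualityScaledDNAStringSet"))
    return(Biostrings::DNAStringSet(as.character(x)))
  Biostrings::DNAStringSet(x)
}

#' Map catalog spacers and primers onto one read and classify it
#'
#' Finds the best approximate (Levenshtein, at most \code{max_edits} edits)
#' non-overlapping occurrences of both primers and every catalog spacer on
#' both strands. If the primer layout indicates the reverse strand, the
#' read is reverse-complemented before classification. Exactly one QC
#' category is assigned, by the precedence
#' \code{MISSING_PRIMER > TOO_SHORT > MIXED_ORIENTATION > MISORDERED >
#' IRREGULAR_SPACING > PASS}.
#'
#' A read passes when both primers are found, the primer-trimmed region is
#' at least \code{min_len} nt, all spacer hits lie on one strand in catalog
#' order, and consecutive hits are separated by one repeat length (within
#' \code{spacing_tol}).
#'
#' @param read character scalar or \code{DNAString}.
#' @param catalog a \code{spacer_catalog}.
#' @param primers named character vector \code{c(FWD = ..., REV = ...)};
#'   REV is the reverse-primer oligo (it matches the read as its reverse
#'   complement).
#' @param max_edits edit tolerance for primer and spacer hits (5).
#' @param min_len minimum primer-trimmed read length (33, roughly one
#'   spacer).
#' @param spacing_tol slack on the inter-spacer gap around the repeat
#'   length (5 nt).
#' @param read_id optional identifier carried into the result.
#' @return a list of class \code{read_qc}: \code{read_id},
#'   \code{category}, \code{matches} (data frame: spacer_id, start, end,
#'   dist, strand), \code{spacer_ids} (ordered, PASS only), \code{seq}
#'   (orientation-normalised sequence), \code{trim} (primer-trimmed
#'   bounds).
#' @export
map_spacers <- function(read, catalog, primers, max_edits = 5L,
                        min_len = 33L, spacing_tol = 5L, read_id = NA) {
  pats <- compile_patterns(catalog, primers)
  map_spacers_impl(read, pats, max_edits = max_edits, min_len = min_len,
                   spacing_tol = spacing_tol, read_id = read_id)
}

# pre-build DNAString pattern objects once per catalog, so that per-read
# mapping avoids repeated string conversions
compile_patterns <- function(catalog, primers) {
  stopifnot(all(c("FWD", "REV") %in% names(primers)))
  ids <- spacer_ids(catalog)
  list(fwd = Biostrings::DNAString(primers[["FWD"]]),
       rev_rc = Biostrings::DNAString(revcomp(primers[["REV"]])),
       ids = ids,
       plus = lapply(catalog$spacers, Biostrings::DNAString),
       minus = lapply(catalog$spacers,
                      function(s) Biostrings::DNAString(revcomp(s))),
       rep_len = nchar(catalog$repeat_sequence))
}

map_spacers_impl <- function(read, pats, max_edits = 5L, min_len = 33L,
                             spacing_tol = 5L, read_id = NA) {
  sq <- as.character(read)
  subj_f <- Biostrings::DNAString(sq)
  score_orient <- function(s) {
    hf <- find_hits(pats$fwd, s, max_edits)
    hr <- find_hits(pats$rev_rc, s, max_edits)
    list(n = (nrow(hf) > 0) + (nrow(hr) > 0), f = hf, r = hr)
  }
  o_f <- score_orient(subj_f)
  if (o_f$n < 2L) {    # try the reverse strand only when forward is deficient
    subj_r <- Biostrings::reverseComplement(subj_f)
    o_r <- score_orient(subj_r)
    if (o_r$n > o_f$n) { sq <- as.character(subj_r); o_f <- o_r }
  }
  qc <- function(category, matches = NULL, spacer_ids = NULL, trim = NULL) {
    structure(list(read_id = read_id, category = category,
                   matches = matches, spacer_ids = spacer_ids,
                   seq = sq, trim = trim),
              class = "read_qc")
  }
  if (o_f$n < 2L) return(qc("MISSING_PRIMER"))
  # trim at the outermost primer hits (first FWD, last REV)
  p_start <- o_f$f$end[1L] + 1L
  p_end <- o_f$r$start[nrow(o_f$r)] - 1L
  if (p_end - p_start + 1L < min_len) return(qc("TOO_SHORT"))
  inner <- Biostrings::DNAString(substr(sq, p_start, p_end))
  cat_ids <- pats$ids
  collect <- function(strands) {
    hits <- NULL
    for (k in seq_along(cat_ids)) {
      for (strand in strands) {
        pat <- if (strand == "+") pats$plus[[k]] else pats$minus[[k]]
        h <- find_hits(pat, inner, max_edits)
        if (nrow(h)) {
          h$spacer_id <- cat_ids[k]; h$strand <- strand
          h$cat_index <- k
          hits <- rbind(hits, h)
        }
      }
    }
    hits
  }
  # plus strand first: a clean read resolves without the minus-strand scan,
  # and a minus-strand spacer between plus hits surfaces as a spacing gap,
  # which triggers the full two-strand scan below
  res <- classify_hits(collect("+"), pats$rep_len, spacing_tol)
  if (res$category != "PASS")
    res <- classify_hits(collect(c("+", "-")), pats$rep_len, spacing_tol)
  hits <- res$hits
  matches <- if (is.null(hits)) {
    data.frame(spacer_id = integer(), start = integer(), end = integer(),
               dist = integer(), strand = character())
  } else {
    data.frame(spacer_id = hits$spacer_id,
               start = hits$start + p_start - 1L,
               end = hits$end + p_start - 1L,
               dist = hits$dist, strand = hits$strand)
  }
  trim <- c(start = p_start, end = p_end)
  qc(res$category, matches,
     spacer_ids = if (res$category == "PASS") hits$spacer_id else NULL,
     trim = trim)
}

# greedy non-overlapping resolution (ascending edit distance, then leftmost)
# followed by category assignment from the resolved hits
classify_hits <- function(hits, rep_len, spacing_tol) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(category = "IRREGULAR_SPACING", hits = NULL))
  hits <- hits[order(hits$dist, hits$start), , drop = FALSE]
  chosen <- logical(nrow(hits))
  occ_s <- integer(); occ_e <- integer()
  for (r in seq_len(nrow(hits))) {
    if (all(hits$end[r] < occ_s | hits$start[r] > occ_e)) {
      chosen[r] <- TRUE
      occ_s <- c(occ_s, hits$start[r]); occ_e <- c(occ_e, hits$end[r])
    }
  }
  hits <- hits[chosen, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  category <- if (length(unique(hits$strand)) > 1L || hits$strand[1L] == "-")
    "MIXED_ORIENTATION"
  else if (is.unsorted(hits$cat_index, strictly = TRUE))
    "MISORDERED"
  else if (nrow(hits) > 1L &&
           any(abs(hits$start[-1L] - hits$end[-nrow(hits)] - 1L - rep_len) >
                 spacing_tol))
    "IRREGULAR_SPACING"
  else "PASS"
  list(category = category, hits = hits)
}

#' @export
print.read_qc <- function(x, ...) {
  cat(sprintf("Read %s: %s", x$read_id, x$category))
  if (x$category == "PASS")
    cat(" [", paste(x$spacer_ids, collapse = "-"), "]", sep = "")
  cat("\n")
  invisible(x)
}

qc_categories <- c("PASS", "MISSING_PRIMER", "TOO_SHORT",
                   "MIXED_ORIENTATION", "MISORDERED", "IRREGULAR_SPACING")

#' Call CRISPR haplotypes per sample
#'
#' Maps spacers onto every read of every sample, keeps PASS reads and
#' aggregates their ordered spacer-id arrays into per-sample haplotype
#' counts, mirroring the discard bookkeeping of amplicon QC.
#'
#' @param samples named list; each element the reads of one sample (a
#'   \code{DNAStringSet}, character vector, or FASTQ path).
#' @param catalog a \code{spacer_catalog}.
#' @param primers named character vector \code{c(FWD=, REV=)}.
#' @param ... passed to \code{\link{map_spacers}}.
#' @return list of class \code{haplotype_call}: \code{table} (data frame
#'   sample_id, haplotype_id, spacer_ids, read_count), \code{haplotypes}
#'   (named list of \code{crispr_array}), \code{qc} (data frame of
#'   per-sample category counts and fractions).
#' @export
call_haplotypes <- function(samples, catalog, primers, ...) {
  if (length(catalog$spacers) == 0L)
    ct_error("invalid_catalog", "catalog is empty")
  stopifnot(!is.null(names(samples)))
  pats <- compile_patterns(catalog, primers)
  tab <- NULL; qc_rows <- NULL
  haps <- list()
  for (s in names(samples)) {
    reads <- as_dna_set(samples[[s]])
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("%s_r%04d", s, seq_along(reads))
    cats <- character(length(reads))
    arrays <- vector("list", length(reads))
    for (i in seq_along(reads)) {
      q <- map_spacers_impl(as.character(reads[[i]]), pats,
                            read_id = ids[i], ...)
      cats[i] <- q$category
      if (q$category == "PASS") arrays[[i]] <- q$spacer_ids
    }
    counts <- table(factor(cats, levels = qc_categories))
    qc_rows <- rbind(qc_rows, data.frame(
      sample_id = s, category = qc_categories,
      n = as.integer(counts),
      fraction = as.integer(counts) / length(reads)))
    pass <- !vapply(arrays, is.null, logical(1))
    if (!any(pass))
      ct_error("empty_sample",
               sprintf("sample '%s' yielded zero PASS reads", s))
    labs <- vapply(arrays[pass], haplotype_label, character(1))
    cnt <- table(labs)
    first <- arrays[pass][match(names(cnt), labs)]
    for (k in seq_along(cnt)) {
      hid <- names(cnt)[k]
      if (is.null(haps[[hid]])) haps[[hid]] <- crispr_array(first[[k]])
      tab <- rbind(tab, data.frame(
        sample_id = s, haplotype_id = hid,
        spacer_ids = paste(first[[k]], collapse = ","),
        read_count = as.integer(cnt[[k]])))
    }
  }
  structure(list(table = tab, haplotypes = haps, qc = qc_rows),
            class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  n_pass <- sum(x$qc$n[x$qc$category == "PASS"])
  n_tot <- sum(x$qc$n)
  cat(sprintf(
    "Haplotype call: %d samples, %d haplotypes, %d/%d reads PASS (%.1f%% discarded)\n",
    length(unique(x$table$sample_id)), length(x$haplotypes),
    n_pass, n_tot, 100 * (1 - n_pass / n_tot)))
  invisible(x)
}

#' Extract putative new-spacer regions from flagged reads
#'
#' For reads flagged \code{IRREGULAR_SPACING}, returns the subsequence
#' spanning each irregular gap between consecutive regular spacer hits,
#' including the bordering repeats, suitable for re-running
#' \code{\link{discover_spacers}} against the existing catalog.
#'
#' @param qcs list of \code{read_qc} objects (non-flagged entries are
#'   ignored).
#' @param repeat_len length of the repeat (used to include the bordering
#'   repeats in the extracted region).
#' @return a \code{DNAStringSet} of candidate regions (possibly empty),
#'   named \code{<read_id>_gap<k>}.
#' @export
extract_putative_new_spacers <- function(qcs, repeat_len) {
  out <- character(); nms <- character()
  for (q in qcs) {
    if (!inherits(q, "read_qc") || q$category != "IRREGULAR_SPACING") next
    m <- q$matches
    if (is.null(m) || nrow(m) < 2L) next
    for (g in seq_len(nrow(m) - 1L)) {
      gap <- m$start[g + 1L] - m$end[g] - 1L
      if (abs(gap - repeat_len) <= 5L) next
      reg <- substr(q$seq, m$end[g] + 1L, m$start[g + 1L] - 1L)
      out <- c(out, reg)
      nms <- c(nms, sprintf("%s_gap%d", q$read_id, g))
    }
  }
  stats::setNames(Biostrings::DNAStringSet(out), nms)
}
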