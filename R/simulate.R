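# Synthetic data emulating the statistical structure of a CRISPR-typing
# study: nested-deletion haplotype diversity around one long ancestral
# array, hierarchically structured populations with strong outer-level and
# weak inner-level differentiation, and error-prone long amplicon reads.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate spacer-array evolution on a tree (ordered spacer loss)
#'
#' Evolves a CRISPR array down a tree under the ordered independent
#' spacer-loss model: every spacer is lost independently at rate 1 per unit
#' branch length; new spacers are inserted at the leader end, the number of
#' post-divergence survivors on a branch of length t being Poisson with
#' mean \code{rho * (1 - exp(-t))}. Tips whose array goes extinct trigger a
#' resimulation (up to \code{max_retry}), then an error.
#'
#' @param n_haplotypes number of tips (ignored when \code{tree} is given).
#' @param ancestor_length number of spacers in the ancestral array (35).
#' @param rho insertion:deletion rate ratio (0 = deletion-only, the
#'   nested-deletion regime).
#' @param time_scale multiplier applied to the coalescent tree's branch
#'   lengths (depth of a random coalescent tree is ~1).
#' @param tree optional \code{phylo} tree to evolve on (branch lengths in
#'   deletions per spacer).
#' @param spacer_len length of generated spacer sequences (35 nt).
#' @param repeat_len length of the generated repeat (30 nt).
#' @param seed mandatory integer seed.
#' @param max_retry resimulation attempts before \code{extinct_array} (100).
#' @param sequences generate spacer sequences and a catalog (default TRUE);
#'   FALSE returns \code{catalog = NULL}, for studies that only need the
#'   id-level arrays (e.g. divergence-recovery experiments).
#' @return list: \code{tree} (true tree), \code{haplotypes} (named list of
#'   \code{crispr_array}, one per tip; names are tip labels),
#'   \code{catalog} (\code{spacer_catalog} of all spacers present in at
#'   least one tip, ids in ancestral leader-to-trailer order),
#'   \code{ancestor} (the ancestral id vector).
#' @export
simulate_oisl_tree <- function(n_haplotypes = 25, ancestor_length = 35,
                               rho = 0, time_scale = 0.3, tree = NULL,
                               spacer_len = 35, repeat_len = 30,
                               seed, max_retry = 100, sequences = TRUE) {
  if (missing(seed)) ct_error("seed_required", "seed is mandatory")
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_retry)) {
    tr <- tree
    if (is.null(tr)) {
      tr <- ape::rcoal(n_haplotypes)
      tr$edge.length <- tr$edge.length * time_scale
    }
    n_tip <- length(tr$tip.label)
    next_id <- ancestor_length + 1L
    ancestor <- seq_len(ancestor_length)
    arrays <- vector("list", n_tip + tr$Nnode)
    root <- n_tip + 1L
    arrays[[root]] <- ancestor
    ok <- TRUE
    # preorder traversal
    ord <- ape::reorder.phylo(tr, "cladewise")$edge
    lens <- tr$edge.length[match(paste(ord[, 1], ord[, 2]),
                                 paste(tr$edge[, 1], tr$edge[, 2]))]
    for (e in seq_len(nrow(ord))) {
      par <- ord[e, 1L]; child <- ord[e, 2L]; t <- lens[e]
      arr <- arrays[[par]]
      keep <- stats::runif(length(arr)) < exp(-t)
      arr <- arr[keep]
      n_new <- stats::rpois(1L, rho * -expm1(-t))
      if (n_new > 0) {
        new_ids <- seq.int(next_id, length.out = n_new)
        next_id <- next_id + n_new
        arr <- c(rev(new_ids), arr)   # newest insertions most leader-ward
      }
      if (length(arr) == 0L && child <= n_tip) { ok <- FALSE; break }
      arrays[[child]] <- arr
    }
    if (!ok) next
    tips <- arrays[seq_len(n_tip)]
    if (any(vapply(tips, length, integer(1)) == 0L)) next
    names(tips) <- tr$tip.label
    catalog <- NULL
    if (sequences) {
      all_ids <- sort(unique(unlist(tips)))
      seqs <- random_dna(length(all_ids), spacer_len)
      repeat_seq <- random_dna(1L, repeat_len)
      catalog <- spacer_catalog(stats::setNames(seqs, all_ids), repeat_seq)
    }
    haplotypes <- lapply(tips, crispr_array)
    return(list(tree = tr, haplotypes = haplotypes, catalog = catalog,
                ancestor = ancestor))
  }
  ct_error("extinct_array",
           sprintf("a tip array went extinct in all %d attempts", max_retry))
}

# split the elements of `x` into k disjoint pools (round-robin after shuffle)
split_pools <- function(x, k) {
  sh <- sample(x)
  split(sh, rep_len(seq_len(k), length(sh)))
}

#' Simulate a hierarchically structured sampling design
#'
#' Draws per-host haplotype frequencies from level-weighted mixtures so
#' that the expected differentiation at each level follows the supplied
#' weights (e.g. strong among regions, negligible among habitats). At a
#' level with weight 1, the parent's haplotype pool is partitioned into
#' disjoint sub-pools, giving maximal differentiation; at weight w in
#' (0, 1) a group-specific Dirichlet draw is mixed into the parent
#' frequencies with proportion w; weight 0 leaves the parent frequencies
#' untouched.
#'
#' @param haplotypes named list of \code{crispr_array} (names used as
#'   haplotype ids).
#' @param design integer vector: number of groups per level, outermost
#'   first, e.g. \code{c(region = 3, habitat = 2, host = 3)} for 3 regions
#'   x 2 habitats x 3 hosts = 18 hosts.
#' @param weights differentiation weight per level, same length as
#'   \code{design}, each in [0, 1].
#' @param depth reads per innermost unit (a host sample); scalar or vector
#'   recycled over units (default 200).
#' @param concentration Dirichlet concentration of the base frequencies
#'   (1 = uniform simplex; smaller = more skewed).
#' @param seed mandatory integer seed.
#' @return data frame with one row per (unit, haplotype): the level
#'   columns, \code{haplotype_id}, \code{count}.
#' @export
simulate_hierarchy <- function(haplotypes, design, weights, depth = 200,
                               concentration = 1, seed) {
  if (missing(seed)) ct_error("seed_required", "seed is mandatory")
  # identical arrays on different tips are one haplotype: deduplicate
  if (!is.null(names(haplotypes)))
    haplotypes <- haplotypes[!duplicated(names(haplotypes))]
  if (length(haplotypes) < 2L)
    ct_error("invalid_array", "need at least two haplotypes")
  stopifnot(length(design) == length(weights), all(weights >= 0),
            all(weights <= 1))
  set.seed(as.integer(seed))
  lev_names <- names(design)
  if (is.null(lev_names)) lev_names <- paste0("level", seq_along(design))
  haps <- names(haplotypes)
  K <- length(haps)
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), alpha)
    g / sum(g)
  }
  base <- rdirichlet1(rep(concentration, K))
  # recursive descent over the design
  units <- list()
  descend <- function(level, labels, freq, pool) {
    if (level > length(design)) {
      units[[length(units) + 1L]] <<- list(labels = labels, freq = freq)
      return(invisible())
    }
    k <- design[level]
    w <- weights[level]
    pools <- if (w >= 1 && length(pool) >= k) split_pools(pool, k)
    else replicate(k, pool, simplify = FALSE)
    for (g in seq_len(k)) {
      f <- freq
      sub_pool <- pools[[g]]
      f[!(haps %in% sub_pool)] <- 0
      if (sum(f) == 0) f[haps %in% sub_pool] <- 1
      f <- f / sum(f)
      if (w > 0 && w < 1) {
        draw <- rep(0, K)
        on <- haps %in% sub_pool
        draw[on] <- rdirichlet1(rep(1, sum(on)))
        f <- (1 - w) * f + w * draw
      }
      # path-unique label: prefix with the parent label so that the same
      # ordinal under different parents never collides
      parent_lab <- if (length(labels)) labels[[length(labels)]] else ""
      lab_val <- sprintf("%s%s%d", parent_lab,
                         substr(lev_names[level], 1, 1), g)
      descend(level + 1L,
              c(labels, stats::setNames(lab_val, lev_names[level])),
              f, sub_pool)
    }
  }
  descend(1L, stats::setNames(character(0), character(0)), base, haps)
  depth <- rep_len(depth, length(units))
  rows <- NULL
  for (u in seq_along(units)) {
    lab <- units[[u]]$labels
    cnt <- stats::rmultinom(1L, depth[u], units[[u]]$freq)[, 1L]
    nz <- cnt > 0
    df <- as.data.frame(as.list(lab), stringsAsFactors = FALSE)
    df <- df[rep(1L, sum(nz)), , drop = FALSE]
    df$haplotype_id <- haps[nz]
    df$count <- as.integer(cnt[nz])
    rows <- rbind(rows, df)
  }
  rownames(rows) <- NULL
  rows
}

# apply iid substitution/indel errors to one sequence
mutate_seq <- function(sq, sub_rate, indel_rate) {
  if (sub_rate <= 0 && indel_rate <= 0) return(sq)
  bases <- strsplit(sq, "")[[1]]
  out <- character(0)
  alph <- c("A", "C", "G", "T")
  for (b in bases) {
    u <- stats::runif(1)
    if (u < indel_rate / 2) {            # deletion
      next
    } else if (u < indel_rate) {         # insertion before the base
      out <- c(out, sample(alph, 1L), b)
    } else if (u < indel_rate + sub_rate) {
      out <- c(out, sample(setdiff(alph, b), 1L))
    } else {
      out <- c(out, b)
    }
  }
  paste(out, collapse = "")
}

#' Simulate long amplicon reads for called haplotypes
#'
#' Each read is \code{primerF + repeat + (spacer + repeat)* + revcomp(primerR)}
#' for its haplotype, with iid per-base substitution and indel errors and a
#' constant quality string. Configurable fractions of deliberately broken
#' reads (primer dropout, truncation) exercise the QC categories.
#'
#' @param hier data frame from \code{\link{simulate_hierarchy}} (or any
#'   table with stratum columns, \code{haplotype_id}, \code{count}).
#' @param haplotypes named list of \code{crispr_array} covering the table's
#'   haplotype ids.
#' @param catalog \code{spacer_catalog} with the spacer sequences.
#' @param primers named character vector \code{c(FWD=, REV=)} (REV as the
#'   oligo; its reverse complement ends the forward-strand read).
#' @param sub_rate,indel_rate per-base error rates (0.005 each).
#' @param dropout_frac fraction of reads with a missing primer (0).
#' @param truncate_frac fraction of reads truncated below the length
#'   filter (0).
#' @param revcomp_frac fraction of reads emitted reverse-complemented
#'   (0.5; the caller must normalise orientation).
#' @param quality_char constant Phred quality character ("I" = Q40).
#' @param seed mandatory integer seed.
#' @return named list (one element per sample, samples being the distinct
#'   stratum combinations joined by ":"): each a
#'   \code{QualityScaledDNAStringSet}. The truth (haplotype per read) is in
#'   \code{attr(x, "truth")}, a data frame (sample_id, read_id,
#'   haplotype_id, corrupted).
#' @export
simulate_reads <- function(hier, haplotypes, catalog, primers,
                           sub_rate = 0.005, indel_rate = 0.005,
                           dropout_frac = 0, truncate_frac = 0,
                           revcomp_frac = 0.5, quality_char = "I",
                           seed) {
  if (missing(seed)) ct_error("seed_required", "seed is mandatory")
  set.seed(as.integer(seed))
  lev_cols <- setdiff(names(hier), c("haplotype_id", "count"))
  sample_id <- apply(hier[lev_cols], 1L, paste, collapse = ":")
  rep_seq <- catalog$repeat_sequence
  fwd <- primers[["FWD"]]; rev_rc <- revcomp(primers[["REV"]])
  out <- list(); truth <- NULL
  for (s in unique(sample_id)) {
    sub <- hier[sample_id == s, , drop = FALSE]
    seqs <- character(); quals <- character(); nms <- character()
    tr_h <- character(); tr_c <- character()
    ri <- 0L
    for (r in seq_len(nrow(sub))) {
      arr <- haplotypes[[sub$haplotype_id[r]]]
      body <- paste0(rep_seq, paste(
        vapply(as.integer(arr),
               function(id) paste0(catalog$spacers[[as.character(id)]],
                                   rep_seq), character(1)),
        collapse = ""))
      clean <- paste0(fwd, body, rev_rc)
      for (cp in seq_len(sub$count[r])) {
        ri <- ri + 1L
        sq <- clean
        corrupt <- "none"
        u <- stats::runif(1)
        if (u < dropout_frac) {
          corrupt <- "dropout"
          sq <- if (stats::runif(1) < 0.5)
            substr(sq, nchar(fwd) + 1L, nchar(sq))
          else substr(sq, 1L, nchar(sq) - nchar(rev_rc))
        } else if (u < dropout_frac + truncate_frac) {
          corrupt <- "truncated"
          inner <- substr(sq, nchar(fwd) + 1L, nchar(sq) - nchar(rev_rc))
          keep <- sample.int(32L, 1L)   # inner part < 33 nt
          sq <- paste0(fwd, substr(inner, 1L, keep), rev_rc)
        }
        sq <- mutate_seq(sq, sub_rate, indel_rate)
        if (stats::runif(1) < revcomp_frac) sq <- revcomp(sq)
        seqs <- c(seqs, sq)
        nms <- c(nms, sprintf("%s_read%05d", s, ri))
        tr_h <- c(tr_h, sub$haplotype_id[r])
        tr_c <- c(tr_c, corrupt)
      }
    }
    perm <- sample.int(length(seqs))
    seqs <- seqs[perm]; nms <- nms[perm]
    tr_h <- tr_h[perm]; tr_c <- tr_c[perm]
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- nms
    q <- Biostrings::PhredQuality(
      vapply(nchar(seqs), function(n)
        paste(rep(quality_char, n), collapse = ""), character(1)))
    out[[s]] <- Biostrings::QualityScaledDNAStringSet(dna, q)
    truth <- rbind(truth, data.frame(
      sample_id = s, read_id = nms, haplotype_id = tr_h,
      corrupted = tr_c, stringsAsFactors = FALSE))
  }
  attr(out, "truth") <- truth
  out
}

#' Write simulated reads to FASTQ files
#'
#' @param reads result of \code{\link{simulate_reads}}.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulated_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in names(reads)) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", s), ".fastq"))
    Biostrings::writeQualityScaledXStringSet(reads[[s]], p)
    paths[s] <- p
  }
  invisible(paths)
}
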