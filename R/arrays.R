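# Core domain types: spacers, spacer catalogs and CRISPR arrays.
#
# A CRISPR array is stored leader-first: position 1 is the leader (5') end
# where new spacers are inserted, the last position is the trailer end.
# Spacers are referenced by integer ids into a catalog.

#' Create a spacer catalog
#'
#' A spacer catalog holds the unique spacer sequences identified for one
#' CRISPR locus, keyed by integer ids, together with the conserved repeat
#' sequence that separates spacers in the array.
#'
#' @param spacers named character vector of uppercase DNA sequences
#'   (A/C/G/T); names are the integer spacer ids.
#' @param repeat_sequence the conserved repeat (~30 nt, at least 20 nt).
#' @param min_separation minimum pairwise Levenshtein distance allowed
#'   between catalog spacers. Spacers closer than this would be uncallable
#'   as distinct under fuzzy matching; construction fails.
#' @return an object of class \code{spacer_catalog}.
#' @export
spacer_catalog <- function(spacers, repeat_sequence, min_separation = 6L) {
  if (length(spacers) == 0L)
    ct_error("invalid_catalog", "catalog must contain at least one spacer")
  ids <- suppressWarnings(as.integer(names(spacers)))
  if (anyNA(ids) || anyDuplicated(ids))
    ct_error("invalid_catalog", "spacer names must be unique integer ids")
  for (s in spacers) ct_stopifnot_dna(s, "spacer sequence")
  ct_stopifnot_dna(repeat_sequence, "repeat sequence")
  if (nchar(repeat_sequence) < 20L)
    ct_error("invalid_catalog", "repeat sequence must be at least 20 nt")
  if (length(spacers) > 1L) {
    dmat <- utils::adist(spacers)
    off <- dmat[upper.tri(dmat)]
    if (any(off < min_separation)) {
      ct_error("invalid_catalog", sprintf(
        "catalog spacers within %d edits of each other cannot be called as distinct (min observed %d)",
        min_separation, min(off)))
    }
  }
  structure(
    list(spacers = stats::setNames(unname(spacers), as.character(ids)),
         repeat_sequence = repeat_sequence),
    class = "spacer_catalog")
}

#' @export
print.spacer_catalog <- function(x, ...) {
  cat(sprintf("Spacer catalog: %d spacers (lengths %d-%d nt), repeat %d nt\n",
              length(x$spacers),
              min(nchar(x$spacers)), max(nchar(x$spacers)),
              nchar(x$repeat_sequence)))
  invisible(x)
}

#' @export
length.spacer_catalog <- function(x) length(x$spacers)

spacer_ids <- function(catalog) as.integer(names(catalog$spacers))

#' Read / write a spacer catalog as FASTA
#'
#' Record ids are the integer spacer ids; the repeat sequence is stored under
#' the reserved record id \code{REPEAT}.
#'
#' @param path file path.
#' @param catalog a \code{spacer_catalog}.
#' @return \code{read_spacer_catalog} returns a \code{spacer_catalog};
#'   \code{write_spacer_catalog} returns \code{path} invisibly.
#' @export
read_spacer_catalog <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  if (!"REPEAT" %in% nm)
    ct_error("invalid_catalog", "catalog FASTA must contain a REPEAT record")
  rep_seq <- as.character(seqs[[which(nm == "REPEAT")[1L]]])
  keep <- nm != "REPEAT"
  spacer_catalog(stats::setNames(as.character(seqs[keep]), nm[keep]), rep_seq)
}

#' @rdname read_spacer_catalog
#' @export
write_spacer_catalog <- function(catalog, path) {
  seqs <- c(catalog$spacers,
            stats::setNames(catalog$repeat_sequence, "REPEAT"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Construct a CRISPR array (ordered spacer ids, leader first)
#'
#' @param spacer_ids integer vector of spacer ids, position 1 = leader (5')
#'   end. Duplicated ids are rejected: the spacer-loss model has no
#'   duplication process, and alignment by shared spacers would be
#'   ill-defined.
#' @return an integer vector of class \code{crispr_array}.
#' @export
crispr_array <- function(spacer_ids) {
  ids <- as.integer(spacer_ids)
  if (length(ids) == 0L || anyNA(ids))
    ct_error("invalid_array", "array must be a non-empty vector of spacer ids")
  if (anyDuplicated(ids))
    ct_error("invalid_array", "duplicated spacer id within one array")
  structure(ids, class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat("CRISPR array (leader -> trailer): ",
      paste(unclass(x), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Align two CRISPR arrays by their shared spacers
#'
#' Partitions the spacers of two arrays into three classes used by the
#' ordered spacer-loss likelihood: spacers shared by both arrays, spacers
#' unique to one array lying at or trailer-ward of the leader-most shared
#' spacer (\emph{internal} unique: explainable as losses in the other
#' lineage), and spacers unique to one array lying leader-ward of all shared
#' spacers (\emph{leader} unique: candidate new insertions).
#'
#' Shared spacers must occur in the same relative order in both arrays;
#' order-discordant pairs are inconsistent with pure ordered
#' insertion/deletion and raise a \code{collinearity_error}.
#'
#' @param a,b \code{crispr_array} objects (or plain integer id vectors).
#' @return a list of class \code{pair_alignment} with elements
#'   \code{shared}, \code{internal_unique_a}, \code{internal_unique_b},
#'   \code{leader_unique_a}, \code{leader_unique_b}.
#' @export
align_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) == 0L || length(b) == 0L)
    ct_error("invalid_array", "cannot align an empty array")
  shared_set <- intersect(a, b)
  sa <- a[a %in% shared_set]
  sb <- b[b %in% shared_set]
  if (!identical(sa, sb))
    ct_error("collinearity_error", sprintf(
      "shared spacers are order-discordant between arrays (%s vs %s)",
      paste(sa, collapse = ","), paste(sb, collapse = ",")))
  if (length(sa) == 0L) {
    lead_a <- length(a); lead_b <- length(b)
    int_a <- 0L; int_b <- 0L
  } else {
    first_a <- match(sa[1L], a)
    first_b <- match(sa[1L], b)
    lead_a <- sum(!(a[seq_len(first_a - 1L)] %in% shared_set))
    lead_b <- sum(!(b[seq_len(first_b - 1L)] %in% shared_set))
    int_a <- length(a) - length(sa) - lead_a
    int_b <- length(b) - length(sb) - lead_b
  }
  structure(
    list(shared = sa,
         internal_unique_a = int_a, internal_unique_b = int_b,
         leader_unique_a = lead_a, leader_unique_b = lead_b),
    class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf(
    "Pair alignment: %d shared; internal unique %d/%d; leader unique %d/%d\n",
    length(x$shared), x$internal_unique_a, x$internal_unique_b,
    x$leader_unique_a, x$leader_unique_b))
  invisible(x)
}

# ordered-subsequence test: is `sub` obtainable from `full` by deletions only?
is_ordered_subsequence <- function(sub, full) {
  sub <- as.integer(sub); full <- as.integer(full)
  if (!all(sub %in% full)) return(FALSE)
  identical(full[full %in% sub], sub)
}

#' Check a haplotype set for the nested-deletion property
#'
#' In a deletion-only history every observed array is an ordered subsequence
#' of the longest (most ancestral) array. This report identifies the longest
#' array and flags arrays that are not nested within it.
#'
#' @param arrays a list of \code{crispr_array} objects (named or not).
#' @return a data frame with one row per array: \code{label}, \code{length},
#'   \code{nested} (logical), plus attributes \code{ancestral_label} and
#'   \code{ancestral} (the longest array). Report-only; never errors on
#'   non-nested input.
#' @export
validate_nested_deletion_set <- function(arrays) {
  if (length(arrays) == 0L)
    ct_error("invalid_array", "need at least one array")
  labels <- names(arrays)
  if (is.null(labels)) labels <- as.character(seq_along(arrays))
  lens <- vapply(arrays, length, integer(1))
  anc_i <- which.max(lens)   # first longest on ties
  anc <- as.integer(arrays[[anc_i]])
  nested <- vapply(arrays, is_ordered_subsequence, logical(1), full = anc)
  out <- data.frame(label = labels, length = lens, nested = nested,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "ancestral_label") <- labels[anc_i]
  attr(out, "ancestral") <- anc
  out
}

#' Read / write haplotype tables
#'
#' The on-disk haplotype table is a TSV with columns \code{sample_id},
#' \code{haplotype_id}, \code{spacer_ids} (comma-joined, leader to trailer)
#' and \code{read_count}.
#'
#' @param x a data frame in that layout (as produced by
#'   \code{\link{call_haplotypes}}).
#' @param path file path.
#' @return \code{read_haplotype_table} returns the data frame;
#'   \code{write_haplotype_table} returns \code{path} invisibly.
#' @export
write_haplotype_table <- function(x, path) {
  stopifnot(all(c("sample_id", "haplotype_id", "spacer_ids", "read_count")
                %in% names(x)))
  utils::write.table(
    x[, c("sample_id", "haplotype_id", "spacer_ids", "read_count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_table
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(spacer_ids = "character"))
  df$read_count <- as.integer(df$read_count)
  df
}

# haplotype table helpers ----------------------------------------------------

# unique arrays from a haplotype table, as a named list of crispr_array
haplotypes_from_table <- function(tab) {
  u <- !duplicated(tab$haplotype_id)
  stats::setNames(
    lapply(strsplit(tab$spacer_ids[u], ","),
           function(s) crispr_array(as.integer(s))),
    tab$haplotype_id[u])
}

# canonical haplotype id for an array: "H" + joined ids (stable across runs)
haplotype_label <- function(ids) paste0("H", paste(as.integer(ids), collapse = "."))
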