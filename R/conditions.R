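# Typed conditions used across the package. Each error carries a class so
# callers (and the command-line driver) can react to specific failure modes.

ct_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "crisprtype_error")))
}

#' @noRd
ct_stopifnot_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    ct_error("invalid_sequence", sprintf("%s must be a non-empty character scalar", what))
  if (grepl("[^ACGT]", x))
    ct_error("invalid_sequence",
             sprintf("%s contains characters outside A/C/G/T", what))
  invisible(x)
}
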