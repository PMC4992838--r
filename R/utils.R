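#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' Round half-up to a fixed number of decimals
#'
#' Percentages in run reports are presented to one decimal with ties rounded
#' away from zero (so 81.45 -> 81.5), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimals.
#' @return numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC alphabet).
#' @return character vector of reverse complements, uppercase.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
}

#' Validate a sequence table
#'
#' @param seqs tibble with columns `id` and `seq`.
#' @return the input, invisibly, after validation.
#' @keywords internal
validate_seqs <- function(seqs) {
  if (!all(c("id", "seq") %in% names(seqs))) {
    stopf("sequence table needs columns 'id' and 'seq'")
  }
  if (anyDuplicated(seqs$id)) {
    stopf("duplicate sequence id: '%s'", seqs$id[duplicated(seqs$id)][1])
  }
  if (any(!nzchar(seqs$id)) || any(grepl("\\s", seqs$id))) {
    stopf("sequence ids must be non-empty and whitespace-free")
  }
  if (any(nchar(seqs$seq) == 0)) {
    stopf("empty sequence for id '%s'", seqs$id[nchar(seqs$seq) == 0][1])
  }
  invisible(seqs)
}

seq_lengths <- function(seqs) stats::setNames(nchar(seqs$seq), seqs$id)
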