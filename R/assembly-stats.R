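#' Assembly summary statistics
#'
#' Computes the usual draft-genome report: sequence count, total/max/min/mean
#' lengths, N50, GC% and N count. N50 is the length of the sequence at which
#' the descending cumulative length first reaches half the total. GC% is
#' `100 * (G + C) / (A + C + G + T)` — N and ambiguity codes are excluded from
#' the denominator so heavily gapped assemblies report base composition, not
#' gap content.
#'
#' @param seqs sequence table (`id`, `seq`).
#' @return a one-row tibble: `n_sequences`, `total_bp`, `max_bp`, `min_bp`,
#'   `mean_bp` (floor), `n50_bp`, `gc_percent` (one decimal), `n_count`.
#' @export
assembly_summary <- function(seqs) {
  validate_seqs(seqs)
  if (nrow(seqs) == 0) stopf("no sequences")
  lens <- nchar(seqs$seq)
  counts <- base_counts(seqs$seq)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  gc <- if (acgt == 0) NA_real_ else
    round_half_up(100 * sum(counts[c("G", "C")]) / acgt, 1)
  tibble::tibble(
    n_sequences = length(lens),
    total_bp = sum(lens),
    max_bp = max(lens),
    min_bp = min(lens),
    mean_bp = floor(sum(lens) / length(lens)),
    n50_bp = n50(lens),
    gc_percent = gc,
    n_count = unname(counts["N"])
  )
}

base_counts <- function(seqs) {
  m <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs))
  tot <- colSums(m)
  out <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  for (b in names(out)) if (b %in% names(tot)) out[b] <- tot[[b]]
  out
}

#' N50 of a length multiset
#'
#' @param lengths integer vector of sequence lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stopf("no lengths")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Completeness percentage (e.g. CEGMA core-gene recovery)
#'
#' @param n_found genes recovered.
#' @param n_total genes assessed.
#' @return percentage, rounded half-up to one decimal.
#' @export
#' @examples
#' completeness_percent(237, 248) # 95.6
completeness_percent <- function(n_found, n_total) {
  assert_scalar_number(n_found, "n_found")
  assert_scalar_number(n_total, "n_total")
  if (n_total <= 0) stopf("n_total must be positive")
  if (n_found < 0 || n_found > n_total) stopf("n_found must lie in [0, n_total]")
  round_half_up(100 * n_found / n_total, 1)
}

#' Estimate genome size from a k-mer depth histogram
#'
#' The histogram of k-mer occurrence depths from shotgun reads typically shows
#' an error spike at low depth, a valley, and a coverage peak at the modal
#' k-mer depth. Genome size is the total number of genuine k-mers divided by
#' that modal depth: `sum(depth * count)` over depths past the valley, divided
#' by the peak depth. When the histogram rises from its first row (no error
#' spike), the valley is forced just below `min_depth` so all rows count.
#'
#' @param histogram tibble with columns `depth`, `count` (depths increasing).
#' @param k k-mer length the histogram was computed with (metadata only).
#' @param min_depth smallest depth at which the error/signal valley may sit.
#' @return a one-row tibble: `k`, `valley_depth`, `peak_depth`,
#'   `genome_size_bp` (floor).
#' @export
estimate_genome_size <- function(histogram, k = 17, min_depth = 2) {
  if (!all(c("depth", "count") %in% names(histogram))) {
    stopf("histogram needs columns depth, count")
  }
  if (nrow(histogram) < 2) stopf("histogram too short")
  if (any(diff(histogram$depth) <= 0)) stopf("depths must be strictly increasing")
  d <- histogram$depth
  ct <- histogram$count
  n <- length(d)
  if (all(diff(ct) <= 0)) stopf("no coverage peak: histogram is monotonically decreasing")
  if (ct[1] < ct[2]) {
    valley <- min_depth - 1      # rises immediately: no error spike to trim
  } else {
    cand <- which(d >= min_depth & seq_len(n) > 1 & seq_len(n) < n &
                    ct <= ct[c(1, seq_len(n - 1))] & ct < ct[c(seq_len(n)[-1], n)])
    if (length(cand) == 0) stopf("no coverage peak: valley not followed by a rise")
    valley <- d[cand[1]]
  }
  past <- d > valley
  peak <- d[past][which.max(ct[past])]
  size <- floor(sum(as.numeric(d[past]) * ct[past]) / peak)
  tibble::tibble(k = k, valley_depth = valley, peak_depth = peak,
                 genome_size_bp = size)
}

#' Assembly coverage of the estimated genome size
#'
#' @param assembly_bp assembled bases.
#' @param genome_size_bp estimated genome size in bases.
#' @return percentage, rounded half-up to one decimal.
#' @export
#' @examples
#' coverage_percent(471834188, 552400000) # 85.4
coverage_percent <- function(assembly_bp, genome_size_bp) {
  assert_scalar_number(assembly_bp, "assembly_bp")
  assert_scalar_number(genome_size_bp, "genome_size_bp")
  if (assembly_bp <= 0 || genome_size_bp <= 0) stopf("inputs must be positive")
  round_half_up(100 * assembly_bp / genome_size_bp, 1)
}
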