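#' Shannon entropy of base and adjacent-pair composition
#'
#' `mono_entropy()` is the plug-in Shannon entropy of the 4-state base
#' histogram, `di_entropy()` of the 16-state dinucleotide histogram built
#' from adjacent pairs. Both are reported in bits (log base 2), with the
#' `0 * log 0 = 0` convention and no pseudocounts, so the maxima are 2 bits
#' per base and 4 bits per pair. Dinucleotides are overlapping by default
#' (`step = 1`: positions (1,2), (2,3), ..., giving `N - 1` pairs);
#' `step = 2` counts disjoint pairs instead.
#'
#' @param residues A single string over `A`, `C`, `G`, `T`.
#' @param step Dinucleotide stride: 1 (overlapping, default) or 2 (disjoint).
#' @return Entropy in bits (scalar).
#' @examples
#' mono_entropy("ACGT") # 2 bits, the 4-state maximum
#' di_entropy("ACACAC") # 2 pair states at 3:2 odds
#' @export
mono_entropy <- function(residues) {
  shannon_bits(entropy_counts(residues)$mono)
}

#' @rdname mono_entropy
#' @export
di_entropy <- function(residues, step = 1) {
  di <- entropy_counts(residues, step = step)$di
  if (is.null(di)) abort("dinucleotide entropy needs a sequence of length >= 2")
  shannon_bits(di)
}

shannon_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Base and dinucleotide counts of a sequence
#'
#' @inheritParams mono_entropy
#' @return A list with `mono` (named length-4 integer vector) and `di`
#'   (named length-16 integer vector, `NULL` when the sequence is a single
#'   base).
#' @export
entropy_counts <- function(residues, step = 1) {
  stopifnot(is.character(residues), length(residues) == 1)
  if (!step %in% c(1, 2)) abort("step must be 1 or 2")
  n <- nchar(residues)
  if (n < 1) abort("cannot compute entropy of an empty sequence")
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (!all(chars %in% bases)) {
    pos <- which(!chars %in% bases)[1]
    abort(sprintf("invalid residue '%s' at position %d", chars[pos], pos))
  }
  mono <- table(factor(chars, levels = bases))
  di <- NULL
  if (n >= 2) {
    starts <- seq.int(1L, n - 1L, by = step)
    pairs <- paste0(chars[starts], chars[starts + 1L])
    lv <- as.vector(outer(bases, bases, paste0))
    di <- table(factor(pairs, levels = sort(lv)))
  }
  list(
    mono = setNames(as.integer(mono), names(mono)),
    di = if (is.null(di)) NULL else setNames(as.integer(di), names(di))
  )
}

#' Mono- versus dinucleotide entropy regression across sequences
#'
#' Across a collection of sequences, the mononucleotide entropy is expected
#' to track the dinucleotide entropy roughly proportionally; this fits
#' ordinary least squares of `mono_bits` on `di_bits` and reports the R².
#'
#' @param metrics A data frame with numeric columns `mono_bits` and
#'   `di_bits`, one row per sequence (e.g. from [seq_metrics()]).
#' @return An [ols_fit()] object.
#' @export
mono_di_correlation <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  if (!all(c("mono_bits", "di_bits") %in% names(metrics))) {
    abort("metrics must have columns mono_bits and di_bits")
  }
  keep <- stats::complete.cases(metrics[, c("mono_bits", "di_bits")])
  if (sum(keep) < 3) abort("at least 3 sequences with both entropies are required")
  ols_fit(metrics$di_bits[keep], metrics$mono_bits[keep])
}
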