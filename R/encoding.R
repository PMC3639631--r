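#' Atomic-number encoding of nucleotide bases
#'
#' The default encoding maps each base to the sum of the atomic numbers of
#' the atoms in its nucleobase: adenine (C5H5N5) 70, cytosine (C4H5N3O) 58,
#' guanine (C5H5N5O) 78, thymine (C5H6N2O2) 66. Uracil (C4H4N2O2) sums to
#' 58, colliding with cytosine, which is why `U` is folded into `T` at read
#' time ([read_fasta()]) rather than encoded on its own.
#'
#' The Higuchi fractal dimension is invariant under affine re-mapping of the
#' encoding values, so any alternative single-scalar-per-base scheme that is
#' an affine image of this one yields identical fractal dimensions.
#'
#' @return Named numeric vector over `A`, `C`, `G`, `T`.
#' @examples
#' default_encoding_map()
#' @export
default_encoding_map <- function() {
  c(A = 70, C = 58, G = 78, T = 66)
}

validate_encoding_map <- function(map) {
  if (!is.numeric(map) || is.null(names(map))) {
    abort("encoding map must be a named numeric vector")
  }
  missing <- setdiff(c("A", "C", "G", "T"), names(map))
  if (length(missing) > 0) {
    abort(paste0("encoding map lacks values for: ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(map[c("A", "C", "G", "T")]))) {
    abort("encoding map values must be finite")
  }
  map[c("A", "C", "G", "T")]
}

#' Read an encoding map from a key=value file
#'
#' One `BASE=value` pair per line; blank lines and lines starting with `#`
#' are ignored. All four of `A`, `C`, `G`, `T` must be present.
#'
#' @param path Path to the key=value file.
#' @return Named numeric vector over `A`, `C`, `G`, `T`.
#' @export
read_encoding_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort(paste0("malformed encoding line: ", lines[bad][1]))
  }
  keys <- toupper(trimws(vapply(parts, `[[`, character(1), 1)))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, character(1), 2))))
  validate_encoding_map(setNames(vals, keys))
}

#' Encode a nucleotide sequence as a numeric series
#'
#' Maps each residue of a validated `{A,C,G,T}` sequence to a scalar,
#' producing the 1-D series whose fluctuation structure the Higuchi
#' estimator measures.
#'
#' @param residues A single character string over `A`, `C`, `G`, `T`.
#' @param map Named numeric encoding, default [default_encoding_map()].
#' @return Numeric vector of the same length as the sequence.
#' @examples
#' encode_atomic("ACGT")
#' @export
encode_atomic <- function(residues, map = default_encoding_map()) {
  stopifnot(is.character(residues), length(residues) == 1)
  map <- validate_encoding_map(map)
  if (nchar(residues) == 0) abort("cannot encode an empty sequence")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  values <- unname(map[chars])
  if (anyNA(values)) {
    pos <- which(is.na(values))[1]
    abort(sprintf("invalid residue '%s' at position %d", chars[pos], pos))
  }
  values
}
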