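#' Read nucleotide sequences from a FASTA file
#'
#' Residues are uppercased and `U` is folded into `T` (transcript pastes are
#' accepted, but uracil must not receive its own encoding value — its atom
#' sum collides with cytosine's). Any character outside `{A, C, G, T, U}`
#' is rejected by default with the offending record and position named;
#' `drop_invalid = TRUE` instead drops such records with a warning, since
#' fractal dimension and entropy are undefined for ambiguity codes under
#' the 4-letter model.
#'
#' @param path Path to a FASTA file (multi-record, wrapped lines allowed).
#' @param drop_invalid Drop records with non-`ACGTU` characters instead of
#'   erroring? Default FALSE.
#' @return A tibble with columns `id`, `residues`, `length`, in file order.
#' @seealso [write_fasta()], [load_pairs()]
#' @export
read_fasta <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("could not parse FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id: ", ids[duplicated(ids)][1]))
  }
  residues <- toupper(as.character(set))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  bad_at <- regexpr("[^ACGT]", residues)
  if (any(bad_at > 0)) {
    idx <- which(bad_at > 0)
    if (!drop_invalid) {
      i <- idx[1]
      abort(sprintf(
        "record '%s': invalid character '%s' at position %d (only A/C/G/T/U allowed)",
        ids[i], substr(residues[i], bad_at[i], bad_at[i]), bad_at[i]
      ))
    }
    warn(paste0(
      "dropping ", length(idx), " record(s) with non-ACGTU characters: ",
      paste(ids[idx], collapse = ", ")
    ))
    keep <- setdiff(seq_along(ids), idx)
    ids <- ids[keep]
    residues <- residues[keep]
  }
  if (any(nchar(residues) == 0)) {
    abort(paste0("empty sequence record: ", ids[nchar(residues) == 0][1]))
  }
  tibble(id = unname(ids), residues = unname(residues), length = nchar(unname(residues)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `residues`.
#' @param path Output path.
#' @param width Line-wrap width, default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Derive the concatenated noncoding remainder of an mRNA
#'
#' The noncoding remainder — the "lncRNA" of an mRNA in this analysis — is
#' the 5' leader and 3' trailer joined together: everything before and after
#' the CDS, in mRNA order. The CDS is located either by 1-based inclusive
#' coordinates or, failing that, by a unique exact substring match; an
#' ambiguous (multiple-match) or absent CDS is an error, since a
#' multi-placement CDS has no well-defined remainder.
#'
#' @param mrna mRNA residue string.
#' @param cds CDS residue string (used when coordinates are not given).
#' @param cds_start,cds_end 1-based inclusive CDS coordinates on the mRNA.
#' @return The noncoding residue string (possibly empty when the CDS spans
#'   the whole mRNA).
#' @examples
#' extract_noncoding("AAACCCGGGTTT", "CCCGGG") # "AAATTT"
#' @export
extract_noncoding <- function(mrna, cds = NULL, cds_start = NULL, cds_end = NULL) {
  stopifnot(is.character(mrna), length(mrna) == 1)
  n <- nchar(mrna)
  if (is.null(cds_start) != is.null(cds_end)) {
    abort("cds_start and cds_end must be given together")
  }
  if (is.null(cds_start)) {
    if (is.null(cds)) abort("either cds or cds_start/cds_end is required")
    loc <- locate_cds(mrna, cds)
    cds_start <- loc$start
    cds_end <- loc$end
  } else {
    cds_start <- as.integer(cds_start)
    cds_end <- as.integer(cds_end)
    if (cds_start < 1 || cds_end > n || cds_start > cds_end) {
      abort(sprintf("CDS coordinates [%d, %d] out of range for mRNA of length %d", cds_start, cds_end, n))
    }
    if (!is.null(cds) && substr(mrna, cds_start, cds_end) != cds) {
      abort("CDS residues do not match the mRNA at the given coordinates")
    }
  }
  paste0(substr(mrna, 1, cds_start - 1), substr(mrna, cds_end + 1, n))
}

# exact-substring CDS placement; errors on absent or ambiguous placement
locate_cds <- function(mrna, cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  if (nchar(cds) == 0 || nchar(cds) > nchar(mrna)) {
    abort("CDS must be non-empty and no longer than the mRNA")
  }
  hits <- stringr::str_locate_all(mrna, stringr::fixed(cds))[[1]]
  if (nrow(hits) == 0) abort("CDS not found as a contiguous substring of the mRNA")
  if (nrow(hits) > 1) {
    abort(sprintf("ambiguous CDS placement: %d matches on the mRNA", nrow(hits)))
  }
  list(start = hits[1, 1], end = hits[1, 2])
}

#' Load mRNA/CDS pairs from a manifest
#'
#' The manifest is tab-separated with a header and columns `gene`,
#' `mrna_id`, and either `cds_id` (the CDS is its own FASTA record) or
#' `cds_start`/`cds_end` (1-based inclusive coordinates on the mRNA — the
#' GenBank feature convention). Each row is resolved against the sequences
#' and the concatenated noncoding remainder is derived. When the CDS is
#' supplied as a record and does not occur as a unique contiguous substring
#' of its mRNA, the pair is kept but its `noncoding` is `NA` (metrics for
#' the remainder are then unavailable).
#'
#' @param manifest Path to the manifest TSV.
#' @param sequences Sequences to resolve ids against: a FASTA file path, a
#'   directory of `.fasta`/`.fa` files, or a tibble from [read_fasta()].
#' @return A tibble with one row per pair: `gene`, `mrna_id`, `cds_id`,
#'   `cds_start`, `cds_end`, `mrna`, `cds`, `noncoding`.
#' @export
load_pairs <- function(manifest, sequences) {
  man <- readr::read_tsv(manifest, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "mrna_id") %in% names(man))) {
    abort("manifest must have columns gene and mrna_id")
  }
  if (!"cds_id" %in% names(man)) man$cds_id <- NA_character_
  if (!"cds_start" %in% names(man)) man$cds_start <- NA_integer_
  if (!"cds_end" %in% names(man)) man$cds_end <- NA_integer_
  seqs <- resolve_sequences(sequences)
  lookup <- setNames(seqs$residues, seqs$id)

  purrr::pmap_dfr(man, function(gene, mrna_id, cds_id, cds_start, cds_end, ...) {
    if (!mrna_id %in% names(lookup)) {
      abort(sprintf("gene %s: mRNA id '%s' not found in sequences", gene, mrna_id))
    }
    mrna <- lookup[[mrna_id]]
    has_coords <- !is.na(cds_start) && !is.na(cds_end)
    has_id <- !is.na(cds_id) && nzchar(cds_id)
    if (has_coords == has_id) {
      abort(sprintf("gene %s: give either cds_id or cds_start/cds_end, not both or neither", gene))
    }
    if (has_coords) {
      cds_start <- as.integer(cds_start)
      cds_end <- as.integer(cds_end)
      if (cds_start < 1 || cds_end > nchar(mrna) || cds_start > cds_end) {
        abort(sprintf(
          "gene %s: CDS coordinates [%d, %d] out of range for mRNA of length %d",
          gene, cds_start, cds_end, nchar(mrna)
        ))
      }
      cds <- substr(mrna, cds_start, cds_end)
      noncoding <- extract_noncoding(mrna, cds_start = cds_start, cds_end = cds_end)
      cds_id <- NA_character_
    } else {
      if (!cds_id %in% names(lookup)) {
        abort(sprintf("gene %s: CDS id '%s' not found in sequences", gene, cds_id))
      }
      cds <- lookup[[cds_id]]
      if (nchar(cds) > nchar(mrna)) {
        abort(sprintf("gene %s: CDS is longer than its mRNA", gene))
      }
      loc <- tryCatch(locate_cds(mrna, cds), error = function(e) NULL)
      if (is.null(loc)) {
        warn(sprintf(
          "gene %s: CDS '%s' has no unique contiguous placement on '%s'; noncoding unavailable",
          gene, cds_id, mrna_id
        ))
        cds_start <- NA_integer_
        cds_end <- NA_integer_
        noncoding <- NA_character_
      } else {
        cds_start <- as.integer(loc$start)
        cds_end <- as.integer(loc$end)
        noncoding <- extract_noncoding(mrna, cds_start = cds_start, cds_end = cds_end)
      }
    }
    tibble(
      gene = gene, mrna_id = mrna_id, cds_id = cds_id,
      cds_start = cds_start, cds_end = cds_end,
      mrna = mrna, cds = cds, noncoding = noncoding
    )
  })
}

resolve_sequences <- function(sequences) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("id", "residues") %in% names(sequences)))
    return(sequences)
  }
  stopifnot(is.character(sequences), length(sequences) == 1)
  if (dir.exists(sequences)) {
    files <- list.files(sequences, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no FASTA files in directory ", sequences))
    out <- purrr::map_dfr(sort(files), read_fasta)
    if (anyDuplicated(out$id)) {
      abort(paste0("duplicate sequence id across files: ", out$id[duplicated(out$id)][1]))
    }
    return(out)
  }
  read_fasta(sequences)
}
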