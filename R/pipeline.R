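#' Per-sequence fractal dimension and entropy metrics
#'
#' Computes, for each sequence, its length, Higuchi fractal dimension of the
#' atomic-number series, and Shannon mono- and dinucleotide entropies.
#' Per-record failures (e.g. a homopolymer, whose fractal dimension is
#' undefined) are recorded in the `error` column; they never abort the
#' batch.
#'
#' @param seqs A data frame with columns `id` and `residues`; any extra
#'   columns (e.g. `group`, `role`) are carried through.
#' @param max_k Largest Higuchi lag, default 7.
#' @param map Encoding map, default [default_encoding_map()].
#' @param di_step Dinucleotide stride (1 overlapping, 2 disjoint).
#' @return A tibble with `id`, carried-through columns, `length`, `fd`,
#'   `intercept`, `mono_bits`, `di_bits`, `error`.
#' @export
seq_metrics <- function(seqs, max_k = 7, map = default_encoding_map(), di_step = 1) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  metrics <- purrr::map_dfr(seqs$residues, function(res) {
    f <- fd_safely(res, max_k = max_k, map = map)
    mono <- tryCatch(mono_entropy(res), error = function(e) NA_real_)
    di <- tryCatch(di_entropy(res, step = di_step), error = function(e) NA_real_)
    tibble(
      length = nchar(res), fd = f$fd, intercept = f$intercept,
      mono_bits = mono, di_bits = di, error = f$error
    )
  })
  dplyr::bind_cols(dplyr::select(seqs, -"residues"), metrics)
}

#' Compare fractal dimension and entropy of mRNAs against their CDSs
#'
#' One row per mRNA/CDS pair, carrying the fractal dimensions of both
#' sequences, their difference `delta = fd_cds - fd_mrna` (positive when
#' the coding sequence is the more irregular one), the CDS/mRNA length
#' ratio, entropies of both, and metrics of the concatenated noncoding
#' remainder when it is available and non-degenerate. Per-pair failures are
#' recorded in `error` and do not abort the batch.
#'
#' @param pairs A data frame of pairs as returned by [load_pairs()] or
#'   [gen_pair_panel()]: columns `gene`, `mrna`, `cds`, optionally
#'   `noncoding` and `mrna_id`.
#' @inheritParams seq_metrics
#' @return A tibble with one row per pair: lengths, `len_ratio`, `fd_mrna`,
#'   `fd_cds`, `delta`, entropies for mRNA/CDS, noncoding metrics
#'   (`fd_noncoding`, `mono_bits_noncoding`, `di_bits_noncoding`, `NA` when
#'   unavailable), and `error`.
#' @export
compare_fd <- function(pairs, max_k = 7, map = default_encoding_map(), di_step = 1) {
  stopifnot(is.data.frame(pairs), all(c("gene", "mrna", "cds") %in% names(pairs)))
  if (nrow(pairs) < 1) abort("at least one pair is required")
  if (!"noncoding" %in% names(pairs)) pairs$noncoding <- NA_character_
  if (!"mrna_id" %in% names(pairs)) pairs$mrna_id <- pairs$gene

  purrr::pmap_dfr(
    dplyr::select(pairs, "gene", "mrna_id", "mrna", "cds", "noncoding"),
    function(gene, mrna_id, mrna, cds, noncoding) {
      fm <- fd_safely(mrna, max_k, map)
      fc <- fd_safely(cds, max_k, map)
      err <- c(
        if (!is.na(fm$error)) paste0("mrna: ", fm$error),
        if (!is.na(fc$error)) paste0("cds: ", fc$error)
      )
      nc_ok <- !is.na(noncoding) && nchar(noncoding) > 1
      fn <- if (nc_ok) fd_safely(noncoding, max_k, map) else list(fd = NA_real_)
      tibble(
        gene = gene, mrna_id = mrna_id,
        len_mrna = nchar(mrna), len_cds = nchar(cds),
        len_ratio = nchar(cds) / nchar(mrna),
        fd_mrna = fm$fd, fd_cds = fc$fd, delta = fc$fd - fm$fd,
        mono_bits_mrna = tryCatch(mono_entropy(mrna), error = function(e) NA_real_),
        di_bits_mrna = tryCatch(di_entropy(mrna, step = di_step), error = function(e) NA_real_),
        mono_bits_cds = tryCatch(mono_entropy(cds), error = function(e) NA_real_),
        di_bits_cds = tryCatch(di_entropy(cds, step = di_step), error = function(e) NA_real_),
        fd_noncoding = fn$fd,
        mono_bits_noncoding = if (nc_ok) tryCatch(mono_entropy(noncoding), error = function(e) NA_real_) else NA_real_,
        di_bits_noncoding = if (nc_ok) tryCatch(di_entropy(noncoding, step = di_step), error = function(e) NA_real_) else NA_real_,
        error = if (length(err)) paste(err, collapse = "; ") else NA_character_
      )
    }
  )
}

#' Regress fractal dimension on the CDS/mRNA length ratio
#'
#' @param rows A [compare_fd()] table.
#' @param which Which fractal dimension to use as response: `"mrna"` or
#'   `"cds"`.
#' @return An [ols_fit()] of `fd` on `len_ratio`.
#' @export
fd_vs_ratio <- function(rows, which = c("mrna", "cds")) {
  which <- match.arg(which)
  col <- paste0("fd_", which)
  stopifnot(is.data.frame(rows), all(c(col, "len_ratio") %in% names(rows)))
  keep <- is.finite(rows[[col]]) & is.finite(rows$len_ratio)
  if (sum(keep) < 3) abort("at least 3 rows with finite values are required")
  ols_fit(rows$len_ratio[keep], rows[[col]][keep])
}

#' Group-inclusion regression study over mRNA/CDS pairs
#'
#' For each named subset of genes, fits ordinary least squares of CDS
#' fractal dimension on mRNA fractal dimension (x = mRNA FD, y = CDS FD)
#' and reports slope, intercept, R² and adjusted R². This is the
#' include/exclude comparison used to judge whether adding a gene family
#' tightens or loosens the mRNA-CDS relation. Undersized or degenerate
#' subsets yield a row with `NA` estimates and an `error` message; the
#' batch continues.
#'
#' @param rows A [compare_fd()] table.
#' @param subsets Named list; each element is a character vector of `gene`
#'   labels selecting rows. Output rows keep the list order.
#' @return A tibble with columns `subset`, `n`, `slope`, `intercept`, `r2`,
#'   `adjusted_r2`, `error`.
#' @export
inclusion_study <- function(rows, subsets) {
  stopifnot(is.data.frame(rows), all(c("gene", "fd_mrna", "fd_cds") %in% names(rows)))
  if (length(subsets) == 0) {
    return(tibble(
      subset = character(), n = integer(), slope = numeric(),
      intercept = numeric(), r2 = numeric(), adjusted_r2 = numeric(),
      error = character()
    ))
  }
  if (is.null(names(subsets)) || any(!nzchar(names(subsets)))) {
    abort("subsets must be a named list of gene-label vectors")
  }
  purrr::imap_dfr(subsets, function(genes, name) {
    sel <- rows[rows$gene %in% genes, , drop = FALSE]
    fit <- tryCatch(
      {
        keep <- is.finite(sel$fd_mrna) & is.finite(sel$fd_cds)
        if (sum(keep) < 3) abort(sprintf("subset selects %d usable rows; need >= 3", sum(keep)))
        ols_fit(sel$fd_mrna[keep], sel$fd_cds[keep])
      },
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      tibble(
        subset = name, n = nrow(sel), slope = NA_real_, intercept = NA_real_,
        r2 = NA_real_, adjusted_r2 = NA_real_, error = conditionMessage(fit)
      )
    } else {
      tibble(
        subset = name, n = fit$n, slope = fit$slope, intercept = fit$intercept,
        r2 = fit$r2, adjusted_r2 = fit$adjusted_r2, error = NA_character_
      )
    }
  })
}

#' Fractal-dimension/entropy map with designated outliers
#'
#' Places each sequence on the (fractal dimension, entropy) plane and
#' regresses entropy on fractal dimension over a designated subset of
#' points. Points outside the subset (e.g. a species known a priori to sit
#' off the trend) are never dropped automatically — exclusion is by
#' explicit id — and are reported with their residual from the fitted
#' line.
#'
#' @param metrics A [seq_metrics()] table (columns `id`, `fd`, `mono_bits`,
#'   `di_bits`).
#' @param entropy_kind `"di"` (default) or `"mono"`: which entropy forms the
#'   y axis.
#' @param regress_on Character vector of `id`s included in the regression;
#'   `NULL` (default) uses all points with finite coordinates.
#' @return An object of class `fd_entropy_map`: list with `points` (tibble
#'   `id`, `fd`, `entropy_bits`, `in_regression`, `residual`), `fit` (an
#'   [ols_fit()]), and `entropy_kind`. [tidy()] returns the points,
#'   [glance()] the fit summary.
#' @export
fd_entropy_map <- function(metrics, entropy_kind = c("di", "mono"), regress_on = NULL) {
  entropy_kind <- match.arg(entropy_kind)
  col <- paste0(entropy_kind, "_bits")
  stopifnot(is.data.frame(metrics), all(c("id", "fd", col) %in% names(metrics)))
  pts <- tibble(
    id = metrics$id,
    fd = metrics$fd,
    entropy_bits = metrics[[col]]
  )
  usable <- is.finite(pts$fd) & is.finite(pts$entropy_bits)
  in_reg <- if (is.null(regress_on)) usable else usable & pts$id %in% regress_on
  if (sum(in_reg) < 3) abort("at least 3 points are required for the regression")
  fit <- ols_fit(pts$fd[in_reg], pts$entropy_bits[in_reg])
  pts$in_regression <- in_reg
  pts$residual <- pts$entropy_bits - (fit$intercept + fit$slope * pts$fd)
  structure(
    list(points = pts, fit = fit, entropy_kind = entropy_kind),
    class = "fd_entropy_map"
  )
}

#' @export
print.fd_entropy_map <- function(x, ...) {
  cat(sprintf(
    "FD-entropy map (%snucleotide entropy): %d points, %d in regression\n",
    x$entropy_kind, nrow(x$points), sum(x$points$in_regression)
  ))
  print(x$fit)
  invisible(x)
}

#' @rdname fd_entropy_map
#' @param x An `fd_entropy_map` object.
#' @param ... Unused.
#' @export
tidy.fd_entropy_map <- function(x, ...) x$points

#' @rdname fd_entropy_map
#' @export
glance.fd_entropy_map <- function(x, ...) {
  dplyr::mutate(glance(x$fit), entropy_kind = x$entropy_kind)
}

#' Per-gene skewness of expression distributions
#'
#' Computes the sample skewness of each gene's expression values across
#' regions (optionally per subject), ranks genes by skewness, and leaves
#' per-gene failures (e.g. a constant row) as `error` entries without
#' aborting the batch. A heavy right tail — high positive skewness — marks
#' a gene whose expression is concentrated in few regions.
#'
#' @param table Expression values, long format: columns `gene`, `region`,
#'   `value`, optionally `subject`. A wide gene-by-region data frame (first
#'   column `gene`, remaining columns numeric) is also accepted and pivoted
#'   internally.
#' @param adjusted Use the adjusted Fisher-Pearson coefficient (default) or
#'   plain `g1`.
#' @param per_subject When TRUE and a `subject` column is present, skewness
#'   is computed per gene and subject instead of pooling subjects.
#' @return A tibble `gene` (+ `subject`), `n`, `mean`, `sd`, `skewness`,
#'   `rank` (1 = most right-skewed), `error`.
#' @export
expression_skewness <- function(table, adjusted = TRUE, per_subject = FALSE) {
  stopifnot(is.data.frame(table))
  if (!all(c("gene", "value") %in% names(table))) {
    num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    if (!"gene" %in% names(table) || length(num_cols) == 0) {
      abort("table must be long (gene, region, value) or wide (gene + numeric region columns)")
    }
    table <- tidyr::pivot_longer(table, dplyr::all_of(num_cols),
      names_to = "region", values_to = "value"
    )
  }
  bad <- !is.finite(table$value)
  if (any(bad)) {
    where <- table[bad, , drop = FALSE]
    abort(paste0(
      "non-finite expression values at: ",
      paste(utils::head(paste0(
        where$gene, "/",
        if ("region" %in% names(where)) where$region else "?"
      ), 5), collapse = ", ")
    ))
  }
  keys <- if (per_subject && "subject" %in% names(table)) c("gene", "subject") else "gene"
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      res = list(tryCatch(skewness(.data$value, adjusted = adjusted), error = function(e) e)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = purrr::map_int(.data$res, ~ if (inherits(.x, "error")) NA_integer_ else .x$n),
      mean = purrr::map_dbl(.data$res, ~ if (inherits(.x, "error")) NA_real_ else .x$mean),
      sd = purrr::map_dbl(.data$res, ~ if (inherits(.x, "error")) NA_real_ else .x$sd),
      skewness = purrr::map_dbl(.data$res, ~ if (inherits(.x, "error")) NA_real_ else .x$skewness),
      error = purrr::map_chr(.data$res, ~ if (inherits(.x, "error")) conditionMessage(.x) else NA_character_)
    ) |>
    dplyr::select(-"res")
  out$rank <- rank(-out$skewness, ties.method = "min", na.last = "keep")
  dplyr::arrange(out, .data$rank)
}

#' Ratio of skewness between two genes
#'
#' Convenience for contrasts such as receptor-versus-receptor skewness
#' comparisons.
#'
#' @param skew_table Output of [expression_skewness()].
#' @param gene_a,gene_b Gene labels; the returned value is
#'   `skew(gene_a)/skew(gene_b)`.
#' @return A single number.
#' @export
skewness_ratio <- function(skew_table, gene_a, gene_b) {
  stopifnot(is.data.frame(skew_table), all(c("gene", "skewness") %in% names(skew_table)))
  a <- skew_table$skewness[match(gene_a, skew_table$gene)]
  b <- skew_table$skewness[match(gene_b, skew_table$gene)]
  if (is.na(a) || is.na(b)) abort("both genes must have a computed skewness")
  a / b
}
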