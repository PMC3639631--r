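# independent oracles and small fixture builders used across the suite

# naive O(N * maxK) double loop over all (i, i - k) pairs, normalized as
# the vectorized implementation claims to be
brute_curve_lengths <- function(x, max_k) {
  n <- length(x)
  vapply(seq_len(max_k), function(k) {
    s <- 0
    for (i in (k + 1):n) s <- s + abs(x[i] - x[i - k])
    s / k / k * (n - 1) / (n - k)
  }, numeric(1))
}

# random encoded-base series of length n
random_base_series <- function(n) {
  unname(c(A = 70, C = 58, G = 78, T = 66)[sample(c("A", "C", "G", "T"), n, replace = TRUE)])
}

random_residues <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# linearized de Bruijn cycle over the 4-letter alphabet, order 2: a string
# of length 17 whose 16 overlapping pairs are exactly the 16 dinucleotides
# (tests assert this property before relying on it)
de_bruijn_order2 <- function() {
  "AACAGATCCGCTGGTTA"
}

write_temp_fasta <- function(seqs, width = 60) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  lines <- unlist(lapply(names(seqs), function(id) {
    res <- seqs[[id]]
    c(paste0(">", id), substring(res, seq(1, nchar(res), width),
      pmin(seq(1, nchar(res), width) + width - 1, nchar(res))
    ))
  }))
  writeLines(lines, path)
  path
}

# compact panel for pipeline tests that do not need the shipped fixture
tiny_panel <- function(seed = 7) {
  gen_pair_panel(
    n_pairs = 4, n_negative = 1, mrna_length = 1200,
    fd_mrna_range = c(2.03, 2.06), seed = seed
  )
}
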