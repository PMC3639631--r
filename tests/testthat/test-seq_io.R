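test_that("FASTA records are normalized: case folded, U to T, file order kept", {
  path <- write_temp_fasta(list(x = "acgt", y = "ACGU", z = "AAccTTgg"))
  seqs <- read_fasta(path)
  expect_equal(seqs$id, c("x", "y", "z"))
  expect_equal(seqs$residues, c("ACGT", "ACGT", "AACCTTGG"))
  expect_equal(seqs$length, c(4, 4, 8))
})

test_that("wrapped multi-line records round-trip through write_fasta", {
  withr::with_seed(808, {
    seqs <- tibble::tibble(
      id = paste0("s", 1:5),
      residues = vapply(sample(150:400, 5), random_residues, character(1))
    )
    path <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(seqs, path, width = 60)
    back <- read_fasta(path)
    expect_equal(back$id, seqs$id)
    expect_equal(back$residues, seqs$residues)
  })
})

test_that("invalid characters are rejected naming record and position", {
  path <- write_temp_fasta(list(x = "ACGNNA"))
  expect_error(read_fasta(path), "record 'x'.*'N' at position 4")
  expect_warning(out <- read_fasta(path, drop_invalid = TRUE), "dropping 1")
  expect_equal(nrow(out), 0)
  # empty and malformed inputs
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no FASTA records|could not parse")
  expect_error(read_fasta("/nonexistent/file.fasta"), "no such file")
  dup <- write_temp_fasta(list(a = "ACGT"))
  cat(">a\nGGCC\n", file = dup, append = TRUE)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("the noncoding remainder is the 5' and 3' flanks joined in mRNA order", {
  expect_equal(extract_noncoding("AAACCCGGGTTT", "CCCGGG"), "AAATTT")
  expect_equal(extract_noncoding("AAACCCGGGTTT", cds_start = 4, cds_end = 9), "AAATTT")
  # CDS spanning the whole mRNA leaves an empty remainder
  expect_equal(extract_noncoding("ACGT", "ACGT"), "")
  # ambiguous placement is refused
  expect_error(extract_noncoding("ACACAC", "CA"), "ambiguous")
  expect_error(extract_noncoding("ACGT", "TTT"), "not found")
  expect_error(extract_noncoding("ACGT", cds_start = 2, cds_end = 9), "out of range")
  expect_error(
    extract_noncoding("AAACCCGGGTTT", "GGGGGG", cds_start = 4, cds_end = 9),
    "do not match"
  )
  # position-faithfulness: remainder is a subsequence of the mRNA
  withr::with_seed(909, {
    for (i in 1:10) {
      m <- random_residues(100)
      st <- sample(1:80, 1)
      en <- st + sample(5:19, 1)
      nc <- extract_noncoding(m, cds_start = st, cds_end = en)
      expect_equal(nc, paste0(substr(m, 1, st - 1), substr(m, en + 1, 100)))
    }
  })
})

test_that("manifests resolve by coordinates with strict range checks", {
  m1 <- random_residues(10)
  fasta <- write_temp_fasta(list(m1 = m1))
  manifest <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmrna_id\tcds_start\tcds_end", "geneX\tm1\t3\t8"), manifest)
  pairs <- load_pairs(manifest, fasta)
  expect_equal(nchar(pairs$cds), 6)
  expect_equal(nchar(pairs$noncoding), 4)
  expect_equal(nchar(pairs$mrna), nchar(pairs$cds) + nchar(pairs$noncoding))
  expect_equal(pairs$cds, substr(m1, 3, 8))
  writeLines(c("gene\tmrna_id\tcds_start\tcds_end", "geneX\tm1\t3\t11"), manifest)
  expect_error(load_pairs(manifest, fasta), "out of range")
  writeLines(c("gene\tmrna_id\tcds_start\tcds_end", "geneX\tmissing\t1\t4"), manifest)
  expect_error(load_pairs(manifest, fasta), "not found")
})

test_that("manifests resolve CDS-as-record; non-contiguous CDS leaves noncoding unavailable", {
  m2 <- "AAACCCGGGTTT"
  fasta <- write_temp_fasta(list(m2 = m2, c2 = "CCCGGG", c3 = "CCCTTT"))
  manifest <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmrna_id\tcds_id", "geneY\tm2\tc2"), manifest)
  pairs <- load_pairs(manifest, fasta)
  expect_equal(pairs$noncoding, "AAATTT")
  expect_equal(pairs$cds_start, 4L)
  expect_equal(pairs$cds_end, 9L)
  # c3 is not a contiguous substring: pair kept, remainder NA
  writeLines(c("gene\tmrna_id\tcds_id", "geneZ\tm2\tc3"), manifest)
  expect_warning(pairs <- load_pairs(manifest, fasta), "no unique contiguous placement")
  expect_equal(pairs$cds, "CCCTTT")
  expect_true(is.na(pairs$noncoding))
  # a CDS longer than its mRNA is structural
  fasta2 <- write_temp_fasta(list(m2 = "ACGT", c2 = "ACGTACGT"))
  writeLines(c("gene\tmrna_id\tcds_id", "geneW\tm2\tc2"), manifest)
  expect_error(load_pairs(manifest, fasta2), "longer than")
})

test_that("sequences can come from a directory of FASTA files or a tibble", {
  dir <- withr::local_tempdir()
  write_fasta(tibble::tibble(id = "m1", residues = "AAACCCGGGTTT"), file.path(dir, "a.fasta"))
  write_fasta(tibble::tibble(id = "c1", residues = "CCCGGG"), file.path(dir, "b.fasta"))
  manifest <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmrna_id\tcds_id", "g\tm1\tc1"), manifest)
  pairs <- load_pairs(manifest, dir)
  expect_equal(pairs$noncoding, "AAATTT")
  seqs <- tibble::tibble(id = c("m1", "c1"), residues = c("AAACCCGGGTTT", "CCCGGG"))
  expect_equal(load_pairs(manifest, seqs)$noncoding, "AAATTT")
})
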