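# Regenerates the frozen synthetic mRNA/CDS panel shipped under
# inst/extdata/. Run from the repository root after installing the package:
#   Rscript data-raw/make_panel_fixture.R
# The panel is fully determined by the generator defaults and PANEL_SEED.
library(fractalseq)

PANEL_SEED <- 1L

panel <- gen_pair_panel(seed = PANEL_SEED)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_fasta(
  data.frame(id = panel$mrna_id, residues = panel$mrna),
  "inst/extdata/synthetic_panel.fasta"
)
readr::write_tsv(
  panel[, c("gene", "mrna_id", "cds_start", "cds_end")],
  "inst/extdata/synthetic_panel_manifest.tsv"
)
readr::write_tsv(
  panel[, c(
    "gene", "planted_group", "fd_mrna_target", "fd_cds_target",
    "fd_mrna_achieved", "fd_cds_achieved", "len_ratio"
  )],
  "inst/extdata/synthetic_panel_planted.tsv"
)

# sanity: the fixture must exhibit its documented shape
rows <- compare_fd(load_pairs(
  "inst/extdata/synthetic_panel_manifest.tsv",
  "inst/extdata/synthetic_panel.fasta"
))
stopifnot(
  sum(rows$delta < 0) == 2,
  identical(rows$gene[rows$delta < 0], panel$gene[panel$planted_group == "offline"])
)
inc <- inclusion_study(rows, list(
  all = panel$gene,
  collinear = panel$gene[panel$planted_group == "collinear"]
))
stopifnot(abs(inc$slope[2] - 1.2) <= 0.06, inc$r2[2] > inc$r2[1])
cat("panel fixture written; collinear slope", inc$slope[2], "\n")
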