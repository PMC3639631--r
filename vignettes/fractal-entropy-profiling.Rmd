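---
title: "Fractal dimension and entropy profiling of nucleotide sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal dimension and entropy profiling of nucleotide sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalseq)
```

## The model

A nucleotide sequence carries information in the *fluctuation* of its bases
along the chain. To quantify that fluctuation the sequence is turned into a
numeric series by mapping each base to the sum of the atomic numbers of the
atoms in its nucleobase:

| base | formula | atom sum |
|------|----------|----------|
| A | C5H5N5 | 70 |
| C | C4H5N3O | 58 |
| G | C5H5N5O | 78 |
| T | C5H6N2O2 | 66 |

Uracil (C4H4N2O2) sums to 58 and would collide with cytosine, so `U` is
folded into `T` when files are read and never encoded separately. The map is
a parameter of every function that encodes sequences, but the fractal
dimension is invariant under any affine re-mapping of the four values, so the
particular scalars matter only through their *ordering pattern* along the
sequence.

### Higuchi fractal dimension

For a series $x_1,\dots,x_N$ and lag $k$, the normalized curve length is

$$L(k) = \frac{N-1}{k^2\,(N-k)} \sum_{i=k+1}^{N} \lvert x_i - x_{i-k}\rvert ,$$

computed for $k = 1,\dots,k_{\max}$ on a unit-step lag grid. If the series is
fractal, $\log L(k)$ is linear in $\log(1/k)$ and the slope of the
ordinary-least-squares line is the fractal dimension (FD). We reproduce this
normalization exactly — including the $1/k^2$ factor and the end-effect
convention of discarding the first $k$ circular-shift differences — rather
than substituting other Higuchi variants (geometric lag grids, per-offset
sub-series averaging). Consequences a user should know:

* a strictly linear series has FD exactly 1 (every $L(k) = (N-1)\,s/k$ for
  slope magnitude $s$), which the tests assert to $10^{-10}$;
* an i.i.d. series has $E\lvert x_{i+k}-x_i\rvert$ constant in $k$, so the
  fitted slope tends to 2;
* a constant series has every $L(k)=0$ and FD is **undefined**: the package
  raises a "degenerate series" error instead of inventing a pseudo-count,
  because homopolymers are outside the model. Batch drivers record the error
  per record and continue.

The default lag cutoff is $k_{\max} = 7$; it is exposed everywhere
(`max_k`), and the shipped panel shows mean $|FD_{k_{\max}=6} -
FD_{k_{\max}=7}|$ well under 0.02, so conclusions do not hinge on the
cutoff. Natural logarithms are used; the slope is base-invariant when both
axes share the base. The FD regression is fit by closed-form normal
equations so the two-point grid $k\in\{1,2\}$ remains usable.

### Shannon entropy

`mono_entropy()` and `di_entropy()` are plug-in Shannon entropies of the
4-state base histogram and the 16-state adjacent-pair histogram, in bits,
with $0\log 0 \equiv 0$ and no pseudocounts (maxima 2 and 4 bits).
Dinucleotides are *overlapping* by default (positions $(i, i+1)$ for
$i = 1..N-1$), the standard convention that also maximizes counts on short
CDSs; `step = 2` gives the disjoint-pair reading. Across sequence panels the
mononucleotide entropy tracks the dinucleotide entropy roughly
proportionally — for an i.i.d. sequence the pair entropy is exactly twice
the base entropy in expectation — and `mono_di_correlation()` quantifies
this with an OLS $R^2$.

### Regression and skewness primitives

`ols_fit()` is one-predictor least squares with $R^2$ equal to the squared
Pearson correlation and adjusted $R^2 = 1-(1-R^2)(n-1)/(n-2)$. A flat
response is reported as $R^2 = 0$ rather than an error (the fit itself is
well-defined); a constant *predictor* is an error. No p-values are offered:
the analyses this package supports compare $R^2$ magnitudes across
include/exclude subsets, using differences on the order of 0.02 as the
working demarcation.

`skewness()` is the adjusted Fisher–Pearson coefficient
$G_1 = g_1\sqrt{n(n-1)}/(n-2)$ (the spreadsheet `SKEW` convention, fitting
the provenance of region-by-gene expression exports); plain $g_1$ is behind
`adjusted = FALSE` for sensitivity checks.

## The pipeline

`load_pairs()` resolves a tab-separated manifest (gene, mRNA id, and either
a CDS record id or 1-based inclusive CDS coordinates — the GenBank feature
convention) against FASTA records, derives the CDS, and joins the 5' and 3'
flanks into the concatenated noncoding remainder — the "lncRNA" of an mRNA
in this analysis. A CDS given as its own record is located by exact, unique
substring match; multi-exon CDSs are out of scope, and a non-locatable CDS
leaves the remainder `NA` rather than guessing.

`compare_fd()` computes per-pair FDs, entropies, lengths and
`delta = fd_cds - fd_mrna`; `inclusion_study()` fits CDS FD on mRNA FD
(project-wide axis convention: x = mRNA, y = CDS) for each named gene
subset, which is how "does adding this gene family tighten or loosen the
relation" questions are answered. `fd_entropy_map()` regresses entropy on
FD over a *designated* subset: outliers are excluded only by explicit id,
never by automated residual thresholding — the analysis tradition this
package serves gives no rule for automatic exclusion, so the package
refuses to invent one and instead reports each excluded point's residual.
`expression_skewness()` ranks genes by the skewness of their expression
distribution across brain regions, pooling subjects by concatenation by
default (`per_subject = TRUE` splits them; both poolings are defensible and
the choice is surfaced rather than hidden).

## What the synthetic generators emulate

Every analysis stage is testable offline against generators with known
truth:

* `gen_iid_sequence()` / `gen_markov_sequence()` — composition- and
  persistence-controlled sequences. A first-order chain started from its
  stationary distribution controls dinucleotide structure independently of
  base composition; the diagonal-stickiness family used internally spans
  realized FDs from roughly 1.16 (strongly persistent) to 2.10
  (anti-persistent), which brackets the FD band real transcripts occupy.
* `gen_fbm_series()` — exact fractional Brownian motion (Davies–Harte
  circulant embedding of fractional Gaussian noise). Theory fixes the path's
  fractal dimension at $2-H$, giving a calibration target with no free
  parameters; the test suite requires recovery within 0.1 at
  $N = 10^4$ over $H \in \{0.2, 0.5, 0.8\}$.
* `gen_pair_panel()` — mRNA/CDS pairs whose (mRNA FD, CDS FD) points follow
  a planted line (default slope 1.2, intercept −0.4, noise sd 0.002) except
  for a planted minority (default 2 of 15) whose CDS is *smoother* than its
  mRNA. There is no closed form linking a transition matrix to a Higuchi
  FD, so each sequence is found by a noisy bisection on the stickiness
  parameter, accepted when the realized FD is within 0.003 of target, with
  bracket re-widening when realization noise strands the search and an
  explicit error when a target lies outside the attainable band (e.g. a
  planted FD of 3). The default planted range (2.022–2.072) sits in the
  anti-persistent part of the band so the 13 collinear pairs all have
  positive delta. CDS/mRNA length ratios (0.3–0.7) are assigned in
  decreasing order of planted FD, planting the negative FD-versus-ratio
  correlation the comparison stage looks for.
* `gen_expression_table()` — gene × region × subject z-score tables (default
  168 regions × 4 subjects, the shape of a brain-atlas export) with per-gene
  target skewness, drawn from a standardized lognormal whose log-sigma is
  solved from the target. The defaults plant one near-symmetric receptor,
  one right-skewed receptor and two skewed ligands (targets 0.04, 0.91, 2.2,
  1.1).

What the generators deliberately do **not** emulate: codon structure, splice
signals, UTR-specific composition, GC-content gradients, or inter-gene
correlation of expression. Passing tests therefore demonstrate estimator
correctness and pipeline logic, not biological realism; conclusions about
real transcripts still require real sequences (see the README's real-data
section).

A frozen 15-pair panel generated with seed 1 ships under `inst/extdata/`
(FASTA + manifest + planted-value table) so the full read–pair–compare path
is exercised on stable files; `data-raw/make_panel_fixture.R` regenerates it
bit-for-bit.

## Numerical choices and problem sizes

* All generator randomness is confined with `withr::with_seed`: a seeded
  call never perturbs the caller's RNG stream, and identical seeds give
  identical output.
* The test suite and the acceptance script size their simulations to run in
  a few minutes on one core: FD calibration uses series of length $10^4$
  (50 seeds i.i.d., 20 per Hurst value), entropy bounds 1000 random
  sequences up to length 5000, panel generation 15 pairs of ~3 kb. These
  sizes put Monte-Carlo noise well inside the asserted tolerances (e.g. the
  sd of a single i.i.d. FD estimate at $N=10^4$ is ≈ 0.005 against a ±0.05
  band on the mean of 50).
* Ties in skewness ranking use `ties.method = "min"`; failed genes keep
  `NA` rank.
* Reports are written with full-precision numerics and are byte-identical
  across identical runs; rounding to the 4 decimals conventional in this
  literature happens only in `print()` methods.

## Known limitations

* The Higuchi normalization is exactly the one given above, not the
  per-offset-averaged variant found in some treatments; FD values are therefore
  comparable *within* this package, and with analyses that use the same
  listing, but not necessarily with other Higuchi implementations.
* Entropies are plug-in estimates with no small-sample bias correction;
  very short sequences (tens of bases) under-estimate both entropies.
* `load_pairs()` treats a CDS as one contiguous block on the mRNA;
  splice-aware assembly is out of scope.
* The FD-planting search is stochastic with a capped budget (~250 draws per
  sequence); pathological targets near the band edges can exhaust it, and
  the error message says so rather than degrading silently.
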