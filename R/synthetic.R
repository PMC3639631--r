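#' Seeded i.i.d. nucleotide sequence
#'
#' Null model for the fractal and entropy estimators: under uniform base
#' probabilities the expected absolute lag difference of the encoded series
#' is constant in the lag, so the Higuchi fractal dimension tends to 2 and
#' both entropies to their maxima.
#'
#' @param n Sequence length.
#' @param probs Base probabilities, named or in `A`, `C`, `G`, `T` order;
#'   nonnegative, summing to 1.
#' @param seed Optional integer; when given, generation is reproducible and
#'   the caller's RNG state is untouched.
#' @return A residue string of length `n`.
#' @export
gen_iid_sequence <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             seed = NULL) {
  probs <- check_probs(probs)
  with_seed_if(seed, {
    bases <- c("A", "C", "G", "T")
    paste(sample(bases, n, replace = TRUE, prob = probs), collapse = "")
  })
}

check_probs <- function(probs) {
  if (!is.numeric(probs) || length(probs) != 4 || any(!is.finite(probs)) ||
    any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort("probs must be 4 nonnegative values summing to 1")
  }
  if (!is.null(names(probs))) {
    if (!setequal(names(probs), c("A", "C", "G", "T"))) {
      abort("named probs must use names A, C, G, T")
    }
    probs <- probs[c("A", "C", "G", "T")]
  }
  unname(probs)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Seeded first-order Markov nucleotide sequence
#'
#' A first-order chain over `{A, C, G, T}` started from its stationary
#' distribution. The transition matrix controls dinucleotide structure
#' independently of base composition: persistent (diagonal-heavy) chains
#' produce runs, lowering both the dinucleotide entropy and the fractal
#' dimension of the encoded series; anti-persistent chains push the
#' fractal dimension slightly above 2.
#'
#' @param n Sequence length.
#' @param P 4x4 row-stochastic transition matrix, rows/columns in
#'   `A`, `C`, `G`, `T` order.
#' @inheritParams gen_iid_sequence
#' @return A residue string of length `n`.
#' @export
gen_markov_sequence <- function(n, P, seed = NULL) {
  P <- check_transition_matrix(P)
  pi0 <- stationary_distribution(P)
  with_seed_if(seed, {
    bases <- c("A", "C", "G", "T")
    cum <- t(apply(P, 1, cumsum))
    s <- integer(n)
    s[1] <- sample.int(4, 1, prob = pi0)
    if (n > 1) {
      u <- runif(n)
      for (i in 2:n) s[i] <- findInterval(u[i], cum[s[i - 1], ]) + 1L
    }
    paste(bases[s], collapse = "")
  })
}

check_transition_matrix <- function(P) {
  if (!is.matrix(P) || !all(dim(P) == c(4, 4)) || any(!is.finite(P)) || any(P < 0)) {
    abort("P must be a 4x4 nonnegative matrix")
  }
  if (any(abs(rowSums(P) - 1) > 1e-8)) abort("P must be row-stochastic (rows sum to 1)")
  unname(P)
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

# diagonal-stickiness family: P(b -> b) = p_same, off-diagonals uniform.
# p_same = 1/4 is i.i.d.; larger is persistent (lower FD), smaller
# anti-persistent (FD slightly above 2).
sticky_transition_matrix <- function(p_same) {
  stopifnot(p_same >= 0, p_same <= 1)
  P <- matrix((1 - p_same) / 3, 4, 4)
  diag(P) <- p_same
  P
}

#' Seeded fractional Brownian motion path
#'
#' Exact simulation by circulant embedding (Davies-Harte): fractional
#' Gaussian noise with Hurst exponent `H` is drawn from its exact
#' covariance via FFT and cumulated. The theoretical fractal dimension of
#' the path is `2 - H`, making this the calibration ground truth for the
#' Higuchi estimator.
#'
#' @param n Path length.
#' @param H Hurst exponent in (0, 1).
#' @inheritParams gen_iid_sequence
#' @return Numeric vector of length `n`.
#' @export
gen_fbm_series <- function(n, H, seed = NULL) {
  if (!is.numeric(H) || length(H) != 1 || !is.finite(H) || H <= 0 || H >= 1) {
    abort("H must lie strictly inside (0, 1)")
  }
  stopifnot(n >= 2)
  with_seed_if(seed, {
    g <- function(h) 0.5 * (abs(h + 1)^(2 * H) - 2 * abs(h)^(2 * H) + abs(h - 1)^(2 * H))
    m <- 2L * n
    lam <- Re(fft(c(g(0:n), g((n - 1):1))))
    # the fGn embedding is nonnegative-definite; clip tiny negative rounding
    lam[lam < 0] <- 0
    w <- complex(length.out = m)
    w[1] <- rnorm(1) * sqrt(m)
    w[n + 1] <- rnorm(1) * sqrt(m)
    re <- rnorm(n - 1, sd = sqrt(m / 2))
    im <- rnorm(n - 1, sd = sqrt(m / 2))
    w[2:n] <- complex(real = re, imaginary = im)
    w[m:(n + 2)] <- Conj(w[2:n])
    cumsum(Re(fft(sqrt(lam) * w / m))[1:n])
  })
}

# drive the sticky-chain parameter until the realized sequence's Higuchi FD
# lands within tol of target. FD is monotone decreasing in p_same in
# expectation; near convergence realization noise dominates, so once the
# bracket is tight we redraw at the midpoint. Errors when the target lies
# outside the attainable band or the iteration budget is exhausted.
search_fd <- function(target, build, tol = 0.003, p_range = c(0.01, 0.95),
                      max_iter = 250L, label = "series") {
  lo <- p_range[1]
  hi <- p_range[2]
  top <- build(lo)
  if (is.na(top$fd)) abort(paste0(label, ": degenerate candidate series"))
  if (abs(top$fd - target) <= tol) return(top)
  if (top$fd < target - 0.02) {
    abort(sprintf(
      "unattainable fractal dimension %.4f for %s: band maximum is about %.4f",
      target, label, top$fd
    ))
  }
  bottom <- build(hi)
  if (abs(bottom$fd - target) <= tol) return(bottom)
  if (bottom$fd > target + 0.02) {
    abort(sprintf(
      "unattainable fractal dimension %.4f for %s: band minimum is about %.4f",
      target, label, bottom$fd
    ))
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cand <- build(mid)
    if (!is.na(cand$fd) && abs(cand$fd - target) <= tol) return(cand)
    if (hi - lo > 2e-3) {
      if (cand$fd > target) lo <- mid else hi <- mid
    } else {
      # realization noise can strand the bracket next to, not on, the
      # target; re-widen around the collapse point and re-localize
      lo <- max(p_range[1], mid - 0.02)
      hi <- min(p_range[2], mid + 0.02)
    }
  }
  abort(sprintf("could not attain fractal dimension %.4f for %s within budget", target, label))
}

build_markov_candidate <- function(n, p_same, max_k, map) {
  res <- gen_markov_sequence(n, sticky_transition_matrix(p_same))
  f <- fd_safely(res, max_k, map)
  list(residues = res, fd = f$fd)
}

#' Synthetic mRNA/CDS panel with a planted fractal-dimension relation
#'
#' Builds `n_pairs` mRNA/CDS pairs whose (mRNA FD, CDS FD) coordinates
#' follow a planted linear relation `fd_cds = slope * fd_mrna + intercept`
#' plus Gaussian noise, except for `n_negative` "off-line" pairs whose CDS
#' fractal dimension is planted *below* the mRNA's by `negative_offset` —
#' mimicking a gene family whose coding sequences are smoother than their
#' transcripts, so that excluding them tightens the regression. Each CDS is
#' generated by searching the sticky-Markov parameter until its realized
#' fractal dimension is within `tol` of target; flanking noncoding regions
#' are then tuned the same way until the full mRNA hits its target. Pairs
#' whose realized `fd_cds - fd_mrna` sign disagrees with the planted sign
#' are regenerated (a capped number of times). No closed form links a
#' transition matrix to a Higuchi fractal dimension, hence the search.
#'
#' The defaults emulate a 15-member disease-gene panel: 13 near-collinear
#' pairs with CDS more irregular than mRNA (slope above 1, negative
#' intercept) plus 2 pairs with the opposite sign.
#'
#' @param n_pairs Number of pairs.
#' @param slope,intercept Planted linear relation on the (FD mRNA, FD CDS)
#'   plane.
#' @param noise_sd Gaussian scatter of planted CDS FD about the line.
#' @param fd_mrna_range Range of planted mRNA fractal dimensions.
#' @param n_negative Number of off-line, negative-delta pairs.
#' @param negative_offset Planted `fd_mrna - fd_cds` for those pairs.
#' @param mrna_length Approximate mRNA length (each pair jitters around it).
#' @param len_ratio_range CDS/mRNA length-ratio range; ratios are assigned
#'   in decreasing order of planted mRNA FD, planting a negative
#'   FD-versus-ratio correlation.
#' @param tol Achieved-versus-planted FD tolerance, per sequence.
#' @param max_k,map Higuchi settings used during the search.
#' @param seed Optional integer seed.
#' @return A tibble, one row per pair: `gene`, `mrna_id`, `cds_id`,
#'   `cds_start`, `cds_end`, `mrna`, `cds`, `noncoding`, `planted_group`
#'   (`"collinear"` or `"offline"`), planted and achieved FDs, `len_ratio`.
#' @export
gen_pair_panel <- function(n_pairs = 15, slope = 1.2, intercept = -0.4,
                           noise_sd = 0.002, fd_mrna_range = c(2.022, 2.072),
                           n_negative = 2, negative_offset = 0.01,
                           mrna_length = 3000, len_ratio_range = c(0.3, 0.7),
                           tol = 0.003, max_k = 7, map = default_encoding_map(),
                           seed = NULL) {
  stopifnot(n_pairs >= 1, n_negative >= 0, n_negative < n_pairs)
  with_seed_if(seed, {
    n_col <- n_pairs - n_negative
    x_col <- seq(fd_mrna_range[1], fd_mrna_range[2], length.out = max(n_col, 2))[seq_len(n_col)]
    y_col <- slope * x_col + intercept + rnorm(n_col, sd = noise_sd)
    x_neg <- if (n_negative > 0) {
      seq(fd_mrna_range[1], fd_mrna_range[2], length.out = n_negative + 2)[1 + seq_len(n_negative)]
    } else {
      numeric(0)
    }
    y_neg <- x_neg - negative_offset
    targets <- tibble(
      fd_mrna_target = c(x_col, x_neg),
      fd_cds_target = c(y_col, y_neg),
      planted_group = rep(c("collinear", "offline"), c(n_col, n_negative))
    )
    # ratios decreasing in planted mRNA FD -> negative FD-vs-ratio relation
    ord <- rank(targets$fd_mrna_target, ties.method = "first")
    ratios <- seq(len_ratio_range[2], len_ratio_range[1], length.out = n_pairs)[ord] +
      runif(n_pairs, -0.01, 0.01)
    ratios <- pmin(pmax(ratios, 0.05), 0.95)

    rows <- purrr::map(seq_len(n_pairs), function(i) {
      gene <- sprintf("gene%02d", i)
      for (attempt in 1:8) {
        len_m <- round(mrna_length * runif(1, 0.9, 1.1))
        len_c <- round(ratios[i] * len_m)
        cds <- search_fd(
          targets$fd_cds_target[i],
          function(p) build_markov_candidate(len_c, p, max_k, map),
          tol = tol, label = paste0(gene, " CDS")
        )
        len_nc <- len_m - len_c
        len5 <- round(len_nc * runif(1, 0.3, 0.6))
        len3 <- len_nc - len5
        mrna <- search_fd(
          targets$fd_mrna_target[i],
          function(p) {
            left <- if (len5 > 0) gen_markov_sequence(len5, sticky_transition_matrix(p)) else ""
            right <- if (len3 > 0) gen_markov_sequence(len3, sticky_transition_matrix(p)) else ""
            res <- paste0(left, cds$residues, right)
            f <- fd_safely(res, max_k, map)
            list(residues = res, fd = f$fd, left = left, right = right)
          },
          tol = tol, label = paste0(gene, " mRNA")
        )
        planted_sign <- sign(targets$fd_cds_target[i] - targets$fd_mrna_target[i])
        if (sign(cds$fd - mrna$fd) == planted_sign) {
          row <- list(
            gene = gene,
            mrna_id = paste0(gene, "_mrna"),
            cds_id = NA_character_,
            cds_start = nchar(mrna$left) + 1L,
            cds_end = nchar(mrna$left) + nchar(cds$residues),
            mrna = mrna$residues,
            cds = cds$residues,
            noncoding = paste0(mrna$left, mrna$right),
            planted_group = targets$planted_group[i],
            fd_mrna_target = targets$fd_mrna_target[i],
            fd_cds_target = targets$fd_cds_target[i],
            fd_mrna_achieved = mrna$fd,
            fd_cds_achieved = cds$fd,
            len_ratio = len_c / len_m
          )
          return(as_tibble(row))
        }
      }
      abort(paste0(gene, ": could not realize the planted delta sign within budget"))
    })
    dplyr::bind_rows(rows)
  })
}

#' Synthetic gene-by-region expression table with controlled skewness
#'
#' Emulates a brain-wide expression export: for each named gene, `n_regions
#' * n_subjects` values drawn from a distribution with the requested sample
#' skewness — a standardized lognormal whose log-scale sigma is solved from
#' the target (mirrored for negative targets), or a normal for target 0 —
#' then z-scored per gene across all values.
#'
#' @param genes Named numeric vector: target skewness per gene. The default
#'   emulates two receptor/ligand contrasts (one near-symmetric receptor,
#'   one right-skewed receptor, two skewed ligands).
#' @param n_regions Regions per subject (>= 3).
#' @param n_subjects Number of subjects pooled by concatenation.
#' @inheritParams gen_iid_sequence
#' @return Long tibble: `gene`, `subject`, `region`, `value`.
#' @export
gen_expression_table <- function(genes = c(HCRTR2 = 0.91, EPOR = 0.04, HCRT = 2.2, EPO = 1.1),
                                 n_regions = 168, n_subjects = 4, seed = NULL) {
  if (!is.numeric(genes) || is.null(names(genes)) || any(!nzchar(names(genes)))) {
    abort("genes must be a named numeric vector of target skewness values")
  }
  if (any(!is.finite(genes))) abort("target skewness values must be finite")
  if (n_regions < 3) abort("n_regions must be at least 3")
  n <- n_regions * n_subjects
  with_seed_if(seed, {
    draws <- purrr::imap(genes, function(target, gene) {
      v <- draw_skewed(n, target)
      tibble(
        gene = gene,
        subject = rep(sprintf("subject%d", seq_len(n_subjects)), each = n_regions),
        region = rep(sprintf("region%03d", seq_len(n_regions)), times = n_subjects),
        value = as.numeric(scale(v))
      )
    })
    dplyr::bind_rows(draws)
  })
}

# lognormal population skewness (w + 2) * sqrt(w - 1), w = exp(sigma^2),
# solved for sigma; sign handled by mirroring
draw_skewed <- function(n, target) {
  if (abs(target) < 1e-8) {
    return(rnorm(n))
  }
  skew_of <- function(sigma) {
    w <- exp(sigma^2)
    (w + 2) * sqrt(w - 1)
  }
  sigma <- uniroot(function(s) skew_of(s) - abs(target), c(1e-4, 3), tol = 1e-10)$root
  v <- exp(sigma * rnorm(n))
  if (target < 0) -v else v
}
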