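# Additive LD scores and cis-interaction LD scores.
#
# For a standardized panel X (columns mean 0, second moment 1, divide-by-N
# convention) the additive LD score of the focal variant j is
#   ell_j = sum_{k in window(j)} w_alpha(k) * r_jk^2
# with r_jk the sample Pearson correlation, self term included. The
# cis-interaction score is
#   f_j = sum_{k in window(j), k != j} w_alpha(k) * v_jk^2
# with v_jk the sample Pearson correlation between x_j and the centered,
# unit-variance Hadamard product x_j o x_k. The fast path never materializes
# the product columns: with s_j = x_j o x_j,
#   cov(x_j, x_j o x_k)  = mean(s_j * x_k)          (x_j has mean 0)
#   var(x_j o x_k)       = mean(s_j * s_k) - mean(x_j * x_k)^2
# so three block cross-products (S'X, S'S, X'X over the window span) give
# every v_jk^2.

#' Specify a score window
#'
#' Windows never cross chromosome boundaries and use an inclusive distance
#' rule (`<= half_width`).
#'
#' @param mode one of `"snps"` (SNP-count distance), `"kb"` (physical
#'   distance, kilobases) or `"cM"` (genetic distance, centimorgans).
#' @param half_width positive half-width in the mode's unit.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(mode = c("snps", "kb", "cM"), half_width) {
  mode <- match.arg(mode)
  if (!is.numeric(half_width) || length(half_width) != 1L || half_width < 0) {
    stop("half_width must be a single non-negative number")
  }
  structure(list(mode = mode, half_width = half_width),
            class = "window_spec")
}

#' Indices of variants inside a focal window
#'
#' Returns the maximal contiguous index set on the focal variant's
#' chromosome whose distance to the focal variant is at most the window
#' half-width (inclusive). The focal index itself is always part of the
#' result; score functions decide whether to use it.
#'
#' @param variants data frame sorted by (chr, bp) with columns `chr`, `bp`
#'   and (for cM windows) `cM`.
#' @param j focal index.
#' @param spec a [window_spec()].
#' @return Integer vector of indices into `variants`.
#' @export
window_indices <- function(variants, j, spec) {
  stopifnot(inherits(spec, "window_spec"))
  chr <- variants$chr
  for (c0 in unique(chr)) {
    if (is.unsorted(variants$bp[chr == c0])) {
      stop("variants must be sorted by (chr, bp)")
    }
  }
  block <- which(chr == chr[j])
  lo_chr <- block[1L]
  hi_chr <- block[length(block)]
  if (spec$mode == "snps") {
    w <- as.integer(spec$half_width)
    return(seq.int(max(lo_chr, j - w), min(hi_chr, j + w)))
  }
  pos <- if (spec$mode == "kb") variants$bp else .variant_cM(variants)
  d <- if (spec$mode == "kb") spec$half_width * 1000 else spec$half_width
  p <- pos[lo_chr:hi_chr]
  lo <- findInterval(pos[j] - d, p, left.open = TRUE) + 1L
  hi <- findInterval(pos[j] + d, p)
  seq.int(lo_chr + lo - 1L, lo_chr + hi - 1L)
}

# cM column if informative, else 1 cM ~ 1 Mb from bp
.variant_cM <- function(variants) {
  cm <- variants$cM
  if (is.null(cm) || all(cm == 0)) cm <- variants$bp * 1e-6
  cm
}

.alpha_weights <- function(maf, alpha, exponent = c("one_plus", "one_minus")) {
  exponent <- match.arg(exponent)
  h <- 2 * maf * (1 - maf) # V[x_k] on the allele-count scale under HWE
  e <- if (exponent == "one_plus") 1 + alpha else 1 - alpha
  w <- h^e
  # unit-mean normalization keeps the regression coefficients on the
  # variance-explained scale for every alpha; at alpha = -1 ("one_plus")
  # the weights are exactly 1
  w / mean(w)
}

.window_table <- function(variants, spec) {
  lapply(seq_len(nrow(variants)), function(j) {
    window_indices(variants, j, spec)
  })
}

#' Additive LD scores
#'
#' @param panel a `standardized_panel` from [standardize()].
#' @param spec window for the score sum; default 1 cM.
#' @param alpha MAF-architecture exponent in `[-1, 0]`. Each pair term is
#'   weighted by `(2 p_k q_k)^(1 + alpha)` so that `alpha = -1` reproduces
#'   unweighted LD scores on standardized genotypes; set
#'   `alpha_exponent = "one_minus"` for the `(1 - alpha)` convention.
#' @param annotations optional J x C matrix of annotation values; one score
#'   column is returned per category, with each pair term multiplied by the
#'   annotation value of the tagging variant.
#' @param bias_correct replace each squared sample correlation `r2` by
#'   `r2 - (1 - r2) / (N - 2)` (small-reference-panel correction).
#' @param alpha_exponent exponent convention for the MAF weight.
#' @return A numeric vector of scores, or a matrix with one column per
#'   annotation category when `annotations` is supplied.
#' @export
additive_ld_scores <- function(panel, spec = window_spec("cM", 1),
                               alpha = -1, annotations = NULL,
                               bias_correct = TRUE,
                               alpha_exponent = "one_plus") {
  stopifnot(inherits(panel, "standardized_panel"))
  n <- panel$n
  if (bias_correct && n <= 2L) {
    stop("bias correction requires more than 2 reference samples")
  }
  x <- panel$matrix
  jn <- panel$j
  wts <- .alpha_weights(panel$maf, alpha, alpha_exponent)
  wins <- .window_table(panel$variants, spec)
  amat <- if (is.null(annotations)) {
    matrix(1, jn, 1L)
  } else {
    as.matrix(annotations)
  }
  if (nrow(amat) != jn) stop("annotations must have one row per variant")
  out <- matrix(0, jn, ncol(amat))
  block_size <- 256L
  for (a in seq.int(1L, jn, by = block_size)) {
    b <- min(a + block_size - 1L, jn)
    span <- range(unlist(wins[a:b]))
    ks <- seq.int(span[1L], span[2L])
    r <- crossprod(x[, ks, drop = FALSE], x[, a:b, drop = FALSE]) / n
    r2 <- r * r
    if (bias_correct) r2 <- r2 - (1 - r2) / (n - 2)
    for (j in a:b) {
      kk <- wins[[j]]
      rows <- kk - span[1L] + 1L
      terms <- wts[kk] * r2[rows, j - a + 1L]
      out[j, ] <- colSums(terms * amat[kk, , drop = FALSE])
    }
  }
  if (is.null(annotations)) {
    drop(out)
  } else {
    colnames(out) <- colnames(amat)
    out
  }
}

#' Cis-interaction LD scores (fast path)
#'
#' Sums squared sample correlations between the focal genotype and its
#' Hadamard products with window neighbors, without materializing the
#' product columns.
#'
#' @inheritParams additive_ld_scores
#' @param spec window for partner selection; default plus/minus 50 SNPs.
#' @param include_self include the `k = j` self-product term (the
#'   interaction of a variant with itself); off by default.
#' @param centered if `TRUE` (default) use true Pearson correlations (the
#'   Hadamard product is centered and scaled); if `FALSE` use the raw
#'   uncentered moment `mean(x_j^2 x_k)^2` instead.
#' @return A list with `f` (numeric score vector), `pair_count` (pairs used
#'   per focal variant) and `skipped` (pairs dropped because the product
#'   column had zero variance).
#' @export
cis_interaction_scores <- function(panel, spec = window_spec("snps", 50),
                                   alpha = -1, include_self = FALSE,
                                   bias_correct = TRUE, centered = TRUE,
                                   alpha_exponent = "one_plus") {
  stopifnot(inherits(panel, "standardized_panel"))
  n <- panel$n
  if (bias_correct && n <= 2L) {
    stop("bias correction requires more than 2 reference samples")
  }
  x <- panel$matrix
  s <- x * x
  jn <- panel$j
  wts <- .alpha_weights(panel$maf, alpha, alpha_exponent)
  wins <- .window_table(panel$variants, spec)
  f <- numeric(jn)
  pair_count <- integer(jn)
  skipped <- 0L
  block_size <- 128L
  for (a in seq.int(1L, jn, by = block_size)) {
    b <- min(a + block_size - 1L, jn)
    span <- range(unlist(wins[a:b]))
    ks <- seq.int(span[1L], span[2L])
    xs <- x[, ks, drop = FALSE]
    ss <- s[, ks, drop = FALSE]
    num <- crossprod(s[, a:b, drop = FALSE], xs) / n  # mean(s_j x_k)
    m2 <- crossprod(s[, a:b, drop = FALSE], ss) / n   # mean(s_j s_k)
    r <- crossprod(x[, a:b, drop = FALSE], xs) / n    # mean(x_j x_k)
    for (j in a:b) {
      kk <- wins[[j]]
      if (!include_self) kk <- kk[kk != j]
      if (length(kk) == 0L) next
      cols <- kk - span[1L] + 1L
      row <- j - a + 1L
      nu <- num[row, cols]
      if (centered) {
        vp <- m2[row, cols] - r[row, cols]^2
        ok <- vp > 1e-12
        skipped <- skipped + sum(!ok)
        v2 <- nu[ok]^2 / vp[ok]
        kk <- kk[ok]
      } else {
        v2 <- nu^2
      }
      if (bias_correct) v2 <- v2 - (1 - v2) / (n - 2)
      f[j] <- sum(wts[kk] * v2)
      pair_count[j] <- length(kk)
    }
  }
  if (skipped > 0L) {
    message("cis_interaction_scores: skipped ", skipped,
            " pair(s) with zero-variance product")
  }
  list(f = f, pair_count = pair_count, skipped = skipped)
}

#' Cis-interaction LD scores by explicit construction (test oracle)
#'
#' Materializes every interaction column `x_j o x_k`, standardizes it, and
#' computes its squared Pearson correlation with the focal genotype. Meant
#' for small panels as an independent check of [cis_interaction_scores()].
#'
#' @inheritParams cis_interaction_scores
#' @return As [cis_interaction_scores()].
#' @export
cis_interaction_scores_bruteforce <- function(panel,
                                              spec = window_spec("snps", 50),
                                              alpha = -1,
                                              include_self = FALSE,
                                              bias_correct = FALSE,
                                              alpha_exponent = "one_plus") {
  stopifnot(inherits(panel, "standardized_panel"))
  n <- panel$n
  x <- panel$matrix
  jn <- panel$j
  wts <- .alpha_weights(panel$maf, alpha, alpha_exponent)
  f <- numeric(jn)
  pair_count <- integer(jn)
  skipped <- 0L
  for (j in seq_len(jn)) {
    kk <- window_indices(panel$variants, j, spec)
    if (!include_self) kk <- kk[kk != j]
    for (k in kk) {
      w <- x[, j] * x[, k]
      w <- w - mean(w)
      sw <- sqrt(mean(w * w))
      if (sw <= 1e-6) {
        skipped <- skipped + 1L
        next
      }
      v <- mean(x[, j] * w) / sw # focal column already unit variance
      v2 <- v * v
      if (bias_correct) v2 <- v2 - (1 - v2) / (n - 2)
      f[j] <- f[j] + wts[k] * v2
      pair_count[j] <- pair_count[j] + 1L
    }
  }
  list(f = f, pair_count = pair_count, skipped = skipped)
}

#' Compute a full score table from a genotype panel
#'
#' Standardizes the panel, computes additive LD scores under `ell_spec`
#' (default 1 cM) and one cis-interaction score column per entry of
#' `specs` (default plus/minus 5, 10, 25 and 50 SNPs).
#'
#' @param panel a [genotype_panel()].
#' @param specs list of [window_spec()]s for the cis-interaction columns.
#' @param ell_spec window for the additive scores.
#' @param alpha MAF-architecture exponent (see [additive_ld_scores()]).
#' @param min_maf MAF threshold passed to [standardize()].
#' @param include_self,bias_correct,centered,alpha_exponent passed through
#'   to the score functions.
#' @param annotations optional per-variant annotation matrix (rows must
#'   match the variants retained after standardization).
#' @return A `score_table`.
#' @export
compute_scores <- function(panel,
                           specs = lapply(c(5, 10, 25, 50), function(w)
                             window_spec("snps", w)),
                           ell_spec = window_spec("cM", 1),
                           alpha = -1, min_maf = 0.01,
                           include_self = FALSE, bias_correct = TRUE,
                           centered = TRUE, alpha_exponent = "one_plus",
                           annotations = NULL) {
  sp <- standardize(panel, min_maf = min_maf)
  ell <- additive_ld_scores(sp, ell_spec, alpha = alpha,
                            annotations = annotations,
                            bias_correct = bias_correct,
                            alpha_exponent = alpha_exponent)
  if (inherits(specs, "window_spec")) specs <- list(specs)
  fs <- lapply(specs, function(spec) {
    cis_interaction_scores(sp, spec, alpha = alpha,
                           include_self = include_self,
                           bias_correct = bias_correct, centered = centered,
                           alpha_exponent = alpha_exponent)
  })
  windows <- vapply(specs, function(spec) {
    if (spec$mode == "snps") {
      format(as.integer(spec$half_width))
    } else {
      paste0(format(spec$half_width), toupper(spec$mode))
    }
  }, character(1))
  vt <- data.frame(
    chr = as.character(sp$variants$chr), id = as.character(sp$variants$id),
    bp = sp$variants$bp, maf = sp$maf, stringsAsFactors = FALSE
  )
  new_score_table(
    vt,
    ell,
    vapply(fs, `[[`, numeric(sp$j), "f"),
    vapply(fs, `[[`, integer(sp$j), "pair_count"),
    windows, n_ref = sp$n, annotations = annotations
  )
}
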