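# Weighted regression of GWAS chi-square statistics on additive and
# cis-interaction LD scores:
#
#   E[chi2_j] = intercept + ell_j * tau + f_j * theta
#
# The regressors are pre-scaled by N/J and N/M so the fitted coefficients
# sit directly on the variance-explained scale: the coefficient on the
# scaled ell column estimates the additive PVE and the coefficient on the
# scaled f column the tagged pairwise-interaction PVE; their sum is the
# heritability estimate. Weights are iteratively recomputed from the fitted
# conditional variance, psi_jj = max(fitted_j, 1)^(-2), and standard errors
# come from a delete-one-block jackknife over contiguous genomic blocks.

.merge_sumstats_scores <- function(sumstats, scores, window,
                                   extra_cols = character(0)) {
  stopifnot(inherits(scores, "score_table"))
  fcols <- colnames(scores$f)
  want <- if (is.character(window) && window %in% fcols) {
    window
  } else {
    paste0("F_W", window)
  }
  if (!want %in% fcols) {
    stop("score table has no window column ", want, "; available: ",
         paste(fcols, collapse = ", "))
  }
  sdf <- data.frame(
    id = scores$variants$id,
    chr = scores$variants$chr,
    bp = scores$variants$bp,
    ell = if (is.matrix(scores$ell)) scores$ell[, 1L] else scores$ell,
    f = scores$f[, want],
    stringsAsFactors = FALSE
  )
  if (length(extra_cols) > 0L) {
    em <- as.matrix(scores$ell)
    miss <- setdiff(extra_cols, colnames(em))
    if (length(miss) > 0L) {
      stop("score table has no annotation column(s): ",
           paste(miss, collapse = ", "))
    }
    for (cc in extra_cols) sdf[[cc]] <- em[, cc]
  }
  m <- merge(as.data.frame(sumstats)[, c("id", "N", "chisq")], sdf,
             by = "id", sort = FALSE)
  m <- m[order(m$chr, m$bp), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "M") <- unname(scores$M[want])
  attr(m, "window") <- want
  m
}

.wls <- function(X, y, w) {
  sw <- sqrt(w)
  fit <- qr(X * sw)
  if (fit$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), sort(fit$pivot[seq_len(fit$rank)]))
    stop("singular design; offending column(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  }
  qr.coef(fit, y * sw)
}

# IRLS engine shared by the single-annotation and stratified fits.
# X must contain the (optional) intercept column named "intercept".
.ildsc_irls <- function(X, y, n_iter = 2L, psi_floor = 1,
                        overcount_weight = FALSE, ell_raw = NULL,
                        offset = 0) {
  const_w <- if (overcount_weight) 1 / pmax(ell_raw, 1) else 1
  beta <- .wls(X, y - offset, rep(1, length(y)))
  w <- rep(1, length(y))
  for (it in seq_len(n_iter)) {
    fitted <- drop(X %*% beta) + offset
    w <- const_w / pmax(fitted, psi_floor)^2
    beta <- .wls(X, y - offset, w)
  }
  fitted <- drop(X %*% beta) + offset
  res <- y - fitted
  # Gaussian pseudo-likelihood with per-SNP variance 1/w
  ll <- -0.5 * sum(log(2 * pi / w) + w * res^2)
  list(coef = beta, weights = w, fitted = fitted, loglik = ll,
       n_iter = n_iter)
}

.build_design <- function(m, J_used, M, free_intercept,
                          extra_cols = character(0), ldsc_only = FALSE) {
  cols <- list()
  if (free_intercept) cols$intercept <- rep(1, nrow(m))
  if (length(extra_cols) == 0L) {
    cols$tau <- m$N * m$ell / J_used
  } else {
    for (cc in extra_cols) cols[[paste0("tau_", cc)]] <- m$N * m[[cc]] / J_used
  }
  if (!ldsc_only) cols$theta <- m$N * m$f / M
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

.ildsc_options <- function(options, N) {
  defaults <- list(
    n_iter = 2L, free_intercept = TRUE,
    max_chisq = max(80, 0.001 * stats::median(N)),
    two_stage = FALSE, overcount_weight = FALSE, psi_floor = 1,
    n_blocks = 200L, jackknife = TRUE, ldsc_only = FALSE
  )
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown option(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, options)
}

.fit_engine <- function(m, options, extra_cols = character(0)) {
  opt <- .ildsc_options(options, m$N)
  keep <- m$chisq <= opt$max_chisq
  n_filtered <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  n_blocks <- min(opt$n_blocks, max(2L, nrow(m) %/% 3L))
  if (nrow(m) < n_blocks + 3L) {
    stop("too few variants after merging and filtering (",
         nrow(m), ") for ", n_blocks, " jackknife blocks")
  }
  J_used <- nrow(m)
  M <- attr(m, "M")
  if (!is.finite(M) || M <= 0) {
    stop("score table carries no positive total pair count M for window ",
         attr(m, "window"))
  }
  X <- .build_design(m, J_used, M, opt$free_intercept, extra_cols,
                     ldsc_only = isTRUE(opt$ldsc_only))
  offset <- if (opt$free_intercept) 0 else 1
  if (isTRUE(opt$two_stage)) {
    # stage 1: intercept from the low-signal subset, then held fixed
    sub <- m$chisq < 30
    if (sum(sub) > ncol(X) + 2L) {
      pre <- .ildsc_irls(X[sub, , drop = FALSE], m$chisq[sub],
                         n_iter = opt$n_iter, psi_floor = opt$psi_floor,
                         overcount_weight = opt$overcount_weight,
                         ell_raw = m$ell[sub], offset = offset)
      if (opt$free_intercept) {
        offset <- pre$coef[["intercept"]]
        X <- X[, colnames(X) != "intercept", drop = FALSE]
        opt$free_intercept <- FALSE
      }
    }
  }
  fit <- .ildsc_irls(X, m$chisq, n_iter = opt$n_iter,
                     psi_floor = opt$psi_floor,
                     overcount_weight = opt$overcount_weight,
                     ell_raw = m$ell, offset = offset)
  list(m = m, X = X, fit = fit, opt = opt, J_used = J_used, M = M,
       offset = offset, n_filtered = n_filtered, extra_cols = extra_cols)
}

.block_bounds <- function(n, n_blocks) {
  cut_pts <- floor(seq(0, n, length.out = n_blocks + 1L))
  cbind(lo = cut_pts[-length(cut_pts)] + 1L, hi = cut_pts[-1L])
}

.jackknife_engine <- function(X, y, w, offset, n_blocks, full_coef) {
  n <- length(y)
  bounds <- .block_bounds(n, n_blocks)
  g <- nrow(bounds)
  est <- matrix(NA_real_, g, length(full_coef),
                dimnames = list(NULL, names(full_coef)))
  for (b in seq_len(g)) {
    idx <- -(bounds[b, "lo"]:bounds[b, "hi"])
    est[b, ] <- tryCatch(
      .wls(X[idx, , drop = FALSE], (y - offset)[idx], w[idx]),
      error = function(e) {
        stop("jackknife block ", b, " makes the design singular: ",
             conditionMessage(e))
      }
    )
  }
  m_j <- bounds[, "hi"] - bounds[, "lo"] + 1L
  h_j <- n / m_j
  # delete-m_j jackknife (Busing et al. 1999); reduces to the standard
  # delete-one-block form for equal blocks
  full <- matrix(full_coef, g, length(full_coef), byrow = TRUE)
  pseudo <- h_j * full - (h_j - 1) * est
  jack_est <- g * full_coef - colSums((1 - m_j / n) * est)
  var_hat <- colMeans(
    (pseudo - matrix(jack_est, g, length(full_coef), byrow = TRUE))^2 /
      (h_j - 1)
  )
  list(se = sqrt(var_hat), estimates = est, n_blocks = g)
}

.assemble_fit <- function(eng, jk) {
  coef <- eng$fit$coef
  opt <- eng$opt
  intercept <- if (opt$free_intercept) coef[["intercept"]] else eng$offset
  ldsc_only <- isTRUE(opt$ldsc_only)
  theta_hat <- if (ldsc_only) 0 else coef[["theta"]]
  tau_names <- grep("^tau", names(coef), value = TRUE)
  tau_hat <- coef[tau_names]
  if (length(tau_hat) == 1L) tau_hat <- unname(tau_hat)
  se <- jk$se
  p_theta <- if (ldsc_only) {
    NA_real_
  } else {
    2 * stats::pnorm(-abs(theta_hat / se[["theta"]]))
  }
  pve_add <- sum(tau_hat)
  pve_int <- theta_hat
  structure(
    list(
      intercept = intercept,
      tau_hat = tau_hat,
      theta_hat = theta_hat,
      se = se,
      p_theta = p_theta,
      pve_add = pve_add,
      pve_int = pve_int,
      pve_total = pve_add + pve_int,
      weights = eng$fit$weights,
      n_blocks = jk$n_blocks,
      n_iter = eng$fit$n_iter,
      J_used = eng$J_used,
      M = eng$M,
      n_filtered = eng$n_filtered,
      log_likelihood = eng$fit$loglik,
      window = attr(eng$m, "window"),
      ids = eng$m$id,
      block_estimates = jk$estimates
    ),
    class = "ildsc_fit"
  )
}

#' Fit the interaction-LD score regression
#'
#' Regresses per-variant GWAS chi-square statistics on additive LD scores
#' and one cis-interaction score column, by iteratively re-weighted least
#' squares, and reports block-jackknife standard errors and the test of the
#' interaction coefficient.
#'
#' @param sumstats a `sumstats` data frame (see [read_sumstats()], [gwas()]).
#' @param scores a `score_table` (see [compute_scores()], [read_scores()]).
#' @param window which cis-interaction column to use; either the bare
#'   window label (e.g. `50`) or the full column name (e.g. `"F_W50"`).
#' @param options named list overriding any of: `n_iter` (weight-update
#'   passes after the unweighted solve; default 2), `free_intercept`
#'   (default `TRUE`; `FALSE` constrains it to 1), `max_chisq` (outlier
#'   filter, default `max(80, 0.001 N)`), `two_stage` (estimate the
#'   intercept on the chi-square < 30 subset first), `overcount_weight`
#'   (extra 1/ell weighting, off by default), `psi_floor` (fitted-value
#'   floor before weight inversion, default 1), `n_blocks` (jackknife
#'   blocks, default 200), `jackknife` (set `FALSE` to skip SEs).
#' @return An object of class `ildsc_fit` with the intercept, `tau_hat` and
#'   `theta_hat` on the variance-explained scale (the regressors are
#'   pre-scaled by N/J and N/M, so `pve_add = tau_hat`,
#'   `pve_int = theta_hat` and `pve_total` is the heritability estimate),
#'   jackknife `se`, `p_theta`, final `weights`, `log_likelihood`, and
#'   bookkeeping fields (`J_used`, `M`, `n_filtered`, `window`, `ids`).
#' @export
fit_ildsc <- function(sumstats, scores, window = 50, options = list()) {
  m <- .merge_sumstats_scores(sumstats, scores, window)
  eng <- .fit_engine(m, options)
  jk <- if (isTRUE(eng$opt$jackknife)) {
    .jackknife_engine(eng$X, eng$m$chisq, eng$fit$weights, eng$offset,
                      eng$opt$n_blocks, eng$fit$coef)
  } else {
    k <- length(eng$fit$coef)
    list(se = stats::setNames(rep(NA_real_, k), names(eng$fit$coef)),
         estimates = NULL, n_blocks = 0L)
  }
  .assemble_fit(eng, jk)
}

#' Block-jackknife standard errors for an i-LDSC fit
#'
#' Partitions the merged variants (in genomic order) into contiguous,
#' near-equal-count blocks, refits the final weighted regression with each
#' block deleted (weights held fixed at the full-fit values), and returns
#' delete-m jackknife standard errors plus the two-sided normal p-value for
#' the interaction coefficient.
#'
#' @inheritParams fit_ildsc
#' @param n_blocks number of contiguous blocks (at least 2).
#' @return A list with `se` (named, one per coefficient), `p_theta` and the
#'   per-block leave-one-out `estimates` matrix.
#' @export
ildsc_jackknife <- function(sumstats, scores, window = 50, options = list(),
                            n_blocks = 200L) {
  if (n_blocks < 2L) stop("n_blocks must be at least 2")
  options$n_blocks <- n_blocks
  options$jackknife <- TRUE
  fit <- fit_ildsc(sumstats, scores, window, options)
  list(se = fit$se, p_theta = fit$p_theta, estimates = fit$block_estimates)
}

#' Model averaging over cis-interaction window sizes
#'
#' Combines fits obtained with different window sizes using normalized
#' importance weights proportional to each fit's Gaussian pseudo-likelihood
#' (log-sum-exp stabilized).
#'
#' @param fits list of `ildsc_fit` objects on the same merged variant set.
#' @return A list with `weights` (per window, summing to 1), `tau_avg`,
#'   `theta_avg`, `pve_total_avg` and `per_window` (the input fits).
#' @export
model_average <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "ildsc_fit")))
  ids <- lapply(fits, `[[`, "ids")
  if (!all(vapply(ids, identical, logical(1), ids[[1L]]))) {
    stop("fits were computed on different merged variant sets")
  }
  ll <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  pi_l <- exp(ll - max(ll))
  pi_l <- pi_l / sum(pi_l)
  list(
    weights = pi_l,
    tau_avg = sum(pi_l * vapply(fits, function(f) sum(f$tau_hat),
                                numeric(1))),
    theta_avg = sum(pi_l * vapply(fits, `[[`, numeric(1), "theta_hat")),
    pve_total_avg = sum(pi_l * vapply(fits, `[[`, numeric(1), "pve_total")),
    per_window = fits
  )
}

#' Stratified fit with annotation LD score columns
#'
#' Fits the same weighted regression with one additive score column per
#' annotation category (computed via the `annotations` argument of
#' [compute_scores()]) plus the cis-interaction column.
#'
#' @inheritParams fit_ildsc
#' @param ell_cols character vector naming the annotation score columns of
#'   `scores$ell` to include; when `NULL`, all columns are used (or the
#'   single unannotated score).
#' @return An `ildsc_fit` whose `tau_hat` and `se` carry one entry per
#'   annotation column; `pve_add` is the summed additive PVE.
#' @export
fit_stratified <- function(sumstats, scores, window = 50, ell_cols = NULL,
                           options = list()) {
  em <- as.matrix(scores$ell)
  if (is.null(ell_cols)) {
    ell_cols <- colnames(em)
    if (is.null(ell_cols)) {
      return(fit_ildsc(sumstats, scores, window, options))
    }
  }
  m <- .merge_sumstats_scores(sumstats, scores, window, extra_cols = ell_cols)
  eng <- .fit_engine(m, options, extra_cols = ell_cols)
  jk <- if (isTRUE(eng$opt$jackknife)) {
    .jackknife_engine(eng$X, eng$m$chisq, eng$fit$weights, eng$offset,
                      eng$opt$n_blocks, eng$fit$coef)
  } else {
    k <- length(eng$fit$coef)
    list(se = stats::setNames(rep(NA_real_, k), names(eng$fit$coef)),
         estimates = NULL, n_blocks = 0L)
  }
  .assemble_fit(eng, jk)
}

#' @export
print.ildsc_fit <- function(x, ...) {
  cat("interaction-LD score regression fit\n")
  cat(sprintf("  variants used: %d (window %s, M = %g)\n",
              x$J_used, x$window, x$M))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  cat(sprintf("  additive PVE (tau):     %.4f (se %.4f)\n",
              x$pve_add, sum(x$se[grep("^tau", names(x$se))])))
  if ("theta" %in% names(x$se)) {
    cat(sprintf("  interaction PVE (theta): %.4f (se %.4f)  p = %.3g\n",
                x$pve_int, x$se[["theta"]], x$p_theta))
  }
  cat(sprintf("  total PVE: %.4f\n", x$pve_total))
  invisible(x)
}
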