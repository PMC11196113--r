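# Synthetic genotype panels and phenotypes.
#
# Genotypes: a Gaussian-copula AR(1) latent field per haplotype, thresholded
# at each variant's MAF quantile, so marginals are Bin(2, p_j) under HWE
# while adjacent variants carry tunable LD. Phenotypes follow
#   y = b0 + X beta + XD omega + W theta + Z gamma + eps
# with the interaction columns being Hadamard products of (centered)
# genotype pairs from a hub/partner architecture. Components are centered,
# orthogonalized in-sample in sequence, and rescaled so that each realized
# variance share hits its configured target exactly and V[y] = 1.

#' Simulate a genotype panel with AR(1) linkage disequilibrium
#'
#' Two latent Gaussian AR(1) haplotype fields per sample are thresholded at
#' each variant's MAF quantile, giving Bin(2, p) marginals under
#' Hardy-Weinberg equilibrium with tunable LD between neighbors. The
#' recombination intensity varies along the chromosome in blocks (drawn
#' geometric with mean `block_len` variants): within a block the
#' adjacent-variant latent correlation is `ld_decay^rate`, with the block
#' rate multiplier drawn log-uniformly over `rate_range`. This hot/cold
#' block structure gives LD scores a realistic dynamic range; a constant
#' rate (set `rate_range = c(1, 1)`) leaves almost no LD-score variation,
#' so additive and interaction scores would co-vary through MAF alone.
#'
#' @param n sample count.
#' @param j variant count (single chromosome, 1 kb spacing; genetic
#'   positions follow 1 cM per Mb).
#' @param ld_decay baseline AR(1) parameter of the latent haplotype field,
#'   in `[0, 1)`; 0 gives independent variants. Default 0.9.
#' @param maf_low,maf_high range of the per-variant minor allele frequency
#'   targets (drawn uniformly). Defaults 0.05 and 0.5.
#' @param block_len mean recombination-block length in variants.
#' @param rate_range range of the log-uniform block rate multiplier.
#' @param seed optional integer seed; the panel is deterministic given it.
#' @return A [genotype_panel()].
#' @export
simulate_genotypes <- function(n, j, ld_decay = 0.9, maf_low = 0.05,
                               maf_high = 0.5, block_len = 50,
                               rate_range = c(0.1, 10), seed = NULL) {
  if (maf_low < 0 || maf_low >= maf_high || maf_high > 0.5) {
    stop("need 0 <= maf_low < maf_high <= 0.5")
  }
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(j, maf_low, maf_high)
  thr <- stats::qnorm(p)
  n_blocks <- max(1L, stats::rpois(1L, j / block_len) + 1L)
  bnd <- if (j > 1L) sort(sample(2:j, min(n_blocks, j - 1L))) else integer(0)
  rate <- exp(stats::runif(length(bnd) + 1L,
                           log(rate_range[1L]), log(rate_range[2L])))
  phi <- (ld_decay^rate)[findInterval(seq_len(j), c(1L, bnd))]
  g <- matrix(0L, n, j)
  for (hap in 1:2) {
    z <- stats::rnorm(n)
    g[, 1L] <- g[, 1L] + (z < thr[1L])
    for (v in seq_len(j - 1L) + 1L) {
      z <- phi[v] * z + sqrt(1 - phi[v]^2) * stats::rnorm(n)
      g[, v] <- g[, v] + (z < thr[v])
    }
  }
  bp <- 1000L * seq_len(j)
  genotype_panel(
    g,
    data.frame(
      chr = "1", id = paste0("snp_", seq_len(j)), cM = bp * 1e-6, bp = bp,
      allele1 = "A", allele2 = "B", stringsAsFactors = FALSE
    )
  )
}

#' Assign hub/partner interaction pairs
#'
#' Samples a fraction of variants uniformly without replacement to act as
#' interaction hubs; each hub is paired with every other variant inside a
#' flanking physical window. Pairs are deduplicated as unordered pairs. A
#' hub with no partner in its window is resampled (with a message).
#'
#' @param panel a [genotype_panel()].
#' @param group1_frac fraction of variants chosen as hubs, in `(0, 1]`.
#' @param group2_window_kb half-width (kb) of the partner window.
#' @param seed optional integer seed.
#' @return A list of class `pair_list` with `pairs` (two-column matrix of
#'   index pairs, first index smaller), `M` (pair count), `group1` (hub
#'   indices) and `group2` (partner indices).
#' @export
assign_interactions <- function(panel, group1_frac = 0.1,
                                group2_window_kb = 10, seed = NULL) {
  validate_panel(panel)
  if (group1_frac <= 0 || group1_frac > 1) {
    stop("group1_frac must be in (0, 1]")
  }
  n_hub <- max(1L, round(group1_frac * panel$j))
  if (!is.null(seed)) set.seed(seed)
  v <- panel$variants
  d <- group2_window_kb * 1000
  partners_of <- function(h) {
    same <- which(v$chr == v$chr[h])
    same[abs(v$bp[same] - v$bp[h]) <= d & same != h]
  }
  pool <- seq_len(panel$j)
  hubs <- sample(pool, n_hub)
  resampled <- 0L
  for (i in seq_along(hubs)) {
    while (length(partners_of(hubs[i])) == 0L) {
      pool <- setdiff(pool, hubs[i])
      if (length(setdiff(pool, hubs)) == 0L) {
        stop("no variant has a partner within the window")
      }
      hubs[i] <- sample(setdiff(pool, hubs), 1L)
      resampled <- resampled + 1L
    }
  }
  if (resampled > 0L) {
    message("assign_interactions: resampled ", resampled,
            " partnerless hub(s)")
  }
  pairs <- do.call(rbind, lapply(hubs, function(h) {
    pk <- partners_of(h)
    cbind(hub = rep.int(h, length(pk)), partner = pk)
  }))
  key <- paste(pmin(pairs[, 1L], pairs[, 2L]),
               pmax(pairs[, 1L], pairs[, 2L]))
  keep <- !duplicated(key)
  pairs <- pairs[keep, , drop = FALSE]
  structure(
    list(
      pairs = pairs, M = nrow(pairs),
      group1 = sort(hubs), group2 = sort(unique(pairs[, "partner"]))
    ),
    class = "pair_list"
  )
}

#' Trait simulation configuration
#'
#' Variance budget: additive effects explain `rho * h2`, an optional extra
#' component (gene-by-environment or gene-by-ancestry) explains
#' `var_extra * h2`, optional dominance explains `var_dom * h2`, and
#' pairwise interactions explain the remainder
#' `(1 - rho - var_extra - var_dom) * h2`; noise explains `1 - h2`.
#'
#' @param h2 broad-sense heritability in `[0, 1]`.
#' @param rho additive proportion of heritability in `[0, 1]`.
#' @param group1_frac,group2_window_kb hub/partner architecture (see
#'   [assign_interactions()]).
#' @param alpha_effects MAF-effect-size exponent: raw additive draws are
#'   multiplied by `(2 p q)^(alpha/2)` on the allele-count scale, so 0
#'   means no MAF dependence.
#' @param extra `"none"`, `"gxe"` (two contiguous environment halves with
#'   second-half effects `gxe_w` times the first) or `"gxancestry"`
#'   (interactions with the top `k_pcs` principal-component loadings).
#' @param gxe_w amplification coefficient for the second environment.
#' @param k_pcs number of ancestry components.
#' @param var_extra share of `h2` explained by the extra component.
#' @param effect_corr correlation between a hub's additive draw and its
#'   interaction draws (bivariate Gaussian; 0 restores independence).
#' @param sparsity optional list `(percentile, side)` restricting nonzero
#'   additive effects to an LD-score percentile set (see
#'   [sparse_architecture_effects()]).
#' @param include_dominance,var_dom optional dominance component using the
#'   `{0, 1, 1}` encoding, standardized.
#' @param b0 generative intercept.
#' @param seed optional integer seed.
#' @return A list of class `trait_config`.
#' @export
trait_config <- function(h2 = 0.6, rho = 1, group1_frac = 0.1,
                         group2_window_kb = 10, alpha_effects = 0,
                         extra = c("none", "gxe", "gxancestry"),
                         gxe_w = 1.5, k_pcs = 10, var_extra = 0,
                         effect_corr = 0, sparsity = NULL,
                         include_dominance = FALSE, var_dom = 0, b0 = 0,
                         seed = NULL) {
  extra <- match.arg(extra)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (var_extra < 0 || var_dom < 0 ||
      rho + var_extra + var_dom > 1 + 1e-12) {
    stop("variance shares rho + var_extra + var_dom exceed 1")
  }
  if (extra == "none" && var_extra > 0) {
    stop("var_extra > 0 requires extra = 'gxe' or 'gxancestry'")
  }
  if (abs(effect_corr) > 1) stop("effect_corr must be in [-1, 1]")
  structure(
    list(
      h2 = h2, rho = rho, group1_frac = group1_frac,
      group2_window_kb = group2_window_kb, alpha_effects = alpha_effects,
      extra = extra, gxe_w = gxe_w, k_pcs = k_pcs, var_extra = var_extra,
      effect_corr = effect_corr, sparsity = sparsity,
      include_dominance = include_dominance, var_dom = var_dom, b0 = b0,
      seed = seed
    ),
    class = "trait_config"
  )
}

.varN <- function(v) mean((v - mean(v))^2)

# map pair indices from panel-column space into standardized (kept) space
.map_pairs <- function(pairs, kept, jn, standardized) {
  if (standardized) {
    if (any(pairs < 1L | pairs > jn)) stop("pair index out of range")
    attr(pairs, "orig_rows") <- seq_len(nrow(pairs))
    return(pairs)
  }
  hub <- match(pairs[, "hub"], kept)
  partner <- match(pairs[, "partner"], kept)
  ok <- !is.na(hub) & !is.na(partner)
  if (!all(ok)) {
    message("simulate_trait: dropped ", sum(!ok),
            " pair(s) involving monomorphic variants")
  }
  out <- cbind(hub = hub[ok], partner = partner[ok])
  if (nrow(out) == 0L) stop("no interaction pairs left after filtering")
  attr(out, "orig_rows") <- which(ok)
  out
}

# center, project out previously accepted components, rescale to an exact
# in-sample variance target
.add_component <- function(state, comp, target, label) {
  comp <- comp - mean(comp)
  if (target <= 0) {
    return(state)
  }
  if (!is.null(state$basis)) {
    comp <- comp - state$basis %*% crossprod(state$basis, comp)
  }
  v <- .varN(comp)
  if (v <= 0) {
    stop("component '", label, "' has zero variance but a positive target")
  }
  scl <- sqrt(target / v)
  comp <- comp * scl
  state$components[[label]] <- drop(comp)
  state$scale[[label]] <- scl
  state$basis <- cbind(state$basis, comp / sqrt(sum(comp^2)))
  state
}

#' Simulate a phenotype from a genotype panel
#'
#' Effects are drawn on the allele-count scale (standard normal times
#' `(2 p q)^(alpha/2)`), interaction columns are Hadamard products of
#' centered allele counts over the supplied hub/partner pairs, and each
#' component is centered, orthogonalized in-sample against the previously
#' assembled ones, and rescaled so its realized variance hits the budget
#' target exactly and `V[y] = 1`.
#'
#' @param panel a [genotype_panel()], or a `standardized_panel` from
#'   [standardize()] (faster when many traits are simulated on one panel;
#'   count-scale components are reconstructed from the stored per-column
#'   standard deviations). Dominance requires a raw `genotype_panel`.
#' @param pairs a `pair_list` from [assign_interactions()]; required when
#'   the interaction share of the variance budget is positive. Pair indices
#'   refer to the columns of `panel`.
#' @param config a [trait_config()].
#' @param ell optional additive LD scores (needed only when
#'   `config$sparsity` is set).
#' @return A list of class `trait_realization` with `y` (unit in-sample
#'   variance), the scaled effect vectors (`beta`, `theta` keyed by pair
#'   rows, optional `omega`, `gamma`), `eps`, and `realized_var` with exact
#'   component shares.
#' @export
simulate_trait <- function(panel, pairs = NULL, config = trait_config(),
                           ell = NULL) {
  stopifnot(inherits(config, "trait_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  h2 <- config$h2
  var_int_share <- 1 - config$rho - config$var_extra - config$var_dom
  targets <- list(
    add = config$rho * h2,
    dom = config$var_dom * h2,
    int = var_int_share * h2,
    extra = config$var_extra * h2
  )
  if (targets$int > 1e-12 && (is.null(pairs) || pairs$M == 0L)) {
    stop("interaction share is positive but no pairs were supplied")
  }
  if (inherits(panel, "standardized_panel")) {
    if (config$include_dominance && targets$dom > 0) {
      stop("dominance simulation needs a raw genotype_panel")
    }
    sp <- panel
    g <- NULL
  } else {
    validate_panel(panel)
    sp <- standardize(panel, min_maf = 0)
    g <- panel$genotypes
  }
  xs <- sp$matrix
  sdc <- sp$sd # count-scale standard deviations (1/N convention)
  p <- sp$maf
  n <- sp$n
  jn <- sp$j

  # additive draws (kept for correlated interaction draws below)
  z_add <- stats::rnorm(jn)
  beta <- z_add * (2 * p * (1 - p))^(config$alpha_effects / 2)
  if (!is.null(config$sparsity)) {
    if (is.null(ell)) stop("sparsity requires additive LD scores (ell)")
    if (length(ell) != jn) stop("ell must match the standardized panel")
    sel <- .percentile_set(ell, config$sparsity$percentile,
                           config$sparsity$side)
    beta[-sel] <- 0
  }
  state <- list(components = list(), scale = list(), basis = NULL)
  state <- .add_component(state, drop(xs %*% (beta * sdc)), targets$add,
                          "add")
  if (targets$add > 0) beta <- beta * state$scale$add else beta[] <- 0

  omega <- NULL
  if (config$include_dominance && targets$dom > 0) {
    storage.mode(g) <- "double"
    gk <- g[, sp$kept, drop = FALSE]
    if (anyNA(gk)) {
      idx <- which(is.na(gk), arr.ind = TRUE)
      gk[idx] <- (sp$mu)[idx[, 2L]]
    }
    xd <- (gk >= 1) * 1
    xd <- sweep(xd, 2L, colMeans(xd), "-")
    sd_d <- sqrt(colMeans(xd^2))
    ok <- sd_d > 0
    xd <- sweep(xd[, ok, drop = FALSE], 2L, sd_d[ok], "/")
    omega <- numeric(jn)
    omega[ok] <- stats::rnorm(sum(ok))
    state <- .add_component(state, drop(xd %*% omega[ok]), targets$dom,
                            "dom")
    omega <- omega * state$scale$dom
  }

  theta <- NULL
  pair_out <- NULL
  if (targets$int > 1e-12) {
    pr <- .map_pairs(pairs$pairs, sp$kept, jn,
                     standardized = inherits(panel, "standardized_panel"))
    r <- config$effect_corr
    z_pair <- r * z_add[pr[, "hub"]] +
      sqrt(1 - r^2) * stats::rnorm(nrow(pr))
    theta <- z_pair
    # count-scale product columns without materializing W:
    # xc_h o xc_k = sd_h sd_k (xs_h o xs_k), accumulated hub by hub
    comp <- numeric(n)
    coefs <- theta * sdc[pr[, "hub"]] * sdc[pr[, "partner"]]
    for (h in unique(pr[, "hub"])) {
      rows <- which(pr[, "hub"] == h)
      comp <- comp + xs[, h] *
        drop(xs[, pr[rows, "partner"], drop = FALSE] %*% coefs[rows])
    }
    state <- .add_component(state, comp, targets$int, "int")
    theta <- theta * state$scale$int
    pair_out <- pairs$pairs[attr(pr, "orig_rows"), , drop = FALSE]
  }

  gamma <- NULL
  if (config$extra != "none" && targets$extra > 0) {
    if (config$extra == "gxe") {
      half <- n %/% 2L
      gamma1 <- stats::rnorm(ncol(xs))
      gamma <- cbind(env1 = gamma1, env2 = config$gxe_w * gamma1)
      comp <- c(xs[seq_len(half), , drop = FALSE] %*% gamma[, 1L],
                xs[(half + 1L):n, , drop = FALSE] %*% gamma[, 2L])
    } else {
      k <- min(config$k_pcs, ncol(xs), n)
      sv <- svd(xs, nu = 0L, nv = k)
      zmat <- xs %*% sv$v[, seq_len(k), drop = FALSE]
      gamma <- stats::rnorm(k)
      comp <- drop(zmat %*% gamma)
    }
    state <- .add_component(state, comp, targets$extra, "extra")
    gamma <- gamma * state$scale$extra
  }

  eps <- stats::rnorm(n)
  state <- .add_component(state, eps, 1 - h2, "eps")
  eps <- state$components$eps
  y <- config$b0 + Reduce(`+`, state$components, accumulate = FALSE)
  realized <- list(
    add = if (is.null(state$components$add)) 0 else
      .varN(state$components$add),
    dom = if (is.null(state$components$dom)) 0 else
      .varN(state$components$dom),
    int = if (is.null(state$components$int)) 0 else
      .varN(state$components$int),
    extra = if (is.null(state$components$extra)) 0 else
      .varN(state$components$extra),
    noise = .varN(eps)
  )
  structure(
    list(
      y = drop(y), beta = beta, theta = theta,
      pairs = pair_out,
      omega = omega, gamma = gamma, eps = eps,
      kept = sp$kept, realized_var = realized, config = config
    ),
    class = "trait_realization"
  )
}

.percentile_set <- function(ell, percentile, side = c("top", "bottom")) {
  side <- match.arg(side)
  k <- round(length(ell) * percentile / 100)
  if (k < 1L) stop("empty percentile selection")
  ord <- order(ell, decreasing = (side == "top"))
  sort(ord[seq_len(k)])
}

#' Sparse additive architectures stratified by LD score
#'
#' Gives nonzero additive effects only to variants in the top or bottom
#' percentile set of LD scores, rescaled to an exact variance target.
#'
#' @param panel a [genotype_panel()].
#' @param ell additive LD scores for the same variants.
#' @param percentile percentage of variants selected (e.g. 10).
#' @param side `"top"` or `"bottom"` of the LD-score distribution.
#' @param h2 target in-sample variance of the additive component.
#' @param seed optional integer seed.
#' @return A list with `beta` (length J) and `selected` (indices).
#' @export
sparse_architecture_effects <- function(panel, ell, percentile,
                                        side = c("top", "bottom"), h2 = 0.6,
                                        seed = NULL) {
  validate_panel(panel)
  side <- match.arg(side)
  if (length(ell) != panel$j) stop("ell must have one entry per variant")
  if (!is.null(seed)) set.seed(seed)
  sel <- .percentile_set(ell, percentile, side)
  beta <- numeric(panel$j)
  beta[sel] <- stats::rnorm(length(sel))
  g <- panel$genotypes
  storage.mode(g) <- "double"
  xc <- sweep(g, 2L, colMeans(g), "-")
  comp <- drop(xc %*% beta)
  v <- .varN(comp)
  if (v <= 0) stop("selected variants carry no genotypic variance")
  beta <- beta * sqrt(h2 / v)
  list(beta = beta, selected = sel)
}

#' Marginal GWAS on a panel
#'
#' Residualizes the phenotype and every genotype column on the covariates
#' (with intercept), re-standardizes both, and computes the marginal least
#' squares effect and the chi-square statistic `N * betahat^2` per variant.
#'
#' @param panel a [genotype_panel()], or a `standardized_panel` from
#'   [standardize()] (faster when running many GWAS on one panel).
#' @param y phenotype vector.
#' @param covariates optional numeric matrix of covariates (full column
#'   rank; an intercept is always added).
#' @param drop_variants optional variants to omit (integer indices into the
#'   panel or character ids), for unobserved-variant designs.
#' @return A `sumstats` data frame with `id`, `allele1`, `allele2`, `N`,
#'   `z` and `chisq`.
#' @export
gwas <- function(panel, y, covariates = NULL, drop_variants = NULL) {
  sp <- if (inherits(panel, "standardized_panel")) {
    panel
  } else {
    validate_panel(panel)
    standardize(panel, min_maf = 0)
  }
  x <- sp$matrix
  v <- sp$variants
  if (!is.null(drop_variants)) {
    drop_ids <- if (is.character(drop_variants)) {
      drop_variants
    } else {
      sp$variants$id[drop_variants]
    }
    keep <- !(v$id %in% drop_ids)
    x <- x[, keep, drop = FALSE]
    v <- v[keep, , drop = FALSE]
  }
  n <- nrow(x)
  y <- as.numeric(y)
  if (length(y) != n) stop("phenotype length does not match panel")
  if (!is.null(covariates)) {
    cmat <- cbind(1, as.matrix(covariates))
    qrc <- qr(cmat)
    if (qrc$rank < ncol(cmat)) stop("covariate matrix is rank deficient")
    y <- qr.resid(qrc, y)
    x <- qr.resid(qrc, x)
    sdx <- sqrt(colMeans(x^2))
    ok <- sdx > 0
    x[, ok] <- sweep(x[, ok, drop = FALSE], 2L, sdx[ok], "/")
  }
  y <- y - mean(y)
  sy <- sqrt(.varN(y))
  if (sy <= 0) stop("phenotype has zero variance")
  y <- y / sy
  bhat <- drop(crossprod(x, y)) / n
  out <- data.frame(
    id = v$id, allele1 = v$allele1, allele2 = v$allele2,
    N = n, z = sqrt(n) * bhat, chisq = n * bhat^2,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Additive genetic variance implied by additive and interaction effects
#'
#' Under Hardy-Weinberg equilibrium and linkage equilibrium, the average
#' effect of variant j combines its additive effect with frequency-weighted
#' pairwise interaction effects,
#' `eta_j = beta_j + 2 * sum_k p_k theta_jk`, and the additive variance is
#' `sigmaA2 = sum_j 2 p_j (1 - p_j) eta_j^2`. This is the upper bound on
#' the variance recoverable from additive GWAS summary statistics.
#'
#' @param maf per-variant frequency of the counted allele, in `(0, 0.5]`.
#' @param beta additive effects on the allele-count scale.
#' @param theta pairwise effects: a data frame or matrix with columns
#'   `j`, `k`, `theta` (variant index pairs), or `NULL` for none.
#' @return A list with `sigmaA2` (total), `eta` (per-variant average
#'   effects) and `per_snp` (per-variant additive variance).
#' @export
additive_variance_bound <- function(maf, beta, theta = NULL) {
  jn <- length(maf)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must be in (0, 0.5]")
  if (length(beta) != jn) stop("beta must match maf in length")
  eta <- as.numeric(beta)
  if (!is.null(theta) && NROW(theta) > 0L) {
    th <- as.data.frame(theta)
    names(th)[1:3] <- c("j", "k", "theta")
    if (any(th$j < 1 | th$j > jn | th$k < 1 | th$k > jn)) {
      stop("pair index out of range")
    }
    for (r in seq_len(nrow(th))) {
      eta[th$j[r]] <- eta[th$j[r]] + 2 * maf[th$k[r]] * th$theta[r]
      eta[th$k[r]] <- eta[th$k[r]] + 2 * maf[th$j[r]] * th$theta[r]
    }
  }
  per_snp <- 2 * maf * (1 - maf) * eta^2
  list(sigmaA2 = sum(per_snp), eta = eta, per_snp = per_snp)
}
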