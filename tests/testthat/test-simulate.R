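test_that("simulated genotypes match their target allele frequencies", {
  panel <- simulate_genotypes(10000, 40, ld_decay = 0.7, maf_low = 0.05,
                              maf_high = 0.5, seed = 1)
  set.seed(1)
  p_target <- stats::runif(40, 0.05, 0.5) # same draws as the generator
  p_hat <- colMeans(panel$genotypes) / 2
  bound <- 2.576 * sqrt(p_target * (1 - p_target) / (2 * 10000))
  expect_true(all(abs(p_hat - p_target) <= bound))
  expect_true(all(panel$genotypes %in% 0:2))
  expect_true(!is.unsorted(panel$variants$bp))
})

test_that("ld_decay = 0 gives independent neighbors; seeds reproduce", {
  panel <- simulate_genotypes(2000, 60, ld_decay = 0, seed = 2)
  sp <- standardize(panel, min_maf = 0)
  r_adj <- vapply(seq_len(sp$j - 1L), function(j)
    stats::cor(sp$matrix[, j], sp$matrix[, j + 1L]), numeric(1))
  expect_lt(abs(mean(r_adj)), 3 / sqrt(2000 * length(r_adj)))

  p1 <- simulate_genotypes(100, 30, seed = 7)
  p2 <- simulate_genotypes(100, 30, seed = 7)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$variants, p2$variants)
  # positive decay produces positive neighbor LD
  p3 <- standardize(simulate_genotypes(2000, 60, ld_decay = 0.9,
                                       rate_range = c(1, 1), seed = 3),
                    min_maf = 0)
  r3 <- vapply(seq_len(p3$j - 1L), function(j)
    stats::cor(p3$matrix[, j], p3$matrix[, j + 1L]), numeric(1))
  expect_gt(mean(r3), 0.4)
})

test_that("hub/partner assignment matches window arithmetic", {
  panel <- make_panel(50, 100, seed = 4)
  pl <- assign_interactions(panel, group1_frac = 0.05,
                            group2_window_kb = 10, seed = 5)
  # every hub is paired with exactly the variants <= 10 kb away
  for (h in pl$group1) {
    want <- which(abs(panel$variants$bp - panel$variants$bp[h]) <= 10000 &
                    seq_len(100) != h)
    got <- sort(unique(c(
      pl$pairs[pl$pairs[, "hub"] == h, "partner"],
      pl$pairs[pl$pairs[, "partner"] == h, "hub"]
    )))
    expect_true(all(want %in% got))
  }
  # interior hubs have exactly 20 partners at 1 kb spacing
  interior <- pl$group1[pl$group1 > 10 & pl$group1 < 91]
  if (length(interior) > 0) {
    h <- interior[1]
    cnt <- sum(pl$pairs[, "hub"] == h | pl$pairs[, "partner"] == h)
    expect_equal(cnt, 20L)
  }

  # all hubs, window spanning everything: every unordered pair once
  small <- make_panel(30, 20, seed = 6)
  all_pairs <- assign_interactions(small, 1, group2_window_kb = 1000,
                                   seed = 7)
  expect_equal(all_pairs$M, 20 * 19 / 2)
  key <- paste(pmin(all_pairs$pairs[, 1], all_pairs$pairs[, 2]),
               pmax(all_pairs$pairs[, 1], all_pairs$pairs[, 2]))
  expect_false(anyDuplicated(key) > 0)
})

test_that("trait realizations hit their variance budget exactly", {
  panel <- make_panel(500, 120, seed = 8)
  pairs <- assign_interactions(panel, 0.1, 10, seed = 9)
  cfg <- trait_config(h2 = 0.6, rho = 0.5, seed = 10)
  tr <- simulate_trait(panel, pairs, cfg)
  v <- tr$realized_var
  expect_equal(v$add, 0.3, tolerance = 1e-10)
  expect_equal(v$int, 0.3, tolerance = 1e-10)
  expect_equal(v$noise, 0.4, tolerance = 1e-10)
  expect_equal(mean((tr$y - mean(tr$y))^2), 1, tolerance = 1e-10)

  # purely additive: no interaction effects at all
  tr1 <- simulate_trait(panel, NULL, trait_config(h2 = 0.6, rho = 1,
                                                  seed = 11))
  expect_null(tr1$theta)
  expect_equal(tr1$realized_var$int, 0)

  # reproducibility
  tr2 <- simulate_trait(panel, pairs, cfg)
  expect_equal(tr2$y, tr$y)
  expect_equal(tr2$beta, tr$beta)

  # infeasible budgets and missing pairs are rejected
  expect_error(trait_config(rho = 0.5, var_extra = 0.6), "exceed")
  expect_error(simulate_trait(panel, NULL, cfg), "no pairs")

  # a standardized panel gives the identical realization
  sp <- standardize(panel, min_maf = 0)
  tr3 <- simulate_trait(sp, pairs, cfg)
  expect_equal(tr3$y, tr$y, tolerance = 1e-12)
})

test_that("gxe, gxancestry and dominance components fill the budget", {
  panel <- make_panel(400, 80, seed = 12)
  pairs <- assign_interactions(panel, 0.1, 10, seed = 13)
  gxe <- simulate_trait(panel, pairs,
                        trait_config(h2 = 0.6, rho = 0.5, extra = "gxe",
                                     gxe_w = 1.5, var_extra = 0.25,
                                     seed = 14))
  expect_equal(gxe$realized_var$extra, 0.25 * 0.6, tolerance = 1e-10)
  expect_equal(gxe$realized_var$int, 0.25 * 0.6, tolerance = 1e-10)
  # second-environment effects are the amplified first-environment ones
  expect_equal(gxe$gamma[, "env2"], 1.5 * gxe$gamma[, "env1"])

  anc <- simulate_trait(panel, pairs,
                        trait_config(h2 = 0.6, rho = 0.5,
                                     extra = "gxancestry", k_pcs = 5,
                                     var_extra = 0.25, seed = 15))
  expect_equal(anc$realized_var$extra, 0.15, tolerance = 1e-10)
  expect_length(anc$gamma, 5)

  dom <- simulate_trait(panel, pairs,
                        trait_config(h2 = 0.6, rho = 0.5,
                                     include_dominance = TRUE,
                                     var_dom = 0.2, seed = 16))
  expect_equal(dom$realized_var$dom, 0.12, tolerance = 1e-10)
  expect_equal(dom$realized_var$int, 0.3 * 0.6, tolerance = 1e-10)
  expect_equal(sum(unlist(dom$realized_var)), 1, tolerance = 1e-10)
})

test_that("sparse architectures select exactly the LD-score percentile", {
  panel <- make_panel(200, 1000, seed = 17)
  sp <- standardize(panel, min_maf = 0)
  ell <- additive_ld_scores(sp, window_spec("snps", 10),
                            bias_correct = FALSE)
  expect_equal(sp$j, panel$j) # nothing dropped at these frequencies
  out <- sparse_architecture_effects(panel, ell, percentile = 10,
                                     side = "top", h2 = 0.6, seed = 18)
  expect_equal(sum(out$beta != 0), 100L)
  expect_setequal(out$selected, order(ell, decreasing = TRUE)[1:100])

  all_c <- sparse_architecture_effects(panel, ell, percentile = 100,
                                       side = "top", seed = 19)
  expect_equal(sum(all_c$beta != 0), 1000L)
  bot <- sparse_architecture_effects(panel, ell, percentile = 5,
                                     side = "bottom", seed = 20)
  expect_setequal(bot$selected, order(ell)[1:50])
  expect_error(sparse_architecture_effects(panel, ell, percentile = 0.01,
                                           side = "top"), "empty")
})

test_that("gwas reproduces forced marginal statistics", {
  panel <- make_panel(300, 20, seed = 21)
  sp <- standardize(panel, min_maf = 0)
  y <- sp$matrix[, 1] # exactly the first standardized genotype
  ss <- gwas(panel, y)
  expect_equal(ss$chisq[1], 300, tolerance = 1e-8)
  expect_equal(ss$N[1], 300)

  # phenotype orthogonalized against a genotype gives chi-square 0
  y2 <- stats::rnorm(300)
  y2 <- y2 - sp$matrix[, 3] * sum(y2 * sp$matrix[, 3]) /
    sum(sp$matrix[, 3]^2)
  ss2 <- gwas(panel, y2)
  expect_lt(ss2$chisq[3], 1e-16)
})

test_that("gwas with covariates equals per-SNP least squares on residuals", {
  set.seed(22)
  panel <- make_panel(250, 15, seed = 23)
  covs <- cbind(stats::rnorm(250), stats::rbinom(250, 1, 0.5))
  y <- stats::rnorm(250) + 0.5 * covs[, 1]
  ss <- gwas(panel, y, covariates = covs)
  sp <- standardize(panel, min_maf = 0)
  q <- qr(cbind(1, covs))
  yr <- qr.resid(q, y)
  yr <- (yr - mean(yr)) / sqrt(mean((yr - mean(yr))^2))
  for (j in c(1, 7, 15)) {
    xr <- qr.resid(q, sp$matrix[, j])
    xr <- xr / sqrt(mean(xr^2))
    expect_equal(ss$chisq[j], 250 * (sum(xr * yr) / 250)^2,
                 tolerance = 1e-10)
  }
  expect_error(gwas(panel, y, covariates = cbind(covs, covs[, 1])),
               "rank")

  # drop_variants omits the requested ids
  ss3 <- gwas(panel, y, drop_variants = c(2L, 4L))
  expect_equal(nrow(ss3), nrow(ss) - 2L)
  expect_false(any(c("snp_2", "snp_4") %in% ss3$id))
})

test_that("additive variance bound matches exhaustive HWE enumeration", {
  # theta = 0 reduces to the classical additive variance
  maf <- c(0.1, 0.25, 0.4)
  beta <- c(0.5, -0.3, 0.2)
  out <- additive_variance_bound(maf, beta)
  expect_equal(out$sigmaA2, sum(2 * maf * (1 - maf) * beta^2),
               tolerance = 1e-14)

  # J = 2 with an interaction: enumerate the 9 genotype combinations under
  # HWE and linkage equilibrium, regress the genetic value on each dosage,
  # and sum the per-locus regression variances
  p <- c(0.3, 0.4)
  beta2 <- c(0.1, 0.2)
  th <- 0.5
  probs1 <- stats::dbinom(0:2, 2, p[1])
  probs2 <- stats::dbinom(0:2, 2, p[2])
  grid <- expand.grid(x1 = 0:2, x2 = 0:2)
  w <- probs1[grid$x1 + 1] * probs2[grid$x2 + 1]
  gval <- beta2[1] * grid$x1 + beta2[2] * grid$x2 + th * grid$x1 * grid$x2
  slope <- function(x) {
    mx <- sum(w * x)
    (sum(w * x * gval) - mx * sum(w * gval)) / (sum(w * x^2) - mx^2)
  }
  var1 <- (sum(w * grid$x1^2) - sum(w * grid$x1)^2) * slope(grid$x1)^2
  var2 <- (sum(w * grid$x2^2) - sum(w * grid$x2)^2) * slope(grid$x2)^2
  out2 <- additive_variance_bound(p, beta2,
                                  data.frame(j = 1, k = 2, theta = th))
  expect_equal(out2$sigmaA2, var1 + var2, tolerance = 1e-12)
  expect_equal(out2$eta, c(beta2[1] + 2 * p[2] * th,
                           beta2[2] + 2 * p[1] * th), tolerance = 1e-14)

  # homogeneity: doubling all effects quadruples the variance
  out3 <- additive_variance_bound(p, 2 * beta2,
                                  data.frame(j = 1, k = 2, theta = 2 * th))
  expect_equal(out3$sigmaA2, 4 * out2$sigmaA2, tolerance = 1e-12)
  expect_error(additive_variance_bound(p, beta2,
                                       data.frame(j = 1, k = 5,
                                                  theta = 1)),
               "out of range")
  expect_error(additive_variance_bound(c(0.6, 0.2), beta2), "maf")
})

test_that("independently drawn components are orthogonal on average", {
  # raw generative draws (before any in-sample orthogonalization): the
  # covariance between X beta and W theta averages to zero over replicates
  panel <- make_panel(300, 60, seed = 24)
  sp <- standardize(panel, min_maf = 0)
  pairs <- assign_interactions(panel, 0.2, 5, seed = 25)
  xs <- sp$matrix
  set.seed(26)
  covs <- replicate(200, {
    beta <- stats::rnorm(sp$j)
    theta <- stats::rnorm(pairs$M)
    ga <- drop(xs %*% beta)
    wi <- xs[, pairs$pairs[, 1]] * xs[, pairs$pairs[, 2]]
    gi <- drop(wi %*% theta)
    mean(ga * gi) - mean(ga) * mean(gi)
  })
  expect_lt(abs(mean(covs)), 3 * stats::sd(covs) / sqrt(length(covs)))
})

test_that("marginal effects decompose as tagged additive plus interaction", {
  # on a simulated trait the GWAS betahat regressed on the in-sample
  # prediction R beta + V theta has slope 1 up to noise
  panel <- make_panel(3000, 80, seed = 27)
  sp <- standardize(panel, min_maf = 0)
  pairs <- assign_interactions(panel, 0.2, 5, seed = 28)
  tr <- simulate_trait(sp, pairs, trait_config(h2 = 0.6, rho = 0.5,
                                               seed = 29))
  ss <- gwas(sp, tr$y)
  xs <- sp$matrix
  n <- sp$n
  pred_add <- drop(crossprod(xs, xs %*% (tr$beta * sp$sd))) / n
  wm <- sweep(xs[, tr$pairs[, 1], drop = FALSE] *
                xs[, tr$pairs[, 2], drop = FALSE], 2,
              sp$sd[tr$pairs[, 1]] * sp$sd[tr$pairs[, 2]], "*")
  pred_int <- drop(crossprod(xs, wm %*% tr$theta)) / n
  bhat <- ss$z / sqrt(ss$N)
  co <- stats::coef(stats::lm(bhat ~ I(pred_add + pred_int)))
  expect_equal(unname(co[2]), 1, tolerance = 0.1)
})
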