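# shared fixture builders (generated in code; nothing stored on disk)

make_panel <- function(n, j, seed, ld_decay = 0.8, maf_low = 0.1,
                       maf_high = 0.5, missing_rate = 0) {
  panel <- simulate_genotypes(n, j, ld_decay = ld_decay, maf_low = maf_low,
                              maf_high = maf_high, seed = seed)
  if (missing_rate > 0) {
    g <- panel$genotypes
    nmiss <- ceiling(missing_rate * length(g))
    g[sample(length(g), nmiss)] <- NA_integer_
    # keep at least one observed call per column
    for (cc in which(colSums(!is.na(g)) == 0)) g[1L, cc] <- 1L
    panel <- genotype_panel(g, panel$variants, panel$samples)
  }
  panel
}

panel_from_dosages <- function(g, bp = NULL, chr = NULL) {
  g <- as.matrix(g)
  j <- ncol(g)
  if (is.null(bp)) bp <- 1000L * seq_len(j)
  if (is.null(chr)) chr <- rep("1", j)
  genotype_panel(
    g,
    data.frame(chr = chr, id = paste0("snp_", seq_len(j)), cM = bp * 1e-6,
               bp = bp, allele1 = "A", allele2 = "B",
               stringsAsFactors = FALSE)
  )
}

# scalar-loop third implementation of the interaction score (no matrix ops);
# cross-validates both the fast path and the brute-force oracle
cis_scores_scalar <- function(panel, half_width, include_self = FALSE) {
  x <- panel$matrix
  n <- panel$n
  jn <- panel$j
  f <- numeric(jn)
  for (j in seq_len(jn)) {
    for (k in max(1L, j - half_width):min(jn, j + half_width)) {
      if (!include_self && k == j) next
      s_xw <- 0; s_w <- 0; s_w2 <- 0
      for (i in seq_len(n)) {
        w_i <- x[i, j] * x[i, k]
        s_xw <- s_xw + x[i, j] * w_i
        s_w <- s_w + w_i
        s_w2 <- s_w2 + w_i * w_i
      }
      vw <- s_w2 / n - (s_w / n)^2
      if (vw <= 1e-12) next
      cov_xw <- s_xw / n - 0 * (s_w / n)
      f[j] <- f[j] + cov_xw^2 / vw
    }
  }
  f
}
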