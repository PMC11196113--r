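# Genotype, summary-statistic and score-table input/output.
#
# PLINK 1 binary panels are decoded bit-exactly: the .bed payload is
# SNP-major, two bits per genotype starting at the least-significant pair of
# each byte, with 00 = two copies of allele1 (the .bim A1 column),
# 10 = one copy, 11 = zero copies and 01 = missing.

PLINK_MAGIC <- as.raw(c(0x6C, 0x1B))
PLINK_SNP_MAJOR <- as.raw(0x01)

# 256 x 4 lookup: byte value -> allele1 dosages of the four packed genotypes
.bed_decode_lut <- local({
  code2dosage <- c(2L, NA_integer_, 1L, 0L) # 2-bit codes 00,01,10,11
  lut <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    lut[b + 1L, ] <- code2dosage[c(
      bitwAnd(b, 3L),
      bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L),
      bitwAnd(bitwShiftR(b, 6L), 3L)
    ) + 1L]
  }
  lut
})

#' Construct a genotype panel
#'
#' Bundles an `N x J` allele-count matrix (entries 0, 1, 2 or `NA` for
#' missing) with per-variant and per-sample metadata. This is the raw,
#' unstandardized container that all score computation starts from.
#'
#' @param genotypes integer or numeric matrix of allele1 counts, samples in
#'   rows, variants in columns. Missing genotypes are `NA`.
#' @param variants data frame with columns `chr`, `id`, `cM`, `bp`,
#'   `allele1`, `allele2` (one row per column of `genotypes`).
#' @param samples character vector of sample identifiers.
#' @return An object of class `genotype_panel` with elements `genotypes`,
#'   `variants`, `samples`, `n`, `j`.
#' @export
genotype_panel <- function(genotypes, variants, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) samples <- paste0("sample_", seq_len(nrow(genotypes)))
  panel <- structure(
    list(
      genotypes = genotypes,
      variants = as.data.frame(variants),
      samples = as.character(samples),
      n = nrow(genotypes),
      j = ncol(genotypes)
    ),
    class = "genotype_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  if (panel$n < 1L || panel$j < 1L) {
    stop("genotype panel must have at least one sample and one variant")
  }
  ok <- g %in% c(0L, 1L, 2L) | is.na(g)
  if (!all(ok)) stop("genotype entries must be in {0, 1, 2, NA}")
  v <- panel$variants
  need <- c("chr", "id", "cM", "bp", "allele1", "allele2")
  if (!all(need %in% names(v))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(v) != panel$j) stop("variant table does not match genotype columns")
  if (length(panel$samples) != panel$n) stop("sample ids do not match rows")
  for (chr in unique(v$chr)) {
    bp <- v$bp[v$chr == chr]
    if (is.unsorted(bp)) {
      stop("bp positions must be non-decreasing within chromosome ", chr)
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d samples x %d variants (%d chromosome(s))\n",
    x$n, x$j, length(unique(x$variants$chr))
  ))
  invisible(x)
}

#' Read a PLINK 1 binary genotype panel
#'
#' @param prefix path stem; `prefix.bed`, `prefix.bim` and `prefix.fam` must
#'   exist. Only SNP-major (mode byte `0x01`) files are supported.
#' @return A [genotype_panel()]; dosages count copies of the .bim A1 allele.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  }
  vtab <- utils::read.table(
    bim,
    col.names = c("chr", "id", "cM", "bp", "allele1", "allele2"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character")
  )
  ftab <- utils::read.table(fam, colClasses = "character")
  samples <- ftab[[2L]]
  n <- nrow(ftab)
  j <- nrow(vtab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_MAGIC) ||
      !identical(raw[3L], PLINK_SNP_MAJOR)) {
    stop("not a SNP-major PLINK .bed file (bad magic or mode byte): ", bed)
  }
  bpv <- ceiling(n / 4) # bytes per variant
  if (length(raw) - 3L != bpv * j) {
    stop(sprintf(
      ".bed payload is %d bytes but %d samples x %d variants needs %d",
      length(raw) - 3L, n, j, bpv * j
    ))
  }
  codes <- .bed_decode_lut[as.integer(raw[-(1:3)]) + 1L, , drop = FALSE]
  # codes is (bpv * j) x 4, variant-major; keep first n slots per variant
  g <- matrix(t(codes), nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  genotype_panel(g, vtab, samples)
}

#' Write a genotype panel as PLINK 1 bed/bim/fam
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path stem.
#' @return Invisibly, the vector of paths written.
#' @export
write_plink <- function(panel, prefix) {
  validate_panel(panel)
  n <- panel$n
  j <- panel$j
  g <- panel$genotypes
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, n, j)
  code[!is.na(g) & g == 2L] <- 0L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 0L] <- 3L
  bpv <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bpv, j) # trailing bits zero
  padded[seq_len(n), ] <- code
  shifted <- padded * c(1L, 4L, 16L, 64L) # recycle over the 4-slot stride
  bytes <- colSums(matrix(shifted, nrow = 4L))
  stopifnot(length(bytes) == bpv * j)
  bed <- paste0(prefix, ".bed")
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(c(PLINK_MAGIC, PLINK_SNP_MAJOR, as.raw(bytes)), con)
  v <- panel$variants
  utils::write.table(
    data.frame(v$chr, v$id, v$cM, v$bp, v$allele1, v$allele2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    data.frame(panel$samples, panel$samples, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Standardize a genotype panel
#'
#' Missing genotypes are mean-imputed per column (so the effective sample
#' size is constant across variants), monomorphic columns and columns below
#' the minor allele frequency threshold are dropped, and each remaining
#' column is centered and scaled by its sample standard deviation using the
#' divide-by-N convention, so that every retained column has exactly unit
#' second moment.
#'
#' @param panel a [genotype_panel()].
#' @param min_maf minimum minor allele frequency, in `[0, 0.5)`. Variants
#'   below the threshold are dropped. Default 0.01.
#' @return An object of class `standardized_panel` with elements `matrix`
#'   (N x J' real matrix), `maf` (per kept variant, computed from
#'   non-missing calls), `variants`, `samples`, `kept` (column indices into
#'   the source panel), `n`, `j`.
#' @export
standardize <- function(panel, min_maf = 0.01) {
  validate_panel(panel)
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must be in [0, 0.5)")
  g <- panel$genotypes
  storage.mode(g) <- "double"
  p <- colMeans(g, na.rm = TRUE) / 2 # counted-allele frequency
  maf <- pmin(p, 1 - p)
  nmiss <- colSums(is.na(g))
  if (any(nmiss > 0L)) {
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- (2 * p)[idx[, 2L]]
  }
  mu <- colMeans(g)
  gc <- sweep(g, 2L, mu, "-")
  v <- colMeans(gc * gc) # 1/N variance
  keep <- which(v > 0 & maf >= min_maf)
  if (length(keep) == 0L) {
    stop("no variants retained after MAF/monomorphism filtering")
  }
  x <- sweep(gc[, keep, drop = FALSE], 2L, sqrt(v[keep]), "/")
  structure(
    list(
      matrix = x,
      mu = mu[keep],
      sd = sqrt(v[keep]),
      maf = maf[keep],
      variants = panel$variants[keep, , drop = FALSE],
      samples = panel$samples,
      kept = keep,
      n = panel$n,
      j = length(keep)
    ),
    class = "standardized_panel"
  )
}

#' @export
print.standardized_panel <- function(x, ...) {
  cat(sprintf("standardized_panel: %d samples x %d variants\n", x$n, x$j))
  invisible(x)
}

#' Read GWAS summary statistics
#'
#' Expects a whitespace- or tab-delimited table with (case-insensitive)
#' header columns SNP, A1, A2, N and at least one of Z or CHISQ. When only Z
#' is present, the chi-square statistic is derived as Z^2. Rows with
#' non-finite or negative chi-square values are dropped with a message.
#'
#' @param path file path.
#' @return A data frame of class `sumstats` with columns `id`, `allele1`,
#'   `allele2`, `N`, `chisq` and (when available) `z`.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  names(tab) <- toupper(names(tab))
  need <- c("SNP", "A1", "A2", "N")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L || !any(c("Z", "CHISQ") %in% names(tab))) {
    stop(
      "sumstats file must have columns SNP, A1, A2, N and Z or CHISQ; ",
      "missing: ", paste(c(miss, if (!any(c("Z", "CHISQ") %in% names(tab)))
        "Z|CHISQ"), collapse = ", ")
    )
  }
  out <- data.frame(
    id = as.character(tab$SNP),
    allele1 = as.character(tab$A1),
    allele2 = as.character(tab$A2),
    N = as.numeric(tab$N),
    stringsAsFactors = FALSE
  )
  if ("Z" %in% names(tab)) out$z <- as.numeric(tab$Z)
  out$chisq <- if ("CHISQ" %in% names(tab)) {
    as.numeric(tab$CHISQ)
  } else {
    out$z^2
  }
  bad <- !is.finite(out$chisq) | out$chisq < 0
  if (any(bad)) {
    message("read_sumstats: dropped ", sum(bad),
            " row(s) with non-finite or negative chi-square")
    out <- out[!bad, , drop = FALSE]
  }
  if (any(out$N <= 1)) stop("sumstats sample sizes must exceed 1")
  rownames(out) <- NULL
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write GWAS summary statistics
#'
#' @param sumstats a data frame as returned by [read_sumstats()] or
#'   [gwas()].
#' @param path output path; tab-delimited with header SNP A1 A2 N Z CHISQ.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(
    SNP = sumstats$id, A1 = sumstats$allele1, A2 = sumstats$allele2,
    N = sumstats$N
  )
  if (!is.null(sumstats$z)) out$Z <- sprintf("%.10g", sumstats$z)
  out$CHISQ <- sprintf("%.10g", sumstats$chisq)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

new_score_table <- function(variants, ell, f, pair_count, windows, n_ref,
                            annotations = NULL) {
  f <- as.matrix(f)
  pair_count <- as.matrix(pair_count)
  colnames(f) <- paste0("F_W", windows)
  colnames(pair_count) <- paste0("F_W", windows)
  structure(
    list(
      variants = variants, # data frame: chr, id, bp, maf
      ell = ell,           # vector, or matrix with one column per annotation
      f = f,               # J x W matrix of cis-interaction scores
      pair_count = pair_count,
      windows = windows,   # labels of the f columns (window half-widths)
      M = colSums(pair_count),
      n_ref = n_ref,
      annotations = annotations
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "score_table: %d variants, reference N = %d, f windows: %s\n",
    nrow(x$variants), x$n_ref, paste(x$windows, collapse = ", ")
  ))
  invisible(x)
}

#' Write an LD / cis-interaction score table
#'
#' Emits a TSV with header columns CHR SNP BP MAF L2 and one `F_W{w}` column
#' per window. Reference size and per-window total pair counts are stored in
#' leading `#`-comment lines so that the header keeps the canonical layout.
#'
#' @param scores a `score_table` as produced by [compute_scores()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  v <- scores$variants
  ell <- if (is.matrix(scores$ell)) scores$ell[, 1L] else scores$ell
  tab <- data.frame(
    CHR = v$chr, SNP = v$id, BP = v$bp,
    MAF = sprintf("%.10g", v$maf), L2 = sprintf("%.10g", ell)
  )
  for (w in seq_along(scores$windows)) {
    tab[[paste0("F_W", scores$windows[w])]] <-
      sprintf("%.10g", scores$f[, w])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_ref=%d", scores$n_ref), con)
  writeLines(sprintf("# M_W%s=%d", scores$windows, scores$M), con)
  utils::write.table(tab, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read an LD / cis-interaction score table
#'
#' @param path a TSV written by [write_scores()] (columns CHR SNP BP MAF L2
#'   and `F_W{w}` per window; `#` comment lines carry the reference size and
#'   total pair counts). Per-variant pair counts are not stored in the file;
#'   on read they are set to `NA` and only the per-window totals `M` are
#'   recovered.
#' @return A `score_table`.
#' @export
read_scores <- function(path) {
  header <- readLines(path, n = 50L)
  comments <- grep("^#", header, value = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  need <- c("CHR", "SNP", "BP", "MAF", "L2")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("score file missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  fcols <- grep("^F_W", names(tab), value = TRUE)
  if (length(fcols) == 0L) stop("score file has no F_W{w} columns")
  if (anyDuplicated(tab$SNP)) stop("duplicated SNP ids in score file")
  windows <- sub("^F_W", "", fcols)
  variants <- data.frame(
    chr = as.character(tab$CHR), id = as.character(tab$SNP),
    bp = as.integer(tab$BP), maf = as.numeric(tab$MAF),
    stringsAsFactors = FALSE
  )
  f <- as.matrix(tab[, fcols, drop = FALSE])
  pc <- matrix(NA_integer_, nrow(tab), length(fcols))
  st <- new_score_table(
    variants, as.numeric(tab$L2), f, pc, windows,
    n_ref = .comment_value(comments, "n_ref", NA_integer_)
  )
  st$M <- vapply(
    windows,
    function(w) .comment_value(comments, paste0("M_W", w), NA_real_),
    numeric(1)
  )
  names(st$M) <- paste0("F_W", windows)
  st
}

.comment_value <- function(comments, key, default) {
  pat <- paste0("^#\\s*", key, "=")
  hit <- grep(pat, comments, value = TRUE)
  if (length(hit) == 0L) return(default)
  as.numeric(sub(pat, "", hit[1L]))
}
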