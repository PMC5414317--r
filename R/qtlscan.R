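# QTL mapping of variant-expression phenotypes in an F2 by marker regression:
# map reduction, single-locus scan with additive + dominance encodings,
# covariate (second-QTL) scans, and permutation-based genome-wide thresholds.

#' Reduce a genotype map by duplicate dropping and minimum spacing
#'
#' First pass drops markers whose genotype column is identical to an earlier
#' (leftmost-kept) marker; optional second pass greedily keeps markers at
#' least `min_distance` apart within each chromosome, where distance is the
#' marker index in the deduplicated map (map units are not assumed).
#' Idempotent.
#'
#' @param geno Character matrix individuals x markers, states `A`/`H`/`B`.
#' @param map Data.frame `chrom`, `pos`, one row per marker.
#' @param min_distance Optional integer index distance for the subsetting
#'   pass; `NULL` skips it.
#' @return A `marker_map`: list `geno`, `map` (with `kept` giving the
#'   original column indices).
#' @export
reduce_map <- function(geno, map, min_distance = NULL) {
  geno <- as.matrix(geno)
  if (!nrow(geno) || !ncol(geno)) stop("empty genotype matrix")
  stopifnot(nrow(map) == ncol(geno))
  cols <- apply(geno, 2L, paste, collapse = "")
  keep <- !duplicated(cols)
  idx <- which(keep)
  if (!is.null(min_distance) && min_distance > 1) {
    sel <- logical(length(idx))
    sub_map <- map[idx, , drop = FALSE]
    for (cc in unique(sub_map$chrom)) {
      ii <- which(sub_map$chrom == cc)
      last <- -Inf
      for (j in ii) {
        if (j - last >= min_distance) {
          sel[j] <- TRUE
          last <- j
        }
      }
    }
    idx <- idx[sel]
  }
  out_map <- map[idx, , drop = FALSE]
  out_map$kept <- idx
  structure(list(geno = geno[, idx, drop = FALSE], map = out_map),
            class = "marker_map")
}

# Additive {-1, 0, 1} and dominance {0, 1, 0} encodings of A/H/B states.
encode_genotypes <- function(geno) {
  add <- (geno == "B") * 1 - (geno == "A") * 1
  dom <- (geno == "H") * 1
  add[is.na(geno)] <- NA
  dom[is.na(geno)] <- NA
  list(add = add, dom = dom)
}

# Core scan engine. Y: n x q matrix of phenotypes (no NAs). X0: null-model
# design (n x p0, including intercept). For each marker, the alternative
# model adds the marker's additive + dominance columns. Missing genotypes
# drop the individual at that marker. Returns markers x q LOD matrix.
# LOD = (n_used / 2) * log10(RSS0 / RSS1); rank-deficient additions give 0.
scan_lod_engine <- function(Y, add, dom, X0) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  m <- ncol(add)
  lod <- matrix(0, m, ncol(Y))
  complete <- !is.na(add[, 1L])
  all_complete <- all(!is.na(add))
  q0 <- qr(X0)
  R0 <- qr.resid(q0, Y)
  rss0_full <- colSums(R0^2)
  for (j in seq_len(m)) {
    xj <- cbind(add[, j], dom[, j])
    use <- if (all_complete) TRUE else !is.na(add[, j])
    if (all_complete || all(use)) {
      nj <- n
      # residualize marker columns against the null design, then regress;
      # columns absorbed by the null design (collinear covariate) are
      # dropped on the scale of the ORIGINAL columns, not the residual
      xr <- qr.resid(q0, xj)
      keep_col <- colSums(xr^2) > 1e-12 * pmax(colSums(xj^2), 1e-300)
      if (!any(keep_col)) next
      qx <- qr(xr[, keep_col, drop = FALSE])
      if (qx$rank == 0L) next
      fit <- qr.fitted(qx, R0)
      rss1 <- rss0_full - colSums(fit^2)
      rss0 <- rss0_full
    } else {
      nj <- sum(use)
      if (nj <= ncol(X0) + 2L) next
      q0j <- qr(X0[use, , drop = FALSE])
      R0j <- qr.resid(q0j, Y[use, , drop = FALSE])
      rss0 <- colSums(R0j^2)
      xju <- xj[use, , drop = FALSE]
      xr <- qr.resid(q0j, xju)
      keep_col <- colSums(xr^2) > 1e-12 * pmax(colSums(xju^2), 1e-300)
      if (!any(keep_col)) next
      qx <- qr(xr[, keep_col, drop = FALSE])
      if (qx$rank == 0L) next
      fit <- qr.fitted(qx, R0j)
      rss1 <- rss0 - colSums(fit^2)
    }
    ok <- rss0 > 0 & rss1 > 0
    lod[j, ok] <- pmax(0, (nj / 2) * log10(rss0[ok] / rss1[ok]))
    # phenotype fully explained by the marker: cap via machine floor
    deg <- rss0 > 0 & rss1 <= 0
    lod[j, deg] <- (nj / 2) * log10(rss0[deg] / .Machine$double.eps)
  }
  lod
}

#' Single-locus QTL scan by marker regression
#'
#' At every marker, compares a 2-df genotype model (additive code
#' `{-1, 0, 1}` plus dominance code `{0, 1, 0}`) against the
#' intercept-only null: `LOD = (n/2) log10(RSS0 / RSS1)`. Marker regression
#' is used rather than interval mapping — simulated maps here are dense, so
#' pseudo-marker interpolation adds nothing. Individuals with a missing
#' genotype are dropped at that marker; a constant phenotype yields an
#' all-zero scan. LOD is invariant under affine transformation of the
#' phenotype.
#'
#' @param phenotype Numeric vector per individual (e.g. a variant's RNA
#'   proportion); individuals with `NA` phenotype are dropped globally.
#' @param mmap A `marker_map` from [reduce_map()] (or a list with `geno`,
#'   `map`).
#' @return A `scan_result` data.frame `chrom`, `pos`, `lod`, with
#'   attributes `model = "single"` and `n`.
#' @export
single_scan <- function(phenotype, mmap) {
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  geno <- mmap$geno[keep, , drop = FALSE]
  n <- length(y)
  if (n < 30L) warning("fewer than 30 individuals in scan")
  enc <- encode_genotypes(geno)
  lod <- if (stats::var(y) == 0) {
    matrix(0, ncol(geno), 1L)
  } else {
    scan_lod_engine(matrix(y, ncol = 1L), enc$add, enc$dom,
                    matrix(1, n, 1L))
  }
  structure(data.frame(chrom = mmap$map$chrom, pos = mmap$map$pos,
                       lod = as.numeric(lod), stringsAsFactors = FALSE),
            class = c("scan_result", "data.frame"),
            model = "single", n = n)
}

#' QTL scan with a second locus as covariate
#'
#' Compares genotype + covariate against covariate-only, absorbing the
#' effect of a known QTL so residual (including epistatic) signal elsewhere
#' becomes visible. The covariate marker is encoded `additive` (its
#' `{-1, 0, 1}` code) or `dominance` (additive plus `{0, 1, 0}` dominance
#' deviation). At a marker collinear with the covariate (including the
#' covariate itself) the LOD is 0.
#'
#' @inheritParams single_scan
#' @param covariate_marker Column index or marker name (`chrom:pos`) of the
#'   covariate locus in `mmap`.
#' @param encoding `"additive"` or `"dominance"`.
#' @return A `scan_result` with `model = "additive_covariate"` or
#'   `"dominance_covariate"`.
#' @export
covariate_scan <- function(phenotype, mmap, covariate_marker,
                           encoding = c("additive", "dominance")) {
  encoding <- match.arg(encoding)
  if (is.character(covariate_marker)) {
    key <- paste(mmap$map$chrom, mmap$map$pos, sep = ":")
    covariate_marker <- match(covariate_marker, key)
  }
  stopifnot(!is.na(covariate_marker), covariate_marker >= 1,
            covariate_marker <= ncol(mmap$geno))
  keep <- !is.na(phenotype) & !is.na(mmap$geno[, covariate_marker])
  y <- phenotype[keep]
  geno <- mmap$geno[keep, , drop = FALSE]
  enc <- encode_genotypes(geno)
  cov_cols <- if (encoding == "additive") {
    cbind(enc$add[, covariate_marker])
  } else {
    cbind(enc$add[, covariate_marker], enc$dom[, covariate_marker])
  }
  X0 <- cbind(1, cov_cols)
  lod <- if (stats::var(y) == 0) matrix(0, ncol(geno), 1L) else
    scan_lod_engine(matrix(y, ncol = 1L), enc$add, enc$dom, X0)
  structure(data.frame(chrom = mmap$map$chrom, pos = mmap$map$pos,
                       lod = as.numeric(lod), stringsAsFactors = FALSE),
            class = c("scan_result", "data.frame"),
            model = paste0(encoding, "_covariate"), n = length(y),
            covariate = covariate_marker)
}

#' Genome-wide LOD thresholds by phenotype permutation
#'
#' Permutes the phenotype over individuals, records the genome-wide maximum
#' LOD of each permuted scan, and returns empirical `1 - alpha` quantiles of
#' that maximum distribution.
#'
#' @inheritParams single_scan
#' @param n_perm Number of permutations (>= 100). Default 1000, matching the
#'   conventional choice.
#' @param alphas Significance levels. Default `c(0.05, 0.10)`.
#' @param seed Seed for the permutations (recorded in the result).
#' @param covariate_marker,encoding Optional covariate model (as in
#'   [covariate_scan()]); permutation maxima are then computed under that
#'   model.
#' @return Named numeric thresholds (`"5%"`, `"10%"`, ...), attributes
#'   `max_lods` and `seed`.
#' @export
permutation_threshold <- function(phenotype, mmap, n_perm = 1000L,
                                  alphas = c(0.05, 0.10), seed = 1L,
                                  covariate_marker = NULL,
                                  encoding = "additive") {
  stopifnot(n_perm >= 100L)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  geno <- mmap$geno[keep, , drop = FALSE]
  n <- length(y)
  enc <- encode_genotypes(geno)
  X0 <- matrix(1, n, 1L)
  if (!is.null(covariate_marker)) {
    cov_cols <- if (encoding == "additive") {
      cbind(enc$add[, covariate_marker])
    } else {
      cbind(enc$add[, covariate_marker], enc$dom[, covariate_marker])
    }
    X0 <- cbind(X0, cov_cols)
  }
  with_seed(seed, {
    if (stats::var(y) == 0) {
      maxs <- rep(0, n_perm)
    } else {
      Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
      lods <- scan_lod_engine(Y, enc$add, enc$dom, X0)
      maxs <- apply(lods, 2L, max)
    }
    thr <- stats::quantile(maxs, 1 - alphas)
    names(thr) <- paste0(format(100 * alphas, trim = TRUE), "%")
    structure(thr, max_lods = maxs, seed = seed)
  })
}
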