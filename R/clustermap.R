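# Assignment of DNA-validated 45S variants to rDNA-2 or rDNA-4 by linkage in
# mapping populations, with a genotype-consistency check and parental-specific
# marker derivation for biparental crosses.

#' Founder-sharing filter for MAGIC variants
#'
#' Only variants shared by few founders can be mapped unambiguously in a
#' multiparent population; variants carried by more than
#' `max_sharing` founders (7 of 19 by default) are excluded from linkage
#' assignment.
#'
#' @param presence Logical vector: DNA-pass status of the variant per
#'   founder.
#' @param max_sharing Maximum carrier count. Default 7.
#' @return `TRUE` if the variant is retained.
#' @export
founder_sharing_filter <- function(presence, max_sharing = 7L) {
  stopifnot(is.logical(presence))
  sum(presence) <= max_sharing
}

# Fast one-way ANOVA -log10(p) of y on each column of a label matrix.
# Y may hold several phenotypes (columns); returns markers x phenotypes.
anova_neglog10p <- function(Y, labels) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(nrow(labels) == n)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  out <- matrix(0, ncol(labels), ncol(Y))
  for (j in seq_len(ncol(labels))) {
    f <- factor(labels[, j])
    g <- nlevels(f)
    if (g < 2L) next
    cnt <- tabulate(f)
    gs <- rowsum(Y, f, reorder = TRUE)
    bss <- colSums(gs^2 / cnt) - colSums(Y)^2 / n
    wss <- pmax(tss - bss, 0)
    df1 <- g - 1L
    df2 <- n - g
    if (df2 <= 0L) next
    Fstat <- (bss / df1) / (wss / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    out[j, ] <- ifelse(is.finite(Fstat) & tss > 0,
                       -log10(pmax(p, .Machine$double.xmin)), 0)
  }
  out
}

# Label markers at the "top" (distal, first fraction of the marker map) of
# chromosomes 2 and 4.
marker_regions <- function(map, top_frac = 0.05) {
  region <- rep("other", nrow(map))
  for (cc in c("chr2", "chr4")) {
    idx <- which(map$chrom == cc)
    if (!length(idx)) next
    ntop <- max(1L, floor(top_frac * length(idx)))
    region[idx[seq_len(ntop)]] <- if (cc == "chr2") "chr2_top" else "chr4_top"
  }
  region
}

#' Linkage scan of variant abundance on a marker map
#'
#' At each marker, a one-way ANOVA of the per-line variant abundance (DNA
#' copy fraction) on the marker's founder label (or any genotype label)
#' gives an association statistic `-log10 p`. A constant abundance yields a
#' flat scan (all statistics 0).
#'
#' @param abundance Numeric vector: variant copy fraction per line.
#' @param labels Matrix of genotype/founder labels, lines x markers.
#' @param map Data.frame `chrom`, `pos` describing the markers.
#' @param top_frac Fraction of each chromosome's markers counted as its
#'   distal "top" region (where the rDNA clusters sit). Default 0.05.
#' @return A `linkage_scan` data.frame (`chrom`, `pos`, `region`, `stat`)
#'   with attributes `peak` (row index of the maximum) and `peak_region`.
#'   Tied maxima are reported via attribute `peak_tied`.
#' @export
linkage_scan <- function(abundance, labels, map, top_frac = 0.05) {
  stopifnot(length(abundance) == nrow(labels), nrow(map) == ncol(labels))
  stat <- as.numeric(anova_neglog10p(matrix(abundance, ncol = 1), labels))
  region <- marker_regions(map, top_frac)
  res <- data.frame(chrom = map$chrom, pos = map$pos, region = region,
                    stat = stat, stringsAsFactors = FALSE)
  # with sparse abundance (non-carriers exactly 0) the maximum is typically a
  # plateau of bit-identical statistics spanning the non-recombined haplotype
  # block around the causal locus; the peak "region" is therefore the set of
  # regions attaining the maximum. Only a plateau touching both rDNA tops
  # (or neither) leaves the location ambiguous.
  at_max <- which(stat == max(stat))
  regs <- unique(region[at_max])
  tops <- intersect(regs, c("chr2_top", "chr4_top"))
  tied <- length(tops) > 1L
  peak_region <- if (tied || !length(tops)) "other" else tops
  peak <- if (length(tops) == 1L) {
    at_max[region[at_max] == peak_region][1L]
  } else at_max[1L]
  structure(res, class = c("linkage_scan", "data.frame"),
            peak = peak, peak_region = peak_region, peak_tied = tied)
}

#' Genome-wide significance threshold for a linkage scan by permutation
#'
#' @inheritParams linkage_scan
#' @param n_perm Number of permutations. Default 200 (a desk-scale stand-in
#'   for the conventional 1000; configurable).
#' @param alpha Significance level. Default 0.05.
#' @param seed Optional seed.
#' @return The empirical `1 - alpha` quantile of the genome-wide maximum
#'   statistic, with attribute `max_stats`.
#' @export
linkage_permutation_threshold <- function(abundance, labels, n_perm = 200L,
                                          alpha = 0.05, seed = NULL) {
  with_seed(seed, {
    n <- length(abundance)
    Y <- vapply(seq_len(n_perm), function(i) abundance[sample.int(n)],
                numeric(n))
    maxs <- apply(anova_neglog10p(Y, labels), 2L, max)
    structure(unname(stats::quantile(maxs, 1 - alpha)), max_stats = maxs)
  })
}

#' Consistency between variant presence and predicted founder-of-origin
#'
#' Compares each line's observed carrier status for a variant with the
#' carrier status predicted from the line's founder at the candidate rDNA
#' locus (a line is predicted to carry the variant if its founder there is a
#' known carrier).
#'
#' @param presence Logical vector: variant detected in each line.
#' @param predicted Logical vector: carrier status predicted from the
#'   candidate cluster's founder-of-origin per line.
#' @return List with `consistency` (fraction of matching lines, `NA` when no
#'   lines) and `discordant` (indices of mismatching lines).
#' @export
check_consistency <- function(presence, predicted) {
  stopifnot(is.logical(presence), is.logical(predicted),
            length(presence) == length(predicted))
  if (!length(presence)) {
    return(list(consistency = NA_real_, discordant = integer()))
  }
  ok <- presence == predicted
  list(consistency = mean(ok), discordant = which(!ok))
}

#' Flag lines (or founders) with recurrently discordant variants
#'
#' Lines whose rDNA genotype disagrees with two or more variants are
#' genotype-correction candidates; founders accumulating `>= 5` discordant
#' variants across the panel are dropped from assignment with a report
#' (generalizing the exclusion of a founder with irreconcilable
#' discrepancies).
#'
#' @param discordant_lists List (one element per variant) of discordant line
#'   indices or ids, as returned by [check_consistency()].
#' @param line_threshold Minimum discordant variants to flag a line.
#' @return Table of flagged ids with their discordance counts.
#' @export
flag_discordant <- function(discordant_lists, line_threshold = 2L) {
  counts <- table(unlist(discordant_lists))
  counts[counts >= line_threshold]
}

#' Assign a variant to an rDNA cluster from scan + consistency evidence
#'
#' A variant is called `rDNA-2` when its scan peak falls in the chr2-top
#' region, the peak is genome-wide significant, the chr4-top region shows no
#' significant marker, and the genotype-consistency fraction reaches
#' `min_consistency`; symmetrically for `rDNA-4`. Anything else (peaks at
#' both tops, a peak elsewhere, tied peaks, undefined consistency) is
#' `ambiguous` — errors must never cross to the wrong cluster.
#'
#' @param scan A `linkage_scan`.
#' @param consistency Consistency fraction from [check_consistency()] for
#'   the peak-region hypothesis.
#' @param threshold Genome-wide significance threshold from
#'   [linkage_permutation_threshold()].
#' @param min_consistency Minimum consistency. Default 0.95.
#' @return List `call` (`"rDNA-2"`, `"rDNA-4"` or `"ambiguous"`),
#'   `peak_region`, `peak_stat`, `consistency`.
#' @export
assign_cluster <- function(scan, consistency, threshold,
                           min_consistency = 0.95) {
  peak_region <- attr(scan, "peak_region")
  peak_stat <- scan$stat[attr(scan, "peak")]
  sig2 <- any(scan$stat[scan$region == "chr2_top"] > threshold)
  sig4 <- any(scan$stat[scan$region == "chr4_top"] > threshold)
  call <- "ambiguous"
  if (!isTRUE(attr(scan, "peak_tied")) && peak_stat > threshold &&
      !is.na(consistency) && consistency >= min_consistency) {
    if (peak_region == "chr2_top" && !sig4) call <- "rDNA-2"
    if (peak_region == "chr4_top" && !sig2) call <- "rDNA-4"
  }
  list(call = call, peak_region = peak_region, peak_stat = peak_stat,
       consistency = consistency)
}

#' Assign MAGIC variants to rDNA clusters end to end
#'
#' Convenience pipeline over a panel of mosaic lines: for each variant,
#' applies the founder-sharing filter, runs the linkage scan and permutation
#' threshold, checks founder-of-origin consistency under the peak-region
#' hypothesis, and calls [assign_cluster()].
#'
#' @param abundance Matrix lines x variants of DNA copy fractions (0 when
#'   the variant was not called in a line).
#' @param presence Logical matrix lines x variants of DNA-pass status.
#' @param founder_presence Logical matrix founders x variants: which
#'   founders carry each variant (from calling the founder panel).
#' @param labels2,labels4 Founder label per line at the rDNA-2 / rDNA-4
#'   locus (from the mosaic genotypes).
#' @param labels Matrix lines x markers of founder labels for the scan.
#' @param map Marker map (`chrom`, `pos`).
#' @param cfg A [filter_config()] (for `max_founder_sharing`).
#' @param n_perm,alpha,min_consistency Scan significance settings.
#' @param seed Optional seed for the permutation thresholds.
#' @return Data.frame, one row per variant: `name`, `retained`, `call`,
#'   `peak_region`, `peak_stat`, `threshold`, `consistency`.
#' @export
assign_clusters_magic <- function(abundance, presence, founder_presence,
                                  labels2, labels4, labels, map,
                                  cfg = filter_config(), n_perm = 200L,
                                  alpha = 0.05, min_consistency = 0.95,
                                  seed = NULL) {
  stopifnot(ncol(abundance) == ncol(presence),
            ncol(abundance) == ncol(founder_presence))
  vn <- colnames(abundance)
  with_seed(seed, {
    res <- lapply(seq_len(ncol(abundance)), function(v) {
      carriers <- rownames(founder_presence)[founder_presence[, v]]
      retained <- founder_sharing_filter(founder_presence[, v],
                                         cfg$max_founder_sharing)
      if (!retained) {
        return(data.frame(name = vn[v], retained = FALSE, call = "excluded",
                          peak_region = NA, peak_stat = NA, threshold = NA,
                          consistency = NA, stringsAsFactors = FALSE))
      }
      scan <- linkage_scan(abundance[, v], labels, map)
      thr <- linkage_permutation_threshold(abundance[, v], labels,
                                           n_perm = n_perm, alpha = alpha)
      predicted <- switch(attr(scan, "peak_region"),
                          chr2_top = labels2 %in% carriers,
                          chr4_top = labels4 %in% carriers,
                          rep(NA, nrow(labels)))
      cons <- if (anyNA(predicted)) NA_real_ else
        check_consistency(presence[, v], predicted)$consistency
      a <- assign_cluster(scan, cons, thr, min_consistency)
      data.frame(name = vn[v], retained = TRUE, call = a$call,
                 peak_region = a$peak_region, peak_stat = a$peak_stat,
                 threshold = thr, consistency = a$consistency,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Parental-specific 45S markers for a biparental cross
#'
#' A variant is a marker for parent A when it is supported by at least
#' `cfg$parental_min_frac` (10%) of the reads spanning its position in A and
#' effectively absent in B — below the variant-calling floor
#' (`cfg$min_frac`), since sequencing error makes literal zero unattainable.
#' Symmetrically for parent B.
#'
#' @param callsA,callsB `variant_calls` for the two parents (single sample
#'   each; failing calls should be retained so absence can be checked
#'   against observed fractions).
#' @param cfg A [filter_config()].
#' @return Data.frame `name`, `parent` (`"A"`/`"B"`), `frac_in`,
#'   `frac_other`.
#' @export
parental_specific_markers <- function(callsA, callsB, cfg = filter_config()) {
  frac_of <- function(calls, names) {
    f <- calls$copy_fraction[match(names, calls$name)]
    ifelse(is.na(f), 0, f)
  }
  one_side <- function(from, other, label) {
    pass <- from[from$status == "pass" &
                   from$copy_fraction >= cfg$parental_min_frac, , drop = FALSE]
    if (!nrow(pass)) return(NULL)
    fo <- frac_of(other, pass$name)
    keep <- fo < cfg$min_frac
    if (!any(keep)) return(NULL)
    data.frame(name = pass$name[keep], parent = label,
               frac_in = pass$copy_fraction[keep], frac_other = fo[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(as.data.frame(callsA), as.data.frame(callsB), "A"),
               one_side(as.data.frame(callsB), as.data.frame(callsA), "B"))
  if (is.null(out)) {
    out <- data.frame(name = character(), parent = character(),
                      frac_in = numeric(), frac_other = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Assign biparental markers to rDNA clusters by perfect co-segregation
#'
#' For each parental-specific marker, carrier status across lines is
#' compared with the predicted carrier status under the rDNA-2 and rDNA-4
#' hypotheses (a line carries a parent-A marker at a locus iff it inherited
#' at least one A haplotype there). The marker is assigned to the locus that
#' co-segregates perfectly across all informative lines; perfect
#' co-segregation with both, neither, or fewer than `min_lines` informative
#' lines gives `ambiguous`.
#'
#' @param presence Logical matrix lines x markers: marker detected per line.
#' @param geno2,geno4 Character vectors (`"AA"`/`"AB"`/`"BB"`) of line
#'   genotypes at the rDNA-2 and rDNA-4 loci (from flanking markers).
#' @param parent Character vector (`"A"`/`"B"`) per marker.
#' @param min_lines Minimum informative lines. Default 8 (with a warning
#'   below it).
#' @return Data.frame `name`, `call` (`rDNA-2`/`rDNA-4`/`ambiguous`),
#'   `match2`, `match4`, `n_lines`.
#' @export
assign_biparental <- function(presence, geno2, geno4, parent,
                              min_lines = 8L) {
  stopifnot(nrow(presence) == length(geno2), length(geno2) == length(geno4),
            ncol(presence) == length(parent))
  carries <- function(geno, p) {
    if (p == "A") geno %in% c("AA", "AB") else geno %in% c("AB", "BB")
  }
  res <- lapply(seq_len(ncol(presence)), function(j) {
    obs <- presence[, j]
    ok <- !is.na(obs) & !is.na(geno2) & !is.na(geno4)
    n <- sum(ok)
    m2 <- all(obs[ok] == carries(geno2[ok], parent[j]))
    m4 <- all(obs[ok] == carries(geno4[ok], parent[j]))
    call <- "ambiguous"
    if (n < min_lines) {
      warning("marker ", colnames(presence)[j], ": only ", n,
              " informative lines; ambiguous")
    } else if (m2 && !m4) call <- "rDNA-2"
    else if (m4 && !m2) call <- "rDNA-4"
    data.frame(name = colnames(presence)[j], call = call,
               match2 = m2, match4 = m4, n_lines = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
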