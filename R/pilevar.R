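# Within-individual variant calling for the multicopy 45S rRNA gene.
# Works from quality-filtered, strand-split per-site allele counts; upstream
# alignment/recalibration is out of scope.

#' Strand-bias score for a variable site
#'
#' Computes `|b/(a+b) - d/(c+d)| / ((b+d)/(a+b+c+d))` where `a`, `c` are the
#' forward/reverse counts of the major allele and `b`, `d` the forward/
#' reverse counts of the minor allele. Degenerate cases (not covered by the
#' published formula) are defined as follows: with no minor reads
#' (`b + d == 0`) the score is 0 (no evidence of bias); if one strand has no
#' reads at all, that strand's minor-fraction term is taken as 0 and a
#' warning is emitted; all-zero counts are an error.
#'
#' @param a,c Forward/reverse counts of the major allele.
#' @param b,d Forward/reverse counts of the minor allele.
#' @return Numeric score(s) >= 0 (vectorized).
#' @examples
#' strand_bias_score(40, 10, 40, 10)  # 0: strands symmetric
#' strand_bias_score(50, 10, 50, 0)   # 1.8333...
#' @export
strand_bias_score <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative strand counts")
  tot <- a + b + c + d
  if (any(tot == 0)) stop("all-zero strand counts at some site(s)")
  if (any((a + c) < (b + d))) {
    stop("major/minor mislabelled: requires (a + c) >= (b + d)")
  }
  fwd <- a + b
  rev_ <- c + d
  if (any((fwd == 0 | rev_ == 0) & (b + d) > 0)) {
    warning("site(s) with zero depth on one strand; treating that strand's ",
            "minor fraction as 0")
  }
  t1 <- ifelse(fwd > 0, b / fwd, 0)
  t2 <- ifelse(rev_ > 0, d / rev_, 0)
  minor <- b + d
  ifelse(minor == 0, 0, abs(t1 - t2) / (minor / tot))
}

# Reference allele lookup for a (sample-subset) site table. Priority:
# explicit argument > 'ref' column.
site_reference <- function(tbl, ref = NULL) {
  if (!is.null(ref)) {
    if (is.data.frame(ref)) ref <- stats::setNames(ref$ref, ref$position)
    return(ref)
  }
  if ("ref" %in% names(tbl)) {
    u <- unique(tbl[, c("position", "ref")])
    if (anyDuplicated(u$position)) {
      stop("conflicting 'ref' entries for some positions")
    }
    return(stats::setNames(u$ref, u$position))
  }
  stop("no reference alleles: supply 'ref' or include a 'ref' column")
}

#' Call within-individual 45S variants from DNA strand-split counts
#'
#' For each sample and site, every non-reference allele with at least one
#' read is evaluated. The copy fraction is the allele's read count divided
#' by the total reads spanning the site. A call passes when
#' (i) the site lies within the transcribed span, (ii) site depth reaches
#' `cfg$min_dna_depth`, (iii) the copy fraction reaches `cfg$min_frac`
#' (5% of spanning reads by default), and (iv) the strand-bias score of the
#' allele against the site's major allele does not exceed `cfg$sb_max`.
#' Failing calls are retained with status `out_of_span`, `low_depth`,
#' `below_frequency` or `strand_biased` (checked in that order).
#'
#' @param tbl A DNA `site_count_table` (see [read_site_counts()]); may hold
#'   several samples.
#' @param cfg A [filter_config()].
#' @param ref Optional reference alleles: named character vector keyed by
#'   position, or data.frame with `position` and `ref`. Defaults to the
#'   table's `ref` column.
#' @return A `variant_calls` data.frame: `sample`, `name`, `position`,
#'   `ref`, `alt`, `copy_fraction`, `sb_score`, `depth`, `status`, with a
#'   `filter_audit` attribute counting sites in and failures per filter.
#' @export
call_variants <- function(tbl, cfg = filter_config(), ref = NULL) {
  tbl <- validate_site_counts(as.data.frame(tbl))
  if (nrow(tbl) && !all(tbl$source == "DNA")) {
    stop("call_variants expects DNA counts; use quantify_rna() for RNA")
  }
  empty <- data.frame(sample = character(), name = character(),
                      position = integer(), ref = character(),
                      alt = character(), copy_fraction = numeric(),
                      sb_score = numeric(), depth = integer(),
                      status = character(), stringsAsFactors = FALSE)
  if (!nrow(tbl)) {
    return(structure(empty, class = c("variant_calls", "data.frame"),
                     filter_audit = integer()))
  }
  refs <- site_reference(tbl, ref)
  tbl <- tbl[order(tbl$sample, tbl$position, tbl$allele), , drop = FALSE]
  out <- vector("list", 256L)
  k <- 0L
  for (s in unique(tbl$sample)) {
    st <- tbl[tbl$sample == s, , drop = FALSE]
    for (p in unique(st$position)) {
      site <- st[st$position == p, , drop = FALSE]
      pref <- refs[as.character(p)]
      if (is.na(pref)) stop("no reference allele for position ", p)
      counts <- site$fwd + site$rev
      depth <- sum(counts)
      if (depth == 0) next
      major_i <- which.max(counts)
      alts <- which(site$allele != pref & counts > 0)
      for (i in alts) {
        frac <- counts[i] / depth
        # strand counts of the site's major allele vs this allele; when the
        # evaluated allele IS the most frequent one, score it against the
        # runner-up so (a + c) >= (b + d) holds.
        jmaj <- if (i == major_i) {
          which.max(replace(counts, i, -1L))
        } else major_i
        minor_first <- counts[i] <= counts[jmaj]
        sb <- if (minor_first) {
          strand_bias_score(site$fwd[jmaj], site$fwd[i],
                            site$rev[jmaj], site$rev[i])
        } else {
          strand_bias_score(site$fwd[i], site$fwd[jmaj],
                            site$rev[i], site$rev[jmaj])
        }
        freq_ok <- if (cfg$frac_strict) frac > cfg$min_frac else
          frac >= cfg$min_frac
        status <- if (p < cfg$span[1] || p > cfg$span[2]) "out_of_span"
          else if (depth < cfg$min_dna_depth) "low_depth"
          else if (!freq_ok) "below_frequency"
          else if (sb > cfg$sb_max) "strand_biased"
          else "pass"
        k <- k + 1L
        if (k > length(out)) out <- c(out, vector("list", length(out)))
        out[[k]] <- data.frame(
          sample = s, name = variant_name(p, pref, site$allele[i]),
          position = as.integer(p), ref = unname(pref),
          alt = site$allele[i], copy_fraction = frac, sb_score = sb,
          depth = depth, status = status, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (k) do.call(rbind, out[seq_len(k)]) else empty
  audit <- c(sites_in = length(unique(paste(tbl$sample, tbl$position))),
             table(factor(calls$status,
                          levels = c("pass", "below_frequency",
                                     "strand_biased", "low_depth",
                                     "out_of_span"))))
  structure(calls, class = c("variant_calls", "data.frame"),
            filter_audit = audit)
}

#' Track the reference allele where an alternative has become the majority
#'
#' At sites where an alternative variant is more frequent (strictly) than
#' the reference allele, the reference allele itself is informative and is
#' emitted as an additional call named `X<pos>.<major alt>.<ref>`, subject
#' to the same filters as ordinary calls.
#'
#' @param calls A `variant_calls` data.frame from [call_variants()].
#' @param tbl The DNA `site_count_table` the calls came from.
#' @param cfg The [filter_config()] used.
#' @param ref Optional reference alleles (as in [call_variants()]).
#' @return `calls` augmented with the extra reference-tracking calls.
#' @export
flip_reference_minority <- function(calls, tbl, cfg = filter_config(),
                                    ref = NULL) {
  tbl <- validate_site_counts(as.data.frame(tbl))
  refs <- site_reference(tbl, ref)
  extra <- vector("list", 32L)
  k <- 0L
  for (s in unique(tbl$sample)) {
    st <- tbl[tbl$sample == s, , drop = FALSE]
    for (p in unique(st$position)) {
      site <- st[st$position == p, , drop = FALSE]
      pref <- refs[as.character(p)]
      counts <- site$fwd + site$rev
      depth <- sum(counts)
      if (depth == 0) next
      iref <- which(site$allele == pref)
      ref_count <- if (length(iref)) counts[iref] else 0L
      ialt <- which(site$allele != pref)
      if (!length(ialt)) next
      imax <- ialt[which.max(counts[ialt])]
      if (counts[imax] <= ref_count) next  # strict "more frequent"
      frac <- ref_count / depth
      sb <- if (length(iref)) {
        strand_bias_score(site$fwd[imax], site$fwd[iref],
                          site$rev[imax], site$rev[iref])
      } else 0
      freq_ok <- if (cfg$frac_strict) frac > cfg$min_frac else
        frac >= cfg$min_frac
      status <- if (p < cfg$span[1] || p > cfg$span[2]) "out_of_span"
        else if (depth < cfg$min_dna_depth) "low_depth"
        else if (!freq_ok) "below_frequency"
        else if (sb > cfg$sb_max) "strand_biased"
        else "pass"
      k <- k + 1L
      if (k > length(extra)) extra <- c(extra, vector("list", length(extra)))
      extra[[k]] <- data.frame(
        sample = s, name = variant_name(p, site$allele[imax], pref),
        position = as.integer(p), ref = site$allele[imax],
        alt = unname(pref), copy_fraction = frac, sb_score = sb,
        depth = depth, status = status, stringsAsFactors = FALSE)
    }
  }
  if (!k) return(calls)
  aug <- rbind(as.data.frame(calls), do.call(rbind, extra[seq_len(k)]))
  structure(aug, class = c("variant_calls", "data.frame"),
            filter_audit = attr(calls, "filter_audit"))
}

#' Quantify DNA-validated variants at the RNA level
#'
#' RNA proportions are only reported for variants validated at the DNA level
#' (status `pass`); sites covered by fewer than `cfg$min_rna_reads` RNA
#' reads (25 by default) are flagged not quantifiable instead of being
#' zero-filled. No strand-bias filter is applied at the RNA level (library
#' protocols differ in strandedness).
#'
#' @param tbl An RNA `site_count_table`.
#' @param dna_calls `variant_calls` from [call_variants()] (possibly
#'   augmented by [flip_reference_minority()]).
#' @param cfg A [filter_config()].
#' @return Data.frame `sample`, `name`, `position`, `alt`, `rna_depth`,
#'   `rna_reads`, `proportion` (NA when not quantifiable), `quantifiable`.
#' @export
quantify_rna <- function(tbl, dna_calls, cfg = filter_config()) {
  tbl <- validate_site_counts(as.data.frame(tbl))
  if (nrow(tbl) && !all(tbl$source == "RNA")) {
    stop("quantify_rna expects RNA counts")
  }
  pass <- as.data.frame(dna_calls)
  dropped <- pass[pass$status != "pass", , drop = FALSE]
  if (nrow(dropped)) {
    message(nrow(dropped),
            " DNA-failed variant record(s) excluded from RNA report")
  }
  pass <- pass[pass$status == "pass", , drop = FALSE]
  if (!nrow(pass)) {
    return(data.frame(sample = character(), name = character(),
                      position = integer(), alt = character(),
                      rna_depth = integer(), rna_reads = integer(),
                      proportion = numeric(), quantifiable = logical(),
                      stringsAsFactors = FALSE))
  }
  depth_by <- stats::aggregate(cbind(depth = fwd + rev) ~ sample + position,
                               data = tbl, FUN = sum)
  res <- pass[, c("sample", "name", "position", "alt")]
  key_tbl <- paste(tbl$sample, tbl$position, tbl$allele, sep = "\r")
  key_res <- paste(res$sample, res$position, res$alt, sep = "\r")
  idx <- match(key_res, key_tbl)
  res$rna_reads <- ifelse(is.na(idx), 0L, tbl$fwd[idx] + tbl$rev[idx])
  dkey_tbl <- paste(depth_by$sample, depth_by$position, sep = "\r")
  dkey_res <- paste(res$sample, res$position, sep = "\r")
  didx <- match(dkey_res, dkey_tbl)
  res$rna_depth <- ifelse(is.na(didx), 0L, depth_by$depth[didx])
  res$quantifiable <- res$rna_depth >= cfg$min_rna_reads
  res$proportion <- ifelse(res$quantifiable, res$rna_reads / res$rna_depth,
                           NA_real_)
  res[, c("sample", "name", "position", "alt", "rna_depth", "rna_reads",
          "proportion", "quantifiable")]
}
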