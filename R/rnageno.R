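# Genotyping F2 individuals from RNA-seq derived per-SNP parental allele
# counts: per-SNP calls, cross-sample bias filter, 50-SNP window
# classification, segmentization with automated breakpoint refinement, and
# genome-wide imputation.

#' Call a SNP genotype from parental read counts
#'
#' A position is homozygous for a parent when strictly more than
#' `hom_frac` (90%) of the reads crossing it come from that parent;
#' otherwise heterozygous. Zero-depth positions are `nocall`.
#'
#' @param nA,nB Reads attributed to parent A / parent B (vectorized).
#' @param hom_frac Homozygosity fraction; the comparison is strict
#'   (`> hom_frac`). Default 0.90.
#' @return Character vector of `homA`, `homB`, `het`, `nocall`.
#' @examples
#' call_snp(19, 1)  # homA: 0.95 > 0.9
#' call_snp(9, 1)   # het:  0.90 is not > 0.9
#' @export
call_snp <- function(nA, nB, hom_frac = 0.90) {
  stopifnot(length(nA) == length(nB), all(nA >= 0), all(nB >= 0))
  depth <- nA + nB
  fA <- ifelse(depth > 0, nA / depth, NA_real_)
  out <- rep("het", length(nA))
  out[depth == 0] <- "nocall"
  out[!is.na(fA) & fA > hom_frac] <- "homA"
  out[!is.na(fA) & (1 - fA) > hom_frac] <- "homB"
  out
}

#' Remove SNPs with biased homozygous-call rates across individuals
#'
#' SNPs called homozygous for one parent at a rate exceeding `fold` times
#' that of the other parent across all samples are removed (such sites can
#' reflect alignment artifacts or allele-specific expression, confounders
#' for RNA-seq genotyping). A zero count in one class with a nonzero count
#' in the other counts as exceeding any fold.
#'
#' @param calls Character matrix SNPs x individuals of genotype calls (from
#'   [call_snp()]).
#' @param fold Fold-change threshold. Default 10.
#' @return Logical vector: `TRUE` for retained SNPs.
#' @export
filter_biased_snps <- function(calls, fold = 10) {
  calls <- as.matrix(calls)
  if (ncol(calls) < 2L) stop("need calls from at least 2 individuals")
  nA <- rowSums(calls == "homA")
  nB <- rowSums(calls == "homB")
  biased <- (nA > fold * nB) | (nB > fold * nA)
  # 0 vs 0 is not biased; x > 10*0 handles the zero denominator as infinite
  !biased
}

#' Classify non-overlapping SNP windows as homozygous or heterozygous
#'
#' Consecutive windows of `window` called SNPs (`nocall`s must be dropped
#' beforehand) are classified `homA`/`homB` when strictly more than
#' `window_frac` (85%) of the window's SNP calls agree on that parent, else
#' `het`. A final partial window of at least `min_partial` SNPs (half the
#' window by default) is classified on its own; a smaller remainder is
#' merged into the previous window.
#'
#' @param calls Character vector of SNP calls (`homA`/`homB`/`het`) ordered
#'   along one chromosome.
#' @param window Window size in SNPs. Default 50.
#' @param window_frac Agreement fraction (strict `>`). Default 0.85.
#' @param min_partial Minimum size of a classifiable terminal window.
#'   Default `ceiling(window / 2)`.
#' @return Data.frame `first`, `last` (SNP indices), `state`; zero rows
#'   (with a warning) when fewer than `min_partial` SNPs are available.
#' @export
window_classify <- function(calls, window = 50L, window_frac = 0.85,
                            min_partial = ceiling(window / 2)) {
  stopifnot(all(calls %in% c("homA", "homB", "het")))
  n <- length(calls)
  if (n < min_partial) {
    warning("fewer than ", min_partial, " usable SNPs; no windows")
    return(data.frame(first = integer(), last = integer(),
                      state = character(), stringsAsFactors = FALSE))
  }
  starts <- seq.int(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  # merge a too-small terminal remainder into the previous window
  k <- length(starts)
  if (k > 1L && (ends[k] - starts[k] + 1L) < min_partial) {
    ends[k - 1L] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
    k <- k - 1L
  }
  state <- vapply(seq_len(k), function(i) {
    w <- calls[starts[i]:ends[i]]
    fA <- mean(w == "homA")
    fB <- mean(w == "homB")
    if (fA > window_frac) "homA" else if (fB > window_frac) "homB" else "het"
  }, "")
  data.frame(first = starts, last = ends, state = state,
             stringsAsFactors = FALSE)
}

# Refine a breakpoint between two states within the SNP calls of the two
# flanking windows: choose the cut maximizing (# calls left of cut matching
# the left state) + (# calls right matching the right state). Returns the
# index of the last SNP belonging to the left segment. agree() counts het
# SNPs as matching 'het' and hom calls as matching their parent.
refine_breakpoint <- function(calls, lo, hi, left_state, right_state) {
  idx <- lo:hi
  matchL <- calls[idx] == left_state
  matchR <- calls[idx] == right_state
  # cut after position t (t in lo-1 .. hi): score(t)
  cumL <- c(0, cumsum(matchL))
  cumR <- c(rev(cumsum(rev(matchR))), 0)
  score <- cumL + cumR
  best <- which.max(score)  # first maximum -> deterministic tie-break
  lo - 1L + (best - 1L)
}

#' Merge classified windows into refined genotype segments
#'
#' Adjacent windows of equal state are merged; each state transition is then
#' refined to the SNP position (within the two flanking windows) that
#' maximizes the two-sided agreement score between SNP-level calls and the
#' flanking segment states. The published procedure refined breakpoints
#' manually; this rule is its deterministic automation. Segments partition
#' the SNP-covered interval and adjacent segments always differ in state.
#'
#' @param windows Window table from [window_classify()].
#' @param calls The SNP-level calls the windows were built from.
#' @param positions Genomic positions of the SNPs (1-based, increasing).
#' @param chrom Chromosome name for the output. Default `"chr"`.
#' @return Data.frame `chrom`, `start`, `end` (positions of the first/last
#'   SNP covered), `first`, `last` (SNP indices), `state`.
#' @export
segment_and_refine <- function(windows, calls, positions,
                               chrom = "chr") {
  stopifnot(length(calls) == length(positions))
  if (!nrow(windows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), first = integer(), last = integer(),
                      state = character(), stringsAsFactors = FALSE))
  }
  # merge same-state runs of windows
  r <- rle(windows$state)
  k <- length(r$values)
  wlast <- cumsum(r$lengths)
  wfirst <- c(1L, utils::head(wlast, -1L) + 1L)
  seg_first <- windows$first[wfirst]
  seg_last <- windows$last[wlast]
  state <- r$values
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      # refine within the two windows flanking the transition
      lo <- windows$first[wlast[i]]
      hi <- windows$last[wfirst[i + 1L]]
      cut <- refine_breakpoint(calls, lo, hi, state[i], state[i + 1L])
      cut <- min(max(cut, seg_first[i]), seg_last[i + 1L] - 1L)
      seg_last[i] <- cut
      seg_first[i + 1L] <- cut + 1L
    }
  }
  keep <- seg_last >= seg_first
  seg_first <- seg_first[keep]; seg_last <- seg_last[keep]
  state <- state[keep]
  # a dropped zero-length segment can leave equal-state neighbours: re-merge
  if (length(state) > 1L) {
    r2 <- rle(state)
    l2 <- cumsum(r2$lengths)
    f2 <- c(1L, utils::head(l2, -1L) + 1L)
    seg_first <- seg_first[f2]
    seg_last <- seg_last[l2]
    state <- r2$values
  }
  data.frame(chrom = chrom, start = positions[seg_first],
             end = positions[seg_last],
             first = seg_first, last = seg_last,
             state = state, stringsAsFactors = FALSE)
}

#' Impute genotypes at arbitrary positions from genotype segments
#'
#' Every position takes the state of its containing segment; positions
#' before the first or after the last segment (or in gaps) take the state of
#' the nearest segment.
#'
#' @param segments Segment table for one chromosome ([segment_and_refine()]
#'   output, or any data.frame with `start`, `end`, `state`).
#' @param positions Positions to impute.
#' @return Character vector of states, one per position.
#' @export
impute_genotypes <- function(segments, positions) {
  if (!nrow(segments)) return(rep(NA_character_, length(positions)))
  segments <- segments[order(segments$start), , drop = FALSE]
  mid_after <- c(-Inf, (segments$start[-1] + utils::head(segments$end, -1)) / 2)
  idx <- findInterval(positions, mid_after)
  idx[idx < 1L] <- 1L
  segments$state[idx]
}

#' Genotype one F2 individual from RNA-seq SNP counts, end to end
#'
#' Applies [call_snp()], drops `nocall`s and (optionally) SNPs flagged by
#' [filter_biased_snps()], classifies windows, segments with refinement, and
#' imputes states back onto the full SNP position list, per chromosome.
#'
#' @param counts Data.frame `chrom`, `pos`, `nA`, `nB` for one individual
#'   (ordered by position within chromosome).
#' @param keep_snps Optional logical vector aligned with `counts` rows
#'   (e.g. from [filter_biased_snps()] across the population).
#' @param window,window_frac,hom_frac See [window_classify()], [call_snp()].
#' @return List with `segments` (all chromosomes bound together) and
#'   `imputed` (data.frame `chrom`, `pos`, `state` covering every input SNP).
#' @export
genotype_individual <- function(counts, keep_snps = NULL, window = 50L,
                                window_frac = 0.85, hom_frac = 0.90) {
  stopifnot(all(c("chrom", "pos", "nA", "nB") %in% names(counts)))
  if (is.null(keep_snps)) keep_snps <- rep(TRUE, nrow(counts))
  segs <- list()
  imp <- list()
  for (cc in unique(counts$chrom)) {
    sub <- counts[counts$chrom == cc, , drop = FALSE]
    keep <- keep_snps[counts$chrom == cc]
    calls <- call_snp(sub$nA, sub$nB, hom_frac)
    usable <- keep & calls != "nocall"
    win <- window_classify(calls[usable], window, window_frac)
    sg <- segment_and_refine(win, calls[usable], sub$pos[usable], chrom = cc)
    segs[[cc]] <- sg
    imp[[cc]] <- data.frame(chrom = cc, pos = sub$pos,
                            state = impute_genotypes(sg, sub$pos),
                            stringsAsFactors = FALSE)
  }
  list(segments = do.call(rbind, c(segs, list(make.row.names = FALSE))),
       imputed = do.call(rbind, c(imp, list(make.row.names = FALSE))))
}

#' Genotype a whole F2 population from RNA-seq SNP counts
#'
#' Runs [call_snp()] over all individuals, applies the population-level
#' [filter_biased_snps()] screen, then genotypes each individual with
#' [genotype_individual()].
#'
#' @param counts Long data.frame `individual`, `chrom`, `pos`, `nA`, `nB`
#'   (as from [simulate_rnaseq_snp_counts()]).
#' @param fold Bias-filter fold change. Default 10.
#' @inheritParams genotype_individual
#' @return List with `segments` (with an `individual` column), `geno`
#'   (matrix SNPs x individuals of imputed states `A`/`H`/`B`), `map`
#'   (`chrom`, `pos`), `kept_snps` (logical).
#' @export
genotype_population <- function(counts, fold = 10, window = 50L,
                                window_frac = 0.85, hom_frac = 0.90) {
  inds <- unique(counts$individual)
  key0 <- counts[counts$individual == inds[1], c("chrom", "pos")]
  callmat <- vapply(inds, function(id) {
    sub <- counts[counts$individual == id, , drop = FALSE]
    stopifnot(nrow(sub) == nrow(key0))
    call_snp(sub$nA, sub$nB, hom_frac)
  }, character(nrow(key0)))
  kept <- filter_biased_snps(callmat, fold)
  state_code <- c(homA = "A", het = "H", homB = "B")
  geno <- matrix(NA_character_, nrow(key0), length(inds),
                 dimnames = list(NULL, inds))
  segs <- vector("list", length(inds))
  for (i in seq_along(inds)) {
    sub <- counts[counts$individual == inds[i], , drop = FALSE]
    g <- genotype_individual(sub, keep_snps = kept, window = window,
                             window_frac = window_frac, hom_frac = hom_frac)
    g$segments$individual <- inds[i]
    segs[[i]] <- g$segments
    geno[, i] <- state_code[g$imputed$state]
  }
  list(segments = do.call(rbind, c(segs, list(make.row.names = FALSE))),
       geno = geno, map = key0, kept_snps = kept)
}
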