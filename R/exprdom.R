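# From DNA/RNA variant proportions to expression-status calls, dominance
# relations between rDNA haplotypes, and the 3x3 two-locus genotype-class
# matrix used to read out epistasis in an F2.

#' Aggregate replicate DNA and RNA proportions per variant
#'
#' Computes per-variant means and standard deviations across biological
#' replicates and the activity ratio `rho = mean RNA / mean DNA`. Variants
#' that are not quantifiable at the RNA level in any replicate (fewer than
#' the required spanning reads) are flagged, not zero-filled; variants
#' without a DNA record are rejected.
#'
#' @param dna Data.frame of DNA proportions per replicate: columns `name`,
#'   `replicate`, `proportion` (copy fractions from [call_variants()]).
#' @param rna Data.frame of RNA quantifications per replicate: columns
#'   `name`, `replicate`, `proportion`, `quantifiable` (from
#'   [quantify_rna()]; `proportion` may be `NA` when not quantifiable).
#' @return An `expression_records` data.frame: `name`, `n_dna`, `n_rna`,
#'   `dna_mean`, `dna_sd`, `rna_mean`, `rna_sd`, `rho`, `quantifiable`,
#'   `single_replicate`.
#' @export
build_expression_records <- function(dna, rna) {
  stopifnot(all(c("name", "replicate", "proportion") %in% names(dna)),
            all(c("name", "replicate", "proportion") %in% names(rna)))
  if (!"quantifiable" %in% names(rna)) {
    rna$quantifiable <- !is.na(rna$proportion)
  }
  orphan <- setdiff(unique(rna$name), unique(dna$name))
  if (length(orphan)) {
    message(length(orphan), " RNA-only variant(s) rejected (no DNA record)")
    rna <- rna[!rna$name %in% orphan, , drop = FALSE]
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  res <- lapply(unique(dna$name), function(v) {
    d <- dna$proportion[dna$name == v]
    rsub <- rna[rna$name == v & rna$quantifiable, , drop = FALSE]
    r <- rsub$proportion
    dna_mean <- mean(d)
    rna_mean <- if (length(r)) mean(r) else NA_real_
    data.frame(name = v, n_dna = length(d), n_rna = length(r),
               dna_mean = dna_mean, dna_sd = sd0(d),
               rna_mean = rna_mean, rna_sd = if (length(r)) sd0(r) else NA_real_,
               rho = if (length(r) && dna_mean > 0) rna_mean / dna_mean
                     else NA_real_,
               quantifiable = length(r) > 0L,
               single_replicate = length(d) < 2L ||
                 (length(r) > 0L && length(r) < 2L),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res),
            class = c("expression_records", "data.frame"))
}

#' Classify haplotype activity from the RNA/DNA ratio
#'
#' The published analysis reads expression off scatter plots of RNA against
#' DNA proportions relative to the one-to-one line; this function
#' operationalizes that visual rule with thresholds on
#' `rho = mean RNA / mean DNA`: `silenced` below `silent_max`, `expressed`
#' within or above the co-dominance band (a variant on active copies of a
#' co-dominant genotype sits near rho = 1; on the only active cluster it can
#' reach rho = 2), else `partial`. Monotone in rho by construction.
#'
#' @param rho Activity ratio(s) (vectorized); `NA` gives `NA`.
#' @param silent_max Upper rho bound for silencing. Default 0.1.
#' @param codominant_band Numeric length-2; rho at or above
#'   `codominant_band[1]` is `expressed`. Default `c(0.5, 2)`.
#' @return Character vector of `silenced`/`partial`/`expressed`.
#' @export
classify_activity <- function(rho, silent_max = 0.1,
                              codominant_band = c(0.5, 2.0)) {
  stopifnot(silent_max > 0, codominant_band[1] > silent_max)
  ifelse(is.na(rho), NA_character_,
         ifelse(rho < silent_max, "silenced",
                ifelse(rho >= codominant_band[1], "expressed", "partial")))
}

#' Dominance relations between rDNA haplotypes from a genotype panel
#'
#' Haplotype H1 dominates H2 when some genotype containing both shows H1's
#' reporter variants expressed and H2's silenced; two haplotypes are
#' co-dominant in a genotype where both are expressed. Relations are
#' reported with supporting genotype ids. Contradictory evidence (both
#' directions observed) is reported as a cycle, not resolved.
#'
#' @param panel Data.frame with one row per (genotype, haplotype):
#'   `genotype_id`, `haplotype`, `status` (`silenced`/`partial`/`expressed`,
#'   e.g. from [classify_activity()] of that haplotype's reporter variants).
#' @return List with `edges` (data.frame `dominant`, `recessive`,
#'   `support`), `codominant` (data.frame `hap1`, `hap2`, `support`) and
#'   `cycles` (character vector describing contradictions, empty if none).
#' @export
dominance_relations <- function(panel) {
  stopifnot(all(c("genotype_id", "haplotype", "status") %in% names(panel)))
  edges <- list()
  codom <- list()
  for (g in unique(panel$genotype_id)) {
    sub <- panel[panel$genotype_id == g, , drop = FALSE]
    if (nrow(sub) < 2L) next
    expr <- sub$haplotype[sub$status == "expressed"]
    sil <- sub$haplotype[sub$status == "silenced"]
    for (h1 in expr) {
      for (h2 in sil) {
        edges[[length(edges) + 1L]] <-
          data.frame(dominant = h1, recessive = h2, support = g,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(expr) > 1L) {
      prs <- utils::combn(sort(expr), 2L)
      for (j in seq_len(ncol(prs))) {
        codom[[length(codom) + 1L]] <-
          data.frame(hap1 = prs[1, j], hap2 = prs[2, j], support = g,
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(dominant = character(), recessive = character(),
               support = character(), stringsAsFactors = FALSE)
  codom <- if (length(codom)) do.call(rbind, codom) else
    data.frame(hap1 = character(), hap2 = character(),
               support = character(), stringsAsFactors = FALSE)
  # detect contradictions: any directed cycle in the unique edge set
  cycles <- character()
  uniq <- unique(edges[, c("dominant", "recessive")])
  if (nrow(uniq)) {
    rev_key <- paste(uniq$recessive, uniq$dominant)
    fwd_key <- paste(uniq$dominant, uniq$recessive)
    two <- fwd_key %in% rev_key
    if (any(two)) {
      cycles <- c(cycles, paste("2-cycle:", fwd_key[two]))
    }
    # longer cycles via iterative removal of sinks/sources (Kahn)
    nodes <- unique(c(uniq$dominant, uniq$recessive))
    ed <- uniq
    repeat {
      indeg <- table(factor(ed$recessive, levels = nodes))
      zero <- nodes[indeg == 0]
      if (!length(zero)) break
      nodes <- setdiff(nodes, zero)
      ed <- ed[!ed$dominant %in% zero, , drop = FALSE]
      if (!nrow(ed)) break
    }
    if (nrow(ed) && !length(cycles)) {
      cycles <- c(cycles, paste("cycle among:",
                                paste(unique(c(ed$dominant, ed$recessive)),
                                      collapse = ", ")))
    }
  }
  list(edges = edges, codominant = codom, cycles = cycles)
}

#' Two-locus genotype-class matrix of DNA and RNA proportions
#'
#' Summarizes a reporter variant over the 3x3 F2 genotype classes
#' (rDNA-2 genotype x rDNA-4 genotype, each `AA`/`AB`/`BB`): per-cell
#' individual count and mean +/- SD of the variant's DNA and RNA
#' proportions. Individuals with an unknown genotype at either locus are
#' excluded and counted; empty cells are reported with `n = 0` and `NA`
#' summaries (no NaN propagation).
#'
#' @param geno2,geno4 Character vectors (`AA`/`AB`/`BB`, `NA` allowed) of
#'   the rDNA-2 and rDNA-4 genotypes per individual.
#' @param dna_prop,rna_prop Numeric vectors of the variant's DNA and RNA
#'   proportions per individual (`NA` when not quantifiable).
#' @return A `class_matrix` data.frame with 9 rows: `geno2`, `geno4`, `n`,
#'   `dna_mean`, `dna_sd`, `rna_mean`, `rna_sd`; attribute `n_excluded`.
#' @export
genotype_class_matrix <- function(geno2, geno4, dna_prop, rna_prop) {
  n <- length(geno2)
  stopifnot(length(geno4) == n, length(dna_prop) == n, length(rna_prop) == n)
  lv <- c("AA", "AB", "BB")
  known <- !is.na(geno2) & !is.na(geno4)
  stopifnot(all(geno2[known] %in% lv), all(geno4[known] %in% lv))
  cells <- expand.grid(geno2 = lv, geno4 = lv, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) c(NA_real_, NA_real_)
    else c(mean(x), if (length(x) > 1L) stats::sd(x) else 0)
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    in_cell <- known & geno2 == cells$geno2[i] & geno4 == cells$geno4[i]
    d <- msd(dna_prop[in_cell])
    r <- msd(rna_prop[in_cell])
    data.frame(geno2 = cells$geno2[i], geno4 = cells$geno4[i],
               n = sum(in_cell), dna_mean = d[1], dna_sd = d[2],
               rna_mean = r[1], rna_sd = r[2], stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res),
            class = c("class_matrix", "data.frame"),
            n_excluded = sum(!known))
}
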