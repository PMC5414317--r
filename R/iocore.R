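#' rdnadom: rDNA cluster-specific variant calling and dominance analysis
#'
#' Analysis toolkit for cluster-specific expression of the two 45S rRNA gene
#' clusters (rDNA-2 on chromosome 2, rDNA-4 on chromosome 4) of
#' *Arabidopsis thaliana*. The pipeline starts from quality-filtered,
#' strand-split per-site allele counts (upstream alignment and base-quality
#' filtering are out of scope) and provides:
#'
#' * within-individual variant calling with a strand-bias filter
#'   ([call_variants()], [strand_bias_score()]),
#' * assignment of variants to rDNA-2 or rDNA-4 by linkage in mapping
#'   populations ([linkage_scan()], [assign_cluster()], [assign_biparental()]),
#' * genotyping of F2 individuals from RNA-seq allele counts
#'   ([call_snp()], [window_classify()], [segment_and_refine()]),
#' * DNA-vs-RNA expression proportion analysis and dominance/epistasis
#'   characterization ([build_expression_records()], [dominance_relations()],
#'   [genotype_class_matrix()]),
#' * QTL scans by marker regression with permutation thresholds
#'   ([single_scan()], [covariate_scan()], [permutation_threshold()]),
#' * a synthetic-data generator with known ground truth
#'   ([make_founders()], [simulate_cross()], [simulate_counts()]).
#'
#' @name rdnadom-package
#' @aliases rdnadom
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Filter configuration
# ---------------------------------------------------------------------------

#' Filtering thresholds for variant calling and downstream stages
#'
#' Bundles the thresholds used throughout the pipeline. Defaults follow the
#' published analysis of 45S rRNA gene variants: alternative alleles must be
#' supported by at least 5% of spanning reads, sites with a strand-bias score
#' above 0.8 are removed, only the transcribed span 300--8009 of the 45S
#' reference is reported, RNA-level quantification requires 25 spanning
#' reads, parental-specific markers require a 10% supporting-read fraction
#' in one parent and absence in the other, and MAGIC variants shared by more
#' than 7 of the 19 founders are not used for linkage assignment.
#'
#' @param min_frac Minimum copy fraction (alternative-read fraction) for a
#'   DNA-level variant call. Default 0.05.
#' @param sb_max Maximum tolerated strand-bias score. Default 0.8.
#' @param span Inclusive 1-based interval of reportable positions on the 45S
#'   reference. Default `c(300, 8009)`.
#' @param min_rna_reads Minimum RNA reads spanning a site to quantify it at
#'   the RNA level. Default 25.
#' @param min_dna_depth Minimum DNA reads spanning a site to evaluate it at
#'   all (mirror of the RNA cutoff; configurable). Default 25.
#' @param parental_min_frac Minimum supporting-read fraction for a
#'   parental-specific marker. Default 0.10.
#' @param max_founder_sharing Maximum number of founders sharing a variant
#'   for it to enter linkage assignment. Default 7.
#' @param frac_strict If `TRUE` the frequency comparison is strict
#'   (`> min_frac`); default `FALSE` keeps fractions `>= min_frac`.
#' @return An object of class `filter_config` (a named list).
#' @examples
#' cfg <- filter_config()
#' cfg$sb_max
#' @export
filter_config <- function(min_frac = 0.05, sb_max = 0.8,
                          span = c(300L, 8009L),
                          min_rna_reads = 25L, min_dna_depth = 25L,
                          parental_min_frac = 0.10,
                          max_founder_sharing = 7L,
                          frac_strict = FALSE) {
  stopifnot(min_frac > 0, min_frac < 1, sb_max >= 0,
            length(span) == 2L, span[1] < span[2],
            min_rna_reads >= 0, min_dna_depth >= 0,
            parental_min_frac > 0, parental_min_frac < 1,
            max_founder_sharing >= 1)
  structure(list(min_frac = min_frac, sb_max = sb_max,
                 span = as.integer(span),
                 min_rna_reads = as.integer(min_rna_reads),
                 min_dna_depth = as.integer(min_dna_depth),
                 parental_min_frac = parental_min_frac,
                 max_founder_sharing = as.integer(max_founder_sharing),
                 frac_strict = isTRUE(frac_strict)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  cat(sprintf("  min_frac            %.3f (%s)\n", x$min_frac,
              if (x$frac_strict) "strict >" else ">="))
  cat(sprintf("  sb_max              %.3f\n", x$sb_max))
  cat(sprintf("  span                [%d, %d]\n", x$span[1], x$span[2]))
  cat(sprintf("  min_dna_depth       %d\n", x$min_dna_depth))
  cat(sprintf("  min_rna_reads       %d\n", x$min_rna_reads))
  cat(sprintf("  parental_min_frac   %.3f\n", x$parental_min_frac))
  cat(sprintf("  max_founder_sharing %d\n", x$max_founder_sharing))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Variant nomenclature: X[position].[reference].[alternative]
# ---------------------------------------------------------------------------

#' Variant name construction and parsing
#'
#' Within-individual 45S variants are named `X<position>.<ref>.<alt>`,
#' e.g. `X2882.T.C`. Deletion alleles are encoded `-` (`X4078.C.-`);
#' insertions are encoded left-anchored as `ins:<seq>` at the anchor
#' position (a package convention; the source nomenclature does not cover
#' insertions).
#'
#' @param position 1-based position(s) on the 45S reference.
#' @param ref,alt Allele strings (`A`, `C`, `G`, `T`, `-`, or `ins:<seq>`).
#' @return `variant_name()` returns a character vector;
#'   `parse_variant_name()` a data.frame with columns
#'   `name`, `position`, `ref`, `alt`.
#' @examples
#' variant_name(2882, "T", "C")
#' parse_variant_name("X4078.C.-")
#' @export
variant_name <- function(position, ref, alt) {
  stopifnot(all(position >= 1), all(nzchar(ref)), all(nzchar(alt)))
  paste0("X", as.integer(position), ".", ref, ".", alt)
}

#' @rdname variant_name
#' @param name Variant name(s) to parse.
#' @export
parse_variant_name <- function(name) {
  m <- regmatches(name, regexec("^X([0-9]+)\\.([^.]+)\\.(.+)$", name))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed variant name(s): ", paste(name[bad], collapse = ", "))
  }
  data.frame(name = name,
             position = as.integer(vapply(m, `[`, "", 2L)),
             ref = vapply(m, `[`, "", 3L),
             alt = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Site count tables
# ---------------------------------------------------------------------------

site_count_columns <- c("sample", "source", "position", "allele", "fwd", "rev")

validate_site_counts <- function(df, file = "<data>") {
  missing_cols <- setdiff(site_count_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("site count table %s: missing column(s) %s", file,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df$fwd <- as.integer(df$fwd)
  df$rev <- as.integer(df$rev)
  bad <- which(is.na(df$position) | df$position < 1L |
                 is.na(df$fwd) | df$fwd < 0L | is.na(df$rev) | df$rev < 0L)
  if (length(bad)) {
    stop(sprintf("site count table %s: invalid position/count in row(s) %s",
                 file, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(df$source %in% c("DNA", "RNA"))) {
    stop(sprintf("site count table %s: source must be 'DNA' or 'RNA'", file),
         call. = FALSE)
  }
  key <- paste(df$sample, df$source, df$position, df$allele, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("site count table %s: duplicated (sample, position, allele) in row(s) %s",
                 file,
                 paste(utils::head(which(duplicated(key)), 10L), collapse = ", ")),
         call. = FALSE)
  }
  class(df) <- c("site_count_table", "data.frame")
  df
}

#' Read / write strand-split per-site allele counts
#'
#' The TSV format has one row per (sample, position, allele) with header
#' columns `sample`, `source` (`DNA`/`RNA`), `position` (1-based on the 45S
#' reference), `allele` (`A`/`C`/`G`/`T`, `-` for a deletion, `ins:<seq>`
#' for an insertion), `fwd` and `rev` (strand-split read counts). An
#' optional `ref` column carries the reference base at the position; it is
#' preserved and used by [call_variants()]. Counts are assumed to be
#' base-quality filtered upstream.
#'
#' @param path Path to a TSV file.
#' @return A validated `site_count_table` data.frame.
#' @seealso [call_variants()], [simulate_counts()]
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_site_counts(df, file = path)
}

#' @rdname read_site_counts
#' @param tbl A `site_count_table`.
#' @export
write_site_counts <- function(tbl, path) {
  tbl <- validate_site_counts(as.data.frame(tbl))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variant call tables
# ---------------------------------------------------------------------------

#' Write a per-sample variant copy-fraction table
#'
#' Writes a wide CSV with one row per sample and one column per variant
#' name (`X<pos>.<ref>.<alt>`) holding copy fractions, emulating the layout
#' of published per-accession 45S variant tables. Columns are ordered by
#' position, then alternative allele (lexicographic).
#'
#' @param calls A `variant_calls` data.frame from [call_variants()] (columns
#'   `sample`, `name`, `position`, `alt`, `copy_fraction`, `status`).
#' @param path Output CSV path.
#' @param pass_only Keep only calls with `status == "pass"`. Default `TRUE`.
#' @return Invisibly, the wide data.frame written.
#' @export
write_variant_table <- function(calls, path, pass_only = TRUE) {
  stopifnot(all(c("sample", "name", "position", "alt", "copy_fraction")
                %in% names(calls)))
  if (pass_only && "status" %in% names(calls)) {
    calls <- calls[calls$status == "pass", , drop = FALSE]
  }
  vars <- unique(calls[, c("name", "position", "alt")])
  if (anyDuplicated(vars$name)) {
    stop("duplicate variant name with conflicting definitions: ",
         paste(unique(vars$name[duplicated(vars$name)]), collapse = ", "))
  }
  vars <- vars[order(vars$position, vars$alt), , drop = FALSE]
  samples <- unique(calls$sample)
  wide <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (v in vars$name) {
    sub <- calls[calls$name == v, , drop = FALSE]
    if (anyDuplicated(sub$sample)) {
      stop("duplicate variant name within a sample: ", v)
    }
    wide[[v]] <- sub$copy_fraction[match(samples, sub$sample)]
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(wide)
}

# ---------------------------------------------------------------------------
# Genotype segments (BED-like I/O)
# ---------------------------------------------------------------------------

validate_segments <- function(seg) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(seg)))
  if (!all(seg$state %in% c("homA", "homB", "het"))) {
    stop("segment state must be one of homA/homB/het")
  }
  if (any(seg$start > seg$end)) stop("segment start > end")
  seg
}

#' Read / write genotype segments as BED-like TSV
#'
#' Segments are held internally with 1-based inclusive `start`/`end`
#' (positions of the first and last SNP they cover). The file dialect only
#' is BED-like half-open: the written `start` column is `start - 1`.
#' Columns: `chrom`, `start`, `end`, `state` (`homA`/`homB`/`het`), plus
#' `individual` when present.
#'
#' @param seg Data.frame of segments (`chrom`, `start`, `end`, `state`,
#'   optionally `individual`).
#' @param path File path.
#' @return `read_genotype_segments()` returns the 1-based segment
#'   data.frame.
#' @export
write_genotype_segments <- function(seg, path) {
  seg <- validate_segments(seg)
  out <- data.frame(chrom = seg$chrom, start = seg$start - 1L,
                    end = seg$end, state = seg$state,
                    stringsAsFactors = FALSE)
  if ("individual" %in% names(seg)) out$individual <- seg$individual
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_genotype_segments
#' @export
read_genotype_segments <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  validate_segments(df)
}

# ---------------------------------------------------------------------------
# Genotype matrices (positions x individuals, states A/H/B)
# ---------------------------------------------------------------------------

#' Read / write an imputed genotype matrix
#'
#' TSV with columns `chrom`, `pos`, then one column per individual holding
#' states `A` (homozygous parent A), `H` (heterozygous), `B`.
#'
#' @param geno Matrix of states (`A`/`H`/`B`), individuals in columns.
#' @param map Data.frame with `chrom` and `pos` for each row of `geno`.
#' @param path File path.
#' @return `read_genotype_matrix()` returns `list(map = <data.frame>,
#'   geno = <character matrix>)`.
#' @export
write_genotype_matrix <- function(geno, map, path) {
  stopifnot(nrow(geno) == nrow(map), all(c("chrom", "pos") %in% names(map)))
  out <- cbind(map[, c("chrom", "pos")], as.data.frame(geno))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  map <- df[, c("chrom", "pos")]
  geno <- as.matrix(df[, setdiff(names(df), c("chrom", "pos")), drop = FALSE])
  list(map = map, geno = geno)
}

# ---------------------------------------------------------------------------
# Configuration files (INI-style: [section] / key = value)
# ---------------------------------------------------------------------------

#' Read / write a structured key-value configuration file
#'
#' Minimal INI dialect: `[section]` headers introduce nested lists,
#' `key = value` pairs are parsed as numbers when possible, `true`/`false`
#' as logicals, comma-separated values as vectors. Lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @return A nested named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  section <- NULL
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    conv <- function(x) {
      if (tolower(x) %in% c("true", "false")) return(tolower(x) == "true")
      n <- suppressWarnings(as.numeric(x))
      if (!is.na(n)) n else x
    }
    out <- lapply(parts, conv)
    if (length(out) == 1L) out[[1]] else unlist(out)
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- parse_val(trimws(paste(kv[-1], collapse = "=")))
      if (is.null(section)) cfg[[key]] <- val else cfg[[section]][[key]] <- val
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  cfg
}

#' @rdname read_config
#' @param cfg Nested named list to serialize.
#' @export
write_config <- function(cfg, path) {
  fmt_val <- function(v) paste(vapply(v, function(x) {
    if (is.logical(x)) tolower(as.character(x)) else format(x, scientific = FALSE)
  }, ""), collapse = ", ")
  out <- character()
  scalars <- cfg[!vapply(cfg, is.list, TRUE)]
  for (k in names(scalars)) out <- c(out, paste(k, "=", fmt_val(scalars[[k]])))
  sections <- cfg[vapply(cfg, is.list, TRUE)]
  for (s in names(sections)) {
    out <- c(out, paste0("[", s, "]"))
    for (k in names(sections[[s]])) {
      out <- c(out, paste(k, "=", fmt_val(sections[[s]][[k]])))
    }
  }
  writeLines(out, path)
  invisible(path)
}
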