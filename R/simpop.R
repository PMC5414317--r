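# Synthetic populations with known rDNA haplotypes, dominance rules and
# strand-split count noise. Everything downstream is validated against the
# ground truth these generators emit.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Deterministic synthetic 45S reference base at a position
#'
#' The generator does not carry a real 45S sequence; reference bases are a
#' fixed periodic function of position so that every component (simulation,
#' calling, naming) agrees on the reference allele without storing a
#' sequence.
#'
#' @param position 1-based position(s).
#' @return Character vector of bases.
#' @export
ref_allele <- function(position) {
  c("A", "C", "G", "T")[(as.integer(position) %% 4L) + 1L]
}

# ---------------------------------------------------------------------------
# Cluster haplotypes and founders
# ---------------------------------------------------------------------------

#' Create a synthetic rDNA cluster haplotype
#'
#' A cluster haplotype is one "allele" of an rDNA cluster: its identity
#' (rDNA-2 or rDNA-4), total 45S copy number, and the set of variants it
#' carries together with the fraction of copies carrying each (rRNA gene
#' variants are rarely homogenized throughout a cluster, so fractions are
#' typically < 1).
#'
#' @param id Haplotype identifier, e.g. `"Col0.rDNA4"`.
#' @param cluster `"rDNA-2"` or `"rDNA-4"`.
#' @param n_private_variants Number of variants to draw.
#' @param copy_number Total 45S copies on this haplotype (> 0).
#' @param fraction_distribution Function `n -> n` fractions in (0, 1]; the
#'   default draws uniform on `[0.2, 1]`.
#' @param span Positions are drawn uniformly without replacement within this
#'   inclusive interval (default the transcribed span 300--8009).
#' @param seed Optional seed (restores the RNG state afterwards).
#' @return A `cluster_haplotype`: list with `id`, `cluster`, `copy_number`,
#'   `composition` (named fractions, names are variant names).
#' @export
make_cluster_haplotype <- function(id, cluster = c("rDNA-2", "rDNA-4"),
                                   n_private_variants = 2L,
                                   copy_number = 100L,
                                   fraction_distribution = function(n)
                                     stats::runif(n, 0.2, 1.0),
                                   span = c(300L, 8009L), seed = NULL) {
  cluster <- match.arg(cluster)
  stopifnot(n_private_variants >= 0, copy_number > 0)
  n_avail <- span[2] - span[1] + 1L
  if (n_private_variants > n_avail) {
    stop("more variants requested than positions available in span")
  }
  with_seed(seed, {
    comp <- numeric(0)
    if (n_private_variants > 0) {
      pos <- sample(seq.int(span[1], span[2]), n_private_variants)
      ref <- ref_allele(pos)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
      frac <- fraction_distribution(n_private_variants)
      if (any(frac < 0 | frac > 1)) stop("composition fractions must lie in [0, 1]")
      comp <- stats::setNames(frac, variant_name(pos, ref, alt))
    }
    structure(list(id = id, cluster = cluster,
                   copy_number = as.integer(copy_number),
                   composition = comp),
              class = "cluster_haplotype")
  })
}

#' Create a panel of founder accessions
#'
#' Each founder contributes one rDNA-2 and one rDNA-4 haplotype with private
#' variants, so every haplotype carries cluster-specific markers.
#'
#' @param n_founders Number of founders (19 for a MAGIC-like panel).
#' @param n_private Private variants per haplotype.
#' @param copy_number_range Copy numbers are drawn uniformly in this range
#'   (cluster sizes vary greatly among accessions).
#' @param fraction_distribution Passed to [make_cluster_haplotype()].
#' @param ids Optional founder names; default `F01`, `F02`, ...
#' @param seed Optional seed.
#' @return Named list of founders; each is `list(id, rdna2, rdna4)` with
#'   `cluster_haplotype` components named `"<id>.rDNA2"` / `"<id>.rDNA4"`.
#' @export
make_founders <- function(n_founders = 19L, n_private = 2L,
                          copy_number_range = c(50L, 200L),
                          fraction_distribution = function(n)
                            stats::runif(n, 0.2, 1.0),
                          ids = NULL, seed = NULL) {
  if (is.null(ids)) ids <- sprintf("F%02d", seq_len(n_founders))
  stopifnot(length(ids) == n_founders, !anyDuplicated(ids))
  with_seed(seed, {
    founders <- lapply(ids, function(id) {
      cn <- sample(seq.int(copy_number_range[1], copy_number_range[2]), 2L,
                   replace = TRUE)
      list(id = id,
           rdna2 = make_cluster_haplotype(paste0(id, ".rDNA2"), "rDNA-2",
                                          n_private, cn[1],
                                          fraction_distribution),
           rdna4 = make_cluster_haplotype(paste0(id, ".rDNA4"), "rDNA-4",
                                          n_private, cn[2],
                                          fraction_distribution))
    })
    stats::setNames(founders, ids)
  })
}

#' Collect the haplotypes of a founder panel into a named list
#'
#' @param founders Output of [make_founders()].
#' @return Named list of `cluster_haplotype` objects keyed by haplotype id.
#' @export
founder_haplotypes <- function(founders) {
  haps <- unlist(lapply(founders, function(f) list(f$rdna2, f$rdna4)),
                 recursive = FALSE)
  stats::setNames(haps, vapply(haps, `[[`, "", "id"))
}

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Count-noise and meiosis configuration for the simulator
#'
#' @param coverage_dna,coverage_rna Mean sequencing depth at a variant site
#'   for DNA-seq and RNA-seq counts (Poisson-distributed per site).
#' @param overdispersion Beta-binomial overdispersion rho in `[0, 1)`;
#'   0 reduces to binomial sampling.
#' @param strand_artifact_rate Probability that a variant's minor-allele
#'   reads are collapsed onto a single strand (creates decoys the
#'   strand-bias filter must catch).
#' @param recomb_rate Expected crossovers per chromosome per meiosis
#'   (Poisson, uniform placement, no interference). Default 1.5.
#' @param rna_region_multiplier Optional function `position -> multiplier`
#'   down-weighting RNA depth, e.g. at ETS/ITS positions for mRNA-seq-like
#'   libraries. Default none.
#' @param seed Optional seed recorded with the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(coverage_dna = 100, coverage_rna = 500,
                       overdispersion = 0, strand_artifact_rate = 0,
                       recomb_rate = 1.5, rna_region_multiplier = NULL,
                       seed = NULL) {
  stopifnot(coverage_dna > 0, coverage_rna > 0,
            overdispersion >= 0, overdispersion < 1,
            strand_artifact_rate >= 0, strand_artifact_rate <= 1,
            recomb_rate >= 0)
  structure(list(coverage_dna = coverage_dna, coverage_rna = coverage_rna,
                 overdispersion = overdispersion,
                 strand_artifact_rate = strand_artifact_rate,
                 recomb_rate = recomb_rate,
                 rna_region_multiplier = rna_region_multiplier,
                 seed = seed),
            class = "sim_config")
}

# Beta-binomial sampler parameterized by mean prob and overdispersion rho.
rbetabinom <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  shape <- (1 - rho) / rho
  p <- stats::rbeta(n, prob * shape, (1 - prob) * shape)
  stats::rbinom(n, size, p)
}

# ---------------------------------------------------------------------------
# Crossing designs
# ---------------------------------------------------------------------------

marker_positions <- function(n_markers, chrom_length = 2e7) {
  as.integer(round(seq(chrom_length / n_markers, chrom_length,
                       length.out = n_markers)))
}

# Indices of the rDNA block: first 1% of markers (at least one) at the
# distal end of chromosomes 2 and 4.
rdna_block <- function(n_markers) seq_len(max(1L, floor(0.01 * n_markers)))

# One gamete from a heterozygous F1: vector of 0/1 (parent A/B origin) along
# marker indices, with Poisson(recomb_rate) crossovers placed uniformly.
sim_gamete <- function(n_markers, recomb_rate) {
  n_xo <- stats::rpois(1L, recomb_rate)
  phase <- stats::rbinom(1L, 1L, 0.5)
  if (n_xo == 0L) return(rep.int(phase, n_markers))
  # crossover falls uniformly on the index interval
  xo <- sort(stats::runif(n_xo, 0, n_markers))
  seg <- findInterval(seq_len(n_markers) - 0.5, xo)
  (phase + seg) %% 2L
}

# Founder mosaic for one chromosome of an inbred MAGIC-like line.
sim_mosaic <- function(n_markers, founder_ids, recomb_rate) {
  n_xo <- stats::rpois(1L, recomb_rate)
  labels <- sample(founder_ids, n_xo + 1L, replace = TRUE)
  if (n_xo == 0L) return(rep(labels, n_markers))
  xo <- sort(stats::runif(n_xo, 0, n_markers))
  labels[findInterval(seq_len(n_markers) - 0.5, xo) + 1L]
}

#' Simulate a mapping population with known rDNA genotypes
#'
#' Generates individual genomes for four designs:
#' * `inbred_panel`: each individual is a homozygous founder (round-robin),
#' * `f1`: heterozygous founder1/founder2 everywhere,
#' * `f2`: selfed-F1 progeny of founders 1 and 2; marker genotypes are
#'   `A`/`H`/`B` with Poisson crossovers per gamete, and the two rDNA loci
#'   (distal blocks of chromosomes 2 and 4) segregate 1:2:1 and
#'   independently,
#' * `magic_mosaic`: inbred founder-labelled mosaics of >= 3 founders, with
#'   the rDNA loci inherited as intact blocks with their flanking markers.
#'
#' The rDNA genotype of every individual is read off the marker state of the
#' distal block of chromosomes 2 and 4 (first 1% of markers), so flanking
#' markers and rDNA locus are consistent by construction.
#'
#' @param design One of `"inbred_panel"`, `"f1"`, `"f2"`, `"magic_mosaic"`.
#' @param founders Founder list from [make_founders()] (2 founders for
#'   `f1`/`f2`, >= 3 for `magic_mosaic`).
#' @param n_individuals Number of genomes to simulate.
#' @param n_markers Markers per chromosome. Default 100.
#' @param n_chromosomes Default 5.
#' @param recomb_rate Expected crossovers per chromosome per meiosis.
#' @param seed Optional seed.
#' @return List of `individual_genome` objects: `id`, `design`,
#'   `rdna2`/`rdna4` (character pair of haplotype ids), `markers`
#'   (data.frame `chrom`, `pos`, `geno` with states `A`/`H`/`B` for `f2`,
#'   founder ids for `magic_mosaic`/`inbred_panel`, `H` for `f1`).
#' @export
simulate_cross <- function(design = c("inbred_panel", "f1", "f2", "magic_mosaic"),
                           founders, n_individuals, n_markers = 100L,
                           n_chromosomes = 5L, recomb_rate = 1.5,
                           seed = NULL) {
  design <- match.arg(design)
  if (design %in% c("f1", "f2") && length(founders) != 2L) {
    stop(design, " design requires exactly 2 founders")
  }
  if (design == "magic_mosaic" && length(founders) < 3L) {
    stop("magic_mosaic requires at least 3 founders")
  }
  pos <- marker_positions(n_markers)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  map <- data.frame(chrom = rep(chroms, each = n_markers),
                    pos = rep(pos, n_chromosomes),
                    stringsAsFactors = FALSE)
  block <- rdna_block(n_markers)
  fid <- names(founders)

  hap_pair <- function(geno_code, locus, A = fid[1], B = fid[2]) {
    suff <- if (locus == 2L) ".rDNA2" else ".rDNA4"
    switch(geno_code,
           A = rep(paste0(A, suff), 2L),
           B = rep(paste0(B, suff), 2L),
           H = paste0(c(A, B), suff),
           rep(paste0(geno_code, suff), 2L))  # founder id (inbred designs)
  }

  with_seed(seed, {
    lapply(seq_len(n_individuals), function(i) {
      geno <- switch(design,
        inbred_panel = {
          f <- fid[((i - 1L) %% length(fid)) + 1L]
          rep(f, nrow(map))
        },
        f1 = rep("H", nrow(map)),
        f2 = {
          unlist(lapply(chroms, function(cc) {
            g <- sim_gamete(n_markers, recomb_rate) +
              sim_gamete(n_markers, recomb_rate)
            c("A", "H", "B")[g + 1L]
          }), use.names = FALSE)
        },
        magic_mosaic = {
          unlist(lapply(chroms, function(cc) {
            m <- sim_mosaic(n_markers, fid, recomb_rate)
            # rDNA block inherited intact with its flanking region:
            m[block] <- m[block[1]]
            m
          }), use.names = FALSE)
        })
      markers <- cbind(map, geno = geno, stringsAsFactors = FALSE)
      g2 <- geno[map$chrom == "chr2"][block[1]]
      g4 <- geno[map$chrom == "chr4"][block[1]]
      structure(list(id = sprintf("%s_%03d", design, i), design = design,
                     rdna2 = hap_pair(g2, 2L), rdna4 = hap_pair(g4, 4L),
                     markers = markers),
                class = "individual_genome")
    })
  })
}

# ---------------------------------------------------------------------------
# Dominance rules
# ---------------------------------------------------------------------------

#' Dominance rule tables for rDNA haplotype activity
#'
#' A rule table maps the unordered four-haplotype genotype (two copies at
#' rDNA-2, two at rDNA-4) to an activity fraction in `[0, 1]` per haplotype.
#' Expression of one cluster depends on the genotype at both clusters, so
#' rules are defined on the full two-locus genotype.
#'
#' `dominance_rules()` wraps an arbitrary rule function
#' `f(rdna2_ids, rdna4_ids) -> named activities`. `rules_from_hierarchy()`
#' builds the common hierarchical case: haplotypes carry a dominance rank
#' and, in any genotype, exactly those present haplotypes sharing the top
#' rank are active (ties give co-dominance). `f2_epistasis_rules()` encodes
#' the two-locus pattern seen in an F2 between a line with dominant rDNA-4
#' (parent A) and one with dominant rDNA-2 (parent B): `A.rDNA4` and
#' `B.rDNA2` are active whenever present, while the recessive `A.rDNA2` and
#' `B.rDNA4` are active only in each other's presence in homozygous state
#' (genotype `A.rDNA2/A.rDNA2` + `B.rDNA4/B.rDNA4`).
#'
#' @param fn Function of `(rdna2_ids, rdna4_ids)` returning a named numeric
#'   vector of activities over the haplotype ids present.
#' @param default Optional fallback activity applied to haplotypes `fn`
#'   leaves out (e.g. 1 for "active unless ruled otherwise").
#' @return A `dominance_rules` object.
#' @export
dominance_rules <- function(fn, default = NULL) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, default = default), class = "dominance_rules")
}

#' @rdname dominance_rules
#' @param ranks Named numeric vector: dominance rank per haplotype id
#'   (higher wins; ties are co-dominant).
#' @export
rules_from_hierarchy <- function(ranks) {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)))
  dominance_rules(function(r2, r4) {
    ids <- unique(c(r2, r4))
    if (!all(ids %in% names(ranks))) {
      stop("genotype not covered by hierarchy: ",
           paste(setdiff(ids, names(ranks)), collapse = ", "))
    }
    r <- ranks[ids]
    stats::setNames(as.numeric(r == max(r)), ids)
  })
}

#' @rdname dominance_rules
#' @param parentA,parentB Founder entries (`list(id, rdna2, rdna4)`) of the
#'   parent with dominant rDNA-4 (A) and dominant rDNA-2 (B).
#' @export
f2_epistasis_rules <- function(parentA, parentB) {
  a2 <- parentA$rdna2$id; a4 <- parentA$rdna4$id
  b2 <- parentB$rdna2$id; b4 <- parentB$rdna4$id
  dominance_rules(function(r2, r4) {
    ids <- unique(c(r2, r4))
    act <- stats::setNames(numeric(length(ids)), ids)
    if (a4 %in% ids) act[a4] <- 1
    if (b2 %in% ids) act[b2] <- 1
    recessive_pair <- all(r2 == a2) && all(r4 == b4)
    if (recessive_pair) {
      act[a2] <- 1
      act[b4] <- 1
    }
    act
  })
}

#' Apply a dominance rule table to one genome
#'
#' @param genome An `individual_genome`.
#' @param rules A `dominance_rules` object.
#' @return Named numeric activities in `[0, 1]` for every haplotype id
#'   present in the genome (copies of the same haplotype share activity).
#' @export
apply_dominance <- function(genome, rules) {
  stopifnot(inherits(rules, "dominance_rules"))
  ids <- unique(c(genome$rdna2, genome$rdna4))
  act <- rules$fn(genome$rdna2, genome$rdna4)
  missing_ids <- setdiff(ids, names(act))
  if (length(missing_ids)) {
    if (is.null(rules$default)) {
      stop("genotype not covered by rule table and no default: ",
           paste(missing_ids, collapse = ", "))
    }
    act[missing_ids] <- rules$default
  }
  act <- act[ids]
  if (any(act < 0 | act > 1)) stop("activities must lie in [0, 1]")
  if (all(act == 0)) stop("rule table silences every haplotype in genotype")
  act
}

# ---------------------------------------------------------------------------
# Expected fractions and count simulation
# ---------------------------------------------------------------------------

genome_copies <- function(genome, haplotypes) {
  ids <- c(genome$rdna2, genome$rdna4)
  if (!all(ids %in% names(haplotypes))) {
    stop("genome references unknown haplotype(s): ",
         paste(setdiff(ids, names(haplotypes)), collapse = ", "))
  }
  haplotypes[ids]
}

#' Analytic DNA and RNA variant fractions for a genome
#'
#' The expected DNA copy fraction of variant v is the copy-number-weighted
#' mean of its composition fraction over the four haplotype copies. The
#' expected RNA fraction weights each copy additionally by its activity:
#' reads are produced only by active copies, so the denominator is the
#' active copy total (a fully silenced genotype yields no RNA reads).
#'
#' @param genome An `individual_genome`.
#' @param activities Named activities from [apply_dominance()].
#' @param haplotypes Named haplotype list, e.g. [founder_haplotypes()].
#' @return Data.frame `name`, `position`, `ref`, `alt`, `f_dna`, `f_rna`.
#' @export
expected_fractions <- function(genome, activities, haplotypes) {
  copies <- genome_copies(genome, haplotypes)
  cn <- vapply(copies, `[[`, 0L, "copy_number")
  if (sum(cn) <= 0) stop("zero total copy number")
  act <- activities[vapply(copies, `[[`, "", "id")]
  if (anyNA(act)) stop("activities missing for some haplotype copies")
  vars <- sort(unique(unlist(lapply(copies, function(h) names(h$composition)))))
  if (!length(vars)) {
    return(data.frame(name = character(), position = integer(),
                      ref = character(), alt = character(),
                      f_dna = numeric(), f_rna = numeric()))
  }
  comp <- vapply(copies, function(h) {
    out <- stats::setNames(numeric(length(vars)), vars)
    out[names(h$composition)] <- h$composition
    out
  }, numeric(length(vars)))
  comp <- matrix(comp, nrow = length(vars))
  f_dna <- as.numeric(comp %*% cn) / sum(cn)
  active_total <- sum(cn * act)
  f_rna <- if (active_total > 0) {
    as.numeric(comp %*% (cn * act)) / active_total
  } else rep(NA_real_, length(vars))
  info <- parse_variant_name(vars)
  data.frame(info, f_dna = f_dna, f_rna = f_rna, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Draw strand-split counts for one source (DNA or RNA) given per-variant
# expected fractions. Multiple alternative alleles at one position share the
# site depth (multinomial).
draw_site_counts <- function(sample_id, source, fr, frac_col, mean_depth,
                             cfg) {
  fr <- fr[!is.na(fr[[frac_col]]), , drop = FALSE]
  if (!nrow(fr)) {
    return(validate_site_counts(data.frame(
      sample = character(), source = character(), position = integer(),
      allele = character(), fwd = integer(), rev = integer(),
      ref = character(), stringsAsFactors = FALSE)))
  }
  rows <- vector("list", length(unique(fr$position)))
  k <- 0L
  for (p in unique(fr$position)) {
    sub <- fr[fr$position == p, , drop = FALSE]
    dm <- mean_depth
    if (source == "RNA" && is.function(cfg$rna_region_multiplier)) {
      dm <- dm * cfg$rna_region_multiplier(p)
    }
    depth <- stats::rpois(1L, dm)
    f <- sub[[frac_col]]
    if (sum(f) > 1) f <- f / sum(f)
    # alt counts sequentially (beta-binomial per alt on the remainder)
    remaining <- depth
    ftail <- 1
    alt_counts <- integer(nrow(sub))
    for (j in seq_len(nrow(sub))) {
      pj <- if (ftail > 0) min(1, f[j] / ftail) else 0
      alt_counts[j] <- if (remaining > 0) {
        rbetabinom(1L, remaining, pj, cfg$overdispersion)
      } else 0L
      remaining <- remaining - alt_counts[j]
      ftail <- ftail - f[j]
    }
    ref_count <- depth - sum(alt_counts)
    ref_fwd <- stats::rbinom(1L, ref_count, 0.5)
    alt_fwd <- integer(nrow(sub))
    for (j in seq_len(nrow(sub))) {
      artifact <- source == "DNA" && cfg$strand_artifact_rate > 0 &&
        stats::runif(1L) < cfg$strand_artifact_rate
      alt_fwd[j] <- if (artifact) {
        if (stats::runif(1L) < 0.5) alt_counts[j] else 0L
      } else {
        stats::rbinom(1L, alt_counts[j], 0.5)
      }
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      sample = sample_id, source = source,
      position = p,
      allele = c(sub$ref[1], sub$alt),
      fwd = c(ref_fwd, alt_fwd),
      rev = c(ref_count - ref_fwd, alt_counts - alt_fwd),
      ref = sub$ref[1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(k)])
  validate_site_counts(out)
}

#' Simulate strand-split DNA and RNA counts for one genome
#'
#' Site depths are Poisson around the configured coverages; variant counts
#' are (beta-)binomial around the analytic expected fractions from
#' [expected_fractions()]; reads split 50:50 over strands unless a strand
#' artifact collapses a variant's minor reads onto one strand (DNA only).
#'
#' @inheritParams expected_fractions
#' @param cfg A [sim_config()].
#' @param sample_id Sample name for the output tables; default `genome$id`.
#' @param seed Optional seed.
#' @return `list(dna = <site_count_table>, rna = <site_count_table>,
#'   truth = <expected_fractions data.frame>)`.
#' @export
simulate_counts <- function(genome, activities, haplotypes, cfg = sim_config(),
                            sample_id = genome$id, seed = NULL) {
  fr <- expected_fractions(genome, activities, haplotypes)
  with_seed(seed, {
    dna <- draw_site_counts(sample_id, "DNA", fr, "f_dna",
                            cfg$coverage_dna, cfg)
    rna <- draw_site_counts(sample_id, "RNA", fr, "f_rna",
                            cfg$coverage_rna, cfg)
    list(dna = dna, rna = rna, truth = fr)
  })
}

# ---------------------------------------------------------------------------
# RNA-seq SNP counts for F2 genotyping
# ---------------------------------------------------------------------------

#' Simulate per-SNP parental allele counts from RNA-seq reads
#'
#' For every marker of every F2 genome, reads crossing the SNP are
#' attributed to parent A or B: at homozygous positions all reads come from
#' one parent apart from an error rate, at heterozygous positions the
#' parent-of-origin is Bernoulli(0.5) per read. Depth is Poisson (truncated
#' at >= 1) around `depth_mean`.
#'
#' @param genomes List of `individual_genome` objects with `A`/`H`/`B`
#'   marker states (an `f2` design from [simulate_cross()]).
#' @param depth_mean Mean read depth per SNP. Default 6.
#' @param error_rate Per-read misattribution probability. Default 0.01.
#' @param seed Optional seed.
#' @return Data.frame `individual`, `chrom`, `pos`, `nA`, `nB`.
#' @export
simulate_rnaseq_snp_counts <- function(genomes, depth_mean = 6,
                                       error_rate = 0.01, seed = NULL) {
  with_seed(seed, {
    out <- lapply(genomes, function(g) {
      mk <- g$markers
      n <- nrow(mk)
      depth <- stats::qpois(stats::runif(n, stats::dpois(0, depth_mean), 1),
                            depth_mean)  # truncated >= 1
      pA <- c(A = 1 - error_rate, H = 0.5, B = error_rate)[mk$geno]
      nA <- stats::rbinom(n, depth, pA)
      data.frame(individual = g$id, chrom = mk$chrom, pos = mk$pos,
                 nA = nA, nB = depth - nA, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Extract the true genotype matrix of a simulated population
#'
#' @param genomes List of `individual_genome` objects.
#' @return `list(map = data.frame(chrom, pos), geno = matrix)` with one
#'   column per individual (states as stored in the genomes).
#' @export
true_genotypes <- function(genomes) {
  map <- genomes[[1]]$markers[, c("chrom", "pos")]
  geno <- vapply(genomes, function(g) g$markers$geno,
                 character(nrow(map)))
  colnames(geno) <- vapply(genomes, `[[`, "", "id")
  list(map = map, geno = geno)
}
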