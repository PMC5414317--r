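# Shared simulation harnesses used by module and acceptance tests.
# Everything is seeded; no fixture files.

# Minimal site-count table from explicit allele counts at one position.
site_tbl <- function(position, alleles, fwd, rev, ref,
                     sample = "s1", source = "DNA") {
  data.frame(sample = sample, source = source, position = position,
             allele = alleles, fwd = fwd, rev = rev, ref = ref,
             stringsAsFactors = FALSE)
}

# "Everything active" dominance rules (pure DNA-level studies).
all_active_rules <- function() {
  dominance_rules(function(r2, r4) {
    ids <- unique(c(r2, r4))
    stats::setNames(rep(1, length(ids)), ids)
  })
}

# True (name, cluster, founder) table of a founder panel.
founder_variant_truth <- function(founders) {
  haps <- founder_haplotypes(founders)
  out <- lapply(haps, function(h) {
    if (!length(h$composition)) return(NULL)
    data.frame(name = names(h$composition), cluster = h$cluster,
               founder = sub("\\.rDNA[24]$", "", h$id),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# End-to-end MAGIC cluster-assignment study: simulate founders and mosaic
# lines, call variants from simulated DNA counts, assign clusters, and
# return assignments merged with the ground truth.
sim_magic_study <- function(seed, n_lines = 200L, n_founders = 19L,
                            n_private = 1L, depth = 100, n_markers = 60L,
                            n_perm = 200L) {
  founders <- make_founders(n_founders, n_private = n_private,
                            seed = seed + 1L)
  haps <- founder_haplotypes(founders)
  truth <- founder_variant_truth(founders)
  rules <- all_active_rules()
  cfg <- sim_config(coverage_dna = depth)
  call_one <- function(g) {
    cts <- simulate_counts(g, apply_dominance(g, rules), haps, cfg)
    call_variants(cts$dna)
  }
  set.seed(seed)
  # founder panel defines the variant universe (DNA-pass in >= 1 founder)
  fgen <- simulate_cross("inbred_panel", founders, n_founders,
                         n_markers = n_markers, seed = seed + 3L)
  fcalls <- lapply(fgen, call_one)
  vnames <- sort(unique(unlist(lapply(fcalls, function(cl)
    cl$name[cl$status == "pass"]))))
  fp <- t(vapply(fcalls, function(cl) vnames %in% cl$name[cl$status == "pass"],
                 logical(length(vnames))))
  rownames(fp) <- names(founders)
  colnames(fp) <- vnames
  lines <- simulate_cross("magic_mosaic", founders, n_lines,
                          n_markers = n_markers, seed = seed + 2L)
  ab <- matrix(0, n_lines, length(vnames), dimnames = list(NULL, vnames))
  pres <- matrix(FALSE, n_lines, length(vnames),
                 dimnames = list(NULL, vnames))
  for (i in seq_along(lines)) {
    cl <- call_one(lines[[i]])
    pass <- cl[cl$status == "pass", , drop = FALSE]
    idx <- match(pass$name, vnames)
    ok <- !is.na(idx)
    ab[i, idx[ok]] <- pass$copy_fraction[ok]
    pres[i, idx[ok]] <- TRUE
  }
  tg <- true_genotypes(lines)
  labels <- t(tg$geno)
  l2 <- vapply(lines, function(g) sub("\\.rDNA2$", "", g$rdna2[1]), "")
  l4 <- vapply(lines, function(g) sub("\\.rDNA4$", "", g$rdna4[1]), "")
  res <- assign_clusters_magic(ab, pres, fp, l2, l4, labels, tg$map,
                               n_perm = n_perm, seed = seed + 4L)
  # truth restricted to the called universe; variants drawn at the same
  # position on both clusters have no unique true cluster
  truth <- truth[truth$name %in% vnames, , drop = FALSE]
  ncl <- tapply(truth$cluster, truth$name, function(x) length(unique(x)))
  unique_truth <- truth[ncl[truth$name] == 1L, , drop = FALSE]
  unique_truth <- unique_truth[!duplicated(unique_truth$name), ]
  list(res = res, truth = truth, unique_truth = unique_truth,
       merged = merge(res, unique_truth, by = "name"),
       n_variants = length(vnames))
}

# End-to-end F2 expression study under the two-locus epistasis rules:
# per-individual DNA/RNA proportions of one recessive reporter variant
# (parent A's rDNA-2), two-locus genotype codes, a reduced marker map and
# the scan phenotype.
sim_f2_epistasis_study <- function(seed, n = 180L, n_markers = 40L,
                                   coverage_dna = 100, coverage_rna = 500) {
  founders <- make_founders(2L, ids = c("A", "B"), n_private = 2L,
                            seed = seed)
  haps <- founder_haplotypes(founders)
  rules <- f2_epistasis_rules(founders$A, founders$B)
  pop <- simulate_cross("f2", founders, n, n_markers = n_markers,
                        seed = seed + 1L)
  cfg <- sim_config(coverage_dna = coverage_dna, coverage_rna = coverage_rna)
  vrec <- names(founders$A$rdna2$composition)[1]
  dna_p <- rna_p <- numeric(n)
  g2 <- g4 <- character(n)
  set.seed(seed + 2L)
  for (i in seq_along(pop)) {
    g <- pop[[i]]
    cts <- simulate_counts(g, apply_dominance(g, rules), haps, cfg)
    cl <- call_variants(cts$dna)
    rq <- suppressMessages(quantify_rna(cts$rna, cl))
    in_pass <- vrec %in% cl$name[cl$status == "pass"]
    dna_p[i] <- if (in_pass) cl$copy_fraction[cl$name == vrec] else 0
    rna_p[i] <- if (vrec %in% rq$name && isTRUE(rq$quantifiable[rq$name == vrec]))
      rq$proportion[rq$name == vrec] else NA_real_
    # genotype codes: AA = homozygous parent A at rDNA-2; at rDNA-4 the
    # recessive partner is parent B's haplotype, code relative to B
    g2[i] <- c("BB", "AB", "AA")[sum(g$rdna2 == "A.rDNA2") + 1L]
    g4[i] <- c("BB", "AB", "AA")[sum(g$rdna4 == "B.rDNA4") + 1L]
  }
  tg <- true_genotypes(pop)
  mmap <- reduce_map(t(tg$geno), tg$map)
  phen <- ifelse(is.na(rna_p), 0, rna_p)
  list(founders = founders, haps = haps, rules = rules, pop = pop,
       variant = vrec, dna_p = dna_p, rna_p = rna_p, g2 = g2, g4 = g4,
       mmap = mmap, phen = phen)
}

# Index of the first marker (the rDNA block) of a chromosome in a reduced map.
rdna_marker_index <- function(mmap, chrom) {
  which(mmap$map$chrom == chrom)[1]
}
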