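test_that("make_cluster_haplotype respects count, determinism and degenerate cases", {
  h0 <- make_cluster_haplotype("x", "rDNA-2", 0)
  expect_length(h0$composition, 0L)
  h1 <- make_cluster_haplotype("x", "rDNA-4", 5, seed = 3)
  h2 <- make_cluster_haplotype("x", "rDNA-4", 5, seed = 3)
  expect_identical(h1, h2)
  expect_length(h1$composition, 5L)
  pos <- parse_variant_name(names(h1$composition))$position
  expect_true(all(pos >= 300 & pos <= 8009))
  expect_false(anyDuplicated(pos) > 0)
  hfix <- make_cluster_haplotype("x", "rDNA-2", 4,
                                 fraction_distribution = function(n) rep(1, n),
                                 seed = 4)
  expect_true(all(hfix$composition == 1))
  expect_error(make_cluster_haplotype("x", "rDNA-2", 10, span = c(300, 305)),
               "more variants")
})

test_that("f1 and f2 designs segregate as expected", {
  founders <- make_founders(2, ids = c("P", "Q"), seed = 10)
  f1 <- simulate_cross("f1", founders, 5, seed = 11)
  for (g in f1) {
    expect_setequal(g$rdna2, c("P.rDNA2", "Q.rDNA2"))
    expect_setequal(g$rdna4, c("P.rDNA4", "Q.rDNA4"))
  }
  f2 <- simulate_cross("f2", founders, 4000, n_markers = 10, seed = 12)
  hom2 <- mean(vapply(f2, function(g) all(g$rdna2 == "P.rDNA2"), TRUE))
  expect_lt(abs(hom2 - 0.25), 0.02)  # ~3 binomial SE at n=4000
  # independence of the two unlinked loci
  s2 <- vapply(f2, function(g) sum(g$rdna2 == "P.rDNA2"), 0L)
  s4 <- vapply(f2, function(g) sum(g$rdna4 == "P.rDNA4"), 0L)
  expect_gt(suppressWarnings(chisq.test(table(s2, s4)))$p.value, 0.01)
  expect_error(simulate_cross("f2", make_founders(3, seed = 1), 10),
               "exactly 2 founders")
  expect_error(simulate_cross("magic_mosaic", founders, 10), "at least 3")
})

test_that("magic mosaics are single-founder everywhere with rDNA inherited as a block", {
  founders <- make_founders(5, seed = 20)
  lines <- simulate_cross("magic_mosaic", founders, 50, n_markers = 100,
                          seed = 21)
  block <- seq_len(1L)  # first 1% of 100 markers
  for (g in lines[1:10]) {
    expect_true(all(g$markers$geno %in% names(founders)))
    m2 <- g$markers$geno[g$markers$chrom == "chr2"]
    expect_identical(g$rdna2[1], paste0(m2[block[1]], ".rDNA2"))
    expect_identical(g$rdna2[1], g$rdna2[2])  # inbred
  }
})

test_that("apply_dominance covers hierarchy, epistasis and default rules", {
  founders <- make_founders(3, ids = c("Col0", "No0", "Edi0"), seed = 30)
  # Col-0-like homozygote: rDNA-4 active, rDNA-2 silent
  ranks <- c(Col0.rDNA2 = 0, Col0.rDNA4 = 1, No0.rDNA2 = 2, No0.rDNA4 = 0,
             Edi0.rDNA2 = 0, Edi0.rDNA4 = 3)
  rules <- rules_from_hierarchy(ranks)
  col0 <- simulate_cross("inbred_panel", founders["Col0"], 1, seed = 31)[[1]]
  act <- apply_dominance(col0, rules)
  expect_equal(act[["Col0.rDNA4"]], 1)
  expect_equal(act[["Col0.rDNA2"]], 0)
  # MAGIC-170-like: No-0 rDNA-2 + Edi-0 rDNA-4 -> rDNA-2 silenced, rDNA-4 on
  g170 <- structure(list(id = "magic170", design = "magic_mosaic",
                         rdna2 = rep("No0.rDNA2", 2),
                         rdna4 = rep("Edi0.rDNA4", 2),
                         markers = col0$markers),
                    class = "individual_genome")
  act <- apply_dominance(g170, rules)
  expect_equal(act[["No0.rDNA2"]], 0)
  expect_equal(act[["Edi0.rDNA4"]], 1)
  # co-dominance via tied ranks (Sf-2 / Col-0 rDNA-4 both active in the F1)
  ranks2 <- c(Sf2.rDNA4 = 1, Col0.rDNA4 = 1, Sf2.rDNA2 = 0, Col0.rDNA2 = 0)
  gf1 <- structure(list(id = "f1", design = "f1",
                        rdna2 = c("Sf2.rDNA2", "Col0.rDNA2"),
                        rdna4 = c("Sf2.rDNA4", "Col0.rDNA4"),
                        markers = col0$markers),
                   class = "individual_genome")
  act <- apply_dominance(gf1, rules_from_hierarchy(ranks2))
  expect_equal(act[["Sf2.rDNA4"]], 1)
  expect_equal(act[["Col0.rDNA4"]], 1)
  # uncovered genotype without default errors; with default does not
  bare <- dominance_rules(function(r2, r4) c())
  expect_error(apply_dominance(col0, bare), "not covered")
  deflt <- dominance_rules(function(r2, r4) c(), default = 1)
  expect_true(all(apply_dominance(col0, deflt) == 1))
})

test_that("expected fractions follow copy-weighted arithmetic", {
  mk <- function(id, cluster, comp, cn = 100L) {
    structure(list(id = id, cluster = cluster, copy_number = cn,
                   composition = comp),
              class = "cluster_haplotype")
  }
  v <- "X1000.A.C"
  haps <- list(
    A.rDNA2 = mk("A.rDNA2", "rDNA-2", setNames(1.0, v)),
    B.rDNA2 = mk("B.rDNA2", "rDNA-2", setNames(1.0, v)),
    A.rDNA4 = mk("A.rDNA4", "rDNA-4", numeric()),
    B.rDNA4 = mk("B.rDNA4", "rDNA-4", numeric()))
  g <- structure(list(id = "x", design = "f1",
                      rdna2 = c("A.rDNA2", "B.rDNA2"),
                      rdna4 = c("A.rDNA4", "B.rDNA4"),
                      markers = data.frame(chrom = "chr1", pos = 1,
                                           geno = "H")),
                 class = "individual_genome")
  all_on <- c(A.rDNA2 = 1, B.rDNA2 = 1, A.rDNA4 = 1, B.rDNA4 = 1)
  ef <- expected_fractions(g, all_on, haps)
  expect_equal(ef$f_dna, 0.5)   # fixed on both rDNA-2 copies, equal copies
  expect_equal(ef$f_rna, 0.5)   # fully active: RNA = DNA (one-to-one line)
  sil2 <- c(A.rDNA2 = 0, B.rDNA2 = 0, A.rDNA4 = 1, B.rDNA4 = 1)
  ef <- expected_fractions(g, sil2, haps)
  expect_equal(ef$f_dna, 0.5)
  expect_equal(ef$f_rna, 0)     # silenced cluster contributes no RNA
  expect_error(expected_fractions(g, all_on[1:2], haps), "missing")
})

test_that("simulated DNA copy fractions match the analytic expectation", {
  founders <- make_founders(2, ids = c("A", "B"), seed = 40)
  haps <- founder_haplotypes(founders)
  g <- simulate_cross("f2", founders, 1, n_markers = 10, seed = 41)[[1]]
  act <- apply_dominance(g, all_active_rules())
  ef <- expected_fractions(g, act, haps)
  depth <- 100
  cfg <- sim_config(coverage_dna = depth)
  nrep <- 200
  set.seed(42)
  est <- matrix(NA_real_, nrep, nrow(ef))
  for (r in seq_len(nrep)) {
    dna <- simulate_counts(g, act, haps, cfg)$dna
    for (j in seq_len(nrow(ef))) {
      site <- dna[dna$position == ef$position[j], ]
      est[r, j] <- sum(site$fwd[site$allele == ef$alt[j]] +
                         site$rev[site$allele == ef$alt[j]]) /
        sum(site$fwd + site$rev)
    }
  }
  mc_se <- sqrt(ef$f_dna * (1 - ef$f_dna) / depth / nrep)
  expect_true(all(abs(colMeans(est) - ef$f_dna) <= 3 * mc_se + 1e-9))
})

test_that("snp count generator matches its sampling model and is deterministic", {
  founders <- make_founders(2, ids = c("A", "B"), seed = 50)
  pop <- simulate_cross("f2", founders, 3, n_markers = 3000, seed = 51)
  s1 <- simulate_rnaseq_snp_counts(pop, depth_mean = 20, error_rate = 0,
                                   seed = 52)
  s2 <- simulate_rnaseq_snp_counts(pop, depth_mean = 20, error_rate = 0,
                                   seed = 52)
  expect_identical(s1, s2)
  truth <- do.call(rbind, lapply(pop, function(g) g$markers))
  homA <- truth$geno == "A"
  expect_true(all(s1$nB[homA] == 0))  # eps = 0: all reads from parent A
  expect_true(all(s1$nA + s1$nB >= 1))
  het <- truth$geno == "H"
  fA <- sum(s1$nA[het]) / sum((s1$nA + s1$nB)[het])
  expect_lt(abs(fA - 0.5), 0.01)
})
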