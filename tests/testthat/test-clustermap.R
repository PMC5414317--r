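test_that("founder sharing filter keeps <= 7 of 19 carriers", {
  pres <- function(k) c(rep(TRUE, k), rep(FALSE, 19 - k))
  expect_true(founder_sharing_filter(pres(1)))
  expect_true(founder_sharing_filter(pres(7)))
  expect_false(founder_sharing_filter(pres(8)))
})

test_that("linkage scan finds a private-founder variant and controls type I error", {
  founders <- make_founders(19, n_private = 0, seed = 60)
  lines <- simulate_cross("magic_mosaic", founders, 200, n_markers = 40,
                          seed = 61)
  tg <- true_genotypes(lines)
  labels <- t(tg$geno)
  l4 <- vapply(lines, function(g) sub("\\.rDNA4$", "", g$rdna4[1]), "")
  set.seed(62)
  # abundance: carriers of F05's rDNA-4 at ~0.3 with binomial noise, depth 100
  ab <- ifelse(l4 == "F05", rbinom(200, 100, 0.3) / 100, 0)
  scan <- linkage_scan(ab, labels, tg$map)
  expect_identical(attr(scan, "peak_region"), "chr4_top")
  thr <- linkage_permutation_threshold(ab, labels, n_perm = 200, seed = 63)
  expect_gt(scan$stat[attr(scan, "peak")], thr)
  # permuted abundance: max stat rarely exceeds the permutation threshold
  hits <- 0L
  for (i in 1:20) {
    scp <- linkage_scan(sample(ab), labels, tg$map)
    if (max(scp$stat) > thr) hits <- hits + 1L
  }
  expect_lte(hits, 3L)
  # constant abundance -> flat scan
  flat <- linkage_scan(rep(0.2, 200), labels, tg$map)
  expect_true(all(flat$stat == 0))
})

test_that("assign_cluster follows the two-condition rule", {
  map <- data.frame(chrom = rep(paste0("chr", 1:5), each = 20),
                    pos = rep(1:20, 5))
  mk_scan <- function(stats) {
    region <- rdnadom:::marker_regions(map)
    at_max <- which(stats == max(stats))
    regs <- unique(region[at_max])
    tops <- intersect(regs, c("chr2_top", "chr4_top"))
    structure(data.frame(chrom = map$chrom, pos = map$pos, region = region,
                         stat = stats),
              class = c("linkage_scan", "data.frame"),
              peak = at_max[1],
              peak_region = if (length(tops) == 1) tops else "other",
              peak_tied = length(tops) > 1)
  }
  s <- rep(0.1, 100)
  i2 <- which(rdnadom:::marker_regions(map) == "chr2_top")[1]
  i4 <- which(rdnadom:::marker_regions(map) == "chr4_top")[1]
  s2 <- replace(s, i2, 10)
  expect_identical(assign_cluster(mk_scan(s2), 1.0, 3)$call, "rDNA-2")
  # low consistency -> ambiguous
  expect_identical(assign_cluster(mk_scan(s2), 0.8, 3)$call, "ambiguous")
  # peaks at both tops -> ambiguous
  s24 <- replace(s2, i4, 10)
  expect_identical(assign_cluster(mk_scan(s24), 1.0, 3)$call, "ambiguous")
  # peak on another chromosome -> ambiguous
  s1 <- replace(s, which(map$chrom == "chr1")[5], 10)
  expect_identical(assign_cluster(mk_scan(s1), 1.0, 3)$call, "ambiguous")
  # not significant -> ambiguous
  expect_identical(assign_cluster(mk_scan(s2), 1.0, 20)$call, "ambiguous")
})

test_that("consistency check scores matches and flags discordant lines", {
  expect_equal(check_consistency(rep(TRUE, 200), rep(TRUE, 200))$consistency,
               1.0)
  pres <- rep(c(TRUE, FALSE), each = 50)
  pred <- pres
  pred[10] <- FALSE
  cc <- check_consistency(pres, pred)
  expect_equal(cc$consistency, 0.99)
  expect_identical(cc$discordant, 10L)
  # random presence: consistency near the carrier frequency, below threshold
  set.seed(64)
  rand <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  cc <- check_consistency(rand, pred)
  expect_lt(cc$consistency, 0.95)
  # no lines -> undefined
  expect_true(is.na(check_consistency(logical(), logical())$consistency))
  # recurrently discordant ids are flagged
  fl <- flag_discordant(list(c(3L, 7L), c(7L), c(7L, 12L)))
  expect_identical(names(fl), "7")
})

test_that("parental-specific markers require 10% support and absence in the other", {
  mk_calls <- function(names, fracs, status = "pass") {
    data.frame(sample = "p", name = names, copy_fraction = fracs,
               status = status, stringsAsFactors = FALSE)
  }
  A <- mk_calls(c("X500.A.G", "X600.C.T", "X700.G.A"), c(0.35, 0.08, 0.40))
  B <- mk_calls(c("X700.G.A", "X800.T.C"), c(0.06, 0.20))
  m <- parental_specific_markers(A, B)
  # X500: 0.35 in A, absent in B -> marker for A
  expect_true(any(m$name == "X500.A.G" & m$parent == "A"))
  # X600: 0.08 < 0.10 -> rejected
  expect_false("X600.C.T" %in% m$name)
  # X700: 0.06 in B >= calling floor -> not absent -> rejected
  expect_false("X700.G.A" %in% m$name)
  # X800 is a marker for B
  expect_true(any(m$name == "X800.T.C" & m$parent == "B"))
  # swapping arguments swaps roles over the same variant set
  m2 <- parental_specific_markers(B, A)
  expect_setequal(m$name, m2$name)
  expect_identical(sort(m$parent), sort(chartr("AB", "BA", m2$parent)))
})

test_that("biparental assignment requires perfect co-segregation and enough lines", {
  set.seed(65)
  n <- 16
  geno2 <- sample(c("AA", "AB", "BB"), n, replace = TRUE)
  geno4 <- sample(c("AA", "AB", "BB"), n, replace = TRUE)
  pres2 <- geno2 %in% c("AA", "AB")   # perfect rDNA-2 A-marker
  pres_no <- rep(c(TRUE, FALSE), 8)   # co-segregates with neither
  pres_almost <- pres2
  pres_almost[3] <- !pres_almost[3]   # 15/16 co-segregation
  presence <- cbind(v2 = pres2, vno = pres_no, valmost = pres_almost)
  res <- assign_biparental(presence, geno2, geno4, parent = c("A", "A", "A"))
  expect_identical(res$call[res$name == "v2"], "rDNA-2")
  expect_identical(res$call[res$name == "vno"], "ambiguous")
  expect_identical(res$call[res$name == "valmost"], "ambiguous")
  expect_warning(
    res8 <- assign_biparental(presence[1:6, 1, drop = FALSE], geno2[1:6],
                              geno4[1:6], parent = "A"),
    "informative lines")
  expect_true(all(res8$call == "ambiguous"))
})

test_that("magic assignment is symmetric under cluster relabelling (small panel)", {
  # one rDNA-2 and one rDNA-4 private variant, roles mirrored
  st <- sim_magic_study(seed = 777, n_lines = 120, n_founders = 8,
                        n_private = 1, n_markers = 40, n_perm = 150)
  m <- st$merged
  m <- m[m$call != "excluded" & m$call != "ambiguous", ]
  expect_gt(nrow(m), 0)
  expect_true(all(m$call == m$cluster))
  expect_true(any(m$cluster == "rDNA-2") && any(m$cluster == "rDNA-4"))
})
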