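test_that("strand-bias score matches the printed formula and degenerate rules", {
  expect_equal(strand_bias_score(40, 10, 40, 10), 0)
  expect_equal(strand_bias_score(50, 10, 50, 0),
               abs(10 / 60 - 0 / 50) / (10 / 110))
  expect_equal(strand_bias_score(30, 0, 30, 0), 0)  # no minor reads: no bias
  expect_error(strand_bias_score(0, 0, 0, 0), "all-zero")
  expect_warning(s <- strand_bias_score(50, 10, 0, 0), "zero depth")
  expect_gt(s, 0)
})

test_that("strand-bias score is invariant to strand swap and count scaling", {
  set.seed(1)
  for (i in 1:50) {
    cnt <- rpois(4, 30) + c(20L, 0L, 20L, 0L)
    s <- strand_bias_score(cnt[1], cnt[2], cnt[3], cnt[4])
    swap <- strand_bias_score(cnt[3], cnt[4], cnt[1], cnt[2])
    scaled <- strand_bias_score(3 * cnt[1], 3 * cnt[2], 3 * cnt[3],
                                3 * cnt[4])
    expect_equal(s, swap)
    expect_equal(s, scaled)
  }
})

make_site_fixture <- function() {
  rbind(
    # depth 200, alt 10 balanced -> fraction exactly 0.05: pass (>= rule)
    site_tbl(1000L, c("A", "G"), c(95L, 5L), c(95L, 5L), "A"),
    # depth 200, alt 8 -> 0.04: below_frequency
    site_tbl(1001L, c("C", "T"), c(96L, 4L), c(96L, 4L), "C"),
    # alt strand-collapsed: SB = |20/70 - 0| / (20/120) = 12/7 > 0.8
    site_tbl(1002L, c("G", "A"), c(50L, 20L), c(50L, 0L), "G"),
    # out of span
    site_tbl(150L, c("T", "C"), c(60L, 40L), c(60L, 40L), "T"),
    # depth below the DNA floor
    site_tbl(1003L, c("A", "C"), c(6L, 4L), c(6L, 4L), "A"))
}

test_that("call_variants applies frequency, strand-bias, span and depth filters", {
  calls <- call_variants(make_site_fixture())
  st <- setNames(calls$status, calls$name)
  expect_identical(st[["X1000.A.G"]], "pass")
  expect_identical(st[["X1001.C.T"]], "below_frequency")
  expect_identical(st[["X1002.G.A"]], "strand_biased")
  expect_identical(st[["X150.T.C"]], "out_of_span")
  expect_identical(st[["X1003.A.C"]], "low_depth")
  expect_equal(calls$copy_fraction[calls$name == "X1000.A.G"], 0.05)
  expect_equal(calls$sb_score[calls$name == "X1002.G.A"], 12 / 7)
  audit <- attr(calls, "filter_audit")
  expect_equal(unname(audit[["sites_in"]]), 5L)
  expect_equal(unname(audit[["pass"]]), 1L)
  # strict comparator drops the exact-5% call
  strict <- call_variants(make_site_fixture(),
                          filter_config(frac_strict = TRUE))
  expect_identical(strict$status[strict$name == "X1000.A.G"],
                   "below_frequency")
  # empty table -> empty calls
  expect_equal(nrow(call_variants(make_site_fixture()[0, ])), 0L)
})

test_that("call_variants is invariant to input row order", {
  tbl <- make_site_fixture()
  set.seed(7)
  shuffled <- tbl[sample.int(nrow(tbl)), ]
  a <- call_variants(tbl)
  b <- call_variants(shuffled)
  a <- a[order(a$name), ]
  b <- b[order(b$name), ]
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("reference-allele flipping emits a mirrored call only when alt is major", {
  tbl <- rbind(
    # ref 30% / alt 70%: reference tracked as X2000.G.A
    site_tbl(2000L, c("A", "G"), c(15L, 35L), c(15L, 35L), "A"),
    # ref 60% / alt 40%: no extra call
    site_tbl(2001L, c("C", "T"), c(30L, 20L), c(30L, 20L), "C"),
    # exact 50/50 tie: strict rule, no extra call
    site_tbl(2002L, c("G", "A"), c(25L, 25L), c(25L, 25L), "G"))
  calls <- call_variants(tbl)
  aug <- flip_reference_minority(calls, tbl)
  extra <- setdiff(aug$name, calls$name)
  expect_identical(extra, "X2000.G.A")
  expect_equal(aug$copy_fraction[aug$name == "X2000.G.A"], 0.3)
  expect_identical(aug$status[aug$name == "X2000.G.A"], "pass")
})

test_that("copy-fraction estimator is unbiased across the acceptance grid", {
  # direct small version; the full 500-replicate version lives in acceptance
  truth <- c(0.1, 0.3)
  depth <- 200
  nrep <- 200
  set.seed(11)
  for (f in truth) {
    est <- replicate(nrep, {
      alt <- rbinom(1, depth, f)
      af <- rbinom(1, alt, 0.5)
      rf <- rbinom(1, depth - alt, 0.5)
      tbl <- site_tbl(4000L, c("A", "G"), c(rf, af),
                      c(depth - alt - rf, alt - af), "A")
      cl <- call_variants(tbl)
      cl$copy_fraction[1]
    })
    expect_lt(abs(mean(est) - f), 3 * sqrt(f * (1 - f) / depth / nrep))
  }
})

test_that("quantify_rna enforces the 25-read floor and DNA validation", {
  dna <- rbind(site_tbl(3000L, c("A", "G"), c(60L, 40L), c(60L, 40L), "A"),
               site_tbl(3001L, c("C", "T"), c(99L, 1L), c(99L, 1L), "C"))
  calls <- call_variants(dna)  # X3001.C.T fails frequency
  rna <- rbind(site_tbl(3000L, c("A", "G"), c(7L, 5L), c(7L, 5L), "A",
                        source = "RNA"),
               site_tbl(3001L, c("C", "T"), c(100L, 100L), c(100L, 100L),
                        "C", source = "RNA"))
  expect_message(rq <- quantify_rna(rna, calls), "excluded")
  # DNA-failed variant absent despite abundant RNA reads
  expect_false("X3001.C.T" %in% rq$name)
  # 24 RNA reads < 25: not quantifiable, NA proportion (not zero-filled)
  row <- rq[rq$name == "X3000.A.G", ]
  expect_equal(row$rna_depth, 24L)
  expect_false(row$quantifiable)
  expect_true(is.na(row$proportion))
  # with depth >= 25 the proportion is reads/depth
  rna2 <- site_tbl(3000L, c("A", "G"), c(40L, 5L), c(40L, 15L), "A",
                   source = "RNA")
  rq2 <- suppressMessages(quantify_rna(rna2, calls))
  expect_equal(rq2$proportion[rq2$name == "X3000.A.G"], 20 / 100)
})
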