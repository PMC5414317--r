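test_that("expression records aggregate replicates and define rho", {
  dna <- data.frame(name = rep("X1000.A.G", 2), replicate = 1:2,
                    proportion = c(0.25, 0.27))
  rna <- data.frame(name = rep("X1000.A.G", 2), replicate = 1:2,
                    proportion = c(0.00, 0.01), quantifiable = TRUE)
  rec <- build_expression_records(dna, rna)
  expect_equal(rec$dna_mean, 0.26)
  expect_equal(rec$rna_mean, 0.005)
  expect_equal(rec$rho, 0.005 / 0.26)
  expect_false(rec$single_replicate)
  # single replicate: SD 0 with a flag
  rec1 <- build_expression_records(dna[1, ], rna[1, ])
  expect_equal(rec1$dna_sd, 0)
  expect_true(rec1$single_replicate)
  # RNA never quantifiable: flagged, not zero-filled
  rna_na <- transform(rna, proportion = NA_real_, quantifiable = FALSE)
  rec2 <- build_expression_records(dna, rna_na)
  expect_false(rec2$quantifiable)
  expect_true(is.na(rec2$rho))
  # RNA-only variant is rejected
  rna_orphan <- data.frame(name = "X9.9.9", replicate = 1,
                           proportion = 0.5, quantifiable = TRUE)
  expect_message(rec3 <- build_expression_records(dna, rna_orphan),
                 "rejected")
  expect_false("X9.9.9" %in% rec3$name)
})

test_that("activity classification bands are correct and monotone in rho", {
  expect_identical(classify_activity(c(0.01, 0.3, 1.0, 2.5, NA)),
                   c("silenced", "partial", "expressed", "expressed", NA))
  # boundary semantics
  expect_identical(classify_activity(0.1), "partial")
  expect_identical(classify_activity(0.5), "expressed")
  # monotonicity: status order never decreases as rho rises
  rank <- c(silenced = 1L, partial = 2L, expressed = 3L)
  rho <- seq(0, 3, by = 0.01)
  expect_true(all(diff(rank[classify_activity(rho)]) >= 0))
})

test_that("dominance relations recover edges, co-dominance and contradictions", {
  panel <- data.frame(
    genotype_id = c("m261", "m261", "m170", "m170", "f1sc", "f1sc", "solo"),
    haplotype = c("No0.rDNA2", "Ler0.rDNA4", "No0.rDNA2", "Edi0.rDNA4",
                  "Sf2.rDNA4", "Col0.rDNA4", "X.rDNA2"),
    status = c("expressed", "silenced", "silenced", "expressed",
               "expressed", "expressed", "expressed"),
    stringsAsFactors = FALSE)
  rel <- dominance_relations(panel)
  expect_true(any(rel$edges$dominant == "No0.rDNA2" &
                    rel$edges$recessive == "Ler0.rDNA4"))
  expect_true(any(rel$edges$dominant == "Edi0.rDNA4" &
                    rel$edges$recessive == "No0.rDNA2"))
  expect_true(any(rel$codominant$hap1 == "Col0.rDNA4" &
                    rel$codominant$hap2 == "Sf2.rDNA4"))
  expect_length(rel$cycles, 0)
  # single-haplotype genotype contributes nothing
  expect_false("X.rDNA2" %in% c(rel$edges$dominant, rel$edges$recessive))
  # a contradiction is reported, not resolved
  contra <- rbind(panel[1:2, ],
                  data.frame(genotype_id = "w", haplotype = panel$haplotype[2:1],
                             status = c("expressed", "silenced")))
  expect_gt(length(dominance_relations(contra)$cycles), 0)
  # single genotype only -> empty relation
  empty <- dominance_relations(panel[panel$genotype_id == "solo", ])
  expect_equal(nrow(empty$edges), 0L)
})

test_that("dominance relations recover a generating hierarchy exactly, noise-free", {
  founders <- make_founders(4, ids = c("W", "X", "Y", "Z"), seed = 80)
  haps <- founder_haplotypes(founders)
  ranks <- c(W.rDNA2 = 4, X.rDNA2 = 2, Y.rDNA2 = 1, Z.rDNA2 = 0,
             W.rDNA4 = 0, X.rDNA4 = 3, Y.rDNA4 = 2, Z.rDNA4 = 1)
  rules <- rules_from_hierarchy(ranks)
  # panel of all heterozygous two-founder combinations, noise-free via
  # analytic fractions
  combos <- utils::combn(names(founders), 2)
  panel <- list()
  for (j in seq_len(ncol(combos))) {
    p <- combos[1, j]; q <- combos[2, j]
    g <- structure(list(id = paste0(p, q), design = "f1",
                        rdna2 = paste0(c(p, q), ".rDNA2"),
                        rdna4 = paste0(c(p, q), ".rDNA4"),
                        markers = data.frame(chrom = "chr1", pos = 1,
                                             geno = "H")),
                   class = "individual_genome")
    act <- apply_dominance(g, rules)
    ef <- expected_fractions(g, act, haps)
    for (hid in names(act)) {
      hv <- names(haps[[hid]]$composition)[1]
      row <- ef[ef$name == hv, ]
      rho <- ifelse(row$f_dna > 0, row$f_rna / row$f_dna, NA)
      panel[[length(panel) + 1L]] <- data.frame(
        genotype_id = g$id, haplotype = hid,
        status = classify_activity(rho), stringsAsFactors = FALSE)
    }
  }
  rel <- dominance_relations(do.call(rbind, panel))
  expect_length(rel$cycles, 0)
  # every strict rank pair that met in some genotype must be recovered
  edges <- unique(rel$edges[, c("dominant", "recessive")])
  for (j in seq_len(ncol(combos))) {
    ids <- c(paste0(combos[, j], ".rDNA2"), paste0(combos[, j], ".rDNA4"))
    top <- ids[which(ranks[ids] == max(ranks[ids]))]
    for (h1 in top) for (h2 in setdiff(ids, top)) {
      expect_true(any(edges$dominant == h1 & edges$recessive == h2),
                  info = paste(h1, ">", h2))
    }
  }
  # and no inverted edge may appear
  expect_true(all(ranks[edges$dominant] > ranks[edges$recessive]))
})

test_that("genotype class matrix counts cells and avoids NaN in empty cells", {
  set.seed(81)
  g2 <- sample(c("AA", "AB", "BB"), 40, replace = TRUE,
               prob = c(0.3, 0.5, 0.2))
  g4 <- rep("AA", 40)  # empty cells at AB/BB rows of locus 4
  g2[1] <- NA
  dna <- runif(40, 0.2, 0.4)
  rna <- runif(40, 0, 0.1)
  cm <- genotype_class_matrix(g2, g4, dna, rna)
  expect_equal(nrow(cm), 9L)
  expect_equal(sum(cm$n), 39L)
  expect_equal(attr(cm, "n_excluded"), 1L)
  empty <- cm[cm$geno4 != "AA", ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$rna_mean)))
  expect_false(any(is.nan(unlist(cm[, c("dna_mean", "rna_mean")]))))
})
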