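# Expression averaging, high-expression thresholding, structure weights and
# the presence-frequency statistic.

test_that("expression averaging collapses donors then probes", {
  rec <- data.frame(gene = "G1", probe = "p1", donor = c("d1", "d2"),
                    structure = "FL", z = c(0.2, 0.4))
  expect_equal(unname(average_expression(rec)["G1", "FL"]), 0.3)

  rec2 <- data.frame(gene = "G1", probe = c("p1", "p2"),
                     donor = c("d1", "d2"), structure = "FL", z = c(1, 1))
  expect_equal(unname(average_expression(rec2)["G1", "FL"]), 1)

  # random record set vs nested-loop oracle
  set.seed(8)
  rec3 <- expand.grid(gene = c("G1", "G2", "G3"), probe = c("p1", "p2"),
                      donor = c("d1", "d2", "d3"),
                      structure = c("FL", "HP"), stringsAsFactors = FALSE)
  rec3$z <- rnorm(nrow(rec3))
  got <- average_expression(rec3)
  for (g in unique(rec3$gene)) for (s in unique(rec3$structure)) {
    probe_means <- c()
    for (p in unique(rec3$probe)) {
      rows <- rec3$gene == g & rec3$probe == p & rec3$structure == s
      probe_means <- c(probe_means, mean(rec3$z[rows]))
    }
    expect_equal(unname(got[g, s]), mean(probe_means))
  }

  # unbalanced donor coverage is reported, not an error
  rec4 <- data.frame(gene = "G1", probe = c("p1", "p1", "p2"),
                     donor = c("d1", "d2", "d1"), structure = "FL",
                     z = c(0, 1, 5))
  expect_message(avg <- average_expression(rec4), "unbalanced")
  expect_equal(unname(avg["G1", "FL"]), mean(c(0.5, 5)))
})

test_that("high-expression calls use the 0.3 threshold on the packaged table", {
  z <- load_zscore_table()
  # canonical alias resolves to the printed row
  expect_identical(high_expression_regions(z, "MAPT"),
                   c("FL", "Ins", "CgG", "OL", "PL", "TL"))
  # HP sits at 0.29, just below the cut
  expect_false("HP" %in% high_expression_regions(z, "MART"))
  expect_identical(high_expression_regions(z, "MART", threshold = 10),
                   character(0))
  expect_length(high_expression_regions(z, "MART", threshold = -Inf), 18)
  expect_error(high_expression_regions(z, "NOPE"), "unknown gene")
  # monotone shrinkage with the threshold
  prev <- NULL
  for (thr in c(-1, 0, 0.3, 1, 2)) {
    cur <- high_expression_regions(z, "CLU", thr)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("structure weights count selected regions per structure", {
  w <- compute_structure_weights(load_region_list())
  expect_equal(sum(w), 20)
  expect_equal(unname(w[c("FL", "Ins", "CgG", "HP", "PHG", "PL", "Amy",
                          "GP", "Str")]),
               c(4L, 1L, 1L, 2L, 2L, 5L, 1L, 2L, 2L))
  expect_true(all(w[c("OL", "TL", "BF", "Cla", "ET", "HT", "ST", "DT", "VT")] == 0))

  # empty selection -> all-zero vector
  w0 <- compute_structure_weights(character(0))
  expect_true(all(w0 == 0))

  # many-to-many: one region under two structures increments both
  map2 <- data.frame(structure = c("FL", "PL"), region_name = "shared")
  w2 <- compute_structure_weights("shared", map2)
  expect_equal(unname(w2[c("FL", "PL")]), c(1L, 1L))
  expect_equal(sum(w2), 2)

  # unmapped selections warn and are reported
  expect_warning(w3 <- compute_structure_weights(c("Amygdala_L", "Mystery")),
                 "Mystery")
  expect_identical(attr(w3, "unmapped"), "Mystery")
})

test_that("presence frequency is the weighted dot product with documented properties", {
  z <- load_zscore_table()
  w <- compute_structure_weights(load_region_list())
  # all-zero weights -> 0 for every gene
  w0 <- setNames(rep(0, 18), colnames(z))
  expect_equal(presence_frequency(w0, z, "CLU"), 0)

  # random weights/Z vs a hand dot product on 4 structures
  set.seed(12)
  zr <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"),
                                               c("s1", "s2", "s3", "s4")))
  class(zr) <- c("expression_table", class(zr))
  wr <- setNames(sample(0:3, 4, replace = TRUE), colnames(zr))
  hand <- sum(wr[1] * zr["A", 1], wr[2] * zr["A", 2],
              wr[3] * zr["A", 3], wr[4] * zr["A", 4])
  expect_equal(presence_frequency(wr, zr, "A"), hand)

  # linearity in Z
  z2 <- zr; z2[] <- 3 * unclass(zr)
  expect_equal(presence_frequency(wr, z2, "A"),
               3 * presence_frequency(wr, zr, "A"))
  # additivity over disjoint weight vectors
  wa <- wr; wa[3:4] <- 0
  wb <- wr; wb[1:2] <- 0
  expect_equal(presence_frequency(wa, zr, "A") + presence_frequency(wb, zr, "A"),
               presence_frequency(wr, zr, "A"))
  # permutation invariance under a consistent column reordering
  perm <- c(3, 1, 4, 2)
  expect_equal(presence_frequency(wr[perm], zr, "A"),
               presence_frequency(wr, zr, "A"))

  # missing Z-scores contribute zero, with a warning
  wHit <- setNames(rep(1L, 18), colnames(z))
  expect_warning(f <- presence_frequency(wHit, z, "MAAD"), "missing")
  expect_equal(f, sum(z["MAAD", ], na.rm = TRUE))
})

test_that("gene ranking orders frequencies and resolves aliases", {
  z <- load_zscore_table()
  w <- compute_structure_weights(load_region_list())
  r <- suppressWarnings(rank_genes(z, w))
  expect_equal(nrow(r), 21)
  expect_identical(r$symbol[r$gene == "MART"], "MAPT")
  expect_true(all(diff(r$frequency) <= 0))

  # single-gene table
  z1 <- z[1, , drop = FALSE]
  class(z1) <- c("expression_table", class(z1))
  expect_equal(rank_genes(z1, w)$rank, 1)

  # weights concentrated on one structure reduce to that column's ranking
  wcol <- setNames(rep(0L, 18), colnames(z))
  wcol["GP"] <- 3L
  r2 <- suppressWarnings(rank_genes(z, wcol))
  want <- rownames(z)[order(-ifelse(is.na(z[, "GP"]), 0, z[, "GP"]),
                            rownames(z))]
  expect_identical(r2$gene, want)
})
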