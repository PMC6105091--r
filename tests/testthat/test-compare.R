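test_that("class codes follow the decision table on constructed cases", {
  r <- mk_tx("R", list(c(0, 100), c(200, 300), c(400, 500)), "+",
             gene_id = "GR")
  expect_equal(class_code(mk_tx("P", list(c(10, 100), c(200, 300), c(400, 480)),
                                "+"), r), "=")
  ## mono vs mono reciprocal >= 80%
  m <- mk_tx("RM", list(c(0, 100)), "+")
  expect_equal(class_code(mk_tx("P", list(c(5, 100)), "+"), m), "_")
  expect_equal(class_code(mk_tx("P", list(c(60, 160)), "+"), m), "o")
  ## n: prediction extends the reference chain
  expect_equal(class_code(
    mk_tx("P", list(c(0, 100), c(200, 300), c(400, 500), c(600, 700)), "+"), r),
    "n")
  ## truncation inside the reference exons is a contained fragment "c"
  expect_equal(class_code(mk_tx("P", list(c(0, 100), c(200, 300)), "+"), r), "c")
  ## truncation protruding into an intron is "J"
  expect_equal(class_code(mk_tx("P", list(c(0, 100), c(200, 350)), "+"), r), "J")
  ## j: shared junction, different chain
  expect_equal(class_code(mk_tx("P", list(c(0, 100), c(200, 320), c(400, 500)),
                                "+"), r), "j")
  ## mono prediction inside one reference exon
  expect_equal(class_code(mk_tx("P", list(c(210, 290)), "+"), r), "c")
  ## mono prediction straddling an exon boundary
  expect_equal(class_code(mk_tx("P", list(c(250, 350)), "+"), r), "e")
  ## multi prediction overlapping (but not containing) a mono reference
  expect_equal(class_code(mk_tx("P", list(c(0, 150), c(250, 400)), "+"),
                          mk_tx("RM2", list(c(20, 170)), "+")), "o")
  expect_equal(class_code(mk_tx("P", list(c(0, 150), c(250, 400)), "+"),
                          mk_tx("RM3", list(c(20, 150)), "+")), "C")
  ## antisense overlap
  expect_equal(class_code(mk_tx("P", list(c(50, 150)), "-"), r), "x")
  expect_equal(class_code(mk_tx("P", list(c(50, 150), c(250, 350)), "-"), r), "X")
  ## within an intron
  expect_equal(class_code(mk_tx("P", list(c(120, 180)), "+"), r), "i")
  expect_equal(class_code(mk_tx("P", list(c(110, 130), c(150, 190)), "+"), r),
               "I")
  ## flanking: downstream "p", upstream "P", far away "u"
  expect_equal(class_code(mk_tx("P", list(c(600, 700)), "+"), r), "p")
  expect_equal(class_code(mk_tx("P", list(c(600, 700)), "+"),
                          mk_tx("Rm", list(c(0, 100), c(200, 300), c(400, 500)),
                                "-")), "P")
  expect_equal(class_code(mk_tx("P", list(c(5000, 5100)), "+"), r), "u")
})

test_that("fusion predictions get the f, prefix", {
  ref <- annotation_set(list(
    mk_tx("R1", list(c(0, 100), c(200, 300)), "+", gene_id = "G1"),
    mk_tx("R2", list(c(600, 700), c(800, 900)), "+", gene_id = "G2")))
  idx <- build_reference_index(ref)
  fusion <- mk_tx("F", list(c(0, 100), c(200, 300), c(600, 700), c(800, 900)),
                  "+")
  row <- classify_prediction(fusion, idx)
  expect_match(row$class_code, "^f,")
  solo <- mk_tx("S", list(c(0, 100), c(200, 300)), "+")
  expect_false(grepl("^f,", classify_prediction(solo, idx)$class_code))
  ## an overlap of <= 10% of the shorter cDNA does not trigger the rule
  graze <- mk_tx("GZ", list(c(95, 100), c(200, 300), c(330, 350)), "+")
  expect_false(grepl("^f,", classify_prediction(graze, idx)$class_code))
})

test_that("the reference index answers overlap queries like a full scan", {
  set.seed(51)
  ref <- random_set(30, "R")
  idx <- build_reference_index(ref)
  for (rep in 1:40) {
    a <- sample.int(5900, 1L) - 1L; b <- a + sample.int(500, 1L)
    got <- sort(query_reference_index(idx, "chr1", a, b))
    want <- sort(names(Filter(function(t) {
      sp <- tx_span(t); sp[1L] < b && a < sp[2L]
    }, ref$transcripts)))
    expect_equal(got, want)
  }
  expect_length(query_reference_index(idx, "chrMissing", 0, 100), 0L)
})

test_that("a half-recovered reference gives the textbook 50/100/66.7", {
  ref <- annotation_set(list(
    mk_tx("R1", list(c(0, 100), c(200, 300)), "+", gene_id = "G1"),
    mk_tx("R2", list(c(1000, 1100), c(1200, 1300)), "+", gene_id = "G2")))
  pred <- annotation_set(list(mk_tx("P1", list(c(0, 100), c(200, 300)), "+")))
  st <- compare_run(ref, pred)$stats
  tx <- st[st$level == "transcript", ]
  expect_equal(tx$recall, 50)
  expect_equal(tx$precision, 100)
  expect_equal(tx$f1, 200 / 3, tolerance = 1e-9)
})

test_that("identity and disjointness give the boundary statistics", {
  set.seed(52)
  ref <- random_set(12, "R")
  same <- compare_run(ref, ref)$stats
  expect_true(all(abs(same$recall - 100) < 1e-9))
  expect_true(all(abs(same$precision - 100) < 1e-9))
  other <- random_set(6, "P", chrom_len = 5000L)
  shifted <- annotation_set(lapply(other$transcripts, function(t) {
    t$exons <- t$exons + 100000L
    t
  }))
  none <- compare_run(ref, shifted)$stats
  expect_true(all(none$f1 == 0))
})

test_that("compare_run matches the all-pairs brute-force oracle", {
  set.seed(53)
  for (rep in 1:4) {
    ref <- random_set(sample(5:12, 1), "R")
    pred <- random_set(sample(5:12, 1), "P")
    got <- compare_run(ref, pred)$stats
    want <- brute_stats(ref, pred)
    for (lv in rownames(want)) {
      expect_equal(got$recall[got$level == lv], unname(want[lv, "recall"]),
                   tolerance = 1e-9, label = paste(lv, "recall"))
      expect_equal(got$precision[got$level == lv], unname(want[lv, "precision"]),
                   tolerance = 1e-9, label = paste(lv, "precision"))
    }
  }
})

test_that("swapping reference and prediction swaps recall and precision", {
  set.seed(54)
  for (rep in 1:3) {
    a <- random_set(sample(4:10, 1), "A")
    b <- random_set(sample(4:10, 1), "B")
    ab <- compare_run(a, b)$stats
    ba <- compare_run(b, a)$stats
    expect_equal(ab$recall, ba$precision, tolerance = 1e-9)
    expect_equal(ab$precision, ba$recall, tolerance = 1e-9)
  }
})

test_that("each prediction contributes exactly one TMAP row", {
  set.seed(55)
  ref <- random_set(10, "R")
  pred <- random_set(8, "P")
  cmp <- compare_run(ref, pred)
  expect_equal(sort(cmp$tmap$prediction_id), sort(names(pred$transcripts)))
  expect_equal(sort(cmp$refmap$ref_id), sort(names(ref$transcripts)))
})

test_that("z-scores standardize per level with population sd", {
  m <- rbind(m1 = c(lvl = 10), m2 = c(lvl = 20), m3 = c(lvl = 30))
  z <- zscore_rank(m)
  expect_equal(z$zscore[z$method == "m3"], 1.2247, tolerance = 1e-4)
  expect_equal(z$zscore[z$method == "m2"], 0)
  expect_equal(z$zscore[z$method == "m1"], -1.2247, tolerance = 1e-4)
  expect_equal(z$rank, 1:3)
  expect_equal(sum(z$zscore), 0, tolerance = 1e-12)
  ## identical vectors: all zero; adding a constant changes nothing
  same <- rbind(a = c(x = 5, y = 7), b = c(x = 5, y = 7))
  expect_equal(zscore_rank(same)$zscore, c(0, 0))
  shifted <- m + 13
  expect_equal(zscore_rank(shifted)$zscore, z$zscore[order(z$method)][c(3, 2, 1)],
               tolerance = 1e-9)
  expect_error(zscore_rank(m[1, , drop = FALSE]), "two methods")
})

test_that("terminal UTR exons are trimmed to the allowed length", {
  ## 120 bp of UTR on the left terminal exon, max 50 -> 50 retained
  t <- mk_tx("T", list(c(0, 200), c(300, 500)), "+",
             cds = list(c(120, 200), c(300, 400)))
  tr <- trim_terminal_utr(t, max_utr = 50L)
  expect_equal(unname(tr$exons[1, ]), c(70L, 200L))
  ## right side: 100 bp UTR trimmed to 50
  expect_equal(unname(tr$exons[2, ]), c(300L, 450L))
  ## within bounds: unchanged
  t2 <- mk_tx("T2", list(c(0, 200)), "+", cds = list(c(30, 180)))
  expect_equal(trim_terminal_utr(t2, 50L)$exons, t2$exons)
  ## UTR-only terminal exon with CDS in the next exon shrinks from the
  ## CDS-proximal side
  t3 <- mk_tx("T3", list(c(0, 150), c(250, 400)), "+",
              cds = list(c(250, 400)))
  tr3 <- trim_terminal_utr(t3, 50L)
  expect_equal(unname(tr3$exons[1, ]), c(100L, 150L))
  ## no CDS: unchanged
  t4 <- mk_tx("T4", list(c(0, 500)), "+")
  expect_identical(trim_terminal_utr(t4, 50L), t4)
})

test_that("reconstructable transcripts need covered bases and junctions", {
  ref <- annotation_set(list(
    mk_tx("A", list(c(0, 100), c(200, 300)), "+", gene_id = "GA"),
    mk_tx("B", list(c(400, 500), c(600, 700)), "+", gene_id = "GB"),
    mk_tx("M", list(c(800, 900)), "+", gene_id = "GM")))
  coverage <- data.frame(chrom = "chr1",
                         start = c(0L, 200L, 400L, 600L, 800L),
                         end = c(100L, 300L, 500L, 700L, 900L), depth = 1L)
  junctions <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                          strand = "+")
  out <- reconstructable_filter(ref, coverage, junctions, max_utr = NULL)
  ## B's junction (500,600) is not detected; M has none and is covered
  expect_setequal(names(out$transcripts), c("A", "M"))
  ## un-covered internal bases exclude a transcript
  cov2 <- coverage[-1, ]
  out2 <- reconstructable_filter(ref, cov2, junctions, max_utr = NULL)
  expect_setequal(names(out2$transcripts), "M")
})
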