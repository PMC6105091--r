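test_that("superloci join flank-bridged spans and respect strand", {
  a <- mk_tx("A", list(c(0, 500)), "+")
  b <- mk_tx("B", list(c(650, 1000)), "+")   # 150 bp gap < 2 * flank
  sl <- build_superloci(list(a, b), flank = 200L)
  expect_length(sl, 1L)
  sl2 <- build_superloci(list(a, b), flank = 50L)
  expect_length(sl2, 2L)
  plus <- mk_tx("P", list(c(0, 100), c(200, 300)), "+")
  minus <- mk_tx("M", list(c(0, 100), c(200, 300)), "-")
  expect_length(build_superloci(list(plus, minus)), 2L)
  dot <- mk_tx("D", list(c(0, 300)), ".")
  expect_length(build_superloci(list(plus, dot)), 1L)
  expect_length(build_superloci(list(plus)), 1L)
})

test_that("subloci group by shared introns (multi) or overlap (mono)", {
  a <- mk_tx("A", list(c(0, 100), c(200, 300)), "+")
  b <- mk_tx("B", list(c(50, 100), c(200, 350)), "+")   # shares intron
  c_ <- mk_tx("C", list(c(0, 120), c(240, 300)), "+")   # overlaps, no shared
  sub <- build_subloci(list(a, b, c_))
  members <- lapply(sub, function(s) sort(vapply(s, `[[`, character(1), "id")))
  expect_true(list(c("A", "B")) %in% members)
  expect_true(list("C") %in% members)
  ## monoexonic inside another's intron: no exonic overlap, separate subloci
  mono_in <- mk_tx("MI", list(c(120, 180)), "+")
  mono_ov <- mk_tx("MO", list(c(150, 250)), "+")
  sub2 <- build_subloci(list(a, mono_in, mono_ov))
  m2 <- lapply(sub2, function(s) sort(vapply(s, `[[`, character(1), "id")))
  expect_true(list("A") %in% m2)
  expect_true(list(c("MI", "MO")) %in% m2)
})

test_that("chimera candidates split unless homology bridges the ORFs", {
  t <- mk_tx("F", list(c(0, 400), c(500, 900)), "+")   # cDNA 800
  orfs <- list(orf_record("F", 10, 310, has_start = TRUE, has_stop = TRUE),
               orf_record("F", 450, 750, has_start = TRUE, has_stop = TRUE))
  hit <- function(target, q1, q2)
    list(target = target, evalue = 1e-30, bitscore = 100,
         hsps = data.frame(qstart = q1, qend = q2, tstart = 0L,
                           tend = (q2 - q1) %/% 3L))
  distinct <- list(hit("P1", 10L, 310L), hit("P2", 450L, 750L))
  out <- detect_and_split_fusions(t, orfs, distinct)
  expect_true(out$split)
  expect_length(out$parts, 2L)
  expect_equal(vapply(out$parts, `[[`, character(1), "id"),
               c("F.split1", "F.split2"))
  ## split windows partition the cDNA at the midpoint (310+450)/2 = 380
  expect_equal(unname(out$parts[[1]]$exons), matrix(c(0L, 380L), ncol = 2))
  expect_equal(unname(out$parts[[2]]$exons),
               matrix(c(380L, 500L, 400L, 900L), ncol = 2))
  expect_equal(sum(out$parts[[1]]$cds[, 2] - out$parts[[1]]$cds[, 1]), 300L)
  ## a single protein spanning both ORFs vetoes the split
  bridging <- list(hit("P3", 10L, 750L))
  expect_false(detect_and_split_fusions(t, orfs, bridging)$split)
  ## one ORF: unchanged
  one <- detect_and_split_fusions(t, orfs[1], distinct)
  expect_false(one$split)
  expect_identical(one$parts[[1]], t)
})

test_that("fusion split respects the 0.2 coverage threshold", {
  t <- mk_tx("F", list(c(0, 1000)), "+")
  orfs <- list(orf_record("F", 0, 300), orf_record("F", 600, 900))
  hit <- function(q1, q2) list(target = "PX", evalue = 1e-20, bitscore = 50,
                               hsps = data.frame(qstart = q1, qend = q2,
                                                 tstart = 0L, tend = 100L))
  ## covers 100% of ORF1 but only 10% of ORF2: still a fusion
  weak <- list(hit(0L, 300L), hit(600L, 630L))
  expect_true(detect_and_split_fusions(t, orfs, weak)$split)
  ## 20% of each: vetoed
  strong <- list(hit(0L, 300L), hit(600L, 660L))
  expect_false(detect_and_split_fusions(t, orfs, strong)$split)
})

test_that("primary selection follows the greedy pruning rule", {
  ## chain A-B-C: A and C do not intersect, so both seed loci
  a <- mk_tx("A", list(c(0, 200)), "+")
  b <- mk_tx("B", list(c(150, 350)), "+")
  c_ <- mk_tx("C", list(c(300, 500)), "+")
  scores <- c(A = 10, B = 8, C = 6)
  loci <- select_primary(list(a, b, c_), scores)
  expect_equal(vapply(loci, function(l) l$primary$id, character(1)),
               c("A", "C"))
  ## all mutually overlapping: single locus with the top scorer
  all_ov <- list(mk_tx("X", list(c(0, 300)), "+"),
                 mk_tx("Y", list(c(100, 400)), "+"),
                 mk_tx("Z", list(c(200, 350)), "+"))
  loci2 <- select_primary(all_ov, c(X = 1, Y = 5, Z = 3))
  expect_length(loci2, 1L)
  expect_equal(loci2[[1]]$primary$id, "Y")
  ## disjoint: every transcript its own locus
  far <- list(mk_tx("P", list(c(0, 100)), "+"),
              mk_tx("Q", list(c(1000, 1100)), "+"))
  expect_length(select_primary(far, c(P = 1, Q = 2)), 2L)
})

test_that("primary selection equals the brute-force oracle on random graphs", {
  set.seed(41)
  for (rep in 1:120) {
    n <- sample(2:6, 1L)
    pairs <- utils::combn(n, 2L, simplify = FALSE)
    edges <- pairs[stats::runif(length(pairs)) < 0.4]
    models <- graph_to_models(n, edges)
    scores <- stats::setNames(round(stats::runif(n, 0, 100), 3),
                              vapply(models, `[[`, character(1), "id"))
    got <- vapply(select_primary(models, scores), function(l) l$primary$id,
                  character(1))
    expect_equal(got, greedy_oracle(models, scores))
  }
})

test_that("alternative splicing enforces ratio, redundancy and class codes", {
  cfg <- default_scoring_config()
  primary <- mk_tx("PRI", list(c(0, 200), c(300, 500), c(600, 800)), "+",
                   cds = list(c(50, 200), c(300, 500), c(600, 700)))
  primary$attributes[["has_start_codon"]] <- "TRUE"
  primary$attributes[["has_stop_codon"]] <- "TRUE"
  ## same-chain candidate: redundant
  twin <- mk_tx("TWIN", list(c(10, 200), c(300, 500), c(600, 790)), "+",
                cds = list(c(50, 200), c(300, 500), c(600, 700)))
  ## shares junctions but different chain (code j), decent structure
  alt <- mk_tx("ALT", list(c(0, 200), c(300, 450), c(600, 800)), "+",
               cds = list(c(50, 200), c(300, 450), c(600, 700)))
  alt$attributes[["has_start_codon"]] <- "TRUE"
  alt$attributes[["has_stop_codon"]] <- "TRUE"
  locus <- list(primary = primary, score = 10, members = "PRI")
  out <- add_alternative_splicing(locus, list(twin, alt), cfg)
  expect_true("ALT" %in% out$members)
  expect_false("TWIN" %in% out$members)
  ## a hopeless candidate (tiny CDS-less fragment, code j) fails the ratio
  weak <- mk_tx("WEAK", list(c(440, 450), c(600, 620)), "+")
  out2 <- add_alternative_splicing(locus, list(weak), cfg)
  expect_equal(out2$members, "PRI")
})

test_that("raising the AS score ratio never adds isoforms", {
  cfg_lo <- default_scoring_config()
  cfg_lo$as_rules$min_score_ratio <- 0.3
  cfg_hi <- default_scoring_config()
  cfg_hi$as_rules$min_score_ratio <- 0.9
  set.seed(43)
  primary <- mk_tx("PRI", list(c(0, 200), c(300, 500), c(600, 800)), "+",
                   cds = list(c(50, 200), c(300, 500), c(600, 700)))
  cands <- list(
    mk_tx("C1", list(c(0, 200), c(300, 470), c(600, 800)), "+",
          cds = list(c(50, 200), c(300, 470))),
    mk_tx("C2", list(c(0, 200), c(320, 500), c(600, 800)), "+"),
    mk_tx("C3", list(c(100, 200), c(300, 500), c(650, 800)), "+"))
  locus <- list(primary = primary, score = 10, members = "PRI")
  n_lo <- length(add_alternative_splicing(locus, cands, cfg_lo)$members)
  n_hi <- length(add_alternative_splicing(locus, cands, cfg_hi)$members)
  expect_gte(n_lo, n_hi)
})

test_that("the isoform cap limits accepted candidates", {
  cfg <- default_scoring_config()
  cfg$as_rules$max_isoforms <- 1L
  primary <- mk_tx("PRI", list(c(0, 200), c(300, 500), c(600, 800)), "+")
  cands <- list(mk_tx("C1", list(c(0, 200), c(300, 480), c(600, 800)), "+"),
                mk_tx("C2", list(c(20, 200), c(300, 500), c(650, 800)), "+"))
  cfg$as_rules$min_score_ratio <- 0
  out <- add_alternative_splicing(list(primary = primary, score = 5,
                                       members = "PRI"), cands, cfg)
  expect_lte(length(out$members) - 1L, 1L)
})

test_that("fragment loci are flagged against higher-scoring neighbors", {
  cfg <- scoring_config()  # no not_fragmentary exemption
  main <- mk_tx("MAIN", list(c(0, 200), c(800, 1000)), "+",
                cds = list(c(50, 200), c(800, 950)))
  intronic <- mk_tx("INTR", list(c(400, 600)), "+")    # inside MAIN's intron
  anti <- mk_tx("ANTI", list(c(100, 180)), "-")        # antisense overlap
  far <- mk_tx("FAR", list(c(9000, 9400)), "+")        # beyond max_distance
  loci <- list(list(primary = main, score = 10, members = "MAIN",
                    transcripts = list(main)),
               list(primary = intronic, score = 2, members = "INTR",
                    transcripts = list(intronic)),
               list(primary = anti, score = 1, members = "ANTI",
                    transcripts = list(anti)),
               list(primary = far, score = 1, members = "FAR",
                    transcripts = list(far)))
  cfg$pick$purge_fragments <- FALSE
  out <- flag_fragments(loci, cfg)
  flags <- stats::setNames(vapply(out, `[[`, logical(1), "fragment"),
                           vapply(out, function(l) l$primary$id, character(1)))
  expect_false(flags[["MAIN"]])
  expect_true(flags[["INTR"]])
  expect_true(flags[["ANTI"]])
  expect_false(flags[["FAR"]])
  cfg$pick$purge_fragments <- TRUE
  expect_length(flag_fragments(loci, cfg), 2L)
  ## not_fragmentary exemption rescues complete coding models
  cfg2 <- default_scoring_config()
  cfg2$pick$purge_fragments <- FALSE
  intronic2 <- intronic
  intronic2$cds <- matrix(c(420L, 580L), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  expect_false(is.null(cfg2$not_fragmentary))
})

test_that("pick_run passes a single valid transcript through unchanged", {
  t <- mk_tx("solo", list(c(0, 200), c(300, 500)), "+")
  res <- pick_run(annotation_set(list(t)))
  expect_length(res$set$transcripts, 1L)
  out <- res$set$transcripts[[1]]
  expect_equal(out$id, "solo")
  expect_equal(out$exons, t$exons)
  expect_equal(out$gene_id, "LOC_1")
})

test_that("requirement-failing transcripts are excluded everywhere", {
  cfg <- default_scoring_config()   # requires cdna_length >= 200
  short <- mk_tx("short", list(c(0, 150)), "+")
  ok <- mk_tx("ok", list(c(0, 250)), "+")
  res <- pick_run(annotation_set(list(short, ok)), config = cfg)
  expect_equal(names(res$set$transcripts), "ok")
  expect_true(any(res$log$id == "short" & res$log$action == "discard"))
})

test_that("selected primaries are pairwise non-intersecting", {
  set.seed(44)
  models <- lapply(1:15, function(i) random_tx(paste0("T", i), chrom_len = 4000L))
  names(models) <- vapply(models, `[[`, character(1), "id")
  res <- pick_run(annotation_set(models),
                  config = scoring_config(scoring = list(
                    cdna_length = list(rescaling = "max", multiplier = 1))))
  prim <- lapply(res$loci, `[[`, "primary")
  if (length(prim) > 1L) {
    for (i in seq_len(length(prim) - 1L)) for (j in (i + 1L):length(prim)) {
      ov <- txloom:::intersect_length(prim[[i]]$exons, prim[[j]]$exons)
      same <- prim[[i]]$chrom == prim[[j]]$chrom &&
        txloom:::strands_compatible(prim[[i]]$strand, prim[[j]]$strand)
      expect_false(ov > 0L && same)
    }
  }
  ## every output id traces to an input id
  expect_true(all(sub("\\.split[0-9]+$", "", names(res$set$transcripts)) %in%
                    names(models)))
})
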