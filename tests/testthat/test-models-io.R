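test_that("GTF exon rows are grouped and converted to 0-based half-open", {
  gtf <- c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";')
  set <- read_gtf(write_lines_tmp(gtf, ".gtf"))
  expect_length(set$transcripts, 1L)
  t1 <- set$transcripts[["T1"]]
  expect_equal(unname(t1$exons), matrix(c(100L, 300L, 200L, 400L), ncol = 2))
  expect_equal(unname(introns(t1)), matrix(c(200L, 300L), ncol = 2))
  expect_equal(t1$gene_id, "G1")
})

test_that("GTF CDS rows become cds segments inside exons", {
  gtf <- c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\tCDS\t151\t200\t.\t+\t0\tgene_id "G1"; transcript_id "T1";')
  t1 <- read_gtf(write_lines_tmp(gtf, ".gtf"))$transcripts[["T1"]]
  expect_equal(unname(t1$cds), matrix(c(150L, 200L), ncol = 2))
})

test_that("GTF parse failures name the offending line or transcript", {
  bad_cols <- write_lines_tmp("chr1\texon\t1\t10", ".gtf")
  expect_error(read_gtf(bad_cols), "line 1")
  bad_coord <- write_lines_tmp(
    'chr1\tsrc\texon\t200\t100\t.\t+\t.\tgene_id "G"; transcript_id "TX9";',
    ".gtf")
  expect_error(read_gtf(bad_coord), "TX9")
  empty <- write_lines_tmp(character(0), ".gtf")
  expect_length(read_gtf(empty)$transcripts, 0L)
})

test_that("GFF3 hierarchy resolves through ID/Parent", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=G1",
           "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=T1;Parent=G1",
           "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=T1",
           "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=T1")
  set <- read_gff3(write_lines_tmp(gff, ".gff3"))
  t1 <- set$transcripts[["T1"]]
  expect_equal(nrow(t1$exons), 2L)
  expect_equal(t1$gene_id, "G1")
})

test_that("multi-parent exons are duplicated per transcript", {
  gff <- c("chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=G1",
           "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=T1;Parent=G1",
           "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=T2;Parent=G1",
           "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=T1,T2",
           "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=T1")
  set <- read_gff3(write_lines_tmp(gff, ".gff3"))
  expect_equal(nrow(set$transcripts[["T1"]]$exons), 2L)
  expect_equal(unname(set$transcripts[["T2"]]$exons),
               matrix(c(0L, 100L), ncol = 2))
})

test_that("dangling Parent raises an error naming the orphan", {
  gff <- "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=missing_mrna"
  expect_error(read_gff3(write_lines_tmp(gff, ".gff3")), "missing_mrna")
})

test_that("CDS phases are preserved in attributes but ignored for structure", {
  gff <- c("chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=T1",
           "chr1\tsrc\texon\t1\t300\t.\t+\t.\tParent=T1",
           "chr1\tsrc\tCDS\t10\t150\t.\t+\t0\tParent=T1",
           "chr1\tsrc\tCDS\t151\t300\t.\t+\t2\tParent=T1")
  t1 <- read_gff3(write_lines_tmp(gff, ".gff3"))$transcripts[["T1"]]
  expect_equal(t1$attributes[["phase"]], "0,2")
  expect_equal(nrow(t1$cds), 2L)
})

test_that("BED12 blocks expand to exons and thick range to CDS", {
  line <- "chr1\t0\t250\tT1\t0\t+\t0\t0\t0\t2\t100,100\t0,150"
  t1 <- read_bed12(write_lines_tmp(line, ".bed"))$transcripts[["T1"]]
  expect_equal(unname(t1$exons), matrix(c(0L, 150L, 100L, 250L), ncol = 2))
  expect_equal(nrow(t1$cds), 0L)  # thickStart == thickEnd: non-coding

  coding <- "chr1\t100\t400\tT2\t0\t-\t150\t350\t0\t2\t100,150\t0,150"
  t2 <- read_bed12(write_lines_tmp(coding, ".bed"))$transcripts[["T2"]]
  expect_equal(unname(t2$cds), matrix(c(150L, 250L, 200L, 350L), ncol = 2))
})

test_that("BED12 block arithmetic inconsistent with chromEnd errors", {
  bad <- "chr1\t0\t240\tT1\t0\t+\t0\t0\t0\t2\t100,100\t0,150"
  expect_error(read_bed12(write_lines_tmp(bad, ".bed")), "arithmetic")
})

test_that("transcript-space BED12 yields ORF records with flags", {
  line <- "T1\t0\t400\tT1.orf1;has_stop\t0\t+\t10\t310\t0\t1\t400\t0"
  orfs <- read_bed12(write_lines_tmp(line, ".bed"), transcript_space = TRUE)
  expect_length(orfs, 1L)
  expect_equal(orfs[[1]]$start, 10L)
  expect_equal(orfs[[1]]$end, 310L)
  expect_true(orfs[[1]]$has_stop)
  expect_true(is.na(orfs[[1]]$has_start))
})

test_that("GFF3 writer round-trips structure, including '.' strands", {
  set <- annotation_set(list(
    mk_tx("A1", list(c(0, 100), c(200, 350)), "+", cds = list(c(50, 100), c(200, 280)),
          gene_id = "GA"),
    mk_tx("B1", list(c(500, 800)), "-", gene_id = "GB"),
    mk_tx("C1", list(c(900, 1000)), ".", gene_id = "GC")))
  path <- tempfile(fileext = ".gff3")
  write_gff3(set, path)
  back <- read_gff3(path)
  expect_equal(names(back$transcripts), names(set$transcripts))
  for (id in names(set$transcripts)) {
    expect_equal(back$transcripts[[id]]$exons, set$transcripts[[id]]$exons)
    expect_equal(back$transcripts[[id]]$cds, set$transcripts[[id]]$cds)
    expect_equal(back$transcripts[[id]]$strand, set$transcripts[[id]]$strand)
    expect_equal(back$transcripts[[id]]$gene_id, set$transcripts[[id]]$gene_id)
  }
  ## "." strand survives verbatim in the file
  expect_true(any(grepl("\t\\.\t\\.\tID=C1", readLines(path))))
})

test_that("written CDS phases follow the 5'->3' reading frame", {
  t_plus <- mk_tx("P", list(c(0, 100), c(200, 300)), "+",
                  cds = list(c(10, 100), c(200, 250)))
  # first CDS segment phase 0; 90 bases consumed -> next phase (3-90%%3)%%3=0
  expect_equal(txloom:::cds_phases(t_plus), c(0L, 0L))
  t_minus <- mk_tx("M", list(c(0, 100), c(200, 300)), "-",
                   cds = list(c(50, 100), c(200, 290)))
  # translation starts at the genomically last segment (90 bases -> phase 0),
  # second-in-frame segment gets (3 - 90 %% 3) %% 3 = 0
  expect_equal(txloom:::cds_phases(t_minus), c(0L, 0L))
  t_shift <- mk_tx("S", list(c(0, 100), c(200, 300)), "+",
                   cds = list(c(10, 99), c(200, 250)))
  expect_equal(txloom:::cds_phases(t_shift), c(0L, 1L))
})

test_that("project_to_genome matches hand-derived examples", {
  t_plus <- mk_tx("T", list(c(0, 100), c(200, 300)), "+")
  expect_equal(unname(project_to_genome(t_plus, 50, 150)),
               matrix(c(50L, 200L, 100L, 250L), ncol = 2))
  t_minus <- mk_tx("T", list(c(0, 100), c(200, 300)), "-")
  expect_equal(unname(project_to_genome(t_minus, 0, 100)),
               matrix(c(200L, 300L), ncol = 2))
  expect_equal(unname(project_to_genome(t_plus, 0, cdna_length(t_plus))),
               unname(t_plus$exons))
  expect_error(project_to_genome(t_plus, 0, 500), "outside")
})

test_that("project_to_genome agrees with the per-base brute-force map", {
  set.seed(11)
  for (i in 1:60) {
    t <- random_tx(paste0("R", i))
    map <- brute_cdna_map(t)
    len <- cdna_length(t)
    a <- sample.int(len, 1L) - 1L
    b <- sample((a + 1L):len, 1L)
    segs <- project_to_genome(t, a, b)
    covered <- unlist(lapply(seq_len(nrow(segs)), function(k)
      seq.int(segs[k, 1L], segs[k, 2L] - 1L)))
    expect_setequal(covered, map[(a + 1L):b])
    expect_equal(sum(segs[, 2L] - segs[, 1L]), b - a)
  }
})

test_that("genome_to_cdna inverts the brute-force map and NAs introns", {
  set.seed(12)
  for (i in 1:30) {
    t <- random_tx(paste0("G", i))
    map <- brute_cdna_map(t)
    expect_equal(genome_to_cdna(t, map), seq_along(map) - 1L)
    ii <- introns(t)
    if (nrow(ii))
      expect_true(is.na(genome_to_cdna(t, ii[1L, 1L])))
  }
})

test_that("cDNA extraction splices and reverse-complements", {
  genome <- mk_genome(chr1 = "AACC")
  expect_equal(extract_cdna(mk_tx("T", list(c(0, 4)), "+"), genome), "AACC")
  expect_equal(extract_cdna(mk_tx("T", list(c(0, 4)), "-"), genome), "GGTT")
  genome2 <- mk_genome(chr1 = "AACCG")
  expect_equal(extract_cdna(mk_tx("T", list(c(0, 2), c(3, 5)), "+"), genome2),
               "AACG")
  expect_error(extract_cdna(mk_tx("T", list(c(0, 10)), "+"), genome), "beyond")
})

test_that("cDNA length equals the sum of exon lengths for random models", {
  set.seed(13)
  genome <- mk_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 10000,
                                          replace = TRUE), collapse = ""))
  for (i in 1:20) {
    t <- random_tx(paste0("L", i))
    expect_equal(nchar(extract_cdna(t, genome)), cdna_length(t))
  }
})

test_that("transcript model invariants are enforced", {
  expect_error(mk_tx("T", list(c(10, 10))), "invalid exon")
  expect_error(mk_tx("T", list(c(0, 100), c(50, 150))), "overlapping")
  expect_error(mk_tx("T", list(c(0, 100)), cds = list(c(50, 150))),
               "not contained")
  expect_error(transcript_model("T", "chr1", "*",
                                matrix(c(0L, 10L), ncol = 2)), "strand")
  expect_error(annotation_set(list(mk_tx("X", list(c(0, 10))),
                                   mk_tx("X", list(c(20, 30))))), "duplicate")
})
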