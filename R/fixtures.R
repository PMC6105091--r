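## Seeded synthetic-data generator: toy genomes, truth annotations and
## assembler-like corrupted transcript sets, so the whole pipeline can be
## exercised and benchmarked without external data.

#' Specification for the synthetic fixture generator
#'
#' Genes carry canonical GT-AG (or reverse-complement) splice sites, an
#' ATG...stop ORF of at least 300 bp and 50 bp UTRs on both ends, so every
#' truth transcript passes the default hard requirements and the default
#' fragment exemption. Corruption rates emulate the error taxonomy of real
#' assemblers: chimeric fusion of neighboring genes, fragmentation,
#' retained introns, strand mislabeling, ragged terminal extension and
#' exact duplication.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param chrom_count,chrom_length number and length (bp) of chromosomes.
#' @param gene_count total genes, distributed round-robin over chromosomes.
#' @param isoform_prob probability that a gene with at least four exons
#'   carries a second, exon-skipping isoform.
#' @param assemblers labels of the simulated assemblies.
#' @param fusion,fragment,retained_intron,strand_error,terminal_extension,duplicate
#'   per-transcript corruption rates in `[0, 1]`, applied independently per
#'   assembler (at most one corruption per transcript per assembler).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, chrom_count = 2L, chrom_length = 50000L,
                         gene_count = 20L, isoform_prob = 0.4,
                         assemblers = c("asm1", "asm2", "asm3"),
                         fusion = 0, fragment = 0, retained_intron = 0,
                         strand_error = 0, terminal_extension = 0,
                         duplicate = 0) {
  rates <- c(fusion = fusion, fragment = fragment,
             retained_intron = retained_intron, strand_error = strand_error,
             terminal_extension = terminal_extension, duplicate = duplicate)
  if (any(rates < 0 | rates > 1)) stop("corruption rates must be in [0, 1]")
  if (sum(rates) > 1) stop("corruption rates must sum to at most 1")
  structure(list(seed = as.integer(seed), chrom_count = as.integer(chrom_count),
                 chrom_length = as.integer(chrom_length),
                 gene_count = as.integer(gene_count),
                 isoform_prob = isoform_prob, assemblers = assemblers,
                 rates = rates), class = "fixture_spec")
}

random_chrom <- function(len) sample(c("A", "C", "G", "T"), len, replace = TRUE)

## write `seq` (5'->3' transcript orientation) into the genome characters at
## the cDNA window starting at cdna_start of transcript t
plant_cdna <- function(chars, t, cdna_start, seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(seq, "")[[1]]
  for (i in seq_along(bases)) {
    g <- project_to_genome(t, cdna_start + i - 1L, cdna_start + i)[1L, 1L]
    chars[g + 1L] <- if (t$strand == "-") comp[[bases[i]]] else bases[i]
  }
  chars
}

#' Generate a synthetic genome and truth annotation
#'
#' @param spec a [fixture_spec()].
#' @return list with `genome` (DNAStringSet), `truth` ([annotation_set()])
#'   and `genes` (data.frame of gene id, chrom, strand, span).
#' @export
generate_truth <- function(spec) {
  set.seed(spec$seed)
  per_chrom <- ceiling(spec$gene_count / spec$chrom_count)
  chroms <- paste0("chr", seq_len(spec$chrom_count))
  genome_chars <- stats::setNames(
    lapply(chroms, function(ch) random_chrom(spec$chrom_length)), chroms)
  models <- list()
  gene_rows <- list()
  gene_n <- 0L
  for (ci in seq_along(chroms)) {
    pos <- sample(200:600, 1L)
    placed <- 0L
    while (placed < per_chrom && gene_n < spec$gene_count) {
      mono <- stats::runif(1) < 0.15
      n_ex <- if (mono) 1L else sample(2:5, 1L)
      ex_len <- if (mono) sample(400:600, 1L) else sample(150:300, n_ex, TRUE)
      if (sum(ex_len) < 400L) ex_len[n_ex] <- ex_len[n_ex] + (400L - sum(ex_len))
      ## CDS length (total - 100) must be a codon multiple
      rem <- (sum(ex_len) - 100L) %% 3L
      if (rem) ex_len[n_ex] <- ex_len[n_ex] + (3L - rem)
      in_len <- if (n_ex > 1L) sample(80:400, n_ex - 1L, TRUE) else integer(0)
      span <- sum(ex_len) + sum(in_len)
      if (pos + span + 600L > spec$chrom_length) break
      strand <- sample(c("+", "-"), 1L)
      starts <- pos + cumsum(c(0L, head_int(ex_len, -1L) + in_len))
      exons <- cbind(starts, starts + ex_len)
      gene_n <- gene_n + 1L; placed <- placed + 1L
      gid <- sprintf("G%02d", gene_n)
      total <- sum(ex_len)
      t1 <- transcript_model(id = paste0(gid, ".1"), gene_id = gid,
                             chrom = chroms[ci], strand = strand,
                             exons = exons,
                             cds = project_to_genome_stub(exons, strand, 50L, total - 50L),
                             source = "truth")
      ## plant splice sites, start and stop codons
  ii <- introns(t1)
      ch <- genome_chars[[chroms[ci]]]
      for (j in seq_len(nrow(ii))) {
        donor <- if (strand == "-") c("C", "T") else c("G", "T")
        acceptor <- if (strand == "-") c("A", "C") else c("A", "G")
        ch[(ii[j, 1L] + 1L):(ii[j, 1L] + 2L)] <- donor
        ch[(ii[j, 2L] - 1L):ii[j, 2L]] <- acceptor
      }
      ch <- plant_cdna(ch, t1, 50L, "ATG")
      ch <- plant_cdna(ch, t1, total - 53L, "TAA")
      genome_chars[[chroms[ci]]] <- ch
      models[[t1$id]] <- t1
      ## optional exon-skipping isoform for genes with >= 4 exons
      if (n_ex >= 4L && stats::runif(1) < spec$isoform_prob) {
        skip <- sample(2:(n_ex - 1L), 1L)
        ex2 <- exons[-skip, , drop = FALSE]
        total2 <- sum(ex2[, 2L] - ex2[, 1L])
        t2 <- transcript_model(id = paste0(gid, ".2"), gene_id = gid,
                               chrom = chroms[ci], strand = strand,
                               exons = ex2,
                               cds = project_to_genome_stub(ex2, strand, 50L, total2 - 50L),
                               source = "truth")
        models[[t2$id]] <- t2
      }
      gene_rows[[gid]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                     strand = strand, start = pos,
                                     end = pos + span, stringsAsFactors = FALSE)
      pos <- pos + span + sample(700:1800, 1L)
    }
  }
  if (gene_n < spec$gene_count)
    stop("infeasible packing: ", spec$gene_count, " genes do not fit in ",
         spec$chrom_count, " x ", spec$chrom_length, " bp (placed ",
         gene_n, ")")
  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, character(1), collapse = ""))
  names(genome) <- chroms
  list(genome = genome, truth = annotation_set(models),
       genes = do.call(rbind, gene_rows))
}

head_int <- function(x, n) utils::head(x, n)

## CDS segments for a cDNA window of a bare exon chain (before the model exists)
project_to_genome_stub <- function(exons, strand, cdna_start, cdna_end) {
  tmp <- transcript_model("tmp", "tmp", strand, exons)
  project_to_genome(tmp, cdna_start, cdna_end)
}

## strip CDS, as assembler outputs carry exon structure only
strip_cds <- function(t) {
  t$cds <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  t
}

#' Corrupt a truth annotation into assembler-like transcript sets
#'
#' Each simulated assembler re-emits every truth transcript, possibly
#' applying one corruption drawn from the spec's rates: `fusion` chains the
#' model with the first transcript of the nearest downstream gene on the
#' same strand (the intergenic gap becomes a non-canonical intron);
#' `fragment` keeps a random contiguous sub-chain (or truncates a
#' monoexonic model to 40-60 percent); `retained_intron` merges two
#' adjacent exons; `strand_error` flips the strand label only;
#' `terminal_extension` extends both terminal exons outward; `duplicate`
#' emits the model twice. Assembler models carry no CDS.
#'
#' @param truth a [generate_truth()] result.
#' @param spec the [fixture_spec()].
#' @return list with `sets` (named list of [annotation_set()] per assembler)
#'   and `log` (data.frame: assembler, source_id, new_id, type, partner_id).
#' @export
corrupt_models <- function(truth, spec) {
  set.seed(spec$seed + 1L)
  rates <- spec$rates
  cuts <- cumsum(rates)
  truth_models <- truth$truth$transcripts
  ## nearest downstream gene partner (same chrom & strand) for fusions
  genes <- truth$genes
  partner_of <- function(t) {
    g <- genes[genes$chrom == t$chrom & genes$strand == t$strand &
                 genes$start > tx_span(t)[2L], , drop = FALSE]
    if (!nrow(g)) return(NULL)
    gid <- g$gene_id[which.min(g$start)]
    truth_models[[paste0(gid, ".1")]]
  }
  sets <- list()
  log_rows <- list()
  note <- function(assembler, source_id, new_id, type, partner = "")
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(assembler = assembler, source_id = source_id, new_id = new_id,
                 type = type, partner_id = partner, stringsAsFactors = FALSE)
  for (a in spec$assemblers) {
    out <- list()
    for (t in truth_models) {
      u <- stats::runif(1)
      type <- names(cuts)[which(u < cuts)[1L]]
      if (is.na(type) || length(type) == 0L) type <- "clean"
      t2 <- strip_cds(t)
      t2$source <- a
      if (type == "fusion") {
        partner <- partner_of(t)
        if (is.null(partner)) type <- "clean" else {
          fused <- transcript_model(
            id = paste0(t$id, "_fus"), gene_id = paste0(t$gene_id, "_fus"),
            chrom = t$chrom, strand = t$strand,
            exons = rbind(t$exons, partner$exons), source = a)
          out[[fused$id]] <- fused
          note(a, t$id, fused$id, "fusion", partner$id)
          next
        }
      }
      if (type == "fragment") {
        k <- nrow(t2$exons)
        if (k == 1L) {
          w <- t2$exons[1L, 2L] - t2$exons[1L, 1L]
          keep <- as.integer(w * stats::runif(1, 0.4, 0.6))
          from_left <- stats::runif(1) < 0.5
          t2$exons <- if (from_left)
            cbind(t2$exons[1L, 1L], t2$exons[1L, 1L] + keep) else
            cbind(t2$exons[1L, 2L] - keep, t2$exons[1L, 2L])
        } else {
          nkeep <- sample(seq_len(k - 1L), 1L)
          i0 <- sample(seq_len(k - nkeep + 1L), 1L)
          t2$exons <- t2$exons[i0:(i0 + nkeep - 1L), , drop = FALSE]
        }
        t2$id <- paste0(t$id, "_frag")
      } else if (type == "retained_intron") {
        k <- nrow(t2$exons)
        if (k < 2L) type <- "clean" else {
          m <- sample(seq_len(k - 1L), 1L)
          merged <- c(t2$exons[m, 1L], t2$exons[m + 1L, 2L])
          t2$exons <- rbind(t2$exons[seq_len(m - 1L), , drop = FALSE],
                            matrix(merged, ncol = 2L),
                            t2$exons[seq(m + 2L, length.out = k - m - 1L), ,
                                     drop = FALSE])
          t2$id <- paste0(t$id, "_ri")
        }
      } else if (type == "strand_error") {
        t2 <- flip_strand(t2)
        t2$id <- paste0(t$id, "_str")
      } else if (type == "terminal_extension") {
        d1 <- sample(30:80, 1L); d2 <- sample(30:80, 1L)
        t2$exons[1L, 1L] <- max(0L, t2$exons[1L, 1L] - d1)
        t2$exons[nrow(t2$exons), 2L] <- t2$exons[nrow(t2$exons), 2L] + d2
        t2$id <- paste0(t$id, "_ext")
      } else if (type == "duplicate") {
        t2a <- t2; t2a$id <- paste0(t$id, "_dupA")
        t2b <- t2; t2b$id <- paste0(t$id, "_dupB")
        out[[t2a$id]] <- t2a; out[[t2b$id]] <- t2b
        note(a, t$id, t2a$id, "duplicate")
        note(a, t$id, t2b$id, "duplicate")
        next
      }
      t2 <- transcript_model(id = t2$id, gene_id = t2$gene_id, chrom = t2$chrom,
                             strand = t2$strand, exons = t2$exons, source = a)
      out[[t2$id]] <- t2
      note(a, t$id, t2$id, type)
    }
    sets[[a]] <- annotation_set(out)
  }
  list(sets = sets, log = do.call(rbind, log_rows))
}

## ORF of one source (truth) transcript mapped onto a corrupted model's cDNA
map_orf_onto <- function(model, source_tx, orf_index = 1L) {
  ## orientation: multiexonic strand errors are corrected in preparation,
  ## so evidence is generated against the true orientation
  m <- model
  mislabeled <- m$strand != source_tx$strand
  if (mislabeled && nrow(m$exons) > 1L) m$strand <- source_tx$strand
  cds_bases <- unlist(lapply(seq_len(nrow(source_tx$cds)), function(i)
    seq.int(source_tx$cds[i, 1L], source_tx$cds[i, 2L] - 1L)))
  mapped <- genome_to_cdna(m, cds_bases)
  hit <- !is.na(mapped)
  if (sum(hit) < 3L) return(NULL)
  lo <- min(mapped[hit]); hi <- max(mapped[hit]) + 1L
  cds_sorted <- sort(cds_bases)
  first3 <- if (source_tx$strand == "-")
    utils::tail(cds_sorted, 3L) else utils::head(cds_sorted, 3L)
  last3 <- if (source_tx$strand == "-")
    utils::head(cds_sorted, 3L) else utils::tail(cds_sorted, 3L)
  has_start <- all(!is.na(genome_to_cdna(m, first3)))
  has_stop <- all(!is.na(genome_to_cdna(m, last3)))
  strand <- "+"
  if (mislabeled && nrow(m$exons) == 1L) {
    ## monoexonic mislabel survives preparation: the ORF appears on the
    ## reverse strand of the stated cDNA
    len <- cdna_length(m)
    tmp <- lo; lo <- len - hi; hi <- len - tmp
    strand <- "-"
  }
  orf_record(transcript_id = model$id, start = lo, end = hi, strand = strand,
             has_start = has_start, has_stop = has_stop,
             orf_id = paste0(model$id, ".orf", orf_index))
}

#' Emit the evidence bundle for a corrupted fixture
#'
#' Produces the three evidence inputs of the integration pipeline, keyed by
#' the prepared transcript ids (`<assembler>.<transcript>`): the trusted
#' junction set (all truth introns), per-transcript ORFs (the truth CDS of
#' each source gene mapped onto the corrupted cDNA; fused models carry two
#' ORFs), protein homology hits (each ORF hits a per-gene synthetic protein,
#' so the two ORFs of a fusion hit two distinct proteins), and a coverage
#' table over the truth exons.
#'
#' @param truth a [generate_truth()] result.
#' @param corrupted a [corrupt_models()] result.
#' @return list with `junctions` (data.frame), `orfs` (named list of
#'   [orf_record()] lists), `hits` (named list), `coverage` (data.frame).
#' @export
emit_bundle <- function(truth, corrupted) {
  truth_models <- truth$truth$transcripts
  ## trusted junctions = deduplicated truth introns
  jrows <- list()
  for (t in truth_models) {
    ii <- introns(t)
    for (j in seq_len(nrow(ii)))
      jrows[[length(jrows) + 1L]] <- data.frame(
        chrom = t$chrom, start = ii[j, 1L], end = ii[j, 2L], strand = t$strand,
        stringsAsFactors = FALSE)
  }
  junctions <- if (length(jrows)) unique(do.call(rbind, jrows)) else
    empty_junctions()
  junctions <- junctions[order(junctions$chrom, junctions$start,
                               junctions$end, method = "radix"), ]
  rownames(junctions) <- NULL
  orfs <- list()
  hit_rows <- list()
  add_orf <- function(model, source_tx, idx) {
    o <- map_orf_onto(model, source_tx, idx)
    if (is.null(o)) return(invisible(NULL))
    orfs[[model$id]] <<- c(orfs[[model$id]], list(o))
    if (o$strand == "+") {
      gene <- source_tx$gene_id
      plen <- (cds_length(source_tx)) %/% 3L
      hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
        qid = model$id, tid = paste0("PROT_", gene), evalue = 1e-60,
        bitscore = round((o$end - o$start) * 1.8, 1),
        qstart = o$start + 1L, qend = o$end, tstart = 1L, tend = plen,
        stringsAsFactors = FALSE)
    }
    invisible(NULL)
  }
  log <- corrupted$log
  for (a in names(corrupted$sets)) {
    set <- corrupted$sets[[a]]
    for (t in set$transcripts) {
      entry <- log[log$assembler == a & log$new_id == t$id, , drop = FALSE]
      src <- truth_models[[entry$source_id[1L]]]
      prepared <- t
      prepared$id <- paste0(a, ".", t$id)
      add_orf(prepared, src, 1L)
      if (entry$type[1L] == "fusion") {
        partner <- truth_models[[entry$partner_id[1L]]]
        add_orf(prepared, partner, 2L)
      }
    }
  }
  ## coverage: every truth exonic base at depth 1
  cov <- list()
  by_chrom <- split(truth_models,
                    vapply(truth_models, `[[`, character(1), "chrom"))
  for (ch in names(by_chrom)) {
    m <- merge_intervals(do.call(rbind, lapply(by_chrom[[ch]], `[[`, "exons")))
    cov[[ch]] <- data.frame(chrom = ch, start = m[, 1L], end = m[, 2L],
                            depth = 1L, stringsAsFactors = FALSE)
  }
  hits_df <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  list(junctions = junctions, orfs = orfs, hits_table = hits_df,
       coverage = do.call(rbind, cov))
}

#' Write a complete synthetic fixture to a directory
#'
#' Generates truth, corrupted assemblies and the evidence bundle, and writes
#' them as plain-text files: `genome.fa`, `truth.gff3`, one
#' `<assembler>.gtf` each, `junctions.bed`, `orfs.bed12`, `homology.tsv`,
#' `coverage.bedgraph`, and `corruptions.tsv` (the truth table of applied
#' corruptions).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return list of the in-memory objects (`truth`, `corrupted`, `bundle`)
#'   plus `paths` (named list of file paths).
#' @export
make_fixture_bundle <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- generate_truth(spec)
  corrupted <- corrupt_models(truth, spec)
  bundle <- emit_bundle(truth, corrupted)
  paths <- list(genome = file.path(dir, "genome.fa"),
                truth = file.path(dir, "truth.gff3"),
                junctions = file.path(dir, "junctions.bed"),
                orfs = file.path(dir, "orfs.bed12"),
                homology = file.path(dir, "homology.tsv"),
                coverage = file.path(dir, "coverage.bedgraph"),
                corruptions = file.path(dir, "corruptions.tsv"))
  Biostrings::writeXStringSet(truth$genome, paths$genome, width = 70L)
  write_gff3(truth$truth, paths$truth)
  for (a in names(corrupted$sets)) {
    paths[[paste0("gtf_", a)]] <- file.path(dir, paste0(a, ".gtf"))
    write_gtf(corrupted$sets[[a]], paths[[paste0("gtf_", a)]])
  }
  ## junctions as BED6
  j <- bundle$junctions
  writeLines(sprintf("%s\t%d\t%d\tjunc%d\t0\t%s", j$chrom, j$start, j$end,
                     seq_len(nrow(j)), j$strand), paths$junctions)
  ## ORFs as transcript-space BED12 with explicit completeness tokens
  orf_lines <- character(0)
  for (qid in names(bundle$orfs)) {
    for (o in bundle$orfs[[qid]]) {
      ## cDNA length: recover from the ORF bound (genome-independent upper
      ## bound is not known here), so store the widest extent we know of
      len <- attr(o, "cdna_len") %||% o$end
      tokens <- c(o$orf_id,
                  if (isTRUE(o$has_start)) "has_start" else "no_start",
                  if (isTRUE(o$has_stop)) "has_stop" else "no_stop")
      orf_lines <- c(orf_lines, sprintf(
        "%s\t0\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d\t0",
        qid, len, paste(tokens, collapse = ";"), o$strand, o$start, o$end, len))
    }
  }
  writeLines(orf_lines, paths$orfs)
  ht <- bundle$hits_table
  hl <- c("qid\ttid\tevalue\tbitscore\tqstart\tqend\ttstart\ttend",
          if (!is.null(ht)) sprintf("%s\t%s\t%g\t%.1f\t%d\t%d\t%d\t%d",
                                    ht$qid, ht$tid, ht$evalue, ht$bitscore,
                                    ht$qstart, ht$qend, ht$tstart, ht$tend))
  writeLines(hl, paths$homology)
  cv <- bundle$coverage
  writeLines(sprintf("%s\t%d\t%d\t%d", cv$chrom, cv$start, cv$end, cv$depth),
             paths$coverage)
  data.table::fwrite(corrupted$log, paths$corruptions, sep = "\t")
  list(truth = truth, corrupted = corrupted, bundle = bundle, paths = paths)
}

#' Run the full integration pipeline on a synthetic fixture
#'
#' Convenience driver used for benchmarking and testing: writes the fixture
#' to `dir` (a temporary directory by default), runs preparation from the
#' assembler GTFs, builds the evidence store from the bundle files, runs
#' picking, and compares both the integrated annotation and every raw
#' assembler set against the truth.
#'
#' @param spec a [fixture_spec()].
#' @param config a [scoring_config()] (default [default_scoring_config()]).
#' @param dir working directory for intermediate files.
#' @return list with `fixture`, `prepared`, `store`, `picked`,
#'   `comparison` (pipeline vs truth), and `assembler_comparisons` (named
#'   list of per-assembler [compare_run()] results).
#' @export
run_fixture_pipeline <- function(spec, config = default_scoring_config(),
                                 dir = tempfile("fixture")) {
  fx <- make_fixture_bundle(spec, dir)
  inputs <- data.frame(
    path = vapply(spec$assemblers, function(a) fx$paths[[paste0("gtf_", a)]],
                  character(1)),
    label = spec$assemblers, strand_specific = TRUE,
    stringsAsFactors = FALSE)
  prepared <- prepare_run(inputs, fx$paths$genome,
                          out_gtf = file.path(dir, "prepared.gtf"),
                          out_fasta = file.path(dir, "prepared.fa"))
  cdna <- Biostrings::readDNAStringSet(file.path(dir, "prepared.fa"))
  store <- evidence_store(
    junctions = load_junctions(fx$paths$junctions),
    orfs = load_orfs(fx$paths$orfs, cdna = cdna)$orfs,
    hits = load_homology(fx$paths$homology))
  picked <- pick_run(prepared$set, store, config)
  comparison <- compare_run(fx$truth$truth, picked$set)
  assembler_comparisons <- lapply(fx$corrupted$sets, function(s)
    compare_run(fx$truth$truth, s))
  list(fixture = fx, prepared = prepared, store = store, picked = picked,
       comparison = comparison, assembler_comparisons = assembler_comparisons)
}
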