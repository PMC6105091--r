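## Reference-vs-prediction comparison: class codes, TMAP/REFMAP tables and
## multi-level accuracy statistics, plus the UTR-trim and reconstructable
## utilities used to build filtered reference sets.

intersect_length <- function(a, b) {
  ## total overlap between two interval matrices (0-based half-open)
  if (!NROW(a) || !NROW(b)) return(0L)
  total <- 0L
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L]); hi <- pmin(a[i, 2L], b[, 2L])
    total <- total + sum(pmax(0L, hi - lo))
  }
  total
}

intron_keys <- function(t) {
  m <- introns(t)
  if (!nrow(m)) character(0) else paste(m[, 1L], m[, 2L], sep = "-")
}

exon_keys <- function(t) paste(t$exons[, 1L], t$exons[, 2L], sep = "-")

## pairwise recall/precision at nucleotide, junction and exon level
pair_stats <- function(p, r) {
  nt_shared <- intersect_length(p$exons, r$exons)
  p_len <- cdna_length(p); r_len <- cdna_length(r)
  pj <- intron_keys(p); rj <- intron_keys(r)
  j_shared <- sum(pj %in% rj)
  pe <- exon_keys(p); re <- exon_keys(r)
  e_shared <- sum(pe %in% re)
  ratio <- function(num, den) if (den > 0) num / den else 0
  out <- list(
    n_recall = ratio(nt_shared, r_len), n_precision = ratio(nt_shared, p_len),
    j_recall = ratio(j_shared, length(rj)), j_precision = ratio(j_shared, length(pj)),
    e_recall = ratio(e_shared, length(re)), e_precision = ratio(e_shared, length(pe)))
  out$n_f1 <- f1(out$n_recall, out$n_precision)
  out$j_f1 <- f1(out$j_recall, out$j_precision)
  out
}

f1 <- function(recall, precision) {
  if (recall + precision == 0) 0 else 2 * recall * precision / (recall + precision)
}

## is `sub` a contiguous ordered sub-sequence of `full`?
is_contiguous_subchain <- function(sub, full) {
  if (!length(sub) || length(sub) > length(full)) return(FALSE)
  hit <- which(full == sub[1L])
  for (h in hit) {
    if (h + length(sub) - 1L <= length(full) &&
        all(full[h:(h + length(sub) - 1L)] == sub))
      return(TRUE)
  }
  FALSE
}

cds_intron_keys <- function(t) {
  if (nrow(t$cds) < 2L) return(character(0))
  n <- nrow(t$cds)
  paste(t$cds[-n, 2L], t$cds[-1L, 1L], sep = "-")
}

#' Structural class code of a prediction against one reference transcript
#'
#' One-symbol label describing the structural relation between a prediction
#' and a reference transcript. The decision table (a re-derivation of the
#' class codes popularized by cuffcompare/gffcompare-style tools) is, in
#' order of evaluation: `=` identical intron chain; `_` monoexonic vs
#' monoexonic with >= 80 percent reciprocal overlap; `n` prediction extends
#' the reference chain (reference chain is a contiguous sub-chain); `J`
#' prediction truncates it; `h` differing chains but identical, non-empty
#' CDS intron chains; `j` at least one shared junction; `c`/`C` exonic
#' containment of the prediction in the reference / vice versa (a truncated
#' chain wholly inside the reference exons is `c` rather than `J`);
#' `e`/`o` other exonic overlap (mono-vs-multi /
#' remaining); `x`/`X` overlap on the opposite strand (mono/multi
#' prediction); `i`/`I` prediction within reference introns (mono/multi);
#' `p`/`P` no overlap but within `flank` bp downstream/upstream of the
#' reference (in its strand orientation); `u` unrelated.
#'
#' @param p,r prediction and reference `tx_model`s.
#' @param flank distance in bp within which non-overlapping transcripts are
#'   classified `p`/`P` rather than `u` (default 1000).
#' @return a single-character class code.
#' @export
class_code <- function(p, r, flank = 1000L) {
  ps <- tx_span(p); rs <- tx_span(r)
  if (p$chrom != r$chrom) return("u")
  span_overlap <- ps[1L] < rs[2L] && rs[1L] < ps[2L]
  nt_shared <- if (span_overlap) intersect_length(p$exons, r$exons) else 0L
  p_mono <- nrow(p$exons) == 1L; r_mono <- nrow(r$exons) == 1L
  opposite <- p$strand %in% c("+", "-") && r$strand %in% c("+", "-") &&
    p$strand != r$strand
  if (nt_shared > 0L) {
    if (opposite) return(if (p_mono) "x" else "X")
    pj <- intron_keys(p); rj <- intron_keys(r)
    if (!p_mono && !r_mono) {
      if (length(pj) == length(rj) && all(pj == rj)) return("=")
      if (is_contiguous_subchain(rj, pj)) return("n")
      if (is_contiguous_subchain(pj, rj)) {
        ## truncated chain: contained fragments (no sequence outside the
        ## reference exons) are "c", truncations that still protrude are "J"
        if (nt_shared == cdna_length(p)) return("c")
        return("J")
      }
      pc <- cds_intron_keys(p); rc <- cds_intron_keys(r)
      if (length(pc) && length(pc) == length(rc) && all(pc == rc)) return("h")
      if (any(pj %in% rj)) return("j")
      p_len <- cdna_length(p); r_len <- cdna_length(r)
      if (nt_shared == p_len) return("c")
      if (nt_shared == r_len) return("C")
      return("o")
    }
    if (p_mono && r_mono) {
      p_len <- cdna_length(p); r_len <- cdna_length(r)
      if (nt_shared >= 0.8 * p_len && nt_shared >= 0.8 * r_len) return("_")
      return("o")
    }
    if (p_mono) {  # mono prediction vs multi reference
      if (nt_shared == cdna_length(p)) return("c")
      return("e")
    }
    ## multi prediction vs mono reference
    if (nt_shared == cdna_length(r)) return("C")
    return("o")
  }
  if (span_overlap) return(if (p_mono) "i" else "I")
  gap_right <- ps[1L] - rs[2L]  # prediction to the right of the reference
  gap_left <- rs[1L] - ps[2L]
  gap <- max(gap_right, gap_left)
  if (gap >= 0L && gap <= flank) {
    downstream <- if (r$strand == "-") gap_left >= 0L else gap_right >= 0L
    return(if (downstream) "p" else "P")
  }
  "u"
}

#' Build an overlap index of a reference annotation
#'
#' Wraps the reference transcript spans in an interval-tree backed container
#' so that all reference transcripts overlapping a query interval can be
#' retrieved in sublinear time.
#'
#' @param reference an [annotation_set()].
#' @return an object of class `reference_index`.
#' @export
build_reference_index <- function(reference) {
  ts <- reference$transcripts
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(ts, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(ts, function(t) tx_span(t)[1L] + 1L, integer(1)),
      end = vapply(ts, function(t) tx_span(t)[2L], integer(1))))
  gr$tx_id <- names(ts)
  structure(list(granges = gr, reference = reference), class = "reference_index")
}

#' Query a reference index
#'
#' @param index a [build_reference_index()] result.
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @return character vector of reference transcript ids overlapping the
#'   interval.
#' @export
query_reference_index <- function(index, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  ## queries on sequences absent from the reference legitimately return
  ## nothing; silence the seqlevel mismatch notice
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index$granges))
  index$granges$tx_id[S4Vectors::subjectHits(hits)]
}

#' Classify one prediction transcript against the reference
#'
#' Evaluates every overlapping reference transcript for nucleotide, junction
#' and exonic recall/precision, reports the best match (highest junction F1,
#' ties broken by nucleotide F1) as a TMAP row, and applies the fusion rule:
#' when the prediction intersects at least one transcript from each of two
#' or more reference genes -- sharing a junction with it or overlapping more
#' than 10 percent of the shorter of the two cDNAs -- the class code is
#' prefixed with `"f,"`.
#'
#' @param p a prediction `tx_model`.
#' @param index a [build_reference_index()] of the reference.
#' @param flank flank for `p`/`P` classification (default 1000).
#' @return one-row data.frame (TMAP row).
#' @export
classify_prediction <- function(p, index, flank = 1000L) {
  sp <- tx_span(p)
  cand_ids <- query_reference_index(index, p$chrom, max(0L, sp[1L] - flank),
                                    sp[2L] + flank)
  ref <- index$reference
  row <- function(gene, tid, code, st)
    data.frame(prediction_id = p$id, ref_gene = gene, ref_id = tid,
               class_code = code,
               n_recall = 100 * st$n_recall, n_precision = 100 * st$n_precision,
               j_recall = 100 * st$j_recall, j_precision = 100 * st$j_precision,
               e_recall = 100 * st$e_recall, e_precision = 100 * st$e_precision,
               stringsAsFactors = FALSE)
  empty_stats <- list(n_recall = 0, n_precision = 0, j_recall = 0,
                      j_precision = 0, e_recall = 0, e_precision = 0,
                      n_f1 = 0, j_f1 = 0)
  if (!length(cand_ids)) return(row("-", "-", "u", empty_stats))
  cands <- ref$transcripts[cand_ids]
  stats <- lapply(cands, pair_stats, p = p)
  codes <- vapply(cands, class_code, character(1), p = p, flank = flank)
  jf1 <- vapply(stats, `[[`, numeric(1), "j_f1")
  nf1 <- vapply(stats, `[[`, numeric(1), "n_f1")
  best <- order(-jf1, -nf1, cand_ids)[1L]
  ## if nothing overlaps at all, the best candidate is only flank-proximal
  pj <- intron_keys(p)
  fused_genes <- character(0)
  for (k in seq_along(cands)) {
    r <- cands[[k]]
    shared_j <- any(intron_keys(r) %in% pj)
    nt <- intersect_length(p$exons, r$exons)
    shorter <- min(cdna_length(p), cdna_length(r))
    if (shared_j || nt > 0.1 * shorter)
      fused_genes <- union(fused_genes, r$gene_id)
  }
  code <- codes[best]
  if (length(fused_genes) >= 2L && !code %in% c("p", "P", "u", "x", "X", "i", "I"))
    code <- paste0("f,", code)
  row(cands[[best]]$gene_id, cand_ids[best], code, stats[[best]])
}

## transcript-level full match: identical intron chain for multiexonic,
## >= 80% reciprocal overlap among monoexonic
transcript_match <- function(p, r) {
  if (!strands_compatible(p$strand, r$strand) || p$chrom != r$chrom)
    return(FALSE)
  p_mono <- nrow(p$exons) == 1L; r_mono <- nrow(r$exons) == 1L
  if (p_mono != r_mono) return(FALSE)
  if (!p_mono) {
    pj <- intron_keys(p); rj <- intron_keys(r)
    return(length(pj) == length(rj) && all(pj == rj))
  }
  nt <- intersect_length(p$exons, r$exons)
  nt >= 0.8 * cdna_length(p) && nt >= 0.8 * cdna_length(r)
}

## base-level totals: merged exonic bases per (chrom, strand); shared bases
## counted from the 'from' side against strand-compatible intervals of 'to'
base_level <- function(from, to) {
  merged_by_cs <- function(set) {
    keys <- paste(vapply(set$transcripts, `[[`, character(1), "chrom"),
                  vapply(set$transcripts, `[[`, character(1), "strand"))
    out <- list()
    for (k in unique(keys)) {
      exs <- do.call(rbind, lapply(set$transcripts[keys == k], `[[`, "exons"))
      out[[k]] <- merge_intervals(exs)
    }
    out
  }
  fm <- merged_by_cs(from); tm <- merged_by_cs(to)
  total <- sum(vapply(fm, function(m) sum(m[, 2L] - m[, 1L]), numeric(1)))
  shared <- 0
  for (k in names(fm)) {
    cs <- strsplit(k, " ", fixed = TRUE)[[1]]
    compatible <- names(tm)[vapply(names(tm), function(k2) {
      cs2 <- strsplit(k2, " ", fixed = TRUE)[[1]]
      cs2[1L] == cs[1L] && strands_compatible(cs[2L], cs2[2L])
    }, logical(1))]
    if (!length(compatible)) next
    target <- merge_intervals(do.call(rbind, tm[compatible]))
    shared <- shared + intersect_length(fm[[k]], target)
  }
  list(total = total, shared = shared)
}

## unique feature keys at exon / intron / intron-chain level, plus a matcher
## tolerant of "." strands
feature_level <- function(from, to, keyfun) {
  strip <- function(keys) sub("^[^|]*\\|.\\|", "", keys)  # not used; keys carry strand
  fk <- unique(unlist(lapply(from$transcripts, keyfun)))
  tk <- unlist(lapply(to$transcripts, keyfun))
  tk <- unique(tk)
  ## keys are "chrom|strand|payload"; match payload with strand compatibility
  split_key <- function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
               strand = vapply(parts, `[[`, character(1), 2L),
               payload = vapply(parts, function(x) paste(x[-(1:2)], collapse = "|"),
                                character(1)),
               stringsAsFactors = FALSE)
  }
  if (!length(fk)) return(list(total = 0L, shared = 0L))
  f <- split_key(fk)
  if (!length(tk)) return(list(total = nrow(f), shared = 0L))
  t2 <- split_key(tk)
  shared <- 0L
  for (i in seq_len(nrow(f))) {
    hit <- t2$chrom == f$chrom[i] & t2$payload == f$payload[i] &
      strands_compatible(f$strand[i], t2$strand)
    if (any(hit)) shared <- shared + 1L
  }
  list(total = nrow(f), shared = shared)
}

exon_level_keys <- function(t)
  paste(t$chrom, t$strand, exon_keys(t), sep = "|")

intron_level_keys <- function(t) {
  k <- intron_keys(t)
  if (!length(k)) return(character(0))
  paste(t$chrom, t$strand, k, sep = "|")
}

chain_level_keys <- function(t) {
  k <- intron_keys(t)
  if (!length(k)) return(character(0))
  paste(t$chrom, t$strand, paste(k, collapse = ","), sep = "|")
}

#' Compare a prediction annotation against a reference
#'
#' Produces the TMAP table (one row per prediction transcript with its best
#' reference match and class code), the REFMAP table (one row per reference
#' transcript with its best prediction), and accuracy statistics -- recall,
#' precision and F1 percentages -- at base, exon, intron, intron-chain,
#' transcript and gene level. Recall is the percentage of reference features
#' correctly predicted; precision is the percentage of predicted features
#' matching the reference.
#'
#' @param reference,prediction [annotation_set()]s.
#' @param flank flank for `p`/`P` classification (default 1000).
#' @return list with `tmap`, `refmap` (data.frames) and `stats` (data.frame
#'   with columns level, recall, precision, f1; percentages).
#' @export
compare_run <- function(reference, prediction, flank = 1000L) {
  index <- build_reference_index(reference)
  tmap <- do.call(rbind, lapply(prediction$transcripts, classify_prediction,
                                index = index, flank = flank))
  if (is.null(tmap))
    tmap <- data.frame(prediction_id = character(0), ref_gene = character(0),
                       ref_id = character(0), class_code = character(0))
  rownames(tmap) <- NULL
  ## refmap: best prediction per reference transcript
  pred_index <- build_reference_index(prediction)
  refmap <- do.call(rbind, lapply(reference$transcripts, function(r) {
    sp <- tx_span(r)
    cand_ids <- query_reference_index(pred_index, r$chrom, sp[1L], sp[2L])
    if (!length(cand_ids))
      return(data.frame(ref_id = r$id, ref_gene = r$gene_id, best_prediction = "-",
                        class_code = "u", j_f1 = 0, n_f1 = 0,
                        stringsAsFactors = FALSE))
    cands <- prediction$transcripts[cand_ids]
    stats <- lapply(cands, pair_stats, r = r)
    jf1 <- vapply(stats, `[[`, numeric(1), "j_f1")
    nf1 <- vapply(stats, `[[`, numeric(1), "n_f1")
    best <- order(-jf1, -nf1, cand_ids)[1L]
    data.frame(ref_id = r$id, ref_gene = r$gene_id,
               best_prediction = cand_ids[best],
               class_code = class_code(cands[[best]], r, flank = flank),
               j_f1 = 100 * jf1[best], n_f1 = 100 * nf1[best],
               stringsAsFactors = FALSE)
  }))
  rownames(refmap) <- NULL
  ## multi-level statistics
  pct <- function(x, n) if (n > 0) 100 * x / n else 0
  levels <- list()
  b_rec <- base_level(reference, prediction)   # from reference side: recall
  b_pre <- base_level(prediction, reference)   # from prediction side: precision
  levels$base <- c(recall = pct(b_rec$shared, b_rec$total),
                   precision = pct(b_pre$shared, b_pre$total))
  for (lv in c("exon", "intron", "intron_chain")) {
    keyfun <- switch(lv, exon = exon_level_keys, intron = intron_level_keys,
                     intron_chain = chain_level_keys)
    rec <- feature_level(reference, prediction, keyfun)
    pre <- feature_level(prediction, reference, keyfun)
    levels[[lv]] <- c(recall = pct(rec$shared, rec$total),
                      precision = pct(pre$shared, pre$total))
  }
  ## transcript level
  match_any <- function(t, other_set, other_index) {
    sp <- tx_span(t)
    cand_ids <- query_reference_index(other_index, t$chrom, sp[1L], sp[2L])
    any(vapply(other_set$transcripts[cand_ids], transcript_match, logical(1),
               r = t))
  }
  ref_matched <- vapply(reference$transcripts, match_any, logical(1),
                        other_set = prediction, other_index = pred_index)
  pred_matched <- vapply(prediction$transcripts, match_any, logical(1),
                         other_set = reference, other_index = index)
  levels$transcript <- c(recall = pct(sum(ref_matched), length(ref_matched)),
                         precision = pct(sum(pred_matched), length(pred_matched)))
  ## gene level: a gene is matched when any of its transcripts is
  ref_genes <- gene_ids(reference); pred_genes <- gene_ids(prediction)
  ref_gene_hit <- tapply(ref_matched, ref_genes, any)
  pred_gene_hit <- tapply(pred_matched, pred_genes, any)
  levels$gene <- c(recall = pct(sum(ref_gene_hit), length(ref_gene_hit)),
                   precision = pct(sum(pred_gene_hit), length(pred_gene_hit)))
  stats <- data.frame(
    level = names(levels),
    recall = vapply(levels, `[[`, numeric(1), "recall"),
    precision = vapply(levels, `[[`, numeric(1), "precision"),
    stringsAsFactors = FALSE)
  stats$f1 <- mapply(function(r, p) 100 * f1(r / 100, p / 100),
                     stats$recall, stats$precision)
  rownames(stats) <- NULL
  list(tmap = tmap, refmap = refmap, stats = stats)
}

#' Write comparison outputs to files
#'
#' Emits `PREFIX.tmap.tsv`, `PREFIX.refmap.tsv` and `PREFIX.stats.txt` (one
#' line per level with recall/precision/F1 to two decimals).
#'
#' @param result a [compare_run()] result.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_compare_result <- function(result, prefix) {
  tmap_path <- paste0(prefix, ".tmap.tsv")
  refmap_path <- paste0(prefix, ".refmap.tsv")
  stats_path <- paste0(prefix, ".stats.txt")
  data.table::fwrite(result$tmap, tmap_path, sep = "\t")
  data.table::fwrite(result$refmap, refmap_path, sep = "\t")
  lines <- sprintf("%-13s recall: %6.2f%%  precision: %6.2f%%  F1: %6.2f%%",
                   result$stats$level, result$stats$recall,
                   result$stats$precision, result$stats$f1)
  writeLines(lines, stats_path)
  invisible(c(tmap_path, refmap_path, stats_path))
}

#' Rank competing methods by cumulative z-score of their F1 values
#'
#' For every accuracy level the F1 values of all methods are standardized
#' (population standard deviation; a zero deviation yields zero z-scores);
#' the cumulative z-score of a method is the sum over levels, and methods
#' are ranked by descending cumulative score.
#'
#' @param f1_by_method named list (or matrix with methods as rows) of
#'   per-level F1 vectors; at least two methods.
#' @return data.frame with method, cumulative z-score, and rank.
#' @export
zscore_rank <- function(f1_by_method) {
  if (is.list(f1_by_method)) f1_by_method <- do.call(rbind, f1_by_method)
  if (nrow(f1_by_method) < 2L)
    stop("z-scores are undefined for fewer than two methods")
  z <- apply(f1_by_method, 2L, function(v) {
    s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))  # population sd
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  cumulative <- rowSums(z)
  out <- data.frame(method = rownames(f1_by_method), zscore = cumulative,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$zscore, out$method), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Trim terminal UTR exons of a transcript
#'
#' Shortens the UTR portion of each terminal exon from the outer end until
#' it is at most `max_utr` bp or the CDS begins, leaving internal exons
#' untouched. Transcripts without CDS are returned unchanged.
#'
#' @param t a `tx_model`.
#' @param max_utr maximum UTR length retained on a terminal exon (bp,
#'   default 50).
#' @return the trimmed `tx_model`.
#' @export
trim_terminal_utr <- function(t, max_utr = 50L) {
  if (!nrow(t$cds)) return(t)
  cds_lo <- min(t$cds[, 1L]); cds_hi <- max(t$cds[, 2L])
  n <- nrow(t$exons)
  ## left terminal exon
  left_utr_end <- min(t$exons[1L, 2L], cds_lo)
  if (left_utr_end - t$exons[1L, 1L] > max_utr)
    t$exons[1L, 1L] <- left_utr_end - max_utr
  ## right terminal exon
  right_utr_start <- max(t$exons[n, 1L], cds_hi)
  if (t$exons[n, 2L] - right_utr_start > max_utr)
    t$exons[n, 2L] <- right_utr_start + max_utr
  t
}

#' Filter a reference down to reconstructable transcripts
#'
#' A transcript is reconstructable when all of its splice junctions (if
#' any) appear in the detected junction set and every exonic base is
#' covered by at least one read. Terminal UTRs are trimmed first (see
#' [trim_terminal_utr()]) to discount the expected coverage drop at
#' transcript ends.
#'
#' @param reference an [annotation_set()].
#' @param coverage data.frame of covered regions (`chrom`, `start`, `end`,
#'   optionally `depth`; 0-based half-open bedgraph convention); rows with
#'   depth 0 are ignored.
#' @param junctions detected junction data.frame as from [load_junctions()].
#' @param max_utr terminal-UTR trim applied before the coverage test
#'   (default 50; `NULL` skips trimming).
#' @return the filtered (and trimmed) [annotation_set()].
#' @export
reconstructable_filter <- function(reference, coverage, junctions,
                                   max_utr = 50L) {
  if (!is.null(max_utr))
    reference <- annotation_set(lapply(reference$transcripts,
                                       trim_terminal_utr, max_utr = max_utr))
  if (!"depth" %in% names(coverage)) coverage$depth <- 1
  coverage <- coverage[coverage$depth >= 1, , drop = FALSE]
  cov_by_chrom <- split(coverage, coverage$chrom)
  cov_merged <- lapply(cov_by_chrom, function(d)
    merge_intervals(cbind(d$start, d$end)))
  keep <- vapply(reference$transcripts, function(t) {
    vi <- verify_introns(t, junctions)
    if (vi[1L] < vi[2L]) return(FALSE)
    cm <- cov_merged[[t$chrom]]
    if (is.null(cm)) return(FALSE)
    covered <- intersect_length(t$exons, cm)
    covered == cdna_length(t)
  }, logical(1))
  annotation_set(reference$transcripts[keep])
}
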