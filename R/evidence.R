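## Stage 2: load trusted junctions, ORFs and homology hits into a unified
## evidence store and attach evidence to transcripts.

#' Construct an ORF record
#'
#' An open reading frame located on a transcript's cDNA (0-based half-open
#' coordinates; position 0 is the transcript 5' end).
#'
#' @param transcript_id id of the transcript the ORF lies on.
#' @param start,end ORF interval on the cDNA.
#' @param strand strand relative to the cDNA (`"+"` or `"-"`).
#' @param has_start,has_stop logical (or `NA` when undetermined): whether the
#'   ORF begins with a start codon / ends with a stop codon.
#' @param orf_id optional identifier of the ORF itself.
#' @return an object of class `orf_record`.
#' @export
orf_record <- function(transcript_id, start, end, strand = "+",
                       has_start = NA, has_stop = NA, orf_id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start) stop("invalid ORF interval [", start, ",", end, ")")
  if (end - start < 3L) stop("ORF shorter than 3 nt")
  structure(list(transcript_id = as.character(transcript_id),
                 start = start, end = end, strand = strand,
                 has_start = has_start, has_stop = has_stop,
                 orf_id = orf_id %||% paste0(transcript_id, ".orf")),
            class = "orf_record")
}

#' Construct an evidence store
#'
#' Bundles the three evidence types consumed during picking: trusted
#' junctions, per-transcript ORFs, and per-transcript homology hits.
#' Lookups for unknown transcript ids return empty results, never fail.
#'
#' @param junctions data.frame of trusted introns (`chrom`, `start`, `end`,
#'   `strand`), as returned by [load_junctions()].
#' @param orfs named list mapping transcript id to a list of [orf_record()]s.
#' @param hits named list mapping transcript id to a list of homology hits.
#' @return an object of class `evidence_store`.
#' @export
evidence_store <- function(junctions = empty_junctions(), orfs = list(),
                           hits = list()) {
  structure(list(junctions = junctions, orfs = orfs, hits = hits),
            class = "evidence_store")
}

empty_junctions <- function()
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)

#' @export
print.evidence_store <- function(x, ...) {
  cat(sprintf("<evidence_store> %d junctions, ORFs for %d transcripts, hits for %d\n",
              nrow(x$junctions), length(x$orfs), length(x$hits)))
  invisible(x)
}

store_orfs_for <- function(store, id) store$orfs[[id]] %||% list()
store_hits_for <- function(store, id) store$hits[[id]] %||% list()

#' Save / load an evidence store
#'
#' Persists the store to a single file; loading restores every record
#' bit-exactly.
#' @param store an [evidence_store()].
#' @param path file path.
#' @return `path` (save) or the restored store (load).
#' @export
save_store <- function(store, path) {
  saveRDS(store, path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  store <- readRDS(path)
  if (!inherits(store, "evidence_store")) stop("not an evidence store: ", path)
  store
}

#' Load trusted splice junctions from a BED file
#'
#' Accepts BED6 rows (the interval is the intron itself) or BED12 rows (the
#' gaps between consecutive blocks are the introns). The result is a
#' deduplicated set; strandless rows (`.`) are kept and later match introns
#' on either strand.
#'
#' @param path BED file of trusted introns.
#' @return data.frame (`chrom`, `start`, `end`, `strand`), 0-based half-open.
#' @export
load_junctions <- function(path) {
  parsed <- read_tab_rows(path, 3L, "BED")
  rows <- list()
  for (k in seq_along(parsed$fields)) {
    f <- parsed$fields[[k]]
    strand <- if (length(f) >= 6L) f[6L] else "."
    if (length(f) >= 12L) {
      rec <- parse_bed12_line(f, parsed$lineno[k], path)
      n <- nrow(rec$exons)
      if (n < 2L) next
      for (j in seq_len(n - 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = rec$chrom, start = rec$exons[j, 2L],
          end = rec$exons[j + 1L, 1L], strand = strand,
          stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[1L], start = as.integer(f[2L]), end = as.integer(f[3L]),
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_junctions())
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$chrom, out$start, out$end, out$strand, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Load ORFs from a transcript-space BED12 or GFF3 file
#'
#' All ORFs of each transcript are retained (sorted by cDNA start) so that
#' multi-ORF transcripts can later be examined as chimera candidates. ORFs
#' on the reverse strand of the cDNA are dropped by default: the preparation
#' stage has already oriented transcripts, so a reverse ORF indicates a
#' conflict rather than usable coding evidence. Completeness flags left
#' undetermined by the file are resolved against the cDNA sequence when
#' `cdna` is supplied (start codon `ATG` at the ORF start, stop codon in the
#' last three bases).
#'
#' @param path transcript-space BED12 (see [read_bed12()]) or GFF3 whose
#'   seqid column holds transcript ids and whose CDS rows delimit ORFs.
#' @param cdna optional DNAStringSet (or FASTA path) of cDNA sequences, used
#'   to validate intervals and resolve completeness flags.
#' @param keep_reverse keep reverse-strand ORFs instead of dropping them.
#' @return list with `orfs` (named list id -> list of [orf_record()]) and
#'   `dropped` (data.frame of rejected records and reasons).
#' @export
load_orfs <- function(path, cdna = NULL, keep_reverse = FALSE) {
  ext <- tolower(tools::file_ext(path))
  records <- if (ext %in% c("bed", "bed12")) {
    read_bed12(path, transcript_space = TRUE)
  } else {
    read_orf_gff3(path)
  }
  if (!is.null(cdna)) cdna <- as_genome(cdna)
  dropped <- list()
  kept <- list()
  for (r in records) {
    if (r$strand == "-" && !keep_reverse) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(transcript_id = r$transcript_id, orf_id = r$orf_id,
                   reason = "reverse_strand", stringsAsFactors = FALSE)
      next
    }
    if (!is.null(cdna) && r$transcript_id %in% names(cdna)) {
      len <- length(cdna[[r$transcript_id]])
      if (r$end > len) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(transcript_id = r$transcript_id, orf_id = r$orf_id,
                     reason = "exceeds_cdna_length", stringsAsFactors = FALSE)
        next
      }
      seq <- cdna[[r$transcript_id]]
      if (is.na(r$has_start))
        r$has_start <- as.character(
          Biostrings::subseq(seq, r$start + 1L, r$start + 3L)) == "ATG"
      if (is.na(r$has_stop))
        r$has_stop <- as.character(
          Biostrings::subseq(seq, r$end - 2L, r$end)) %in% c("TAA", "TAG", "TGA")
    }
    kept[[r$transcript_id]] <- c(kept[[r$transcript_id]], list(r))
  }
  kept <- lapply(kept, function(lst)
    lst[order(vapply(lst, `[[`, integer(1), "start"))])
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(transcript_id = character(0), orf_id = character(0),
               reason = character(0))
  list(orfs = kept, dropped = dropped)
}

read_orf_gff3 <- function(path) {
  parsed <- read_tab_rows(path, 9L, "GFF3")
  recs <- list()
  for (k in seq_along(parsed$fields)) {
    f <- parsed$fields[[k]]
    if (f[3L] != "CDS") next
    attrs <- parse_gff3_attributes(f[9L])
    se <- check_coords(f[4L], f[5L], parsed$lineno[k], path)
    id <- attrs[["ID"]] %||% attrs[["Parent"]] %||% paste0(f[1L], ".orf", k)
    recs[[length(recs) + 1L]] <- orf_record(
      transcript_id = f[1L], start = se[1L] - 1L, end = se[2L],
      strand = f[7L], orf_id = id)
  }
  recs
}

#' Load protein homology hits from a tabular digest
#'
#' Consumes a TSV with columns `qid`, `tid`, `evalue`, `bitscore`, `qstart`,
#' `qend`, `tstart`, `tend` (coordinates 1-based inclusive in the file, as
#' printed by BLAST/DIAMOND tabular output). Rows are grouped into hits by
#' (query, target); each hit aggregates its HSPs. Hits are sorted by
#' ascending e-value, then descending bit score.
#'
#' @param path TSV file; a header line starting with `qid` is allowed.
#' @return named list mapping query transcript id to a list of hits; each
#'   hit is a list with `target`, `evalue`, `bitscore`, and `hsps` (a
#'   data.frame of `qstart`, `qend` on cDNA and `tstart`, `tend` on the
#'   protein, 0-based half-open).
#' @export
load_homology <- function(path) {
  parsed <- read_tab_rows(path, 8L, "homology TSV")
  hits <- list()
  for (k in seq_along(parsed$fields)) {
    f <- parsed$fields[[k]]
    if (f[1L] == "qid") next
    ev <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(ev))
      stop("non-numeric e-value at line ", parsed$lineno[k], " of ", path)
    if (ev < 0) stop("negative e-value at line ", parsed$lineno[k], " of ", path)
    key <- paste(f[1L], f[2L], sep = "\r")
    hsp <- data.frame(qstart = as.integer(f[5L]) - 1L, qend = as.integer(f[6L]),
                      tstart = as.integer(f[7L]) - 1L, tend = as.integer(f[8L]))
    if (is.null(hits[[key]])) {
      hits[[key]] <- list(query = f[1L], target = f[2L], evalue = ev,
                          bitscore = as.numeric(f[4L]), hsps = hsp)
    } else {
      hits[[key]]$hsps <- rbind(hits[[key]]$hsps, hsp)
      hits[[key]]$evalue <- min(hits[[key]]$evalue, ev)
      hits[[key]]$bitscore <- max(hits[[key]]$bitscore, as.numeric(f[4L]))
    }
  }
  out <- list()
  for (h in hits) out[[h$query]] <- c(out[[h$query]], list(h[-1L]))
  lapply(out, function(lst) {
    ev <- vapply(lst, `[[`, numeric(1), "evalue")
    bs <- vapply(lst, `[[`, numeric(1), "bitscore")
    lst[order(ev, -bs)]
  })
}

#' Count verified introns of a transcript
#'
#' An intron is verified when it is present in the trusted junction set;
#' strandless junctions match an intron on either strand.
#'
#' @param t a `tx_model`.
#' @param junctions trusted junction data.frame ([load_junctions()]) or an
#'   [evidence_store()].
#' @return integer vector `c(verified, total)`.
#' @export
verify_introns <- function(t, junctions) {
  if (inherits(junctions, "evidence_store")) junctions <- junctions$junctions
  ii <- introns(t)
  if (!nrow(ii)) return(c(verified = 0L, total = 0L))
  j <- junctions[junctions$chrom == t$chrom &
                   (junctions$strand == "." | t$strand == "." |
                      junctions$strand == t$strand), , drop = FALSE]
  ok <- vapply(seq_len(nrow(ii)), function(i)
    any(j$start == ii[i, 1L] & j$end == ii[i, 2L]), logical(1))
  c(verified = sum(ok), total = nrow(ii))
}

#' Assign ORFs to a transcript
#'
#' The primary ORF is the longest on the cDNA (ties broken 5'-most); its
#' projection onto the genome becomes the transcript's CDS. The number of
#' ORFs that do not overlap the primary on the cDNA (the primary included)
#' is recorded as the internal ORF count, the signal used downstream to flag
#' chimera candidates.
#'
#' @param t a `tx_model`.
#' @param orfs list of [orf_record()]s for `t` (cDNA coordinates).
#' @return `t` with updated `cds`, plus attributes `number_internal_orfs`,
#'   `has_start_codon`, `has_stop_codon`.
#' @export
assign_orfs <- function(t, orfs) {
  if (!length(orfs)) {
    t$cds <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    t$attributes[["number_internal_orfs"]] <- "0"
    return(t)
  }
  lens <- vapply(orfs, function(o) o$end - o$start, integer(1))
  starts <- vapply(orfs, `[[`, integer(1), "start")
  primary <- orfs[[order(-lens, starts)[1L]]]
  t$cds <- project_to_genome(t, primary$start, primary$end)
  disjoint <- vapply(orfs, function(o)
    o$end <= primary$start || o$start >= primary$end, logical(1))
  t$attributes[["number_internal_orfs"]] <- as.character(1L + sum(disjoint))
  t$attributes[["has_start_codon"]] <- as.character(isTRUE(primary$has_start))
  t$attributes[["has_stop_codon"]] <- as.character(isTRUE(primary$has_stop))
  t
}
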