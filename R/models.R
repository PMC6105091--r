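#' Construct a transcript model
#'
#' A transcript model is the basic unit handled by the package: one assembled
#' transcript with its exon chain, an optional coding region, a source label
#' identifying the originating assembly, and free-form attributes. All
#' coordinates are stored 0-based, half-open; readers and writers convert
#' to/from the 1-based inclusive conventions of GTF/GFF3 at the boundary.
#'
#' @param id unique transcript identifier.
#' @param chrom chromosome (sequence) name.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param exons two-column matrix (start, end) of exon intervals, 0-based
#'   half-open. Rows are sorted by start and must not overlap.
#' @param cds optional two-column matrix of CDS segments; every segment must
#'   be contained in an exon.
#' @param gene_id parent gene identifier (defaults to `id`).
#' @param source label of the originating assembly/sample.
#' @param score optional numeric score carried over from the input file.
#' @param attributes named list of character attributes, preserved verbatim.
#' @return an object of class `tx_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, cds = NULL,
                             gene_id = id, source = "", score = NA_real_,
                             attributes = list()) {
  exons <- as_interval_matrix(exons)
  if (nrow(exons) == 0L) stop("transcript '", id, "' has no exons")
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", id, "' has an invalid exon interval (end <= start)")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript '", id, "' has overlapping exons")
  if (!strand %in% c("+", "-", ".")) stop("invalid strand '", strand, "'")
  cds <- if (is.null(cds) || NROW(cds) == 0L) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    as_interval_matrix(cds)
  }
  if (nrow(cds)) {
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1))
    if (!all(contained))
      stop("transcript '", id, "': CDS segment not contained in any exon")
  }
  structure(list(
    id = as.character(id), gene_id = as.character(gene_id),
    source = as.character(source), chrom = as.character(chrom),
    strand = strand, exons = exons, cds = cds,
    score = as.numeric(score), attributes = attributes
  ), class = "tx_model")
}

as_interval_matrix <- function(x) {
  m <- matrix(as.integer(round(as.matrix(x))), ncol = 2L)
  colnames(m) <- c("start", "end")
  m
}

#' @export
print.tx_model <- function(x, ...) {
  cat(sprintf("<tx_model %s> %s:%d-%d(%s) exons=%d cds=%d cdna=%dbp\n",
              x$id, x$chrom, tx_span(x)[1L] + 1L, tx_span(x)[2L], x$strand,
              nrow(x$exons), nrow(x$cds), cdna_length(x)))
  invisible(x)
}

#' Total exonic (cDNA) length of a transcript
#' @param t a `tx_model`.
#' @return integer, sum of exon lengths.
#' @export
cdna_length <- function(t) sum(t$exons[, 2L] - t$exons[, 1L])

#' Intron intervals of a transcript
#'
#' Introns are the gaps between consecutive exons, in genomic coordinates
#' (0-based half-open). Monoexonic transcripts yield a zero-row matrix.
#' @param t a `tx_model`.
#' @return two-column integer matrix (start, end).
#' @export
introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
}

#' Genomic span of a transcript
#' @param t a `tx_model`.
#' @return integer vector `c(start, end)` covering all exons.
#' @export
tx_span <- function(t) c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L])

cds_length <- function(t) if (nrow(t$cds)) sum(t$cds[, 2L] - t$cds[, 1L]) else 0L

## canonical string forms used for deduplication / chain identity
exon_chain_key <- function(t)
  paste(t$chrom, t$strand, paste(t$exons[, 1L], t$exons[, 2L], sep = "-",
                                 collapse = ","), sep = "|")

intron_chain_key <- function(t) {
  ii <- introns(t)
  paste(t$chrom, t$strand,
        paste(ii[, 1L], ii[, 2L], sep = "-", collapse = ","), sep = "|")
}

## strand compatibility used across clustering and comparison ("." joins either)
strands_compatible <- function(a, b) a == b | a == "." | b == "."

#' Construct an annotation set
#'
#' A container of transcript models keyed by id, with gene-to-transcript
#' grouping. Ordering is deterministic: (chrom, start, end, id).
#'
#' @param transcripts list of `tx_model` objects.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts = list()) {
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  transcripts <- sort_models(transcripts)
  structure(list(transcripts = transcripts), class = "annotation_set")
}

sort_models <- function(transcripts) {
  if (!length(transcripts)) return(transcripts)
  chrom <- vapply(transcripts, `[[`, character(1), "chrom")
  start <- vapply(transcripts, function(t) tx_span(t)[1L], integer(1))
  end   <- vapply(transcripts, function(t) tx_span(t)[2L], integer(1))
  ids   <- vapply(transcripts, `[[`, character(1), "id")
  transcripts[order(chrom, start, end, ids, method = "radix")]
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcripts, %d genes, %d sequences\n",
              length(x$transcripts), length(unique(gene_ids(x))),
              length(unique(vapply(x$transcripts, `[[`, character(1), "chrom")))))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$transcripts)

gene_ids <- function(set) vapply(set$transcripts, `[[`, character(1), "gene_id")

#' Group transcripts of an annotation set by gene
#' @param set an `annotation_set`.
#' @return named list mapping gene id to character vector of transcript ids.
#' @export
genes_of <- function(set) {
  split(names(set$transcripts), gene_ids(set))
}

#' Project a cDNA interval onto the genome
#'
#' Maps an interval on the transcript (cDNA, 0-based half-open; position 0 is
#' the transcript 5' end, so for minus-strand transcripts it corresponds to
#' the genomically last exon base) to the genomic exon-clipped segments it
#' covers. The summed length of the result equals the interval length.
#'
#' @param t a `tx_model`.
#' @param cdna_start,cdna_end interval on the cDNA, 0-based half-open.
#' @return two-column integer matrix of genomic segments, sorted by start.
#' @export
project_to_genome <- function(t, cdna_start, cdna_end) {
  len <- cdna_length(t)
  if (cdna_start < 0 || cdna_end > len || cdna_start >= cdna_end)
    stop("cDNA interval [", cdna_start, ",", cdna_end,
         ") outside transcript of length ", len)
  widths <- t$exons[, 2L] - t$exons[, 1L]
  n <- nrow(t$exons)
  ## cumulative cDNA offset of each exon in 5'->3' order
  ord <- if (t$strand == "-") rev(seq_len(n)) else seq_len(n)
  offs <- cumsum(c(0L, widths[ord]))[seq_len(n)]
  segs <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    lo <- max(cdna_start, offs[k]); hi <- min(cdna_end, offs[k] + widths[i])
    if (lo >= hi) next
    if (t$strand == "-") {
      ## cDNA offset 'offs[k]' is the genomically last base of exon i
      g_end <- t$exons[i, 2L] - (lo - offs[k])
      g_start <- t$exons[i, 2L] - (hi - offs[k])
      segs[[k]] <- c(g_start, g_end)
    } else {
      segs[[k]] <- c(t$exons[i, 1L] + (lo - offs[k]), t$exons[i, 1L] + (hi - offs[k]))
    }
  }
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(segs))
    segs <- matrix(integer(0), ncol = 2L)
  segs <- matrix(as.integer(segs), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  segs[order(segs[, 1L]), , drop = FALSE]
}

#' Map genomic positions to cDNA coordinates
#'
#' Inverse of [project_to_genome()] at single-base resolution: for each
#' genomic position (0-based) returns the cDNA offset, or `NA` for positions
#' not covered by an exon.
#' @param t a `tx_model`.
#' @param positions integer vector of 0-based genomic positions.
#' @return integer vector of cDNA offsets (0-based), `NA` where intronic or
#'   outside the transcript.
#' @export
genome_to_cdna <- function(t, positions) {
  widths <- t$exons[, 2L] - t$exons[, 1L]
  n <- nrow(t$exons)
  ord <- if (t$strand == "-") rev(seq_len(n)) else seq_len(n)
  offs <- integer(n)
  offs[ord] <- cumsum(c(0L, widths[ord]))[seq_len(n)]
  out <- rep(NA_integer_, length(positions))
  for (i in seq_len(n)) {
    hit <- positions >= t$exons[i, 1L] & positions < t$exons[i, 2L]
    if (!any(hit)) next
    out[hit] <- if (t$strand == "-") {
      offs[i] + (t$exons[i, 2L] - 1L - positions[hit])
    } else {
      offs[i] + (positions[hit] - t$exons[i, 1L])
    }
  }
  out
}

#' Extract the cDNA sequence of a transcript
#'
#' Concatenates the exon sequences (5' to 3'; reverse-complemented for
#' minus-strand transcripts) from a genome.
#'
#' @param t a `tx_model`.
#' @param genome a [Biostrings::DNAStringSet] (names are chromosome names) or
#'   path to a FASTA file.
#' @return a character scalar of length `cdna_length(t)`.
#' @export
extract_cdna <- function(t, genome) {
  genome <- as_genome(genome)
  if (!t$chrom %in% names(genome))
    stop("chromosome '", t$chrom, "' not present in genome")
  chrlen <- length(genome[[t$chrom]])
  if (any(t$exons[, 2L] > chrlen))
    stop("transcript '", t$id, "' extends beyond end of '", t$chrom, "'")
  parts <- Biostrings::extractAt(
    genome[[t$chrom]],
    IRanges::IRanges(start = t$exons[, 1L] + 1L, end = t$exons[, 2L]))
  seq <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (t$strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path")
  ## names may carry FASTA descriptions; keep first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}
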