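## Readers and writers for GTF / GFF3 / BED12. All conversion between the
## 1-based inclusive file conventions and the package's 0-based half-open
## internal coordinates happens here, and only here.

read_tab_rows <- function(path, ncol_expected, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep))
    return(list(fields = list(), lineno = integer(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < ncol_expected)
  if (length(bad))
    stop("malformed ", what, " row at line ", keep[bad[1L]], " of ", path,
         ": expected ", ncol_expected, " tab-separated columns, found ",
         lengths(fields)[bad[1L]])
  list(fields = fields, lineno = keep)
}

parse_gtf_attributes <- function(s) {
  ## key "value"; pairs (tolerates unquoted values)
  parts <- regmatches(s, gregexpr('(\\w+)\\s+(("[^"]*")|([^;]+))', s))[[1]]
  out <- list()
  for (p in parts) {
    key <- sub("\\s.*$", "", p)
    val <- sub("^\\S+\\s+", "", p)
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

parse_gff3_attributes <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2L) next
    out[[trimws(p[1L])]] <- utils::URLdecode(paste(p[-1L], collapse = "="))
  }
  out
}

check_coords <- function(start, end, lineno, path) {
  s <- suppressWarnings(as.integer(start)); e <- suppressWarnings(as.integer(end))
  if (is.na(s) || is.na(e))
    stop("malformed coordinates at line ", lineno, " of ", path,
         ": '", start, "'-'", end, "'")
  c(s, e)
}

build_models_from_rows <- function(rows, default_source) {
  ## rows: list of per-transcript accumulators
  models <- lapply(rows, function(r) {
    ex <- do.call(rbind, r$exons)
    transcript_model(
      id = r$id, gene_id = r$gene_id, source = r$source %||% default_source,
      chrom = r$chrom, strand = r$strand,
      exons = ex, cds = if (length(r$cds)) do.call(rbind, r$cds) else NULL,
      score = r$score %||% NA_real_, attributes = r$attributes %||% list())
  })
  annotation_set(models)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a GTF file
#'
#' Transcripts are reconstructed from `exon` (and optional `CDS`) feature
#' rows grouped by `transcript_id`; a `transcript` feature row is not
#' required. 1-based inclusive file coordinates are converted to the 0-based
#' half-open internal convention.
#'
#' @param path path to a GTF file.
#' @param source label recorded on every transcript (defaults to the GTF
#'   source column of the first exon row of each transcript).
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path, source = NULL) {
  parsed <- read_tab_rows(path, 9L, "GTF")
  rows <- list()
  for (k in seq_along(parsed$fields)) {
    f <- parsed$fields[[k]]; lineno <- parsed$lineno[k]
    type <- f[3L]
    if (!type %in% c("exon", "CDS")) next
    se <- check_coords(f[4L], f[5L], lineno, path)
    attrs <- parse_gtf_attributes(f[9L])
    tid <- attrs[["transcript_id"]]
    if (is.null(tid))
      stop("GTF row at line ", lineno, " of ", path, " lacks transcript_id")
    if (se[2L] < se[1L])
      stop("feature with end < start in transcript '", tid,
           "' (line ", lineno, " of ", path, ")")
    iv <- c(se[1L] - 1L, se[2L])
    if (is.null(rows[[tid]])) {
      keep_attrs <- attrs[setdiff(names(attrs), c("transcript_id", "gene_id"))]
      rows[[tid]] <- list(id = tid, gene_id = attrs[["gene_id"]] %||% tid,
                          chrom = f[1L], strand = f[7L],
                          source = if (is.null(source)) f[2L] else source,
                          score = suppressWarnings(as.numeric(f[6L])),
                          attributes = keep_attrs,
                          exons = list(), cds = list())
    }
    slot <- if (type == "exon") "exons" else "cds"
    rows[[tid]][[slot]] <- c(rows[[tid]][[slot]], list(iv))
  }
  no_exon <- vapply(rows, function(r) length(r$exons) == 0L, logical(1))
  if (any(no_exon))
    stop("transcript(s) with CDS but no exon rows: ",
         paste(names(rows)[no_exon], collapse = ", "))
  build_models_from_rows(rows, "gtf")
}

#' Read a GFF3 file
#'
#' Expects the usual gene / mRNA (or transcript) / exon / CDS hierarchy
#' connected through `ID` and `Parent` attributes. Exons with multiple
#' parents are duplicated into each parent transcript. CDS phase columns are
#' ignored for structure but preserved in the transcript attributes.
#'
#' @inheritParams read_gtf
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path, source = NULL) {
  parsed <- read_tab_rows(path, 9L, "GFF3")
  feature_parent <- character(0)   # ID -> parent gene for transcript features
  tx_meta <- list()
  rows <- list()
  ## first pass: register candidate transcript container features
  for (k in seq_along(parsed$fields)) {
    f <- parsed$fields[[k]]
    attrs <- parse_gff3_attributes(f[9L])
    id <- attrs[["ID"]]
    if (!is.null(id) && !f[3L] %in% c("exon", "CDS")) {
      tx_meta[[id]] <- list(parent = attrs[["Parent"]], type = f[3L],
                            chrom = f[1L], strand = f[7L], src = f[2L])
    }
  }
  for (k in seq_along(parsed$fields)) {
    f <- parsed$fields[[k]]; lineno <- parsed$lineno[k]
    type <- f[3L]
    if (!type %in% c("exon", "CDS")) next
    attrs <- parse_gff3_attributes(f[9L])
    parents <- attrs[["Parent"]]
    if (is.null(parents))
      stop(type, " row at line ", lineno, " of ", path, " lacks Parent")
    se <- check_coords(f[4L], f[5L], lineno, path)
    if (se[2L] < se[1L])
      stop("feature with end < start at line ", lineno, " of ", path)
    iv <- c(se[1L] - 1L, se[2L])
    for (tid in strsplit(parents, ",", fixed = TRUE)[[1]]) {
      meta <- tx_meta[[tid]]
      if (is.null(meta))
        stop("dangling Parent '", tid, "' at line ", lineno, " of ", path,
             ": no feature with that ID")
      if (is.null(rows[[tid]])) {
        gid <- meta$parent %||% tid
        rows[[tid]] <- list(id = tid, gene_id = gid, chrom = meta$chrom,
                            strand = meta$strand,
                            source = if (is.null(source)) meta$src else source,
                            attributes = list(), exons = list(), cds = list())
      }
      slot <- if (type == "exon") "exons" else "cds"
      rows[[tid]][[slot]] <- c(rows[[tid]][[slot]], list(iv))
      if (type == "CDS" && f[8L] != ".") {
        ph <- rows[[tid]]$attributes[["phase"]]
        rows[[tid]]$attributes[["phase"]] <-
          if (is.null(ph)) f[8L] else paste(ph, f[8L], sep = ",")
      }
    }
  }
  build_models_from_rows(rows, "gff3")
}

parse_bed12_line <- function(f, lineno, path) {
  chrom_start <- as.integer(f[2L]); chrom_end <- as.integer(f[3L])
  n_blocks <- as.integer(f[10L])
  sizes  <- as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1]])
  starts <- as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1]])
  if (length(sizes) != n_blocks || length(starts) != n_blocks)
    stop("BED12 block count mismatch at line ", lineno, " of ", path)
  if (starts[1L] != 0L ||
      chrom_start + starts[n_blocks] + sizes[n_blocks] != chrom_end)
    stop("BED12 block arithmetic inconsistent with chromEnd at line ",
         lineno, " of ", path)
  exons <- cbind(start = chrom_start + starts,
                 end = chrom_start + starts + sizes)
  list(chrom = f[1L], start = chrom_start, end = chrom_end,
       name = f[4L], score = suppressWarnings(as.numeric(f[5L])),
       strand = f[6L], thick_start = as.integer(f[7L]),
       thick_end = as.integer(f[8L]), exons = exons)
}

#' Read a BED12 file
#'
#' In genomic mode (default) each line becomes a transcript model whose
#' blocks are the exons; the thick range, intersected with the exons, becomes
#' the CDS. In transcript-space mode (`transcript_space = TRUE`) lines are
#' interpreted as ORFs on cDNA coordinates: the chrom column is the
#' transcript id and the thick range is the ORF. In that mode completeness
#' flags may be encoded as `;`-separated tokens in the name column
#' (`has_start`, `has_stop`, `complete`, `no_start`, `no_stop`); absent
#' tokens leave the flags `NA`
#' so that [load_orfs()] can resolve them against the cDNA sequence.
#'
#' @param path path to a 12-column BED file.
#' @param transcript_space logical; see Details.
#' @param source label recorded on transcripts (genomic mode).
#' @return an [annotation_set()] (genomic mode) or a list of [orf_record()]s.
#' @export
read_bed12 <- function(path, transcript_space = FALSE, source = "bed12") {
  parsed <- read_tab_rows(path, 12L, "BED12")
  recs <- lapply(seq_along(parsed$fields), function(k)
    parse_bed12_line(parsed$fields[[k]], parsed$lineno[k], path))
  if (transcript_space) {
    return(lapply(recs, function(r) {
      tokens <- strsplit(r$name, ";", fixed = TRUE)[[1]]
      flags <- tokens[-1L]
      has_start <- if (any(c("complete", "has_start") %in% flags)) TRUE else
        if ("no_start" %in% flags) FALSE else NA
      has_stop <- if (any(c("complete", "has_stop") %in% flags)) TRUE else
        if ("no_stop" %in% flags) FALSE else NA
      orf_record(transcript_id = r$chrom, start = r$thick_start,
                 end = r$thick_end, strand = r$strand,
                 has_start = has_start, has_stop = has_stop,
                 orf_id = tokens[1L])
    }))
  }
  models <- lapply(recs, function(r) {
    cds <- NULL
    if (r$thick_end > r$thick_start) {
      lo <- pmax(r$exons[, 1L], r$thick_start)
      hi <- pmin(r$exons[, 2L], r$thick_end)
      keep <- lo < hi
      if (any(keep)) cds <- cbind(lo[keep], hi[keep])
    }
    transcript_model(id = r$name, chrom = r$chrom, strand = r$strand,
                     exons = r$exons, cds = cds, source = source,
                     score = r$score)
  })
  annotation_set(models)
}

cds_phases <- function(t) {
  ## phase of each CDS segment in translation (5'->3') order, returned in
  ## genomic row order of t$cds
  n <- nrow(t$cds)
  if (!n) return(integer(0))
  ord <- if (t$strand == "-") rev(seq_len(n)) else seq_len(n)
  lens <- (t$cds[, 2L] - t$cds[, 1L])[ord]
  prior <- cumsum(c(0L, lens))[seq_len(n)]
  ph <- (3L - (prior %% 3L)) %% 3L
  out <- integer(n); out[ord] <- ph
  out
}

format_gff3_attr <- function(x) {
  enc <- function(v) gsub(";", "%3B", gsub("=", "%3D", v, fixed = TRUE), fixed = TRUE)
  paste(vapply(names(x), function(k) paste0(k, "=", enc(x[[k]])), character(1)),
        collapse = ";")
}

#' Write an annotation set as GFF3
#'
#' Emits a spec-conformant gene / mRNA / exon / CDS hierarchy, sorted by
#' (chrom, start, end, id), with coordinates converted back to 1-based
#' inclusive and CDS phases computed in the 5' to 3' reading direction.
#' Reading the output back recovers the same exon/CDS/strand/id structure.
#'
#' @param set an [annotation_set()].
#' @param path output file path.
#' @param source value of the GFF3 source column (default `"txloom"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(set, path, source = "txloom") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  by_gene <- split(set$transcripts, gene_ids(set))
  ## order genes by position for deterministic output
  gstart <- vapply(by_gene, function(ts) min(vapply(ts, function(t) tx_span(t)[1L], integer(1))), integer(1))
  gend <- vapply(by_gene, function(ts) max(vapply(ts, function(t) tx_span(t)[2L], integer(1))), integer(1))
  gchrom <- vapply(by_gene, function(ts) ts[[1L]]$chrom, character(1))
  ord <- order(gchrom, gstart, gend, names(by_gene), method = "radix")
  row <- function(chrom, type, start, end, score, strand, phase, attrs)
    paste(chrom, source, type, start + 1L, end,
          ifelse(is.na(score), ".", format(score, trim = TRUE)),
          strand, phase, attrs, sep = "\t")
  for (g in names(by_gene)[ord]) {
    ts <- by_gene[[g]]
    writeLines(row(gchrom[g], "gene", gstart[g], gend[g], NA, ts[[1L]]$strand,
                   ".", format_gff3_attr(list(ID = g))), con)
    for (t in ts) {
      sp <- tx_span(t)
      writeLines(row(t$chrom, "mRNA", sp[1L], sp[2L], t$score, t$strand, ".",
                     format_gff3_attr(c(list(ID = t$id, Parent = g),
                                        t$attributes[setdiff(names(t$attributes), "phase")]))), con)
      for (i in seq_len(nrow(t$exons)))
        writeLines(row(t$chrom, "exon", t$exons[i, 1L], t$exons[i, 2L], NA,
                       t$strand, ".", format_gff3_attr(list(Parent = t$id))), con)
      ph <- cds_phases(t)
      for (i in seq_len(nrow(t$cds)))
        writeLines(row(t$chrom, "CDS", t$cds[i, 1L], t$cds[i, 2L], NA,
                       t$strand, ph[i], format_gff3_attr(list(Parent = t$id))), con)
    }
  }
  invisible(path)
}

#' Write an annotation set as GTF
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_gtf <- function(set, path, source = "txloom") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (t in set$transcripts) {
    base_attr <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id, t$id)
    extra <- t$attributes[setdiff(names(t$attributes), "phase")]
    if (length(extra))
      base_attr <- paste(base_attr, paste(sprintf('%s "%s";', names(extra),
                                                  unlist(extra)), collapse = " "))
    sp <- tx_span(t)
    row <- function(type, start, end, phase = ".")
      paste(t$chrom, t$source %||% source, type, start + 1L, end,
            ifelse(is.na(t$score), ".", format(t$score, trim = TRUE)),
            t$strand, phase, base_attr, sep = "\t")
    writeLines(row("transcript", sp[1L], sp[2L]), con)
    for (i in seq_len(nrow(t$exons)))
      writeLines(row("exon", t$exons[i, 1L], t$exons[i, 2L]), con)
    ph <- cds_phases(t)
    for (i in seq_len(nrow(t$cds)))
      writeLines(row("CDS", t$cds[i, 1L], t$cds[i, 2L], ph[i]), con)
  }
  invisible(path)
}

#' Write transcript cDNA sequences to FASTA
#'
#' @param set an [annotation_set()].
#' @param genome DNAStringSet or FASTA path.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cdna_fasta <- function(set, genome, path) {
  genome <- as_genome(genome)
  seqs <- Biostrings::DNAStringSet(
    vapply(set$transcripts, extract_cdna, character(1), genome = genome))
  names(seqs) <- names(set$transcripts)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}
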