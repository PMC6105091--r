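# shared builders for tiny in-code fixtures

mk_tx <- function(id, exons, strand = "+", chrom = "chr1", cds = NULL, ...) {
  transcript_model(id = id, chrom = chrom, strand = strand,
                   exons = matrix(unlist(exons), ncol = 2, byrow = TRUE),
                   cds = if (is.null(cds)) NULL else
                     matrix(unlist(cds), ncol = 2, byrow = TRUE), ...)
}

# deterministic random transcript on a chromosome of length chrom_len
random_tx <- function(id, chrom_len = 10000L, max_exons = 6L, strand = NULL) {
  n <- sample(seq_len(max_exons), 1L)
  widths <- sample(20:200, n, replace = TRUE)
  gaps <- if (n > 1L) sample(20:300, n - 1L, replace = TRUE) else integer(0)
  start <- sample.int(max(1L, chrom_len - sum(widths) - sum(gaps) - 10L), 1L)
  starts <- start + cumsum(c(0L, head(widths, -1L) + gaps))
  mk_tx(id, Map(c, starts, starts + widths),
        strand = strand %||% sample(c("+", "-"), 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

mk_genome <- function(...) {
  seqs <- Biostrings::DNAStringSet(unlist(list(...)))
  names(seqs) <- names(list(...))
  seqs
}

# brute-force per-base cDNA -> genome map, the oracle for project_to_genome
brute_cdna_map <- function(t) {
  per_exon <- lapply(seq_len(nrow(t$exons)), function(i)
    seq.int(t$exons[i, 1L], t$exons[i, 2L] - 1L))
  bases <- unlist(per_exon)
  if (t$strand == "-") bases <- rev(bases)
  bases  # bases[k] = genomic position of cDNA offset k-1
}
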