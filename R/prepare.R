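## Stage 1: validate, strand-correct, deduplicate, length-filter and sort
## transcript models from many input files into one coordinate-ordered GTF
## plus a cDNA FASTA.

## canonical splice dinucleotide pairs (U2 GT-AG / GC-AG and U12 AT-AC);
## the minus-strand forms are their reverse complements read on the plus
## strand of the genome.
CANONICAL_PLUS <- c("GT-AG", "GC-AG", "AT-AC")
CANONICAL_MINUS <- c("CT-AC", "CT-GC", "GT-AT")

#' Classify the introns of a transcript by splice-site canonicity
#'
#' Reads the donor and acceptor dinucleotides of every intron from the
#' genome (always on the plus strand) and reports, for each intron, whether
#' the pair is canonical when interpreted on the plus strand, the minus
#' strand, or neither.
#'
#' @param t a multiexonic `tx_model`.
#' @param genome DNAStringSet or FASTA path.
#' @param canonical_pairs plus-strand canonical donor-acceptor pairs
#'   (`"GT-AG"` style); minus-strand forms are derived automatically.
#' @return data.frame with columns `start`, `end`, `donor2`, `acceptor2`,
#'   `canonical_on` (one of `"+"`, `"-"`, `"none"`).
#' @export
classify_introns <- function(t, genome, canonical_pairs = CANONICAL_PLUS) {
  genome <- as_genome(genome)
  ii <- introns(t)
  if (!nrow(ii))
    return(data.frame(start = integer(0), end = integer(0),
                      donor2 = character(0), acceptor2 = character(0),
                      canonical_on = character(0)))
  minus_pairs <- vapply(strsplit(canonical_pairs, "-", fixed = TRUE),
                        function(p) {
                          rc <- function(x) as.character(
                            Biostrings::reverseComplement(Biostrings::DNAString(x)))
                          paste(rc(p[2L]), rc(p[1L]), sep = "-")
                        }, character(1))
  chrom_seq <- genome[[t$chrom]]
  out <- data.frame(start = ii[, 1L], end = ii[, 2L],
                    donor2 = NA_character_, acceptor2 = NA_character_,
                    canonical_on = "none", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ii))) {
    if (ii[i, 2L] - ii[i, 1L] < 4L) {
      warning("intron of transcript '", t$id, "' shorter than 4 nt; ",
              "treated as non-canonical")
      next
    }
    donor <- as.character(Biostrings::subseq(chrom_seq, ii[i, 1L] + 1L, ii[i, 1L] + 2L))
    acceptor <- as.character(Biostrings::subseq(chrom_seq, ii[i, 2L] - 1L, ii[i, 2L]))
    out$donor2[i] <- donor
    out$acceptor2[i] <- acceptor
    pair <- paste(donor, acceptor, sep = "-")
    out$canonical_on[i] <- if (pair %in% canonical_pairs) "+"
      else if (pair %in% minus_pairs) "-" else "none"
  }
  out
}

#' Decide the fate of a transcript from its intron canonicity
#'
#' Applies the strand-correction rules: a multiexonic transcript whose
#' canonical introns all sit on the opposite strand is flipped; a transcript
#' with canonical introns on both strands is discarded (unless
#' `keep_mixed`); a monoexonic transcript from a non-strand-specific source
#' has its strand stripped.
#'
#' @param t a `tx_model`.
#' @param verdicts result of [classify_introns()] for `t` (ignored for
#'   monoexonic transcripts).
#' @param strand_specific logical; whether the source assembly is
#'   strand-specific.
#' @param keep_mixed keep transcripts with canonical introns on both strands
#'   instead of discarding them.
#' @return list with `id`, `action` (one of `keep`, `flip_strand`,
#'   `strip_strand`, `discard`) and `reason`.
#' @export
resolve_strand <- function(t, verdicts = NULL, strand_specific = TRUE,
                           keep_mixed = FALSE) {
  decision <- function(action, reason) list(id = t$id, action = action, reason = reason)
  if (nrow(t$exons) == 1L) {
    if (!strand_specific && t$strand != ".")
      return(decision("strip_strand", "monoexonic_unstranded_source"))
    return(decision("keep", "monoexonic"))
  }
  canon <- verdicts$canonical_on
  n_plus <- sum(canon == "+"); n_minus <- sum(canon == "-")
  if (n_plus > 0L && n_minus > 0L) {
    if (keep_mixed) return(decision("keep", "mixed_strand_kept"))
    return(decision("discard", "introns_on_both_strands"))
  }
  if (t$strand %in% c("+", ".")) {
    same <- n_plus; opposite <- n_minus
  } else {
    same <- n_minus; opposite <- n_plus
  }
  if (opposite >= 1L && same == 0L && t$strand != ".")
    return(decision("flip_strand", "canonical_introns_on_opposite_strand"))
  if (t$strand == "." && (n_plus > 0L || n_minus > 0L))
    return(decision("flip_strand", "strand_inferred_from_introns"))
  decision("keep", "ok")
}

flip_strand <- function(t) {
  t$strand <- if (t$strand == "-") "+" else "-"
  t
}

#' Remove exact duplicate transcript models
#'
#' Transcripts identical in (chrom, strand, exon chain) collapse to one
#' representative. The survivor is the first in source order (the order of
#' `source_rank`), ties broken lexicographically by id.
#'
#' @param set an [annotation_set()].
#' @param source_rank character vector of source labels in precedence order;
#'   unknown sources rank last.
#' @return list with `set` (deduplicated [annotation_set()]) and `removed`
#'   (data.frame of removed id, surviving id, key).
#' @export
deduplicate_models <- function(set, source_rank = NULL) {
  ts <- set$transcripts
  if (!length(ts))
    return(list(set = set, removed = data.frame(removed_id = character(0),
                                                kept_id = character(0))))
  keys <- vapply(ts, exon_chain_key, character(1))
  srcs <- vapply(ts, `[[`, character(1), "source")
  rank <- if (is.null(source_rank)) rep(0L, length(ts)) else {
    r <- match(srcs, source_rank)
    r[is.na(r)] <- length(source_rank) + 1L
    r
  }
  ids <- names(ts)
  ord <- order(keys, rank, ids, method = "radix")
  keep <- !duplicated(keys[ord])
  kept_idx <- ord[keep]
  survivor_of <- stats::setNames(ids[kept_idx][match(keys, keys[kept_idx])], ids)
  removed_ids <- ids[!ids %in% ids[kept_idx]]
  removed <- data.frame(removed_id = removed_ids,
                        kept_id = unname(survivor_of[removed_ids]),
                        stringsAsFactors = FALSE)
  list(set = annotation_set(ts[sort(ids[kept_idx])]), removed = removed)
}

#' Run the full preparation stage
#'
#' Reads transcript models from multiple annotation files, applies the
#' minimum cDNA length filter, classifies introns and resolves strands,
#' removes exact duplicates, tags each surviving transcript with its
#' canonical-intron proportion, and writes a coordinate-sorted GTF plus the
#' matching cDNA FASTA.
#'
#' @param inputs data.frame with columns `path`, `label`,
#'   `strand_specific` (logical), one row per input annotation (GTF, GFF3 or
#'   BED12 by file extension).
#' @param genome DNAStringSet or FASTA path.
#' @param min_length minimum cDNA length in bp (default 200); shorter models
#'   are discarded.
#' @param keep_mixed keep models with canonical introns on both strands.
#' @param out_gtf,out_fasta optional output paths; written when non-`NULL`.
#' @return list with `set` (the prepared [annotation_set()]), `decisions`
#'   (data.frame: id, source, action, reason) and the output paths.
#' @export
prepare_run <- function(inputs, genome, min_length = 200L,
                        keep_mixed = FALSE, out_gtf = NULL, out_fasta = NULL) {
  genome <- as_genome(genome)
  stopifnot(all(c("path", "label", "strand_specific") %in% names(inputs)))
  all_models <- list()
  decisions <- list()
  note <- function(id, source, action, reason)
    decisions[[length(decisions) + 1L]] <<-
      data.frame(id = id, source = source, action = action, reason = reason,
                 stringsAsFactors = FALSE)
  for (i in seq_len(nrow(inputs))) {
    path <- inputs$path[i]; label <- inputs$label[i]
    ext <- tolower(tools::file_ext(path))
    set <- switch(ext,
      gtf = read_gtf(path, source = label),
      gff = , gff3 = read_gff3(path, source = label),
      bed = , bed12 = read_bed12(path, source = label),
      stop("unrecognised annotation extension: ", path))
    for (t in set$transcripts) {
      t$source <- label
      orig_id <- t$id
      ## ids may collide across input files; qualify with the source label
      qid <- paste0(label, ".", orig_id)
      if (cdna_length(t) < min_length) {
        note(qid, label, "discard", "below_min_length")
        next
      }
      verdicts <- if (nrow(t$exons) > 1L) classify_introns(t, genome) else NULL
      d <- resolve_strand(t, verdicts, strand_specific = inputs$strand_specific[i],
                          keep_mixed = keep_mixed)
      if (d$action == "discard") {
        note(qid, label, d$action, d$reason)
        next
      }
      if (d$action == "flip_strand") {
        if (t$strand == ".") {
          ## unstranded model with canonical introns: adopt that strand
          side <- verdicts$canonical_on[verdicts$canonical_on != "none"]
          t$strand <- names(sort(table(side), decreasing = TRUE))[1L]
        } else {
          t <- flip_strand(t)
        }
      }
      if (d$action == "strip_strand") t$strand <- "."
      if (!is.null(verdicts)) {
        canon_strand <- if (t$strand == "-") "-" else "+"
        t$attributes[["canonical_proportion"]] <-
          format(mean(verdicts$canonical_on == canon_strand), digits = 6)
      }
      t$attributes[["alias"]] <- orig_id
      t$id <- qid
      t$gene_id <- paste0(label, ".", t$gene_id)
      all_models[[length(all_models) + 1L]] <- t
      note(qid, label, d$action, d$reason)
    }
  }
  ## dedup on exact exon chains, in source order of the input list;
  ## a duplicate's log entry is overwritten so every input transcript
  ## carries exactly one final decision
  set <- annotation_set(all_models)
  dd <- deduplicate_models(set, source_rank = inputs$label)
  decisions <- if (length(decisions)) do.call(rbind, decisions) else
    data.frame(id = character(0), source = character(0),
               action = character(0), reason = character(0))
  if (nrow(dd$removed)) {
    idx <- match(dd$removed$removed_id, decisions$id)
    decisions$action[idx] <- "discard"
    decisions$reason[idx] <- "exact_duplicate"
  }
  if (!length(dd$set$transcripts))
    warning("no transcripts survived preparation; outputs will be empty")
  if (!is.null(out_gtf)) write_gtf(dd$set, out_gtf)
  if (!is.null(out_fasta)) write_cdna_fasta(dd$set, genome, out_fasta)
  list(set = dd$set, decisions = decisions, out_gtf = out_gtf,
       out_fasta = out_fasta)
}
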