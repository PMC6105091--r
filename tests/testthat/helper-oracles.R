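# build transcripts realizing a prescribed overlap graph: one private exon
# slot per vertex plus one shared slot per edge (slots 100 bp apart)
graph_to_models <- function(n, edges) {
  slots <- list()
  for (v in seq_len(n)) slots[[v]] <- (v - 1L)  # private slot per vertex
  next_slot <- n
  for (e in edges) {
    slots[[e[1L]]] <- c(slots[[e[1L]]], next_slot)
    slots[[e[2L]]] <- c(slots[[e[2L]]], next_slot)
    next_slot <- next_slot + 1L
  }
  lapply(seq_len(n), function(v) {
    s <- sort(slots[[v]])
    mk_tx(sprintf("v%02d", v), Map(c, s * 100L, s * 100L + 50L), "+")
  })
}

# independent oracle: literal restatement of the greedy selection rule
greedy_oracle <- function(models, scores) {
  picked <- character(0)
  left <- models
  while (length(left)) {
    ids <- vapply(left, `[[`, character(1), "id")
    lens <- vapply(left, cdna_length, integer(1))
    best <- left[[order(-scores[ids], -lens, ids)[1L]]]
    picked <- c(picked, best$id)
    left <- Filter(function(t) {
      if (t$id == best$id) return(FALSE)
      ov <- txloom:::intersect_length(t$exons, best$exons) > 0L &&
        t$chrom == best$chrom
      !(ov && txloom:::strands_compatible(t$strand, best$strand))
    }, left)
  }
  picked
}


# independent all-pairs restatement of the multi-level statistics, used as
# the oracle for compare_run
brute_stats <- function(reference, prediction) {
  ref <- reference$transcripts; pred <- prediction$transcripts
  compat <- function(a, b) a == b || a == "." || b == "."
  bases_of <- function(t) paste(t$chrom,
                                unlist(lapply(seq_len(nrow(t$exons)), function(i)
                                  seq.int(t$exons[i, 1], t$exons[i, 2] - 1L))))
  set_bases <- function(ts) unique(unlist(lapply(ts, bases_of)))
  base_shared <- function(from, to) {
    shared <- 0L
    for (t in from) {
      mine <- unique(bases_of(t))
      theirs <- unique(unlist(lapply(Filter(function(o)
        compat(t$strand, o$strand) && o$chrom == t$chrom, to), bases_of)))
      shared <- shared + sum(mine %in% theirs)
    }
    shared
  }
  ## careful: overlapping transcripts share bases; count per merged set
  per_strand_bases <- function(ts, strand_of) {
    keys <- unique(unlist(lapply(ts, function(t)
      paste(t$chrom, t$strand, sub("^\\S+ ", "", bases_of(t))))))
    keys
  }
  all_base_keys <- function(ts) unique(unlist(lapply(ts, function(t)
    paste(t$chrom, t$strand,
          unlist(lapply(seq_len(nrow(t$exons)), function(i)
            seq.int(t$exons[i, 1], t$exons[i, 2] - 1L)))))))
  key_match <- function(keys_a, keys_b) {
    pa <- do.call(rbind, strsplit(keys_a, " "))
    pb <- do.call(rbind, strsplit(keys_b, " "))
    vapply(seq_len(nrow(pa)), function(i)
      any(pb[, 1] == pa[i, 1] & pb[, 3] == pa[i, 3] &
            (pb[, 2] == pa[i, 2] | pb[, 2] == "." | pa[i, 2] == ".")),
      logical(1))
  }
  lvl <- function(ref_keys, pred_keys) {
    recall <- if (length(ref_keys)) 100 * mean(key_match(ref_keys, pred_keys))
      else 0
    precision <- if (length(pred_keys))
      100 * mean(key_match(pred_keys, ref_keys)) else 0
    f1 <- if (recall + precision > 0)
      2 * recall * precision / (recall + precision) else 0
    c(recall = recall, precision = precision, f1 = f1)
  }
  exon_keys_of <- function(ts) unique(unlist(lapply(ts, function(t)
    paste(t$chrom, t$strand, paste(t$exons[, 1], t$exons[, 2], sep = ":")))))
  intron_keys_of <- function(ts) unique(unlist(lapply(ts, function(t) {
    ii <- introns(t)
    if (!nrow(ii)) return(character(0))
    paste(t$chrom, t$strand, paste(ii[, 1], ii[, 2], sep = ":"))
  })))
  chain_keys_of <- function(ts) unique(unlist(lapply(ts, function(t) {
    ii <- introns(t)
    if (!nrow(ii)) return(character(0))
    paste(t$chrom, t$strand,
          paste(ii[, 1], ii[, 2], sep = ":", collapse = ";"))
  })))
  tx_matched <- function(t, others) {
    any(vapply(others, function(o) {
      if (!compat(t$strand, o$strand) || t$chrom != o$chrom) return(FALSE)
      mono_t <- nrow(t$exons) == 1L; mono_o <- nrow(o$exons) == 1L
      if (mono_t != mono_o) return(FALSE)
      if (!mono_t) {
        it <- introns(t); io <- introns(o)
        return(nrow(it) == nrow(io) && all(it == io))
      }
      lo <- max(t$exons[1, 1], o$exons[1, 1])
      hi <- min(t$exons[1, 2], o$exons[1, 2])
      ov <- max(0L, hi - lo)
      ov >= 0.8 * cdna_length(t) && ov >= 0.8 * cdna_length(o)
    }, logical(1)))
  }
  ref_hit <- vapply(ref, tx_matched, logical(1), others = pred)
  pred_hit <- vapply(pred, tx_matched, logical(1), others = ref)
  pc <- function(x, n) if (n) 100 * x / n else 0
  tx_lvl <- c(recall = pc(sum(ref_hit), length(ref)),
              precision = pc(sum(pred_hit), length(pred)))
  gene_hit_r <- tapply(ref_hit, vapply(ref, `[[`, character(1), "gene_id"), any)
  gene_hit_p <- tapply(pred_hit, vapply(pred, `[[`, character(1), "gene_id"), any)
  gene_lvl <- c(recall = pc(sum(gene_hit_r), length(gene_hit_r)),
                precision = pc(sum(gene_hit_p), length(gene_hit_p)))
  add_f1 <- function(v) c(v, f1 = unname(
    if (v[1] + v[2] > 0) 2 * v[1] * v[2] / (v[1] + v[2]) else 0))
  rbind(base = lvl(all_base_keys(ref), all_base_keys(pred)),
        exon = lvl(exon_keys_of(ref), exon_keys_of(pred)),
        intron = lvl(intron_keys_of(ref), intron_keys_of(pred)),
        intron_chain = lvl(chain_keys_of(ref), chain_keys_of(pred)),
        transcript = add_f1(tx_lvl),
        gene = add_f1(gene_lvl))
}

random_set <- function(n, prefix, chrom_len = 6000L, genes = NULL) {
  models <- lapply(seq_len(n), function(i) {
    t <- random_tx(paste0(prefix, i), chrom_len = chrom_len)
    t$gene_id <- paste0(prefix, "G", (i - 1L) %/% 2L)
    t
  })
  annotation_set(models)
}

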