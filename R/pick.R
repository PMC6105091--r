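## Stage 3: cluster transcripts into loci through sequential phases, split
## chimeras, select locus primaries by iterative graph pruning, add
## alternative-splicing isoforms and flag fragments.

## connected components of an undirected adjacency predicate over models
components_of <- function(models, connected) {
  n <- length(models)
  if (!n) return(list())
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (connected(models[[i]], models[[j]])) {
        ci <- comp[comp == comp[i]]; cj <- comp[j]
        comp[comp == cj] <- comp[i]
      }
    }
  }
  unname(split(seq_len(n), comp))
}

exonic_overlap <- function(a, b)
  a$chrom == b$chrom && intersect_length(a$exons, b$exons) > 0L

#' Group transcripts into superloci
#'
#' First clustering phase: transcripts whose genomic spans, extended by
#' `flank` bp, overlap and whose strands are compatible (`.` joins either)
#' are transitively grouped.
#'
#' @param models an [annotation_set()] or list of `tx_model`s.
#' @param flank span extension in bp (default 200).
#' @return list of lists of `tx_model`s, ordered by position.
#' @export
build_superloci <- function(models, flank = 200L) {
  if (inherits(models, "annotation_set")) models <- models$transcripts
  models <- sort_models(models)
  connected <- function(a, b) {
    if (a$chrom != b$chrom || !strands_compatible(a$strand, b$strand))
      return(FALSE)
    sa <- tx_span(a); sb <- tx_span(b)
    sa[1L] - flank < sb[2L] + flank && sb[1L] - flank < sa[2L] + flank
  }
  lapply(components_of(models, connected), function(idx) models[idx])
}

#' Group a superlocus into subloci
#'
#' Multiexonic transcripts are grouped transitively by sharing at least one
#' identical intron; monoexonic transcripts are grouped by exonic overlap.
#' Mono- and multiexonic transcripts are never co-grouped.
#'
#' @param superlocus list of `tx_model`s (one superlocus).
#' @return list of lists of `tx_model`s.
#' @export
build_subloci <- function(superlocus) {
  mono <- Filter(function(t) nrow(t$exons) == 1L, superlocus)
  multi <- Filter(function(t) nrow(t$exons) > 1L, superlocus)
  share_intron <- function(a, b)
    strands_compatible(a$strand, b$strand) && a$chrom == b$chrom &&
      any(intron_keys(a) %in% intron_keys(b))
  mono_overlap <- function(a, b)
    strands_compatible(a$strand, b$strand) && exonic_overlap(a, b)
  c(lapply(components_of(multi, share_intron), function(i) multi[i]),
    lapply(components_of(mono, mono_overlap), function(i) mono[i]))
}

## group ORFs of one transcript into cDNA-disjoint clusters (hull intervals)
orf_clusters <- function(orfs) {
  if (!length(orfs)) return(list())
  starts <- vapply(orfs, `[[`, integer(1), "start")
  ord <- order(starts)
  clusters <- list()
  cur <- list(orfs = list(orfs[[ord[1L]]]),
              start = orfs[[ord[1L]]]$start, end = orfs[[ord[1L]]]$end)
  for (k in ord[-1L]) {
    o <- orfs[[k]]
    if (o$start < cur$end) {
      cur$orfs <- c(cur$orfs, list(o))
      cur$end <- max(cur$end, o$end)
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- list(orfs = list(o), start = o$start, end = o$end)
    }
  }
  clusters[[length(clusters) + 1L]] <- cur
  clusters
}

#' Detect and split a chimeric (fusion) transcript
#'
#' A transcript with two or more cDNA-disjoint ORFs is a chimera candidate.
#' Protein homology can veto the split: if any single target protein has
#' HSPs covering at least `min_overlap` of two or more of the ORF clusters,
#' the ORFs are taken to derive from the same gene and the transcript is
#' kept whole. Otherwise the transcript is split into one part per ORF
#' cluster, with exons clipped at the cDNA midpoint between consecutive
#' clusters and each part's CDS set to its ORF projection. Part ids carry a
#' `.split<k>` suffix.
#'
#' @param t a `tx_model`.
#' @param orfs list of [orf_record()]s on `t`'s cDNA.
#' @param hits homology hits for `t` ([load_homology()] entry), may be empty.
#' @param min_overlap homology coverage fraction vetoing the split
#'   (default 0.2).
#' @return list with `original` (id), `split` (logical) and `parts` (list of
#'   `tx_model`s; the unchanged transcript when not split).
#' @export
detect_and_split_fusions <- function(t, orfs, hits = list(), min_overlap = 0.2) {
  no_split <- function() list(original = t$id, split = FALSE, parts = list(t))
  clusters <- orf_clusters(orfs)
  if (length(clusters) < 2L) return(no_split())
  ## homology veto: one protein bridging >= 2 ORF clusters
  by_target <- split(hits, vapply(hits, `[[`, character(1), "target"))
  for (target_hits in by_target) {
    q <- do.call(rbind, lapply(target_hits, function(h)
      as.matrix(h$hsps[, c("qstart", "qend")])))
    q <- merge_intervals(q)
    covered <- vapply(clusters, function(cl) {
      ov <- intersect_length(q, matrix(c(cl$start, cl$end), ncol = 2L))
      ov / (cl$end - cl$start)
    }, numeric(1))
    if (sum(covered >= min_overlap) >= 2L) return(no_split())
  }
  len <- cdna_length(t)
  bounds <- integer(0)
  for (k in seq_len(length(clusters) - 1L))
    bounds <- c(bounds, (clusters[[k]]$end + clusters[[k + 1L]]$start) %/% 2L)
  windows <- cbind(c(0L, bounds), c(bounds, len))
  parts <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    ex <- project_to_genome(t, windows[k, 1L], windows[k, 2L])
    ## pick the cluster's longest ORF (ties 5'-most) as the part's CDS
    lens <- vapply(cl$orfs, function(o) o$end - o$start, integer(1))
    starts <- vapply(cl$orfs, `[[`, integer(1), "start")
    primary <- cl$orfs[[order(-lens, starts)[1L]]]
    cds <- project_to_genome(t, primary$start, primary$end)
    part <- transcript_model(
      id = paste0(t$id, ".split", k), gene_id = paste0(t$gene_id, ".split", k),
      chrom = t$chrom, strand = t$strand, exons = ex, cds = cds,
      source = t$source, attributes = t$attributes)
    part$attributes[["number_internal_orfs"]] <- "1"
    part$attributes[["has_start_codon"]] <- as.character(isTRUE(primary$has_start))
    part$attributes[["has_stop_codon"]] <- as.character(isTRUE(primary$has_stop))
    part$attributes[["split_of"]] <- t$id
    parts[[k]] <- part
  }
  list(original = t$id, split = TRUE, parts = parts)
}

## deterministic ordering of candidate ids by (score desc, cDNA desc, id asc)
order_by_score <- function(models, scores) {
  ids <- vapply(models, `[[`, character(1), "id")
  len <- vapply(models, cdna_length, integer(1))
  order(-scores[ids], -len, ids)
}

#' Select primary transcripts by iterative graph pruning
#'
#' Greedy iteration over a group: pick the highest-scoring transcript (ties
#' broken by longer cDNA, then lexicographic id), remove every transcript
#' directly intersecting it (exonic overlap on a compatible strand), and
#' repeat until no transcript remains. Each pick seeds one locus, so
#' unresolved read-throughs connecting several genes cannot suppress a
#' locus.
#'
#' @param group list of `tx_model`s.
#' @param scores named numeric vector of scores (by transcript id).
#' @return list of loci; each locus is a list with `primary` (a `tx_model`),
#'   `score`, and `members` (initially just the primary's id).
#' @export
select_primary <- function(group, scores) {
  loci <- list()
  remaining <- group
  while (length(remaining)) {
    ord <- order_by_score(remaining, scores)
    top <- remaining[[ord[1L]]]
    loci[[length(loci) + 1L]] <- list(
      primary = top, score = unname(scores[top$id]), members = top$id)
    remaining <- Filter(function(t)
      !(strands_compatible(t$strand, top$strand) && exonic_overlap(t, top)),
      remaining[-ord[1L]])
  }
  loci
}

#' Add alternative-splicing isoforms to a locus
#'
#' Candidates are considered in decreasing score order and accepted when
#' their class code against the primary is in the valid set, their intron
#' chain differs from every transcript already in the locus, and their score
#' (recomputed in the context of the locus) is at least `min_score_ratio`
#' of the primary's, up to `max_isoforms` isoforms.
#'
#' @param locus a locus as returned by [select_primary()].
#' @param candidates list of candidate `tx_model`s.
#' @param config a [scoring_config()].
#' @param store an [evidence_store()] (optional, for evidence metrics).
#' @return the locus, with `members`, `transcripts` and `scores` updated.
#' @export
add_alternative_splicing <- function(locus, candidates, config, store = NULL) {
  primary <- locus$primary
  group <- c(list(primary), candidates)
  ids <- vapply(group, `[[`, character(1), "id")
  names(group) <- ids
  mvs <- lapply(group, compute_metrics, group = group, store = store)
  scores <- score_group(mvs, config)
  accepted <- list(primary)
  accepted_chains <- intron_chain_key(primary)
  rules <- config$as_rules
  for (k in order_by_score(candidates, scores)) {
    cand <- candidates[[k]]
    if (length(accepted) - 1L >= rules$max_isoforms) break
    code <- class_code(cand, primary)
    if (!code %in% rules$valid_class_codes) next
    if (intron_chain_key(cand) %in% accepted_chains) next
    if (scores[cand$id] < rules$min_score_ratio * scores[primary$id]) next
    accepted <- c(accepted, list(cand))
    accepted_chains <- c(accepted_chains, intron_chain_key(cand))
  }
  locus$transcripts <- accepted
  locus$members <- vapply(accepted, `[[`, character(1), "id")
  locus$scores <- scores[locus$members]
  locus
}

#' Flag (and optionally purge) fragment loci
#'
#' A locus is flagged as a fragment when the class code of its primary
#' against the primary of a neighboring (within `max_distance` bp)
#' higher-scoring locus is in the fragment code set (by default intronic,
#' flank-proximal and antisense codes: i, I, p, P, x, X). Loci whose
#' primary satisfies the configuration's `not_fragmentary` expression are
#' exempt.
#'
#' @param loci list of loci (with `primary` and `score`).
#' @param config a [scoring_config()].
#' @param store an [evidence_store()] (for the `not_fragmentary` metrics).
#' @param max_distance neighbor search distance in bp (default from config).
#' @return `loci` with a `fragment` flag set on each locus; when
#'   `config$pick$purge_fragments` is TRUE flagged loci are removed.
#' @export
flag_fragments <- function(loci, config, store = NULL, max_distance = NULL) {
  max_distance <- max_distance %||% config$pick$fragment_max_distance
  frag_codes <- config$pick$fragment_codes
  n <- length(loci)
  flagged <- logical(n)
  if (n > 1L) {
    spans <- lapply(loci, function(l) tx_span(l$primary))
    chroms <- vapply(loci, function(l) l$primary$chrom, character(1))
    scores <- vapply(loci, function(l) l$score %||% 0, numeric(1))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || chroms[i] != chroms[j]) next
        if (scores[j] <= scores[i]) next
        gap <- max(spans[[i]][1L] - spans[[j]][2L],
                   spans[[j]][1L] - spans[[i]][2L], 0L)
        if (gap > max_distance) next
        code <- class_code(loci[[i]]$primary, loci[[j]]$primary,
                           flank = max_distance)
        if (code %in% frag_codes) {
          flagged[i] <- TRUE
          break
        }
      }
      if (flagged[i] && !is.null(config$not_fragmentary)) {
        mv <- compute_metrics(loci[[i]]$primary, list(loci[[i]]$primary), store)
        if (evaluate_requirements(mv, config$not_fragmentary)$pass)
          flagged[i] <- FALSE
      }
    }
  }
  for (i in seq_len(n)) loci[[i]]$fragment <- flagged[i]
  if (isTRUE(config$pick$purge_fragments)) loci <- loci[!flagged]
  loci
}

#' Run the full picking stage
#'
#' Per superlocus: hard-requirements filter, chimera splitting, sublocus
#' construction, relative scoring, monosublocus winner selection, primary
#' selection by iterative pruning, alternative-splicing addition; then
#' fragment flagging across all loci. Final transcripts are re-grouped into
#' genes named `<prefix><n>` in positional order; every output transcript
#' id traces back to an input id (with a `.split<k>` suffix for resolved
#' chimeras).
#'
#' @param prepared an [annotation_set()] (output of [prepare_run()]) or path
#'   to its GTF.
#' @param store an [evidence_store()] or path to a saved store.
#' @param config a [scoring_config()] (default [default_scoring_config()]).
#' @param gene_prefix prefix for output gene ids.
#' @return list with `set` (final [annotation_set()]), `loci` (list of locus
#'   records), `metrics` (data.frame of all computed metric vectors),
#'   `scores` (data.frame of transcript scores), `log` (data.frame of
#'   per-transcript decisions).
#' @export
pick_run <- function(prepared, store = NULL, config = default_scoring_config(),
                     gene_prefix = "LOC_") {
  if (is.character(prepared)) prepared <- read_gtf(prepared)
  if (is.character(store)) store <- load_store(store)
  if (is.null(store)) store <- evidence_store()
  log_rows <- list()
  note <- function(id, stage, action, detail = "")
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(id = id, stage = stage, action = action, detail = detail,
                 stringsAsFactors = FALSE)
  ## attach ORF-derived CDS to every transcript up front
  models <- lapply(prepared$transcripts, function(t) {
    orfs <- store_orfs_for(store, t$id)
    if (length(orfs)) assign_orfs(t, orfs) else t
  })
  superloci <- build_superloci(models, flank = config$pick$flank)
  all_loci <- list()
  metric_rows <- list()
  for (sl in superloci) {
    ## hard requirements, evaluated in superlocus context
    names(sl) <- vapply(sl, `[[`, character(1), "id")
    mvs <- lapply(sl, compute_metrics, group = sl, store = store)
    passing <- list()
    for (id in names(sl)) {
      verdict <- evaluate_requirements(mvs[[id]], config$requirements)
      if (verdict$pass) {
        passing[[id]] <- sl[[id]]
      } else {
        note(id, "requirements", "discard",
             paste(verdict$failing, collapse = ","))
      }
    }
    if (!length(passing)) next
    ## chimera resolution
    resolved <- list()
    for (t in passing) {
      out <- detect_and_split_fusions(
        t, store_orfs_for(store, t$id), store_hits_for(store, t$id),
        min_overlap = config$pick$fusion_min_overlap)
      if (out$split)
        note(t$id, "fusion", "split", paste0(length(out$parts), " parts"))
      for (p in out$parts) resolved[[p$id]] <- p
    }
    ## subloci and their winners
    subloci <- build_subloci(resolved)
    winners <- list()
    winner_scores <- numeric(0)
    for (sub in subloci) {
      names(sub) <- vapply(sub, `[[`, character(1), "id")
      sub_mvs <- lapply(sub, compute_metrics, group = sub, store = store)
      sub_scores <- score_group(sub_mvs, config)
      for (id in names(sub))
        metric_rows[[id]] <- c(list(id = id, score = unname(sub_scores[id])),
                               lapply(sub_mvs[[id]], as.numeric))
      best <- order_by_score(sub, sub_scores)[1L]
      winners[[length(winners) + 1L]] <- sub[[best]]
      winner_scores[sub[[best]]$id] <- sub_scores[best]
    }
    ## primary selection among monosublocus winners
    loci <- select_primary(winners, winner_scores)
    ## alternative splicing: candidates must map to exactly one locus
    primaries <- lapply(loci, `[[`, "primary")
    candidates <- resolved[!names(resolved) %in%
                             vapply(primaries, `[[`, character(1), "id")]
    for (li in seq_along(loci)) {
      overlap_count <- function(cand) sum(vapply(primaries, function(pr)
        strands_compatible(cand$strand, pr$strand) && exonic_overlap(cand, pr),
        logical(1)))
      mine <- Filter(function(cand)
        overlap_count(cand) == 1L &&
          strands_compatible(cand$strand, loci[[li]]$primary$strand) &&
          exonic_overlap(cand, loci[[li]]$primary),
        candidates)
      loci[[li]] <- add_alternative_splicing(loci[[li]], unname(mine), config,
                                             store)
      if (is.null(loci[[li]]$transcripts))
        loci[[li]]$transcripts <- list(loci[[li]]$primary)
    }
    all_loci <- c(all_loci, loci)
  }
  ## fragment filtering across the whole run
  n_before <- length(all_loci)
  all_loci <- flag_fragments(all_loci, config, store)
  if (length(all_loci) < n_before)
    note("", "fragments", "purged", paste(n_before - length(all_loci), "loci"))
  ## renumber genes in positional order
  if (length(all_loci)) {
    ord <- order(vapply(all_loci, function(l) l$primary$chrom, character(1)),
                 vapply(all_loci, function(l) tx_span(l$primary)[1L], integer(1)),
                 vapply(all_loci, function(l) l$primary$id, character(1)),
                 method = "radix")
    all_loci <- all_loci[ord]
  }
  final <- list()
  score_rows <- list()
  for (gi in seq_along(all_loci)) {
    locus <- all_loci[[gi]]
    gid <- paste0(gene_prefix, gi)
    all_loci[[gi]]$gene_id <- gid
    for (t in locus$transcripts) {
      t$gene_id <- gid
      t$attributes[["locus_score"]] <-
        format(unname(locus$scores[t$id] %||% locus$score), digits = 6)
      t$attributes[["is_primary"]] <- as.character(t$id == locus$primary$id)
      final[[t$id]] <- t
      score_rows[[t$id]] <- data.frame(
        id = t$id, gene = gid, score = unname(locus$scores[t$id] %||% locus$score),
        primary = t$id == locus$primary$id, stringsAsFactors = FALSE)
    }
  }
  metrics <- if (length(metric_rows))
    do.call(rbind, lapply(metric_rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE))) else data.frame()
  rownames(metrics) <- NULL
  scores <- if (length(score_rows)) do.call(rbind, score_rows) else data.frame()
  rownames(scores) <- NULL
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(id = character(0), stage = character(0), action = character(0),
               detail = character(0))
  list(set = annotation_set(final), loci = all_loci, metrics = metrics,
       scores = scores, log = log)
}
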