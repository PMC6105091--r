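## Per-transcript metrics evaluated in locus context, the scoring
## configuration (requirements + scoring directives), and the relative
## scoring of transcripts within a group.

#' Names of the built-in transcript metrics
#'
#' @return character vector of metric names computable by
#'   [compute_metrics()].
#' @export
metric_names <- function() c(
  "cdna_length", "exon_num", "max_intron_length", "min_intron_length",
  "is_monoexonic", "canonical_intron_proportion", "cds_length",
  "cds_fraction", "number_internal_orfs", "utr_length", "five_utr_length",
  "three_utr_length", "five_utr_num", "three_utr_num", "has_start_codon",
  "has_stop_codon", "is_complete", "end_distance_from_junction",
  "exon_fraction", "intron_fraction", "retained_intron_num",
  "retained_fraction", "verified_introns_num",
  "proportion_verified_introns", "best_bitscore", "best_hit_coverage")

## cDNA-space CDS interval of a transcript (NULL when no CDS)
cds_cdna_interval <- function(t) {
  if (!nrow(t$cds)) return(NULL)
  n <- nrow(t$cds)
  first_base <- if (t$strand == "-") t$cds[n, 2L] - 1L else t$cds[1L, 1L]
  last_base  <- if (t$strand == "-") t$cds[1L, 1L] else t$cds[n, 2L] - 1L
  c1 <- genome_to_cdna(t, first_base)
  c2 <- genome_to_cdna(t, last_base)
  c(c1, c2 + 1L)
}

## cDNA offsets at which each exon (in transcript order) starts, and the
## cDNA positions of the splice junctions
exon_cdna_offsets <- function(t) {
  widths <- t$exons[, 2L] - t$exons[, 1L]
  ord <- if (t$strand == "-") rev(seq_len(nrow(t$exons))) else seq_len(nrow(t$exons))
  w <- widths[ord]
  list(offsets = cumsum(c(0L, w))[seq_along(w)], widths = w)
}

merge_intervals <- function(m) {
  if (!NROW(m)) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

attr_num <- function(t, key, default = NA_real_) {
  v <- t$attributes[[key]]
  if (is.null(v)) default else suppressWarnings(as.numeric(v))
}

#' Compute the metric vector of a transcript in its locus context
#'
#' Intrinsic metrics (lengths, exon counts, CDS/UTR structure) depend only
#' on the transcript; locus-relative metrics (`exon_fraction`,
#' `intron_fraction`, retained-intron metrics) depend on the other
#' transcripts currently grouped with it; evidence metrics (verified
#' junctions, homology) come from the [evidence_store()].
#'
#' @param t a `tx_model`; must be a member of `group`.
#' @param group list of `tx_model`s of the same locus stage (including `t`).
#' @param store an [evidence_store()] (optional).
#' @return named list of metric values (booleans as logical).
#' @export
compute_metrics <- function(t, group = list(t), store = NULL) {
  mv <- list()
  ii <- introns(t)
  mv$cdna_length <- cdna_length(t)
  mv$exon_num <- nrow(t$exons)
  mv$is_monoexonic <- nrow(t$exons) == 1L
  ilen <- ii[, 2L] - ii[, 1L]
  mv$max_intron_length <- if (length(ilen)) max(ilen) else 0L
  mv$min_intron_length <- if (length(ilen)) min(ilen) else 0L
  mv$canonical_intron_proportion <-
    if (mv$is_monoexonic) 0 else attr_num(t, "canonical_proportion", 1)
  mv$cds_length <- cds_length(t)
  mv$cds_fraction <- if (mv$cdna_length > 0) mv$cds_length / mv$cdna_length else 0
  n_orfs <- attr_num(t, "number_internal_orfs")
  if (is.na(n_orfs)) {
    orfs <- if (is.null(store)) list() else store_orfs_for(store, t$id)
    n_orfs <- if (!length(orfs)) as.numeric(nrow(t$cds) > 0L) else {
      lens <- vapply(orfs, function(o) o$end - o$start, integer(1))
      starts <- vapply(orfs, `[[`, integer(1), "start")
      p <- orfs[[order(-lens, starts)[1L]]]
      1 + sum(vapply(orfs, function(o) o$end <= p$start || o$start >= p$end,
                     logical(1)))
    }
  }
  mv$number_internal_orfs <- n_orfs
  cc <- cds_cdna_interval(t)
  if (is.null(cc)) {
    mv$utr_length <- mv$five_utr_length <- mv$three_utr_length <- 0L
    mv$five_utr_num <- mv$three_utr_num <- 0L
    mv$end_distance_from_junction <- 0L
  } else {
    mv$five_utr_length <- cc[1L]
    mv$three_utr_length <- mv$cdna_length - cc[2L]
    mv$utr_length <- mv$five_utr_length + mv$three_utr_length
    eo <- exon_cdna_offsets(t)
    mv$five_utr_num <- sum(eo$offsets < cc[1L])
    mv$three_utr_num <- sum(eo$offsets + eo$widths > cc[2L])
    junction_pos <- (eo$offsets + eo$widths)[-length(eo$widths)]
    mv$end_distance_from_junction <- if (!length(junction_pos)) 0L else
      max(0L, max(junction_pos) - cc[2L])
  }
  has_start <- t$attributes[["has_start_codon"]]
  has_stop <- t$attributes[["has_stop_codon"]]
  mv$has_start_codon <- isTRUE(has_start == "TRUE") && nrow(t$cds) > 0L
  mv$has_stop_codon <- isTRUE(has_stop == "TRUE") && nrow(t$cds) > 0L
  mv$is_complete <- mv$has_start_codon && mv$has_stop_codon
  ## locus-context fractions over exact-interval identity
  exon_key <- function(x) paste(x$exons[, 1L], x$exons[, 2L], sep = "-")
  intron_key <- function(x) {
    m <- introns(x); paste(m[, 1L], m[, 2L], sep = "-")
  }
  grp_exons <- unique(unlist(lapply(group, exon_key)))
  grp_introns <- unique(unlist(lapply(group, intron_key)))
  mv$exon_fraction <- if (length(grp_exons))
    sum(exon_key(t) %in% grp_exons) / length(grp_exons) else 1
  mv$intron_fraction <- if (length(grp_introns))
    sum(intron_key(t) %in% grp_introns) / length(grp_introns) else 1
  ## retained introns: an exon of t fully containing an intron of another
  ## group member whose two flanking exons both overlap that exon
  retained <- logical(nrow(t$exons))
  for (other in group) {
    if (other$id == t$id) next
    oi <- introns(other)
    for (j in seq_len(nrow(oi))) {
      fl_left <- other$exons[j, ]; fl_right <- other$exons[j + 1L, ]
      for (e in seq_len(nrow(t$exons))) {
        ex <- t$exons[e, ]
        if (ex[1L] <= oi[j, 1L] && oi[j, 2L] <= ex[2L] &&
            fl_left[1L] < ex[2L] && ex[1L] < fl_left[2L] &&
            fl_right[1L] < ex[2L] && ex[1L] < fl_right[2L])
          retained[e] <- TRUE
      }
    }
  }
  mv$retained_intron_num <- sum(retained)
  mv$retained_fraction <- if (mv$cdna_length > 0)
    sum((t$exons[retained, 2L] - t$exons[retained, 1L])) / mv$cdna_length else 0
  ## evidence metrics
  if (!is.null(store)) {
    vi <- verify_introns(t, store)
    mv$verified_introns_num <- unname(vi[1L])
    mv$proportion_verified_introns <- if (vi[2L] > 0) vi[1L] / vi[2L] else 0
    hits <- store_hits_for(store, t$id)
    if (length(hits)) {
      mv$best_bitscore <- max(vapply(hits, `[[`, numeric(1), "bitscore"))
      best <- hits[[1L]]  # hits are sorted by ascending e-value
      merged <- merge_intervals(as.matrix(best$hsps[, c("qstart", "qend")]))
      mv$best_hit_coverage <- sum(merged[, 2L] - merged[, 1L]) / mv$cdna_length
    } else {
      mv$best_bitscore <- 0
      mv$best_hit_coverage <- 0
    }
  } else {
    mv$verified_introns_num <- 0L
    mv$proportion_verified_introns <- 0
    mv$best_bitscore <- 0
    mv$best_hit_coverage <- 0
  }
  mv
}

REQ_OPERATORS <- c("eq", "ne", "gt", "ge", "lt", "le", "in", "within")

apply_operator <- function(value, op, ref) {
  switch(op,
         eq = value == ref, ne = value != ref,
         gt = value > ref, ge = value >= ref,
         lt = value < ref, le = value <= ref,
         `in` = value %in% ref,
         within = value >= min(ref) & value <= max(ref),
         stop("unknown operator '", op, "'"))
}

compile_requirements <- function(req, where = "requirements") {
  if (is.null(req) || !length(req$parameters %||% list()))
    return(NULL)
  atoms <- req$parameters
  for (nm in names(atoms)) {
    a <- atoms[[nm]]
    if (is.null(a$metric)) {
      ## allow atom names of the form metric or metric.suffix
      a$metric <- sub("\\.[^.]*$", "", nm)
      atoms[[nm]]$metric <- a$metric
    }
    if (!a$metric %in% metric_names())
      stop("unknown metric '", a$metric, "' in ", where, " atom '", nm, "'")
    if (is.null(a$operator) || !a$operator %in% REQ_OPERATORS)
      stop("invalid operator in ", where, " atom '", nm, "'")
    if (is.null(a$value)) stop("missing value in ", where, " atom '", nm, "'")
  }
  expr_text <- req$expression %||% paste(names(atoms), collapse = " and ")
  expr_r <- gsub("\\bnot\\b", "!", gsub("\\bor\\b", "|",
                 gsub("\\band\\b", "&", expr_text)))
  expr <- tryCatch(str2lang(expr_r),
                   error = function(e) stop("cannot parse ", where,
                                            " expression: ", expr_text))
  used <- all.vars(expr)
  missing <- setdiff(used, names(atoms))
  if (length(missing))
    stop(where, " expression references undefined atoms: ",
         paste(missing, collapse = ", "))
  list(atoms = atoms, expression = expr, expression_text = expr_text)
}

#' Build a scoring configuration
#'
#' A scoring configuration has four parts: `requirements` (hard filters a
#' transcript must pass to be considered at all), `not_fragmentary`
#' (transcripts matching this expression are exempt from fragment
#' filtering), `scoring` (per-metric directives that turn metric values into
#' a relative score), and `as_rules` (rules governing the addition of
#' alternative-splicing isoforms). Unknown metric names raise an error at
#' construction time, not during evaluation.
#'
#' @param requirements,not_fragmentary lists with `expression` (a boolean
#'   formula over atom names, using `and`/`or`/`not`) and `parameters` (a
#'   named list of atoms `list(metric=, operator=, value=)`; atom names of
#'   the form `metric.suffix` may omit `metric`).
#' @param scoring named list: metric name -> directive
#'   `list(rescaling = "max"|"min"|"target", target =, multiplier =,
#'   filter = list(operator=, value=))`.
#' @param as_rules list with `min_score_ratio` (default 0.5), `max_isoforms`
#'   (default 5), `valid_class_codes` (default `c("j","J","h","G")`).
#' @param pick list of picking parameters: `flank` (superlocus clustering
#'   flank, default 200), `fragment_max_distance` (default 2000),
#'   `fragment_codes` (default `c("i","I","p","P","x","X")`),
#'   `fusion_min_overlap` (homology coverage needed to call two ORFs the
#'   same gene, default 0.2), `purge_fragments` (default TRUE).
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(requirements = NULL, not_fragmentary = NULL,
                           scoring = list(), as_rules = list(), pick = list()) {
  for (m in names(scoring)) {
    if (!m %in% metric_names())
      stop("unknown metric '", m, "' in scoring section")
    d <- scoring[[m]]
    if (is.null(d$rescaling) || !d$rescaling %in% c("max", "min", "target"))
      stop("scoring directive for '", m, "' needs rescaling max/min/target")
    if (d$rescaling == "target" && is.null(d$target))
      stop("scoring directive for '", m, "' uses target rescaling without a target")
    if (!is.null(d$multiplier) && d$multiplier <= 0)
      stop("multiplier for '", m, "' must be > 0")
    scoring[[m]]$multiplier <- d$multiplier %||% 1
    if (!is.null(d$filter)) {
      if (is.null(d$filter$operator) || !d$filter$operator %in% REQ_OPERATORS)
        stop("invalid filter operator for '", m, "'")
    }
  }
  as_defaults <- list(min_score_ratio = 0.5, max_isoforms = 5L,
                      valid_class_codes = c("j", "J", "h", "G"))
  as_rules <- utils::modifyList(as_defaults, as_rules)
  pick_defaults <- list(flank = 200L, fragment_max_distance = 2000L,
                        fragment_codes = c("i", "I", "p", "P", "x", "X"),
                        fusion_min_overlap = 0.2, purge_fragments = TRUE)
  pick <- utils::modifyList(pick_defaults, pick)
  structure(list(
    requirements = compile_requirements(requirements, "requirements"),
    not_fragmentary = compile_requirements(not_fragmentary, "not_fragmentary"),
    scoring = scoring, as_rules = as_rules, pick = pick
  ), class = "scoring_config")
}

#' Read a scoring configuration from a YAML file
#'
#' @param path YAML file with sections `requirements`, `not_fragmentary`,
#'   `scoring`, `as_rules`, `pick` (all optional); see [scoring_config()].
#' @return a `scoring_config`.
#' @export
read_scoring_config <- function(path) {
  y <- yaml::read_yaml(path)
  scoring_config(requirements = y$requirements,
                 not_fragmentary = y$not_fragmentary,
                 scoring = y$scoring %||% list(),
                 as_rules = y$as_rules %||% list(),
                 pick = y$pick %||% list())
}

#' Default scoring configuration
#'
#' Prioritizes complete protein-coding models: long CDS with a high coding
#' fraction, validated and canonical splice junctions, homology support, and
#' penalizes retained introns and excess UTR. Requirements impose the
#' 200 bp minimum cDNA length.
#'
#' @return a `scoring_config`.
#' @export
default_scoring_config <- function() {
  scoring_config(
    requirements = list(
      expression = "cdna_length.min",
      parameters = list(
        cdna_length.min = list(metric = "cdna_length", operator = "ge",
                               value = 200))),
    not_fragmentary = list(
      expression = "is_complete.true and cds_length.min",
      parameters = list(
        is_complete.true = list(metric = "is_complete", operator = "eq",
                                value = TRUE),
        cds_length.min = list(metric = "cds_length", operator = "ge",
                              value = 300))),
    scoring = list(
      cds_length = list(rescaling = "max", multiplier = 3),
      cds_fraction = list(rescaling = "max", multiplier = 2),
      is_complete = list(rescaling = "max", multiplier = 2),
      proportion_verified_introns = list(rescaling = "max", multiplier = 2),
      verified_introns_num = list(rescaling = "max", multiplier = 1),
      canonical_intron_proportion = list(rescaling = "max", multiplier = 1),
      retained_fraction = list(rescaling = "min", multiplier = 2),
      number_internal_orfs = list(rescaling = "target", target = 1,
                                  multiplier = 1),
      best_hit_coverage = list(rescaling = "max", multiplier = 1),
      end_distance_from_junction = list(rescaling = "min", multiplier = 1))
  )
}

#' Evaluate hard requirements on a metric vector
#'
#' @param mv named list of metric values ([compute_metrics()]).
#' @param requirements compiled requirements (the `requirements` or
#'   `not_fragmentary` element of a [scoring_config()]), or `NULL` for
#'   "always pass".
#' @return list with `pass` (logical) and `failing` (names of atoms that
#'   evaluated FALSE).
#' @export
evaluate_requirements <- function(mv, requirements) {
  if (is.null(requirements)) return(list(pass = TRUE, failing = character(0)))
  env <- new.env(parent = baseenv())
  failing <- character(0)
  for (nm in names(requirements$atoms)) {
    a <- requirements$atoms[[nm]]
    val <- mv[[a$metric]]
    res <- isTRUE(apply_operator(val, a$operator, a$value))
    if (!res) failing <- c(failing, nm)
    assign(nm, res, envir = env)
  }
  pass <- isTRUE(eval(requirements$expression, env))
  list(pass = pass, failing = failing)
}

#' Score a group of transcripts relative to one another
#'
#' For every metric directive the group's values are rescaled to
#' `[0, multiplier]`: `max` rewards the largest value, `min` the smallest,
#' and `target` the value closest to the target. When all values are equal
#' the metric is uninformative and every transcript receives the full
#' multiplier. A per-metric filter, when present and failing, forces that
#' transcript's contribution for the metric to zero. The transcript score is
#' the sum over all directives; boolean metrics are cast to 0/1.
#'
#' @param mvs named list (by transcript id) of metric vectors computed on
#'   exactly this group.
#' @param config a [scoring_config()].
#' @return named numeric vector of scores; the per-metric breakdown matrix
#'   is attached as attribute `"breakdown"`.
#' @export
score_group <- function(mvs, config) {
  ids <- names(mvs)
  breakdown <- matrix(0, nrow = length(ids), ncol = length(config$scoring),
                      dimnames = list(ids, names(config$scoring)))
  eps <- 1e-9
  for (m in names(config$scoring)) {
    d <- config$scoring[[m]]
    v <- vapply(mvs, function(mv) as.numeric(mv[[m]]), numeric(1))
    lo <- min(v); hi <- max(v)
    s <- if (hi == lo) {
      rep(d$multiplier, length(v))
    } else if (d$rescaling == "max") {
      d$multiplier * (v - lo) / (hi - lo)
    } else if (d$rescaling == "min") {
      d$multiplier * (hi - v) / (hi - lo)
    } else {
      tgt <- d$target
      denom <- max(abs(hi - tgt), abs(lo - tgt), eps)
      d$multiplier * (1 - abs(v - tgt) / denom)
    }
    if (!is.null(d$filter)) {
      ok <- vapply(mvs, function(mv)
        isTRUE(apply_operator(mv[[m]], d$filter$operator, d$filter$value)),
        logical(1))
      s[!ok] <- 0
    }
    breakdown[, m] <- s
  }
  scores <- rowSums(breakdown)
  attr(scores, "breakdown") <- breakdown
  scores
}
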