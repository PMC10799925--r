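#' @title Candidate screening procedures
#' @description The four decision procedures composed from the primitives:
#'   the anti-CRISPR screen, the defense-candidate screen, the counter-defense
#'   remote-homolog rule, and the fusion scan -- each with full funnel logging
#'   (per-stage in/retained/excluded counts that must chain and conserve).
#' @name screens
NULL

#' Screening thresholds
#'
#' All thresholds of the two discovery pipelines in one injectable object.
#' Defaults: Acr candidates at most 200 aa, clustered at 95\% identity;
#' defense candidates clustered at 50\% identity, at least 200 aa; sequence
#' divergence requires identity at most 30\% and E-value at least 0.1 versus
#' every reference; pI at most 7; any CDD-style domain hit at E-value at or
#' below 0.01 excludes; structural similarity calls at TM 0.6 (Acr,
#' counter-defense) and 0.65 (defense); counter-defense additionally requires
#' the shorter chain at least 70\% the longer's length; island gaps 1-15 kb.
#'
#' @param acr_max_len,defense_min_len residue-length bounds.
#' @param acr_cluster_id,defense_cluster_id clustering identity fractions.
#' @param max_ref_identity,evalue_cut divergence-filter thresholds.
#' @param max_pi isoelectric-point retention bound.
#' @param domain_evalue_cut domain-hit exclusion E-value.
#' @param acr_tm_cut,defense_tm_cut,counter_tm_cut TM-score calls.
#' @param counter_len_ratio shorter/longer length ratio floor.
#' @param island_min_gap,island_max_gap inter-system gap window in bp.
#' @param fusion_jaccard candidate-segment Jaccard below which two reference
#'   hits count as disjoint segments (putative fusion).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(acr_max_len = 200L, acr_cluster_id = 0.95,
                          defense_cluster_id = 0.50, max_ref_identity = 0.30,
                          evalue_cut = 0.1, max_pi = 7.0,
                          domain_evalue_cut = 0.01, acr_tm_cut = 0.6,
                          defense_tm_cut = 0.65, counter_tm_cut = 0.6,
                          counter_len_ratio = 0.70, defense_min_len = 200L,
                          island_min_gap = 1000L, island_max_gap = 15000L,
                          fusion_jaccard = 0.25) {
  cfg <- list(acr_max_len = acr_max_len, acr_cluster_id = acr_cluster_id,
              defense_cluster_id = defense_cluster_id,
              max_ref_identity = max_ref_identity, evalue_cut = evalue_cut,
              max_pi = max_pi, domain_evalue_cut = domain_evalue_cut,
              acr_tm_cut = acr_tm_cut, defense_tm_cut = defense_tm_cut,
              counter_tm_cut = counter_tm_cut,
              counter_len_ratio = counter_len_ratio,
              defense_min_len = defense_min_len,
              island_min_gap = island_min_gap,
              island_max_gap = island_max_gap,
              fusion_jaccard = fusion_jaccard)
  fr <- c("acr_cluster_id", "defense_cluster_id", "max_ref_identity",
          "counter_len_ratio", "acr_tm_cut", "defense_tm_cut",
          "counter_tm_cut")
  for (f in fr) if (cfg[[f]] <= 0 || cfg[[f]] > 1)
    stop(f, " must lie in (0, 1]")
  structure(cfg, class = "screen_config")
}

new_funnel <- function() {
  data.frame(stage = character(0), n_in = integer(0),
             n_retained = integer(0), n_excluded = integer(0),
             stringsAsFactors = FALSE)
}

funnel_add <- function(funnel, stage, n_in, n_retained) {
  rbind(funnel, data.frame(stage = stage, n_in = n_in,
                           n_retained = n_retained,
                           n_excluded = n_in - n_retained,
                           stringsAsFactors = FALSE))
}

verdict_add <- function(verdicts, ids, stage, passed_ids, detail = "") {
  for (id in ids) {
    verdicts[[id]] <- rbind(
      verdicts[[id]],
      data.frame(stage = stage, passed = id %in% passed_ids,
                 detail = detail, stringsAsFactors = FALSE))
  }
  verdicts
}

domain_hit_ids <- function(ids, domains, cut) {
  if (is.null(domains) || nrow(domains) == 0) return(character(0))
  unique(domains$protein_id[domains$protein_id %in% ids &
                              domains$evalue <= cut])
}

align_vs_references <- function(cand_ids, catalog, structures, refs,
                                tm_cut, strict, config, align_cfg, scoring) {
  hits <- list()
  for (id in cand_ids) {
    cs <- structures[[id]]
    for (rid in names(refs$structures)) {
      al <- structure_align(cs, refs$structures[[rid]], align_cfg)
      tmdec <- tm_decision(al, align_cfg)
      ok <- if (strict) tmdec > tm_cut else tmdec >= tm_cut
      if (!ok) next
      ident <- NA_real_; ev <- NA_real_
      rrec <- refs$records
      if (!is.null(rrec) && rid %in% rrec$protein_id) {
        sal <- local_align(catalog$sequence[catalog$protein_id == id][1],
                           rrec$sequence[rrec$protein_id == rid][1], scoring)
        ident <- sal$identity; ev <- sal$evalue
      }
      hits[[length(hits) + 1]] <- data.frame(
        candidate_id = id, reference_id = rid, tm_query = al$tm_query,
        tm_target = al$tm_target, tm_shorter = al$tm_shorter,
        rmsd = al$rmsd, identity = ident, evalue = ev,
        qstart = min(al$pairs[, 1]), qend = max(al$pairs[, 1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(candidate_id = character(0),
                      reference_id = character(0), tm_query = numeric(0),
                      tm_target = numeric(0), tm_shorter = numeric(0),
                      rmsd = numeric(0), identity = numeric(0),
                      evalue = numeric(0), qstart = integer(0),
                      qend = integer(0)))
  do.call(rbind, hits)
}

build_reports <- function(ids, verdicts, hits) {
  reports <- list()
  for (id in ids) {
    h <- hits[hits$candidate_id == id, , drop = FALSE]
    h <- h[order(-h$tm_shorter), , drop = FALSE]
    v <- verdicts[[id]]
    reports[[id]] <- list(
      candidate_id = id, stage_verdicts = v, reference_hits = h,
      best_reference = if (nrow(h)) h$reference_id[1] else NA_character_,
      retained = all(v$passed))
  }
  reports
}

#' The anti-CRISPR candidate screen
#'
#' Filtration cascade over a protein catalog, in order: (1) length at most
#' `acr_max_len`; (2) greedy clustering at `acr_cluster_id`, centroids
#' proceed (members inherit the centroid verdict via the cluster map);
#' (3) sequence-divergence exclusion versus the reference Acrs; (4) pI filter;
#' (5) domain filter -- any domain hit at E-value at or below
#' `domain_evalue_cut` excludes; (6) candidates without a structure model are
#' excluded at a logged stage; (7) structural alignment against every
#' reference, a hit needs TM at or above `acr_tm_cut`; per reference the
#' maximum-TM hit is flagged best.
#'
#' @param catalog a [protein_records()] table.
#' @param structures named list of [ca_trace()] models (by protein_id).
#' @param acr_refs `list(records =, structures =)` of reference Acrs
#'   (non-empty).
#' @param domains optional domain table (see [read_domain_table()]).
#' @param config a [screen_config()].
#' @param align_cfg an [align_config()].
#' @param scoring an [aln_scoring()].
#' @return `list(reports, funnel, hits, clusters)`; `hits` has one row per
#'   candidate x reference structural hit with a `best` flag.
#' @export
acr_screen <- function(catalog, structures, acr_refs, domains = NULL,
                       config = screen_config(), align_cfg = align_config(),
                       scoring = aln_scoring()) {
  if (is.null(acr_refs$structures) || length(acr_refs$structures) == 0)
    stop("empty Acr reference set")
  funnel <- new_funnel()
  verdicts <- list()
  ids <- catalog$protein_id

  keep <- catalog$protein_id[catalog$length <= config$acr_max_len]
  verdicts <- verdict_add(verdicts, ids, "length", keep,
                          sprintf("<= %d aa", config$acr_max_len))
  funnel <- funnel_add(funnel, "length", length(ids), length(keep))

  if (length(keep)) {
    clusters <- greedy_cluster(catalog[catalog$protein_id %in% keep, ,
                                       drop = FALSE],
                               config$acr_cluster_id, scoring)
  } else {
    clusters <- data.frame(cluster_id = character(0),
                           centroid_id = character(0))
    clusters$member_ids <- list()
  }
  cents <- clusters$centroid_id
  verdicts <- verdict_add(verdicts, keep, "cluster-centroid", cents,
                          sprintf("%.0f%% identity", 100 * config$acr_cluster_id))
  funnel <- funnel_add(funnel, "cluster-centroid", length(keep), length(cents))

  cent_rec <- catalog[match(cents, catalog$protein_id), , drop = FALSE]
  div <- divergence_filter(cent_rec, acr_refs$records,
                           config$max_ref_identity, config$evalue_cut,
                           scoring)
  keep <- div$retained$protein_id
  verdicts <- verdict_add(verdicts, cents, "sequence-divergence", keep)
  funnel <- funnel_add(funnel, "sequence-divergence", length(cents),
                       length(keep))

  pf <- pi_filter(catalog[match(keep, catalog$protein_id), , drop = FALSE],
                  config$max_pi)
  prev <- keep; keep <- pf$retained$protein_id
  verdicts <- verdict_add(verdicts, prev, "isoelectric-point", keep,
                          sprintf("pI <= %.1f", config$max_pi))
  funnel <- funnel_add(funnel, "isoelectric-point", length(prev), length(keep))

  dom_hit <- domain_hit_ids(keep, domains, config$domain_evalue_cut)
  prev <- keep; keep <- setdiff(keep, dom_hit)
  verdicts <- verdict_add(verdicts, prev, "no-known-domain", keep)
  funnel <- funnel_add(funnel, "no-known-domain", length(prev), length(keep))

  prev <- keep; keep <- keep[keep %in% names(structures)]
  verdicts <- verdict_add(verdicts, prev, "structure-available", keep)
  funnel <- funnel_add(funnel, "structure-available", length(prev),
                       length(keep))

  hits <- align_vs_references(keep, catalog, structures, acr_refs,
                              config$acr_tm_cut, strict = FALSE, config,
                              align_cfg, scoring)
  with_hit <- unique(hits$candidate_id)
  verdicts <- verdict_add(verdicts, keep, "structural-similarity", with_hit,
                          sprintf("TM(shorter) >= %.2f", config$acr_tm_cut))
  funnel <- funnel_add(funnel, "structural-similarity", length(keep),
                       length(with_hit))

  hits$best <- logical(nrow(hits))
  if (nrow(hits))
    for (rid in unique(hits$reference_id)) {
      sel <- which(hits$reference_id == rid)
      hits$best[sel[which.max(hits$tm_shorter[sel])]] <- TRUE
    }

  list(reports = build_reports(ids, verdicts, hits), funnel = funnel,
       hits = hits, clusters = clusters)
}

#' The single-gene defense-candidate screen
#'
#' Cascade over the proteins mined from inter-system regions, in order:
#' (1) greedy clustering at `defense_cluster_id`; (2) domain filter (no
#' CDD-style hit); (3) length at least `defense_min_len` (exactly 200 aa is
#' retained); (4) structure availability; (5) structural alignment against
#' the single-gene defense references, a hit needs TM strictly above
#' `defense_tm_cut`; (6) sequence-divergence check versus the references so
#' only remote homologs survive.
#'
#' @inheritParams acr_screen
#' @param intervening a [protein_records()] table (e.g. from
#'   [extract_intervening_proteins()]).
#' @param defense_refs `list(records =, structures =)` of single-gene defense
#'   systems.
#' @return `list(reports, funnel, hits, clusters)`.
#' @export
defense_candidate_screen <- function(intervening, structures, defense_refs,
                                     domains = NULL, config = screen_config(),
                                     align_cfg = align_config(),
                                     scoring = aln_scoring()) {
  if (is.null(defense_refs$structures) || length(defense_refs$structures) == 0)
    stop("empty defense reference set")
  funnel <- new_funnel()
  verdicts <- list()
  ids <- intervening$protein_id

  if (nrow(intervening)) {
    clusters <- greedy_cluster(intervening, config$defense_cluster_id,
                               scoring)
  } else {
    clusters <- data.frame(cluster_id = character(0),
                           centroid_id = character(0))
    clusters$member_ids <- list()
  }
  keep <- clusters$centroid_id
  verdicts <- verdict_add(verdicts, ids, "cluster-centroid", keep,
                          sprintf("%.0f%% identity",
                                  100 * config$defense_cluster_id))
  funnel <- funnel_add(funnel, "cluster-centroid", length(ids), length(keep))

  dom_hit <- domain_hit_ids(keep, domains, config$domain_evalue_cut)
  prev <- keep; keep <- setdiff(keep, dom_hit)
  verdicts <- verdict_add(verdicts, prev, "no-known-domain", keep)
  funnel <- funnel_add(funnel, "no-known-domain", length(prev), length(keep))

  prev <- keep
  lens <- intervening$length[match(keep, intervening$protein_id)]
  keep <- keep[lens >= config$defense_min_len]
  verdicts <- verdict_add(verdicts, prev, "length", keep,
                          sprintf(">= %d aa", config$defense_min_len))
  funnel <- funnel_add(funnel, "length", length(prev), length(keep))

  prev <- keep; keep <- keep[keep %in% names(structures)]
  verdicts <- verdict_add(verdicts, prev, "structure-available", keep)
  funnel <- funnel_add(funnel, "structure-available", length(prev),
                       length(keep))

  hits <- align_vs_references(keep, intervening, structures, defense_refs,
                              config$defense_tm_cut, strict = TRUE, config,
                              align_cfg, scoring)
  with_hit <- unique(hits$candidate_id)
  verdicts <- verdict_add(verdicts, keep, "structural-similarity", with_hit,
                          sprintf("TM(shorter) > %.2f", config$defense_tm_cut))
  funnel <- funnel_add(funnel, "structural-similarity", length(keep),
                       length(with_hit))

  prev <- with_hit
  if (!is.null(defense_refs$records) && length(prev)) {
    div <- divergence_filter(
      intervening[match(prev, intervening$protein_id), , drop = FALSE],
      defense_refs$records, config$max_ref_identity, config$evalue_cut,
      scoring)
    keep <- div$retained$protein_id
  } else keep <- prev
  verdicts <- verdict_add(verdicts, prev, "sequence-divergence", keep)
  funnel <- funnel_add(funnel, "sequence-divergence", length(prev),
                       length(keep))

  hits <- hits[hits$candidate_id %in% keep, , drop = FALSE]
  hits$best <- logical(nrow(hits))
  if (nrow(hits))
    for (rid in unique(hits$reference_id)) {
      sel <- which(hits$reference_id == rid)
      hits$best[sel[which.max(hits$tm_shorter[sel])]] <- TRUE
    }

  list(reports = build_reports(ids, verdicts, hits), funnel = funnel,
       hits = hits, clusters = clusters)
}

#' The counter-defense remote-homolog rule
#'
#' Pairwise rule over candidate x reference pairs: retain a pair iff the
#' shorter-chain TM-score exceeds `counter_tm_cut`, the shorter sequence is
#' at least `counter_len_ratio` of the longer's length, and there is NO
#' detectable sequence similarity (identity at most `max_ref_identity` and
#' E-value at least `evalue_cut`). All three criteria are reported per pair.
#'
#' @param candidates `list(records =, structures =)`.
#' @param refs `list(records =, structures =)` of counter-defense references
#'   (anti-CBASS, anti-RecBCD, anti-restriction, anti-Thoeris and the like).
#' @param config a [screen_config()].
#' @param align_cfg an [align_config()].
#' @param scoring an [aln_scoring()].
#' @return `data.frame` with one row per pair: TM scores, length ratio,
#'   identity, evalue, the three criterion flags and `retained`.
#' @export
counterdefense_screen <- function(candidates, refs, config = screen_config(),
                                  align_cfg = align_config(),
                                  scoring = aln_scoring()) {
  rows <- list()
  n_db <- sum(refs$records$length)
  for (cid in names(candidates$structures)) {
    crec <- candidates$records[candidates$records$protein_id == cid, ]
    for (rid in names(refs$structures)) {
      rrec <- refs$records[refs$records$protein_id == rid, ]
      al <- structure_align(candidates$structures[[cid]],
                            refs$structures[[rid]], align_cfg)
      ratio <- min(crec$length, rrec$length) / max(crec$length, rrec$length)
      sal <- local_align(crec$sequence, rrec$sequence, scoring)
      ev <- karlin_altschul_evalue(sal$score, crec$length, n_db)
      tm_ok <- al$tm_shorter > config$counter_tm_cut
      len_ok <- ratio >= config$counter_len_ratio
      div_ok <- !(ev < config$evalue_cut ||
                    (ev <= config$evalue_cut &&
                       sal$identity > config$max_ref_identity))
      rows[[length(rows) + 1]] <- data.frame(
        candidate_id = cid, reference_id = rid,
        tm_shorter = al$tm_shorter, length_ratio = ratio,
        identity = sal$identity, evalue = ev,
        tm_ok = tm_ok, length_ok = len_ok, divergence_ok = div_ok,
        retained = tm_ok && len_ok && div_ok, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(candidate_id = character(0)))
  do.call(rbind, rows)
}

interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}

#' Scan candidate reports for multi-reference hits and putative fusions
#'
#' Selects candidates hit (TM at or above `acr_tm_cut`) by at least two
#' DISTINCT references, annotates the candidate-side aligned interval per
#' reference and the pairwise segment overlap (Jaccard over candidate residue
#' indices), and flags candidates whose two reference hits cover disjoint
#' segments (Jaccard below `fusion_jaccard`) as putative fusions.
#'
#' @param reports candidate reports from [acr_screen()] (or a compatible
#'   screen), whose hits carry `qstart`/`qend`.
#' @param config a [screen_config()].
#' @return `data.frame`: `candidate_id`, `n_references`, `reference_ids`
#'   (list column), `segments` (list column of intervals), `jaccard_min`,
#'   `putative_fusion`.
#' @export
fusion_scan <- function(reports, config = screen_config()) {
  rows <- list()
  for (r in reports) {
    h <- r$reference_hits
    if (is.null(h) || nrow(h) == 0) next
    h <- h[h$tm_shorter >= config$acr_tm_cut, , drop = FALSE]
    h <- h[!duplicated(h$reference_id), , drop = FALSE]  # best per reference
    if (nrow(h) < 2) next
    segs <- lapply(seq_len(nrow(h)), function(i) c(h$qstart[i], h$qend[i]))
    jmin <- Inf
    for (i in seq_len(nrow(h) - 1)) for (j in (i + 1):nrow(h))
      jmin <- min(jmin, interval_jaccard(segs[[i]], segs[[j]]))
    rows[[length(rows) + 1]] <- data.frame(
      candidate_id = r$candidate_id, n_references = nrow(h),
      jaccard_min = jmin, putative_fusion = jmin < config$fusion_jaccard,
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$reference_ids <- list(h$reference_id)
    rows[[length(rows)]]$segments <- list(segs)
  }
  if (!length(rows))
    return(data.frame(candidate_id = character(0), n_references = integer(0),
                      jaccard_min = numeric(0), putative_fusion = logical(0)))
  do.call(rbind, rows)
}

#' Check funnel-log conservation
#'
#' Asserts that every stage satisfies `n_in == n_retained + n_excluded` and
#' that consecutive stages chain (`n_in` of stage k+1 equals `n_retained` of
#' stage k).
#'
#' @param funnel a funnel `data.frame` as returned by the screens.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_funnel <- function(funnel) {
  bad <- which(funnel$n_in != funnel$n_retained + funnel$n_excluded)
  if (length(bad))
    stop("funnel conservation violated at stage '", funnel$stage[bad[1]], "'")
  if (nrow(funnel) > 1) {
    chain <- funnel$n_in[-1] != funnel$n_retained[-nrow(funnel)]
    if (any(chain))
      stop("funnel chaining violated before stage '",
           funnel$stage[which(chain)[1] + 1], "'")
  }
  invisible(TRUE)
}
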