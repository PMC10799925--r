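#' @title Pairwise sequence alignment, greedy clustering, divergence filter
#' @description Needleman-Wunsch / Smith-Waterman alignment with BLASTP-style
#'   scoring (the BLASTP stand-in), Karlin-Altschul E-values, greedy
#'   identity-threshold centroid clustering (the USEARCH stand-in), and the
#'   sequence-divergence exclusion filter used to keep only remote homologs.
#' @name seqcluster
NULL

#' Alignment scoring scheme
#'
#' BLASTP defaults: BLOSUM62 with affine gaps, where a gap of length L costs
#' `gap_open + L * gap_extend` (open 11, extend 1).
#'
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend positive gap costs.
#' @return a list of class `aln_scoring`.
#' @export
aln_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(ls(e)[1], envir = e)
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "aln_scoring")
}

#' Karlin-Altschul parameters
#'
#' Standard constants for gapped BLOSUM62 (11/1) local alignment statistics:
#' `lambda = 0.267` nats per raw score unit, `K = 0.041`.
#'
#' @param lambda scale, > 0.
#' @param K search-space constant, > 0.
#' @return a list of class `ka_params`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(lambda = lambda, K = K), class = "ka_params")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: monotone decreasing in score and
#' proportional to the search space `m * n`.
#'
#' @param score raw local alignment score.
#' @param m query length (>= 1).
#' @param n database residue count (>= 1).
#' @param params a [ka_params()].
#' @return the expected number of chance hits at this score.
#' @export
karlin_altschul_evalue <- function(score, m, n, params = ka_params()) {
  if (m < 1 || n < 1) stop("m and n must be >= 1")
  params$K * m * n * exp(-params$lambda * score)
}

aln_stats <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  n_columns <- length(p)
  n_identical <- sum(p == s & p != "-")
  list(n_identical = n_identical, n_columns = n_columns,
       identity = if (n_columns) n_identical / n_columns else 0)
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Optimal global alignment under the scoring scheme. Identity is the number
#' of identical columns divided by the total number of alignment columns,
#' terminal gaps included -- the stricter denominator used for clustering.
#'
#' @param a,b non-empty sequences.
#' @param scoring an [aln_scoring()].
#' @return a list of class `seq_alignment` with fields `query`, `subject`
#'   (aligned strings), `score`, `n_identical`, `n_columns`, `identity`.
#' @export
global_align <- function(a, b, scoring = aln_scoring()) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- as.character(Biostrings::alignedPattern(al))
  sub <- as.character(Biostrings::alignedSubject(al))
  st <- aln_stats(pat, sub)
  structure(c(list(query = pat, subject = sub, score = Biostrings::score(al),
                   type = "global"), st), class = "seq_alignment")
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Optimal local alignment under the scoring scheme, with identity computed
#' over the local alignment columns only (BLAST semantics) and a
#' Karlin-Altschul E-value attached.
#'
#' @param a,b non-empty sequences.
#' @param scoring an [aln_scoring()].
#' @param params a [ka_params()].
#' @return a `seq_alignment` with additional fields `evalue`, `query_range`,
#'   `subject_range`.
#' @export
local_align <- function(a, b, scoring = aln_scoring(), params = ka_params()) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- as.character(Biostrings::alignedPattern(al))
  sub <- as.character(Biostrings::alignedSubject(al))
  st <- aln_stats(pat, sub)
  sc <- Biostrings::score(al)
  structure(c(list(query = pat, subject = sub, score = sc, type = "local",
                   query_range = c(Biostrings::start(Biostrings::pattern(al)),
                                   Biostrings::end(Biostrings::pattern(al))),
                   subject_range = c(Biostrings::start(Biostrings::subject(al)),
                                     Biostrings::end(Biostrings::subject(al))),
                   evalue = karlin_altschul_evalue(sc, nchar(a), nchar(b),
                                                   params)),
              st), class = "seq_alignment")
}

# identity of each sequence in `seqs` against `ref`, global, vectorized;
# identical columns / alignment columns (terminal gaps included, which for a
# global alignment is the full alignment width)
global_identities <- function(seqs, ref, scoring) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(ref), type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Greedy identity-threshold clustering
#'
#' Deterministic centroid clustering in the USEARCH role: records are visited
#' in seed order (length descending, ties by id), each record joins the first
#' existing centroid with global identity at or above the threshold, else
#' founds a new cluster. Clusters partition the input.
#'
#' @param records a [protein_records()] table.
#' @param threshold identity fraction in (0, 1].
#' @param scoring an [aln_scoring()].
#' @return a `data.frame` with one row per cluster: `cluster_id`,
#'   `centroid_id`, `member_ids` (list column) and `threshold`.
#' @export
greedy_cluster <- function(records, threshold, scoring = aln_scoring()) {
  if (nrow(records) == 0) stop("no records to cluster")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  ord <- order(-records$length, records$protein_id)
  recs <- records[ord, , drop = FALSE]
  centroid_seq <- character(0)
  centroid_id <- character(0)
  members <- list()
  for (i in seq_len(nrow(recs))) {
    assigned <- 0L
    if (length(centroid_seq)) {
      # identity <= shorter/longer length ratio, so pairs below the
      # threshold on length alone need no alignment
      cl <- nchar(centroid_seq); rl <- recs$length[i]
      feasible <- which(pmin(cl, rl) / pmax(cl, rl) >= threshold)
      if (length(feasible)) {
        ident <- global_identities(centroid_seq[feasible],
                                   recs$sequence[i], scoring)
        hit <- feasible[ident >= threshold]
        if (length(hit)) assigned <- hit[1]
      }
    }
    if (assigned) {
      members[[assigned]] <- c(members[[assigned]], recs$protein_id[i])
    } else {
      centroid_seq <- c(centroid_seq, recs$sequence[i])
      centroid_id <- c(centroid_id, recs$protein_id[i])
      members[[length(centroid_id)]] <- recs$protein_id[i]
    }
  }
  out <- data.frame(cluster_id = sprintf("C%04d", seq_along(centroid_id)),
                    centroid_id = centroid_id, stringsAsFactors = FALSE)
  out$member_ids <- members
  out$threshold <- threshold
  out
}

#' Sequence-divergence exclusion filter
#'
#' The remote-homolog gate, with BLASTP-run semantics: every candidate is
#' locally aligned to every reference, E-values are computed against the
#' whole reference set (`n` = total reference residues, database-search
#' statistics), and alignments reported at the run's E-value cutoff
#' (`report_evalue`) count as hits. A candidate is excluded when any hit has
#' identity above `max_identity` or E-value below `evalue_cut` -- detectable
#' sequence similarity disqualifies it. With the default
#' `report_evalue == evalue_cut` the E-value clause decides and the identity
#' clause labels high-identity exclusions; raising `report_evalue` (e.g. to
#' BLAST's reporting default of 10) makes the identity clause bite on weaker
#' hits too. Each exclusion records the triggering reference and criterion.
#'
#' @param candidates a [protein_records()] table (typically cluster centroids).
#' @param references a non-empty [protein_records()] table of known proteins.
#' @param max_identity exclusion identity threshold (default 0.30).
#' @param evalue_cut exclusion E-value threshold (default 0.1).
#' @param scoring an [aln_scoring()].
#' @param params a [ka_params()].
#' @param report_evalue E-value cutoff of the simulated BLAST run; only
#'   alignments at or below it are hits (default `evalue_cut`).
#' @return `list(retained =, excluded =)`; `excluded` carries columns
#'   `trigger_reference`, `trigger_criterion`, `identity`, `evalue`.
#' @export
divergence_filter <- function(candidates, references, max_identity = 0.30,
                              evalue_cut = 0.1, scoring = aln_scoring(),
                              params = ka_params(),
                              report_evalue = evalue_cut) {
  if (nrow(references) == 0) stop("reference set is empty")
  n_db <- sum(references$length)
  n <- nrow(candidates)
  excl <- logical(n)
  trig_ref <- trig_crit <- rep(NA_character_, n)
  trig_id <- trig_ev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(references$sequence),
      Biostrings::AAString(candidates$sequence[i]), type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    ident <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    ev <- karlin_altschul_evalue(Biostrings::score(al),
                                 candidates$length[i], n_db, params)
    hit <- which(ev <= report_evalue &
                   (ident > max_identity | ev < evalue_cut))
    if (length(hit)) {
      j <- hit[1]
      excl[i] <- TRUE
      trig_ref[i] <- references$protein_id[j]
      trig_crit[i] <- if (ident[j] > max_identity) "identity" else "evalue"
      trig_id[i] <- ident[j]
      trig_ev[i] <- ev[j]
    }
  }
  excluded <- candidates[excl, , drop = FALSE]
  excluded$trigger_reference <- trig_ref[excl]
  excluded$trigger_criterion <- trig_crit[excl]
  excluded$identity <- trig_id[excl]
  excluded$evalue <- trig_ev[excl]
  list(retained = candidates[!excl, , drop = FALSE], excluded = excluded)
}
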