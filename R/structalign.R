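#' @title Native TM-score structural alignment of CA traces
#' @description Kabsch least-squares superposition, the TM-score functional
#'   under explicit length normalizations, and a seed + iterative dynamic
#'   programming alignment search in the TM-align tradition. Sequence-order
#'   dependent only; CA traces suffice for the TM-score.
#' @name structalign
NULL

#' Alignment search configuration
#'
#' @param d0_floor lower bound on the d0 distance scale in Angstrom
#'   (default 0.5; keeps the TM-score defined for chains under 22 residues).
#' @param gap_open linear dynamic-programming gap penalty (default -0.6,
#'   no extension penalty; terminal gaps are free).
#' @param max_iterations cap on superposition/DP refinement rounds.
#' @param seed_fragment_length window length for fragment seeds.
#' @param convergence stop when the TM-score improves by less than this.
#' @param tm_norm which normalization screening decisions use
#'   (`"shorter"`, `"query"` or `"target"`).
#' @return a list of class `align_config`.
#' @export
align_config <- function(d0_floor = 0.5, gap_open = -0.6, max_iterations = 20L,
                         seed_fragment_length = 20L, convergence = 1e-6,
                         tm_norm = c("shorter", "query", "target")) {
  if (d0_floor <= 0) stop("d0_floor must be positive")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(d0_floor = d0_floor, gap_open = gap_open,
                 max_iterations = as.integer(max_iterations),
                 seed_fragment_length = as.integer(seed_fragment_length),
                 convergence = convergence, tm_norm = match.arg(tm_norm)),
            class = "align_config")
}

#' Kabsch superposition
#'
#' Closed-form least-squares rigid superposition of index-paired point sets
#' via SVD, with the reflection corrected so the rotation is always proper
#' (determinant +1). The transform maps `P` onto `Q`:
#' `P' = P %*% t(rotation) + translation`.
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3, row i of P paired with
#'   row i of Q.
#' @return `list(rotation, translation, rmsd)` with `rmsd` the minimized
#'   root-mean-square deviation.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("P and Q must be paired n x 3 matrices")
  if (nrow(P) < 3) stop("superposition needs at least 3 points")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cq - as.vector(R %*% cp)
  Pfit <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pfit - Qc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8` Angstrom, floored at `d0_floor` so the
#' score stays defined for short chains (the floor engages for L <= 21).
#'
#' @param L_norm normalizing chain length (>= 1).
#' @param d0_floor lower bound in Angstrom.
#' @return d0 in Angstrom, monotone non-decreasing in `L_norm`.
#' @export
tm_d0 <- function(L_norm, d0_floor = 0.5) {
  if (any(L_norm < 1)) stop("L_norm must be >= 1")
  raw <- ifelse(L_norm > 15, 1.24 * (L_norm - 15)^(1 / 3) - 1.8, -Inf)
  pmax(raw, d0_floor)
}

pair_dists <- function(query_xyz, target_xyz, pairs, rotation, translation) {
  qf <- apply_transform(query_xyz[pairs[, 1], , drop = FALSE],
                        rotation, translation)
  sqrt(rowSums((qf - target_xyz[pairs[, 2], , drop = FALSE])^2))
}

tm_sum <- function(d, d0, L_norm) sum(1 / (1 + (d / d0)^2)) / L_norm

#' TM-score for a fixed residue correspondence
#'
#' Maximizes `(1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)` over rigid
#' superpositions by iterative refinement: start from the Kabsch fit on all
#' pairs (and on sliding windows of `seed_fragment_length` pairs), then
#' repeatedly re-superpose on the close subset `d_i < max(2 d0, 4.5)` until
#' the score converges. The running best never decreases.
#'
#' @param query,target [ca_trace()] models.
#' @param pairs m x 2 matrix of (query index, target index), m >= 3.
#' @param L_norm normalizing length.
#' @param config an [align_config()].
#' @return `list(tm, rmsd, rotation, translation, trace)`; `rmsd` is over the
#'   aligned pairs under the Kabsch fit, `trace` is the running-best TM per
#'   refinement step.
#' @export
tm_from_pairs <- function(query, target, pairs, L_norm,
                          config = align_config()) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 aligned pairs")
  d0 <- tm_d0(L_norm, config$d0_floor)
  P <- query$coords[pairs[, 1], , drop = FALSE]
  Q <- target$coords[pairs[, 2], , drop = FALSE]
  n <- nrow(pairs)
  starts <- list(seq_len(n))
  lf <- config$seed_fragment_length
  if (n > lf) {
    for (s in seq(1, n - lf + 1, by = max(1L, lf %/% 2L)))
      starts[[length(starts) + 1]] <- s:(s + lf - 1)
  }
  best <- list(tm = -Inf)
  trace <- numeric(0)
  for (idx in starts) {
    if (length(idx) < 3) next
    sup <- kabsch_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    prev <- -Inf
    for (it in seq_len(config$max_iterations)) {
      d <- round(sqrt(rowSums((apply_transform(P, sup$rotation,
                                               sup$translation) - Q)^2)), 6)
      tm <- round(tm_sum(d, d0, L_norm), 9)
      if (tm > best$tm)
        best <- list(tm = tm, rotation = sup$rotation,
                     translation = sup$translation)
      trace <- c(trace, best$tm)
      if (abs(tm - prev) < config$convergence) break
      prev <- tm
      keep <- which(d < max(2 * d0, 4.5))
      if (length(keep) < 3) keep <- order(d)[1:3]
      sup <- kabsch_superpose(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    }
  }
  full <- kabsch_superpose(P, Q)
  list(tm = best$tm, rmsd = full$rmsd, rotation = best$rotation,
       translation = best$translation, trace = trace)
}

# gapless correspondence of query/target at a given shift (j = i + shift)
gapless_pairs <- function(Lq, Lt, shift) {
  i <- max(1L, 1L - shift):min(Lq, Lt - shift)
  cbind(i, i + shift)
}

# one seed -> iterative DP refinement; returns best pairs/tm under L_norm
refine_seed <- function(qxyz, txyz, sup, d0, L_norm, config) {
  best <- list(tm = -Inf, pairs = NULL, rotation = NULL, translation = NULL)
  prev <- -Inf
  for (it in seq_len(config$max_iterations)) {
    qf <- apply_transform(qxyz, sup$rotation, sup$translation)
    d2 <- outer(rowSums(qf^2), rowSums(txyz^2), "+") - 2 * qf %*% t(txyz)
    d2[d2 < 0] <- 0
    # quantize the similarity matrix so DP tie-breaks fall identically in
    # every coordinate frame (rigid-transform invariance of the search)
    S <- round(1 / (1 + d2 / d0^2), 6)
    pairs <- .dp_trace(S, config$gap_open)
    if (nrow(pairs) < 3) break
    sup2 <- kabsch_superpose(qxyz[pairs[, 1], , drop = FALSE],
                             txyz[pairs[, 2], , drop = FALSE])
    d <- round(pair_dists(qxyz, txyz, pairs, sup2$rotation,
                          sup2$translation), 6)
    tm <- round(tm_sum(d, d0, L_norm), 9)
    # re-superpose on the close subset for the next DP round
    keep <- which(d < max(2 * d0, 4.5))
    if (length(keep) >= 3) {
      supc <- kabsch_superpose(qxyz[pairs[keep, 1], , drop = FALSE],
                               txyz[pairs[keep, 2], , drop = FALSE])
      dc <- round(pair_dists(qxyz, txyz, pairs, supc$rotation,
                             supc$translation), 6)
      tmc <- round(tm_sum(dc, d0, L_norm), 9)
      if (tmc > tm) { tm <- tmc; sup2 <- supc }
    }
    if (tm > best$tm)
      best <- list(tm = tm, pairs = pairs, rotation = sup2$rotation,
                   translation = sup2$translation)
    if (abs(tm - prev) < config$convergence) break
    prev <- tm
    sup <- sup2
  }
  best
}

#' Pairwise structural alignment
#'
#' Heuristic TM-score alignment search: initial correspondences come from
#' (a) gapless threading of the shorter chain onto the longer at every
#' offset and (b) Kabsch superpositions of all fragment-window pairs whose
#' quick score beats the running best; each surviving seed is expanded by
#' iterative dynamic programming (similarity `1/(1 + (d_ij/d0)^2)` under the
#' current superposition, linear gap penalty, re-superpose on the new pairs)
#' until the TM-score converges. The best alignment by the shorter-chain
#' normalization is reported with all three TM normalizations filled in,
#' each under its own d0. Deterministic for a fixed configuration.
#'
#' @param query,target [ca_trace()] models with at least 3 residues.
#' @param config an [align_config()].
#' @return a list of class `struct_alignment`: `query_id`, `target_id`,
#'   `pairs` (strictly increasing in both indices), `rotation`,
#'   `translation`, `rmsd`, `tm_query`, `tm_target`, `tm_shorter`.
#' @export
structure_align <- function(query, target, config = align_config()) {
  qxyz <- query$coords; txyz <- target$coords
  Lq <- nrow(qxyz); Lt <- nrow(txyz)
  Ls <- min(Lq, Lt)
  d0s <- tm_d0(Ls, config$d0_floor)
  lf <- min(config$seed_fragment_length, Ls)

  # (a) threading seeds: shorter gapless inside longer
  shifts <- if (Lq <= Lt) 0:(Lt - Lq) else -(0:(Lq - Lt))
  seeds <- lapply(shifts, function(s) gapless_pairs(Lq, Lt, s))

  best <- list(tm = -Inf, pairs = NULL)
  quick_best <- -Inf
  first <- TRUE
  for (sp in seeds) {
    if (nrow(sp) < 3) next
    sup <- kabsch_superpose(qxyz[sp[, 1], , drop = FALSE],
                            txyz[sp[, 2], , drop = FALSE])
    d <- pair_dists(qxyz, txyz, sp, sup$rotation, sup$translation)
    quick <- round(tm_sum(d, d0s, Ls), 9)   # frame-stable gating
    if (quick > quick_best || first) {
      quick_best <- max(quick_best, quick)
      first <- FALSE
      res <- refine_seed(qxyz, txyz, sup, d0s, Ls, config)
      if (res$tm > best$tm) best <- res
    }
  }

  # (b) fragment seeds: window-vs-window superpositions; quick-score by the
  # TM of the gapless extension at the fragment's shift, refine climbers
  if (lf >= 3) {
    qstarts <- seq(1, Lq - lf + 1, by = max(1L, lf %/% 2L))
    tstarts <- seq(1, Lt - lf + 1, by = max(1L, lf %/% 2L))
    for (qs in qstarts) for (ts in tstarts) {
      wp <- cbind(qs:(qs + lf - 1), ts:(ts + lf - 1))
      sup <- kabsch_superpose(qxyz[wp[, 1], , drop = FALSE],
                              txyz[wp[, 2], , drop = FALSE])
      ext <- gapless_pairs(Lq, Lt, ts - qs)
      d <- pair_dists(qxyz, txyz, ext, sup$rotation, sup$translation)
      quick <- round(tm_sum(d, d0s, Ls), 9)
      if (quick > quick_best) {
        quick_best <- quick
        res <- refine_seed(qxyz, txyz, sup, d0s, Ls, config)
        if (res$tm > best$tm) best <- res
      }
    }
  }

  if (is.null(best$pairs)) {
    # degenerate fall-back: full gapless threading at shift 0
    best$pairs <- gapless_pairs(Lq, Lt, 0L)
  }
  pairs <- best$pairs
  tmq <- tm_from_pairs(query, target, pairs, Lq, config)
  tmt <- tm_from_pairs(query, target, pairs, Lt, config)
  tms <- if (Lq <= Lt) tmq else tmt
  sup <- kabsch_superpose(qxyz[pairs[, 1], , drop = FALSE],
                          txyz[pairs[, 2], , drop = FALSE])
  structure(list(query_id = query$protein_id, target_id = target$protein_id,
                 pairs = pairs, rotation = tms$rotation,
                 translation = tms$translation, rmsd = sup$rmsd,
                 tm_query = tmq$tm, tm_target = tmt$tm, tm_shorter = tms$tm),
            class = "struct_alignment")
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf("<struct_alignment> %s vs %s: %d pairs, rmsd %.2f A, ",
              x$query_id, x$target_id, nrow(x$pairs), x$rmsd))
  cat(sprintf("TM(query) %.3f, TM(target) %.3f, TM(shorter) %.3f\n",
              x$tm_query, x$tm_target, x$tm_shorter))
  invisible(x)
}

# the TM score a screen should act on, per config$tm_norm
tm_decision <- function(alignment, config) {
  switch(config$tm_norm, shorter = alignment$tm_shorter,
         query = alignment$tm_query, target = alignment$tm_target)
}

#' All-vs-all structural alignment
#'
#' Aligns every unordered pair of models once (query = lexicographically
#' smaller id, diagonal omitted) and attaches a symmetric square matrix view
#' of `tm_shorter` for reporting.
#'
#' @param models list of [ca_trace()] models (>= 2).
#' @param config an [align_config()].
#' @return list with `alignments` (length n(n-1)/2) and `tm_matrix`
#'   (symmetric, unit diagonal).
#' @export
all_vs_all <- function(models, config = align_config()) {
  if (length(models) < 2) stop("need at least 2 models")
  ids <- vapply(models, function(m) m$protein_id, "")
  if (anyDuplicated(ids)) stop("duplicate model ids")
  models <- models[order(ids)]
  ids <- sort(ids)
  n <- length(models)
  mat <- diag(1, n)
  dimnames(mat) <- list(ids, ids)
  alns <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- structure_align(models[[i]], models[[j]], config)
    alns[[length(alns) + 1]] <- al
    mat[i, j] <- mat[j, i] <- al$tm_shorter
  }
  list(alignments = alns, tm_matrix = mat)
}
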