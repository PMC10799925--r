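# Independent oracles used across the suite. Each is a straightforward,
# self-contained computation of the quantity it checks, deliberately not
# sharing code with the implementation path it validates.

# Optimal pairwise alignment score by memoized recursion over all alignments
# (states: M = last column was a substitution, X = gap in b, Y = gap in a).
# A gap of length L costs open + L * extend, as in the package's scoring.
oracle_align_score <- function(a, b, mat, open = 11, extend = 1,
                               type = c("global", "local")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[av[i], bv[j]]
    best_prev <- max(M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- best_prev + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                           X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                           Y[i + 1, j] - extend)
    if (type == "local") {
      M[i + 1, j + 1] <- max(M[i + 1, j + 1], 0)
    }
  }
  if (type == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else max(M)
}

# Truly exhaustive recursion over every alignment path (tiny inputs only);
# used to validate the memoized oracle itself.
oracle_enumerate_global <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(av))
      best <- max(best, -(if (state == "X") extend else open + extend) +
                    rec(i + 1, j, "X"))
    if (j <= length(bv))
      best <- max(best, -(if (state == "Y") extend else open + extend) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

# Brute-force rigid superposition: dense Euler-angle grid with optimal
# translation (centroid matching) per rotation, then Nelder-Mead refinement.
oracle_kabsch_rmsd <- function(P, Q, grid_deg = 20) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  rotmat <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((Pc %*% t(rotmat(ang)) - Qc)^2)))
  gs <- seq(0, 2 * pi, by = grid_deg * pi / 180)
  gb <- seq(0, pi, by = grid_deg * pi / 180)
  best <- c(0, 0, 0); bv <- obj(best)
  for (a1 in gs) for (b1 in gb) for (g1 in gs) {
    v <- obj(c(a1, b1, g1))
    if (v < bv) { bv <- v; best <- c(a1, b1, g1) }
  }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(bv, res$value)
}

# Brute-force TM-score for a FIXED residue correspondence: Kabsch fits on
# every contiguous window of the pairs (all offsets, several widths), each
# iterated to a fixpoint on its close subset; the maximum TM wins.
oracle_tm_fixed_pairs <- function(qxyz, txyz, pairs, L_norm, d0) {
  P <- qxyz[pairs[, 1], , drop = FALSE]
  Q <- txyz[pairs[, 2], , drop = FALSE]
  n <- nrow(pairs)
  kab <- function(idx) {
    p <- P[idx, , drop = FALSE]; q <- Q[idx, , drop = FALSE]
    cp <- colMeans(p); cq <- colMeans(q)
    H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
    s <- svd(H)
    R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
    list(R = R, t = cq - as.vector(R %*% cp))
  }
  tm_of <- function(sup) {
    d <- sqrt(rowSums((sweep(P %*% t(sup$R), 2, sup$t, "+") - Q)^2))
    sum(1 / (1 + (d / d0)^2)) / L_norm
  }
  best <- -Inf
  widths <- unique(pmin(n, c(3, 4, 6, 9, 14, 21, 32, 48, 72, n)))
  for (w in widths) for (s0 in seq(1, n - w + 1)) {
    sup <- kab(s0:(s0 + w - 1))
    for (it in 1:30) {
      tm <- tm_of(sup)
      if (tm > best) best <- tm
      d <- sqrt(rowSums((sweep(P %*% t(sup$R), 2, sup$t, "+") - Q)^2))
      keep <- which(d < max(2 * d0, 4.5))
      if (length(keep) < 3) break
      sup2 <- kab(keep)
      if (abs(tm_of(sup2) - tm) < 1e-9) { best <- max(best, tm_of(sup2)); break }
      sup <- sup2
    }
  }
  best
}

# Dense grid scan for the isoelectric point: coarse pass over the full pH
# range, then a fine 1e-4 grid around the sign change (the charge is
# monotone, so the root lies inside the bracketing coarse cell).
oracle_pi_grid <- function(sequence, pka, step = 1e-4) {
  coarse <- seq(step, 14 - step, by = 0.01)
  qc <- vapply(coarse, function(p) net_charge(sequence, p, pka), 0)
  c0 <- coarse[which.min(abs(qc))]
  fine <- seq(max(step, c0 - 0.02), min(14 - step, c0 + 0.02), by = step)
  qf <- vapply(fine, function(p) net_charge(sequence, p, pka), 0)
  fine[which.min(abs(qf))]
}

# Plain re-statement of the greedy clustering rule, one pairwise alignment
# at a time, no length prefilter, no vectorization.
oracle_greedy_cluster <- function(records, threshold) {
  ord <- order(-records$length, records$protein_id)
  recs <- records[ord, , drop = FALSE]
  cents <- character(0); assign_to <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    found <- NA_character_
    for (cid in cents) {
      cseq <- records$sequence[records$protein_id == cid]
      if (global_align(cseq, recs$sequence[i])$identity >= threshold) {
        found <- cid; break
      }
    }
    if (is.na(found)) {
      cents <- c(cents, recs$protein_id[i])
      assign_to[i] <- recs$protein_id[i]
    } else assign_to[i] <- found
  }
  split(recs$protein_id, factor(assign_to, levels = cents))
}

random_peptide <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
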