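random_rot <- function(seed) {
  set.seed(seed)
  q <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_that("Kabsch: identity on self, exact recovery of a planted transform", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  k <- kabsch_superpose(P, P)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)
  expect_equal(k$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)

  R0 <- random_rot(4); t0 <- c(3, -2, 7)
  Q <- sweep(P %*% t(R0), 2, t0, "+")
  k2 <- kabsch_superpose(P, Q)
  expect_equal(k2$rmsd, 0, tolerance = 1e-9)
  expect_equal(k2$rotation, R0, tolerance = 1e-9)
  expect_equal(k2$translation, t0, tolerance = 1e-9)
})

test_that("Kabsch returns a proper rotation even for planted reflections", {
  set.seed(2)
  P <- matrix(rnorm(24), 8)
  Q <- P %*% diag(c(1, 1, -1))   # mirror image
  k <- kabsch_superpose(P, Q)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_gt(k$rmsd, 0)
})

test_that("Kabsch handles collinear points and rejects degenerate input", {
  P <- cbind(1:5, 0, 0)
  k <- kabsch_superpose(P, P)          # rank-deficient covariance
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  Pn <- P; Pn[1, 1] <- NaN
  expect_error(kabsch_superpose(Pn, P), "non-finite")
})

test_that("Kabsch RMSD matches the Euler-grid brute-force minimizer", {
  for (s in 1:6) {
    set.seed(s)
    P <- matrix(rnorm(24), 8)
    Q <- sweep(P %*% t(random_rot(s + 50)), 2, runif(3, -5, 5), "+") +
      matrix(rnorm(24, sd = 0.5), 8)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_kabsch_rmsd(P, Q),
                 tolerance = 1e-6, info = paste("seed", s))
  }
})

test_that("d0 closed form, floor and monotonicity", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(100), 3.652, tolerance = 1e-3)
  expect_equal(tm_d0(15), 0.5)            # formula is negative, floored
  expect_equal(tm_d0(21), 0.5)            # floor still engaged at 21
  expect_gt(tm_d0(22), 0.5)
  d <- tm_d0(1:500)
  expect_true(all(diff(d) >= 0))
})

test_that("TM from pairs: exact identity, rigid invariance, monotone ascent", {
  m <- gen_fold("helix_hairpin", 50, seed = 2)
  pairs <- cbind(1:50, 1:50)
  res <- tm_from_pairs(m, m, pairs, 50)
  expect_equal(res$tm, 1.0, tolerance = 1e-9)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_true(all(diff(res$trace) >= 0))   # running best never decreases

  m2 <- m
  m2$coords <- sweep(m$coords %*% t(random_rot(9)), 2, c(5, 5, 5), "+")
  res2 <- tm_from_pairs(m, m2, pairs, 50)
  expect_equal(res2$tm, 1.0, tolerance = 1e-6)
  expect_error(tm_from_pairs(m, m, pairs[1:2, ], 50), "3")
})

test_that("TM for a fixed correspondence matches the dense-search oracle", {
  for (s in 1:3) {
    m <- gen_fold("helix", 40, seed = s)
    mp <- perturb_structure(m, 1.0, rigid = TRUE, seed = s + 20)
    pairs <- cbind(1:40, 1:40)
    got <- tm_from_pairs(m, mp, pairs, 40)$tm
    want <- oracle_tm_fixed_pairs(m$coords, mp$coords, pairs, 40, tm_d0(40))
    expect_equal(got, want, tolerance = 0.02, info = paste("seed", s))
  }
})

test_that("self-alignment is exact for every fold archetype", {
  for (arch in c("helix", "strand", "helix_hairpin", "coil")) {
    m <- gen_fold(arch, 48, seed = 5)
    al <- structure_align(m, m)
    expect_equal(al$tm_query, 1.0, tolerance = 1e-6, info = arch)
    expect_equal(al$tm_target, 1.0, tolerance = 1e-6, info = arch)
    expect_equal(al$rmsd, 0, tolerance = 1e-6, info = arch)
    expect_equal(al$pairs, cbind(i = 1:48, 1:48), ignore_attr = TRUE)
  }
})

test_that("TM scores are invariant under rigid transforms of either input", {
  m <- gen_fold("coil", 60, seed = 8)
  n <- gen_fold("coil", 55, seed = 9)
  base <- structure_align(m, n)
  n2 <- n
  n2$coords <- sweep(n$coords %*% t(random_rot(13)), 2, c(-4, 8, 1), "+")
  moved <- structure_align(m, n2)
  expect_equal(moved$tm_query, base$tm_query, tolerance = 1e-6)
  expect_equal(moved$tm_target, base$tm_target, tolerance = 1e-6)
  expect_equal(moved$tm_shorter, base$tm_shorter, tolerance = 1e-6)
})

test_that("alignment output satisfies its structural invariants", {
  m <- gen_fold("helix_hairpin", 70, seed = 3)
  n <- perturb_structure(m, 1.0, rigid = TRUE, seed = 4)
  al <- structure_align(m, n)
  expect_true(all(diff(al$pairs[, 1]) > 0))      # strictly increasing
  expect_true(all(diff(al$pairs[, 2]) > 0))
  expect_equal(crossprod(al$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(al$rotation), 1, tolerance = 1e-9)
  expect_true(al$tm_shorter > 0 && al$tm_shorter <= 1)
  expect_equal(al$tm_shorter, al$tm_query)       # equal lengths: shorter = query
})

test_that("a truncated rigid copy still aligns nearly perfectly", {
  m <- gen_fold("helix_hairpin", 60, seed = 6)
  trunc <- ca_trace("trunc",
                    sweep(m$coords[1:55, ] %*% t(random_rot(21)), 2,
                          c(2, -7, 4), "+"),
                    m$residues[1:55])
  al <- structure_align(trunc, m)
  expect_gte(al$tm_shorter, 0.95)
})

test_that("a helix and an extended strand are structurally dissimilar", {
  h <- gen_fold("helix", 60, seed = 1)
  s <- gen_fold("strand", 60, seed = 1)
  expect_lt(structure_align(h, s)$tm_shorter, 0.6)
})

test_that("all-vs-all covers every unordered pair and finds the planted match", {
  a1 <- gen_fold("coil", 60, seed = 31, protein_id = "a1")
  a2 <- perturb_structure(a1, 0.6, rigid = TRUE, seed = 32, protein_id = "a2")
  b <- gen_fold("coil", 60, seed = 33, protein_id = "b")
  d <- gen_fold("helix", 60, seed = 34, protein_id = "d")
  res <- all_vs_all(list(a1, a2, b, d))
  expect_length(res$alignments, 6)               # 4*3/2
  expect_equal(res$tm_matrix, t(res$tm_matrix))
  expect_equal(diag(res$tm_matrix), setNames(rep(1, 4), c("a1", "a2", "b", "d")))
  hi <- res$tm_matrix > 0.6 & upper.tri(res$tm_matrix)
  expect_equal(which(hi), which(rownames(res$tm_matrix) == "a1") +
                 4 * (which(colnames(res$tm_matrix) == "a2") - 1))

  same <- gen_fold("helix", 30, seed = 1)
  trip <- all_vs_all(list(ca_trace("x1", same$coords),
                          ca_trace("x2", same$coords),
                          ca_trace("x3", same$coords)))
  expect_true(all(vapply(trip$alignments,
                         function(a) a$tm_shorter, 0) > 0.999))
})
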