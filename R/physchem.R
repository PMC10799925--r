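#' @title Peptide charge and isoelectric point
#' @description Henderson-Hasselbalch net charge, bisection isoelectric point
#'   and the acidity filter used by the Acr screen (candidates with pI above
#'   7 are discarded, because most experimentally validated Acrs are acidic).
#' @name physchem
NULL

#' pKa table (EMBOSS set)
#'
#' Acid-dissociation constants for the ionizable groups of a peptide: the two
#' termini, the basic side chains (K, R, H) and the acidic side chains
#' (D, E, C, Y). The EMBOSS values are the default; any table with the same
#' names can be injected into [net_charge()] and [isoelectric_point()].
#' Absolute pI values are table-dependent; the acid/base partition at pI 7 is
#' robust for strongly acidic or basic sequences.
#'
#' @param N_term,C_term terminal group pKa.
#' @param K,R,H basic side-chain pKa (contribute positive charge).
#' @param D,E,C,Y acidic side-chain pKa (contribute negative charge).
#' @return a named list of class `pka_table`.
#' @export
pka_table <- function(N_term = 8.6, C_term = 3.6, K = 10.8, R = 12.5,
                      H = 6.5, D = 3.9, E = 4.1, C = 8.5, Y = 10.1) {
  tab <- list(N_term = N_term, C_term = C_term, K = K, R = R, H = H,
              D = D, E = E, C = C, Y = Y)
  vals <- unlist(tab)
  if (any(vals <= 0 | vals >= 14)) stop("pKa values must lie in (0, 14)")
  structure(tab, class = "pka_table")
}

BASIC_GROUPS <- c("K", "R", "H")
ACIDIC_GROUPS <- c("D", "E", "C", "Y")

#' Net charge of a peptide at a given pH
#'
#' Standard ampholyte sum: each basic group contributes
#' `+1 / (1 + 10^(pH - pKa))`, each acidic group
#' `-1 / (1 + 10^(pKa - pH))`; the free termini always count. `X` residues
#' carry no ionizable group. Strictly decreasing in pH.
#'
#' @param sequence non-empty amino-acid string.
#' @param pH in (0, 14).
#' @param pka a [pka_table()].
#' @return net charge in elementary charges.
#' @export
net_charge <- function(sequence, pH, pka = pka_table()) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% AA_ALPHABET)
  if (length(bad)) stop("unknown residue '", aa[bad[1]], "'")
  counts <- table(factor(aa, levels = AA_ALPHABET))
  pos <- 1 / (1 + 10^(pH - pka$N_term))
  neg <- 1 / (1 + 10^(pka$C_term - pH))
  for (g in BASIC_GROUPS)
    pos <- pos + counts[[g]] / (1 + 10^(pH - pka[[g]]))
  for (g in ACIDIC_GROUPS)
    neg <- neg + counts[[g]] / (1 + 10^(pka[[g]] - pH))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' The net charge is strictly monotone decreasing in pH, so it has exactly one
#' root on (0, 14); bisection on `[0, 14]` finds it deterministically.
#'
#' @param sequence amino-acid string.
#' @param pka a [pka_table()].
#' @param tol absolute charge tolerance at the root (default `1e-4`).
#' @return the pI.
#' @export
isoelectric_point <- function(sequence, pka = pka_table(), tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection did not converge; is the pKa table corrupt?")
}

#' Isoelectric-point filter
#'
#' Partitions a catalog into records retained (pI at or below `max_pi`) and
#' excluded (pI above `max_pi`). A pI of exactly `max_pi` is retained.
#'
#' @param records a [protein_records()] table.
#' @param max_pi retention threshold (default 7.0).
#' @param pka a [pka_table()].
#' @return `list(retained =, excluded =)`, both with an added `pI` column.
#' @export
pi_filter <- function(records, max_pi = 7.0, pka = pka_table()) {
  pI <- vapply(records$sequence, isoelectric_point, 0, pka = pka,
               USE.NAMES = FALSE)
  records$pI <- pI
  keep <- pI <= max_pi
  list(retained = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}
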