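---
title: "Structure-guided screening for anti-CRISPR and anti-phage defense proteins"
author: "acrminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided screening for anti-CRISPR and anti-phage defense proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrminer)
```

## The problem

Phages carry anti-CRISPR (Acr) and other counter-defense proteins that
inactivate bacterial immune systems; bacteria in turn carry rare single-gene
anti-phage defense proteins that tend to co-localize in defense islands.
Both classes evolve so fast that primary-sequence search misses most of
them: experimentally validated Acrs are short, acidic, and largely
non-homologous to one another, yet they converge on a small set of folds
and mechanisms. `acrminer` implements the two discovery pipelines that
exploit this: a sequence-filtration cascade followed by TM-score structural
homology screening against known references (for phage counter-defense),
and defense-island co-localization mining followed by the same structural
screening (for bacterial defense), together with seeded generators that
make every step testable at desk scale.

## Structural similarity: TM-score on CA traces

The screening currency is the template-modeling score between two
alpha-carbon traces,

$$\mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L_{\text{norm}}}
\sum_{i \in \text{aligned}} \frac{1}{1 + (d_i/d_0(L_{\text{norm}}))^2},
\qquad d_0(L) = 1.24\,(L-15)^{1/3} - 1.8\ \text{Å},$$

where $d_i$ are distances between aligned residues after rigid
superposition. $d_0$ is floored at 0.5 Å so the score stays defined below
22 residues (the floor engages for $L \le 21$). All three normalizations
(query, target, shorter chain) are always computed; screening decisions use
the shorter-chain normalization, the only one the length-ratio rule of the
counter-defense screen names explicitly, and a config switch
(`align_config(tm_norm = )`) exposes the others.

The superposition search is a seed-and-refine heuristic in the TM-align
tradition, not a reimplementation of any particular tool: initial
correspondences come from gapless threading of the shorter chain onto the
longer at every offset and from Kabsch superpositions of fragment-window
pairs (20 residues, half-window stride); each seed whose quick score beats
the running best is expanded by iterative dynamic programming — similarity
matrix $S_{ij} = 1/(1+(d_{ij}/d_0)^2)$ under the current superposition, a
linear gap penalty of $-0.6$ with free terminal gaps, re-superposition on
the new pairs, to convergence ($\Delta \mathrm{TM} < 10^{-6}$, at most 20
rounds). Superpositions are always proper rotations (sign-corrected SVD).
Alignments are sequence-order dependent; non-sequential alignment is out of
scope. On hard pairs a heuristic of this family can land below the global
optimum, which is why correctness is established against constructed
fixtures with known answers (planted rigid transforms, brute-force
superposition oracles) rather than against an external aligner.

## The filtration cascades

The Acr screen runs, in order: length at most 200 aa (over 90% of known
Acrs are smaller); greedy identity clustering at 95% with centroids as
representatives; sequence-divergence exclusion against the reference Acrs;
isoelectric point at most 7 (validated Acrs are acidic); exclusion of
anything with a known domain (E-value at or below 0.01); then structural
alignment of the surviving centroids against every reference, calling hits
at TM of at least 0.6 and flagging the best hit per reference. The defense
screen mines proteins lying wholly between two annotated defense systems
separated by 1-15 kb (adjacent systems only, inclusive bounds,
edge-to-edge distance), clusters at 50%, keeps candidates with no known
domain and at least 200 aa, and calls structural hits against single-gene
defense references at TM above 0.65, again requiring sequence divergence.
Every stage logs in/retained/excluded counts; the funnel must conserve
counts and chain, and `check_funnel()` asserts this on every run.

Two boundary choices are deliberate: pI exactly 7.0 is retained ("above 7"
is discarded), and a defense candidate of exactly 200 aa is retained
("below 200" is discarded).

## Divergence-filter semantics

The exclusion rule — drop a candidate with more than 30% identity or
E-value below 0.1 to any reference — is stated in BLAST terms, and applying
it to every optimal Smith-Waterman alignment would be far stricter than any
BLAST run: unrelated proteins routinely share a short local alignment above
30% identity, and per-pair E-values fire on a fixed fraction of random
pairs. `divergence_filter()` therefore reproduces a BLASTP *run*: E-values
use database-search statistics (Karlin-Altschul with $n$ the total residue
count of the reference set; gapped BLOSUM62 constants $\lambda = 0.267$,
$K = 0.041$, gap open 11 extend 1, all injectable), and the identity and
E-value criteria apply to alignments reported at the run's E-value cutoff
(`report_evalue`, default equal to `evalue_cut`). With the defaults the
E-value clause decides and the identity clause labels high-identity
exclusions; raising `report_evalue` toward BLAST's reporting default of 10
makes the identity clause bite on weaker hits. Query coverage is a
reporting option of local search, not part of this filter.

Identity itself has two denominators, on purpose: for clustering, identical
columns over all alignment columns including terminal gaps (stricter and
stable under the greedy order); for the divergence filter, identical
columns over the local alignment only (BLAST semantics).

## Clustering

`greedy_cluster()` is a deterministic stand-in for USEARCH-style centroid
clustering: records are visited longest-first (ties by id) and join the
first centroid with global identity at or above the threshold, else found a
new cluster. The exact k-mer heuristics of production tools are not
reproduced — what the screens consume is the partition semantics (every
protein in exactly one cluster, members within the threshold of their
centroid), which the tests verify against an independent restatement of the
rule. Since identity cannot exceed the shorter/longer length ratio, pairs
failing the threshold on length alone are skipped without alignment; this
is an exact shortcut, not an approximation. The pI filter runs on centroids
only, and cluster members inherit the centroid verdict — the reading that
matches computing pI "for representative sequences".

## Isoelectric point

Net charge is the standard Henderson-Hasselbalch ampholyte sum (basic
groups $+1/(1+10^{\mathrm{pH}-pK_a})$, acidic groups
$-1/(1+10^{pK_a-\mathrm{pH}})$, termini always counted, `X` inert), which
is strictly decreasing in pH, so the pI is the unique root and bisection on
[0, 14] finds it to $10^{-4}$ charge tolerance in at most 100 iterations.
The EMBOSS pKa set is the default and the table is injectable; absolute pI
values are table-dependent, but the acidic/basic partition at 7 is robust
for the strongly charged sequences the screen cares about.

## Island mining and prevalence

"Separated by 1-15 kb" is read as the edge-to-edge gap
(`right.start - left.end - 1`) within inclusive bounds, between *adjacent*
systems only — a third system inside a gap splits it, which prevents
double-counting intervening genes. Intervening proteins must lie fully
inside the open interval between the two footprints; boundary-straddling
genes are excluded since they likely belong to the flanking systems.
Marker prevalence conditions on the genomes carrying the system: `total` is
the number of distinct genomes with at least one annotation of the system,
`carriers` those also carrying the marker, and the percent is rounded
half-up to two decimals (21 of 7308 prints 0.29).

## What the generators emulate — and what they do not

`gen_fold()` builds ideal-geometry CA traces (helix: radius 2.3 Å, rise
1.5 Å, 100°/residue; strand: 3.5 Å/residue with a 0.5 Å zig-zag; two
antiparallel helices joined by a 4-residue turn; self-avoiding random walk
coils with 3.8 Å steps). Ideal geometry keeps oracle TM-scores computable
and gives the screens exactly what they consume: same-fold pairs score
high, cross-fold pairs low. `perturb_structure()` degrades similarity
monotonically with Gaussian coordinate noise plus a random proper rigid
transform. References use coil folds so distinct references are mutually
dissimilar; helices would all superpose on one another.

`gen_screen_fixture()` plants structural homologs (perturbed reference
folds, σ = 0.8 Å by default) whose sequences are mutated to 10% global
identity with acid-leaning replacements — below the 25% ceiling the
recovery property assumes, and acidic like their references so the pI
filter is informative. Because a low *global* identity does not by itself
preclude a BLAST-detectable local run, the generator re-mutates
(deterministically reseeded) until the planted sequence clears the
divergence gate against every reference: the planted condition is
"structural homology without detectable sequence similarity", and the
generator owns that guarantee. Decoys straddle the 200 aa bound
(lengths 80-260), alternate acidic/basic composition around pI 7, cycle
all four fold archetypes, and a fifth carry domain annotations below the
exclusion cutoff. The truth table records each record's role and the first
stage expected to exclude it by construction; a decoy can occasionally fall
at the (earlier) divergence stage instead, since that filter has a
deliberate false-positive rate on random sequences, so recovery assertions
key on roles, not stage labels. `gen_defense_genomes()` plants the marker
by count rounding (not Bernoulli draws), so prevalence recovery is exact.

What the generators do *not* emulate: real protein evolution (mutations are
iid), AlphaFold-quality decoys, compositional biases of natural proteomes,
multi-domain architectures beyond simple concatenation, or
nucleotide-level genomes. Passing tests therefore demonstrate the decision
logic — filters, thresholds, bookkeeping, recovery of controlled signals —
not performance on real catalogs.

## Numerical choices and degenerate inputs

Kabsch superposition needs at least 3 paired points, tolerates collinear
points (SVD handles rank deficiency), and rejects non-finite coordinates.
DP traceback breaks ties diagonal > up > left, as does the sequence
aligner, so results are bit-reproducible. PDB reading takes the first
model, first chain, altloc blank or A, CA atoms only, residues ordered by
residue number; B-factors are read as pLDDT when all lie in [0, 100]. No
pLDDT-based filtering is applied before alignment — confidence is carried,
not acted on. Coordinates are 1-based inclusive in all files. Sequence
`*` is allowed only as a terminal stop and stripped.

## Problem sizes

The shipped test and acceptance workloads use catalogs of ~50 decoys with 3
planted homologs (150-residue references) across five generator seeds, and
400 annotated genomes for island mining — sizes at which every quantity can
also be computed by brute-force oracles (Euler-grid superposition search,
exhaustive alignment recursion, dense pI grid scans) in minutes on one
core. The algorithms themselves are quadratic per pair and handle
thousands of proteins; survey-scale inputs (tens of millions of
proteins, hundreds of thousands of genomes) are explicitly out of scope.

## Known limitations

The structural aligner claims no parity with US-align; non-sequential
alignments, multimers and nucleic acids are unsupported. E-values are
analytic Karlin-Altschul values, not empirically calibrated to the score
distribution of any particular sequence ensemble, so the divergence
filter's false-positive rate on random sequences is approximate. The
greedy clustering partition can differ from USEARCH's on borderline pairs.
pI ignores post-translational chemistry. The island miner assumes correct,
non-overlapping system annotations on assembled contigs.
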