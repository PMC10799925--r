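#' @title Seeded synthetic-data generators
#' @description Generators for every input class the pipeline consumes, so
#'   the full discovery logic is testable with no downloads: ideal-geometry
#'   CA folds with controlled structural similarity, sequences with
#'   controlled identity and charge composition, screen fixtures with planted
#'   structural homologs among decoys, and annotated toy genomes with planted
#'   defense islands and marker prevalence. All generators are deterministic
#'   under a fixed seed.
#' @name synthetic_data
NULL

#' Generate an ideal-geometry CA fold
#'
#' Archetypes: `helix` (radius 2.3 A, rise 1.5 A/residue, 100 deg/residue),
#' `strand` (3.5 A/residue near-linear with an alternating 0.5 A zig-zag),
#' `helix_hairpin` (two antiparallel helices joined by a 4-residue turn) and
#' `coil` (seeded self-avoiding random walk with 3.8 A steps). Consecutive
#' CA distances fall in [3.6, 4.0] A outside coil/turn regions.
#'
#' @param archetype one of `"helix"`, `"strand"`, `"helix_hairpin"`, `"coil"`.
#' @param length residue count (>= 10).
#' @param seed integer seed (used by `coil` and for the residue codes).
#' @param protein_id id for the model.
#' @param sequence optional residue string (random if omitted).
#' @return a [ca_trace()].
#' @export
gen_fold <- function(archetype = c("helix", "strand", "helix_hairpin", "coil"),
                     length, seed = 1L, protein_id = archetype,
                     sequence = NULL) {
  archetype <- match.arg(archetype)
  if (length < 10) stop("fold length must be >= 10")
  coords <- with_seed(seed, switch(
    archetype,
    helix = helix_coords(length),
    strand = strand_coords(length),
    helix_hairpin = hairpin_coords(length),
    coil = coil_coords(length)))
  res <- if (is.null(sequence)) {
    with_seed(seed + 7L, paste(sample(setdiff(AA_ALPHABET, "X"), length,
                                      replace = TRUE), collapse = ""))
  } else sequence
  ca_trace(protein_id, coords, strsplit(res, "")[[1]])
}

helix_coords <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}

strand_coords <- function(n) {
  cbind(3.5 * (seq_len(n) - 1), 0.5 * (-1)^seq_len(n), 0)
}

hairpin_coords <- function(n) {
  n_arm <- (n - 4) %/% 2
  arm1 <- helix_coords(n_arm)
  arm2 <- helix_coords(n - 4 - n_arm)
  # second arm antiparallel, displaced in x
  arm2 <- cbind(10 - arm2[, 1], arm2[, 2],
                max(arm1[, 3]) - arm2[, 3])
  a <- arm1[nrow(arm1), ]; b <- arm2[1, ]
  turn <- t(vapply(1:4, function(k) {
    w <- k / 5
    p <- (1 - w) * a + w * b
    p[3] <- p[3] + 3.0 * sin(pi * w)   # arc the turn above the arms
    p
  }, numeric(3)))
  rbind(arm1, turn, arm2)
}

coil_coords <- function(n, step = 3.8, min_sep = 3.5) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    for (try in 1:200) {
      v <- rnorm(3)
      cand <- xyz[i - 1, ] + step * v / sqrt(sum(v^2))
      prior <- xyz[seq_len(i - 2), , drop = FALSE]
      if (i == 2 || nrow(prior) == 0 ||
          min(sqrt(rowSums(sweep(prior, 2, cand)^2))) >= min_sep) break
    }
    xyz[i, ] <- cand
  }
  xyz
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Perturb a structure with coordinate noise and a rigid transform
#'
#' Adds isotropic Gaussian noise (sigma per axis) to every CA coordinate,
#' then optionally applies a random proper rotation and translation. Residue
#' codes are preserved. This is the controlled knob for planted structural
#' homology: the TM-score to the original degrades monotonically with sigma.
#'
#' @param model a [ca_trace()].
#' @param sigma noise standard deviation in Angstrom (>= 0).
#' @param rigid apply a random rigid transform (default `TRUE`).
#' @param seed integer seed.
#' @param protein_id id of the perturbed copy.
#' @return a [ca_trace()].
#' @export
perturb_structure <- function(model, sigma, rigid = TRUE, seed = 1L,
                              protein_id = paste0(model$protein_id, "_pert")) {
  if (sigma < 0) stop("sigma must be >= 0")
  with_seed(seed, {
    xyz <- model$coords + matrix(rnorm(3 * nrow(model$coords), sd = sigma),
                                 ncol = 3)
    if (rigid) {
      R <- random_rotation()
      xyz <- sweep(xyz %*% t(R), 2, runif(3, -20, 20), "+")
    }
    ca_trace(protein_id, xyz, model$residues, model$plddt)
  })
}

#' Sample a sequence with controlled charge composition
#'
#' Residues are drawn with extra weight `acid_fraction` spread over D/E and
#' `base_fraction` over K/R, the remainder uniform over the other standard
#' residues -- the knob used to place decoys on either side of pI 7.
#'
#' @param length residue count.
#' @param acid_fraction,base_fraction composition weights in `[0, 1]`.
#' @param seed integer seed.
#' @return an amino-acid string.
#' @export
compose_sequence <- function(length, acid_fraction = 0.1, base_fraction = 0.1,
                             seed = 1L) {
  if (acid_fraction < 0 || base_fraction < 0 ||
      acid_fraction + base_fraction > 1)
    stop("composition fractions must be non-negative and sum to <= 1")
  aa <- setdiff(AA_ALPHABET, "X")
  w <- setNames(rep((1 - acid_fraction - base_fraction) /
                      (length(aa) - 4), length(aa)), aa)
  w[c("D", "E")] <- acid_fraction / 2
  w[c("K", "R")] <- base_fraction / 2
  with_seed(seed,
            paste(sample(aa, length, replace = TRUE, prob = w), collapse = ""))
}

#' Mutate a sequence down to a target global identity
#'
#' Substitutes uniformly chosen positions with replacement residues (by
#' default uniform over the standard alphabet, excluding the current residue)
#' until the global-alignment identity to the original drops to or below the
#' target. Length-preserving and deterministic under the seed. Random
#' sequences share roughly 5\% identity, so targets below 0.05 are
#' unreachable.
#'
#' @param sequence the starting amino-acid string.
#' @param target_identity fraction in (0, 1].
#' @param seed integer seed.
#' @param replacement_weights optional named weights over residues for the
#'   substituted positions (e.g. acid-leaning, to preserve acidity while
#'   destroying similarity).
#' @param scoring an [aln_scoring()] used for the identity check.
#' @return the mutated sequence.
#' @export
mutate_to_identity <- function(sequence, target_identity, seed = 1L,
                               replacement_weights = NULL,
                               scoring = aln_scoring()) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must lie in (0, 1]")
  if (target_identity < 0.05)
    stop("targets below 0.05 are unreachable for random sequences")
  if (target_identity == 1) return(sequence)
  aa <- setdiff(AA_ALPHABET, "X")
  w <- if (is.null(replacement_weights)) setNames(rep(1, length(aa)), aa)
       else replacement_weights[aa]
  w[is.na(w)] <- 0
  with_seed(seed, {
    cur <- strsplit(sequence, "")[[1]]
    n <- length(cur)
    for (round in 1:200) {
      ident <- global_identities(paste(cur, collapse = ""), sequence,
                                 scoring)
      if (ident <= target_identity) break
      # step size proportional to the remaining identity excess
      k <- max(1L, ceiling(n * (ident - target_identity) * 0.8))
      pos <- sample(n, min(k, n))
      for (p in pos) {
        pool <- setdiff(aa, cur[p])
        cur[p] <- sample(pool, 1, prob = w[pool])
      }
    }
    paste(cur, collapse = "")
  })
}

acid_weights <- function() {
  aa <- setdiff(AA_ALPHABET, "X")
  w <- setNames(rep(1, length(aa)), aa)
  w[c("D", "E")] <- 3; w[c("K", "R", "H")] <- 0.3
  w
}

#' Generate an Acr-screen fixture with planted homologs
#'
#' Builds a protein catalog of decoys plus planted structural homologs of a
#' set of reference proteins, with ground truth. Decoys straddle the 200 aa
#' length bound and the pI 7 bound, carry mixed fold archetypes, and a subset
#' carries domain annotations below the exclusion E-value. Each plant has the
#' structure of its reference perturbed by Gaussian noise plus a rigid
#' transform, and a sequence mutated to the configured identity with
#' acid-leaning replacements (structural homology without detectable sequence
#' similarity -- the signal the screen exists to find). References use coil
#' folds so that distinct references are mutually dissimilar.
#'
#' @param config list with (all optional): `seed`, `n_decoys` (50),
#'   `n_refs` (3), `ref_length` (150), `n_plants` (3),
#'   `plant_identity` (0.10), `plant_sigma` (0.8), `plant_rigid` (TRUE),
#'   `n_fusions` (0), `decoy_length_range` (c(80, 260)),
#'   `domain_fraction` (0.2).
#' @return list with `catalog` ([protein_records()]), `structures` (named
#'   list of [ca_trace()]), `domains` (domain table), `refs`
#'   (`list(records, structures)`), `truth` (`data.frame` with one row per
#'   catalog entry: `role`, `planted_ref`, `expected_stage` -- the first
#'   screen stage expected to exclude it, or `"retained"`).
#' @export
gen_screen_fixture <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1L, n_decoys = 50L, n_refs = 3L, ref_length = 150L,
    n_plants = 3L, plant_identity = 0.10, plant_sigma = 0.8,
    plant_rigid = TRUE, n_fusions = 0L, decoy_length_range = c(80L, 260L),
    domain_fraction = 0.2), config)
  seed <- as.integer(cfg$seed)

  # references: distinct coil folds with acidic sequences
  ref_ids <- sprintf("acrRef%02d", seq_len(cfg$n_refs))
  ref_seqs <- vapply(seq_len(cfg$n_refs), function(i)
    compose_sequence(cfg$ref_length, acid_fraction = 0.15,
                     base_fraction = 0.05, seed = seed * 1000L + i), "")
  ref_structs <- lapply(seq_len(cfg$n_refs), function(i)
    gen_fold("coil", cfg$ref_length, seed = seed * 1000L + i,
             protein_id = ref_ids[i], sequence = ref_seqs[i]))
  names(ref_structs) <- ref_ids
  refs <- list(records = protein_records(ref_ids, ref_seqs),
               structures = ref_structs)

  ids <- character(0); seqs <- character(0)
  structures <- list(); truth <- list(); dom_rows <- list()
  add <- function(id, seq, struct, role, planted_ref, expected_stage) {
    ids <<- c(ids, id); seqs <<- c(seqs, seq)
    structures[[id]] <<- struct
    truth[[length(truth) + 1]] <<- data.frame(
      protein_id = id, role = role, planted_ref = planted_ref,
      expected_stage = expected_stage, stringsAsFactors = FALSE)
  }

  # plants: perturbed reference structure, near-random acid-leaning sequence.
  # The planted condition is structural homology WITHOUT detectable sequence
  # similarity, so mutation continues (reseeded) until the sequence clears
  # the divergence gate against every reference -- the generator guarantees
  # its own ground truth rather than leaving it to chance.
  for (p in seq_len(cfg$n_plants)) {
    ri <- ((p - 1) %% cfg$n_refs) + 1
    id <- sprintf("plant%02d", p)
    for (k in 0:25) {
      seq <- mutate_to_identity(ref_seqs[ri], cfg$plant_identity,
                                seed = seed * 100L + p + 7919L * k,
                                replacement_weights = acid_weights())
      div <- divergence_filter(protein_records(id, seq), refs$records)
      if (nrow(div$retained) == 1) break
    }
    st <- perturb_structure(ref_structs[[ri]], cfg$plant_sigma,
                            rigid = cfg$plant_rigid, seed = seed * 100L + p,
                            protein_id = id)
    st$residues <- strsplit(seq, "")[[1]]
    add(id, seq, st, "plant", ref_ids[ri], "retained")
  }

  # fusions: two perturbed reference folds concatenated end to end
  for (f in seq_len(cfg$n_fusions)) {
    r1 <- ((f - 1) %% cfg$n_refs) + 1
    r2 <- (f %% cfg$n_refs) + 1
    id <- sprintf("fusion%02d", f)
    s1 <- perturb_structure(ref_structs[[r1]], cfg$plant_sigma, rigid = FALSE,
                            seed = seed * 300L + f)
    s2 <- perturb_structure(ref_structs[[r2]], cfg$plant_sigma, rigid = FALSE,
                            seed = seed * 300L + 100L + f)
    off <- s1$coords[nrow(s1$coords), ] + c(4, 0, 0) - s2$coords[1, ]
    xyz <- rbind(s1$coords, sweep(s2$coords, 2, off, "+"))
    for (k in 0:25) {
      seq <- mutate_to_identity(paste0(ref_seqs[r1], ref_seqs[r2]),
                                cfg$plant_identity,
                                seed = seed * 300L + f + 7919L * k,
                                replacement_weights = acid_weights())
      div <- divergence_filter(protein_records(id, seq), refs$records)
      if (nrow(div$retained) == 1) break
    }
    st <- ca_trace(id, xyz, strsplit(seq, "")[[1]])
    add(id, seq, st, "fusion", paste(ref_ids[c(r1, r2)], collapse = ","),
        "fusion")
  }

  # decoys: cycle fold archetypes, straddle length 200 and pI 7
  arch <- c("helix", "strand", "helix_hairpin", "coil")
  lr <- cfg$decoy_length_range
  decoy_lens <- with_seed(seed + 11L,
                          sample(seq(lr[1], lr[2]), cfg$n_decoys,
                                 replace = TRUE))
  n_domained <- ceiling(cfg$domain_fraction * cfg$n_decoys)
  for (d in seq_len(cfg$n_decoys)) {
    id <- sprintf("decoy%03d", d)
    len <- decoy_lens[d]
    acidic <- d %% 2 == 0
    seq <- compose_sequence(len,
                            acid_fraction = if (acidic) 0.25 else 0.03,
                            base_fraction = if (acidic) 0.03 else 0.25,
                            seed = seed * 10000L + d)
    st <- gen_fold(arch[(d %% length(arch)) + 1], len,
                   seed = seed * 10000L + d, protein_id = id, sequence = seq)
    has_domain <- d <= n_domained
    if (has_domain)
      dom_rows[[length(dom_rows) + 1]] <- data.frame(
        protein_id = id, domain_id = sprintf("CDD%05d", d), evalue = 1e-5,
        stringsAsFactors = FALSE)
    expected <- if (len > 200) "length"
      else if (!acidic) "isoelectric-point"
      else if (has_domain) "no-known-domain"
      else "structural-similarity"
    add(id, seq, st, "decoy", NA_character_, expected)
  }

  domains <- if (length(dom_rows)) do.call(rbind, dom_rows)
    else data.frame(protein_id = character(0), domain_id = character(0),
                    evalue = numeric(0))
  list(catalog = protein_records(ids, seqs), structures = structures,
       domains = domains, refs = refs,
       truth = do.call(rbind, truth), config = cfg)
}

#' Write a screen fixture to disk
#'
#' Writes the catalog FASTA, a PDB directory, the domain TSV, reference
#' FASTA + PDB directory and the truth TSV -- the file layout consumed by
#' [run_acr_pipeline()].
#'
#' @param fixture output of [gen_screen_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdbd <- file.path(dir, "pdb"); dir.create(pdbd, showWarnings = FALSE)
  refd <- file.path(dir, "refs_pdb"); dir.create(refd, showWarnings = FALSE)
  write_fasta(fixture$catalog, file.path(dir, "catalog.faa"))
  for (id in names(fixture$structures))
    write_ca_trace(fixture$structures[[id]],
                   file.path(pdbd, paste0(id, ".pdb")))
  write_fasta(fixture$refs$records, file.path(dir, "refs.faa"))
  for (id in names(fixture$refs$structures))
    write_ca_trace(fixture$refs$structures[[id]],
                   file.path(refd, paste0(id, ".pdb")))
  write.table(fixture$domains, file.path(dir, "domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate annotated toy genomes with planted defense islands
#'
#' Each genome is one contig carrying 2-4 defense systems; the gap between
#' consecutive systems is drawn from a mixture inside and outside the
#' `[1000, 15000]` bp window. Intervening genes are placed fully inside each
#' gap. A marker gene is planted in a BREX-adjacent in-window gap for a
#' `marker_prevalence` fraction (by count rounding, so recovery is exact) of
#' the BREX-bearing genomes. The truth list records every expected region,
#' its intervening ids, and the carrier/total counts.
#'
#' @param config list with (all optional): `seed`, `n_genomes` (400),
#'   `brex_fraction` (0.6), `marker_prevalence` (0.05), `p_gap_in` (0.7),
#'   `marker_length` (220).
#' @return list with `systems` (annotation table), `genes`
#'   ([protein_records()] with coordinates), `marker_hits` (genome ids),
#'   `truth` (`list(regions, carriers, total, marker_ids)`).
#' @export
gen_defense_genomes <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1L, n_genomes = 400L, brex_fraction = 0.6,
    marker_prevalence = 0.05, p_gap_in = 0.7, marker_length = 220L), config)
  seed <- as.integer(cfg$seed)
  other_systems <- c("RM_type_I", "CBASS", "Gabija", "Thoeris", "Hachiman")

  n_brex <- as.integer(round(cfg$brex_fraction * cfg$n_genomes))
  carriers_n <- as.integer(round(cfg$marker_prevalence * n_brex))

  systems <- list(); genes <- list(); regions <- list()
  marker_hits <- character(0); marker_ids <- character(0)

  with_seed(seed, {
    brex_genomes <- sort(sample(cfg$n_genomes, n_brex))
    carrier_genomes <- brex_genomes[seq_len(carriers_n)]
    for (g in seq_len(cfg$n_genomes)) {
      gid <- sprintf("MAG%04d", g)
      contig <- paste0(gid, "_c1")
      has_brex <- g %in% brex_genomes
      is_carrier <- g %in% carrier_genomes
      n_sys <- sample(2:4, 1)
      sys_names <- sample(other_systems, n_sys, replace = TRUE)
      if (has_brex) sys_names[sample(n_sys - 1, 1)] <- "BREX_type_3"
      pos <- sample(3000:8000, 1)
      gene_n <- 0L
      prev_sys <- NULL
      for (s in seq_len(n_sys)) {
        n_memb <- sample(3:6, 1)
        s_start <- pos
        memb_ids <- character(0)
        for (m in seq_len(n_memb)) {
          gene_n <- gene_n + 1L
          id <- sprintf("%s_g%03d", gid, gene_n)
          glen <- sample(600:1200, 1)
          genes[[length(genes) + 1]] <- list(id = id, genome = gid,
                                             contig = contig, start = pos,
                                             end = pos + glen - 1,
                                             aa = glen %/% 3)
          memb_ids <- c(memb_ids, id)
          pos <- pos + glen + sample(20:120, 1)
        }
        s_end <- genes[[length(genes)]]$end
        systems[[length(systems) + 1]] <- data.frame(
          genome_id = gid, contig_id = contig, system_name = sys_names[s],
          start = s_start, end = s_end, strand = "+", stringsAsFactors = FALSE)
        systems[[length(systems)]]$gene_ids <- list(memb_ids)

        if (s < n_sys) {
          # choose the gap to the next system
          force_in <- is_carrier && sys_names[s] == "BREX_type_3" &&
            !length(marker_ids[marker_hits == gid])
          gap_in <- force_in || runif(1) < cfg$p_gap_in
          gap <- if (gap_in) sample(2000:14000, 1)
                 else if (runif(1) < 0.5) sample(100:900, 1)
                 else sample(15500:25000, 1)
          left_end <- s_end
          right_start <- left_end + gap + 1
          iv_ids <- character(0)
          if (gap_in) {
            plant_marker <- is_carrier && !gid %in% marker_hits &&
              (sys_names[s] == "BREX_type_3" ||
                 sys_names[s + 1] == "BREX_type_3")
            n_iv <- if (plant_marker) 1L else sample(1:3, 1)
            slots <- floor(seq(left_end + 50, right_start - 50,
                               length.out = n_iv + 1))
            for (v in seq_len(n_iv)) {
              gene_n <- gene_n + 1L
              id <- sprintf("%s_g%03d", gid, gene_n)
              aa <- if (plant_marker && v == 1) cfg$marker_length
                    else sample(60:180, 1)
              glen <- min(3 * aa, slots[v + 1] - slots[v] - 20)
              aa <- glen %/% 3
              genes[[length(genes) + 1]] <- list(id = id, genome = gid,
                                                 contig = contig,
                                                 start = slots[v],
                                                 end = slots[v] + glen - 1,
                                                 aa = aa)
              iv_ids <- c(iv_ids, id)
              if (plant_marker && v == 1) {
                marker_hits <- c(marker_hits, gid)
                marker_ids <- c(marker_ids, id)
              }
            }
            regions[[length(regions) + 1]] <- data.frame(
              genome_id = gid, contig_id = contig,
              left_system = sys_names[s], right_system = sys_names[s + 1],
              left_end = left_end, right_start = right_start, gap_bp = gap,
              stringsAsFactors = FALSE)
            regions[[length(regions)]]$intervening_protein_ids <- list(iv_ids)
          }
          pos <- right_start
          prev_sys <- sys_names[s]
        }
      }
    }
    systems <- do.call(rbind, systems)
    gene_df <- do.call(rbind, lapply(genes, as.data.frame))
    seqs <- vapply(seq_len(nrow(gene_df)), function(i)
      compose_sequence(max(30L, gene_df$aa[i]), seed = seed * 100000L + i),
      "")
    gene_rec <- protein_records(gene_df$id, seqs, genome_id = gene_df$genome,
                                contig_id = gene_df$contig,
                                start = gene_df$start, end = gene_df$end,
                                strand = "+")
    list(systems = systems, genes = gene_rec, marker_hits = marker_hits,
         truth = list(regions = do.call(rbind, regions),
                      carriers = length(marker_hits), total = n_brex,
                      marker_ids = marker_ids),
         config = cfg)
  })
}

#' Write a defense-genome fixture to disk
#'
#' Writes the systems TSV, gene table TSV, gene FASTA and marker-hit TSV --
#' the file layout consumed by [run_defense_pipeline()].
#'
#' @param fixture output of [gen_defense_genomes()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_defense_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_defense_table(fixture$systems, file.path(dir, "systems.tsv"))
  g <- fixture$genes
  write.table(g[, c("protein_id", "genome_id", "contig_id", "start", "end",
                    "strand")],
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(g, file.path(dir, "genes.faa"))
  write.table(data.frame(genome_id = fixture$marker_hits),
              file.path(dir, "marker_hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
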