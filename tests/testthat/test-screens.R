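# a small screen fixture shared by several blocks
small_fix <- local({
  gen_screen_fixture(list(seed = 42, n_decoys = 12, n_plants = 2))
})

test_that("the Acr screen recovers planted homologs and rejects decoys", {
  res <- acr_screen(small_fix$catalog, small_fix$structures, small_fix$refs,
                    small_fix$domains)
  plants <- small_fix$truth$protein_id[small_fix$truth$role == "plant"]
  got <- unique(res$hits$candidate_id)
  expect_setequal(got, plants)
  for (p in plants) {
    h <- res$hits[res$hits$candidate_id == p, ]
    expect_gte(max(h$tm_shorter), 0.6)
    expect_equal(h$reference_id[which.max(h$tm_shorter)],
                 small_fix$truth$planted_ref[small_fix$truth$protein_id == p])
  }
  # the best flag marks the max-TM hit per reference
  for (rid in unique(res$hits$reference_id)) {
    sel <- res$hits[res$hits$reference_id == rid, ]
    expect_equal(sel$candidate_id[sel$best],
                 sel$candidate_id[which.max(sel$tm_shorter)])
  }
  expect_error(acr_screen(small_fix$catalog, small_fix$structures,
                          list(structures = list()), small_fix$domains),
               "empty")
})

test_that("a domain annotation on the planted homolog silences it", {
  dom <- rbind(small_fix$domains,
               data.frame(protein_id = "plant01", domain_id = "CDD999",
                          evalue = 1e-5))
  res <- acr_screen(small_fix$catalog, small_fix$structures, small_fix$refs,
                    dom)
  expect_false("plant01" %in% res$hits$candidate_id)
  v <- res$reports[["plant01"]]$stage_verdicts
  expect_false(v$passed[v$stage == "no-known-domain"])
  # a weak domain hit above the cutoff does not exclude
  dom2 <- rbind(small_fix$domains,
                data.frame(protein_id = "plant01", domain_id = "CDD999",
                           evalue = 0.5))
  res2 <- acr_screen(small_fix$catalog, small_fix$structures, small_fix$refs,
                     dom2)
  expect_true("plant01" %in% res2$hits$candidate_id)
})

test_that("an oversized structural homolog is excluded by length alone", {
  ref <- gen_fold("coil", 250, seed = 77, protein_id = "bigRef",
                  sequence = compose_sequence(250, 0.15, 0.05, seed = 77))
  refs <- list(records = protein_records("bigRef",
                                         paste(ref$residues, collapse = "")),
               structures = list(bigRef = ref))
  plant <- perturb_structure(ref, 0.5, rigid = TRUE, seed = 78,
                             protein_id = "bigplant")
  seq <- compose_sequence(250, 0.15, 0.05, seed = 79)
  plant$residues <- strsplit(seq, "")[[1]]
  catalog <- protein_records("bigplant", seq)
  res <- acr_screen(catalog, list(bigplant = plant), refs)
  expect_equal(nrow(res$hits), 0)
  v <- res$reports[["bigplant"]]$stage_verdicts
  expect_equal(v$stage[!v$passed][1], "length")
})

test_that("funnel conservation and chaining hold at every stage", {
  res <- acr_screen(small_fix$catalog, small_fix$structures, small_fix$refs,
                    small_fix$domains)
  f <- res$funnel
  expect_true(check_funnel(f))
  expect_equal(f$n_in, f$n_retained + f$n_excluded)
  expect_equal(f$n_in[-1], f$n_retained[-nrow(f)])
  expect_equal(f$n_in[1], nrow(small_fix$catalog))
  bad <- f; bad$n_excluded[2] <- bad$n_excluded[2] + 1
  expect_error(check_funnel(bad), "conservation")
})

test_that("per-candidate filters commute: the funnel equals the predicate intersection", {
  cat <- small_fix$catalog
  res <- acr_screen(cat, small_fix$structures, small_fix$refs,
                    small_fix$domains)
  cents <- res$clusters$centroid_id
  # recompute each pure per-candidate predicate independently
  len_ok <- cat$protein_id[cat$length <= 200]
  div_ok <- divergence_filter(cat[match(cents, cat$protein_id), ],
                              small_fix$refs$records)$retained$protein_id
  pi_ok <- cat$protein_id[vapply(cat$sequence, isoelectric_point, 0) <= 7]
  dom_bad <- unique(small_fix$domains$protein_id[small_fix$domains$evalue <= 0.01])
  expected <- Reduce(intersect, list(len_ok, cents, div_ok, pi_ok,
                                     setdiff(cat$protein_id, dom_bad)))
  structural_in <- res$funnel$n_in[res$funnel$stage == "structural-similarity"]
  expect_equal(structural_in, length(expected))
})

test_that("the defense screen finds a planted large homolog among small decoys", {
  ref <- gen_fold("coil", 230, seed = 11, protein_id = "pdRef",
                  sequence = compose_sequence(230, 0.1, 0.1, seed = 11))
  refs <- list(records = protein_records("pdRef",
                                         paste(ref$residues, collapse = "")),
               structures = list(pdRef = ref))
  plant <- perturb_structure(ref, 0.8, rigid = TRUE, seed = 12,
                             protein_id = "cand_big")
  pseq <- compose_sequence(230, 0.1, 0.1, seed = 13)
  plant$residues <- strsplit(pseq, "")[[1]]
  ids <- c("cand_big", sprintf("small%02d", 1:6))
  seqs <- c(pseq, vapply(1:6, function(s)
    compose_sequence(90, 0.1, 0.1, seed = 1000 + s), ""))
  intervening <- protein_records(ids, seqs)
  structs <- c(list(cand_big = plant),
               setNames(lapply(1:6, function(s)
                 gen_fold("helix", 90, seed = 1000 + s,
                          protein_id = sprintf("small%02d", s))),
                 sprintf("small%02d", 1:6)))
  res <- defense_candidate_screen(intervening, structs, refs)
  expect_equal(unique(res$hits$candidate_id), "cand_big")
  expect_gt(res$hits$tm_shorter[1], 0.65)
  expect_true(check_funnel(res$funnel))

  # a 150-aa version of the same homolog dies at the length stage
  short <- ca_trace("cand_short", plant$coords[1:150, ], plant$residues[1:150])
  intervening2 <- protein_records("cand_short", substr(pseq, 1, 150))
  res2 <- defense_candidate_screen(intervening2, list(cand_short = short),
                                   refs)
  expect_equal(nrow(res2$hits), 0)
  v <- res2$reports[["cand_short"]]$stage_verdicts
  expect_false(v$passed[v$stage == "length"])

  # raising the TM threshold above the planted pair's score empties the hits
  hard <- screen_config(defense_tm_cut = 0.999)
  res3 <- defense_candidate_screen(intervening, structs, refs, config = hard)
  expect_equal(nrow(res3$hits), 0)
})

test_that("counter-defense rule: TM, length ratio and divergence all required", {
  ref <- gen_fold("coil", 200, seed = 21, protein_id = "antiRM",
                  sequence = compose_sequence(200, 0.1, 0.1, seed = 21))
  refs <- list(records = protein_records("antiRM",
                                         paste(ref$residues, collapse = "")),
               structures = list(antiRM = ref))

  # remote homolog: first 180 residues of the fold, unrelated sequence
  part <- perturb_structure(ca_trace("p", ref$coords[1:180, ]), 0.6,
                            rigid = TRUE, seed = 22, protein_id = "remote")
  rseq <- compose_sequence(180, 0.1, 0.1, seed = 23)
  part$residues <- strsplit(rseq, "")[[1]]
  cands <- list(records = protein_records("remote", rseq),
                structures = list(remote = part))
  out <- counterdefense_screen(cands, refs)
  expect_true(out$retained)
  expect_equal(out$length_ratio, 0.9)

  # truncating to 120 residues fails the 70% length-ratio rule
  short <- ca_trace("shorty", part$coords[1:120, ], part$residues[1:120])
  cands2 <- list(records = protein_records("shorty", substr(rseq, 1, 120)),
                 structures = list(shorty = short))
  out2 <- counterdefense_screen(cands2, refs)
  expect_false(out2$retained)
  expect_false(out2$length_ok)
  expect_true(out2$tm_ok)

  # a structurally similar pair with near-identical sequence is rejected
  twin <- perturb_structure(ref, 0.3, rigid = TRUE, seed = 24,
                            protein_id = "twin")
  cands3 <- list(records = protein_records("twin", refs$records$sequence),
                 structures = list(twin = twin))
  out3 <- counterdefense_screen(cands3, refs)
  expect_false(out3$retained)
  expect_false(out3$divergence_ok)
  expect_gt(out3$identity, 0.3)
})

test_that("the fusion scan flags concatenated folds and ignores single hits", {
  fix <- gen_screen_fixture(list(seed = 9, n_decoys = 6, n_plants = 1,
                                 n_fusions = 1, ref_length = 90))
  res <- acr_screen(fix$catalog, fix$structures, fix$refs, fix$domains)
  fus <- fusion_scan(res$reports)
  expect_true("fusion01" %in% fus$candidate_id)
  row <- fus[fus$candidate_id == "fusion01", ]
  expect_equal(row$n_references, 2)
  expect_true(row$putative_fusion)
  expect_lt(row$jaccard_min, 0.25)
  # the single-reference plant is not reported by the fusion scan
  expect_false("plant01" %in% fus$candidate_id)

  # two hits by the SAME reference do not qualify
  rep_same <- list(list(
    candidate_id = "dup",
    stage_verdicts = data.frame(stage = "s", passed = TRUE, detail = ""),
    reference_hits = data.frame(candidate_id = "dup",
                                reference_id = c("r1", "r1"),
                                tm_query = 0.8, tm_target = 0.8,
                                tm_shorter = c(0.8, 0.7), rmsd = 1,
                                identity = 0.1, evalue = 10,
                                qstart = c(1L, 60L), qend = c(50L, 110L)),
    best_reference = "r1"))
  expect_equal(nrow(fusion_scan(rep_same)), 0)
})

test_that("raising any threshold never grows the hit set", {
  res <- acr_screen(small_fix$catalog, small_fix$structures, small_fix$refs,
                    small_fix$domains)
  stricter <- screen_config(acr_tm_cut = 0.8, max_pi = 6.0,
                            acr_max_len = 180L)
  res2 <- acr_screen(small_fix$catalog, small_fix$structures, small_fix$refs,
                     small_fix$domains, config = stricter)
  expect_true(all(unique(res2$hits$candidate_id) %in%
                    unique(res$hits$candidate_id)))
})
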