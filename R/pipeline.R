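#' @title Config-driven end-to-end pipelines
#' @description YAML-configured entry points wiring the modules into the two
#'   discovery pipelines (Acr screen + fusion scan; island mining + defense
#'   screen + prevalence), with a run manifest recording the config snapshot,
#'   input checksums, seed, per-stage funnel counts and wall-clock so runs
#'   are reproducible and auditable.
#' @name cli_pipeline
NULL

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  config
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]]))
      stop("config is missing required input '", k, "'", call. = FALSE)
    if (!file.exists(cfg[[k]]))
      stop("input path does not exist: ", cfg[[k]], call. = FALSE)
  }
}

screen_config_from <- function(cfg) {
  known <- names(formals(screen_config))
  do.call(screen_config, cfg[intersect(names(cfg), known)])
}

read_pdb_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  models <- lapply(files, read_ca_trace)
  names(models) <- vapply(models, function(m) m$protein_id, "")
  models
}

write_manifest <- function(out_dir, cfg, inputs, seed, funnel, timings) {
  manifest <- list(
    tool = paste0("acrminer ",
                  as.character(utils::packageVersion("acrminer"))),
    seed = seed,
    config = cfg[!vapply(cfg, is.function, TRUE)],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    funnel = funnel,
    wallclock_sec = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the Acr discovery pipeline
#'
#' Reads the catalog FASTA, structure PDB directory, reference FASTA + PDB
#' directory and optional domain TSV named in the config, executes
#' [acr_screen()] followed by [fusion_scan()], and writes `report.tsv`,
#' `funnel.tsv`, `fusions.tsv` and `manifest.json` to the output directory.
#'
#' @param config a YAML file path or an equivalent named list. Required
#'   keys: `catalog_fasta`, `pdb_dir`, `refs_fasta`, `refs_pdb_dir`.
#'   Optional: `domains_tsv`, `out_dir`, `seed`, plus any [screen_config()]
#'   field.
#' @param out_dir overrides the config's output directory.
#' @return the output directory, invisibly.
#' @export
run_acr_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  require_inputs(cfg, c("catalog_fasta", "pdb_dir", "refs_fasta",
                        "refs_pdb_dir"))
  out_dir <- out_dir %||% cfg$out_dir %||% "acr_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  catalog <- read_fasta(cfg$catalog_fasta)
  structures <- read_pdb_dir(cfg$pdb_dir)
  refs <- list(records = read_fasta(cfg$refs_fasta),
               structures = read_pdb_dir(cfg$refs_pdb_dir))
  domains <- if (!is.null(cfg$domains_tsv)) read_domain_table(cfg$domains_tsv)
  scfg <- screen_config_from(cfg)

  res <- acr_screen(catalog, structures, refs, domains, scfg)
  check_funnel(res$funnel)
  fus <- fusion_scan(res$reports, scfg)

  write_report(res$reports, file.path(out_dir, "report.tsv"))
  write.table(res$funnel, file.path(out_dir, "funnel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fus_out <- fus
  if (nrow(fus_out)) {
    fus_out$reference_ids <- vapply(fus_out$reference_ids, paste, "",
                                    collapse = ",")
    fus_out$segments <- NULL
  }
  write.table(fus_out, file.path(out_dir, "fusions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  inputs <- cfg[c("catalog_fasta", "refs_fasta")]
  write_manifest(out_dir, cfg, inputs, cfg$seed %||% NA, res$funnel,
                 proc.time()[["elapsed"]] - t0)
  message("acr pipeline: ", sum(res$funnel$n_retained[nrow(res$funnel)]),
          " candidate(s) with structural hits; outputs in ", out_dir)
  invisible(out_dir)
}

#' Run the defense-discovery pipeline
#'
#' Reads the defense-system TSV, gene coordinate TSV and gene FASTA named in
#' the config, mines inter-system regions, extracts intervening proteins,
#' runs [defense_candidate_screen()] when reference structures are supplied,
#' computes marker [prevalence()] when a marker-hit table and system name are
#' supplied, and writes `regions.tsv`, `intervening.faa`, `report.tsv`,
#' `funnel.tsv`, `prevalence.tsv` and `manifest.json`.
#'
#' @param config YAML path or named list. Required keys: `systems_tsv`,
#'   `genes_tsv`, `genes_fasta`. Optional: `pdb_dir`, `refs_fasta`,
#'   `refs_pdb_dir`, `domains_tsv`, `marker_hits_tsv`, `system_name`,
#'   `out_dir`, `seed`, plus any [screen_config()] field.
#' @param out_dir overrides the config's output directory.
#' @return the output directory, invisibly.
#' @export
run_defense_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  require_inputs(cfg, c("systems_tsv", "genes_tsv", "genes_fasta"))
  out_dir <- out_dir %||% cfg$out_dir %||% "defense_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  scfg <- screen_config_from(cfg)

  systems <- read_defense_table(cfg$systems_tsv)
  coords <- read.delim(cfg$genes_tsv, stringsAsFactors = FALSE)
  seqs <- read_fasta(cfg$genes_fasta)
  genes <- protein_records(coords$protein_id,
                           seqs$sequence[match(coords$protein_id,
                                               seqs$protein_id)],
                           genome_id = coords$genome_id,
                           contig_id = coords$contig_id,
                           start = coords$start, end = coords$end,
                           strand = coords$strand)

  regions <- find_intersystem_regions(systems, genes,
                                      scfg$island_min_gap,
                                      scfg$island_max_gap)
  intervening <- extract_intervening_proteins(regions, genes)
  reg_out <- regions
  reg_out$intervening_protein_ids <-
    vapply(regions$intervening_protein_ids, paste, "", collapse = ",")
  write.table(reg_out, file.path(out_dir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(intervening))
    write_fasta(intervening, file.path(out_dir, "intervening.faa"))

  funnel <- NULL
  if (!is.null(cfg$refs_pdb_dir) && nrow(intervening)) {
    structures <- if (!is.null(cfg$pdb_dir)) read_pdb_dir(cfg$pdb_dir)
      else list()
    refs <- list(records = if (!is.null(cfg$refs_fasta))
                   read_fasta(cfg$refs_fasta),
                 structures = read_pdb_dir(cfg$refs_pdb_dir))
    domains <- if (!is.null(cfg$domains_tsv))
      read_domain_table(cfg$domains_tsv)
    res <- defense_candidate_screen(intervening, structures, refs, domains,
                                    scfg)
    check_funnel(res$funnel)
    funnel <- res$funnel
    write_report(res$reports, file.path(out_dir, "report.tsv"))
    write.table(res$funnel, file.path(out_dir, "funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$marker_hits_tsv) && !is.null(cfg$system_name)) {
    hits <- read.delim(cfg$marker_hits_tsv, stringsAsFactors = FALSE)
    prev <- prevalence(systems, hits$genome_id, cfg$system_name)
    write.table(data.frame(system_name = prev$system_name,
                           carriers = prev$carriers, total = prev$total,
                           percent = prev$percent),
                file.path(out_dir, "prevalence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message(sprintf("prevalence: %d/%d = %.2f%%", prev$carriers, prev$total,
                    prev$percent))
  }

  inputs <- cfg[c("systems_tsv", "genes_tsv", "genes_fasta")]
  write_manifest(out_dir, cfg, inputs, cfg$seed %||% NA, funnel,
                 proc.time()[["elapsed"]] - t0)
  invisible(out_dir)
}
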