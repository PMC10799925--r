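#' @title Protein records and external file formats
#' @description Readers and writers for every external representation the
#'   pipeline touches: FASTA protein catalogs, PDB CA traces, domain-hit
#'   tables (CDD-style), defense-system annotation tables (PADLOC-style) and
#'   candidate reports. All tables are tab-delimited UTF-8 with a header row;
#'   genomic coordinates are 1-based inclusive in every file.
#' @name io_formats
NULL

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Construct a protein record table
#'
#' The in-memory catalog is a plain `data.frame` with one row per protein:
#' columns `protein_id`, `sequence`, `length` and optional genomic columns
#' `genome_id`, `contig_id`, `start`, `end`, `strand`.
#'
#' @param protein_id character vector of unique ids.
#' @param sequence amino-acid sequences over `ACDEFGHIKLMNPQRSTVWYX`
#'   (lowercase accepted, a single terminal `*` is stripped).
#' @param genome_id,contig_id optional character vectors.
#' @param start,end optional 1-based inclusive bp coordinates, `start <= end`.
#' @param strand optional `"+"`/`"-"`.
#' @return a `data.frame` of class `protein_records`.
#' @export
protein_records <- function(protein_id, sequence, genome_id = NA_character_,
                            contig_id = NA_character_, start = NA_integer_,
                            end = NA_integer_, strand = NA_character_) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id: ", protein_id[duplicated(protein_id)][1])
  sequence <- toupper(as.character(sequence))
  sequence <- sub("\\*$", "", sequence)
  for (i in seq_along(sequence)) {
    if (!nzchar(sequence[i]))
      stop("empty sequence for record '", protein_id[i], "'")
    bad <- which(!strsplit(sequence[i], "")[[1]] %in% AA_ALPHABET)
    if (length(bad))
      stop("invalid residue in '", protein_id[i], "' at position ", bad[1])
  }
  df <- data.frame(protein_id = protein_id, sequence = sequence,
                   length = nchar(sequence), genome_id = genome_id,
                   contig_id = contig_id, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$start) & !is.na(df$end) & df$start > df$end
  if (any(bad))
    stop("start > end for record '", df$protein_id[which(bad)[1]], "'")
  class(df) <- c("protein_records", "data.frame")
  df
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased, a single terminal stop character `*` is stripped,
#' and ids are the first whitespace-delimited token of each header. Record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a [protein_records()] table.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("empty sequence under header '", names(set)[empty[1]], "'")
  protein_records(protein_id = ids, sequence = seqs)
}

#' Write a protein FASTA file
#'
#' @param records a [protein_records()] table (non-empty, unique ids).
#' @param path output path; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0) stop("cannot write an empty record set")
  if (anyDuplicated(records$protein_id))
    stop("duplicate protein_id: ",
         records$protein_id[duplicated(records$protein_id)][1])
  set <- Biostrings::BStringSet(setNames(records$sequence, records$protein_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Construct a CA-trace structure model
#'
#' @param protein_id identifier.
#' @param coords n x 3 numeric matrix of CA coordinates in Angstrom.
#' @param residues one-letter residue codes, one per coordinate row.
#' @param plddt optional per-residue model confidence in `[0, 100]`.
#' @return object of class `ca_trace`.
#' @export
ca_trace <- function(protein_id, coords, residues = NULL, plddt = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (nrow(coords) < 3) stop("a CA trace needs at least 3 residues")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(residues)) residues <- rep("A", nrow(coords))
  if (length(residues) != nrow(coords))
    stop("residues and coords lengths differ")
  if (!is.null(plddt)) {
    if (length(plddt) != nrow(coords)) stop("plddt length mismatch")
    if (any(plddt < 0 | plddt > 100)) stop("plddt outside [0, 100]")
  }
  structure(list(protein_id = as.character(protein_id), coords = coords,
                 residues = as.character(residues), plddt = plddt),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("<ca_trace>", x$protein_id, "-", nrow(x$coords), "residues\n")
  invisible(x)
}

#' @export
length.ca_trace <- function(x) nrow(x$coords)

#' Read a CA trace from a PDB file
#'
#' Reads the first MODEL only, the first chain encountered, altloc blank or
#' `'A'` only, CA atoms only, ordered by residue sequence number. The B-factor
#' column is stored as per-residue pLDDT when every value lies in `[0, 100]`
#' (the AlphaFold2 convention). Residues that lack a CA atom are skipped with
#' a warning.
#'
#' @param path path to a PDB file with ATOM records.
#' @return a [ca_trace()] model.
#' @export
read_ca_trace <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  chain <- at$chain[1]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  n_res <- length(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in ", path)
  if (nrow(ca) < n_res)
    warning(n_res - nrow(ca), " residue(s) without a CA atom skipped in ",
            basename(path))
  if (nrow(ca) < 3) stop("fewer than 3 CA residues in ", path)
  plddt <- ca$b
  if (any(is.na(plddt)) || any(plddt < 0 | plddt > 100)) plddt <- NULL
  res1 <- suppressWarnings(bio3d::aa321(ca$resid))
  res1[is.na(res1) | !res1 %in% AA_ALPHABET] <- "X"
  id <- sub("\\.pdb$", "", basename(path))
  ca_trace(id, as.matrix(ca[, c("x", "y", "z")]), res1, plddt)
}

#' Write a CA trace as a PDB file
#'
#' One ATOM record per residue (CA only, chain A); pLDDT, when present, is
#' written to the B-factor column. Coordinates use the fixed-width PDB
#' precision of 3 decimals.
#'
#' @param model a [ca_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(model, path) {
  n <- nrow(model$coords)
  res3 <- bio3d::aa123(model$residues)
  res3[is.na(res3)] <- "UNK"
  b <- model$plddt %||% rep(0, n)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), res3, seq_len(n),
    model$coords[, 1], model$coords[, 2], model$coords[, 3], 1, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a defense-system annotation table
#'
#' Tab-delimited with header columns `genome_id`, `contig_id`, `system_name`,
#' `start`, `end`, `strand`, `gene_ids` (comma-joined member protein ids).
#'
#' @param path path to the TSV.
#' @return a `data.frame` with `gene_ids` as a list column.
#' @export
read_defense_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("genome_id", "contig_id", "system_name", "start", "end",
            "strand", "gene_ids")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      stop("non-integer ", col, " in row ", bad[1])
    df[[col]] <- v
  }
  bad <- which(df$start > df$end)
  if (length(bad)) stop("start > end in row ", bad[1])
  df$gene_ids <- lapply(strsplit(df$gene_ids, ","), trimws)
  if (any(lengths(df$gene_ids) == 0)) stop("empty gene_ids")
  df
}

#' Write a defense-system annotation table
#' @param systems a defense-system `data.frame` as from [read_defense_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_defense_table <- function(systems, path) {
  out <- systems
  out$gene_ids <- vapply(systems$gene_ids, paste, "", collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain-annotation (CDD-style) table
#'
#' Tab-delimited with header columns `protein_id`, `domain_id`, `evalue`.
#' A protein may carry zero or more domain hits.
#'
#' @param path path to the TSV.
#' @return a `data.frame` with typed columns.
#' @export
read_domain_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_id", "evalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$evalue <- as.numeric(df$evalue)
  if (any(is.na(df$evalue)) && nrow(df)) stop("non-numeric evalue")
  if (any(df$evalue < 0)) stop("negative evalue")
  df[, need, drop = FALSE]
}

#' Write candidate reports as a TSV
#'
#' One row per candidate x reference hit, ordered by `candidate_id` then
#' descending `tm_shorter`. Candidates without reference hits are omitted
#' (their funnel verdicts live in the funnel log).
#'
#' @param reports list of candidate reports as produced by the screens.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  cols <- c("candidate_id", "reference_id", "tm_query", "tm_target",
            "tm_shorter", "rmsd", "identity", "filters_passed")
  rows <- lapply(reports, function(r) {
    if (is.null(r$reference_hits) || nrow(r$reference_hits) == 0) return(NULL)
    h <- r$reference_hits
    data.frame(candidate_id = r$candidate_id, reference_id = h$reference_id,
               tm_query = round(h$tm_query, 4), tm_target = round(h$tm_target, 4),
               tm_shorter = round(h$tm_shorter, 4), rmsd = round(h$rmsd, 4),
               identity = round(h$identity, 4),
               filters_passed = paste(r$stage_verdicts$stage[r$stage_verdicts$passed],
                                      collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(candidate_id = character(0),
                       reference_id = character(0), tm_query = numeric(0),
                       tm_target = numeric(0), tm_shorter = numeric(0),
                       rmsd = numeric(0), identity = numeric(0),
                       filters_passed = character(0))
  rows <- rows[order(rows$candidate_id, -rows$tm_shorter), , drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate report TSV written by [write_report()]
#' @param path path to the TSV.
#' @return a `data.frame`.
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
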