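# File interfaces: FASTQ pairs, FASTA references, sample sheets, count and
# truth tables, study manifests.

#' Read a pair of FASTQ files into the pipeline's pair tibble
#'
#' @param r1_path,r2_path Paths to mate FASTQ files (phred+33; `.gz`
#'   supported). Records are paired by position.
#' @return Tibble (`read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) abort("mate files have different record counts")
  tibble(read_id = sub(" .*", "", names(r1)),
         r1_seq = as.character(r1),
         r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
         r2_seq = as.character(r2),
         r2_qual = as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write simulated reads as a FASTQ pair
#'
#' @param reads Tibble with `read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (e.g. `simulate_reads()$reads`).
#' @param r1_path,r2_path Output paths (plain text).
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  check_columns(reads, c("read_id", "r1_seq", "r1_qual", "r2_seq", "r2_qual"), "reads")
  write_one <- function(ids, seqs, quals, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  write_one(reads$read_id, reads$r1_seq, reads$r1_qual, r1_path)
  write_one(reads$read_id, reads$r2_seq, reads$r2_qual, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Write a barcode reference as FASTA
#'
#' Headers carry the allele id and its member strains
#' (`>A01 strains=S01+S02`).
#'
#' @param reference A `barcode_reference`.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_reference_fasta <- function(reference, path) {
  stopifnot(inherits(reference, "barcode_reference"))
  members <- reference$membership |>
    group_by(.data$allele_id) |>
    summarise(strains = paste(sort(.data$strain_id), collapse = "+"), .groups = "drop")
  headers <- paste0(names(reference$alleles), " strains=",
                    members$strains[match(names(reference$alleles), members$allele_id)])
  writeLines(paste0(">", headers, "\n", unname(reference$alleles)), path)
  invisible(path)
}

#' Read a barcode reference from FASTA
#'
#' @param path FASTA path written by [write_reference_fasta()] (or any FASTA
#'   whose headers are `allele_id strains=a+b`); without a strains field,
#'   each allele maps to a strain of the same name.
#' @return A `barcode_reference`.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*", "", names(ss))
  strains_field <- sub(".*strains=([^ ]+).*", "\\1", names(ss))
  strains_field[!grepl("strains=", names(ss))] <- ids[!grepl("strains=", names(ss))]
  membership <- purrr::map2_dfr(ids, strains_field, function(a, s) {
    tibble(allele_id = a, strain_id = strsplit(s, "+", fixed = TRUE)[[1]])
  })
  new_barcode_reference(setNames(as.character(ss), ids), membership)
}

#' Write a complete synthetic study to disk
#'
#' Emits per-run FASTQ pair, sample sheet TSV, reference FASTA, truth tables
#' (mixture proportions, truth counts, presence matrix, planted effects) and
#' a JSON manifest with all parameters.
#'
#' @param study List from [simulate_study()] (with `reads`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  if (is.null(study$reads)) abort("study has no reads: rerun simulate_study(reads = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq_pairs(study$reads$reads, file.path(dir, "run_R1.fastq"),
                    file.path(dir, "run_R2.fastq"))
  readr::write_tsv(study$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_reference_fasta(study$reference, file.path(dir, "reference.fasta"))
  readr::write_tsv(study$mixtures, file.path(dir, "truth_proportions.tsv"))
  readr::write_tsv(study$reads$truth_counts, file.path(dir, "truth_counts.tsv"))
  readr::write_tsv(study$pangenome$presence, file.path(dir, "truth_presence.tsv"))
  readr::write_tsv(study$effects, file.path(dir, "planted_effects.tsv"))
  writeLines(paste0(">", study$panel$strains$strain_id, "\n",
                    study$panel$strains$marker_sequence),
             file.path(dir, "panel_markers.fasta"))
  manifest <- c(study$reads$params,
                attr(study$mixtures, "params"),
                study$pangenome$params,
                list(n_strains = nrow(study$panel$strains),
                     allele_length = study$panel$allele_length,
                     primer_fwd = study$panel$primer_fwd,
                     primer_rev = study$panel$primer_rev))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a long count table as a strains x samples TSV
#'
#' @param counts Long tibble (`sample_id`, `strain_id`, `count`).
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_count_table <- function(counts, path) {
  wide <- counts |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}
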