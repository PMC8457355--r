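# Exact-match processing chain: merge pairs, demultiplex by 5' tag, trim
# primers, track expected error, dereplicate, flag chimeras (QC only),
# assign reads strictly identical to reference alleles.

#' Merge paired reads by best ungapped overlap
#'
#' For each pair, all relative offsets of the forward read against the
#' reverse complement of the reverse read are scored (+1 match, -2
#' mismatch over the overlap); the best offset is accepted when its overlap
#' is at least `min_overlap` long with a mismatch fraction at most
#' `max_mismatch_fraction`. Staggered layouts (one read overhanging the
#' other's 5' end) are trimmed to the overlap when `allow_stagger`, rejected
#' otherwise. Posterior qualities: agreement gives `min(Q1 + Q2, qcap)`,
#' conflict keeps the higher-quality base with `|Q1 - Q2|`.
#'
#' @param pairs Tibble with columns `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`
#'   (and optionally `read_id`), e.g. from [simulate_reads()] or
#'   [read_fastq_pairs()].
#' @param min_overlap Minimum overlap length in bp (>= 8).
#' @param max_mismatch_fraction Maximum mismatch fraction in the overlap.
#' @param allow_stagger Keep staggered pairs (trimmed to the overlap)?
#' @param qcap Posterior quality cap.
#' @return Tibble `read_id`, `sequence`, `quality`, `status` (`merged`,
#'   `no_overlap` or `stagger_rejected`); unmerged rows carry NA sequence.
#' @export
merge_pairs <- function(pairs, min_overlap = 16, max_mismatch_fraction = 0.25,
                        allow_stagger = TRUE, qcap = 41) {
  check_columns(pairs, c("r1_seq", "r1_qual", "r2_seq", "r2_qual"), "pairs")
  if (min_overlap < 8) abort("min_overlap must be >= 8")
  res <- .merge_pairs_cpp(pairs$r1_seq, pairs$r1_qual, pairs$r2_seq, pairs$r2_qual,
                          as.integer(min_overlap), max_mismatch_fraction,
                          allow_stagger, as.integer(qcap))
  tibble(read_id = pairs$read_id %||% sprintf("read_%d", seq_len(nrow(pairs))),
         sequence = res$sequence, quality = res$quality, status = res$status)
}

#' Demultiplex merged reads by exact 5' tag match
#'
#' A read is assigned to a sample iff its 5' prefix equals that sample's tag
#' exactly (full length, zero mismatches); the tag is clipped on assignment.
#'
#' @param reads Tibble with a `sequence` column (and optionally `quality`).
#' @param tag_map Tibble (`sample_id`, `tag`) or named character vector of
#'   tags named by sample; tags must be equal-length and pairwise distinct.
#' @return Input tibble with `sample_id` filled for assigned reads, tag
#'   clipped from `sequence`/`quality`; unassigned reads have NA `sample_id`
#'   and untouched sequence.
#' @export
demultiplex <- function(reads, tag_map) {
  check_columns(reads, "sequence", "reads")
  if (is.character(tag_map) && !is.null(names(tag_map))) {
    tag_map <- tibble(sample_id = names(tag_map), tag = unname(tag_map))
  }
  check_columns(tag_map, c("sample_id", "tag"), "tag_map")
  if (anyDuplicated(tag_map$tag)) abort("duplicate tags in tag_map")
  if (length(unique(nchar(tag_map$tag))) != 1) abort("tags must be equal-length")
  tl <- nchar(tag_map$tag[[1]])
  prefix <- substr(reads$sequence, 1, tl)
  hit <- match(prefix, tag_map$tag)
  out <- reads
  out$sample_id <- tag_map$sample_id[hit]
  assigned <- !is.na(hit) & !is.na(reads$sequence)
  out$sample_id[is.na(reads$sequence)] <- NA_character_
  out$sequence[assigned] <- substr(reads$sequence[assigned], tl + 1,
                                   nchar(reads$sequence[assigned]))
  if ("quality" %in% names(out)) {
    out$quality[assigned] <- substr(reads$quality[assigned], tl + 1,
                                    nchar(reads$quality[assigned]))
  }
  out
}

#' Trim anchored primers from both read ends
#'
#' The forward primer must match at the 5' end and the reverse-complemented
#' reverse primer at the 3' end; each may run off its read boundary down to
#' `min_match_fraction` of the primer length, with a per-alignment mismatch
#' rate at most `max_error_rate`. Reads lacking either primer are rejected;
#' primers overlapping each other inside the read are rejected with a
#' distinct reason.
#'
#' @param reads Tibble with `sequence` (and optionally `quality`).
#' @param primer_fwd,primer_rev Primer sequences (plus strand).
#' @param min_match_fraction Minimum retained fraction of a boundary-
#'   truncated primer (default 2/3).
#' @param max_error_rate Maximum mismatch rate within a primer alignment.
#' @return Input tibble with `sequence`/`quality` replaced by the insert and
#'   a `trim_status` column (`retained`, `no_fwd_primer`, `no_rev_primer`,
#'   `primer_overlap`).
#' @export
trim_primers <- function(reads, primer_fwd, primer_rev,
                         min_match_fraction = 2 / 3, max_error_rate = 0.1) {
  check_columns(reads, "sequence", "reads")
  if (min_match_fraction <= 0 || min_match_fraction > 1)
    abort("min_match_fraction must be in (0, 1]")
  seqs <- reads$sequence
  keep <- !is.na(seqs)
  quals <- if ("quality" %in% names(reads)) reads$quality else rep(NA_character_, length(seqs))
  res <- .trim_primers_cpp(ifelse(keep, seqs, ""), ifelse(keep, quals, ""),
                           primer_fwd, primer_rev, min_match_fraction, max_error_rate)
  out <- reads
  out$sequence <- ifelse(keep, res$sequence, NA_character_)
  if ("quality" %in% names(out)) out$quality <- ifelse(keep, res$quality, NA_character_)
  out$trim_status <- ifelse(keep, res$status, "not_merged")
  out
}

#' Expected error of quality strings
#'
#' EE = sum over bases of `10^(-Q/10)` with phred+33 encoding.
#'
#' @param qualities Character vector of quality strings (NA gives NA).
#' @return Numeric vector of expected errors; empty strings give 0.
#' @export
estimate_expected_error <- function(qualities) {
  out <- rep(NA_real_, length(qualities))
  ok <- !is.na(qualities)
  out[ok] <- .expected_error_cpp(qualities[ok])
  out
}

#' Dereplicate reads into unique sequences
#'
#' Collapses strictly identical sequences per sample, recording abundance and
#' the lowest expected error among members.
#'
#' @param reads Tibble with `sequence`, optionally `sample_id`,
#'   `expected_error` (or `quality`, from which EE is computed).
#' @return Tibble (`sample_id`, `sequence`, `abundance`,
#'   `min_expected_error`) sorted by decreasing abundance within sample.
#' @export
dereplicate <- function(reads) {
  check_columns(reads, "sequence", "reads")
  df <- reads |> filter(!is.na(.data$sequence))
  if (!"sample_id" %in% names(df)) df$sample_id <- "pool"
  if (!"expected_error" %in% names(df)) {
    df$expected_error <- if ("quality" %in% names(df))
      estimate_expected_error(df$quality) else NA_real_
  }
  df |>
    group_by(.data$sample_id, .data$sequence) |>
    summarise(abundance = n(),
              min_expected_error = suppressWarnings(min(.data$expected_error)),
              .groups = "drop") |>
    mutate(min_expected_error = ifelse(is.finite(.data$min_expected_error),
                                       .data$min_expected_error, NA_real_)) |>
    arrange(.data$sample_id, desc(.data$abundance), .data$sequence)
}

#' Flag putative chimeras among unique sequences (QC only)
#'
#' A sequence is flagged iff some pair of parents, each at least
#' `min_parent_ratio` times more abundant, explains it as a single-crossover
#' hybrid with at least `min_improvement` fewer mismatches than the best
#' single parent. Flags never remove reads from counting.
#'
#' @param uniques Tibble from [dereplicate()] (per sample or pooled).
#' @param min_parent_ratio Minimum parent/query abundance ratio.
#' @param min_improvement Required mismatch improvement of the two-parent
#'   model over the best single parent.
#' @param max_parents Cap on candidate parents examined per query (most
#'   abundant first).
#' @return `uniques` with a logical `chimera_flag` column.
#' @export
flag_chimeras <- function(uniques, min_parent_ratio = 2, min_improvement = 2,
                          max_parents = 20) {
  check_columns(uniques, c("sequence", "abundance"), "uniques")
  flag_one_pool <- function(df) {
    df <- df[order(-df$abundance), , drop = FALSE]
    n <- nrow(df)
    flags <- rep(FALSE, n)
    if (n >= 3) {
      lens <- nchar(df$sequence)
      for (i in seq_len(n)) {
        parents <- which(df$abundance >= min_parent_ratio * df$abundance[i] &
                           lens == lens[i])
        parents <- head(parents, max_parents)
        if (length(parents) < 2) next
        q <- strsplit(df$sequence[i], "", fixed = TRUE)[[1]]
        pm <- do.call(rbind, strsplit(df$sequence[parents], "", fixed = TRUE))
        mism <- sweep(pm, 2, q, FUN = "!=") * 1L
        cum_l <- t(apply(mism, 1, cumsum))                   # mismatches in q[1..p]
        tot <- cum_l[, ncol(cum_l)]
        best_single <- min(tot)
        # best crossover: left parent a up to position p, right parent b after
        L <- length(q)
        best_two <- best_single
        suffix <- tot - cum_l                                 # mismatches in q[(p+1)..L]
        for (p in seq_len(L - 1)) {
          two <- min(cum_l[, p]) + min(suffix[, p])
          if (two < best_two) best_two <- two
        }
        flags[i] <- (best_single - best_two) >= min_improvement
      }
    }
    df$chimera_flag <- flags
    df
  }
  if ("sample_id" %in% names(uniques)) {
    uniques |> group_by(.data$sample_id) |> group_modify(~flag_one_pool(.x)) |> ungroup()
  } else flag_one_pool(uniques)
}

#' Assign unique sequences to reference alleles by strict identity
#'
#' A unique sequence contributes its abundance to exactly the allele it is
#' string-equal to; everything else is discarded (tallied in the log
#' attribute). Collision-group alleles accrue counts at the allele-group
#' level.
#'
#' @param uniques Tibble from [dereplicate()].
#' @param reference A `barcode_reference`.
#' @return Tibble (`sample_id`, `allele_id`, `count`) with attribute
#'   `discarded` (tibble of per-sample discarded read counts).
#' @export
assign_exact <- function(uniques, reference) {
  stopifnot(inherits(reference, "barcode_reference"))
  check_columns(uniques, c("sequence", "abundance"), "uniques")
  if (anyDuplicated(reference$alleles)) abort("reference alleles must be pairwise distinct")
  df <- uniques
  if (!"sample_id" %in% names(df)) df$sample_id <- "pool"
  df$allele_id <- names(reference$alleles)[match(df$sequence, reference$alleles)]
  assigned <- df |>
    filter(!is.na(.data$allele_id)) |>
    group_by(.data$sample_id, .data$allele_id) |>
    summarise(count = sum(.data$abundance), .groups = "drop")
  discarded <- df |>
    group_by(.data$sample_id) |>
    summarise(discarded = sum(.data$abundance[is.na(.data$allele_id)]),
              .groups = "drop")
  structure(assigned, discarded = discarded)
}

#' Tabulate per-strain counts across samples
#'
#' Expands assignments to a complete long count table (zero-filled), labels
#' collision groups by their member strains, and attaches the processing log.
#'
#' @param assignments Tibble from [assign_exact()].
#' @param sample_sheet Tibble with `sample_id` (and any design columns);
#'   every assigned sample must appear in it.
#' @param reference A `barcode_reference`, used to label alleles by strain
#'   (collision groups get `"id1+id2"` labels).
#' @param log Optional named list of per-stage read counts to store.
#' @return Tibble (`sample_id`, `strain_id`, `count`) of class `epc_counts`
#'   covering every sheet sample x allele group, with attributes
#'   `processing_log` and `sample_sheet`.
#' @export
tabulate_counts <- function(assignments, sample_sheet, reference, log = list()) {
  check_columns(assignments, c("sample_id", "allele_id", "count"), "assignments")
  check_columns(sample_sheet, "sample_id", "sample_sheet")
  orphans <- setdiff(unique(assignments$sample_id), sample_sheet$sample_id)
  if (length(orphans))
    abort(sprintf("sample(s) absent from sheet: %s", paste(orphans, collapse = ", ")))
  label <- reference$membership |>
    group_by(.data$allele_id) |>
    summarise(strain_id = paste(sort(.data$strain_id), collapse = "+"), .groups = "drop")
  full <- tidyr::expand_grid(sample_id = sample_sheet$sample_id,
                             allele_id = names(reference$alleles)) |>
    left_join(assignments, by = c("sample_id", "allele_id")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    left_join(label, by = "allele_id") |>
    select("sample_id", "strain_id", "count")
  structure(full, class = c("epc_counts", class(full)),
            processing_log = log, sample_sheet = sample_sheet)
}

#' Run the full exact-match quantification chain
#'
#' Merge, demultiplex, primer-trim, compute expected errors, dereplicate,
#' optionally flag chimeras, assign exactly, tabulate. The per-stage read
#' funnel is recorded in the result's `processing_log` attribute.
#'
#' @param pairs Raw read pairs (see [merge_pairs()]).
#' @param sample_sheet Tibble with `sample_id` and `tag` columns.
#' @param reference A `barcode_reference`.
#' @param primer_fwd,primer_rev Amplification primers.
#' @param min_overlap,max_mismatch_fraction,allow_stagger Merging parameters.
#' @param min_match_fraction,max_error_rate Primer-trim parameters.
#' @param flag_chimeras_qc Run the chimera QC flagging stage?
#' @return List with `counts` (an `epc_counts` tibble), `uniques`, and `log`.
#' @export
quantify_reads <- function(pairs, sample_sheet, reference,
                           primer_fwd = default_primers()[["fwd"]],
                           primer_rev = default_primers()[["rev"]],
                           min_overlap = 16, max_mismatch_fraction = 0.25,
                           allow_stagger = TRUE, min_match_fraction = 2 / 3,
                           max_error_rate = 0.1, flag_chimeras_qc = FALSE) {
  check_columns(sample_sheet, c("sample_id", "tag"), "sample_sheet")
  merged <- merge_pairs(pairs, min_overlap = min_overlap,
                        max_mismatch_fraction = max_mismatch_fraction,
                        allow_stagger = allow_stagger)
  demuxed <- demultiplex(merged, sample_sheet[, c("sample_id", "tag")])
  demuxed <- demuxed |> filter(!is.na(.data$sample_id))
  trimmed <- trim_primers(demuxed, primer_fwd, primer_rev,
                          min_match_fraction = min_match_fraction,
                          max_error_rate = max_error_rate)
  retained <- trimmed |> filter(.data$trim_status == "retained")
  retained$expected_error <- estimate_expected_error(retained$quality)
  uniques <- dereplicate(retained)
  if (flag_chimeras_qc) uniques <- flag_chimeras(uniques)
  assigned <- assign_exact(uniques, reference)
  log <- list(
    raw = nrow(pairs),
    merged = sum(merged$status == "merged"),
    demultiplexed = nrow(demuxed),
    primer_retained = nrow(retained),
    assigned = sum(assigned$count),
    discarded_nonidentical = sum(attr(assigned, "discarded")$discarded)
  )
  counts <- tabulate_counts(assigned, sample_sheet, reference, log = log)
  list(counts = counts, uniques = uniques, log = log)
}
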