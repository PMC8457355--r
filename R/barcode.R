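# Barcode window design over an aligned marker gene, allele reference
# construction, and core-collection selection.

#' Scan an alignment for discriminating fixed-length windows
#'
#' Slides a window of `window_length` alignment columns over a marker-gene
#' alignment and, for each admissible start, counts the distinct gap-stripped
#' window sequences (`n_alleles`) and checks that both flanking
#' `primer_length` windows are conserved: every strain must be within
#' `max_primer_mismatch` mismatches of the column-consensus in each flank
#' (`primer_ok`). Coordinates are 0-based, half-open.
#'
#' @param aligned_markers Named character vector of equal-length aligned
#'   sequences (gaps as `-`), or a `Biostrings::DNAStringSet`.
#' @param window_length Window length in alignment columns.
#' @param primer_length Length of each flanking primer site.
#' @param max_primer_mismatch Per-strain mismatch budget against the flank
#'   consensus.
#' @return Tibble with one row per admissible start: `start`, `length`,
#'   `n_alleles`, `primer_ok`.
#' @export
scan_windows <- function(aligned_markers, window_length, primer_length = 20,
                         max_primer_mismatch = 1) {
  seqs <- as_sequence_vector(aligned_markers)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    abort("sequences have unequal lengths: supply a pre-computed multiple alignment")
  L <- lens[[1]]
  if (window_length + 2 * primer_length > L)
    abort("window_length + 2*primer_length exceeds the alignment length")
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))

  consensus_ok <- function(cols) {
    sub <- mat[, cols, drop = FALSE]
    cons <- apply(sub, 2, function(col) names(which.max(table(col))))
    mism <- rowSums(sweep(sub, 2, cons, FUN = "!="))
    all(mism <= max_primer_mismatch)
  }
  starts <- seq.int(primer_length, L - window_length - primer_length) # 0-based
  purrr::map_dfr(starts, function(s) {
    win <- substr(seqs, s + 1, s + window_length)
    win <- gsub("-", "", win, fixed = TRUE)
    tibble(start = s, length = window_length,
           n_alleles = length(unique(win)),
           primer_ok = consensus_ok(seq.int(s - primer_length + 1, s)) &&
             consensus_ok(seq.int(s + window_length + 1, s + window_length + primer_length)))
  })
}

#' Pick the most discriminating admissible window
#'
#' @param reports Tibble from [scan_windows()].
#' @param tie_break Tie rule among windows with maximal `n_alleles`;
#'   only `"leftmost"` is implemented.
#' @return The selected one-row report.
#' @export
select_barcode <- function(reports, tie_break = c("leftmost")) {
  tie_break <- match.arg(tie_break)
  check_columns(reports, c("start", "n_alleles", "primer_ok"), "reports")
  ok <- reports[reports$primer_ok, , drop = FALSE]
  if (nrow(ok) == 0) abort("no conserved primer site: no admissible window")
  ok <- ok[order(-ok$n_alleles, ok$start), , drop = FALSE]
  ok[1, , drop = FALSE]
}

#' Build the allele reference for a chosen barcode window
#'
#' Extracts the gap-stripped window sequence of every strain, groups strains
#' by identical allele, and reports collision groups (alleles shared by two
#' or more strains).
#'
#' @param aligned_markers Named aligned sequences (as in [scan_windows()]).
#' @param window One-row window report (`start`, `length`), 0-based
#'   half-open, or a list with those fields.
#' @return Object of class `barcode_reference`: list with `alleles` (named
#'   character), `membership` tibble (`allele_id`, `strain_id`), and
#'   `collision_groups`.
#' @export
build_reference <- function(aligned_markers, window) {
  seqs <- as_sequence_vector(aligned_markers)
  if (is.null(names(seqs))) names(seqs) <- sprintf("S%02d", seq_along(seqs))
  s <- window$start[[1]]; w <- window$length[[1]]
  if (any(nchar(seqs) < s + w)) abort("window not admissible for every strain")
  win <- gsub("-", "", substr(seqs, s + 1, s + w), fixed = TRUE)
  allele_seqs <- unique(win)
  allele_ids <- sprintf("A%02d", seq_along(allele_seqs))
  membership <- tibble(strain_id = names(seqs),
                       allele_id = allele_ids[match(win, allele_seqs)]) |>
    select("allele_id", "strain_id") |>
    arrange(.data$allele_id, .data$strain_id)
  new_barcode_reference(setNames(allele_seqs, allele_ids), membership)
}

new_barcode_reference <- function(alleles, membership) {
  stopifnot(!anyDuplicated(alleles), !anyDuplicated(membership$strain_id))
  groups <- membership |> count(.data$allele_id) |> filter(.data$n >= 2)
  collision <- purrr::map(setNames(groups$allele_id, groups$allele_id), function(a) {
    membership$strain_id[membership$allele_id == a]
  })
  structure(list(alleles = alleles, membership = membership,
                 collision_groups = collision),
            class = "barcode_reference")
}

#' Barcode reference of a simulated panel
#'
#' The simulator knows each strain's allele directly; this builds the same
#' `barcode_reference` object that [build_reference()] derives from an
#' alignment.
#'
#' @param panel A `strain_panel`.
#' @return A `barcode_reference`.
#' @export
as_barcode_reference <- function(panel) {
  stopifnot(inherits(panel, "strain_panel"))
  new_barcode_reference(panel$alleles,
                        panel$strains |> select("allele_id", "strain_id") |>
                          arrange(.data$allele_id, .data$strain_id))
}

#' @export
print.barcode_reference <- function(x, ...) {
  cat(sprintf("<barcode_reference> %d alleles over %d strains, %d collision group(s)\n",
              length(x$alleles), nrow(x$membership), length(x$collision_groups)))
  invisible(x)
}

#' Select a core collection of strains with unique barcodes
#'
#' Chooses exactly one strain per allele, greedily maximizing coverage of
#' metadata diversity in priority order: new genospecies/Nod-group
#' combinations first, then hosts of isolation, then geographic origins, then
#' nodX presence/absence balance. Deterministic given input order (ties keep
#' the earlier strain).
#'
#' @param reference A `barcode_reference`.
#' @param metadata Tibble with `strain_id` and any of `genospecies`,
#'   `nod_group`, `host_of_isolation`, `origin`, `nodX`.
#' @param target_size Number of strains to select; must not exceed the
#'   number of alleles.
#' @return Character vector of selected strain ids (one per allele, first
#'   `target_size` alleles in reference order).
#' @export
select_core_collection <- function(reference, metadata, target_size = length(reference$alleles)) {
  stopifnot(inherits(reference, "barcode_reference"))
  check_columns(metadata, "strain_id", "metadata")
  if (target_size > length(reference$alleles))
    abort("target_size exceeds the number of alleles: unique barcodes impossible")
  md <- metadata
  feat <- function(s, col) {
    if (!col %in% names(md)) return(NA_character_)
    v <- md[[col]][match(s, md$strain_id)]
    as.character(v)
  }
  combo <- function(s) paste(feat(s, "genospecies"), feat(s, "nod_group"), sep = "/")

  seen_combo <- character(0); seen_host <- character(0); seen_origin <- character(0)
  n_nodx <- c(`TRUE` = 0, `FALSE` = 0)
  selected <- character(0)
  allele_ids <- names(reference$alleles)[seq_len(target_size)]
  for (a in allele_ids) {
    cands <- reference$membership$strain_id[reference$membership$allele_id == a]
    if (length(cands) > 1) {
      score <- vapply(cands, function(s) {
        sc <- 0
        if (!combo(s) %in% seen_combo) sc <- sc + 1000
        if (!is.na(feat(s, "host_of_isolation")) &&
            !feat(s, "host_of_isolation") %in% seen_host) sc <- sc + 100
        if (!is.na(feat(s, "origin")) && !feat(s, "origin") %in% seen_origin) sc <- sc + 10
        nx <- feat(s, "nodX")
        if (!is.na(nx)) { # favor the rarer nodX status so far
          other <- setdiff(c("TRUE", "FALSE"), nx)
          if (n_nodx[[nx]] < n_nodx[[other]]) sc <- sc + 1
        }
        sc
      }, numeric(1))
      pick <- cands[which.max(score)]
    } else pick <- cands
    selected <- c(selected, pick)
    seen_combo <- union(seen_combo, combo(pick))
    seen_host <- union(seen_host, feat(pick, "host_of_isolation"))
    seen_origin <- union(seen_origin, feat(pick, "origin"))
    nx <- feat(pick, "nodX")
    if (!is.na(nx)) n_nodx[[nx]] <- n_nodx[[nx]] + 1
  }
  selected
}

# Accept a named character vector, a DNAStringSet, or anything coercible.
as_sequence_vector <- function(x) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    abort("sequences must be a character vector or a Biostrings XStringSet")
  }
  toupper(out)
}
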