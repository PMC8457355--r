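# Early Partner Choice index: per-sample percentages, replicate means and
# CV%, detection filtering, and host/strain profile clustering.

#' Compute the EPC index per sample
#'
#' The EPC index of a strain in a sample is its percentage of all assigned
#' barcode reads in that sample: `epc = 100 * count / sample_total`. Samples
#' with zero assigned reads yield missing values and a warning.
#'
#' @param counts Long count tibble (`sample_id`, `strain_id`, `count`), e.g.
#'   an `epc_counts` object from [tabulate_counts()].
#' @return Tibble (`sample_id`, `strain_id`, `count`, `total`, `epc`).
#' @export
compute_epc <- function(counts) {
  check_columns(counts, c("sample_id", "strain_id", "count"), "counts")
  if (any(counts$count < 0)) abort("negative counts")
  out <- counts |>
    group_by(.data$sample_id) |>
    mutate(total = sum(.data$count)) |>
    ungroup() |>
    mutate(epc = ifelse(.data$total > 0, 100 * .data$count / .data$total, NA_real_))
  empty <- unique(out$sample_id[out$total == 0])
  if (length(empty))
    warn(sprintf("sample(s) with zero assigned reads reported as missing: %s",
                 paste(empty, collapse = ", ")))
  out
}

#' Summarize EPC over biological replicates
#'
#' Means are taken over replicate percentages (not pooled counts); CV% is
#' `100 * sd / mean` with the sample (n-1) standard deviation, missing when
#' the mean is 0 or fewer than two usable replicates exist.
#'
#' @param epc Tibble from [compute_epc()].
#' @param sample_sheet Tibble (`sample_id`, `host_genotype`, ...).
#' @return Object of class `epc_summary`: tibble (`host_genotype`,
#'   `strain_id`, `epc_mean`, `cv_percent`, `n_replicates`).
#' @export
summarize_replicates <- function(epc, sample_sheet) {
  check_columns(epc, c("sample_id", "strain_id", "epc"), "epc")
  check_columns(sample_sheet, c("sample_id", "host_genotype"), "sample_sheet")
  df <- epc |>
    inner_join(sample_sheet |> distinct(.data$sample_id, .data$host_genotype),
               by = "sample_id")
  bad <- df |>
    group_by(.data$host_genotype, .data$strain_id) |>
    summarise(usable = sum(!is.na(.data$epc)), .groups = "drop") |>
    filter(.data$usable == 0)
  if (nrow(bad))
    abort(sprintf("condition(s) with zero usable replicates: %s",
                  paste(unique(bad$host_genotype), collapse = ", ")))
  out <- df |>
    filter(!is.na(.data$epc)) |>
    group_by(.data$host_genotype, .data$strain_id) |>
    summarise(epc_mean = mean(.data$epc),
              epc_sd = if (n() > 1) sd(.data$epc) else NA_real_,
              n_replicates = n(), .groups = "drop") |>
    mutate(cv_percent = ifelse(.data$epc_mean > 0, 100 * .data$epc_sd / .data$epc_mean,
                               NA_real_)) |>
    select("host_genotype", "strain_id", "epc_mean", "cv_percent", "n_replicates")
  structure(out, class = c("epc_summary", class(out)))
}

#' Partition strains into detected and undetected sets
#'
#' A strain is undetected iff its total count over all samples is zero;
#' strains with any read anywhere, however rare, are retained.
#'
#' @param counts Long count tibble (`sample_id`, `strain_id`, `count`).
#' @return List with `detected` and `removed` character vectors.
#' @export
filter_undetected <- function(counts) {
  check_columns(counts, c("strain_id", "count"), "counts")
  tot <- counts |>
    group_by(.data$strain_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  detected <- sort(tot$strain_id[tot$total > 0])
  removed <- sort(tot$strain_id[tot$total == 0])
  if (length(removed))
    inform(sprintf("%d strain(s) undetected in every sample removed: %s",
                   length(removed), paste(removed, collapse = ", ")))
  list(detected = detected, removed = removed)
}

#' Standardized recovery deviations of estimated EPC against simulation truth
#'
#' For simulated studies: compares each barcode group's mean EPC per host to
#' the realized per-replicate mixture proportions (the generator's truth),
#' standardized by the multinomial standard error at each sample's assigned
#' read depth. Under a correct pipeline the z values are approximately
#' standard normal.
#'
#' @param epc_summary Tibble from [summarize_replicates()].
#' @param counts Long count tibble (`sample_id`, `strain_id`, `count`).
#' @param mixtures A `truth_mixtures` tibble with per-sample proportions.
#' @param reference The `barcode_reference` used for assignment.
#' @param sample_sheet Tibble (`sample_id`, `host_genotype`).
#' @return Tibble (`host_genotype`, `strain_id`, `epc_mean`,
#'   `truth_mean_pct`, `sd_pct`, `z`).
#' @export
epc_recovery_deviations <- function(epc_summary, counts, mixtures, reference,
                                    sample_sheet) {
  members <- split(reference$membership$strain_id, reference$membership$allele_id)
  label_of <- vapply(members, function(m) paste(sort(m), collapse = "+"), character(1))
  assigned <- counts |>
    group_by(.data$sample_id) |>
    summarise(n_assigned = sum(.data$count), .groups = "drop")
  truth <- mixtures |>
    inner_join(tibble(strain_id = unlist(members),
                      group = rep(unname(label_of), lengths(members))),
               by = "strain_id") |>
    group_by(.data$sample_id, .data$group) |>
    summarise(p = sum(.data$proportion), .groups = "drop") |>
    inner_join(assigned, by = "sample_id") |>
    inner_join(sample_sheet |> distinct(.data$sample_id, .data$host_genotype),
               by = "sample_id") |>
    group_by(.data$host_genotype, .data$group) |>
    summarise(truth_mean_pct = 100 * mean(.data$p),
              sd_pct = 100 * sqrt(sum(.data$p * (1 - .data$p) / .data$n_assigned)) / n(),
              .groups = "drop")
  epc_summary |>
    inner_join(truth, by = c("host_genotype", "strain_id" = "group")) |>
    mutate(z = ifelse(.data$sd_pct > 0,
                      (.data$epc_mean - .data$truth_mean_pct) / .data$sd_pct, 0)) |>
    select("host_genotype", "strain_id", "epc_mean", "truth_mean_pct",
           "sd_pct", "z")
}

#' Hierarchically cluster hosts and strains by EPC profile
#'
#' Agglomerative clustering of the host-by-strain mean-EPC matrix along both
#' margins (default Euclidean distance, complete linkage). Leaf order is made
#' deterministic by sorting labels before clustering.
#'
#' @param epc_summary Tibble from [summarize_replicates()] (or any tibble
#'   with `host_genotype`, `strain_id`, `epc_mean`).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return Object of class `epc_clustering`: list with `host_hclust`,
#'   `strain_hclust`, the `matrix` (strains x hosts), and the method labels.
#' @export
cluster_profiles <- function(epc_summary, metric = "euclidean", linkage = "complete") {
  check_columns(epc_summary, c("host_genotype", "strain_id", "epc_mean"), "epc_summary")
  wide <- epc_summary |>
    select("host_genotype", "strain_id", "epc_mean") |>
    tidyr::pivot_wider(names_from = "host_genotype", values_from = "epc_mean")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$strain_id
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  if (anyNA(mat))
    abort("missing cells in the EPC matrix: rerun on complete conditions (no imputation)")
  if (nrow(mat) < 2 || ncol(mat) < 2) abort("need >= 2 strains and >= 2 hosts")
  structure(list(
    host_hclust = hclust(dist(t(mat), method = metric), method = linkage),
    strain_hclust = hclust(dist(mat, method = metric), method = linkage),
    matrix = mat, metric = metric, linkage = linkage
  ), class = "epc_clustering")
}

#' Cut the host dendrogram into k profile groups
#'
#' @param clustering An `epc_clustering`.
#' @param k Number of host groups.
#' @return Tibble (`host_genotype`, `group`).
#' @export
cut_host_groups <- function(clustering, k) {
  stopifnot(inherits(clustering, "epc_clustering"))
  cl <- cutree(clustering$host_hclust, k = k)
  tibble(host_genotype = names(cl), group = unname(cl))
}

#' Export the host and strain dendrograms as Newick strings
#'
#' @param clustering An `epc_clustering`.
#' @return Named character vector (`host`, `strain`) of Newick trees.
#' @export
dendrogram_newick <- function(clustering) {
  stopifnot(inherits(clustering, "epc_clustering"))
  c(host = ape::write.tree(ape::as.phylo(clustering$host_hclust)),
    strain = ape::write.tree(ape::as.phylo(clustering$strain_hclust)))
}

#' @export
print.epc_clustering <- function(x, ...) {
  cat(sprintf("<epc_clustering> %d strains x %d hosts (%s distance, %s linkage)\n",
              nrow(x$matrix), ncol(x$matrix), x$metric, x$linkage))
  invisible(x)
}
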