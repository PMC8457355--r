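# ggplot2 views of pipeline results.

#' Heatmap of EPC profiles ordered by the hierarchical clustering
#'
#' @param object An `epc_clustering`.
#' @param ... Unused.
#' @return A ggplot: strains x hosts tile plot, margins ordered by the
#'   dendrogram leaf orders.
#' @method autoplot epc_clustering
#' @export
autoplot.epc_clustering <- function(object, ...) {
  mat <- object$matrix
  strain_order <- rownames(mat)[object$strain_hclust$order]
  host_order <- colnames(mat)[object$host_hclust$order]
  df <- as_tibble(as.data.frame.table(mat, stringsAsFactors = FALSE)) |>
    setNames(c("strain_id", "host_genotype", "epc_mean")) |>
    mutate(strain_id = factor(.data$strain_id, levels = strain_order),
           host_genotype = factor(.data$host_genotype, levels = host_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$host_genotype, y = .data$strain_id,
                                   fill = .data$epc_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "EPC (%)") +
    ggplot2::labs(x = "Host genotype", y = "Strain",
                  title = sprintf("EPC profiles (%s distance, %s linkage)",
                                  object$metric, object$linkage)) +
    ggplot2::theme_minimal()
}

#' Replicate reliability view: CV% against mean EPC
#'
#' @param object An `epc_summary`.
#' @param cv_guide Horizontal reference line (default 50%).
#' @param ... Unused.
#' @return A ggplot of CV% versus mean EPC, log-scaled x.
#' @method autoplot epc_summary
#' @export
autoplot.epc_summary <- function(object, cv_guide = 50, ...) {
  df <- object |> filter(!is.na(.data$cv_percent), .data$epc_mean > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epc_mean, y = .data$cv_percent)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = cv_guide, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean EPC (%)", y = "CV (%)",
                  title = "Replicate reliability of EPC estimates") +
    ggplot2::theme_minimal()
}

#' Tidy an EPC summary into one row per strain x host assay
#'
#' @param x An `epc_summary`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy epc_summary
#' @export
tidy.epc_summary <- function(x, ...) as_tibble(x)

#' One-row overview of an EPC summary
#'
#' @param x An `epc_summary`.
#' @param cv_threshold CV% reliability threshold for the reported fraction.
#' @param ... Unused.
#' @return Tibble with assay counts, EPC range, and the fraction of assays
#'   with CV below `cv_threshold`.
#' @method glance epc_summary
#' @export
glance.epc_summary <- function(x, cv_threshold = 50, ...) {
  tibble(n_assays = nrow(x),
         n_strains = dplyr::n_distinct(x$strain_id),
         n_hosts = dplyr::n_distinct(x$host_genotype),
         epc_min = min(x$epc_mean), epc_max = max(x$epc_mean),
         frac_cv_below = mean(x$cv_percent < cv_threshold, na.rm = TRUE))
}
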