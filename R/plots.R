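# ggplot2 displays: correlation heatmap partitioned into factor blocks,
# leave-one-out delta grid, permutation-null histograms, and grouped
# correlate-coefficient bars.

#' Heatmap of a tetrachoric correlation matrix
#'
#' @param object A `tetra_result`.
#' @param model Optional `cfa_model`; when supplied, diagnoses are ordered by
#'   factor block ([heatmap_order()]) and block boundaries are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tetra_result <- function(object, model = NULL, ...) {
  R <- object$rho
  blocks <- NULL
  if (!is.null(model)) {
    ord <- heatmap_order(R, model)
    R <- R[ord$order, ord$order]
    blocks <- ord$blocks
  }
  df <- tibble::as_tibble(as.table(R), .name_repair = "minimal")
  names(df) <- c("row", "col", "rho")
  df$row <- factor(df$row, levels = rev(rownames(R)))
  df$col <- factor(df$col, levels = colnames(R))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
  if (!is.null(blocks)) {
    d <- nrow(R)
    p <- p +
      ggplot2::geom_vline(xintercept = blocks$end[-nrow(blocks)] + 0.5,
                          linewidth = 0.3) +
      ggplot2::geom_hline(yintercept = d - blocks$end[-nrow(blocks)] + 0.5,
                          linewidth = 0.3)
  }
  p
}

#' Dot plot of standardized loadings
#'
#' @param object A `cfa_fit`.
#' @param ... Unused.
#' @return A ggplot object; error bars show +/- 1 SE when SEs are attached.
#' @export
autoplot.cfa_fit <- function(object, ...) {
  td <- tidy.cfa_fit(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$loading,
                                        y = .data$indicator,
                                        colour = .data$primary)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = "standardized loading", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  if ("se" %in% names(td) && !all(is.na(td$se)))
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$loading - .data$se,
                   xmax = .data$loading + .data$se), height = 0.2)
  p
}

#' Histograms of permutation-null index distributions
#'
#' @param x A `null_result`.
#' @param indices Which indices to show.
#' @return A ggplot object with the observed value marked.
#' @export
plot_null <- function(x, indices = c("cfi", "rmsea", "srmr", "fl")) {
  stopifnot(inherits(x, "null_result"))
  long <- tidyr::pivot_longer(x$draws[x$draws$converged %in% TRUE, ],
                              dplyr::all_of(indices),
                              names_to = "index", values_to = "value")
  obs <- tidyr::pivot_longer(x$observed[indices], dplyr::all_of(indices),
                             names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        colour = "#B2182B", linewidth = 0.7) +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = NULL, y = "null models") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Heat grid of leave-one-out loading changes
#'
#' @param x A `loo_result`.
#' @return A ggplot object (rows: affected diagnosis, columns: removed
#'   diagnosis).
#' @export
plot_loo <- function(x) {
  stopifnot(inherits(x, "loo_result"))
  df <- tibble::as_tibble(as.table(x$delta), .name_repair = "minimal")
  names(df) <- c("affected", "removed", "delta")
  lim <- max(abs(df$delta), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$removed, y = .data$affected,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim), na.value = "grey90") +
    ggplot2::labs(x = "diagnosis removed", y = "loading affected",
                  fill = expression(Delta * lambda)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Grouped bar chart of correlate coefficients by dimension
#'
#' @param x A `correlate_reg`.
#' @return A ggplot object with +/- 1 SE error bars.
#' @export
plot_correlates <- function(x) {
  stopifnot(inherits(x, "correlate_reg"))
  df <- x$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$estimate,
                                   fill = .data$factor)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$se,
                                        ymax = .data$estimate + .data$se),
                           width = 0.3) +
    ggplot2::facet_wrap(~correlate, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "coefficient") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
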