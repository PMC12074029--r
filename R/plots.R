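# ggplot2 autoplot methods for the package's result types.

#' @method tidy edge_screen
#' @export
tidy.edge_screen <- function(x, ...) as_tibble(x)

#' @method glance edge_screen
#' @export
glance.edge_screen <- function(x, ...) {
  tibble(n_edges = nrow(x),
         n_significant = sum(x$selected_significance, na.rm = TRUE),
         n_effect = sum(x$selected_effect, na.rm = TRUE),
         n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
         alpha = attr(x, "config")$alpha,
         correction = attr(x, "config")$correction)
}

#' Plot methods
#'
#' `autoplot()` methods: connectivity-matrix heatmap (`fc_matrix`),
#' effect/significance volcano (`edge_screen`), NMI bar distribution
#' (`nmi_result`), power spectral density (`spectral_result`), Morlet
#' scalogram (`cwt_result`), and an axial t-map slice (`seed_tmap`).
#'
#' @param object The result object.
#' @param ... Unused.
#' @param slice Axial slice index for `seed_tmap` (default middle).
#' @return A ggplot.
#' @name fcscreen-autoplot
NULL

#' @rdname fcscreen-autoplot
#' @method autoplot fc_matrix
#' @export
autoplot.fc_matrix <- function(object, ...) {
  n <- nrow(object)
  rois <- rownames(object) %||% paste0("ROI", seq_len(n))
  df <- tidyr::expand_grid(roi_i = factor(rois, rois), roi_j = factor(rois, rois))
  df$value <- as.numeric(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_j, .data$roi_i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  name = fc_domain(object)) +
    ggplot2::scale_y_discrete(limits = rev(rois)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname fcscreen-autoplot
#' @method autoplot edge_screen
#' @export
autoplot.edge_screen <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- as_tibble(object)
  df$set <- dplyr::case_when(
    df$selected_significance & df$selected_effect ~ "both",
    df$selected_significance ~ "significant",
    df$selected_effect ~ "large effect",
    TRUE ~ "neither")
  ggplot2::ggplot(df, ggplot2::aes(.data$d, -log10(.data$p_adj), colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cfg$d_threshold, linetype = 2) +
    ggplot2::labs(x = "Cohen's D (A - B)", y = expression(-log[10]~p[adj])) +
    ggplot2::theme_minimal()
}

#' @rdname fcscreen-autoplot
#' @method autoplot nmi_result
#' @export
autoplot.nmi_result <- function(object, ...) {
  df <- tidy(object)
  df$roi <- factor(df$roi, df$roi[order(df$rank, decreasing = TRUE)])
  ggplot2::ggplot(df, ggplot2::aes(.data$nmi, .data$roi, fill = .data$nmi > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "#2166AC")) +
    ggplot2::labs(x = "Node Modulation Index", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname fcscreen-autoplot
#' @method autoplot spectral_result
#' @export
autoplot.spectral_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$frequency, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD~(units^2/Hz))) +
    ggplot2::theme_minimal()
}

#' @rdname fcscreen-autoplot
#' @method autoplot cwt_result
#' @export
autoplot.cwt_result <- function(object, ...) {
  df <- tidyr::expand_grid(f = object$freqs,
                           t = (seq_len(ncol(object$magnitude)) - 1) / object$fs)
  df <- df[order(df$f, df$t), ]
  df$mag <- as.numeric(t(object$magnitude))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$f, fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|W|") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @rdname fcscreen-autoplot
#' @method autoplot seed_tmap
#' @export
autoplot.seed_tmap <- function(object, slice = NULL, ...) {
  d <- dim(object$t)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df <- df[order(df$y, df$x), ]
  df$t <- as.numeric(object$t[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", high = "#B2182B", name = "t") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("axial slice %d", slice)) +
    ggplot2::theme_minimal()
}
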