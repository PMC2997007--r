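#' Plot expression time profiles
#'
#' Line plot of per-gene log2 treatment:LPS profiles, faceted by treatment
#' (and by mode when a mode assignment is joined in).
#'
#' @param object A `phyto_profiles` tibble from [build_profiles()].
#' @param modes Optional mode assignment from [classify_modes()]; when
#'   given, panels are split by regulation mode.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phyto_profiles <- function(object, modes = NULL, alpha = 0.4, ...) {
  df <- as_tibble(object)
  if (!is.null(modes)) {
    df <- left_join(df, modes, by = c("gene_symbol", "treatment"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_h, y = .data$log2_ratio,
    group = .data$gene_symbol)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "time (h)", y = "log2 ratio (treatment : LPS)") +
    ggplot2::theme_bw()
  if (is.null(modes)) {
    p + ggplot2::facet_wrap(~treatment)
  } else {
    p + ggplot2::facet_grid(mode ~ treatment)
  }
}

#' Dendrogram plot of a UPGMA linkage
#'
#' @param object An object from [upgma()].
#' @param ... Unused.
#' @return A ggplot object drawing the ultrametric dendrogram with leaves
#'   in the deterministic display order.
#' @export
autoplot.upgma <- function(object, ...) {
  n <- length(object$labels)
  leaf_x <- setNames(seq_len(n), object$order)
  x_of <- numeric(nrow(object$merge))
  h_of <- function(k) if (k < 0) 0 else object$height[k] / 2
  pos_of <- function(k) if (k < 0) leaf_x[[as.character(-k)]] else x_of[k]
  segs <- purrr::map_dfr(seq_len(nrow(object$merge)), function(s) {
    a <- object$merge[s, 1]
    b <- object$merge[s, 2]
    h <- object$height[s] / 2
    xa <- pos_of(a)
    xb <- pos_of(b)
    x_of[s] <<- (xa + xb) / 2
    tibble(x = c(xa, xb, min(xa, xb)),
           xend = c(xa, xb, max(xa, xb)),
           y = c(h_of(a), h_of(b), h),
           yend = c(h, h, h))
  })
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = leaf_order(object)) +
    ggplot2::labs(x = NULL, y = "cophenetic height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Bar chart of mode concordance against the reference treatment
#'
#' @param conc Output of [concordance_table()].
#' @return A ggplot object.
#' @export
plot_concordance <- function(conc) {
  ggplot2::ggplot(conc, ggplot2::aes(x = .data$other_treatment,
                                     y = .data$percent_same)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    .data$percent_same)),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~mode_group) +
    ggplot2::labs(x = NULL,
                  y = "% genes in the reference treatment's mode") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_bw()
}

#' Heat map of a hit table
#'
#' log2-scaled tile map of the treatment ratio columns of a fold-change
#' hit table (or any wide ratio table), rows ordered by UPGMA leaf order.
#'
#' @param tbl Wide ratio table with `gene_symbol` and one numeric column
#'   per treatment.
#' @param treatments Ratio columns to draw; defaults to all numeric
#'   columns except `gene_id` and `time_h`.
#' @return A ggplot object.
#' @export
plot_hit_heatmap <- function(tbl, treatments = NULL) {
  if (is.null(treatments)) {
    num <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
    treatments <- setdiff(num, c("gene_id", "time_h"))
  }
  mat <- tbl[c("gene_symbol", treatments)]
  ord <- if (nrow(mat) > 2) {
    leaf_order(upgma(profile_dist(mat, values = "linear")))
  } else mat$gene_symbol
  long <- tidyr::pivot_longer(mat, -"gene_symbol",
                              names_to = "treatment", values_to = "ratio")
  long$gene_symbol <- factor(long$gene_symbol, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment,
                                     y = .data$gene_symbol,
                                     fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green3", mid = "black",
                                  high = "red", name = "log2 ratio") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
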