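# broom-style methods and plotting for result objects.

#' Tidy a QTL scan
#'
#' @param x a `qtl_scan`.
#' @param ... unused.
#' @return the per-position profile tibble (pos, lod, pvar, class means and
#'   SEs).
#' @export
tidy.qtl_scan <- function(x, ...) x$profile

#' One-row summary of a QTL scan
#'
#' @param x a `qtl_scan`.
#' @param ... unused.
#' @return the peak row: position, LOD, %variance, class means/SEs, one-
#'   and two-LOD support intervals, nearest marker, key parent.
#' @export
glance.qtl_scan <- function(x, ...) x$peak

#' @export
print.qtl_scan <- function(x, ...) {
  p <- x$peak
  cat("<qtl_scan> ", x$lg, ": peak LOD ", round(p$lod, 2), " at ",
      p$pos, " cM (", round(p$pvar, 1), "% variance, key parent ",
      p$key_parent, ")\n", sep = "")
  cat("  1-LOD support [", p$lower1, ", ", p$upper1, "] cM; 2-LOD [",
      p$lower2, ", ", p$upper2, "] cM; nearest marker ",
      p$nearest_marker, "\n", sep = "")
  invisible(x)
}

#' Tidy an MDS map
#'
#' @param x an `mds_map`.
#' @param ... unused.
#' @return tibble (marker, pos).
#' @export
tidy.mds_map <- function(x, ...) x$map

#' One-row summary of an MDS map
#'
#' @param x an `mds_map`.
#' @param ... unused.
#' @export
glance.mds_map <- function(x, ...) {
  tibble(n_markers = nrow(x$map), length_cm = max(x$map$pos),
         stress = x$stress, nnfit = x$nnfit, weighting = x$weighting,
         dims = x$dims, n_outliers = length(x$outliers))
}

#' Plot a LOD profile
#'
#' @param object a `qtl_scan`.
#' @param threshold optional genome-wide LOD threshold to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak$pos, linetype = "dotted") +
    ggplot2::annotate("segment",
                      x = object$peak$lower1, xend = object$peak$upper1,
                      y = object$peak$lod - 1, yend = object$peak$lod - 1) +
    ggplot2::labs(x = "Position (cM)", y = "LOD",
                  title = paste0("QTL scan, ", object$lg)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  p
}

#' Plot a linkage map
#'
#' @param object an `mds_map`.
#' @param ... unused.
#' @return a ggplot with marker positions as rug ticks.
#' @export
autoplot.mds_map <- function(object, ...) {
  ggplot2::ggplot(object$map, ggplot2::aes(x = 1, y = .data$pos)) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(y = "Position (cM)", x = NULL,
                  title = paste0("Linkage map (", object$weighting, ", ",
                                 object$dims, "-d)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Side-by-side comparison of two marker orders
#'
#' @param map1,map2 tibbles (marker, pos); shared markers are connected.
#' @param labels panel labels.
#' @return a ggplot.
#' @export
plot_order_comparison <- function(map1, map2, labels = c("order 1", "order 2")) {
  shared <- intersect(map1$marker, map2$marker)
  df <- tibble(marker = shared,
               pos1 = map1$pos[match(shared, map1$marker)],
               pos2 = map2$pos[match(shared, map2$marker)])
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = 2, y = .data$pos1,
                                       yend = .data$pos2), alpha = 0.4) +
    ggplot2::scale_x_continuous(breaks = c(1, 2), labels = labels,
                                limits = c(0.8, 2.2)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Position (cM)") +
    ggplot2::theme_minimal()
}
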