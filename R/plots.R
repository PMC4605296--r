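#' Plot a fragment-length histogram
#'
#' @param object A [length_histogram()] result.
#' @param ... Unused.
#' @return A ggplot: counts per fragment length with the modal length marked.
#' @method autoplot nuc_length_hist
#' @export
autoplot.nuc_length_hist <- function(object, ...) {
  modal <- attr(object, "modal_length")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = modal, linetype = "dashed") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  title = sprintf("Protected fragment sizes (mode %s bp)", modal)) +
    ggplot2::theme_minimal()
}

#' Plot an occupancy track
#'
#' @param object An `occ_track`.
#' @param region Optional `c(start, end)` 0-based window to display.
#' @param ... Unused.
#' @return A ggplot of signal versus position.
#' @method autoplot occ_track
#' @export
autoplot.occ_track <- function(object, region = NULL, ...) {
  df <- tidy(object)
  if (!is.null(region)) df <- df[df$pos >= region[1] & df$pos < region[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = sprintf("%s position (bp)", object$chrom),
                  y = sprintf("%s occupancy", object$kind)) +
    ggplot2::theme_minimal()
}

#' Plot an NDR size distribution
#'
#' @param object An `ndr_size_dist`.
#' @param highlight Optional numeric sizes to mark as points on the curve
#'   (e.g. the NDRs of a locus of interest against the genome-wide curve).
#' @param ... Unused.
#' @return A ggplot of the size density on a log x axis.
#' @method autoplot ndr_size_dist
#' @export
autoplot.ndr_size_dist <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(object$density,
                       ggplot2::aes(x = .data$size, y = .data$density)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "internucleosomal distance (bp)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hd <- tibble(size = highlight,
                 density = vapply(highlight, function(s) {
                   mean(dnorm(s, mean = as.numeric(object$sizes), sd = object$bw))
                 }, numeric(1)))
    p <- p + ggplot2::geom_point(data = hd, size = 2)
  }
  p
}

#' Plot a meta-occupancy profile
#'
#' @param object A [meta_occupancy()] result.
#' @param ... Unused.
#' @return A ggplot of mean occupancy versus offset from the site center.
#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$mean_occ)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "offset from site center (bp)",
                  y = sprintf("mean occupancy (%s, n=%d sites)",
                              attr(object, "normalization"), attr(object, "n_sites"))) +
    ggplot2::theme_minimal()
}

#' Plot a nucleotide composition track
#'
#' @param object A [nucleotide_composition()] result.
#' @param ... Unused.
#' @return A ggplot with one line per base.
#' @method autoplot composition_track
#' @export
autoplot.composition_track <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"pos",
                            names_to = "base", values_to = "fraction")
  df$base <- sub("^f", "", df$base)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$fraction,
                                   colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window center (bp)",
                  y = sprintf("base fraction (%d bp windows)", attr(object, "window"))) +
    ggplot2::theme_minimal()
}
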