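#' Tidy an accuracy report
#'
#' One row per replicate with insertion counts and percent accuracy.
#'
#' @param x an `insertion_accuracy` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.insertion_accuracy <- function(x, ...) {
  x$per_replicate
}

#' One-row summary of an accuracy report
#'
#' @param x an `insertion_accuracy` object.
#' @param ... unused.
#' @return a tibble with `mean_accuracy`, `sd_accuracy`, `n_replicates`.
#' @export
glance.insertion_accuracy <- function(x, ...) {
  x$summary
}

#' Plot per-replicate assembly accuracy
#'
#' @param object an `insertion_accuracy` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.insertion_accuracy <- function(object, ...) {
  per <- object$per_replicate
  ggplot2::ggplot(per, ggplot2::aes(x = factor(.data$replicate),
                                    y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$summary$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "replicate", y = "accuracy (%)",
                  title = sprintf("insertion assembly accuracy: %.2f%% +/- %.2f%%",
                                  object$summary$mean_accuracy,
                                  object$summary$sd_accuracy)) +
    ggplot2::ylim(0, 100)
}

#' Plot a depth-of-coverage profile
#'
#' Depth per reference position with the covered-genome mean overlaid;
#' over-coverage regions (copied-insertion sources) stand out at multiples
#' of the mean.
#'
#' @param object a `coverage_profile`.
#' @param bin bin width in bp for display averaging.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.coverage_profile <- function(object, bin = 100L, ...) {
  d <- object$depth
  nb <- ceiling(length(d) / bin)
  grp <- rep(seq_len(nb), each = bin)[seq_along(d)]
  df <- tibble::tibble(pos = (seq_len(nb) - 0.5) * bin,
                       depth = as.numeric(tapply(d, grp, mean)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = object$mu_doc, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "reference position (bp)", y = "depth",
                  title = sprintf("mean depth over covered positions: %.1fX",
                                  object$mu_doc))
}
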