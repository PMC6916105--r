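#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.substitution_of <- function(channel) substr(channel, 3, 5)

.sbs_palette <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
                  "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")

#' Plot an SBS96 spectrum
#'
#' Standard 96-channel bar chart, one facet per substitution type.
#'
#' @param object An `sbs_spectrum`.
#' @param title Plot title.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sbs_spectrum <- function(object, title = NULL, ...) {
  df <- tibble::tibble(
    channel = factor(names(object$proportions), levels = sbs96_channels()),
    substitution = .substitution_of(names(object$proportions)),
    proportion = as.numeric(object$proportions)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$proportion,
                                   fill = .data$substitution)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::scale_fill_manual(values = .sbs_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "proportion", title = title,
                  subtitle = sprintf("n = %d", object$n)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot fitted signature weights
#'
#' @param object A `signature_fit`.
#' @param title Plot title.
#' @param artifacts Optional artifact names, highlighted in dark red.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_fit <- function(object, title = NULL, artifacts = NULL, ...) {
  df <- tidy(object)
  df$role <- ifelse(df$signature %in% (artifacts %||% character(0)),
                    "artifact", "biological")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$signature,
                                                      .data$weight),
                                   y = .data$weight, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(artifact = "#8B1A1A",
                                          biological = "#2E7D32")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weight", title = title,
                  subtitle = sprintf("cosine = %.3f, n = %d",
                                     object$cosine, object$n)) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot the optimization trace
#'
#' Best-so-far and generation-mean objective per generation.
#'
#' @param object A `refinement`.
#' @param ... Unused.
#' @return A ggplot (or `NULL` for a skipped run).
#' @export
autoplot.refinement <- function(object, ...) {
  if (is.null(object$trace)) return(NULL)
  df <- tidyr::pivot_longer(object$trace[, c("generation", "best", "mean")],
                            c("best", "mean"), names_to = "series",
                            values_to = "objective")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$objective,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "objective",
                  title = "Genetic-algorithm objective trace") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot a motif profile
#'
#' Base frequency by position relative to the variant site.
#'
#' @param profile A `motif_profile`.
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_motif_profile <- function(profile, title = NULL) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$frequency,
                                        color = .data$base)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(values = c(A = "#4CAF50", C = "#2196F3",
                                           G = "#FF9800", T = "#F44336")) +
    ggplot2::labs(x = "position relative to variant", y = "base frequency",
                  title = title) +
    ggplot2::theme_minimal(base_size = 10)
}
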