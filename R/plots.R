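# ggplot2 graphics for fits and scan results.

#' Plot posterior summaries of a fitted TRD model
#'
#' Marginal posterior densities of every parameter, faceted, with the null
#' value marked -- the visual counterpart of the Savage-Dickey Bayes factor.
#'
#' @param object An `epitrd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epitrd_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$chain$draws) |>
    dplyr::mutate(.iter = dplyr::row_number()) |>
    tidyr::pivot_longer(-".iter", names_to = "term", values_to = "value") |>
    dplyr::mutate(term = factor(.data$term, levels = object$params))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", color = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "firebrick") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(
      x = "parameter value", y = "posterior density",
      title = sprintf(
        "%s TRD model: %s x %s", object$model,
        object$snpA, object$snpB
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a TRD scan result
#'
#' Maximum epistatic log10 Bayes factor per pair against the pair index,
#' colored by effect category, with selected pairs highlighted.
#'
#' @param object A tibble returned by [trd_scan()] / [trd_scan_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_scan <- function(object, ...) {
  d <- object |>
    dplyr::filter(!is.na(.data$max_epi_bf)) |>
    dplyr::mutate(pair_index = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$pair_index, y = .data$max_epi_bf,
    color = .data$category, shape = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "SNP pair", y = "max epistatic log10 BF",
      color = "effect category", shape = "selected"
    ) +
    ggplot2::theme_minimal()
}
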