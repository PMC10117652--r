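# broom-style accessors for fitted TRD models.

#' Tidy a fitted TRD model
#'
#' One row per model parameter with posterior summaries.
#'
#' @param x An `epitrd_fit` from [fit_pair()] or [fit_simplified()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `cv` (SD / |mean|, `NA` when the mean is zero) and
#'   `log10_bf` (Savage-Dickey Bayes factor against the point null).
#' @export
tidy.epitrd_fit <- function(x, ...) {
  tibble::tibble(
    term = x$params,
    estimate = unname(x$estimate),
    std.error = unname(x$sd),
    cv = unname(x$cv),
    log10_bf = unname(x$log10_bf)
  )
}

#' Glance at a fitted TRD model
#'
#' @param x An `epitrd_fit`.
#' @param ... Unused.
#' @return One-row tibble with `model`, `log10_lr`, `dic`,
#'   `acceptance_rate`, `n_kept` and `n_informative_offspring`.
#' @export
glance.epitrd_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    log10_lr = x$log10_lr,
    dic = x$dic,
    acceptance_rate = x$acceptance_rate,
    n_kept = x$n_kept,
    n_informative_offspring = x$n_informative_offspring
  )
}
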