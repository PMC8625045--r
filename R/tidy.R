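#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for reconstruction results
#'
#' `tidy()` returns the per-iteration objective trace; `glance()` a
#' one-row summary of the final iterate.
#'
#' @param x A `recon_result` from [forward_backward_solve()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy recon_result
#' @export
tidy.recon_result <- function(x, ...) x$trace

#' @rdname tidy.recon_result
#' @method glance recon_result
#' @export
glance.recon_result <- function(x, ...) {
  tibble::tibble(
    niter = nrow(x$trace) - 1L,
    objective = x$trace$objective[nrow(x$trace)],
    fidelity = x$fidelity,
    regularizer = x$regularizer,
    alpha = x$config$alpha,
    s = x$config$s
  )
}

#' @rdname tidy.recon_result
#' @param object A `recon_result`.
#' @method autoplot recon_result
#' @export
autoplot.recon_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iter, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "iteration", y = "NETT objective",
      title = "Forward-backward objective trace"
    )
}

#' Tidiers for reconstruction studies
#'
#' `tidy()` returns the full per-phantom table; `glance()` the mean MSE
#' per noise level and method; `autoplot()` plots mean MSE against noise
#' level per method on a log scale.
#'
#' @param x,object A `study_report` from [reconstruction_study()].
#' @param ... Unused.
#' @return A tibble (or a ggplot for `autoplot()`).
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) x$table

#' @rdname tidy.study_report
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$table, .data$sigma, .data$method),
    mean_mse = mean(.data$mse),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' @rdname tidy.study_report
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(
    g,
    ggplot2::aes(
      x = .data$sigma, y = .data$mean_mse,
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "relative noise level", y = "mean MSE",
      title = "Reconstruction error by method and noise level"
    )
}

#' Tidiers for convergence-rate experiments
#'
#' `tidy()` returns the (eps, Bregman distance) table; `glance()` the
#' fitted log-log slope; `autoplot()` the log-log scatter with the fit.
#'
#' @param x,object A `rates_result` from [rates_experiment()].
#' @param ... Unused.
#' @return A tibble (or a ggplot for `autoplot()`).
#' @method tidy rates_result
#' @export
tidy.rates_result <- function(x, ...) x$table

#' @rdname tidy.rates_result
#' @method glance rates_result
#' @export
glance.rates_result <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_eps = length(x$config$eps), n_rep = x$config$n_rep,
    solution = x$config$solution
  )
}

#' @rdname tidy.rates_result
#' @method autoplot rates_result
#' @export
autoplot.rates_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$eps, y = .data$bregman)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "noise norm", y = "absolute Bregman distance",
      title = sprintf("Convergence rate (fitted slope %.2f)", object$slope)
    )
}

#' @importFrom rlang .data
NULL
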