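#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ICC result
#'
#' @param x an `icc_result`.
#' @param ... unused.
#' @return one-row tibble: `estimate`, `ci_low`, `ci_high`, `label`.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_low = x$ci_low,
                 ci_high = x$ci_high, label = x$label)
}

#' @rdname tidy.icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 k_measurements = x$k_measurements, model = x$model,
                 alpha = x$alpha)
}

#' Tidy a prediction band
#'
#' @param x a `prediction_band`.
#' @param ... unused.
#' @return tibble of coefficients (term, estimate).
#' @export
tidy.prediction_band <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "age"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.prediction_band
#' @export
glance.prediction_band <- function(x, ...) {
  tibble::tibble(residual_sd = x$residual_sd, n = x$n, level = x$level,
                 mean_x = x$mean_x, sxx = x$sxx)
}
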