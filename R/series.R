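#' Convert a beat series to log heart rate
#'
#' The model works on \eqn{X_t = \log} HR.  RR intervals (seconds) are
#' first converted to instantaneous heart rate, HR = 60/RR (bpm).  The
#' natural logarithm is used throughout, which makes the log transform
#' and the \eqn{e^{-Y^2}} restoring kernel symmetric.
#'
#' @param values numeric vector of strictly positive beat values.
#' @param kind `"rr_seconds"` for RR intervals or `"hr_bpm"` for heart rate.
#' @return An object of class `hr_series` with components `raw`, `kind`,
#'   `x` (log-HR values) and `n`.
#' @examples
#' to_log_hr(c(1, 0.9, 1.1), "rr_seconds")$x
#' @export
to_log_hr <- function(values, kind = c("rr_seconds", "hr_bpm")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), length(values) >= 1L)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("nonpositive or non-finite beat value at index ", bad[1L],
         call. = FALSE)
  hr <- if (kind == "rr_seconds") 60 / values else values
  structure(list(raw = values, kind = kind, x = log(hr),
                 n = length(values)),
            class = "hr_series")
}

#' Remove the linear trend from a log-HR series
#'
#' Fits the OLS regression line \eqn{X_t = a + b t + u_t} over
#' \eqn{t = 1, \dots, n} and returns the residual series
#' \eqn{Y_t = X_t - \hat a - \hat b t}, the heart-rate-variability
#' component the model is estimated on.  The slope \eqn{\hat b}
#' estimates \eqn{\eta_1 = \omega/\alpha}.
#'
#' @param x an `hr_series` object or a numeric log-HR vector.
#' @return A list of class `trend_fit` with `a_hat`, `b_hat` and the
#'   detrended series `y`.
#' @export
detrend <- function(x) {
  if (inherits(x, "hr_series")) x <- x$x
  stopifnot(is.numeric(x), length(x) >= 3L)
  t <- seq_along(x)
  fit <- lm.fit(cbind(intercept = 1, t = t), x)
  structure(list(a_hat = unname(fit$coefficients[1L]),
                 b_hat = unname(fit$coefficients[2L]),
                 y = unname(fit$residuals)),
            class = "trend_fit")
}
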