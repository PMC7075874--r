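#' Group-level parameter summaries
#'
#' Pools per-window parameter estimates across the \eqn{p} sample
#' periods and \eqn{q} subjects of a group and reports
#' \deqn{\bar\phi = (pq)^{-1} \sum_{i}\sum_{j} \hat\phi_{ij}, \qquad
#'  sd(\phi) = \sqrt{(pq - 1)^{-1} \sum_i \sum_j
#'   (\hat\phi_{ij} - \bar\phi)^2}.}
#'
#' @param estimates a numeric matrix (periods x subjects) of estimates
#'   for one parameter, or a data.frame whose columns are parameters and
#'   whose rows are period-subject combinations.
#' @param group optional group label stored on the result.
#' @return A `data.frame` of class `nlari_group` with columns
#'   `parameter`, `mean`, `sd`, `n`.
#' @examples
#' group_assessment(matrix(c(1, 3), nrow = 1))  # mean 2, sd sqrt(2)
#' @export
group_assessment <- function(estimates, group = NULL) {
  if (is.matrix(estimates)) {
    estimates <- data.frame(phi = as.vector(estimates))
  }
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L)
  vals <- lapply(estimates, function(v) v[!is.na(v)])
  if (any(lengths(vals) < 2L))
    stop("need at least 2 estimates (pq >= 2) per parameter", call. = FALSE)
  out <- data.frame(parameter = names(vals),
                    mean = vapply(vals, mean, numeric(1)),
                    sd = vapply(vals, sd, numeric(1)),
                    n = lengths(vals), row.names = NULL)
  attr(out, "group") <- group
  class(out) <- c("nlari_group", "data.frame")
  out
}

#' Multiplicative risk predictor for sudden cardiac death
#'
#' Combines three risk factors relative to control standards
#' \eqn{(\alpha_c, \sigma_c, \gamma_c)} (typically healthy-young group
#' means): elevated myocardial electrical resistance
#' (\eqn{\alpha/\alpha_c}), elevated variability of the myocardial
#' metabolic rate (\eqn{\sigma/\sigma_c}), and deviation of the HRV
#' stability coefficient in either direction from the control value:
#' \deqn{\rho = \frac{\alpha}{\alpha_c}\frac{\sigma}{\sigma_c}
#'  \times \begin{cases}\gamma_c/\gamma & \gamma \le \gamma_c\\
#'  \gamma/\gamma_c & \gamma > \gamma_c\end{cases}}
#'
#' @param inputs named vector or list with `alpha`, `sigma`, `gamma`
#'   for the assessed subject or group; all `> 0`.
#' @param controls same three values for the control standard.
#' @return A list of class `nlari_risk` with `rho`, the `branch`
#'   (`"low"` if `gamma <= gamma_c`), and the inputs.
#' @examples
#' scd_risk(c(alpha = 1, sigma = 1, gamma = 0.5),
#'          c(alpha = 1, sigma = 1, gamma = 0.25))$rho  # 2
#' @export
scd_risk <- function(inputs, controls) {
  g <- function(x, nm) {
    v <- x[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a positive finite number", call. = FALSE)
    v
  }
  a <- g(inputs, "alpha"); s <- g(inputs, "sigma"); gm <- g(inputs, "gamma")
  ac <- g(controls, "alpha"); sc <- g(controls, "sigma"); gc <- g(controls, "gamma")
  branch <- if (gm <= gc) "low" else "high"
  rho <- (a / ac) * (s / sc) * if (branch == "low") gc / gm else gm / gc
  structure(list(rho = rho, branch = branch,
                 inputs = c(alpha = a, sigma = s, gamma = gm),
                 controls = c(alpha = ac, sigma = sc, gamma = gc)),
            class = "nlari_risk")
}

#' @export
print.nlari_risk <- function(x, ...) {
  cat(sprintf("SCD risk predictor rho = %.4g (%s-gamma branch)\n",
              x$rho, x$branch))
  invisible(x)
}

#' Compare a group's parameters with a control group
#'
#' Per-parameter ratio of group means against the control group, with
#' qualitative direction labels at configurable thresholds: a ratio at
#' or above `thresholds[1]` is an increase, at or above `thresholds[2]`
#' an ultraincrease (reciprocals for decreases).
#'
#' @param group,control `nlari_group` summaries sharing a parameter set.
#' @param thresholds ratio cut-offs, default `c(1.25, 2)`.
#' @return A `data.frame` with `parameter`, group and control means,
#'   `ratio` and `alteration` label.
#' @export
compare_to_control <- function(group, control, thresholds = c(1.25, 2)) {
  stopifnot(inherits(group, "nlari_group"), inherits(control, "nlari_group"),
            length(thresholds) == 2L, thresholds[1L] > 1,
            thresholds[2L] > thresholds[1L])
  m <- merge(as.data.frame(group)[, c("parameter", "mean")],
             as.data.frame(control)[, c("parameter", "mean")],
             by = "parameter", suffixes = c("_group", "_control"))
  if (nrow(m) != nrow(group))
    stop("group and control must share the same parameter set", call. = FALSE)
  ratio <- m$mean_group / m$mean_control
  label <- ifelse(ratio >= thresholds[2L], "ultraincrease",
           ifelse(ratio >= thresholds[1L], "increase",
           ifelse(ratio <= 1 / thresholds[2L], "ultradecrease",
           ifelse(ratio <= 1 / thresholds[1L], "decrease", "unchanged"))))
  data.frame(parameter = m$parameter, mean_group = m$mean_group,
             mean_control = m$mean_control, ratio = ratio,
             alteration = label, row.names = NULL)
}
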