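#' Typical sampling variance
#'
#' Representative ("typical") within-study sampling variance used in the
#' multilevel I-squared: with weights \eqn{w_i = 1/v_i},
#' \deqn{\tilde v = (k-1) \sum w_i / ((\sum w_i)^2 - \sum w_i^2).}
#' An arithmetic-mean alternative (\code{sum(v)/k}) is available for
#' sensitivity checks.
#'
#' @param v sampling variances, all positive, length >= 2.
#' @param method \code{"higgins"} (default) or \code{"mean"}.
#' @return scalar typical sampling variance.
#' @export
#' @examples
#' typical_sampling_variance(c(0.5, 0.5, 0.5)) # 0.5
typical_sampling_variance <- function(v, method = c("higgins", "mean")) {
  method <- match.arg(method)
  k <- length(v)
  if (k < 2L) stop("need at least 2 sampling variances", call. = FALSE)
  if (any(v <= 0)) stop("sampling variances must be > 0", call. = FALSE)
  if (method == "mean") return(sum(v) / k)
  w <- 1 / v
  (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Multilevel I-squared and typical sampling variance
#'
#' Share of total variability attributable to heterogeneity rather than
#' sampling error, partitioned across random levels:
#' \deqn{I^2_l = 100 \sigma^2_l / (\sum_m \sigma^2_m + \tilde v)} and
#' \eqn{I^2_{total} = \sum_l I^2_l}. The typical sampling variance
#' \eqn{\tilde v} is computed from the sampling-variance diagonal only.
#'
#' @param fit fitted [mlma()] model.
#' @param typical method passed to [typical_sampling_variance()], or a
#'   numeric value to use directly.
#' @return list with \code{typical_v}, \code{i2_by_level} (named, %),
#'   \code{i2_total} (%).
#' @export
heterogeneity <- function(fit, typical = "higgins") {
  stopifnot(inherits(fit, "mlma"))
  tv <- if (is.numeric(typical)) typical
        else typical_sampling_variance(diag(fit$Vs), typical)
  s2 <- fit$sigma2
  denom <- sum(s2) + tv
  i2 <- if (denom > 0) 100 * s2 / denom else s2 * 0
  list(typical_v = tv, i2_by_level = i2, i2_total = sum(i2))
}

#' Marginal R-squared of a moderator model
#'
#' Percentage of heterogeneity explained by the fixed effects:
#' \deqn{R^2 = 100 \sigma^2_{fixed} / (\sigma^2_{fixed} + \sum_l
#' \sigma^2_l)} where \eqn{\sigma^2_{fixed}} is the variance of the
#' fitted values across effect sizes, clipped to [0, 100]. An
#' intercept-only model has constant fitted values and returns 0.
#'
#' @param fit fitted moderator model.
#' @param null_fit optional null model fitted to the same data; when
#'   supplied, a mismatch in effect count is an error.
#' @return percentage in [0, 100].
#' @export
r2_marginal <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "mlma"))
  if (!is.null(null_fit) && null_fit$k != fit$k)
    stop("null and moderator fits use different data", call. = FALSE)
  sf <- stats::var(fit$fitted.values - fit$offset) *
    (fit$k - 1) / fit$k   # population variance of X beta-hat
  r2 <- 100 * sf / (sf + sum(fit$sigma2))
  if (!is.finite(r2)) r2 <- 0
  min(max(r2, 0), 100)
}
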