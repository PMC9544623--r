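#' @export
print.mlma <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic model (", x$method, ")\n", sep = "")
  cat("k =", x$k, "effect sizes;", x$p, "fixed coefficient(s)\n")
  if (length(x$sigma2)) {
    cat("\nVariance components:\n")
    print(round(x$sigma2, digits))
  } else cat("\nNo random effects (GLS fit)\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nlogLik:", format(x$logLik, digits = digits + 2), "\n")
  invisible(x)
}

#' Wald-type coefficient summary
#'
#' Per-coefficient estimate, standard error, z statistic, two-sided
#' normal p-value and Wald confidence interval
#' (estimate +/- z_(1-alpha/2) * SE).
#'
#' @param object fitted [mlma()] model.
#' @param level coverage probability of the confidence intervals.
#' @param df optional degrees of freedom; when given, t quantiles and
#'   p-values are used instead of normal ones.
#' @param ... unused.
#' @return object of class \code{"summary.mlma"} whose \code{$coefficients}
#'   is a data.frame with columns estimate, se, zval, pval, ci.lb, ci.ub.
#' @export
summary.mlma <- function(object, level = 0.95, df = NULL, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  zval <- est / se
  if (is.null(df)) {
    crit <- stats::qnorm(1 - (1 - level) / 2)
    pval <- 2 * stats::pnorm(-abs(zval))
  } else {
    crit <- stats::qt(1 - (1 - level) / 2, df)
    pval <- 2 * stats::pt(-abs(zval), df)
  }
  tab <- data.frame(estimate = est, se = se, zval = zval, pval = pval,
                    ci.lb = est - crit * se, ci.ub = est + crit * se)
  out <- list(coefficients = tab, sigma2 = object$sigma2,
              logLik = object$logLik, method = object$method,
              k = object$k, level = level)
  class(out) <- "summary.mlma"
  out
}

#' @export
print.summary.mlma <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic model (", x$method, "), k = ", x$k,
      "\n\n", sep = "")
  if (length(x$sigma2)) {
    cat("Variance components:\n")
    print(round(x$sigma2, digits))
    cat("\n")
  }
  tab <- x$coefficients
  printCoefmat(as.matrix(tab[, c("estimate", "se", "zval", "pval")]),
               digits = digits, cs.ind = 1:2, tst.ind = 3,
               P.values = TRUE, has.Pvalue = TRUE)
  ci <- round(tab[, c("ci.lb", "ci.ub")], digits)
  cat("\n", format(100 * x$level), "% CI:\n", sep = "")
  print(ci)
  invisible(x)
}

#' @export
coef.mlma <- function(object, ...) object$coefficients

#' @export
vcov.mlma <- function(object, ...) object$vcov

#' @export
logLik.mlma <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- object$p + length(object$sigma2)
  attr(val, "nobs") <- object$k
  class(val) <- "logLik"
  val
}

#' @export
fitted.mlma <- function(object, ...) object$fitted.values

#' @export
residuals.mlma <- function(object, ...) object$residuals

#' Model-based predictions with confidence and prediction intervals
#'
#' For each (unique) moderator combination, returns the estimated mean
#' effect, its Wald confidence interval, and the prediction interval for
#' the effect expected in a new study, which widens the confidence
#' interval by the summed random-effect variances:
#' half-width \eqn{z \sqrt{SE^2 + \sum_l \sigma^2_l}}.
#'
#' @param object fitted [mlma()] model.
#' @param newdata data.frame of moderator values; default: unique design
#'   rows of the fitted data.
#' @param level coverage probability.
#' @param ... unused.
#' @return data.frame with columns pred, se, ci.lb, ci.ub, pi.lb, pi.ub.
#' @export
predict.mlma <- function(object, newdata = NULL, level = 0.95, ...) {
  tt <- stats::delete.response(stats::terms(object$formula))
  if (is.null(newdata)) {
    X0 <- unique(object$X)
  } else {
    mf <- stats::model.frame(tt, newdata,
                             xlev = attr(object$X, "xlevels"))
    X0 <- stats::model.matrix(tt, mf)
    X0 <- X0[, colnames(object$X), drop = FALSE]
  }
  est <- drop(X0 %*% object$coefficients)
  se <- sqrt(pmax(rowSums((X0 %*% object$vcov) * X0), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tau2 <- sum(object$sigma2)
  out <- data.frame(pred = est, se = se,
                    ci.lb = est - z * se, ci.ub = est + z * se,
                    pi.lb = est - z * sqrt(se^2 + tau2),
                    pi.ub = est + z * sqrt(se^2 + tau2))
  rownames(out) <- rownames(X0)
  out
}

#' Likelihood-ratio test between nested ML fits
#'
#' Statistic \eqn{2(\ell_{alt} - \ell_{null})} (clipped at zero),
#' chi-square reference with df equal to the difference in fixed
#' coefficient counts. Both fits must use ML on the same data; REML
#' likelihoods are not comparable across fixed-effect structures.
#'
#' @param object null (smaller) model.
#' @param object2 alternative (larger) model.
#' @param ... unused.
#' @return data.frame with columns statistic, df, pval.
#' @export
anova.mlma <- function(object, object2, ...) {
  if (missing(object2)) stop("supply two fits to compare", call. = FALSE)
  if (object$method != "ML" || object2$method != "ML")
    stop("likelihood-ratio tests of moderators require ML fits",
         call. = FALSE)
  if (object$k != object2$k)
    stop("fits use different numbers of effect sizes", call. = FALSE)
  df <- object2$p - object$p
  if (df < 0)
    stop("the alternative model has fewer fixed coefficients than the null",
         call. = FALSE)
  stat <- max(0, 2 * (object2$logLik - object$logLik))
  pval <- if (df == 0) as.numeric(stat <= 0) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, pval = pval)
}

#' Simulate responses from a fitted model
#'
#' Draws \code{nsim} response vectors from the fitted marginal
#' distribution \eqn{N(X\hat\beta, \hat V)}.
#'
#' @param object fitted [mlma()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one column per simulation.
#' @export
simulate.mlma <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- marginal_vcov(object)
  L <- chol(V)
  mu <- object$fitted.values
  out <- replicate(nsim, mu + drop(crossprod(L, stats::rnorm(object$k))))
  as.data.frame(out)
}

#' Caterpillar-style plot of model predictions
#'
#' Plots the estimated mean effect for each moderator level with bold
#' confidence-interval and thin prediction-interval segments, the usual
#' display for categorical meta-regression results.
#'
#' @param x fitted [mlma()] model.
#' @param level coverage probability for both interval types.
#' @param xlab x-axis label.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mlma <- function(x, level = 0.95, xlab = "effect size", ...) {
  pr <- predict(x, level = level)
  nlev <- nrow(pr)
  labs <- rownames(pr)
  graphics::plot(pr$pred, seq_len(nlev),
                 xlim = range(pr$pi.lb, pr$pi.ub, 0),
                 ylim = c(0.5, nlev + 0.5), yaxt = "n",
                 xlab = xlab, ylab = "", pch = 21, bg = "white", ...)
  graphics::axis(2, at = seq_len(nlev), labels = labs, las = 1)
  graphics::segments(pr$pi.lb, seq_len(nlev), pr$pi.ub, lwd = 1)
  graphics::segments(pr$ci.lb, seq_len(nlev), pr$ci.ub, lwd = 3)
  graphics::points(pr$pred, seq_len(nlev), pch = 21, bg = "white")
  graphics::abline(v = 0, lty = 2)
  invisible(pr)
}
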