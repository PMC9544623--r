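#' Leave-one-publication-out analysis
#'
#' Refits the random-effects-only (null) model once per publication,
#' leaving that publication's effect sizes out, and reports how the
#' overall estimate moves. Publications whose removal moves the estimate
#' far flag influential studies.
#'
#' @param data validated dataset.
#' @param type effect-size type for the null model.
#' @param level CI coverage.
#' @return object of class \code{"sensitivity_report"}: per-iteration
#'   estimates and CIs, plus the full-data estimate and the min/max
#'   range.
#' @export
leave_one_publication_out <- function(data, type = "lnCVR",
                                      level = 0.95) {
  pubs <- unique(data$publication_id)
  if (length(pubs) < 2L)
    stop("need at least 2 publications", call. = FALSE)
  full <- null_fit(data, type)
  rows <- lapply(pubs, function(p) {
    sub <- data[data$publication_id != p, , drop = FALSE]
    fit <- null_fit(sub, type)
    sm <- summary(fit, level = level)$coefficients[1, ]
    data.frame(left_out = p, estimate = sm$estimate,
               ci.lb = sm$ci.lb, ci.ub = sm$ci.ub,
               stringsAsFactors = FALSE)
  })
  report(do.call(rbind, rows), coef(full)[1], "leave-one-publication-out")
}

#' Subsample one effect size per comparison
#'
#' Repeatedly refits the null model keeping exactly one uniformly chosen
#' effect size per experimental comparison, to check that conclusions do
#' not hinge on comparisons contributing many effect sizes. Reproducible
#' under the given seed.
#'
#' @param data validated dataset.
#' @param type effect-size type.
#' @param replicates number of subsampling replicates (>= 1).
#' @param seed integer seed.
#' @param level CI coverage.
#' @return a \code{"sensitivity_report"}.
#' @export
one_effect_per_comparison <- function(data, type = "lnCVR",
                                      replicates = 100, seed = 1,
                                      level = 0.95) {
  stopifnot(replicates >= 1)
  full <- null_fit(data, type)
  set.seed(seed %% 2147483647L)
  idx_by <- split(seq_len(nrow(data)), data$comparison_id)
  rows <- lapply(seq_len(replicates), function(r) {
    pick <- vapply(idx_by, function(ix)
      if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
    sub <- data[sort(pick), , drop = FALSE]
    fit <- null_fit(sub, type)
    sm <- summary(fit, level = level)$coefficients[1, ]
    data.frame(left_out = paste0("replicate_", r),
               estimate = sm$estimate, ci.lb = sm$ci.lb,
               ci.ub = sm$ci.ub, stringsAsFactors = FALSE)
  })
  out <- report(do.call(rbind, rows), coef(full)[1],
                "one-effect-per-comparison subsample")
  out$seed <- seed
  out
}

#' Time-lag bias test
#'
#' Fits mean-centred publication year as a continuous moderator; a
#' non-zero slope indicates that reported effects drift over time (early
#' striking results followed by regression toward smaller effects).
#'
#' @param data validated dataset.
#' @param type effect-size type.
#' @param level CI coverage.
#' @return list with \code{fit} and \code{slope} (see
#'   [covariate_regression()]).
#' @export
time_lag_test <- function(data, type = "lnCVR", level = 0.95) {
  yr <- data$year
  if (length(unique(yr)) < 2L)
    stop("publication year is constant; the slope is not estimable",
         call. = FALSE)
  covariate_regression(data, type, yr - mean(yr), level = level)
}

#' Egger-type regression with effective sample size
#'
#' Publication-bias (small-study asymmetry) test for the mean-effect
#' (lnRR) analysis: the square root of the inverse effective sample size,
#' \eqn{\sqrt{1/\tilde n}}, enters the multilevel model as a continuous
#' moderator. A slope distinguishable from zero indicates that
#' small-sample comparisons report systematically different effects.
#'
#' @param data validated dataset.
#' @param type effect-size type (the mean-effect analysis uses
#'   \code{"lnRR"}).
#' @param variant effective-n definition:
#'   \code{"harmonic"} (default) \eqn{\tilde n = n_T n_C/(n_T+n_C)}, or
#'   \code{"four"} \eqn{\tilde n = 4 n_T n_C/(n_T+n_C)}.
#' @param level CI coverage.
#' @return list with \code{fit}, \code{slope} and the moderator values
#'   (\code{inv_sqrt_n}).
#' @export
egger_effective_n <- function(data, type = "lnRR",
                              variant = c("harmonic", "four"),
                              level = 0.95) {
  variant <- match.arg(variant)
  if (anyNA(data$n_t) || anyNA(data$n_c))
    stop("arm sample sizes are required", call. = FALSE)
  n_eff <- data$n_t * data$n_c / (data$n_t + data$n_c)
  if (variant == "four") n_eff <- 4 * n_eff
  x <- sqrt(1 / n_eff)
  out <- covariate_regression(data, type, x, level = level)
  out$inv_sqrt_n <- x
  out
}

null_fit <- function(data, type, method = "REML") {
  es <- effect_sizes(data, type)
  mlma(yi ~ 1, data = es, V = build_vcv(es), method = method)
}

report <- function(tab, full_estimate, what) {
  structure(list(iterations = tab, full_estimate = full_estimate,
                 range = range(tab$estimate), what = what),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, digits = 4, ...) {
  cat("Sensitivity analysis:", x$what, "\n")
  cat(nrow(x$iterations), "refits; full-data estimate",
      round(x$full_estimate, digits), "\n")
  cat("estimate range:", round(x$range[1], digits), "to",
      round(x$range[2], digits), "\n")
  invisible(x)
}
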