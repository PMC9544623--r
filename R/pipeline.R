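#' Z-standardise arm means within context groups
#'
#' Standardises the chosen arm's mean yield to z-scores within each
#' crop x response-measure x spatial-scale combination, so that yields
#' reported in different units and contexts become comparable as a
#' moderator. Groups of size 1, or groups with zero spread, yield NA
#' (those rows drop out of any model using the covariate).
#'
#' @param data validated dataset.
#' @param arm \code{"treatment"} or \code{"control"}.
#' @return numeric vector of z-scores aligned with \code{data} rows.
#' @export
z_standardise <- function(data, arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  x <- if (arm == "treatment") data$mean_t else data$mean_c
  grp <- interaction(data$crop, data$response_measure, data$scale,
                     drop = TRUE)
  z <- rep(NA_real_, length(x))
  for (idx in split(seq_along(x), grp)) {
    if (length(idx) < 2L) next
    s <- stats::sd(x[idx])
    if (s == 0) next
    z[idx] <- (x[idx] - mean(x[idx])) / s
  }
  if (anyNA(z))
    message(sum(is.na(z)), " row(s) in singleton or zero-spread groups; ",
            "covariate set to NA")
  z
}

#' Convert a log-ratio estimate to a percent change
#'
#' \code{"stability"} treats negative log-ratios as improvements (a lower
#' CV or SD in the treated arm) and reports \code{(1 - exp(b)) * 100};
#' \code{"yield"} and \code{"variance"} report the usual
#' \code{(exp(b) - 1) * 100}.
#'
#' @param b log-ratio estimate(s).
#' @param mode one of \code{"stability"}, \code{"yield"},
#'   \code{"variance"}.
#' @return percent change(s).
#' @export
#' @examples
#' percent_change(-0.3857, "stability") # ~32
percent_change <- function(b, mode = c("stability", "yield", "variance")) {
  mode <- match.arg(mode)
  if (mode == "stability") (1 - exp(b)) * 100 else (exp(b) - 1) * 100
}

#' Univariate multilevel covariate regression
#'
#' Fits an intercept + continuous-covariate multilevel model for one
#' effect-size type, treating the covariate as fixed and error-free, and
#' reports the slope with Wald inference. Used for the lnCVR ~ lnRR,
#' lnCVR ~ z-yield and lnRR ~ z-yield analyses.
#'
#' @param data validated dataset.
#' @param response_type effect-size type of the response.
#' @param covariate numeric vector aligned with \code{data} rows.
#' @param method fitting method for the reported model.
#' @param level CI coverage.
#' @return list with \code{fit} (the [mlma()] object) and \code{slope}
#'   (one-row data.frame: estimate, se, ci.lb, ci.ub, zval, pval).
#' @export
covariate_regression <- function(data,
                                 response_type = c("lnCVR", "lnVR", "lnRR"),
                                 covariate, method = "REML",
                                 level = 0.95) {
  response_type <- match.arg(response_type)
  es <- effect_sizes(data, response_type)
  es$x_cov <- covariate
  V <- build_vcv(es)
  fit <- mlma(yi ~ x_cov, data = es, V = V, method = method)
  sm <- summary(fit, level = level)$coefficients
  list(fit = fit, slope = sm["x_cov", , drop = FALSE])
}

#' Suite configuration
#'
#' @param models character vector of model labels to run (subset of
#'   CVR0-CVR7, SD0-SD2, RR0, RR1, VR0).
#' @param level CI coverage for reported intervals.
#' @param reml refit reported models by REML (ML fits are always run for
#'   the likelihood-ratio tests).
#' @param merged_scale treat plot and cohort as one spatial-scale level.
#' @return list of class \code{"suite_config"}.
#' @export
suite_config <- function(models = c("CVR0", "SD0", "RR0", "VR0",
                                    "CVR1", "SD1", "CVR2", "SD2",
                                    "CVR3", "CVR4", "RR1",
                                    "CVR5", "CVR6", "CVR7"),
                         level = 0.95, reml = TRUE,
                         merged_scale = TRUE) {
  structure(list(models = models, level = level, reml = reml,
                 merged_scale = merged_scale),
            class = "suite_config")
}

RANDOM_LEVELS <- c("publication_id", "comparison_id", "effect_id")

#' Run the full yield-stability model suite
#'
#' Orchestrates the model suite on a validated dataset: null models per
#' effect-size type (CVR0, VR0, RR0) and the arm-based ln(SD) analysis
#' (SD0); crop and spatial-scale moderator models (CVR1/SD1, CVR2/SD2);
#' resource-limitation covariate models (CVR3: lnCVR ~ lnRR; CVR4:
#' lnCVR ~ z-yield of treated arms; RR1: lnRR ~ z-yield of control arms);
#' pollinator-type models (CVR5, CVR6) and the pollination-intensity
#' model on the intensity subset (CVR7).
#'
#' Contrast-based models carry the shared-control sampling VCV and nested
#' publication / comparison / effect-size random effects; categorical
#' moderators are fitted in cell-means coding for reported estimates and
#' in reference coding (by ML) for likelihood-ratio tests against the
#' nested null. Arm-based models use per-arm rows, sampling variance
#' 1/(2(n-1)), the same random structure keyed on arms, and CR2
#' cluster-robust inference clustered on the experimental comparison.
#' Covariate models treat the covariate as fixed and error-free.
#'
#' @param data validated dataset.
#' @param cfg a [suite_config()].
#' @return object of class \code{"suite_result"}: per-model entries
#'   (fit, robust/heterogeneity summaries, percent-scale translations),
#'   an LRT table, and the headline summary from
#'   [headline_numbers()].
#' @export
run_suite <- function(data, cfg = suite_config()) {
  method <- if (cfg$reml) "REML" else "ML"
  res <- list()
  lrt <- list()
  want <- function(m) m %in% cfg$models

  es <- list(lnCVR = effect_sizes(data, "lnCVR"),
             lnRR = effect_sizes(data, "lnRR"),
             lnVR = effect_sizes(data, "lnVR"))
  Vs <- lapply(es, build_vcv)
  arms <- arm_rows(data)
  arm_random <- c("publication_id", "comparison_id", "arm_id")

  contrast <- function(formula, type, dat = es[[type]], V = Vs[[type]],
                       meth = method) {
    mlma(formula, data = dat, V = V, random = RANDOM_LEVELS, method = meth)
  }
  arm_fit <- function(formula, meth = method) {
    mlma(formula, data = arms, vi = "vi", random = arm_random,
         method = meth)
  }
  add_lrt <- function(label, null_ml, alt_ml) {
    tab <- anova(null_ml, alt_ml)
    tab$comparison <- label
    lrt[[label]] <<- tab
  }

  ml_null <- list()   # ML null fits per type, reused by the LRTs
  for (type in c("lnCVR", "lnRR", "lnVR"))
    ml_null[[type]] <- contrast(yi ~ 1, type, meth = "ML")

  # -- null models ---------------------------------------------------
  if (want("CVR0")) {
    fit <- contrast(yi ~ 1, "lnCVR")
    res$CVR0 <- list(
      fit = fit, het = heterogeneity(fit),
      percent = pct_ci(fit, "(Intercept)", "stability", cfg$level))
  }
  if (want("RR0")) {
    fit <- contrast(yi ~ 1, "lnRR")
    res$RR0 <- list(fit = fit, het = heterogeneity(fit),
                    percent = pct_ci(fit, "(Intercept)", "yield",
                                     cfg$level))
  }
  if (want("VR0")) {
    fit <- contrast(yi ~ 1, "lnVR")
    res$VR0 <- list(fit = fit, het = heterogeneity(fit),
                    percent = pct_ci(fit, "(Intercept)", "variance",
                                     cfg$level))
  }
  if (want("SD0")) {
    fit <- arm_fit(ln_sd ~ ln_mean + condition)
    rob <- robust(fit, arms$comparison_id, level = cfg$level)
    res$SD0 <- list(fit = fit, robust = rob,
                    percent = pct_ci_robust(rob, "conditiontreated",
                                            "stability"))
  }

  # -- categorical moderators ---------------------------------------
  cat_model <- function(label, var, subset_rows = NULL, lrt_null = NULL,
                        lrt_label = NULL) {
    dat <- es$lnCVR
    V <- Vs$lnCVR
    if (!is.null(subset_rows)) {
      dat <- dat[subset_rows, , drop = FALSE]
      V <- V[subset_rows, subset_rows, drop = FALSE]
    }
    if (length(unique(dat[[var]])) < 2L)
      return(list(skipped = paste("moderator", var,
                                  "has a single level in the data")))
    cm <- stats::as.formula(paste("yi ~ 0 +", var))
    rf <- stats::as.formula(paste("yi ~", var))
    fit <- mlma(cm, data = dat, V = V, random = RANDOM_LEVELS,
                method = method)
    fit_ml <- mlma(rf, data = dat, V = V, random = RANDOM_LEVELS,
                   method = "ML")
    if (!is.null(lrt_null)) add_lrt(lrt_label, lrt_null, fit_ml)
    pred <- predict(fit, level = cfg$level)
    pct <- data.frame(level = sub(var, "", names(coef(fit)), fixed = TRUE),
                      percent = percent_change(coef(fit), "stability"),
                      lo = percent_change(pred$ci.ub, "stability"),
                      hi = percent_change(pred$ci.lb, "stability"))
    list(fit = fit, fit_ml = fit_ml, het = heterogeneity(fit),
         r2 = r2_marginal(fit), percent = pct, predict = pred)
  }

  if (want("CVR1"))
    res$CVR1 <- cat_model("CVR1", "crop", lrt_null = ml_null$lnCVR,
                          lrt_label = "CVR1 vs CVR0")
  if (want("CVR2"))
    res$CVR2 <- cat_model("CVR2", "scale", lrt_null = ml_null$lnCVR,
                          lrt_label = "CVR2 vs CVR0")
  if (want("CVR5"))
    res$CVR5 <- cat_model("CVR5", "treatment_type",
                          lrt_null = ml_null$lnCVR,
                          lrt_label = "CVR5 vs CVR0")
  if (want("CVR6")) {
    es$lnCVR$open_pollinated <- ifelse(es$lnCVR$treatment_type == "open",
                                       "open", "other")
    res$CVR6 <- cat_model("CVR6", "open_pollinated")
    if (!is.null(res$CVR6$fit_ml) && !is.null(res$CVR5$fit_ml))
      add_lrt("CVR6 vs CVR5", res$CVR6$fit_ml, res$CVR5$fit_ml)
  }
  if (want("CVR7")) {
    sub <- which(es$lnCVR$intensity %in% c("high", "low"))
    if (length(sub) == 0L) {
      res$CVR7 <- list(skipped = "no rows with a pollination-intensity contrast")
    } else {
      res$CVR7 <- cat_model("CVR7", "intensity", subset_rows = sub)
      if (is.null(res$CVR7$skipped)) {
        null_sub <- mlma(yi ~ 1, data = es$lnCVR[sub, , drop = FALSE],
                         V = Vs$lnCVR[sub, sub, drop = FALSE],
                         random = RANDOM_LEVELS, method = "ML")
        add_lrt("CVR7 vs null", null_sub, res$CVR7$fit_ml)
      }
    }
  }

  # -- arm-based moderator models -----------------------------------
  arm_mod <- function(var) {
    arms2 <- arms
    arms2[[var]] <- data[[var]][match(arms2$comparison_id,
                                      data$comparison_id)]
    if (length(unique(arms2[[var]])) < 2L)
      return(list(skipped = paste("moderator", var, "has a single level")))
    f <- stats::as.formula(paste(
      "ln_sd ~ ln_mean +", var, "+ condition:", var))
    fit <- mlma(f, data = arms2, vi = "vi", random = arm_random,
                method = method)
    rob <- robust(fit, arms2$comparison_id, level = cfg$level)
    eff <- grep("conditiontreated", names(coef(fit)), value = TRUE)
    pct <- data.frame(
      coefficient = eff,
      percent = percent_change(coef(fit)[eff], "stability"),
      lo = percent_change(rob$coefficients[eff, "ci.ub"], "stability"),
      hi = percent_change(rob$coefficients[eff, "ci.lb"], "stability"))
    list(fit = fit, robust = rob, percent = pct)
  }
  if (want("SD1")) res$SD1 <- arm_mod("crop")
  if (want("SD2")) res$SD2 <- arm_mod("scale")

  # -- covariate models ---------------------------------------------
  if (want("CVR3")) {
    cv3 <- covariate_regression(data, "lnCVR", es$lnRR$yi,
                                method = method, level = cfg$level)
    res$CVR3 <- c(cv3, list(r2 = r2_marginal(cv3$fit)))
  }
  if (want("CVR4")) {
    z_t <- z_standardise(data, "treatment")
    cv4 <- covariate_regression(data, "lnCVR", z_t, method = method,
                                level = cfg$level)
    res$CVR4 <- c(cv4, list(r2 = r2_marginal(cv4$fit)))
  }
  if (want("RR1")) {
    z_c <- z_standardise(data, "control")
    rr1 <- covariate_regression(data, "lnRR", z_c, method = method,
                                level = cfg$level)
    res$RR1 <- c(rr1, list(r2 = r2_marginal(rr1$fit)))
  }

  skipped <- setdiff(cfg$models, names(res))
  for (m in skipped) res[[m]] <- list(skipped = "not applicable to dataset")

  out <- list(models = res,
              lrt = if (length(lrt)) do.call(rbind, lrt) else NULL,
              config = cfg, counts = dataset_counts(data))
  class(out) <- "suite_result"
  out$headline <- headline_numbers(out)
  out
}

# percent change with CI from a contrast-model coefficient
pct_ci <- function(fit, coef_name, mode, level = 0.95) {
  sm <- summary(fit, level = level)$coefficients[coef_name, ]
  if (mode == "stability")
    data.frame(percent = percent_change(sm$estimate, mode),
               lo = percent_change(sm$ci.ub, mode),
               hi = percent_change(sm$ci.lb, mode))
  else
    data.frame(percent = percent_change(sm$estimate, mode),
               lo = percent_change(sm$ci.lb, mode),
               hi = percent_change(sm$ci.ub, mode))
}

pct_ci_robust <- function(rob, coef_name, mode) {
  sm <- rob$coefficients[coef_name, ]
  data.frame(percent = percent_change(sm$estimate, mode),
             lo = percent_change(sm$ci.ub, mode),
             hi = percent_change(sm$ci.lb, mode))
}

#' Headline quantities of a suite run
#'
#' Collects the main reported numbers from a [run_suite()] result into a
#' flat named list: overall percent effects with CIs, total and residual
#' I-squared, per-crop and site-scale stability percentages, and the
#' covariate slopes.
#'
#' @param suite a \code{suite_result}.
#' @return named list of numbers (NULL entries for models not run).
#' @export
headline_numbers <- function(suite) {
  res <- if (inherits(suite, "suite_result")) suite$models else suite
  g <- function(m, f) if (!is.null(res[[m]]) && is.null(res[[m]]$skipped))
    f(res[[m]]) else NULL
  crop_pct <- g("CVR1", function(m) {
    p <- m$percent; stats::setNames(p$percent, p$level)
  })
  site_pct <- g("CVR2", function(m) {
    p <- m$percent; p$percent[p$level == "site"]
  })
  list(
    cvr0_stability_pct = g("CVR0", function(m) m$percent$percent),
    cvr0_ci = g("CVR0", function(m) c(m$percent$lo, m$percent$hi)),
    sd0_stability_pct = g("SD0", function(m) m$percent$percent),
    rr0_yield_pct = g("RR0", function(m) m$percent$percent),
    vr0_variance_pct = g("VR0", function(m) m$percent$percent),
    i2_total = g("CVR0", function(m) m$het$i2_total),
    i2_residual = g("CVR0", function(m)
      m$het$i2_by_level[["effect_id"]]),
    crop_stability_pct = crop_pct,
    site_stability_pct = site_pct,
    cvr3_slope = g("CVR3", function(m) m$slope$estimate),
    cvr4_slope = g("CVR4", function(m) m$slope$estimate),
    rr1_slope = g("RR1", function(m) m$slope$estimate))
}

#' @export
print.suite_result <- function(x, digits = 3, ...) {
  cat("Yield-stability model suite:", x$counts$n_publications,
      "publications,", x$counts$n_comparisons, "comparisons,",
      x$counts$n_effects, "effect sizes\n\n")
  for (m in names(x$models)) {
    entry <- x$models[[m]]
    if (!is.null(entry$skipped)) {
      cat(sprintf("%-5s skipped: %s\n", m, entry$skipped))
    } else if (!is.null(entry$percent) && nrow(entry$percent) == 1L &&
               is.null(entry$percent$level)) {
      cat(sprintf("%-5s %6.1f%% (%.1f to %.1f)\n", m,
                  entry$percent$percent[1], entry$percent$lo[1],
                  entry$percent$hi[1]))
    } else if (!is.null(entry$slope)) {
      cat(sprintf("%-5s slope %.3f (p = %.3g)\n", m,
                  entry$slope$estimate, entry$slope$pval))
    } else if (!is.null(entry$percent)) {
      cat(sprintf("%-5s %s\n", m,
                  paste(sprintf("%s %.1f%%",
                                entry$percent[[1]],
                                entry$percent$percent),
                        collapse = ", ")))
    }
  }
  if (!is.null(x$lrt)) {
    cat("\nLikelihood-ratio tests (ML):\n")
    print(round(x$lrt[, c("statistic", "df", "pval")], 4))
  }
  invisible(x)
}
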