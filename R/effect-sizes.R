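#' Bias-corrected log response ratio (lnRR)
#'
#' Computes the small-sample bias-corrected log ratio of arm means together
#' with its sampling variance, from two-arm summary statistics. The
#' correction removes the leading-order bias of \code{log(xbar)} as an
#' estimator of \code{log(mu)}, which matters at the small per-arm sample
#' sizes typical of pollination-exclusion experiments.
#'
#' Estimate: \code{log(mt/mc) + (cvt^2/nt - cvc^2/nc)/2} where
#' \code{cv = sd/mean}; sampling variance: \code{cvt^2/nt + cvc^2/nc}.
#'
#' @param mean_t,sd_t,n_t treatment-arm mean, standard deviation and number
#'   of experimental units. Vectorised.
#' @param mean_c,sd_c,n_c control-arm summaries.
#' @return data.frame with columns \code{yi} (estimate) and \code{vi}
#'   (sampling variance).
#' @seealso [lnvr()], [lncvr()], [effect_sizes()]
#' @export
#' @examples
#' lnrr(20, 2, 10, 10, 1, 10)
lnrr <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  check_arms(mean_t, sd_t, n_t, mean_c, sd_c, n_c,
             need_pos_mean = TRUE, need_pos_sd = FALSE)
  st2 <- sd_t^2 / (n_t * mean_t^2)
  sc2 <- sd_c^2 / (n_c * mean_c^2)
  data.frame(yi = log(mean_t / mean_c) + (st2 - sc2) / 2,
             vi = st2 + sc2)
}

#' Bias-corrected log variability ratio (lnVR)
#'
#' Log ratio of arm standard deviations with the small-sample bias
#' correction \code{1/(2(n-1))} per arm; measures the difference in
#' absolute variability between arms, ignoring the means.
#'
#' Estimate: \code{log(sd_t/sd_c) + 1/(2(n_t-1)) - 1/(2(n_c-1))};
#' sampling variance: \code{1/(2(n_t-1)) + 1/(2(n_c-1))}.
#'
#' @inheritParams lnrr
#' @return data.frame with columns \code{yi} and \code{vi}.
#' @export
#' @examples
#' lnvr(mean_t = 1, sd_t = 4, n_t = 10, mean_c = 1, sd_c = 2, n_c = 5)
lnvr <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  check_arms(mean_t, sd_t, n_t, mean_c, sd_c, n_c,
             need_pos_mean = FALSE, need_pos_sd = TRUE)
  ct <- 1 / (2 * (n_t - 1))
  cc <- 1 / (2 * (n_c - 1))
  data.frame(yi = log(sd_t / sd_c) + ct - cc,
             vi = ct + cc)
}

#' Bias-corrected log coefficient of variation ratio (lnCVR)
#'
#' Log ratio of arm coefficients of variation (CV = sd/mean) with
#' small-sample bias corrections for both the log-SD and log-mean
#' components. Negative values mean the treatment arm is relatively more
#' stable per unit of mean than the control arm.
#'
#' Estimate: \code{log(cvt/cvc) + [1/(2(n_t-1)) - 1/(2(n_c-1))] -
#' [cvt^2/n_t - cvc^2/n_c]/2}. Sampling variance (default): sum of the
#' lnRR and lnVR component variances,
#' \code{cvt^2/n_t + 1/(2(n_t-1)) + cvc^2/n_c + 1/(2(n_c-1))}. The
#' mean-variance correlation cross-term of the full estimator needs a
#' within-arm correlation between log mean and log SD that two-arm summary
#' tables do not report; it is exposed through \code{mv_cor} and defaults
#' to zero.
#'
#' @inheritParams lnrr
#' @param mv_cor correlation between log mean and log SD within an arm,
#'   used in the optional cross-term of the sampling variance; default 0
#'   (term off).
#' @return data.frame with columns \code{yi} and \code{vi}.
#' @export
#' @examples
#' lncvr(20, 2, 10, 10, 2, 10)
lncvr <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c, mv_cor = 0) {
  check_arms(mean_t, sd_t, n_t, mean_c, sd_c, n_c,
             need_pos_mean = TRUE, need_pos_sd = TRUE)
  cvt <- sd_t / mean_t
  cvc <- sd_c / mean_c
  ct <- 1 / (2 * (n_t - 1))
  cc <- 1 / (2 * (n_c - 1))
  yi <- log(cvt / cvc) + (ct - cc) - (cvt^2 / n_t - cvc^2 / n_c) / 2
  vi <- cvt^2 / n_t + ct + cvc^2 / n_c + cc -
    2 * mv_cor * (sqrt(cvt^2 / n_t * ct) + sqrt(cvc^2 / n_c * cc))
  data.frame(yi = yi, vi = vi)
}

check_arms <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c,
                       need_pos_mean, need_pos_sd) {
  if (any(n_t < 2) || any(n_c < 2))
    stop("arm sample sizes must be >= 2", call. = FALSE)
  if (need_pos_mean && (any(mean_t <= 0) || any(mean_c <= 0)))
    stop("arm means must be > 0 for ratio effect sizes", call. = FALSE)
  if (need_pos_sd && (any(sd_t <= 0) || any(sd_c <= 0)))
    stop("arm SDs must be > 0 for log-variability effect sizes",
         call. = FALSE)
  if (any(sd_t < 0) || any(sd_c < 0))
    stop("arm SDs must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Compute effect sizes for a pollination dataset
#'
#' Adds effect-size columns \code{yi}, \code{vi} (and \code{es_type}) to a
#' validated dataset, in the style of an effect-size calculator: the input
#' rows are preserved and annotated.
#'
#' @param data data.frame in the package schema (see [read_yield_data()]).
#' @param type one of \code{"lnCVR"}, \code{"lnVR"}, \code{"lnRR"}.
#' @param mv_cor passed to [lncvr()].
#' @return the input data.frame with \code{yi}, \code{vi}, \code{es_type}
#'   columns appended.
#' @export
effect_sizes <- function(data, type = c("lnCVR", "lnVR", "lnRR"),
                         mv_cor = 0) {
  type <- match.arg(type)
  es <- switch(type,
    lnRR  = lnrr(data$mean_t, data$sd_t, data$n_t,
                 data$mean_c, data$sd_c, data$n_c),
    lnVR  = lnvr(data$mean_t, data$sd_t, data$n_t,
                 data$mean_c, data$sd_c, data$n_c),
    lnCVR = lncvr(data$mean_t, data$sd_t, data$n_t,
                  data$mean_c, data$sd_c, data$n_c, mv_cor = mv_cor))
  data$yi <- es$yi
  data$vi <- es$vi
  data$es_type <- rep(type, nrow(data))
  data
}

#' Build arm-level rows for the arm-based ln(SD) analysis
#'
#' Converts a two-arm dataset to one row per experimental arm, the input
#' format of the arm-based model (ln SD as response, treatment condition
#' and ln mean as fixed effects). Each distinct control group — identified
#' by \code{shared_control_id} — contributes exactly one row, so arms
#' reused across several treatment comparisons are not duplicated.
#'
#' \code{ln_sd} is bias-corrected (\code{log(sd) + 1/(2(n-1))}) so that the
#' treatment-condition coefficient of the arm-based model lines up with
#' the bias-corrected contrast effect sizes; \code{vi = 1/(2(n-1))} is the
#' sampling variance of \code{log(sd)}.
#'
#' @param data dataset in the package schema.
#' @return data.frame with columns \code{arm_id}, \code{condition}
#'   (factor control/treated), \code{ln_sd}, \code{ln_mean}, \code{vi},
#'   \code{publication_id}, \code{comparison_id}.
#' @export
arm_rows <- function(data) {
  if (any(data$sd_t <= 0 | data$sd_c <= 0))
    stop("arm SDs must be > 0 for ln(SD) rows", call. = FALSE)
  if (any(data$mean_t <= 0 | data$mean_c <= 0))
    stop("arm means must be > 0 for ln(mean)", call. = FALSE)

  treat <- data.frame(
    arm_id = paste0("t:", data$effect_id),
    condition = "treated",
    ln_sd = log(data$sd_t) + 1 / (2 * (data$n_t - 1)),
    ln_mean = log(data$mean_t),
    vi = 1 / (2 * (data$n_t - 1)),
    publication_id = data$publication_id,
    comparison_id = data$comparison_id,
    stringsAsFactors = FALSE)

  first <- !duplicated(data$shared_control_id)
  ctl <- data[first, , drop = FALSE]
  # rows sharing a control must carry identical control summaries
  key <- paste(data$mean_c, data$sd_c, data$n_c)
  if (any(tapply(key, data$shared_control_id,
                 function(k) length(unique(k))) > 1L))
    stop("inconsistent control summaries within a shared_control_id",
         call. = FALSE)
  control <- data.frame(
    arm_id = paste0("c:", ctl$shared_control_id),
    condition = "control",
    ln_sd = log(ctl$sd_c) + 1 / (2 * (ctl$n_c - 1)),
    ln_mean = log(ctl$mean_c),
    vi = 1 / (2 * (ctl$n_c - 1)),
    publication_id = ctl$publication_id,
    comparison_id = ctl$comparison_id,
    stringsAsFactors = FALSE)

  out <- rbind(treat, control)
  out$condition <- factor(out$condition, levels = c("control", "treated"))
  rownames(out) <- NULL
  out
}

#' Sampling covariance induced by a shared control arm
#'
#' Two effect sizes that compare different treatment arms with the same
#' control arm have correlated sampling errors; the covariance is the part
#' of each sampling variance contributed by the common control arm.
#'
#' @param type effect-size type, one of \code{"lnRR"}, \code{"lnVR"},
#'   \code{"lnCVR"}.
#' @param mean_c,sd_c,n_c summaries of the shared control arm.
#' @return covariance (scalar, or vector if the inputs are vectors).
#' @export
#' @examples
#' shared_control_cov("lnVR", mean_c = 10, sd_c = 1, n_c = 10) # 1/18
shared_control_cov <- function(type = c("lnRR", "lnVR", "lnCVR"),
                               mean_c, sd_c, n_c) {
  type <- match.arg(type)
  switch(type,
    lnRR  = sd_c^2 / (n_c * mean_c^2),
    lnVR  = 1 / (2 * (n_c - 1)),
    lnCVR = sd_c^2 / (n_c * mean_c^2) + 1 / (2 * (n_c - 1)))
}

#' Assemble the block sampling variance-covariance matrix
#'
#' Builds the k x k sampling VCV for a set of effect sizes of one type:
#' sampling variances on the diagonal, shared-control covariances within
#' blocks of rows that share a control arm, zeros elsewhere. The result is
#' checked for positive semi-definiteness; tiny negative eigenvalues from
#' floating-point rounding are repaired by inflating the diagonal, with a
#' message.
#'
#' @param data data.frame with columns \code{yi}, \code{vi},
#'   \code{es_type}, \code{shared_control_id}, \code{mean_c}, \code{sd_c},
#'   \code{n_c} (as produced by [effect_sizes()]).
#' @return symmetric PSD matrix with dimnames = \code{effect_id} when the
#'   column is present.
#' @export
build_vcv <- function(data) {
  k <- nrow(data)
  V <- matrix(0, k, k)
  if (k == 0L) return(V)
  if (length(unique(data$es_type)) > 1L)
    stop("effects of different types cannot share one sampling VCV",
         call. = FALSE)
  type <- data$es_type[1L]
  diag(V) <- data$vi
  for (idx in split(seq_len(k), data$shared_control_id)) {
    if (length(idx) < 2L) next
    i1 <- idx[1L]
    cv <- shared_control_cov(type, data$mean_c[i1], data$sd_c[i1],
                             data$n_c[i1])
    for (a in idx) for (b in idx) if (a != b) V[a, b] <- cv
  }
  if (!is.null(data$effect_id)) dimnames(V) <- list(data$effect_id,
                                                    data$effect_id)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(ev, 0)
  if (min(ev) < -tol) {
    # implied correlations > 1 signal inconsistent inputs, not rounding
    stop("sampling VCV is not positive semi-definite; check shared-control ",
         "blocks with implied correlation >= 1", call. = FALSE)
  }
  if (min(ev) < 0) {
    message("repairing sampling VCV: adding ", format(-min(ev)),
            " to the diagonal to absorb rounding")
    diag(V) <- diag(V) - min(ev)
  }
  V
}
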