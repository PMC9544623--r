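#' Configuration for the summary-level synthetic generator
#'
#' Describes a synthetic collection of pollination-exclusion experiments
#' with the multilevel structure the analysis assumes: publications
#' containing experimental comparisons, several response measures
#' (effect sizes) per comparison, and several treatment arms sharing one
#' control arm. Defaults emulate the structure of the analysed corpus:
#' 47 publications, 215 comparisons, 498 effect sizes.
#'
#' True row-level effects are built additively on the log-ratio scale:
#' overall mean plus independent normal deviates at the publication,
#' comparison and effect-size levels (variances \code{sigma2}). Unit
#' yields are lognormal — yield is positive and right-skewed, and
#' multiplicative noise reproduces the strong mean-variance relationship
#' of real yield data. The generator realises target effect sizes exactly
#' at the distribution level; sampling noise enters only through the
#' finite number of units per arm.
#'
#' @param n_publications number of publications.
#' @param comparisons_per_publication comparisons in each publication;
#'   NULL (default) allocates 215 comparisons across publications.
#' @param effects_per_comparison response measures per comparison; NULL
#'   (default) allocates 498 effects across 215 comparisons.
#' @param treatments_per_control treatment arms compared against one
#'   shared control arm (default 2).
#' @param true_mu named vector of true mean log-ratios,
#'   \code{c(lnCVR = ..., lnRR = ...)}.
#' @param sigma2 named vector of heterogeneity variances
#'   \code{c(publication = ..., comparison = ..., effect = ...)}.
#' @param unit_n_range integer range of experimental units per arm.
#' @param control_mean,control_cv control-arm lognormal mean and
#'   coefficient of variation.
#' @param prop_intensity fraction of publications whose comparisons carry
#'   a high/low pollination-intensity contrast (populates the intensity
#'   moderator; others get "none").
#' @param seed master integer seed; per-publication substreams are
#'   derived from it so earlier publications are unchanged when the count
#'   grows.
#' @return list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_publications = 47,
                             comparisons_per_publication = NULL,
                             effects_per_comparison = NULL,
                             treatments_per_control = 2,
                             true_mu = c(lnCVR = -0.4, lnRR = 0.7),
                             sigma2 = c(publication = 0.05,
                                        comparison = 0.02,
                                        effect = 0.01),
                             unit_n_range = c(5, 30),
                             control_mean = 10, control_cv = 0.5,
                             prop_intensity = 0.25,
                             seed = 1) {
  stopifnot(n_publications >= 1, treatments_per_control >= 1,
            all(sigma2 >= 0), control_cv > 0, control_mean > 0,
            length(unit_n_range) == 2, unit_n_range[1] >= 2)
  structure(as.list(environment()), class = "generator_config")
}

# spread `total` items over `n` slots as evenly as possible (first slots
# get the remainder), so default corpus counts are hit exactly
allocate_counts <- function(total, n) {
  base <- total %/% n
  extra <- total - base * n
  c(rep(base + 1L, extra), rep(base, n - extra))
}

lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_arm <- function(n, mean, cv) {
  p <- lnorm_pars(mean, cv)
  x <- stats::rlnorm(n, p$meanlog, p$sdlog)
  c(mean = mean(x), sd = stats::sd(x), n = n)
}

CROPS <- c("apple", "oilseed_rape", "faba_bean")
SCALES <- c("flower", "plant", "plot_or_cohort", "site")
TREATMENTS <- c("hand", "honeybee", "bumblebee", "hoverfly", "solitary",
                "open")

#' Generate a summary-level synthetic dataset
#'
#' Simulates the full corpus described by a [generator_config()]: for
#' each effect row, lognormal unit yields are drawn for the treatment arm
#' whose true mean and CV realise the row's true lnRR and lnCVR relative
#' to a shared control draw, then summarised to (mean, SD, n). Output is
#' a validated dataset in the package CSV schema.
#'
#' @param cfg a [generator_config()].
#' @return validated data.frame (see [read_yield_data()]).
#' @export
#' @examples
#' ds <- generate_summary_dataset(generator_config(n_publications = 3,
#'   comparisons_per_publication = 2, effects_per_comparison = 2))
#' dataset_counts(ds)
generate_summary_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  np <- cfg$n_publications
  cpp <- if (is.null(cfg$comparisons_per_publication))
    allocate_counts(215L, np) else
    rep_len(cfg$comparisons_per_publication, np)
  total_comp <- sum(cpp)
  epc_all <- if (is.null(cfg$effects_per_comparison))
    allocate_counts(498L, total_comp) else
    rep_len(cfg$effects_per_comparison, total_comp)

  rows <- vector("list", np)
  comp_offset <- 0L
  n_int_pubs <- floor(cfg$prop_intensity * np)
  for (p in seq_len(np)) {
    # per-publication substream; double arithmetic avoids integer overflow
    set.seed(as.integer((as.numeric(cfg$seed) * 1000003 + p * 7919) %%
                          2147483647))
    b_pub <- stats::rnorm(2, 0, sqrt(cfg$sigma2[["publication"]]))
    ncomp <- cpp[p]
    epc <- epc_all[comp_offset + seq_len(ncomp)]
    comp_offset <- comp_offset + ncomp
    has_intensity <- p <= n_int_pubs

    # comparisons grouped into shared-control sets
    grp <- (seq_len(ncomp) - 1L) %/% cfg$treatments_per_control + 1L
    out <- list()
    for (g in unique(grp)) {
      comps <- which(grp == g)
      e_g <- max(epc[comps])
      n_units <- cfg$unit_n_range[1] +
        sample.int(cfg$unit_n_range[2] - cfg$unit_n_range[1] + 1L, 1L) - 1L
      # one control draw per response measure, shared across treatments
      ctl <- lapply(seq_len(e_g), function(r)
        draw_arm(n_units, cfg$control_mean, cfg$control_cv))
      for (ti in seq_along(comps)) {
        ci <- comps[ti]
        b_comp <- stats::rnorm(2, 0, sqrt(cfg$sigma2[["comparison"]]))
        for (r in seq_len(epc[ci])) {
          b_eff <- stats::rnorm(2, 0, sqrt(cfg$sigma2[["effect"]]))
          true_cvr <- cfg$true_mu[["lnCVR"]] + b_pub[1] + b_comp[1] + b_eff[1]
          true_rr <- cfg$true_mu[["lnRR"]] + b_pub[2] + b_comp[2] + b_eff[2]
          m_t <- cfg$control_mean * exp(true_rr)
          cv_t <- cfg$control_cv * exp(true_cvr)
          trt <- draw_arm(n_units, m_t, cv_t)
          out[[length(out) + 1L]] <- data.frame(
            publication_id = sprintf("pub%03d", p),
            comparison_id = sprintf("pub%03d_c%02d", p, ci),
            effect_id = sprintf("pub%03d_c%02d_e%d", p, ci, r),
            crop = CROPS[(p - 1L) %% 3L + 1L],
            country = "synthetic",
            scale = SCALES[(p - 1L) %% 4L + 1L],
            response_measure = paste0("measure_", r),
            treatment_type = TREATMENTS[(p + ci - 2L) %% 6L + 1L],
            intensity = if (has_intensity)
              c("high", "low")[(ti - 1L) %% 2L + 1L] else "none",
            year = 1985L + (p * 13L) %% 35L,
            mean_t = trt[["mean"]], disp_t = trt[["sd"]],
            n_t = trt[["n"]],
            mean_c = ctl[[r]][["mean"]], disp_c = ctl[[r]][["sd"]],
            n_c = ctl[[r]][["n"]],
            dispersion_kind = "SD",
            shared_control_id = sprintf("pub%03d_g%02d_m%d", p, g, r),
            stringsAsFactors = FALSE)
        }
      }
    }
    rows[[p]] <- do.call(rbind, out)
  }
  df <- do.call(rbind, rows)
  validate_yield_data(df, provenance = sprintf(
    "stabmeta summary generator, seed %d", cfg$seed))
}

#' Configuration for the mechanistic resource-ceiling generator
#'
#' Unit-level simulator of the ceiling-effect mechanism: every
#' experimental unit has a maximum potential yield (its resource
#' ceiling); animal pollination multiplies pre-ceiling yield by
#' \code{pollination_gain}, and realised yield is the minimum of the two.
#' When the ceiling binds, well-pollinated units cluster just under their
#' ceilings, compressing the treated arm's CV and producing the negative
#' association between lnCVR and lnRR.
#'
#' @param ceiling_mean,ceiling_cv lognormal mean and CV of the per-unit
#'   maximum potential yield (response-measure units).
#' @param pollination_gain multiplicative effect(s) of animal pollination
#'   on pre-ceiling yield; a vector gives a grid of comparisons.
#' @param baseline_mean,baseline_cv lognormal mean and CV of
#'   auto-pollinated pre-ceiling yield.
#' @param units_per_arm experimental units per arm.
#' @param comparisons_per_gain independent comparisons simulated at each
#'   gain value.
#' @param seed integer seed.
#' @return list of class \code{"ceiling_config"}.
#' @export
ceiling_config <- function(ceiling_mean = 12, ceiling_cv = 0.3,
                           pollination_gain = c(1.2, 2, 4),
                           baseline_mean = 6, baseline_cv = 0.5,
                           units_per_arm = 20, comparisons_per_gain = 10,
                           seed = 1) {
  stopifnot(ceiling_mean > 0, ceiling_cv > 0, baseline_mean > 0,
            baseline_cv > 0, all(pollination_gain > 0),
            units_per_arm >= 2, comparisons_per_gain >= 1)
  structure(as.list(environment()), class = "ceiling_config")
}

#' Generate a dataset from the resource-ceiling mechanism
#'
#' For each comparison: draws per-unit ceilings and pre-ceiling baseline
#' yields, applies the pollination gain to the treated arm, truncates
#' both arms at the ceiling, and summarises each arm to (mean, SD, n).
#' Comparisons across the \code{pollination_gain} grid form a
#' multi-comparison dataset on which the lnCVR-vs-lnRR association can
#' be fitted.
#'
#' @param cfg a [ceiling_config()].
#' @return validated data.frame in the package schema.
#' @export
generate_ceiling_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ceiling_config"))
  set.seed(cfg$seed %% 2147483647L)
  ce <- lnorm_pars(cfg$ceiling_mean, cfg$ceiling_cv)
  ba <- lnorm_pars(cfg$baseline_mean, cfg$baseline_cv)
  out <- list()
  i <- 0L
  for (gain in cfg$pollination_gain) {
    for (rep in seq_len(cfg$comparisons_per_gain)) {
      i <- i + 1L
      n <- cfg$units_per_arm
      ceil_c <- stats::rlnorm(n, ce$meanlog, ce$sdlog)
      ceil_t <- stats::rlnorm(n, ce$meanlog, ce$sdlog)
      base_c <- stats::rlnorm(n, ba$meanlog, ba$sdlog)
      base_t <- stats::rlnorm(n, ba$meanlog, ba$sdlog)
      yc <- pmin(base_c, ceil_c)
      yt <- pmin(base_t * gain, ceil_t)
      out[[i]] <- data.frame(
        publication_id = sprintf("ceil%03d", i),
        comparison_id = sprintf("ceil%03d_c1", i),
        effect_id = sprintf("ceil%03d_c1_e1", i),
        crop = "oilseed_rape", country = "synthetic", scale = "plant",
        response_measure = "yield_mass", treatment_type = "open",
        intensity = "none", year = 2000L,
        mean_t = mean(yt), disp_t = stats::sd(yt), n_t = n,
        mean_c = mean(yc), disp_c = stats::sd(yc), n_c = n,
        dispersion_kind = "SD",
        shared_control_id = sprintf("ceil%03d_ctl", i),
        gain = gain,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  gain_col <- df$gain
  df$gain <- NULL
  ds <- validate_yield_data(df, provenance = sprintf(
    "stabmeta ceiling generator, seed %d", cfg$seed))
  ds$gain <- gain_col[match(ds$effect_id, df$effect_id)]
  ds
}

#' Write a generated dataset as a CSV fixture
#'
#' Writes in the package schema with a schema-version comment line;
#' round-trips through [read_yield_data()] without loss of the schema
#' columns.
#'
#' @param ds dataset (e.g. from [generate_summary_dataset()]).
#' @param path output path.
#' @export
write_fixture <- function(ds, path) {
  write_yield_data(ds, path, header_note = "stabmeta dataset schema v1")
}
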