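#' @section Dataset schema:
#' One row per effect size (one treatment arm vs. one control arm), columns:
#' \code{publication_id}, \code{comparison_id}, \code{effect_id},
#' \code{crop}, \code{country}, \code{scale}, \code{response_measure},
#' \code{treatment_type}, \code{intensity}, \code{year},
#' \code{mean_t}, \code{disp_t}, \code{n_t},
#' \code{mean_c}, \code{disp_c}, \code{n_c},
#' \code{dispersion_kind} (\code{"SD"} or \code{"SE"}),
#' \code{shared_control_id}.
#' After loading, \code{disp_*} become \code{sd_*} (SE converted via
#' \code{sd = se * sqrt(n)}).
#' @name yield_data_schema
#' @keywords internal
NULL

REQUIRED_COLUMNS <- c(
  "publication_id", "comparison_id", "effect_id", "crop", "country",
  "scale", "response_measure", "treatment_type", "intensity", "year",
  "mean_t", "disp_t", "n_t", "mean_c", "disp_c", "n_c",
  "dispersion_kind", "shared_control_id")

#' Read and validate a pollination-experiment dataset
#'
#' Reads a CSV of two-arm experimental summaries (see
#' \link{yield_data_schema}), converts reported standard errors to
#' standard deviations (\code{sd = se * sqrt(n)}), validates every row and
#' drops rows that cannot enter ratio effect sizes. Validation messages
#' are collected in a report attached as an attribute.
#'
#' Rows are rejected when: an arm mean is non-positive, an arm has fewer
#' than 2 units, or an arm SD is negative. Rows with a zero SD in either
#' arm are excluded with a warning (log of zero is undefined for the ratio
#' measures). Rows sharing a \code{shared_control_id} must carry identical
#' control summaries; violations are a hard error.
#'
#' @param path CSV file (comma-separated, UTF-8, header row, decimal
#'   point).
#' @param merge_plot_cohort collapse "plot" and "cohort" scale labels into
#'   one level \code{"plot_or_cohort"} (default TRUE; the two describe
#'   equivalent aggregation units).
#' @return validated data.frame with attributes \code{validation}
#'   (list: counts per level, rejected effect_ids with reasons) and
#'   \code{provenance}.
#' @export
read_yield_data <- function(path, merge_plot_cohort = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#", fileEncoding = "UTF-8")
  validate_yield_data(raw, merge_plot_cohort = merge_plot_cohort,
                      provenance = path)
}

#' Validate an in-memory dataset
#'
#' Same checks and normalisation as [read_yield_data()], for data already
#' in a data.frame.
#'
#' @param raw data.frame with the schema columns.
#' @inheritParams read_yield_data
#' @param provenance free-text source note stored on the result.
#' @return validated data.frame; see [read_yield_data()].
#' @export
validate_yield_data <- function(raw, merge_plot_cohort = TRUE,
                                provenance = "in-memory") {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(raw$effect_id))
    stop("effect_id values must be unique", call. = FALSE)

  # nesting: an effect belongs to exactly one comparison and publication
  nest <- unique(raw[, c("publication_id", "comparison_id")])
  if (anyDuplicated(nest$comparison_id))
    stop("comparison_id values appear under more than one publication_id; ",
         "use publication-qualified comparison labels", call. = FALSE)

  df <- raw
  kind <- toupper(df$dispersion_kind)
  if (!all(kind %in% c("SD", "SE")))
    stop("dispersion_kind must be 'SD' or 'SE'", call. = FALSE)
  df$sd_t <- ifelse(kind == "SE", df$disp_t * sqrt(df$n_t), df$disp_t)
  df$sd_c <- ifelse(kind == "SE", df$disp_c * sqrt(df$n_c), df$disp_c)

  if (merge_plot_cohort)
    df$scale[df$scale %in% c("plot", "cohort")] <- "plot_or_cohort"

  reasons <- character(0); bad_ids <- character(0)
  flag <- function(mask, why) {
    if (any(mask)) {
      bad_ids <<- c(bad_ids, df$effect_id[mask])
      reasons <<- c(reasons, rep(why, sum(mask)))
    }
  }
  flag(df$mean_t <= 0 | df$mean_c <= 0, "non-positive arm mean")
  flag(df$n_t < 2 | df$n_c < 2, "arm n < 2")
  flag(df$sd_t < 0 | df$sd_c < 0, "negative arm SD")
  zero_sd <- df$sd_t == 0 | df$sd_c == 0
  zero_sd[df$effect_id %in% bad_ids] <- FALSE
  if (any(zero_sd)) {
    warning(sum(zero_sd), " row(s) with zero arm SD excluded (log of zero ",
            "undefined): ", paste(df$effect_id[zero_sd], collapse = ", "),
            call. = FALSE)
    flag(zero_sd, "zero arm SD")
  }

  keep <- !(df$effect_id %in% bad_ids)
  out <- df[keep, , drop = FALSE]

  # shared-control consistency on retained rows
  key <- paste(out$mean_c, out$sd_c, out$n_c)
  bad_sc <- tapply(key, out$shared_control_id,
                   function(k) length(unique(k)) > 1L)
  if (any(bad_sc))
    stop("rows sharing a control id report different control summaries: ",
         paste(names(bad_sc)[bad_sc], collapse = ", "), call. = FALSE)

  rownames(out) <- NULL
  attr(out, "validation") <- list(
    n_publications = length(unique(out$publication_id)),
    n_comparisons = length(unique(out$comparison_id)),
    n_effects = nrow(out),
    rejected = if (length(bad_ids))
      data.frame(effect_id = bad_ids, reason = reasons,
                 stringsAsFactors = FALSE)
      else data.frame(effect_id = character(0), reason = character(0)))
  attr(out, "provenance") <- provenance
  out
}

#' Counts per nesting level
#'
#' @param data validated dataset.
#' @return named list: \code{n_publications}, \code{n_comparisons},
#'   \code{n_effects}.
#' @export
dataset_counts <- function(data) {
  list(n_publications = length(unique(data$publication_id)),
       n_comparisons = length(unique(data$comparison_id)),
       n_effects = nrow(data))
}

#' Write a dataset back to CSV
#'
#' Writes the schema columns (not the derived \code{sd_*} columns) so that
#' a write/read round trip reproduces the dataset.
#'
#' @param data dataset in the package schema.
#' @param path output CSV path.
#' @param header_note optional comment line (prefixed \code{#}) stamped at
#'   the top, e.g. a schema version.
#' @export
write_yield_data <- function(data, path,
                             header_note = "stabmeta dataset schema v1") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_note)) writeLines(paste("#", header_note), con)
  utils::write.csv(data[, REQUIRED_COLUMNS, drop = FALSE], con,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Publication-level summary table
#'
#' One row per publication (and crop/scale combination within it): mean
#' lnCVR, mean lnRR across the publication's effect sizes, and the effect
#' count — the layout of a study-characteristics table.
#'
#' @param data validated dataset.
#' @return data.frame with columns \code{publication_id}, \code{crop},
#'   \code{country}, \code{scale}, \code{mean_lncvr}, \code{mean_lnrr},
#'   \code{n_effects}.
#' @export
summarize_publications <- function(data) {
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  cvr <- effect_sizes(data, "lnCVR")
  rr <- effect_sizes(data, "lnRR")
  key <- interaction(data$publication_id, data$crop, data$scale, drop = TRUE)
  idx <- split(seq_len(nrow(data)), key)
  rows <- lapply(idx, function(i) data.frame(
    publication_id = data$publication_id[i[1L]],
    crop = data$crop[i[1L]],
    country = data$country[i[1L]],
    scale = data$scale[i[1L]],
    mean_lncvr = mean(cvr$yi[i]),
    mean_lnrr = mean(rr$yi[i]),
    n_effects = length(i),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$publication_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
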