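# builders for small in-code fixtures

SCHEMA_COLS <- c(
  "publication_id", "comparison_id", "effect_id", "crop", "country",
  "scale", "response_measure", "treatment_type", "intensity", "year",
  "mean_t", "disp_t", "n_t", "mean_c", "disp_c", "n_c",
  "dispersion_kind", "shared_control_id")

# one schema row from explicit arm summaries
schema_row <- function(effect_id = "e1", publication_id = "p1",
                       comparison_id = paste0(publication_id, "_c1"),
                       mean_t = 20, sd_t = 2, n_t = 10,
                       mean_c = 10, sd_c = 1, n_c = 10,
                       crop = "apple", scale = "plant",
                       response_measure = "yield_mass",
                       treatment_type = "open", intensity = "none",
                       year = 2005, dispersion_kind = "SD",
                       shared_control_id = paste0(comparison_id, "_ctl"),
                       country = "testland") {
  data.frame(publication_id = publication_id,
             comparison_id = comparison_id, effect_id = effect_id,
             crop = crop, country = country, scale = scale,
             response_measure = response_measure,
             treatment_type = treatment_type, intensity = intensity,
             year = year, mean_t = mean_t, disp_t = sd_t, n_t = n_t,
             mean_c = mean_c, disp_c = sd_c, n_c = n_c,
             dispersion_kind = dispersion_kind,
             shared_control_id = shared_control_id,
             stringsAsFactors = FALSE)
}

# m independent single-effect records with given per-row treatment CVs
schema_rows <- function(cv_t, mean_t = 20, n = 10, mean_c = 10,
                        cv_c = 0.3, pub_prefix = "p") {
  m <- length(cv_t)
  do.call(rbind, lapply(seq_len(m), function(i)
    schema_row(effect_id = sprintf("%s%03d_e1", pub_prefix, i),
               publication_id = sprintf("%s%03d", pub_prefix, i),
               comparison_id = sprintf("%s%03d_c1", pub_prefix, i),
               mean_t = mean_t, sd_t = cv_t[i] * mean_t, n_t = n,
               mean_c = mean_c, sd_c = cv_c * mean_c, n_c = n)))
}

# dense, direct REML/ML log-likelihood used as an independent oracle:
# straight evaluation of the marginal normal likelihood with solve()
oracle_loglik <- function(y, X, V, method = "REML") {
  k <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  if (method == "ML")
    -0.5 * (k * log(2 * pi) + determinant(V)$modulus[1] + q)
  else
    -0.5 * ((k - p) * log(2 * pi) + determinant(V)$modulus[1] +
              determinant(XtViX)$modulus[1] + q)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
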