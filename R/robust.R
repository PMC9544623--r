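#' Cluster-robust (CR2) variance estimation
#'
#' Bias-reduced cluster-robust sandwich covariance of the fixed
#' coefficients with Satterthwaite degrees of freedom, for models where
#' sampling dependence within clusters is not fully captured by the
#' modelled covariance — notably arm-based ln(SD) analyses, where the two
#' arms of each comparison share experimental material. The CR2 adjustment
#' rescales each cluster's residuals so the meat of the sandwich is
#' unbiased when the working model (the fitted marginal covariance) is
#' correct.
#'
#' @param fit fitted [mlma()] model.
#' @param cluster clustering variable: a column name in the model data or
#'   a vector aligned with the fitted rows.
#' @param level coverage probability for the reported intervals.
#' @return object of class \code{"robust_mlma"}: list with
#'   \code{vcov} (robust covariance), \code{coefficients} table
#'   (estimate, se, df, tval, pval, ci.lb, ci.ub with t quantiles at the
#'   Satterthwaite df), \code{n_clusters}.
#' @export
robust <- function(fit, cluster, level = 0.95) {
  stopifnot(inherits(fit, "mlma"))
  if (is.character(cluster) && length(cluster) == 1L)
    cluster <- fit$data[[cluster]]
  cluster <- factor(cluster)
  if (length(cluster) != fit$k)
    stop("cluster length does not match fitted rows", call. = FALSE)
  m <- nlevels(cluster)
  if (m < 2L) stop("need at least 2 clusters", call. = FALSE)

  X <- fit$X
  p <- ncol(X)
  Vhat <- marginal_vcov(fit)
  W <- chol2inv(chol(Vhat))
  M <- chol2inv(chol(t(X) %*% W %*% X))
  H <- X %*% M %*% t(X) %*% W
  R <- diag(fit$k) - H
  e <- fit$residuals
  Bfull <- R %*% Vhat %*% t(R)
  WX_M <- W %*% X %*% M        # k x p

  idx_by <- split(seq_len(fit$k), cluster)
  meat <- matrix(0, p, p)
  Alist <- vector("list", m)
  for (j in seq_len(m)) {
    idx <- idx_by[[j]]
    Phi <- Vhat[idx, idx, drop = FALSE]
    B <- Bfull[idx, idx, drop = FALSE]
    Phih <- mat_sqrt(Phi)
    Mstar <- Phih$inv %*% B %*% Phih$inv
    A <- Phih$sqrt %*% mat_sqrt(Mstar)$inv %*% Phih$inv
    Alist[[j]] <- A
    ae <- drop(A %*% e[idx])
    s <- drop(t(X) %*% W[, idx, drop = FALSE] %*% ae)
    meat <- meat + tcrossprod(s)
  }
  Vr <- M %*% meat %*% M
  dimnames(Vr) <- dimnames(fit$vcov)

  # Satterthwaite df per coefficient from the model-implied distribution
  # of the variance estimator (quadratic form in the residuals)
  dfs <- numeric(p)
  for (l in seq_len(p)) {
    S <- matrix(0, fit$k, m)
    for (j in seq_len(m)) {
      idx <- idx_by[[j]]
      u <- drop(t(Alist[[j]]) %*% WX_M[idx, l])
      S[, j] <- drop(crossprod(R[idx, , drop = FALSE], u))
    }
    G <- t(S) %*% Vhat %*% S
    dfs[l] <- sum(diag(G))^2 / sum(G^2)
  }

  est <- fit$coefficients
  se <- sqrt(diag(Vr))
  tval <- est / se
  crit <- stats::qt(1 - (1 - level) / 2, dfs)
  tab <- data.frame(estimate = est, se = se, df = dfs, tval = tval,
                    pval = 2 * stats::pt(-abs(tval), dfs),
                    ci.lb = est - crit * se, ci.ub = est + crit * se)
  structure(list(vcov = Vr, coefficients = tab, n_clusters = m,
                 level = level),
            class = "robust_mlma")
}

#' @export
print.robust_mlma <- function(x, digits = 4, ...) {
  cat("Cluster-robust (CR2) inference,", x$n_clusters, "clusters\n\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

# symmetric square root and its (pseudo-)inverse, by eigendecomposition
mat_sqrt <- function(A, tol = 1e-12) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- eg$values > tol * max(abs(eg$values))
  d <- sqrt(pmax(eg$values, 0))
  dinv <- ifelse(pos, 1 / d, 0)
  U <- eg$vectors
  list(sqrt = U %*% (d * t(U)), inv = U %*% (dinv * t(U)))
}
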