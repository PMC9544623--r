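#' Fit a multilevel meta-analytic model
#'
#' Fits the marginal model \eqn{y \sim N(X\beta, V)} with
#' \eqn{V = V_s + \sum_l \sigma^2_l Z_l Z_l'}, where \eqn{V_s} is the
#' known sampling variance-covariance matrix of the effect sizes
#' (diagonal, or with shared-control covariance blocks) and each random
#' level \eqn{l} contributes an independent normal intercept per group.
#' Variance components are estimated by restricted maximum likelihood
#' (REML, the default, for reported estimates) or maximum likelihood (ML,
#' required for likelihood-ratio tests of moderators); fixed effects by
#' generalised least squares at the variance-component estimates.
#'
#' Random levels must be nested (e.g. publication / comparison / effect
#' size); nesting is enforced internally by building compound group
#' labels, so a comparison label reused across publications is treated as
#' distinct groups. The innermost level is usually one group per row and
#' captures residual heterogeneity.
#'
#' Optimisation is over \eqn{\log \sigma^2_l} with a floor of 1e-10
#' (effective zero) using bounded L-BFGS-B with an analytic gradient,
#' multi-started from \{0.1, 1, 10\} times the mean sampling variance;
#' the best converged start is kept, making the fit deterministic given
#' its inputs.
#'
#' @param formula model formula, response on the left and moderators on
#'   the right, e.g. \code{yi ~ 1}, \code{yi ~ 0 + crop}, or
#'   \code{ln_sd ~ condition + offset(ln_mean)} (an offset fixes a
#'   coefficient at 1).
#' @param data data.frame holding all model variables.
#' @param vi sampling variances: a column name (character) or numeric
#'   vector. Ignored when \code{V} is given.
#' @param V full sampling variance-covariance matrix (see
#'   [build_vcv()]); rows must match \code{data}.
#' @param random character vector of grouping columns, outermost first,
#'   e.g. \code{c("publication_id", "comparison_id", "effect_id")}; NULL
#'   for a fixed-effects (GLS) model with all variance components 0.
#' @param method \code{"REML"} or \code{"ML"}.
#' @param control list: \code{starts} (multiplier vector for multi-start,
#'   default \code{c(0.1, 1, 10)}), \code{factr} (L-BFGS-B tolerance,
#'   default 1e7), \code{floor} (variance floor, default 1e-10).
#' @return object of class \code{"mlma"}; see [summary.mlma()],
#'   [predict.mlma()], [anova.mlma()], [robust()], [heterogeneity()].
#' @export
#' @examples
#' d <- data.frame(yi = c(-0.2, -0.5, -0.3, -0.6),
#'                 vi = c(0.05, 0.04, 0.06, 0.05),
#'                 pub = c("a", "a", "b", "b"))
#' fit <- mlma(yi ~ 1, data = d, vi = "vi", random = c("pub"))
#' summary(fit)
mlma <- function(formula, data, vi = NULL, V = NULL,
                 random = c("publication_id", "comparison_id", "effect_id"),
                 method = c("REML", "ML"), control = list()) {
  method <- match.arg(method)
  cl <- match.call()
  ctrl <- utils::modifyList(
    list(starts = c(0.1, 1, 10), factr = 1e7, floor = 1e-10), control)

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  if (!is.null(random))
    keep <- keep & stats::complete.cases(data[, random, drop = FALSE])
  mf <- mf[keep, , drop = FALSE]
  k <- nrow(mf)
  if (k < 1L) stop("no complete rows to fit", call. = FALSE)

  y <- stats::model.response(mf)
  off <- stats::model.offset(mf)
  if (is.null(off)) off <- rep(0, k)
  X <- stats::model.matrix(stats::terms(mf), mf)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  if (is.null(V)) {
    if (is.null(vi)) stop("supply vi or V", call. = FALSE)
    if (is.character(vi)) vi <- data[[vi]]
    vi <- vi[keep]
    if (any(!is.finite(vi)) || any(vi <= 0))
      stop("sampling variances must be finite and > 0", call. = FALSE)
    Vs <- diag(vi, nrow = k)
  } else {
    Vs <- V[keep, keep, drop = FALSE]
    if (nrow(Vs) != k) stop("V dimension does not match data", call. = FALSE)
  }

  # nested compound grouping factors, outermost first
  groups <- list()
  if (!is.null(random) && length(random)) {
    lab <- NULL
    for (nm in random) {
      lab <- if (is.null(lab)) as.character(data[[nm]][keep])
             else paste(lab, data[[nm]][keep], sep = "\r")
      groups[[nm]] <- factor(lab)
    }
  }

  blocks <- independent_blocks(Vs, groups)
  bd <- precompute_blocks(Vs, X, y - off, groups, blocks)

  nsig <- length(groups)
  if (nsig == 0L) {
    lk <- loglik_eval(bd, numeric(0), method)
    sigma2 <- numeric(0)
    opt <- list(convergence = 0L)
    converged <- TRUE
    ll <- lk$ll
    beta <- lk$beta; M <- lk$M
  } else {
    vbar <- mean(diag(Vs))
    lower <- rep(log(ctrl$floor), nsig)
    upper <- rep(log(1e7 * max(vbar, ctrl$floor)), nsig)
    runs <- list()
    for (s in ctrl$starts) {
      par0 <- pmin(pmax(rep(log(s * vbar), nsig), lower), upper)
      o <- try(stats::optim(par0,
                            fn = function(th) neg2ll(bd, th, method),
                            gr = function(th) neg2ll_grad(bd, th, method),
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = ctrl$factr)),
               silent = TRUE)
      if (!inherits(o, "try-error")) runs[[length(runs) + 1L]] <- o
    }
    if (!length(runs))
      stop("variance-component optimisation failed from every start",
           call. = FALSE)
    vals <- vapply(runs, `[[`, numeric(1), "value")
    ok <- vapply(runs, function(o) o$convergence == 0L, logical(1))
    # a non-converged start only wins if it beats every converged one
    # by more than the objective tolerance
    best <- if (any(ok) &&
                min(vals[ok]) <= min(vals) + 1e-6) {
      runs[ok][[which.min(vals[ok])]]
    } else runs[[which.min(vals)]]
    if (best$convergence != 0L) {
      # L-BFGS-B sometimes stops with code 52 when the line search cannot
      # improve further; accept if the projected gradient has vanished
      g <- neg2ll_grad(bd, best$par, method)
      g[best$par <= lower + 1e-8 & g > 0] <- 0
      g[best$par >= upper - 1e-8 & g < 0] <- 0
      if (max(abs(g)) < 1e-3) best$convergence <- 0L
    }
    opt <- best
    converged <- best$convergence == 0L
    if (!converged)
      warning("optimiser did not report convergence (code ",
              best$convergence, ")", call. = FALSE)
    sigma2 <- exp(best$par)
    sigma2[sigma2 <= ctrl$floor * (1 + 1e-6)] <- 0
    names(sigma2) <- names(groups)
    lk <- loglik_eval(bd, log(pmax(sigma2, ctrl$floor)), method)
    ll <- lk$ll
    beta <- lk$beta; M <- lk$M
  }

  names(beta) <- colnames(X)
  dimnames(M) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% beta) + off

  structure(list(
    coefficients = beta, vcov = M, sigma2 = sigma2,
    logLik = ll, method = method, k = k, p = p,
    X = X, y = y, offset = off, Vs = Vs, groups = groups,
    fitted.values = fitted, residuals = y - fitted,
    converged = converged, optim = opt, call = cl,
    formula = formula, rows = which(keep),
    data = data[keep, , drop = FALSE]),
    class = "mlma")
}

# partition rows into independent blocks: rows are linked when they share
# any random-level group or a nonzero sampling covariance
independent_blocks <- function(Vs, groups) {
  k <- nrow(Vs)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (g in groups) {
    for (idx in split(seq_len(k), g)) {
      if (length(idx) > 1L) for (j in idx[-1L]) union2(idx[1L], j)
    }
  }
  nz <- which(Vs != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1L] < nz[, 2L], , drop = FALSE]
  if (nrow(nz)) for (r in seq_len(nrow(nz))) union2(nz[r, 1L], nz[r, 2L])
  roots <- vapply(seq_len(k), find, integer(1))
  unname(split(seq_len(k), roots))
}

# per-block quantities reused across objective evaluations
precompute_blocks <- function(Vs, X, y, groups, blocks) {
  bl <- lapply(blocks, function(idx) {
    gidx <- lapply(groups, function(g) {
      sp <- split(seq_along(idx), droplevels(g[idx]))
      sp[lengths(sp) > 0L]
    })
    list(idx = idx, Vs = Vs[idx, idx, drop = FALSE],
         X = X[idx, , drop = FALSE], y = y[idx], gidx = gidx)
  })
  list(blocks = bl, k = nrow(X), p = ncol(X), nsig = length(groups))
}

block_V <- function(b, sigma2) {
  M <- b$Vs
  for (l in seq_along(sigma2)) {
    s2 <- sigma2[l]
    if (s2 == 0) next
    for (idx in b$gidx[[l]]) M[idx, idx] <- M[idx, idx] + s2
  }
  M
}

# profile log-likelihood (beta profiled by GLS) and GLS pieces
loglik_eval <- function(bd, theta, method, pieces = FALSE) {
  sigma2 <- exp(theta)
  p <- bd$p
  XtX <- matrix(0, p, p); Xty <- numeric(p)
  yty <- 0; logdet <- 0
  store <- if (pieces) vector("list", length(bd$blocks))
  for (i in seq_along(bd$blocks)) {
    b <- bd$blocks[[i]]
    Vb <- block_V(b, sigma2)
    L <- chol(Vb)
    logdet <- logdet + 2 * sum(log(diag(L)))
    Xw <- backsolve(L, b$X, transpose = TRUE)
    yw <- backsolve(L, b$y, transpose = TRUE)
    XtX <- XtX + crossprod(Xw)
    Xty <- Xty + drop(crossprod(Xw, yw))
    yty <- yty + sum(yw^2)
    if (pieces) store[[i]] <- list(L = L)
  }
  M <- chol2inv(chol(XtX))
  beta <- drop(M %*% Xty)
  q <- yty - sum(beta * Xty)
  k <- bd$k
  ll <- if (method == "ML") {
    -0.5 * (k * log(2 * pi) + logdet + q)
  } else {
    -0.5 * ((k - p) * log(2 * pi) + logdet +
              determinant(XtX, logarithm = TRUE)$modulus[1] + q)
  }
  list(ll = ll, beta = beta, M = M, XtX = XtX, store = store)
}

neg2ll <- function(bd, theta, method) -2 * loglik_eval(bd, theta, method)$ll

# analytic gradient of -2*loglik w.r.t. theta = log(sigma2)
neg2ll_grad <- function(bd, theta, method) {
  sigma2 <- exp(theta)
  nsig <- bd$nsig
  p <- bd$p
  lk <- loglik_eval(bd, theta, method)
  beta <- lk$beta; M <- lk$M
  trVG <- numeric(nsig)          # tr(V^-1 G_l)
  quad <- numeric(nsig)          # r' V^-1 G_l V^-1 r
  XGX <- vector("list", nsig)    # X' V^-1 G_l V^-1 X
  for (l in seq_len(nsig)) XGX[[l]] <- matrix(0, p, p)
  for (b in bd$blocks) {
    Vb <- block_V(b, sigma2)
    L <- chol(Vb)
    Vinv <- chol2inv(L)
    r <- b$y - drop(b$X %*% beta)
    w <- drop(Vinv %*% r)
    C <- Vinv %*% b$X
    for (l in seq_len(nsig)) {
      for (idx in b$gidx[[l]]) {
        trVG[l] <- trVG[l] + sum(Vinv[idx, idx])
        quad[l] <- quad[l] + sum(w[idx])^2
        S <- colSums(C[idx, , drop = FALSE])
        XGX[[l]] <- XGX[[l]] + tcrossprod(S)
      }
    }
  }
  g <- numeric(nsig)
  for (l in seq_len(nsig)) {
    tr_term <- if (method == "ML") trVG[l]
               else trVG[l] - sum(M * XGX[[l]])
    g[l] <- (tr_term - quad[l]) * sigma2[l]
  }
  g
}

# assemble the full fitted marginal covariance matrix V-hat
marginal_vcov <- function(object) {
  V <- object$Vs
  for (l in seq_along(object$sigma2)) {
    s2 <- object$sigma2[l]
    if (s2 == 0) next
    g <- object$groups[[l]]
    for (idx in split(seq_len(object$k), g))
      if (length(idx)) V[idx, idx] <- V[idx, idx] + s2
  }
  V
}
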