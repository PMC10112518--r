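#' Multi-kernel linear mixed model fit by REML
#'
#' Fits `y = X beta + sum_k Z_k u_k + e` with `u_k ~ N(0, K_k sigma2_k)` and
#' `e ~ N(0, I sigma2_e)` by direct numerical maximization of the restricted
#' log-likelihood over log variance components (Nelder-Mead with a polishing
#' restart; convergence when the restricted log-likelihood changes by less
#' than `tol`). Fixed effects (BLUEs) and random-effect predictions (BLUPs)
#' at the optimum are recovered from the generalized-least-squares equations,
#' which is equivalent to solving Henderson's mixed-model equations.
#'
#' Each random term is a list with elements `Z` (incidence matrix,
#' observations x levels; `NULL` means identity, requiring as many levels as
#' observations) and `K` (level covariance; `NULL` means identity). Kernels
#' are symmetrized and, when indefinite beyond `-1e-8`, bent by eigenvalue
#' clipping with a warning; a ridge of `1e-8` on the kernel diagonal keeps
#' singular kernels usable for prediction.
#'
#' Aliased columns of `X` are dropped with a warning. Variance components are
#' floored at `1e-8 * var(y)`.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (defaults to an intercept).
#' @param random named list of random terms (see Details).
#' @param fix_varcomp optional named numeric of variance components to hold
#'   fixed; names are random-term names or `"residual"`.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter maximum optimizer iterations per start.
#' @param bend_kernels check each kernel's smallest eigenvalue and bend when
#'   indefinite (default). Callers passing kernels that are positive
#'   semidefinite by construction (cross-product relationship matrices) may
#'   disable the check; the stabilizing diagonal ridge is applied either way.
#' @return an object of class `mm_fit`: `beta` (named, `NA` for aliased
#'   columns), `u` (list of per-term BLUP vectors), `varcomp` (named, includes
#'   `residual`), `reml_loglik`, `converged`, `n_iter`, plus internal state
#'   used by [predict_masked()].
#' @examples
#' set.seed(1)
#' y <- rnorm(40) + rep(rnorm(8), each = 5)
#' Z <- model.matrix(~ 0 + factor(rep(1:8, each = 5)))
#' fit <- fit_reml(y, random = list(group = list(Z = Z, K = NULL)))
#' fit$varcomp
#' @export
fit_reml <- function(y, X = NULL, random = list(), fix_varcomp = NULL,
                     tol = 1e-6, max_iter = 1000, bend_kernels = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) stop("need at least 2 observations")
  if (any(!is.finite(y))) stop("response must be finite")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) != n) stop("X must have one row per observation")

  # drop aliased fixed-effect columns
  qrX <- qr(X)
  keep_x <- qrX$pivot[seq_len(qrX$rank)]
  aliased <- setdiff(seq_len(ncol(X)), keep_x)
  if (length(aliased)) {
    warning(sprintf("dropping %d aliased fixed-effect column(s): %s",
                    length(aliased),
                    paste(colnames(X)[aliased], collapse = ", ")))
  }
  Xu <- X[, sort(keep_x), drop = FALSE]
  p <- ncol(Xu)

  if (length(random) && is.null(names(random)))
    names(random) <- paste0("K", seq_along(random))
  terms <- lapply(seq_along(random), function(k) {
    tm <- random[[k]]
    Z <- tm$Z
    K <- tm$K
    if (!is.null(K)) K <- as.matrix(K)
    if (is.null(Z)) {
      q <- if (is.null(K)) n else nrow(K)
      if (q != n) stop("identity incidence requires one level per observation")
      Z <- NULL                         # treated as identity
    } else {
      Z <- as.matrix(Z)
      if (nrow(Z) != n) stop("incidence matrix must have one row per observation")
    }
    if (!is.null(K)) {
      if (nrow(K) != ncol(K)) stop("kernel must be square")
      K <- (K + t(K)) / 2
      ev_min <- if (bend_kernels)
        min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) else 0
      if (ev_min < -1e-8) {
        warning(sprintf("bending indefinite kernel '%s' (min eigenvalue %.3g)",
                        names(random)[k], ev_min))
        ed <- eigen(K, symmetric = TRUE)
        K <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
        K <- (K + t(K)) / 2
      }
      diag(K) <- diag(K) + 1e-8
    }
    # observation-level covariance contribution ZKZ'
    V <- if (is.null(Z) && is.null(K)) diag(n)
         else if (is.null(Z)) K
         else if (is.null(K)) tcrossprod(Z)
         else Z %*% tcrossprod(K, Z)
    list(name = names(random)[k], Z = Z, K = K, V = (V + t(V)) / 2)
  })
  names(terms) <- names(random)
  k_terms <- length(terms)

  vy <- var(y)
  if (vy == 0) vy <- 1
  floor_v <- 1e-8 * vy
  par_names <- c(names(terms), "residual")
  fixed_mask <- rep(FALSE, k_terms + 1L)
  fixed_val <- rep(NA_real_, k_terms + 1L)
  if (!is.null(fix_varcomp)) {
    bad <- setdiff(names(fix_varcomp), par_names)
    if (length(bad)) stop("unknown variance component(s): ",
                          paste(bad, collapse = ", "))
    ix <- match(names(fix_varcomp), par_names)
    fixed_mask[ix] <- TRUE
    fixed_val[ix] <- pmax(as.numeric(fix_varcomp), floor_v)
  }

  neg2_reml <- function(sig2) {
    V <- diag(sig2[k_terms + 1L], n)
    for (k in seq_len(k_terms)) V <- V + sig2[k] * terms[[k]]$V
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    A <- backsolve(cV, cbind(Xu, y), transpose = TRUE)
    Ax <- A[, seq_len(p), drop = FALSE]
    Ay <- A[, p + 1L]
    XtViX <- crossprod(Ax)
    XtViy <- crossprod(Ax, Ay)[, 1L]
    cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cXtViX)) return(1e10)
    beta <- backsolve(cXtViX, backsolve(cXtViX, XtViy, transpose = TRUE))
    yPy <- sum(Ay^2) - sum(XtViy * beta)
    2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXtViX))) + yPy
  }

  full_sig2 <- function(theta_free) {
    s <- fixed_val
    s[!fixed_mask] <- exp(theta_free)
    pmax(s, floor_v)
  }
  obj <- function(theta_free) neg2_reml(full_sig2(theta_free))

  n_free <- sum(!fixed_mask)
  n_iter <- 0L
  converged <- TRUE
  if (n_free > 0) {
    start <- log(rep(vy / (k_terms + 1L), n_free))
    if (n_free == 1L) {
      op <- optim(start, obj, method = "Brent",
                  lower = log(floor_v), upper = log(1e4 * vy),
                  control = list(maxit = max_iter))
      n_iter <- 1L
      theta <- op$par
      val <- op$value
    } else {
      op <- optim(start, obj, method = "Nelder-Mead",
                  control = list(maxit = max_iter, reltol = 1e-13))
      # polish from the first optimum; accept only non-increasing values
      op2 <- optim(op$par, obj, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-13))
      theta <- if (op2$value <= op$value) op2$par else op$par
      val <- min(op$value, op2$value)
      n_iter <- op$counts[1L] + op2$counts[1L]
      converged <- abs(op$value - op2$value) < tol
    }
    sig2 <- full_sig2(theta)
  } else {
    sig2 <- full_sig2(numeric(0))
    val <- neg2_reml(sig2)
  }

  # solution at the optimum
  V <- diag(sig2[k_terms + 1L], n)
  for (k in seq_len(k_terms)) V <- V + sig2[k] * terms[[k]]$V
  cV <- chol(V)
  A <- backsolve(cV, cbind(Xu, y), transpose = TRUE)
  Ax <- A[, seq_len(p), drop = FALSE]
  Ay <- A[, p + 1L]
  XtViX <- crossprod(Ax)
  beta_u <- solve(XtViX, crossprod(Ax, Ay)[, 1L])
  resid <- y - Xu %*% beta_u
  Vi_r <- backsolve(cV, backsolve(cV, resid, transpose = TRUE))[, 1L]
  u <- lapply(seq_len(k_terms), function(k) {
    tm <- terms[[k]]
    ZtVir <- if (is.null(tm$Z)) Vi_r else crossprod(tm$Z, Vi_r)[, 1L]
    uk <- if (is.null(tm$K)) sig2[k] * ZtVir
          else sig2[k] * (tm$K %*% ZtVir)[, 1L]
    if (!is.null(tm$K) && !is.null(rownames(tm$K))) names(uk) <- rownames(tm$K)
    else if (!is.null(tm$Z) && !is.null(colnames(tm$Z))) names(uk) <- colnames(tm$Z)
    uk
  })
  names(u) <- names(terms)

  beta <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  beta[sort(keep_x)] <- beta_u

  structure(list(
    beta = beta, u = u,
    varcomp = setNames(sig2, par_names),
    reml_loglik = -0.5 * (val + (n - p) * log(2 * pi)),
    converged = converged, n_iter = as.integer(n_iter),
    terms = terms, Vi_r = Vi_r, X_kept = sort(keep_x), n_obs = n),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("mm_fit:", x$n_obs, "observations,", length(x$u), "random term(s)\n")
  cat("variance components:\n")
  print(round(x$varcomp, 6))
  cat(sprintf("REML log-likelihood %.4f (converged: %s)\n",
              x$reml_loglik, x$converged))
  invisible(x)
}

#' Predict genetic values of masked observations
#'
#' Fits the model on the unmasked observations only, then predicts every
#' random-term level (including levels observed nowhere in the training set)
#' from the kernel covariance between masked and observed units at the fitted
#' variance components: `u_hat_k = sigma2_k K_k Z_k' V^{-1} (y - X beta)`
#' evaluated on the training rows. The prediction for a masked observation is
#' the sum of its random-term predictions plus the contributions of any fixed
#' columns named in `fixed_keep` (covariates, such as mutation-load counts,
#' that are known for masked units). Levels connected to the training set
#' only through an identity kernel predict as 0 — no information flows
#' without covariance.
#'
#' @param y,X,random as in [fit_reml()]; rows cover all observations, masked
#'   ones included (masked `y` entries are ignored).
#' @param masked integer or logical index of the masked observations.
#' @param fixed_keep character vector of `X` column names whose fixed-effect
#'   contribution is added to the prediction (default none).
#' @param ... passed to [fit_reml()].
#' @return list with `pred` (named numeric, one value per masked observation)
#'   and `fit` (the training [fit_reml()] object).
#' @export
predict_masked <- function(y, X = NULL, random = list(), masked,
                           fixed_keep = character(0), ...) {
  n <- length(y)
  if (is.logical(masked)) masked <- which(masked)
  if (!length(masked)) stop("no masked observations given")
  if (min(masked) < 1 || max(masked) > n) stop("masked index out of range")
  obs <- setdiff(seq_len(n), masked)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  rnd_obs <- lapply(random, function(tm) {
    Z <- tm$Z
    if (is.null(Z)) {
      q <- if (is.null(tm$K)) n else nrow(tm$K)
      if (q != n) stop("identity incidence requires one level per observation; ",
                       "supply Z explicitly for kernel '", tm$name, "'")
      Z <- diag(n)
    }
    list(Z = Z[obs, , drop = FALSE], K = tm$K)
  })
  names(rnd_obs) <- names(random)
  fit <- fit_reml(y[obs], X[obs, , drop = FALSE], rnd_obs, ...)

  # per-term predictions at every level, via kernel cross-covariance
  u_all <- lapply(seq_along(rnd_obs), function(k) {
    tm <- rnd_obs[[k]]
    ZtVir <- crossprod(tm$Z, fit$Vi_r)[, 1L]
    s2 <- fit$varcomp[k]
    if (is.null(tm$K)) s2 * ZtVir else s2 * (tm$K %*% ZtVir)[, 1L]
  })
  pred <- rep(0, length(masked))
  for (k in seq_along(random)) {
    Zm <- random[[k]]$Z
    Zm <- if (is.null(Zm)) diag(n)[masked, , drop = FALSE]
          else as.matrix(Zm)[masked, , drop = FALSE]
    pred <- pred + (Zm %*% u_all[[k]])[, 1L]
  }
  if (length(fixed_keep)) {
    miss <- setdiff(fixed_keep, colnames(X))
    if (length(miss)) stop("fixed_keep names not in X: ",
                           paste(miss, collapse = ", "))
    b <- fit$beta[fixed_keep]
    b[is.na(b)] <- 0       # aliased columns contribute nothing
    pred <- pred + (X[masked, fixed_keep, drop = FALSE] %*% b)[, 1L]
  }
  names(pred) <- if (!is.null(rownames(X))) rownames(X)[masked] else masked
  list(pred = pred, fit = fit)
}
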