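#' REML fit of the kinship mixed model
#'
#' Fits `y = X b + g + e` with `var(y) = sigma_g^2 K + sigma_e^2 I` by
#' restricted maximum likelihood. The kinship matrix is eigendecomposed once;
#' the restricted likelihood is profiled over the variance ratio
#' `delta = sigma_e^2 / sigma_g^2` on a log-spaced grid (default 100 points
#' on `[1e-5, 1e5]`), then refined by Brent optimization around the best grid
#' point. Ties on the grid break toward the smaller delta. Pseudo-
#' heritability is `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) = 1/(1+delta)`
#' (the IBS kinship has unit diagonal).
#'
#' @param y numeric phenotype vector (complete).
#' @param covariates optional numeric matrix of fixed covariates; an
#'   intercept is always included.
#' @param K kinship matrix (symmetrized internally; eigenvalues clipped at 0).
#' @param n_grid,delta_bounds profile-grid resolution and bounds.
#' @param eigen_K optional precomputed eigensystem of K (list with `values`,
#'   `vectors`), to avoid repeating the decomposition across fits on the
#'   same kinship.
#' @return object of class `null_model_fit`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `h2`, `reml_loglik`, `boundary` flag, plus the cached eigensystem and
#'   rotated responses used by the association scan.
#' @export
reml_fit <- function(y, covariates = NULL, K,
                     n_grid = 100L, delta_bounds = c(1e-5, 1e5),
                     eigen_K = NULL) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("collinear covariates")

  if (is.null(eigen_K)) {
    stopifnot(all(dim(K) == c(n, n)))
    eigen_K <- eigen((K + t(K)) / 2, symmetric = TRUE)
  }
  lam <- pmax(eigen_K$values, 0)
  U <- eigen_K$vectors
  ys <- as.numeric(crossprod(U, y))
  Xs <- crossprod(U, X)
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  # profiled restricted log-likelihood at a given delta
  rll <- function(delta) {
    w <- 1 / (lam + delta)
    XtWX <- crossprod(Xs, Xs * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, w * ys)))
    r <- ys - Xs %*% beta
    rwr <- sum(w * r^2)
    if (!is.finite(rwr) || rwr <= 0) return(-Inf)
    sg2 <- rwr / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) +
              sum(log(lam + delta)) + 2 * sum(log(diag(ch))) - ldXX)
  }

  grid <- exp(seq(log(delta_bounds[1]), log(delta_bounds[2]),
                  length.out = n_grid))
  ll_grid <- vapply(grid, rll, numeric(1))
  if (!any(is.finite(ll_grid))) stop("restricted likelihood non-finite everywhere")
  i <- which.max(ll_grid)  # first max: ties break toward smaller delta
  lo <- if (i > 1L) grid[i - 1L] else grid[1L]
  hi <- if (i < n_grid) grid[i + 1L] else grid[n_grid]
  opt <- stats::optimize(function(ld) rll(exp(ld)), c(log(lo), log(hi)),
                         maximum = TRUE, tol = 1e-8)
  delta <- if (opt$objective >= ll_grid[i]) exp(opt$maximum) else grid[i]
  ll <- max(opt$objective, ll_grid[i])

  w <- 1 / (lam + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, w * ys))
  r <- ys - Xs %*% beta
  sg2 <- sum(w * r^2) / (n - p)
  se2 <- delta * sg2
  boundary <- delta <= delta_bounds[1] * 1.0001 ||
    delta >= delta_bounds[2] * 0.9999

  structure(list(sigma_g2 = sg2, sigma_e2 = se2, delta = delta,
                 h2 = 1 / (1 + delta), reml_loglik = ll,
                 boundary = boundary, beta = as.numeric(beta),
                 eigenvalues = lam, U = U, ys = ys, Xs = Xs, n = n, p = p),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(
    "REML kinship model: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f%s (logLik %.2f)\n",
    x$sigma_g2, x$sigma_e2, x$h2, if (x$boundary) " [boundary]" else "",
    x$reml_loglik))
  invisible(x)
}

#' SNP-heritability of a phenotype
#'
#' Pseudo-heritability from an intercept-only REML fit of the kinship mixed
#' model; invariant to rescaling of `y`.
#'
#' @inheritParams reml_fit
#' @return fraction in `[0, 1]`.
#' @export
snp_heritability <- function(y, K) {
  reml_fit(y, covariates = NULL, K = K)$h2
}
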