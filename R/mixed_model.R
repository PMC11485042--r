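# Shared kinship variance-model machinery.
#
# The trait model is y = Xb + g + e with g ~ N(0, sg2 * 2K) and e ~ N(0, se2 I),
# so V = sg2 * 2K + se2 * I. The variance components are fit ONCE per trait by
# profile REML over the heritability ratio (EMMA-style, via the eigen
# decomposition of 2K), and every downstream test reuses the resulting
# whitening transform. With K = 0 (or NULL) the model collapses exactly to OLS.

#' Fit the trait variance model under kinship
#'
#' Restricted maximum likelihood for `V = sg2 * 2K + se2 * I` using a 1-D grid
#' plus golden-section refinement over `h2 = sg2 / (sg2 + se2)`. Non-PSD
#' kinship eigenvalues are clipped at zero with a warning.
#'
#' @param y Numeric trait (residual) vector.
#' @param K Kinship matrix (n x n, symmetric; self-kinship on the diagonal,
#'   e.g. 0.5), or NULL / all-zero for unrelated samples.
#' @param X Fixed-effect design for the REML fit (default intercept only).
#' @return Object of class `"variance_model"`: list with `sg2`, `se2`, `h2`,
#'   `U`, `d` (eigenvectors / eigenvalues of 2K), `vinv_diag_rot` (1/(sg2*d +
#'   se2)), and `whiten(M)` returning `V^{-1/2} M` in the rotated basis.
#' @export
fit_variance_model <- function(y, K = NULL, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (is.null(K) || max(abs(K)) < 1e-12) {
    vm <- list(sg2 = 0, se2 = as.numeric(var(y)), h2 = 0,
               U = NULL, d = rep(0, n), n = n)
    class(vm) <- "variance_model"
    return(vm)
  }
  K <- as.matrix(K)
  if (nrow(K) != n || ncol(K) != n) stop("kinship dimension mismatch")
  K <- (K + t(K)) / 2
  eg <- eigen(2 * K, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-8 * max(abs(d))) {
    warning("kinship matrix not PSD; clipping negative eigenvalues at 0")
  }
  d <- pmax(d, 0)
  U <- eg$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)

  # profile REML log-likelihood at heritability h2
  reml_ll <- function(h2) {
    w <- h2 * d + (1 - h2)            # V/(sg2+se2) eigenvalues
    wi <- 1 / w
    XtWX <- crossprod(Xr, Xr * wi)
    XtWy <- crossprod(Xr, yr * wi)
    b <- solve(XtWX, XtWy)
    r <- yr - Xr %*% b
    rss <- sum(r^2 * wi)
    q <- ncol(X)
    s2 <- rss / (n - q)
    -0.5 * ((n - q) * log(s2) + sum(log(w)) + determinant(XtWX)$modulus[1] + (n - q))
  }
  grid <- seq(0.01, 0.99, by = 0.02)
  ll <- vapply(grid, reml_ll, numeric(1))
  # include boundary h2 -> 0 (OLS)
  ll0 <- reml_ll(1e-6)
  if (max(ll) <= ll0) {
    h2 <- 0
  } else {
    j <- which.max(ll)
    lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
    h2 <- optimize(reml_ll, interval = c(lo, hi), maximum = TRUE)$maximum
  }
  w <- h2 * d + (1 - h2)
  wi <- 1 / w
  XtWX <- crossprod(Xr, Xr * wi)
  b <- solve(XtWX, crossprod(Xr, yr * wi))
  r <- yr - Xr %*% b
  s2tot <- sum(r^2 * wi) / (n - ncol(X))
  vm <- list(sg2 = h2 * s2tot, se2 = (1 - h2) * s2tot, h2 = h2,
             U = U, d = d, n = n)
  class(vm) <- "variance_model"
  vm
}

# V^{-1/2} M (rotated basis). For K = 0 this is M / sqrt(se2).
whiten <- function(vm, M) {
  M <- as.matrix(M)
  v <- vm$sg2 * vm$d + vm$se2
  if (is.null(vm$U)) return(M / sqrt(vm$se2))
  crossprod(vm$U, M) / sqrt(v)
}

# V^{-1} M
vinv <- function(vm, M) {
  M <- as.matrix(M)
  v <- vm$sg2 * vm$d + vm$se2
  if (is.null(vm$U)) return(M / vm$se2)
  vm$U %*% (crossprod(vm$U, M) / v)
}

#' Generalized least squares slope test under a fitted variance model
#'
#' Tests the slope of `y` on each column of `G` (plus an intercept) under
#' `V` from [fit_variance_model()]. With `K = 0` this is exactly the OLS
#' slope t-test.
#'
#' @param y Response vector.
#' @param G Predictor matrix (n x m), one test per column.
#' @param vm A `"variance_model"`.
#' @return data.frame with columns `beta`, `se`, `p` (two-sided t, df = n-2).
#' @export
gls_slope_test <- function(y, G, vm) {
  G <- as.matrix(G)
  n <- length(y)
  yw <- as.numeric(whiten(vm, y))
  Gw <- whiten(vm, G)
  onew <- as.numeric(whiten(vm, rep(1, n)))
  s11 <- sum(onew^2)
  s1y <- sum(onew * yw)
  s1g <- as.numeric(crossprod(Gw, onew))
  sgg <- colSums(Gw^2)
  sgy <- as.numeric(crossprod(Gw, yw))
  syy <- sum(yw^2)
  # slope of weighted regression with intercept
  den <- sgg - s1g^2 / s11
  beta <- (sgy - s1g * s1y / s11) / den
  rss <- syy - s1y^2 / s11 - beta^2 * den
  df <- n - 2
  sigma2 <- rss / df
  se <- sqrt(sigma2 / den)
  tval <- beta / se
  data.frame(beta = beta, se = se,
             p = 2 * stats::pt(-abs(tval), df = df))
}
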