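#' Residualize a response on a covariate matrix
#'
#' Ordinary least squares residuals of `y` on `X` (an intercept column is
#' added when absent). Collinear columns are dropped with a warning via a
#' rank-revealing QR.
#'
#' @param y Numeric response vector.
#' @param X Covariate matrix (n x q) or data.frame; may be NULL (intercept
#'   only).
#' @return Numeric residual vector (names preserved) with attribute
#'   `coefficients`.
#' @export
residualize <- function(y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("y and X must have the same number of rows")
  if (anyNA(y) || anyNA(X)) stop("missing values: filter rows before residualizing")
  has_int <- any(apply(X, 2L, function(c) all(abs(c - c[1]) < 1e-12) && abs(c[1]) > 0))
  if (!has_int) X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("dropping %d collinear covariate column(s)", ncol(X) - qrX$rank))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, y)
  names(res) <- names(y)
  attr(res, "coefficients") <- qr.coef(qrX, y)
  res
}

#' Forward stepwise adjustment for principal components
#'
#' Walks the PC columns in index order (PC1 first); a PC is retained iff its
#' marginal association with the *current* residual has p < `alpha`. After the
#' pass the residual is re-fit jointly on the retained set.
#'
#' @param residuals Numeric vector (already covariate-adjusted).
#' @param PCs Matrix of principal components, columns ordered PC1..PCk.
#' @param alpha Retention threshold on the marginal p-value (default 0.05).
#' @return Residual vector with attribute `retained` (integer indices of
#'   retained PCs).
#' @export
stepwise_pc_adjust <- function(residuals, PCs, alpha = 0.05) {
  PCs <- as.matrix(PCs)
  if (nrow(PCs) != length(residuals)) stop("dimension mismatch")
  cur <- as.numeric(residuals)
  retained <- integer(0)
  for (j in seq_len(ncol(PCs))) {
    pj <- marginal_slope_p(cur, PCs[, j])
    if (is.finite(pj) && pj < alpha) {
      retained <- c(retained, j)
      cur <- as.numeric(residualize(cur, PCs[, j, drop = FALSE]))
    }
  }
  out <- if (length(retained) > 0L) {
    as.numeric(residualize(as.numeric(residuals), PCs[, retained, drop = FALSE]))
  } else {
    as.numeric(residuals)
  }
  names(out) <- names(residuals)
  attr(out, "retained") <- retained
  out
}

# two-sided p of the simple-regression slope, via the correlation t-test
# (identical to summary(lm(y ~ x))$coefficients[2, 4])
marginal_slope_p <- function(y, x) {
  n <- length(y)
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx <= 0 || sy <= 0) return(NA_real_)
  r <- cor(y, x)
  r <- max(min(r, 1), -1)
  df <- n - 2L
  tt <- r * sqrt(df / max(1 - r^2, 1e-300))
  2 * stats::pt(-abs(tt), df = df)
}

#' Rank-based inverse normal transform (Blom offset)
#'
#' Maps values to normal quantiles via `qnorm((r - 3/8) / (n + 1/4))` where
#' `r` are average ranks (ties share their mean rank).
#'
#' @param values Numeric vector, `n >= 3`, not all equal.
#' @return Transformed vector (names preserved).
#' @export
inverse_normal_transform <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  if (anyNA(values)) stop("missing values not allowed")
  if (max(values) - min(values) <= 0) stop("constant input: all values tied")
  r <- rank(values, ties.method = "average")
  out <- qnorm((r - 3 / 8) / (n + 1 / 4))
  names(out) <- names(values)
  out
}

#' Genomic inflation factor (lambda)
#'
#' Median association chi-square (1 df, from two-sided p) divided by the null
#' median `qchisq(0.5, 1) = 0.4549`.
#'
#' @param pvals p-values in (0, 1].
#' @return lambda (positive scalar).
#' @export
genomic_inflation_factor <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) stop("no p-values")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  chisq <- qnorm(pvals / 2)^2
  median(chisq) / qchisq(0.5, df = 1)
}

#' Empirical-null correction of z-scores
#'
#' Fits a 3-component normal mixture by EM (a dominant null component anchored
#' near the centre plus two signal components) and rescales:
#' `z_corrected = (z - bias) / inflation` where bias and inflation are the
#' mean and sd of the dominant central component. Corrected p-values are
#' two-sided. On EM failure the estimator falls back to median/MAD with a
#' warning.
#'
#' @param z Numeric vector of z-scores (n >= 500 recommended).
#' @param max_iter,tol EM controls.
#' @return List with `null` (list: bias, inflation, weights, means, sds,
#'   method), `z_corrected`, and `p_corrected`.
#' @export
empirical_null_correct <- function(z, max_iter = 2000L, tol = 1e-8) {
  z <- as.numeric(z)
  if (anyNA(z)) stop("missing z-scores")
  m0 <- median(z); s0 <- mad(z)
  if (s0 <= 0) s0 <- sd(z)
  if (!is.finite(s0) || s0 <= 0) stop("degenerate z-scores")
  # dominant null component seeded at the robust centre; wide low-weight
  # signal components so the null keeps the bulk of the mass
  fit <- em_normal_mixture(
    z,
    mu = c(m0, m0 - 4 * s0, m0 + 4 * s0),
    sigma = c(s0, 4 * s0, 4 * s0),
    w = c(0.98, 0.01, 0.01),
    max_iter = max_iter, tol = tol
  )
  if (is.null(fit)) {
    warning("EM did not converge; falling back to median/MAD null")
    null <- list(bias = m0, inflation = s0, weights = 1, means = m0, sds = s0,
                 method = "median_mad")
  } else {
    k <- which.max(fit$w)
    null <- list(bias = fit$mu[k], inflation = fit$sigma[k], weights = fit$w,
                 means = fit$mu, sds = fit$sigma, method = "em_mixture")
  }
  zc <- (z - null$bias) / null$inflation
  list(null = null, z_corrected = zc, p_corrected = clip_p(2 * pnorm(-abs(zc))))
}

# Plain EM for a k-component univariate normal mixture. A component whose
# expected membership collapses below 2 observations is dropped and the EM
# continues with the survivors (a signal-free input then degenerates cleanly
# to a single-normal fit). Returns NULL only on true degeneracy (caller falls
# back to median/MAD); hitting max_iter returns the current state, since the
# EM likelihood ascent makes it a usable estimate.
em_normal_mixture <- function(x, mu, sigma, w, max_iter = 2000L, tol = 1e-8) {
  n <- length(x)
  ll_old <- -Inf
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    k <- length(mu)
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    if (k == 1L) dens <- matrix(dens, ncol = 1L)
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || anyNA(rowsum_d)) return(NULL)
    gamma <- dens / rowsum_d
    nk <- colSums(gamma)
    drop <- nk < 2 | !is.finite(nk)
    if (any(drop)) {
      if (!any(!drop)) return(NULL)
      mu <- mu[!drop]; sigma <- sigma[!drop]; w <- w[!drop] / sum(w[!drop])
      ll_old <- -Inf
      next
    }
    w <- nk / n
    mu <- colSums(gamma * x) / nk
    sigma <- sqrt(colSums(gamma * (outer(x, mu, "-")^2)) / nk)
    if (any(sigma < 1e-6)) return(NULL)
    ll <- sum(log(rowsum_d))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (!is.finite(ll)) return(NULL)
  list(mu = mu, sigma = sigma, w = w, loglik = ll, iters = it)
}

#' Prepare analysis-ready trait residuals
#'
#' Covariate adjustment, forward-stepwise adjustment for genetic principal
#' components, and a rank-based inverse normal transform, in that order.
#'
#' @param y Named numeric trait vector.
#' @param covariates Covariate matrix / data.frame (samples in rows), or NULL.
#' @param PCs Genetic principal components (samples x PCs), or NULL to skip.
#' @param alpha Stepwise retention threshold.
#' @param log_transform If TRUE, `log(y)` is taken first (e.g. triglycerides).
#' @return Named residual vector (inverse-normal transformed) with attribute
#'   `retained_pcs`.
#' @export
prepare_trait <- function(y, covariates = NULL, PCs = NULL, alpha = 0.05,
                          log_transform = FALSE) {
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires positive trait values")
    y <- log(y)
  }
  res <- residualize(y, covariates)
  retained <- integer(0)
  if (!is.null(PCs)) {
    res <- stepwise_pc_adjust(res, PCs, alpha = alpha)
    retained <- attr(res, "retained")
  }
  out <- inverse_normal_transform(as.numeric(res))
  names(out) <- names(y)
  attr(out, "retained_pcs") <- retained
  out
}
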