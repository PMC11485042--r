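#' Filter an expression count matrix
#'
#' A gene is dropped iff the fraction of samples with CPM < `cpm_min` exceeds
#' `max_low_fraction` (default: CPM < 3 in more than 98.5% of samples). A
#' sample is dropped iff its supplied intergenic read fraction exceeds
#' `max_intergenic`, or its library size is zero (with a warning).
#'
#' @param counts Gene x sample non-negative integer matrix.
#' @param intergenic_fraction Optional named per-sample metric in `[0, 1]`.
#' @param cpm_min CPM threshold (default 3).
#' @param max_low_fraction Maximum tolerated fraction of low-CPM samples
#'   (default 0.985).
#' @param max_intergenic Maximum intergenic read fraction (default 0.08).
#' @return List: `counts` (filtered matrix), `kept_genes`, `kept_samples`,
#'   `dropped_genes`, `dropped_samples`.
#' @export
expression_filter <- function(counts, intergenic_fraction = NULL,
                              cpm_min = 3, max_low_fraction = 0.985,
                              max_intergenic = 0.08) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  keep_s <- rep(TRUE, ncol(counts))
  if (any(lib == 0)) {
    warning(sprintf("dropping %d sample(s) with zero library size", sum(lib == 0)))
    keep_s <- keep_s & lib > 0
  }
  if (!is.null(intergenic_fraction)) {
    ig <- intergenic_fraction[colnames(counts)]
    keep_s <- keep_s & !(ig > max_intergenic)
  }
  sub <- counts[, keep_s, drop = FALSE]
  cpm <- sweep(sub, 2L, colSums(sub), "/") * 1e6
  low_frac <- rowMeans(cpm < cpm_min)
  keep_g <- low_frac <= max_low_fraction
  list(
    counts = sub[keep_g, , drop = FALSE],
    kept_genes = rownames(counts)[keep_g],
    kept_samples = colnames(counts)[keep_s],
    dropped_genes = rownames(counts)[!keep_g],
    dropped_samples = colnames(counts)[!keep_s]
  )
}

#' Transform counts and adjust for covariates and expression structure
#'
#' Applies a `log2(CPM + 0.5)` variance-stabilizing transform, residualizes
#' every gene on the base covariates, then adjusts stepwise (forward, index
#' order, marginal p < `alpha`) for the supplied batch column(s) followed by
#' the top `n_pcs` principal components of the transformed, base-adjusted
#' expression matrix. Constant genes after transform are dropped.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param covariates Base covariate matrix (samples x q) or NULL.
#' @param batch Optional batch indicator(s) (samples x b matrix or vector);
#'   enters the stepwise pass before the PCs.
#' @param n_pcs Number of expression PCs in the stepwise pass (default 10).
#' @param alpha Stepwise retention threshold (default 0.05).
#' @return List: `residuals` (gene x sample matrix), `pcs` (samples x n_pcs),
#'   `retained` (list per gene of retained stepwise column indices),
#'   `dropped_genes`.
#' @export
transform_and_adjust <- function(counts, covariates = NULL, batch = NULL,
                                 n_pcs = 10L, alpha = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size; filter samples first")
  expr <- log2(sweep(counts, 2L, lib, "/") * 1e6 + 0.5)
  v <- apply(expr, 1L, var)
  dropped <- rownames(expr)[v <= 0 | !is.finite(v)]
  expr <- expr[v > 0 & is.finite(v), , drop = FALSE]

  X <- if (is.null(covariates)) matrix(1, ncol(expr), 1) else {
    X0 <- as.matrix(covariates)
    cbind(intercept = 1, X0)
  }
  qrX <- qr(X)
  base_adj <- t(qr.resid(qrX, t(expr)))
  dimnames(base_adj) <- dimnames(expr)

  n_pcs <- min(n_pcs, ncol(base_adj) - 1L, nrow(base_adj))
  pcs <- prcomp(t(base_adj), center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  step_cols <- pcs
  if (!is.null(batch)) {
    batch <- as.matrix(batch)
    colnames(batch) <- paste0("batch", seq_len(ncol(batch)))
    step_cols <- cbind(batch, pcs)
  }

  # forward stepwise across all genes at once: per column, a gene retains the
  # column iff the marginal slope p of its *current* residual on the column is
  # < alpha; retained columns are projected out immediately (same rule as
  # stepwise_pc_adjust, vectorized over genes)
  cur <- base_adj
  n <- ncol(cur)
  df <- n - 2L
  retained_mat <- matrix(FALSE, nrow(cur), ncol(step_cols))
  for (j in seq_len(ncol(step_cols))) {
    x <- step_cols[, j]
    xc <- x - mean(x)
    ssx <- sum(xc^2)
    if (ssx <= 0) next
    rm_ <- rowMeans(cur)
    num <- as.numeric(cur %*% xc)              # sum((g - gbar) * xc)
    ssg <- rowSums(cur^2) - n * rm_^2
    r <- num / sqrt(pmax(ssx * ssg, 1e-300))
    r <- pmax(pmin(r, 1), -1)
    tt <- r * sqrt(df / pmax(1 - r^2, 1e-300))
    pj <- 2 * stats::pt(-abs(tt), df = df)
    keep <- is.finite(pj) & pj < alpha
    if (any(keep)) {
      retained_mat[keep, j] <- TRUE
      coef <- num[keep] / ssx
      # subtract fitted intercept + slope: g - gbar - b*(x - xbar)
      cur[keep, ] <- cur[keep, , drop = FALSE] - rm_[keep] - outer(coef, xc)
    }
  }
  # final joint re-fit on each gene's retained set (grouped by identical sets)
  key <- apply(retained_mat, 1L, function(z) paste(which(z), collapse = ","))
  out <- base_adj
  for (k in unique(key)) {
    idx <- which(key == k)
    if (k == "") next
    cols <- as.integer(strsplit(k, ",")[[1]])
    qs <- qr(cbind(1, step_cols[, cols, drop = FALSE]))
    out[idx, ] <- t(qr.resid(qs, t(base_adj[idx, , drop = FALSE])))
  }
  retained <- lapply(seq_len(nrow(out)), function(i) which(retained_mat[i, ]))
  names(retained) <- rownames(base_adj)
  list(residuals = out, pcs = pcs, retained = retained, dropped_genes = dropped)
}

#' Expression-trait association under kinship
#'
#' Per-gene generalized least squares slope test of the trait residual on the
#' adjusted expression residual, under the trait's variance model
#' `V = sg2 * 2K + se2 * I` (fit once per trait). With `K = 0` this reduces
#' exactly to OLS. When the genomic inflation factor of the resulting
#' p-values exceeds `gif_threshold`, the z-scores are recalibrated by
#' [empirical_null_correct()].
#'
#' @param expr_residuals Gene x sample matrix from [transform_and_adjust()].
#' @param trait_residuals Named trait residual vector (aligned samples).
#' @param kinship Kinship matrix or NULL.
#' @param trait Trait label.
#' @param gif_threshold Inflation trigger for the empirical-null correction
#'   (default 1.1).
#' @return A [gene_score_table()] with `source = "TWAS"`, beta populated, and
#'   attributes `gif_raw`, `gif_used`, `null_model` (NULL when no correction
#'   was applied).
#' @export
expression_trait_assoc <- function(expr_residuals, trait_residuals,
                                   kinship = NULL, trait = "trait",
                                   gif_threshold = 1.1) {
  expr_residuals <- as.matrix(expr_residuals)
  n <- length(trait_residuals)
  if (ncol(expr_residuals) != n) stop("sample dimension mismatch")
  vm <- fit_variance_model(as.numeric(trait_residuals), kinship)
  fit <- gls_slope_test(as.numeric(trait_residuals), t(expr_residuals), vm)
  p <- clip_p(fit$p)
  gif_raw <- genomic_inflation_factor(p)
  null_model <- NULL
  gif_used <- gif_raw
  if (is.finite(gif_raw) && gif_raw > gif_threshold && length(p) >= 50L) {
    z <- sign(fit$beta) * p_to_abs_z(p)
    corr <- empirical_null_correct(z)
    p <- corr$p_corrected
    null_model <- corr$null
    gif_used <- genomic_inflation_factor(p)
  }
  out <- gene_score_table(rownames(expr_residuals), trait, "TWAS", "none",
                          p, beta = fit$beta, n_units = n)
  attr(out, "gif_raw") <- gif_raw
  attr(out, "gif_used") <- gif_used
  attr(out, "null_model") <- null_model
  out
}
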