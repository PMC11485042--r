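#' Convert p-values to upper-tail z-scores
#'
#' `z = qnorm(1 - p)`, direction-free (gene-level GWAS and RVA p-values carry
#' no sign). p-values are clipped to `[1e-300, 1]` first and the result is
#' clipped to `[-37, 37]` so `p = 1` maps to a finite -37.
#'
#' @param p p-values in (0, 1].
#' @return z-scores (NA propagated).
#' @export
p_to_z <- function(p) {
  ok <- !is.na(p)
  if (any(ok & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]")
  z <- rep(NA_real_, length(p))
  z[ok] <- pmax(pmin(qnorm(clip_p(p[ok]), lower.tail = FALSE), 37), -37)
  z
}

#' Estimate the inter-source null correlation matrix
#'
#' Estimates the K x K correlation between the z-scores of the meta-analysis
#' inputs from the genes themselves. The default (Pearson) estimator uses the
#' null subset of genes -- complete cases whose p-values all exceed
#' `null_p_min` -- to keep planted/true signals from inflating the estimate;
#' if fewer than `min_genes` such genes exist it falls back to all
#' complete-case genes with a warning. The tetrachoric estimator
#' median-dichotomizes each z column and fits rho per pair by maximizing the
#' 2x2 multinomial likelihood under the bivariate-normal quadrant probability
#' (closed form at median thresholds: `P11 = 1/4 + asin(rho) / (2 pi)`).
#' Off-diagonals are clipped to [-0.99, 0.99] and the matrix is made PSD by
#' eigenvalue clipping.
#'
#' @param Z Gene x source matrix of z-scores (NA for missing entries).
#' @param P Optional matching matrix of p-values (used for the null mask);
#'   when NULL the mask is computed from `Z` as `p = 1 - pnorm(z)`.
#' @param estimator `"pearson"` (default) or `"tetrachoric"`.
#' @param null_p_min Null-mask threshold (default 1e-4).
#' @param min_genes Minimum null-subset size before falling back (default 50).
#' @return Object of class `"correlation_model"`: list with `sigma` (K x K),
#'   `sources`, `estimator`, `n_genes` (size of the estimation set),
#'   `null_mask_rule`.
#' @export
estimate_null_correlation <- function(Z, P = NULL, estimator = c("pearson", "tetrachoric"),
                                      null_p_min = 1e-4, min_genes = 50L) {
  estimator <- match.arg(estimator)
  Z <- as.matrix(Z)
  K <- ncol(Z)
  if (is.null(P)) P <- pnorm(Z, lower.tail = FALSE)
  cc <- complete.cases(Z)
  nullset <- cc & apply(P > null_p_min, 1L, all)
  fellback <- FALSE
  if (sum(nullset) < min_genes) {
    warning(sprintf("only %d null-subset genes; falling back to all complete cases",
                    sum(nullset)))
    nullset <- cc
    fellback <- TRUE
  }
  sigma <- diag(K)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      # estimation rows: the null subset when rich enough, else the pairwise
      # complete observations (a pair with < 3 usable genes gets rho = 0)
      rows <- if (sum(nullset) >= 3L) nullset else !is.na(Z[, i]) & !is.na(Z[, j])
      if (sum(rows) < 3L) {
        if (!fellback) warning("too few genes for a pair; using rho = 0")
        sigma[i, j] <- sigma[j, i] <- 0
        next
      }
      rho <- if (estimator == "pearson") {
        cor(Z[rows, i], Z[rows, j])
      } else {
        tetrachoric_median(Z[rows, i], Z[rows, j])
      }
      if (!is.finite(rho)) rho <- 0
      sigma[i, j] <- sigma[j, i] <- max(min(rho, 0.99), -0.99)
    }
  }
  sigma <- psd_clip(sigma)
  dimnames(sigma) <- list(colnames(Z), colnames(Z))
  structure(list(sigma = sigma, sources = colnames(Z), estimator = estimator,
                 n_genes = sum(nullset),
                 null_mask_rule = sprintf("complete cases with all p > %g", null_p_min)),
            class = "correlation_model")
}

#' Tetrachoric correlation of two median-dichotomized vectors
#'
#' Dichotomizes both vectors at their medians and fits the latent
#' bivariate-normal correlation by a 1-D maximum-likelihood search. At median
#' thresholds the upper-upper quadrant probability is
#' `1/4 + asin(rho) / (2 pi)` (no bivariate CDF needed).
#'
#' @param x,y Numeric vectors of equal length.
#' @return rho in `[-0.999, 0.999]`.
#' @export
tetrachoric_median <- function(x, y) {
  a <- x > median(x)
  b <- y > median(y)
  tetrachoric_from_table(table2x2(a, b))
}

# counts: c(n11, n10, n01, n00) with 1 = above median
table2x2 <- function(a, b) {
  c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}

# ML tetrachoric rho from a 2x2 table of median splits
tetrachoric_from_table <- function(n) {
  stopifnot(length(n) == 4L)
  if (sum(n) == 0L) return(0)
  loglik <- function(rho) {
    p11 <- 0.25 + asin(rho) / (2 * pi)
    p10 <- 0.5 - p11
    p01 <- p10
    p00 <- p11
    probs <- pmax(c(p11, p10, p01, p00), 1e-12)
    sum(n * log(probs))
  }
  opt <- optimize(loglik, interval = c(-0.999, 0.999), maximum = TRUE)
  opt$maximum
}

# make a symmetric matrix PSD by clipping eigenvalues at 0 (unit diagonal
# restored afterwards)
psd_clip <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(eg$values) >= 0) return(S)
  S2 <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  d <- sqrt(pmax(diag(S2), 1e-12))
  S2 <- S2 / outer(d, d)
  diag(S2) <- 1
  S2
}

#' Combine correlated z-scores into one p-value
#'
#' Correlated Stouffer combination over the observed subset S:
#' `T = sum(z_S)`, `sd = sqrt(1' Sigma_SS 1)`, `p = 1 - pnorm(T / sd)`.
#' With a single observed source the input p is returned exactly; with
#' `Sigma = I` this is the classic unweighted Stouffer test.
#'
#' @param z K-vector of z-scores (NA = missing source).
#' @param sigma K x K correlation matrix or a `"correlation_model"`.
#' @return Combined p-value in (0, 1].
#' @export
combine <- function(z, sigma) {
  if (inherits(sigma, "correlation_model")) sigma <- sigma$sigma
  obs <- which(!is.na(z))
  if (length(obs) == 0L) stop("need at least one non-missing z-score")
  S <- sigma[obs, obs, drop = FALSE]
  v <- sum(S)
  if (v <= 0) {
    S <- psd_clip(S)
    v <- max(sum(S), 1e-12)
  }
  clip_p(pnorm(sum(z[obs]) / sqrt(v), lower.tail = FALSE))
}

#' Run the correlated meta-analysis across the rare-variant categories
#'
#' For each of the 10 RVA functional categories, builds the gene x
#' {GWAS, TWAS, RVA-category} z-matrix (genes may miss entries; e.g. a gene
#' with no RVA row in that category combines GWAS + TWAS only), estimates the
#' inter-source correlation per run, and combines per gene. The total test
#' count is aggregated across all runs and a gene is significant iff any of
#' its category p-values beats `alpha / total_tests`.
#'
#' @param scores A [gene_score_table()] holding GWAS, TWAS and RVA rows for
#'   one trait.
#' @param alpha Family-wise level (default 0.05).
#' @param estimator Correlation estimator, see [estimate_null_correlation()].
#' @param categories Category set to iterate over (default [rva_categories()]).
#' @return List of class `"cma_result"`: `p` (gene x category matrix),
#'   `min_p`, `min_category`, `total_tests`, `threshold`, `significant`
#'   (logical named by gene), `correlations` (per-category
#'   `correlation_model`), `table` (long [gene_score_table()] with
#'   `source = "CMA"`), `trait`.
#' @export
run_cma <- function(scores, alpha = 0.05, estimator = "pearson",
                    categories = rva_categories()) {
  scores <- as.data.frame(scores)
  trait <- unique(scores$trait)
  if (length(trait) != 1L) stop("run_cma expects a single trait")
  src <- split(scores, scores$source)
  have <- intersect(c("GWAS", "TWAS", "RVA"), names(src))
  if (length(have) < 2L) stop("need at least two sources for meta-analysis")
  genes <- sort(unique(scores$gene_id))
  base <- matrix(NA_real_, length(genes), 2,
                 dimnames = list(genes, c("GWAS", "TWAS")))
  for (s in intersect(c("GWAS", "TWAS"), have)) {
    tab <- src[[s]]
    base[tab$gene_id, s] <- tab$p
  }
  rva <- if ("RVA" %in% have) src[["RVA"]] else NULL

  pmat <- matrix(NA_real_, length(genes), length(categories),
                 dimnames = list(genes, categories))
  corrs <- list()
  for (cat in categories) {
    P <- base
    if (!is.null(rva)) {
      rv <- rva[rva$category == cat, , drop = FALSE]
      pc <- rep(NA_real_, length(genes))
      pc[match(rv$gene_id, genes)] <- rv$p
      P <- cbind(base, RVA = pc)
    }
    P <- P[, colSums(!is.na(P)) > 0, drop = FALSE]
    if (ncol(P) == 0L) next
    Z <- P
    Z[] <- p_to_z(as.numeric(P))
    tested <- rowSums(!is.na(Z)) > 0
    if (!any(tested)) next
    cm <- if (ncol(Z) >= 2L) {
      estimate_null_correlation(Z, P, estimator = estimator)
    } else {
      structure(list(sigma = diag(1), sources = colnames(Z),
                     estimator = "identity", n_genes = sum(tested),
                     null_mask_rule = "single source"),
                class = "correlation_model")
    }
    pmat[tested, cat] <- apply(Z[tested, , drop = FALSE], 1L, combine, sigma = cm$sigma)
    corrs[[cat]] <- cm
  }
  tests_per_run <- colSums(!is.na(pmat))
  total_tests <- sum(tests_per_run)
  threshold <- alpha / max(total_tests, 1L)
  tested_any <- rowSums(!is.na(pmat)) > 0
  min_p <- apply(pmat, 1L, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  min_cat <- apply(pmat, 1L, function(x) {
    if (all(is.na(x))) NA_character_ else categories[which.min(x)]
  })
  significant <- !is.na(min_p) & min_p < threshold
  long <- which(!is.na(pmat), arr.ind = TRUE)
  tab <- gene_score_table(
    gene_id = genes[long[, 1L]], trait = trait, source = "CMA",
    category = categories[long[, 2L]], p = pmat[long],
    n_units = NA_integer_
  )
  structure(list(p = pmat, min_p = min_p, min_category = min_cat,
                 tests_per_run = tests_per_run, total_tests = total_tests,
                 threshold = threshold, significant = significant,
                 correlations = corrs, table = tab, trait = trait,
                 alpha = alpha),
            class = "cma_result")
}

#' Replication calls against a second cohort
#'
#' A discovery-significant unit is replicated iff its replication p-value
#' beats `alpha / n_discovery_significant`, where the count is over genes
#' (GWAS, TWAS) or gene-category pairs (CMA, RVA). For TWAS the sign
#' concordance of the discovery and replication betas is reported alongside.
#'
#' @param discovery data.frame of discovery-significant rows: `gene_id`,
#'   optionally `category` (required for mode `"cma"`), optionally `beta`.
#' @param replication A [gene_score_table()] (or data.frame) from the
#'   replication cohort with `gene_id`, `p`, optionally `category`, `beta`.
#' @param mode `"gene"` (count genes: GWAS / TWAS) or `"cma"` (count
#'   gene-category pairs: CMA / RVA).
#' @param alpha Family-wise level (default 0.05).
#' @return data.frame with one row per discovery unit: replication p,
#'   `replicated` flag, `direction_consistent` (NA when betas are absent),
#'   plus attribute `threshold`. Zero discovery rows yield a zero-row frame
#'   with threshold NA.
#' @export
replicate_calls <- function(discovery, replication, mode = c("gene", "cma"),
                            alpha = 0.05) {
  mode <- match.arg(mode)
  discovery <- as.data.frame(discovery)
  replication <- as.data.frame(replication)
  if (nrow(discovery) == 0L) {
    out <- data.frame(gene_id = character(0), category = character(0),
                      p_replication = numeric(0), replicated = logical(0),
                      direction_consistent = logical(0))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  if (mode == "cma" && !"category" %in% names(discovery)) {
    stop("mode 'cma' needs a category column (gene-category pairs)")
  }
  n_units <- if (mode == "gene") length(unique(discovery$gene_id)) else nrow(unique(discovery[c("gene_id", "category")]))
  threshold <- alpha / n_units
  key_rep <- if (mode == "cma" && "category" %in% names(replication)) {
    paste(replication$gene_id, replication$category)
  } else replication$gene_id
  key_dis <- if (mode == "cma" && "category" %in% names(replication)) {
    paste(discovery$gene_id, discovery$category)
  } else discovery$gene_id
  idx <- match(key_dis, key_rep)
  p_rep <- replication$p[idx]
  out <- data.frame(
    gene_id = discovery$gene_id,
    category = if ("category" %in% names(discovery)) discovery$category else "none",
    p_replication = p_rep,
    replicated = !is.na(p_rep) & p_rep < threshold,
    direction_consistent = if ("beta" %in% names(discovery) && "beta" %in% names(replication)) {
      ifelse(is.na(idx) | is.na(discovery$beta) | is.na(replication$beta[idx]),
             NA, sign(discovery$beta) == sign(replication$beta[idx]))
    } else NA,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  attr(out, "n_discovery") <- n_units
  out
}
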