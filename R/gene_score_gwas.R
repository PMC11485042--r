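#' Assign common variants to genes by a window around the gene body
#'
#' A variant is assigned to every gene for which it lies within `window` bp of
#' the gene body (inclusive boundaries); variants inside overlapping windows
#' map to multiple genes. Only variants passing the common-variant MAF filter
#' (`maf >= maf_min`) are assigned. Interval logic uses GenomicRanges.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based) and `maf`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive). Strand, if present, is ignored.
#' @param window Flank size in bp (default 50000).
#' @param maf_min Minimum MAF for inclusion (default 0.05).
#' @return Named list: `gene_id` -> character vector of variant ids (possibly
#'   empty), with attribute `n_variants` (named integer).
#' @export
assign_snps_to_genes <- function(variants, genes, window = 50000L,
                                 maf_min = 0.05) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)))
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("gene intervals must have start <= end")
  keep <- if ("maf" %in% names(variants)) variants$maf >= maf_min else rep(TRUE, nrow(variants))
  v <- variants[keep, , drop = FALSE]
  out <- setNames(vector("list", nrow(genes)), genes$gene_id)
  out[] <- list(character(0))
  if (nrow(v) > 0L) {
    vg <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    gg <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(1L, genes$start - window), genes$end + window)
    )
    hits <- GenomicRanges::findOverlaps(vg, gg)
    if (length(hits) > 0L) {
      sp <- split(v$variant_id[S4Vectors::queryHits(hits)],
                  genes$gene_id[S4Vectors::subjectHits(hits)])
      out[names(sp)] <- sp
    }
  }
  structure(out, n_variants = vapply(out, length, integer(1)))
}

#' LD correlation matrix for a set of variants
#'
#' Pairwise Pearson correlation of mean-imputed dosages, with a small ridge
#' toward the identity (`R <- (1 - eps) R + eps I`) so the matrix is positive
#' semi-definite despite finite-sample noise. Zero-variance variants are
#' dropped with a warning.
#'
#' @param dosages Variant x sample dosage matrix (NA allowed).
#' @param eps Shrinkage weight on the identity (default 0.001).
#' @return List with `R` (correlation matrix), `variant_ids`, and `dropped`
#'   (ids of zero-variance variants).
#' @export
ld_correlation <- function(dosages, eps = 0.001) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 1L) stop("no variants")
  # mean-impute missing dosages per variant (test-statistic convention)
  if (anyNA(dosages)) {
    mu <- rowMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 1L]]
  }
  v <- apply(dosages, 1L, var)
  dropped <- rownames(dosages)[v <= 0 | !is.finite(v)]
  if (length(dropped) > 0L) {
    warning(sprintf("dropping %d zero-variance variant(s) from LD", length(dropped)))
    dosages <- dosages[v > 0 & is.finite(v), , drop = FALSE]
  }
  if (nrow(dosages) == 0L) stop("no variants with nonzero variance")
  R <- cor(t(dosages))
  k <- nrow(R)
  R <- (1 - eps) * R + eps * diag(k)
  list(R = R, variant_ids = rownames(dosages), dropped = dropped)
}

#' Gene-level sum-of-chi-squares test
#'
#' The gene statistic is `T = sum(z_i^2)` over the gene's variants, where
#' `z_i` is the |z| magnitude of the two-sided per-variant GWAS p-value.
#' Under the null `T ~ sum(lambda_j chisq_1)` with `lambda_j` the eigenvalues
#' of the LD correlation matrix; the tail is evaluated by [quadform_tail()].
#' With a single variant this returns that variant's p exactly.
#'
#' @param z Per-variant |z| magnitudes (capped at 37).
#' @param R LD correlation matrix (same order as `z`), or the list returned by
#'   [ld_correlation()].
#' @return Gene p-value in (0, 1] with attribute `method`.
#' @export
gene_sum_test <- function(z, R) {
  if (is.list(R) && !is.null(R$R)) R <- R$R
  R <- as.matrix(R)
  z <- pmin(abs(z), 37)
  if (length(z) != nrow(R) || nrow(R) != ncol(R)) {
    stop("dimension mismatch between z and R")
  }
  T <- sum(z^2)
  lambda <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  quadform_tail(T, lambda)
}

#' Two-sided p-value to |z| magnitude
#'
#' `|z| = qnorm(1 - p/2)`, capped at 37 so extreme p stay finite.
#'
#' @param p Two-sided p-values in (0, 1].
#' @return Non-negative |z| magnitudes.
#' @export
p_to_abs_z <- function(p) {
  p <- clip_p(p)
  pmin(qnorm(p / 2, lower.tail = FALSE), 37)
}

#' Aggregate per-variant GWAS summary statistics to gene scores
#'
#' Runs the full sum-of-chi-squares aggregation: common-variant filter, window
#' assignment, in-cohort LD from dosages, and the sum-of-chi-squares tail per
#' gene. Genes whose window holds more than `max_variants` variants are
#' thinned to the `max_variants` highest-MAF variants (eigen cost control).
#'
#' @param summary_stats data.frame with `variant_id`, `chrom`, `pos`, `p`,
#'   optionally `beta`, `se`, `maf` (MAF taken from dosages when absent).
#' @param genes Gene model data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param dosages Variant x sample dosage matrix for LD (rownames =
#'   variant_id).
#' @param trait Trait label for the output rows.
#' @param window,maf_min See [assign_snps_to_genes()].
#' @param max_variants Per-gene variant cap (default 3000).
#' @return A [gene_score_table()] with `source = "GWAS"` (one row per gene
#'   with >= 1 assigned variant); `n_units` is the variant count used.
#' @export
gene_scores_gwas <- function(summary_stats, genes, dosages, trait,
                             window = 50000L, maf_min = 0.05,
                             max_variants = 3000L) {
  ss <- summary_stats
  if (!"maf" %in% names(ss)) {
    ss$maf <- apply(dosages[ss$variant_id, , drop = FALSE], 1L, compute_maf)
  }
  ss$p <- clip_p(ss$p)
  assign <- assign_snps_to_genes(ss, genes, window = window, maf_min = maf_min)
  rows <- lapply(names(assign), function(g) {
    vids <- intersect(assign[[g]], rownames(dosages))
    if (length(vids) == 0L) return(NULL)
    if (length(vids) > max_variants) {
      ord <- order(ss$maf[match(vids, ss$variant_id)], decreasing = TRUE)
      vids <- vids[ord][seq_len(max_variants)]
    }
    ld <- ld_correlation(dosages[vids, , drop = FALSE])
    vids <- ld$variant_ids
    if (length(vids) == 0L) return(NULL)
    z <- p_to_abs_z(ss$p[match(vids, ss$variant_id)])
    p <- gene_sum_test(z, ld$R)
    data.frame(gene_id = g, p = as.numeric(p), n_units = length(vids),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(gene_score_table(character(0), character(0), character(0),
                            character(0), numeric(0)))
  }
  gene_score_table(rows$gene_id, trait, "GWAS", "none", rows$p,
                   beta = NA_real_, n_units = rows$n_units)
}

#' Per-variant association scan under the trait variance model
#'
#' Mixed-model Wald test of each variant's dosage against the prepared trait
#' residual, used to produce GWAS summary statistics from genotypes (the
#' per-variant stage upstream of gene aggregation). Missing dosages are
#' mean-imputed inside the test.
#'
#' @param dosages Variant x sample dosage matrix.
#' @param y Trait residual vector (aligned to dosage columns).
#' @param vm Fitted [fit_variance_model()] for the trait (NULL = OLS).
#' @return data.frame: variant_id, beta, se, p, maf.
#' @export
gwas_scan <- function(dosages, y, vm = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(vm)) vm <- fit_variance_model(y, K = NULL)
  maf <- apply(dosages, 1L, compute_maf)
  G <- dosages
  if (anyNA(G)) {
    mu <- rowMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 1L]]
  }
  keep <- apply(G, 1L, var) > 0
  res <- data.frame(variant_id = rownames(dosages), beta = NA_real_,
                    se = NA_real_, p = NA_real_, maf = maf,
                    stringsAsFactors = FALSE)
  if (any(keep)) {
    fit <- gls_slope_test(y, t(G[keep, , drop = FALSE]), vm)
    res$beta[keep] <- fit$beta
    res$se[keep] <- fit$se
    res$p[keep] <- fit$p
  }
  res
}
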