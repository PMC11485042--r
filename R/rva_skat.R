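#' Annotation principal-component Phred weights
#'
#' Integrates a matrix of functional annotation scores (conservation,
#' epigenetic, protein-function, pathogenicity proxies) into one weight per
#' variant: standardize columns, take first principal-component scores,
#' orient the PC so it correlates positively with the row-mean of the
#' standardized matrix, convert scores to upper-tail percentiles
#' `u_i = rank(s_i) / (n + 1)` and Phred-scale them,
#' `aPC_i = -10 * log10(1 - u_i)`.
#'
#' @param A Variant x annotation numeric matrix (>= 2 variants). Constant
#'   columns are ignored; if all columns are constant, uniform weights are
#'   returned with a warning.
#' @return Numeric vector of positive aPC scores (named by rownames of `A`),
#'   with attribute `pc_scores`.
#' @export
annotation_pc_weights <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 variants")
  sds <- apply(A, 2L, sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) {
    warning("all annotation columns constant; using uniform weights")
    u <- rep(0.5, n)
    out <- rep(-10 * log10(1 - 0.5), n)
    names(out) <- rownames(A)
    attr(out, "pc_scores") <- rep(0, n)
    return(out)
  }
  Z <- scale(A[, keep, drop = FALSE])
  s <- prcomp(Z, center = FALSE, scale. = FALSE)$x[, 1L]
  # deterministic sign: positive correlation with the standardized row-mean
  rm_ <- rowMeans(Z)
  if (sd(rm_) > 0 && cor(s, rm_) < 0) s <- -s
  r <- rank(s, ties.method = "average")
  u <- r / (n + 1)
  out <- -10 * log10(1 - u)
  names(out) <- rownames(A)
  attr(out, "pc_scores") <- s
  out
}

#' Combined SKAT variant weights
#'
#' Combination of the classic rare-variant MAF weight with the
#' annotation PC score: `w_j^2 = Beta(MAF_j; 1, 25)^2 * aPC_j / mean(aPC)`.
#' Scaling all weights by a constant leaves the SKAT p-value unchanged, so
#' only relative weights matter.
#'
#' @param maf Minor allele frequencies of the variants.
#' @param apc aPC Phred scores from [annotation_pc_weights()], or NULL for
#'   MAF-beta weights alone.
#' @return Positive weight vector `w` (the square root of `w^2` above) with
#'   attributes `maf_beta` and `apc_factor`.
#' @export
skat_weights <- function(maf, apc = NULL) {
  b <- stats::dbeta(maf, 1, 25)
  fac <- if (is.null(apc)) rep(1, length(maf)) else {
    if (mean(apc) <= 0) rep(1, length(apc)) else apc / mean(apc)
  }
  w <- sqrt(b^2 * fac)
  if (any(!is.finite(w) | w <= 0)) stop("weights must be finite and positive")
  structure(w, maf_beta = b, apc_factor = fac)
}

#' Weighted SKAT test of a rare-variant set
#'
#' Variance-component score statistic
#' `Q = r' V^{-1} G W^2 G' V^{-1} r` whose null distribution is the mixture
#' of 1-df chi-squares with weights `eigen(W G' P0 G W)`, where `P0` is the
#' V-metric projection removing the intercept
#' (`P0 = V^{-1} - V^{-1} 1 (1' V^{-1} 1)^{-1} 1' V^{-1}`). The tail is
#' evaluated by [quadform_tail()]. Fewer than `min_variants` variants yields
#' a missing result (`NA`), per the minimum-2-variants rule.
#'
#' @param G Sample x variant dosage matrix of rare variants (NA mean-imputed
#'   per variant inside the statistic).
#' @param w Positive variant weights (length = ncol(G)).
#' @param r Trait residual vector.
#' @param vm Fitted [fit_variance_model()] (NULL = unrelated, OLS variance).
#' @param min_variants Minimum variant count to run (default 2).
#' @return p-value (attribute `Q`, `method`), or `NA_real_` when fewer than
#'   `min_variants` variants are available.
#' @export
skat_test <- function(G, w, r, vm = NULL, min_variants = 2L) {
  G <- as.matrix(G)
  if (ncol(G) < min_variants) return(NA_real_)
  if (length(w) != ncol(G)) stop("weight / variant dimension mismatch")
  if (nrow(G) != length(r)) stop("sample dimension mismatch")
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  if (is.null(vm)) vm <- fit_variance_model(r, K = NULL)
  GW <- sweep(G, 2L, w, "*")
  # remove the GLS intercept from r (the eigenvalue reference distribution
  # projects the variant columns off the intercept in the V metric)
  r <- r - sum(vinv(vm, r)) / sum(vinv(vm, rep(1, length(r))))
  # Q = || W G' V^{-1} r ||^2
  vr <- vinv(vm, r)
  Q <- sum(as.numeric(crossprod(GW, vr))^2)
  # lambda = eigen(W G' P0 G W): project whitened GW off the whitened intercept
  GWw <- whiten(vm, GW)
  onew <- as.numeric(whiten(vm, rep(1, nrow(G))))
  proj <- GWw - outer(onew, as.numeric(crossprod(GWw, onew)) / sum(onew^2))
  M <- crossprod(proj)
  lambda <- pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (sum(lambda) <= 0) return(NA_real_)
  p <- quadform_tail(Q, lambda)
  structure(as.numeric(p), Q = Q, method = attr(p, "method"))
}

#' Category-wise rare-variant analysis for one gene
#'
#' Splits the gene's rare variants (already windowed and MAF-filtered) into
#' the 10 functional categories, computes annotation-PC weights within each
#' category's variant set, and runs a weighted SKAT per category holding at
#' least `min_variants` variants.
#'
#' @param gene_id Gene label for the output rows.
#' @param dosages Sample x variant dosage matrix of the gene's rare variants.
#' @param categories Named character: variant_id -> functional category (one
#'   of [rva_categories()]).
#' @param annotations Variant x annotation score matrix (rownames =
#'   variant_id), or NULL for MAF-only weights.
#' @param r Trait residual vector.
#' @param vm Variance model (NULL = unrelated).
#' @param trait Trait label.
#' @param min_variants Minimum variants per category (default 2).
#' @return A [gene_score_table()] with `source = "RVA"` and one row per
#'   category with >= `min_variants` variants (possibly zero rows).
#' @export
run_rva_gene <- function(gene_id, dosages, categories, annotations = NULL,
                         r, vm = NULL, trait = "trait", min_variants = 2L) {
  dosages <- as.matrix(dosages)
  vids <- colnames(dosages)
  if (!all(vids %in% names(categories))) stop("every variant needs a category")
  cats <- categories[vids]
  bad <- setdiff(unique(cats), rva_categories())
  if (length(bad) > 0L) stop("unknown category label: ", paste(bad, collapse = ", "))
  rows <- list()
  for (cat in unique(cats)) {
    ids <- vids[cats == cat]
    if (length(ids) < min_variants) next
    Gc <- dosages[, ids, drop = FALSE]
    maf <- apply(t(Gc), 1L, compute_maf)
    poly <- maf > 0
    if (sum(poly) < min_variants) next
    Gc <- Gc[, poly, drop = FALSE]
    ids <- ids[poly]
    maf <- maf[poly]
    apc <- if (is.null(annotations)) NULL else {
      annotation_pc_weights(annotations[ids, , drop = FALSE])
    }
    w <- skat_weights(maf, apc)
    p <- skat_test(Gc, w, r, vm, min_variants = min_variants)
    if (is.na(p)) next
    rows[[cat]] <- data.frame(category = cat, p = as.numeric(p),
                              n_units = length(ids), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(gene_score_table(character(0), character(0), character(0),
                            character(0), numeric(0)))
  }
  df <- do.call(rbind, rows)
  gene_score_table(gene_id, trait, "RVA", df$category, df$p,
                   beta = NA_real_, n_units = df$n_units)
}

#' Rare-variant analysis across genes
#'
#' Assigns rare variants (MAF < `maf_max`) to genes with the same +/- window
#' rule as the GWAS aggregation, then runs [run_rva_gene()] per gene.
#'
#' @param variants data.frame: variant_id, chrom, pos, maf.
#' @param genes Gene models (gene_id, chrom, start, end).
#' @param dosages Variant x sample dosage matrix.
#' @param categories Named character: variant_id -> category.
#' @param annotations Variant x annotation matrix or NULL.
#' @param r Trait residual vector (aligned to dosage columns).
#' @param kinship Kinship matrix or NULL.
#' @param trait Trait label.
#' @param window Gene window in bp (default 50000).
#' @param maf_max Rare-variant MAF cutoff, exclusive (default 0.05).
#' @param min_variants Minimum variants per category (default 2).
#' @return A [gene_score_table()] with `source = "RVA"` rows for every
#'   (gene, category) meeting the minimum-variant rule.
#' @export
run_rva <- function(variants, genes, dosages, categories, annotations = NULL,
                    r, kinship = NULL, trait = "trait", window = 50000L,
                    maf_max = 0.05, min_variants = 2L) {
  rare <- variants[variants$maf < maf_max & variants$maf > 0, , drop = FALSE]
  # only variants with a functional category label are testable
  rare <- rare[rare$variant_id %in% names(categories), , drop = FALSE]
  # reuse the GWAS windowing with the MAF filter disabled (already applied)
  assign <- assign_snps_to_genes(rare, genes, window = window, maf_min = 0)
  r <- as.numeric(r)
  vm <- fit_variance_model(r, kinship)

  # whiten all rare dosages once (the per-gene tests then only touch small
  # k x k matrices); mean-impute missing dosages inside the statistic
  all_ids <- intersect(unique(unlist(assign)), rownames(dosages))
  if (length(all_ids) == 0L) {
    return(gene_score_table(character(0), character(0), character(0),
                            character(0), numeric(0)))
  }
  G_all <- t(dosages[all_ids, , drop = FALSE])   # samples x variants
  if (anyNA(G_all)) {
    mu <- colMeans(G_all, na.rm = TRUE)
    idx <- which(is.na(G_all), arr.ind = TRUE)
    G_all[idx] <- mu[idx[, 2L]]
  }
  maf_all <- setNames(rare$maf[match(all_ids, rare$variant_id)], all_ids)
  r <- r - sum(vinv(vm, r)) / sum(vinv(vm, rep(1, length(r))))
  vr <- vinv(vm, r)
  gvr_all <- setNames(as.numeric(crossprod(G_all, vr)), all_ids)  # G' V^-1 r
  Gw_all <- whiten(vm, G_all)
  colnames(Gw_all) <- all_ids
  onew <- as.numeric(whiten(vm, rep(1, length(r))))
  s11 <- sum(onew^2)

  out <- list()
  for (g in names(assign)) {
    vids <- intersect(assign[[g]], all_ids)
    if (length(vids) < min_variants) next
    cats <- categories[vids]
    for (cat in unique(cats)) {
      ids <- vids[cats == cat]
      ids <- ids[maf_all[ids] > 0]
      if (length(ids) < min_variants) next
      apc <- if (is.null(annotations)) NULL else {
        annotation_pc_weights(annotations[ids, , drop = FALSE])
      }
      w <- skat_weights(maf_all[ids], apc)
      Q <- sum((w * gvr_all[ids])^2)
      Bw <- sweep(Gw_all[, ids, drop = FALSE], 2L, w, "*")
      proj <- Bw - outer(onew, as.numeric(crossprod(Bw, onew)) / s11)
      lambda <- pmax(eigen(crossprod(proj), symmetric = TRUE,
                           only.values = TRUE)$values, 0)
      if (sum(lambda) <= 0) next
      p <- quadform_tail(Q, lambda)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, category = cat, p = as.numeric(p),
        n_units = length(ids), stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(gene_score_table(character(0), character(0), character(0),
                            character(0), numeric(0)))
  }
  res <- do.call(rbind, out)
  gene_score_table(res$gene_id, trait, "RVA", res$category, res$p,
                   beta = NA_real_, n_units = res$n_units)
}
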