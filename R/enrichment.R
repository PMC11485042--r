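#' Remove single-source genes from modules
#'
#' Genes whose gene-level p-values come from only one of the three sources
#' (GWAS, TWAS, RVA) are removed from every module before enrichment; modules
#' shrinking below `min_size` genes are dropped with a warning.
#'
#' @param modules Named list of gene-id vectors (a `module_collection`).
#' @param gene_sources Named list or data.frame mapping gene_id to the number
#'   of sources with a p-value; either a named integer vector or a
#'   [gene_score_table()] (counted per gene over GWAS/TWAS/RVA rows).
#' @param min_size Minimum surviving module size (default 2).
#' @return Filtered module list with attribute `dropped_modules`.
#' @export
filter_module_genes <- function(modules, gene_sources, min_size = 2L) {
  if (is.data.frame(gene_sources)) {
    gs <- gene_sources[gene_sources$source %in% c("GWAS", "TWAS", "RVA"), , drop = FALSE]
    counts <- tapply(gs$source, gs$gene_id, function(s) length(unique(s)))
    gene_sources <- setNames(as.integer(counts), names(counts))
  }
  multi <- names(gene_sources)[gene_sources >= 2L]
  out <- lapply(modules, function(g) g[g %in% multi])
  keep <- vapply(out, length, integer(1)) >= min_size
  if (any(!keep)) {
    warning(sprintf("dropping %d module(s) below %d genes after single-source removal",
                    sum(!keep), min_size))
  }
  structure(out[keep], dropped_modules = names(out)[!keep])
}

#' Chi-square fusion p-value for a module
#'
#' Module statistic `T = sum_g qchisq(1 - p_g, df = 1)` referenced to a
#' chi-square with `k = module size` degrees of freedom (the gene-score
#' fusion used for pathway/module enrichment). Inputs are each member gene's
#' minimum-category meta-analysis p-value.
#'
#' @param p Member-gene p-values in (0, 1].
#' @param method `"chisq"` (default) or `"fisher"` (-2 sum log p against
#'   chi-square 2k) for sensitivity analysis.
#' @return Raw enrichment p-value, attribute `statistic`.
#' @export
module_fusion_pvalue <- function(p, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p <- clip_p(p)
  k <- length(p)
  if (method == "chisq") {
    T <- sum(qchisq(p, df = 1, lower.tail = FALSE))
    structure(pchisq(T, df = k, lower.tail = FALSE), statistic = T)
  } else {
    T <- -2 * sum(log(p))
    structure(pchisq(T, df = 2 * k, lower.tail = FALSE), statistic = T)
  }
}

#' Module enrichment over a gene p-value table
#'
#' Computes the fusion p per module and corrects over the modules tested
#' (Bonferroni by default; Benjamini-Hochberg available). Because the gene
#' inputs are minima over the 10 per-category meta-analysis runs (hence
#' anti-conservative against a uniform reference), an empirical null is
#' available and recommended for headline results: the fusion statistic of
#' each module is ranked against `n_random` size-matched random gene sets
#' drawn from the same p table.
#'
#' @param modules Named list of gene-id vectors (already filtered via
#'   [filter_module_genes()]).
#' @param gene_p Named numeric: gene_id -> p (e.g. min-category CMA p).
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @param empirical_null Use the size-matched random-set null (default FALSE).
#' @param n_random Random sets per module size (default 10000).
#' @param min_overlap Minimum member genes with a p-value (default 2).
#' @param method Fusion flavour, see [module_fusion_pvalue()].
#' @return data.frame: module, trait-agnostic raw `p`, `p_corrected`,
#'   `n_genes`, `statistic`, sorted by raw p; attribute `n_tested`.
#' @export
enrich_modules <- function(modules, gene_p, correction = c("bonferroni", "BH"),
                           empirical_null = FALSE, n_random = 10000L,
                           min_overlap = 2L, method = "chisq") {
  correction <- match.arg(correction)
  gene_p <- gene_p[!is.na(gene_p)]
  rows <- list()
  stats <- numeric(0)
  sizes <- integer(0)
  for (nm in names(modules)) {
    gp <- gene_p[intersect(modules[[nm]], names(gene_p))]
    if (length(gp) < min_overlap) next
    pv <- module_fusion_pvalue(gp, method = method)
    rows[[nm]] <- data.frame(module = nm, p = as.numeric(pv),
                             statistic = attr(pv, "statistic"),
                             n_genes = length(gp), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(module = character(0), p = numeric(0),
                      statistic = numeric(0), n_genes = integer(0),
                      p_corrected = numeric(0))
    attr(out, "n_tested") <- 0L
    return(out)
  }
  out <- do.call(rbind, rows)
  if (empirical_null) {
    qp <- qchisq(clip_p(gene_p), df = 1, lower.tail = FALSE)
    if (method == "fisher") qp <- -2 * log(clip_p(gene_p))
    null_stats <- lapply(sort(unique(out$n_genes)), function(k) {
      matrix(sample(qp, k * n_random, replace = TRUE), nrow = n_random)
    })
    names(null_stats) <- as.character(sort(unique(out$n_genes)))
    out$p <- vapply(seq_len(nrow(out)), function(i) {
      Tn <- rowSums(null_stats[[as.character(out$n_genes[i])]])
      (1 + sum(Tn >= out$statistic[i])) / (n_random + 1)
    }, numeric(1))
  }
  out$p_corrected <- if (correction == "bonferroni") {
    pmin(1, out$p * nrow(out))
  } else {
    p.adjust(out$p, method = "BH")
  }
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(out)
  out
}

#' GO over-representation analysis of a gene set
#'
#' Upper-tail hypergeometric test of the overlap between the module's genes
#' and each GO set, against a background universe, with Benjamini-Hochberg
#' FDR across terms.
#'
#' @param module_genes Character vector of gene ids (intersected with the
#'   background).
#' @param go_sets Named list of GO term gene sets.
#' @param background Character vector: the gene universe (must be non-empty;
#'   GO sets are intersected with it).
#' @param fdr_threshold Flagging threshold (default 0.05).
#' @return data.frame: term, overlap, set_size, module_size, background_size,
#'   p, fdr, significant; sorted by p.
#' @export
go_ora <- function(module_genes, go_sets, background, fdr_threshold = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  mod <- unique(intersect(module_genes, background))
  rows <- lapply(names(go_sets), function(term) {
    set <- unique(intersect(go_sets[[term]], background))
    if (length(set) == 0L) return(NULL)
    ov <- length(intersect(mod, set))
    # P(X >= ov), X ~ Hypergeometric(set in background, draws = module)
    p <- phyper(ov - 1L, length(set), length(background) - length(set),
                length(mod), lower.tail = FALSE)
    data.frame(term = term, overlap = ov, set_size = length(set),
               module_size = length(mod), background_size = length(background),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(term = character(0), overlap = integer(0),
                      set_size = integer(0), module_size = integer(0),
                      background_size = integer(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  }
  rows$fdr <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$fdr < fdr_threshold
  rows <- rows[order(rows$p), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Greedy Jaccard pruning of redundant GO terms
#'
#' Walks the ORA results in ascending p order and keeps a term iff its
#' gene-overlap Jaccard index with every already-kept term is at most
#' `jaccard_threshold` (replaces clustering-based redundancy removal).
#'
#' @param ora [go_ora()] result (or any data.frame with a `term` column,
#'   sorted by p ascending).
#' @param go_sets Named list of the term gene sets (restricted to the
#'   background used in the ORA when applicable).
#' @param jaccard_threshold Maximum tolerated overlap (default 0.5).
#' @return The pruned data.frame (row order preserved).
#' @export
prune_redundant_terms <- function(ora, go_sets, jaccard_threshold = 0.5) {
  if (nrow(ora) == 0L) return(ora)
  kept <- logical(nrow(ora))
  kept_sets <- list()
  for (i in seq_len(nrow(ora))) {
    s <- unique(go_sets[[ora$term[i]]])
    ok <- TRUE
    for (ks in kept_sets) {
      jac <- length(intersect(s, ks)) / length(union(s, ks))
      if (jac > jaccard_threshold) { ok <- FALSE; break }
    }
    if (ok) {
      kept[i] <- TRUE
      kept_sets[[length(kept_sets) + 1L]] <- s
    }
  }
  ora[kept, , drop = FALSE]
}
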