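#' Run the full gene-level integration pipeline on one cohort
#'
#' Orchestrates trait preparation, per-variant GWAS and gene aggregation,
#' expression-trait association, category-wise rare-variant tests, the
#' 10-run correlated meta-analysis, module enrichment and GO
#' over-representation, in that order. When a replication cohort is given,
#' the same stages run there and gene- and module-level replication calls are
#' made against the discovery results.
#'
#' @param cohort A `"cohort_bundle"` (see [simulate_cohort()] or
#'   [read_cohort()]).
#' @param replication Optional second `"cohort_bundle"`.
#' @param alpha Family-wise level (default 0.05).
#' @param window Gene window in bp (default 50000).
#' @param maf_cut Common/rare MAF boundary (default 0.05).
#' @param gif_threshold Inflation trigger for the TWAS empirical-null
#'   correction (default 1.1).
#' @param estimator Inter-source correlation estimator (default "pearson").
#' @param empirical_null Use the size-matched empirical null for module
#'   enrichment (default TRUE, recommended because module inputs are minima
#'   over the 10 runs).
#' @param n_random Random sets for the empirical module null (default
#'   10000; the attainable floor of the corrected p is n_modules / n_random).
#' @param out_dir Optional directory: when given, all result tables and a run
#'   manifest are written as TSV/YAML.
#' @return List of class `"pipeline_result"`: `scores` (combined
#'   [gene_score_table()]), `cma` (`"cma_result"`), `modules`
#'   (enrichment data.frame), `ora` (list per enriched module), `replication`
#'   (list with `gene`, `cma`, `modules` call tables or NULL), `manifest`.
#' @export
run_all <- function(cohort, replication = NULL, alpha = 0.05,
                    window = 50000L, maf_cut = 0.05, gif_threshold = 1.1,
                    estimator = "pearson", empirical_null = TRUE,
                    n_random = 10000L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  res_one <- function(ch) {
    trait <- ch$trait_name
    # A: trait preparation
    y <- stage("trait_prep", prepare_trait(ch$trait, ch$covariates, ch$pcs))
    vm <- fit_variance_model(as.numeric(y), ch$kinship)

    # B1: per-variant GWAS + gene aggregation
    common <- ch$variants[ch$variants$maf >= maf_cut, , drop = FALSE]
    gw <- stage("gwas", {
      ss <- gwas_scan(ch$dosages[common$variant_id, , drop = FALSE],
                      as.numeric(y), vm)
      ss <- cbind(ss, common[match(ss$variant_id, common$variant_id),
                             c("chrom", "pos")])
      ss <- ss[!is.na(ss$p), , drop = FALSE]
      gene_scores_gwas(ss, ch$genes, ch$dosages[common$variant_id, , drop = FALSE],
                       trait, window = window, maf_min = maf_cut)
    })

    # B2: TWAS on the RNA subset
    tw <- stage("twas", {
      al <- if (is.null(ch$kinship)) {
        align_samples(trait = y, counts = ch$counts,
                      samples_in = c("rows", "cols"))
      } else {
        align_samples(trait = y, counts = ch$counts, kin = ch$kinship,
                      samples_in = c("rows", "cols", "rows"))
      }
      filt <- expression_filter(al$counts, ch$intergenic_fraction)
      y_rna <- al$trait[filt$kept_samples]
      adj <- transform_and_adjust(filt$counts[, filt$kept_samples, drop = FALSE],
                                  covariates = ch$covariates[filt$kept_samples, , drop = FALSE])
      kin_rna <- if (is.null(ch$kinship)) NULL else
        ch$kinship[filt$kept_samples, filt$kept_samples]
      expression_trait_assoc(adj$residuals, y_rna, kin_rna, trait,
                             gif_threshold = gif_threshold)
    })

    # B3: category-wise rare-variant tests
    rv <- stage("rva", run_rva(ch$variants, ch$genes, ch$dosages,
                               ch$categories, ch$annotations, as.numeric(y),
                               ch$kinship, trait, window = window,
                               maf_max = maf_cut))

    scores <- rbind(as.data.frame(gw), as.data.frame(tw), as.data.frame(rv))
    scores <- gene_score_table(scores$gene_id, scores$trait, scores$source,
                               scores$category, scores$p, scores$beta,
                               scores$n_units)

    # C: correlated meta-analysis, 10 runs
    cma <- stage("cma", run_cma(scores, alpha = alpha, estimator = estimator))
    list(scores = scores, cma = cma, gif_twas = attr(tw, "gif_raw"))
  }

  disc <- res_one(cohort)

  # D: module enrichment on min-category CMA p + GO ORA
  modres <- stage("modules", {
    filt_mod <- suppressWarnings(
      filter_module_genes(cohort$modules, as.data.frame(disc$scores))
    )
    gene_p <- disc$cma$min_p[!is.na(disc$cma$min_p)]
    enr <- enrich_modules(filt_mod, gene_p, empirical_null = empirical_null,
                          n_random = n_random)
    enriched <- enr$module[enr$p_corrected < alpha]
    background <- names(gene_p)
    ora <- lapply(enriched, function(m) {
      o <- go_ora(filt_mod[[m]], cohort$go_sets, background)
      prune_redundant_terms(o, cohort$go_sets)
    })
    names(ora) <- enriched
    list(enrichment = enr, ora = ora, modules_used = filt_mod)
  })

  repl <- NULL
  if (!is.null(replication)) {
    repl <- stage("replicate", {
      rep_res <- res_one(replication)
      cma_sig <- which(disc$cma$significant)
      disc_pairs <- data.frame(
        gene_id = names(disc$cma$significant)[cma_sig],
        category = disc$cma$min_category[cma_sig],
        stringsAsFactors = FALSE
      )
      rep_cma_tab <- as.data.frame(rep_res$cma$table)
      cma_calls <- replicate_calls(disc_pairs, rep_cma_tab, mode = "cma",
                                   alpha = alpha)
      # gene-level TWAS replication with direction check
      d_tw <- as.data.frame(disc$scores)
      d_tw <- d_tw[d_tw$source == "TWAS", , drop = FALSE]
      n_genes_tw <- max(nrow(d_tw), 1L)
      d_tw_sig <- d_tw[d_tw$p < alpha / n_genes_tw, , drop = FALSE]
      r_tw <- as.data.frame(rep_res$scores)
      r_tw <- r_tw[r_tw$source == "TWAS", , drop = FALSE]
      twas_calls <- replicate_calls(d_tw_sig, r_tw, mode = "gene", alpha = alpha)
      # module replication: Bonferroni over discovery-enriched modules
      enr_d <- modres$enrichment
      enriched_d <- enr_d$module[enr_d$p_corrected < alpha]
      mod_rep <- NULL
      if (length(enriched_d) > 0L) {
        filt_mod_r <- suppressWarnings(
          filter_module_genes(replication$modules, as.data.frame(rep_res$scores))
        )
        gene_p_r <- rep_res$cma$min_p[!is.na(rep_res$cma$min_p)]
        enr_r <- enrich_modules(filt_mod_r[intersect(enriched_d, names(filt_mod_r))],
                                gene_p_r, empirical_null = empirical_null,
                                n_random = n_random)
        thr <- alpha / length(enriched_d)
        mod_rep <- data.frame(module = enr_r$module, p = enr_r$p,
                              replicated = enr_r$p < thr)
        attr(mod_rep, "threshold") <- thr
      }
      list(scores = rep_res$scores, cma = rep_res$cma,
           cma_calls = cma_calls, twas_calls = twas_calls, modules = mod_rep)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("omicsfuse")),
    alpha = alpha, window = window, maf_cut = maf_cut,
    gif_threshold = gif_threshold, estimator = estimator,
    empirical_null = empirical_null, n_random = n_random,
    gif_twas = disc$gif_twas,
    cma_total_tests = disc$cma$total_tests,
    cma_threshold = disc$cma$threshold,
    n_cma_significant = sum(disc$cma$significant, na.rm = TRUE),
    n_modules_tested = attr(modres$enrichment, "n_tested")
  )
  out <- list(scores = disc$scores, cma = disc$cma,
              modules = modres$enrichment, ora = modres$ora,
              replication = repl, manifest = manifest)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' Write pipeline results to a directory
#'
#' @param result A `"pipeline_result"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(result$scores), file.path(dir, "gene_scores.tsv"))
  write_tsv(as.data.frame(result$cma$table), file.path(dir, "cma_scores.tsv"))
  cma_sum <- data.frame(
    gene_id = rownames(result$cma$p),
    min_p = result$cma$min_p,
    min_category = result$cma$min_category,
    significant = result$cma$significant
  )
  write_tsv(cma_sum, file.path(dir, "cma_summary.tsv"))
  write_tsv(result$modules, file.path(dir, "module_enrichment.tsv"))
  if (length(result$ora) > 0L) {
    ora <- do.call(rbind, Map(function(m, o) {
      if (nrow(o) == 0L) return(NULL)
      cbind(module = m, o)
    }, names(result$ora), result$ora))
    if (!is.null(ora)) write_tsv(ora, file.path(dir, "go_ora.tsv"))
  }
  if (!is.null(result$replication)) {
    write_tsv(result$replication$cma_calls, file.path(dir, "replication_cma.tsv"))
    write_tsv(result$replication$twas_calls, file.path(dir, "replication_twas.tsv"))
    if (!is.null(result$replication$modules)) {
      write_tsv(result$replication$modules, file.path(dir, "replication_modules.tsv"))
    }
  }
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort bundle from a directory written by [write_cohort()]
#'
#' @param dir Directory holding genotypes.vcf, genes.tsv, traits.tsv,
#'   covariates.tsv, genetic_pcs.tsv, kinship.tsv (optional),
#'   expression_counts.tsv, rna_sample_metrics.tsv, variant_categories.tsv,
#'   annotations.tsv, modules.gmt, go_sets.gmt.
#' @param trait Trait column to use from traits.tsv (default: first).
#' @return A `"cohort_bundle"`.
#' @export
read_cohort <- function(dir, trait = NULL) {
  vcf <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  traits <- read_tsv(file.path(dir, "traits.tsv"), rownames_col = "sample_id")
  if (is.null(trait)) trait <- names(traits)[1]
  y <- setNames(traits[[trait]], rownames(traits))
  cov <- as.matrix(read_tsv(file.path(dir, "covariates.tsv"),
                            rownames_col = "sample_id"))
  pcs <- as.matrix(read_tsv(file.path(dir, "genetic_pcs.tsv"),
                            rownames_col = "sample_id"))
  kin <- if (file.exists(file.path(dir, "kinship.tsv"))) {
    read_kinship(file.path(dir, "kinship.tsv"))
  } else NULL
  counts <- as.matrix(read_tsv(file.path(dir, "expression_counts.tsv"),
                               rownames_col = "gene_id"))
  metrics <- read_tsv(file.path(dir, "rna_sample_metrics.tsv"),
                      rownames_col = "sample_id")
  cats <- read_tsv(file.path(dir, "variant_categories.tsv"))
  ann <- as.matrix(read_tsv(file.path(dir, "annotations.tsv"),
                            rownames_col = "variant_id"))
  out <- list(
    variants = vcf$variants, dosages = vcf$dosages, genes = genes,
    kinship = kin, samples = names(y), trait = y, covariates = cov,
    pcs = pcs, counts = counts, rna_samples = colnames(counts),
    intergenic_fraction = setNames(metrics$intergenic_fraction, rownames(metrics)),
    categories = setNames(cats$category, cats$variant_id),
    annotations = ann,
    modules = read_gmt(file.path(dir, "modules.gmt")),
    go_sets = read_gmt(file.path(dir, "go_sets.gmt")),
    trait_name = trait
  )
  class(out) <- "cohort_bundle"
  out
}
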