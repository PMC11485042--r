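#' Simulation configuration
#'
#' Assembles the configuration for the synthetic cohort generator. Defaults
#' give a desk-scale family cohort with the statistical structure the
#' pipeline assumes: LD blocks within gene windows, sib-pair relatedness, a
#' polygenic trait component, negative-binomial expression counts with zeros,
#' informative rare-variant annotations, and planted causal genes for each
#' source.
#'
#' @param n_samples Cohort size (default 1000; made even for sib pairs).
#' @param n_rna_samples Samples with expression data (default 500).
#' @param n_genes Number of genes (default 2000).
#' @param common_per_gene,rare_per_gene Variants per gene window (6 / 8).
#' @param ld_rho Latent within-block correlation of common variants (0.5).
#' @param common_maf_range,rare_maf_range Target MAF ranges.
#' @param kinship `"sib_pairs"` (default) or `"unrelated"`.
#' @param h2_polygenic Polygenic trait variance fraction (default 0.2).
#' @param dispersion Negative-binomial dispersion of counts (default 0.1).
#' @param n_annotations Annotation columns (default 6).
#' @param planted_gwas,planted_twas,planted_rva Integer counts of planted
#'   causal genes per source (defaults 0: null cohort). Planted gene ids are
#'   drawn deterministically from the front of the gene list: GWAS genes
#'   first, then TWAS, then RVA; `planted_multi` genes get all three effects.
#' @param planted_multi Genes planted in all three sources (default 0).
#' @param gwas_h2 Per-gene variance fraction of a planted common variant
#'   (default 0.025).
#' @param twas_beta Trait effect per sd of planted gene expression (0.3).
#' @param rva_effect Trait shift per carried rare allele of a planted variant
#'   (default 0.25); `rva_frac` of the gene's plof-category variants are causal.
#' @param rva_frac Fraction of planted-gene rare variants that are causal
#'   (default 0.6).
#' @param expr_loading Loading of the latent expression signal on the
#'   log-scale count mean (default 0.5).
#' @param n_modules Module count (default 220).
#' @param module_size_range Module sizes (default 5..30).
#' @param n_go GO sets (default 60).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 1000L, n_rna_samples = 500L,
                       n_genes = 2000L, common_per_gene = 6L,
                       rare_per_gene = 8L, ld_rho = 0.5,
                       common_maf_range = c(0.05, 0.5),
                       rare_maf_range = c(0.005, 0.05),
                       kinship = c("sib_pairs", "unrelated"),
                       h2_polygenic = 0.2, dispersion = 0.1,
                       n_annotations = 6L,
                       planted_gwas = 0L, planted_twas = 0L, planted_rva = 0L,
                       planted_multi = 0L,
                       gwas_h2 = 0.025, twas_beta = 0.3,
                       rva_effect = 0.25, rva_frac = 0.6,
                       expr_loading = 0.5,
                       n_modules = 220L, module_size_range = c(5L, 30L),
                       n_go = 60L) {
  kinship <- match.arg(kinship)
  cfg <- as.list(environment())
  stopifnot(n_samples > 3, n_genes > 0, common_per_gene > 0, rare_per_gene > 0,
            ld_rho >= 0, ld_rho < 1, n_rna_samples <= n_samples)
  cfg$n_samples <- as.integer(2L * ceiling(n_samples / 2))
  class(cfg) <- "sim_config"
  cfg
}

# Latent haplotype correlation needed so thresholded indicators at allele
# frequency f realize a target dosage correlation (inverts the threshold-model
# attenuation). Cached on the rounded (target, f) pair.
latent_rho_for_dosage <- local({
  cache <- new.env(parent = emptyenv())
  function(target, f) {
    if (target <= 0) return(0)
    key <- sprintf("%.3f_%.3f", target, f)
    if (!is.null(cache[[key]])) return(cache[[key]])
    t <- qnorm(1 - f)
    ind_cor <- function(rho) {
      p11 <- integrate(function(z) dnorm(z) * pnorm((rho * z - t) / sqrt(1 - rho^2)),
                       lower = t, upper = Inf, rel.tol = 1e-9)$value
      (p11 - f^2) / (f * (1 - f))
    }
    hi <- 0.9999
    if (ind_cor(hi) <= target) {
      rho <- hi
    } else {
      rho <- stats::uniroot(function(r) ind_cor(r) - target,
                            lower = max(target - 0.05, 1e-6), upper = hi,
                            tol = 1e-6)$root
    }
    cache[[key]] <- rho
    rho
  }
})

# planted gene ids by source, deterministic from the config
planted_genes <- function(cfg, gene_ids) {
  nm <- cfg$planted_multi
  multi <- if (nm > 0) gene_ids[seq_len(nm)] else character(0)
  at <- nm
  take <- function(k) {
    if (k <= 0) return(character(0))
    ids <- gene_ids[at + seq_len(k)]
    at <<- at + k
    ids
  }
  list(multi = multi,
       gwas = c(multi, take(cfg$planted_gwas)),
       twas = c(multi, take(cfg$planted_twas)),
       rva = c(multi, take(cfg$planted_rva)))
}

#' Simulate genotypes for a synthetic cohort
#'
#' Latent multivariate-normal threshold model: within each gene window the
#' common variants share a latent exchangeable correlation `ld_rho` per
#' haplotype (thresholds set from target allele frequencies), rare variants
#' are independent. Sib-pair relatedness is realized by children sharing
#' parental haplotypes (one per parent, drawn at random, no recombination),
#' giving an expected kinship of 1/4 between sibs.
#'
#' @param cfg A [sim_config()].
#' @return List: `variants` (data.frame with variant_id, chrom, pos, ref, alt,
#'   maf (empirical), target_maf, type, gene_id), `dosages` (variant x sample
#'   integer matrix), `genes` (gene models), `kinship` (pedigree-expected
#'   matrix), `samples`.
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  # genes spaced 200 kb apart so 50 kb windows never overlap
  starts <- 1e5 + (seq_len(cfg$n_genes) - 1L) * 2e5
  genes <- data.frame(gene_id = gene_ids, chrom = "1",
                      start = as.integer(starts),
                      end = as.integer(starts + 2e4),
                      strand = "+", stringsAsFactors = FALSE)
  k_common <- cfg$common_per_gene
  k_rare <- cfg$rare_per_gene
  k_tot <- k_common + k_rare
  n_hap <- 2L * n

  # haplotype ancestry: for sib pairs, haplotypes of the two sibs are copies
  # of 4 parental haplotypes; hap index matrix maps (sample, hap1/hap2) to a
  # founder haplotype id
  if (cfg$kinship == "sib_pairs") {
    n_fam <- n %/% 2L
    founder_of <- matrix(0L, n, 2L)
    n_founder <- 4L * n_fam
    for (f in seq_len(n_fam)) {
      base <- 4L * (f - 1L)
      s1 <- 2L * f - 1L; s2 <- 2L * f
      founder_of[s1, ] <- base + c(sample(1:2, 1), sample(3:4, 1))
      founder_of[s2, ] <- base + c(sample(1:2, 1), sample(3:4, 1))
    }
    K <- diag(0.5, n)
    for (f in seq_len(n_fam)) {
      K[2L * f - 1L, 2L * f] <- K[2L * f, 2L * f - 1L] <- 0.25
    }
  } else {
    founder_of <- cbind(seq_len(n) * 2L - 1L, seq_len(n) * 2L)
    n_founder <- n_hap
    K <- NULL
  }
  dimnames_v <- sprintf("V%06d", seq_len(cfg$n_genes * k_tot))
  dos <- matrix(0L, cfg$n_genes * k_tot, n,
                dimnames = list(dimnames_v, samples))
  vinfo <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    f_common <- runif(k_common, cfg$common_maf_range[1], cfg$common_maf_range[2])
    f_rare <- runif(k_rare, cfg$rare_maf_range[1], cfg$rare_maf_range[2])
    thr_c <- qnorm(1 - f_common)
    # latent correlation boosted so the *dosage* correlation hits ld_rho
    rho_lat <- latent_rho_for_dosage(cfg$ld_rho, round(mean(f_common), 2))
    sq <- sqrt(rho_lat)
    # founder haplotypes: common = thresholded exchangeable latent; rare = iid
    shared <- rnorm(n_founder)
    lat <- sq * shared + sqrt(1 - rho_lat) * matrix(rnorm(n_founder * k_common), n_founder)
    hap_c <- t(lat) > thr_c            # k_common x n_founder logical
    hap_c <- t(hap_c * 1L)             # n_founder x k_common
    hap_r <- matrix(rbinom(n_founder * k_rare, 1L, rep(f_rare, each = n_founder)),
                    n_founder, k_rare)
    hap <- cbind(hap_c, hap_r)         # n_founder x k_tot
    d <- hap[founder_of[, 1L], ] + hap[founder_of[, 2L], ]
    rows <- (g - 1L) * k_tot + seq_len(k_tot)
    dos[rows, ] <- t(d)
    pos <- genes$start[g] + sort(sample.int(2e4 + 1e5, k_tot)) - 5e4
    vinfo[[g]] <- data.frame(
      variant_id = dimnames_v[rows], chrom = "1",
      pos = as.integer(pmax(1L, pos)), ref = "A", alt = "G",
      target_maf = c(f_common, f_rare),
      type = rep(c("common", "rare"), c(k_common, k_rare)),
      gene_id = gene_ids[g], stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, vinfo)
  af <- rowMeans(dos) / 2
  variants$maf <- pmin(af, 1 - af)
  if (!is.null(K)) dimnames(K) <- list(samples, samples)
  list(variants = variants, dosages = dos, genes = genes, kinship = K,
       samples = samples)
}

#' Simulate the phenome over simulated genotypes
#'
#' Builds the trait (covariate effects + planted genetic / expression / rare
#' burden effects + kinship polygenic term + noise), covariates, genetic PCs,
#' negative-binomial expression counts on an RNA subset with cis effects for
#' planted TWAS genes, rare-variant functional categories and annotations
#' (informative for planted causal rare variants), protein-interaction style
#' modules with one planted enriched module, and GO sets with one planted
#' term.
#'
#' @param geno Output of [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A cohort bundle (list of class `"cohort_bundle"`): everything in
#'   `geno` plus `trait` (named vector), `covariates`, `pcs`, `counts`
#'   (gene x RNA-sample), `rna_samples`, `intergenic_fraction`, `categories`,
#'   `annotations`, `modules`, `go_sets`, `planted` (per-source gene ids and
#'   causal variant ids), `trait_name`.
#' @export
simulate_phenome <- function(geno, cfg) {
  n <- length(geno$samples)
  gene_ids <- geno$genes$gene_id
  pl <- planted_genes(cfg, gene_ids)

  # covariates: age, age^2 (implicit via adjustment), sex, field center
  age <- rnorm(n, 55, 10)
  sex <- rbinom(n, 1L, 0.5)
  center <- rbinom(n, 1L, 0.5)
  covariates <- cbind(age = age, age2 = age^2, sex = sex, center = center)
  rownames(covariates) <- geno$samples

  # polygenic term from the pedigree kinship (block-diagonal sib pairs)
  sg <- sqrt(cfg$h2_polygenic)
  if (is.null(geno$kinship)) {
    poly <- rnorm(n) * sg
  } else {
    # chol of 2K for a sib pair: [[1, .5], [.5, 1]]
    a <- rnorm(n); b <- rnorm(n)
    poly <- a
    for (f in seq_len(n %/% 2L)) {
      i <- 2L * f - 1L; j <- 2L * f
      poly[j] <- 0.5 * a[i] + sqrt(0.75) * b[j]
    }
    poly <- poly * sg
  }

  y <- 0.02 * (age - 55) + 0.3 * sex + 0.15 * center + poly +
    rnorm(n, 0, sqrt(1 - cfg$h2_polygenic))

  causal <- list(gwas = character(0), rva = character(0))
  # planted common-variant effects
  for (g in pl$gwas) {
    vids <- geno$variants$variant_id[geno$variants$gene_id == g &
                                       geno$variants$type == "common"]
    vid <- vids[which.max(geno$variants$maf[match(vids, geno$variants$variant_id)])]
    dose <- geno$dosages[vid, ]
    if (var(dose) > 0) {
      beta <- sqrt(cfg$gwas_h2 / var(dose))
      y <- y + beta * dose
      causal$gwas <- c(causal$gwas, vid)
    }
  }

  # rare-variant burden in the plof category of planted RVA genes
  categories <- setNames(rep(NA_character_, nrow(geno$variants)),
                         geno$variants$variant_id)
  rare_ids <- geno$variants$variant_id[geno$variants$type == "rare"]
  categories[rare_ids] <- sample(rva_categories(), length(rare_ids), replace = TRUE)
  for (g in pl$rva) {
    vids <- geno$variants$variant_id[geno$variants$gene_id == g &
                                       geno$variants$type == "rare"]
    categories[vids] <- "plof"                   # concentrate the signal
    k_causal <- max(2L, round(cfg$rva_frac * length(vids)))
    cv <- vids[seq_len(min(k_causal, length(vids)))]
    burden <- colSums(geno$dosages[cv, , drop = FALSE])
    y <- y + cfg$rva_effect * burden
    causal$rva <- c(causal$rva, cv)
  }
  categories <- categories[rare_ids]

  # expression: latent per-gene signal; planted TWAS genes feed the trait
  rna_samples <- geno$samples[seq_len(cfg$n_rna_samples)]
  idx_rna <- match(rna_samples, geno$samples)
  e_lat <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n,
                  dimnames = list(gene_ids, geno$samples))
  for (g in pl$twas) {
    y <- y + cfg$twas_beta * e_lat[g, ]
  }
  # counts: NB with lognormal baselines (some genes near zero to exercise the
  # CPM filter), library-size variation, and a mild batch shift
  base_expr <- rnorm(cfg$n_genes, 4, 2)
  base_expr[seq(1L, cfg$n_genes, by = 37L)] <- -6   # forced-low genes
  lib <- exp(rnorm(cfg$n_rna_samples, 0, 0.15))
  batch <- rbinom(cfg$n_rna_samples, 1L, 0.5)
  log_mu <- outer(base_expr, log(lib), "+") +
    cfg$expr_loading * e_lat[, idx_rna, drop = FALSE] +
    matrix(rep(0.1 * batch, each = cfg$n_genes), cfg$n_genes)
  mu <- exp(log_mu)
  size <- 1 / cfg$dispersion
  counts <- matrix(rpois(length(mu), rgamma(length(mu), shape = size, rate = size / mu)),
                   nrow = cfg$n_genes,
                   dimnames = list(gene_ids, rna_samples))
  intergenic <- setNames(runif(cfg$n_rna_samples, 0.01, 0.05), rna_samples)

  # annotations: standard-normal scores, shifted upward for causal variants
  ann <- matrix(rnorm(length(rare_ids) * cfg$n_annotations),
                length(rare_ids), cfg$n_annotations,
                dimnames = list(rare_ids,
                                paste0("annot", seq_len(cfg$n_annotations))))
  if (length(causal$rva) > 0L) {
    ann[causal$rva, ] <- ann[causal$rva, , drop = FALSE] + 1.5
  }

  # modules: random gene sets; module 1 planted with the causal genes
  sizes <- pmin(sample(cfg$module_size_range[1]:cfg$module_size_range[2],
                       cfg$n_modules, replace = TRUE), cfg$n_genes)
  modules <- lapply(sizes, function(k) sample(gene_ids, k))
  names(modules) <- sprintf("MOD%03d", seq_len(cfg$n_modules))
  planted_set <- unique(c(pl$gwas, pl$twas, pl$rva))
  if (length(planted_set) > 0L) {
    pool <- setdiff(gene_ids, planted_set)
    fill <- sample(pool, min(length(pool), max(0L, 12L - length(planted_set))))
    modules[["MOD001"]] <- c(planted_set, fill)
  }
  go_sizes <- pmin(sample(10:40, cfg$n_go, replace = TRUE), cfg$n_genes)
  go_sets <- lapply(go_sizes, function(k) sample(gene_ids, k))
  names(go_sets) <- sprintf("GO:%07d", seq_len(cfg$n_go))
  if (length(planted_set) > 0L) {
    go_sets[["GO:0000001"]] <- unique(c(planted_set,
                                        sample(gene_ids, min(10L, cfg$n_genes))))
  }

  # genetic PCs from a thinned set of common variants
  common_ids <- geno$variants$variant_id[geno$variants$type == "common"]
  thin <- common_ids[seq(1L, length(common_ids),
                         length.out = min(1000L, length(common_ids)))]
  Gt <- t(geno$dosages[thin, , drop = FALSE])
  Gt <- Gt[, apply(Gt, 2L, var) > 0, drop = FALSE]
  pcs <- prcomp(Gt, center = TRUE, scale. = TRUE)$x[, 1:10, drop = FALSE]
  rownames(pcs) <- geno$samples

  names(y) <- geno$samples
  out <- c(geno, list(
    trait = y, covariates = covariates, pcs = pcs, counts = counts,
    rna_samples = rna_samples, intergenic_fraction = intergenic,
    categories = categories, annotations = ann, modules = modules,
    go_sets = go_sets, planted = c(pl, list(causal = causal)),
    trait_name = "trait1", config = cfg
  ))
  class(out) <- "cohort_bundle"
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: seeds the RNG, simulates genotypes and the phenome.
#' A fixed seed gives a fully deterministic cohort.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A `"cohort_bundle"`, see [simulate_phenome()].
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  simulate_phenome(simulate_genotypes(cfg), cfg)
}

#' Write a synthetic cohort to disk
#'
#' Emits files matching every reader in the package: a VCF of all variants,
#' TSVs for trait/covariates/kinship/annotations/categories/counts, and GMTs
#' for modules and GO sets.
#'
#' @param cohort A `"cohort_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(cohort$variants, cohort$dosages, file.path(dir, "genotypes.vcf"))
  write_tsv(cohort$genes, file.path(dir, "genes.tsv"))
  tr <- data.frame(sample_id = names(cohort$trait), trait1 = cohort$trait)
  write_tsv(tr, file.path(dir, "traits.tsv"))
  cov <- data.frame(sample_id = rownames(cohort$covariates), cohort$covariates)
  write_tsv(cov, file.path(dir, "covariates.tsv"))
  pcs <- data.frame(sample_id = rownames(cohort$pcs), cohort$pcs)
  write_tsv(pcs, file.path(dir, "genetic_pcs.tsv"))
  if (!is.null(cohort$kinship)) {
    write_tsv(as.data.frame(cohort$kinship), file.path(dir, "kinship.tsv"),
              rownames_col = "sample_id")
  }
  write_tsv(as.data.frame(cohort$counts), file.path(dir, "expression_counts.tsv"),
            rownames_col = "gene_id")
  write_tsv(data.frame(sample_id = names(cohort$intergenic_fraction),
                       intergenic_fraction = cohort$intergenic_fraction),
            file.path(dir, "rna_sample_metrics.tsv"))
  write_tsv(data.frame(variant_id = names(cohort$categories),
                       category = cohort$categories),
            file.path(dir, "variant_categories.tsv"))
  write_tsv(as.data.frame(cohort$annotations), file.path(dir, "annotations.tsv"),
            rownames_col = "variant_id")
  write_gmt(cohort$modules, file.path(dir, "modules.gmt"))
  write_gmt(cohort$go_sets, file.path(dir, "go_sets.gmt"))
  invisible(dir)
}

#' Write variants and dosages as a minimal VCF
#'
#' @param variants data.frame: variant_id, chrom, pos, ref, alt.
#' @param dosages Variant x sample dosage matrix in {0,1,2,NA}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, dosages, path) {
  samples <- colnames(dosages)
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  d <- dosages[v$variant_id, , drop = FALSE]
  gt <- matrix("./.", nrow(d), ncol(d))
  for (k in 0:2) gt[!is.na(d) & d == k] <- gt_codes[[as.character(k)]]
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
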