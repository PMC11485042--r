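test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 60L, n_rna_samples = 30L, n_genes = 10L,
                    n_modules = 5L, n_go = 4L)
  c1 <- simulate_cohort(cfg, seed = 9L)
  c2 <- simulate_cohort(cfg, seed = 9L)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$trait, c2$trait)
  expect_identical(c1$counts, c2$counts)
  # byte-identical VCF on rerun
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(c1$variants, c1$dosages, f1)
  write_vcf(c2$variants, c2$dosages, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("target allele frequencies and LD are realized", {
  cfg <- sim_config(n_samples = 2000L, n_rna_samples = 10L, n_genes = 8L,
                    common_maf_range = c(0.3, 0.3), ld_rho = 0.8,
                    kinship = "unrelated", n_modules = 2L, n_go = 2L)
  set.seed(61)
  g <- simulate_genotypes(cfg)
  common <- g$variants[g$variants$type == "common", ]
  expect_true(all(common$maf > 0.27 & common$maf < 0.33))
  # mean within-block dosage correlation (threshold-model attenuation)
  cors <- sapply(unique(common$gene_id), function(gid) {
    ids <- common$variant_id[common$gene_id == gid]
    R <- cor(t(g$dosages[ids, ]))
    mean(R[upper.tri(R)])
  })
  expect_gt(mean(cors), 0.6)
  expect_lt(mean(cors), 0.9)
  # rare variants stay in the rare band
  rare <- g$variants[g$variants$type == "rare", ]
  expect_true(all(rare$maf < 0.06))
})

test_that("sib-pair cohorts realize the pedigree kinship", {
  cfg <- sim_config(n_samples = 1000L, n_rna_samples = 10L, n_genes = 20L,
                    n_modules = 2L, n_go = 2L)
  set.seed(62)
  g <- simulate_genotypes(cfg)
  expect_equal(g$kinship[1, 2], 0.25)
  expect_equal(g$kinship[1, 1], 0.5)
  expect_equal(g$kinship[2, 3], 0)
  # empirical dosage correlation between sibs ~ 2 * kinship = 0.5
  odd <- seq(1, 1000, by = 2)
  common <- g$variants$variant_id[g$variants$type == "common"]
  rr <- sapply(common[seq(1, length(common), by = 5)], function(v)
    cor(g$dosages[v, odd], g$dosages[v, odd + 1]))
  expect_gt(mean(rr), 0.4)
  expect_lt(mean(rr), 0.6)
})

test_that("a written cohort round-trips through the readers", {
  ch <- small_planted_cohort()
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$dosages[rownames(ch$dosages), colnames(ch$dosages)],
               ch$dosages + 0)          # storage mode double after VCF
  expect_equal(back$trait, ch$trait)
  expect_equal(back$kinship, ch$kinship)
  expect_equal(unclass(back$modules), unclass(ch$modules), ignore_attr = TRUE)
  expect_equal(back$categories[names(ch$categories)], ch$categories)
  expect_equal(back$annotations[rownames(ch$annotations), ], ch$annotations,
               tolerance = 1e-6)
  expect_equal(back$genes$start, ch$genes$start)
})

test_that("a zero-effect cohort yields uniform p-values in every source", {
  ch <- simulate_cohort(sim_config(n_samples = 500L, n_rna_samples = 250L,
                                   n_genes = 300L, n_modules = 20L, n_go = 5L),
                        seed = 63L)
  res <- suppressWarnings(run_all(ch, empirical_null = FALSE))
  sc <- as.data.frame(res$scores)
  for (s in c("GWAS", "TWAS", "RVA")) {
    ps <- sc$p[sc$source == s]
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  }
})

test_that("planted effects give the planted genes detectable signal", {
  ch <- small_planted_cohort()
  res <- fixture("small_planted_result", function()
    suppressWarnings(run_all(small_planted_cohort(), empirical_null = FALSE)))
  sc <- as.data.frame(res$scores)
  planted <- ch$planted$multi
  null_genes <- setdiff(unique(sc$gene_id), unique(unlist(ch$planted[c("gwas", "twas", "rva")])))
  # planted genes' CMA minima are collectively smaller than null genes'
  expect_lt(median(res$cma$min_p[planted], na.rm = TRUE),
            median(res$cma$min_p[null_genes], na.rm = TRUE))
})
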