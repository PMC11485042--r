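test_that("single-source genes are removed from modules before enrichment", {
  scores <- gene_score_table(
    gene_id = c("A", "B", "B", "C", "C", "D"),
    trait = "t",
    source = c("GWAS", "GWAS", "TWAS", "GWAS", "RVA", "TWAS"),
    category = c("none", "none", "none", "none", "plof", "none"),
    p = rep(0.5, 6)
  )
  mods <- list(M1 = c("A", "B", "C"), M2 = c("A", "D"), M3 = c("B", "C"))
  expect_warning(filt <- filter_module_genes(mods, scores), "dropping")
  expect_equal(filt$M1, c("B", "C"))     # A has GWAS only
  expect_false("M2" %in% names(filt))    # all members single-source
  expect_equal(filt$M3, c("B", "C"))     # unchanged
})

test_that("fusion p-value matches chi-square closed forms and is order-invariant", {
  expect_equal(as.numeric(module_fusion_pvalue(0.2)), 0.2, tolerance = 1e-12)
  T2 <- 2 * qchisq(0.95, 1)
  expect_equal(as.numeric(module_fusion_pvalue(c(0.05, 0.05))), exp(-T2 / 2),
               tolerance = 1e-10)
  set.seed(51)
  p <- runif(8)
  expect_equal(as.numeric(module_fusion_pvalue(p)),
               as.numeric(module_fusion_pvalue(sample(p))), tolerance = 1e-12)
  expect_error(module_fusion_pvalue(c(0.5, 0)), "0, 1")
})

test_that("fusion p is uniform over null modules and a p=1 gene adds no signal", {
  set.seed(52)
  ps <- replicate(1000, as.numeric(module_fusion_pvalue(runif(sample(3:20, 1)))))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # appending an uninformative p=1 gene raises the df but adds no statistic:
  # the result is conservative, never inflated
  set.seed(53)
  p_with <- replicate(500, as.numeric(module_fusion_pvalue(c(runif(10), 1))))
  expect_lte(mean(p_with < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
  expect_gte(mean(p_with), 0.5)
})

test_that("module enrichment ranks a planted module first and corrects correctly", {
  # Bonferroni arithmetic
  mods <- setNames(lapply(1:13, function(i) sprintf("g%02d", i + 0:4)),
                   paste0("M", 1:13))
  gene_p <- setNames(rep(0.5, 30), sprintf("g%02d", 1:30))
  gene_p[mods$M1] <- 1e-5
  enr <- enrich_modules(mods, gene_p)
  expect_equal(attr(enr, "n_tested"), 13L)
  expect_equal(enr$p_corrected, pmin(1, enr$p * 13))
  expect_equal(enr$module[1], "M1")
  # all-0.5 module is far from significant
  expect_gt(enr$p_corrected[enr$module == "M13"], 0.99)

  # planted Beta(0.1, 1) module ranks first among 200 nulls in >= 18/20 seeds
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    genes <- sprintf("g%04d", 1:2000)
    gp <- setNames(runif(2000), genes)
    mods <- lapply(1:200, function(i) sample(genes, 10))
    names(mods) <- paste0("M", 1:200)
    gp[mods$M1] <- rbeta(10, 0.1, 1)
    enr <- enrich_modules(mods, gp)
    if (enr$module[1] == "M1") wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("empirical-null enrichment agrees with the analytic p on null data", {
  set.seed(54)
  genes <- sprintf("g%04d", 1:1000)
  gp <- setNames(runif(1000), genes)
  mods <- lapply(1:50, function(i) sample(genes, 12))
  names(mods) <- paste0("M", 1:50)
  enr_a <- enrich_modules(mods, gp)
  enr_e <- enrich_modules(mods, gp, empirical_null = TRUE, n_random = 4000L)
  m <- match(enr_a$module, enr_e$module)
  expect_gt(cor(enr_a$p, enr_e$p[m]), 0.98)
})

test_that("hypergeometric ORA matches enumeration and flags by BH FDR", {
  # extreme table: all 5 module genes inside a 5-gene set, background 20
  bg <- sprintf("g%02d", 1:20)
  go <- list(T1 = bg[1:5])
  res <- go_ora(bg[1:5], go, bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-10)
  # zero overlap has p = 1
  go0 <- list(T1 = bg[6:10])
  expect_equal(go_ora(bg[1:5], go0, bg)$p, 1)

  # enumeration oracle on a toy instance
  set.seed(55)
  bg2 <- sprintf("h%02d", 1:15)
  mod <- sample(bg2, 6)
  gos <- list(A = sample(bg2, 4), B = sample(bg2, 7), C = sample(bg2, 3))
  res2 <- go_ora(mod, gos, bg2)
  for (i in seq_len(nrow(res2))) {
    K <- res2$set_size[i]; nmod <- res2$module_size[i]; N <- 15
    # P(overlap >= k) by direct summation of hypergeometric mass
    kk <- res2$overlap[i]:min(K, nmod)
    mass <- sum(choose(K, kk) * choose(N - K, nmod - kk) / choose(N, nmod))
    expect_equal(res2$p[i], mass, tolerance = 1e-10)
  }
  expect_equal(res2$fdr, p.adjust(res2$p, "BH"))
})

test_that("BH step-up matches a hand-computed oracle on a 10-term vector", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up: adjusted_i = min_{j >= i} (n p_(j) / j), capped at 1
  n <- length(p)
  adj <- rev(cummin(rev(p * n / seq_len(n))))
  expect_equal(p.adjust(p, "BH"), pmin(adj, 1))
})

test_that("greedy Jaccard pruning keeps the smaller-p of identical terms", {
  sets <- list(T1 = c("a", "b", "c"), T2 = c("a", "b", "c"),
               T3 = c("x", "y"), T4 = c("a", "x"))
  ora <- data.frame(term = c("T1", "T2", "T3", "T4"),
                    p = c(0.001, 0.002, 0.01, 0.02))
  pr <- prune_redundant_terms(ora, sets, jaccard_threshold = 0.5)
  expect_equal(pr$term, c("T1", "T3", "T4"))
  # disjoint terms all kept
  pr2 <- prune_redundant_terms(ora[3:4, ], sets)
  expect_equal(pr2$term, c("T3", "T4"))
  # threshold 1 keeps everything
  pr3 <- prune_redundant_terms(ora, sets, jaccard_threshold = 1)
  expect_equal(pr3$term, ora$term)
})
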