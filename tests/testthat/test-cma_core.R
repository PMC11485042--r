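test_that("p-to-z conversion is the upper-tail normal quantile", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.025), 1.95996, tolerance = 1e-5)
  expect_equal(p_to_z(1), -37)          # clipped boundary
  expect_true(is.finite(p_to_z(1e-320)))
  expect_error(p_to_z(0), "0, 1")
  expect_error(p_to_z(1.2), "0, 1")
})

test_that("tetrachoric estimator solves the median-split likelihood", {
  expect_equal(omicsfuse:::tetrachoric_from_table(c(25, 25, 25, 25)), 0,
               tolerance = 1e-6)
  expect_gte(omicsfuse:::tetrachoric_from_table(c(50, 0, 0, 50)), 0.99)
  # grid-search oracle on random tables
  set.seed(41)
  for (i in 1:5) {
    n <- c(rmultinom(1, 200, runif(4, 0.1, 1)))
    grid <- seq(-0.999, 0.999, by = 0.0005)
    ll <- sapply(grid, function(rho) {
      p11 <- 0.25 + asin(rho) / (2 * pi)
      probs <- pmax(c(p11, 0.5 - p11, 0.5 - p11, p11), 1e-12)
      sum(n * log(probs))
    })
    expect_lt(abs(omicsfuse:::tetrachoric_from_table(n) - grid[which.max(ll)]),
              2e-3)
  }
})

test_that("null correlation estimation detects shared and independent sources", {
  set.seed(42)
  z1 <- rnorm(5000)
  Z <- cbind(A = z1, B = z1, C = rnorm(5000))
  cm <- estimate_null_correlation(Z)
  expect_equal(cm$sigma["A", "B"], 0.99)       # duplicated column, clipped
  expect_lt(abs(cm$sigma["A", "C"]), 0.05)      # independent
  expect_equal(cm$estimator, "pearson")
  expect_gte(min(eigen(cm$sigma, only.values = TRUE)$values), -1e-12)

  cm2 <- estimate_null_correlation(Z, estimator = "tetrachoric")
  expect_gte(cm2$sigma["A", "B"], 0.99)
  expect_lt(abs(cm2$sigma["A", "C"]), 0.08)

  # too few null genes falls back with a warning
  Zs <- Z[1:40, ]
  expect_warning(estimate_null_correlation(Zs), "falling back")
})

test_that("combine is exact for K=1, Stouffer at identity, and redundant at rho=1", {
  expect_equal(combine(p_to_z(0.03), matrix(1, 1, 1)), 0.03, tolerance = 1e-12)
  # Sigma = I reduces to unweighted Stouffer on 1000 random inputs
  set.seed(43)
  for (i in 1:1000) {
    K <- sample(2:3, 1)
    p <- runif(K, 1e-6, 1)
    z <- p_to_z(p)
    stouffer <- pnorm(sum(z) / sqrt(K), lower.tail = FALSE)
    expect_lt(abs(combine(z, diag(K)) - stouffer), 1e-12)
  }
  # fully correlated identical inputs return the common p
  S <- matrix(c(1, 1, 1, 1), 2)
  expect_lt(abs(combine(p_to_z(c(0.05, 0.05)), S) - 0.05), 1e-10)
  # K=2, both p=0.05, rho=0: (1.6449+1.6449)/sqrt(2) = 2.3262
  expect_equal(combine(p_to_z(c(0.05, 0.05)), diag(2)),
               pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  # a gene with one observed source gets exactly that source's p back
  expect_equal(combine(c(NA, p_to_z(0.2), NA), diag(3)), 0.2, tolerance = 1e-12)
})

test_that("combine is monotone in each input p", {
  set.seed(44)
  S <- matrix(0.3, 3, 3); diag(S) <- 1
  for (i in 1:50) {
    p <- runif(3, 0.01, 0.99)
    p0 <- combine(p_to_z(p), S)
    j <- sample(3, 1)
    p_dec <- p; p_dec[j] <- p[j] * 0.5
    expect_lte(combine(p_to_z(p_dec), S), p0 + 1e-14)
  }
})

test_that("run_cma aggregates tests across the 10 category runs", {
  set.seed(45)
  n_genes <- 400
  genes <- sprintf("g%03d", 1:n_genes)
  mk <- function(src, cat = "none", p) {
    gene_score_table(genes, "bmi", src, cat, p)
  }
  scores <- rbind(mk("GWAS", p = runif(n_genes)), mk("TWAS", p = runif(n_genes)))
  # RVA rows in 3 categories only, on subsets
  for (cat in c("plof", "missense", "UTR")) {
    sub <- sample(genes, 300)
    scores <- rbind(scores, gene_score_table(sub, "bmi", "RVA", cat, runif(300)))
  }
  scores <- gene_score_table(scores$gene_id, scores$trait, scores$source,
                             scores$category, scores$p, scores$beta,
                             scores$n_units)
  res <- run_cma(scores)
  # every gene tested in every run (GWAS+TWAS present throughout)
  expect_equal(unname(res$tests_per_run), rep(n_genes, 10))
  expect_equal(res$total_tests, sum(res$tests_per_run))
  expect_equal(res$threshold, 0.05 / res$total_tests)
  expect_true(all(res$min_p <= apply(res$p, 1, min, na.rm = TRUE) + 1e-15))

  # a gene with an extreme TWAS p is significant wherever tested
  scores2 <- as.data.frame(scores)
  scores2$p[scores2$gene_id == "g001" & scores2$source == "TWAS"] <- 1e-10
  scores2$p[scores2$gene_id == "g001" & scores2$source == "GWAS"] <- 0.5
  scores2 <- gene_score_table(scores2$gene_id, scores2$trait, scores2$source,
                              scores2$category, scores2$p, scores2$beta,
                              scores2$n_units)
  res2 <- run_cma(scores2)
  expect_true(res2$significant[["g001"]])

  # fewer than two sources is an error
  expect_error(run_cma(mk("GWAS", p = runif(n_genes))), "two sources")
})

test_that("replication thresholds count genes or gene-category pairs", {
  disc <- data.frame(gene_id = sprintf("g%02d", 1:30), beta = rep(c(1, -1), 15))
  repl <- gene_score_table(sprintf("g%02d", 1:30), "t", "TWAS", "none",
                           c(1e-4, rep(0.5, 29)), beta = rep(1, 30))
  calls <- replicate_calls(disc, repl, mode = "gene")
  expect_equal(attr(calls, "threshold"), 0.05 / 30)
  expect_true(calls$replicated[1])
  expect_equal(sum(calls$replicated), 1L)
  expect_true(calls$direction_consistent[1])
  expect_false(calls$direction_consistent[2])

  # gene-category pairs for CMA mode
  disc2 <- data.frame(gene_id = c("g1", "g1", "g2"),
                      category = c("plof", "UTR", "plof"))
  repl2 <- gene_score_table(c("g1", "g1", "g2"), "t", "CMA",
                            c("plof", "UTR", "plof"), c(0.001, 0.9, 0.9))
  calls2 <- replicate_calls(disc2, repl2, mode = "cma")
  expect_equal(attr(calls2, "threshold"), 0.05 / 3)
  expect_equal(calls2$replicated, c(TRUE, FALSE, FALSE))

  # zero discovery rows: empty output, no threshold
  empty <- replicate_calls(disc[0, , drop = FALSE], repl, mode = "gene")
  expect_equal(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "threshold")))
})
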