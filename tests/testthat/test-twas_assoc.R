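test_that("expression filter applies the CPM rule exactly", {
  # all-zero gene always dropped
  cnt <- rbind(zero = rep(0L, 4), ok = c(100L, 200L, 150L, 120L))
  colnames(cnt) <- paste0("S", 1:4)
  f <- expression_filter(cnt)
  expect_false("zero" %in% f$kept_genes)
  expect_true("ok" %in% f$kept_genes)

  # CPM < 3 in 2/3 samples = 0.667 <= 0.985 -> kept
  cnt2 <- matrix(c(0L, 0L, 5L), 1, dimnames = list("g", paste0("S", 1:3)))
  cnt2 <- rbind(cnt2, lib = c(1e6L, 1e6L, 1e6L) - as.integer(cnt2[1, ]))
  f2 <- expression_filter(cnt2)
  expect_true("g" %in% f2$kept_genes)

  # brute-force oracle on a random matrix
  set.seed(8)
  M <- matrix(rpois(200 * 100, exp(rnorm(200 * 100, 1, 2))), 200, 100,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:100)))
  f3 <- expression_filter(M)
  cpm <- sweep(M, 2, colSums(M), "/") * 1e6
  keep_oracle <- rownames(M)[sapply(seq_len(nrow(M)), function(i)
    mean(cpm[i, ] < 3) <= 0.985)]
  expect_equal(f3$kept_genes, keep_oracle)

  # intergenic-fraction sample filter
  ig <- setNames(c(0.02, 0.09, 0.03, 0.01), colnames(cnt))
  f4 <- expression_filter(cnt, intergenic_fraction = ig)
  expect_equal(f4$kept_samples, c("S1", "S3", "S4"))

  # zero library size dropped with warning
  cnt5 <- cnt; cnt5[, 2] <- 0L
  expect_warning(f5 <- expression_filter(cnt5), "zero library")
  expect_false("S2" %in% f5$kept_samples)
})

test_that("transform and adjustment remove covariate and batch structure", {
  set.seed(15)
  n <- 120; g <- 60
  lib <- rep(1e6L, n)
  base <- matrix(rpois(g * n, 400), g, n,
                 dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  # no covariate effect: residual ~ transform output
  adj0 <- transform_and_adjust(base, covariates = NULL, n_pcs = 0L)
  raw <- log2(sweep(base, 2, colSums(base), "/") * 1e6 + 0.5)
  cors <- sapply(seq_len(g), function(i)
    cor(adj0$residuals[i, ], raw[i, ] - mean(raw[i, ])))
  expect_gt(min(cors), 0.999)

  # planted +2 log2 batch shift (half the genes, half the samples) is removed
  batch <- rep(c(0, 1), each = n / 2)
  shifted <- base
  shifted[1:30, batch == 1] <- round(base[1:30, batch == 1] * 4)
  adj1 <- transform_and_adjust(shifted, covariates = NULL,
                               batch = batch, n_pcs = 5L)
  bdiff <- apply(adj1$residuals, 1, function(r)
    abs(mean(r[batch == 1]) - mean(r[batch == 0])))
  expect_lt(max(bdiff), 0.05)

  # alpha = 0 retains nothing: residuals equal base-covariate residuals
  adj2 <- transform_and_adjust(base, covariates = NULL, n_pcs = 5L, alpha = 0)
  expect_true(all(lengths(adj2$retained) == 0))
  expect_equal(adj2$residuals, adj0$residuals[rownames(adj2$residuals), ])
})

test_that("expression-trait association reduces to OLS when unrelated", {
  set.seed(16)
  n <- 100
  e <- matrix(rnorm(n), 1, n, dimnames = list("g1", paste0("s", 1:n)))
  y <- setNames(0.4 * e[1, ] + rnorm(n), colnames(e))
  tab <- expression_trait_assoc(e, y, kinship = NULL, trait = "t")
  fit <- summary(lm(y ~ e[1, ]))$coefficients
  expect_equal(tab$beta, fit[2, 1], tolerance = 1e-8)
  expect_equal(tab$p, fit[2, 4], tolerance = 1e-8)
})

test_that("expression-trait association is calibrated under the null", {
  set.seed(17)
  n <- 200; g <- 1000
  e <- matrix(rnorm(g * n), g, n, dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  y <- setNames(rnorm(n), colnames(e))
  tab <- expression_trait_assoc(e, y, kinship = NULL, trait = "t")
  gif <- genomic_inflation_factor(tab$p)
  expect_gt(gif, 0.9)
  expect_lt(gif, 1.1)
  expect_gt(stats::ks.test(tab$p, "punif")$p.value, 0.01)
})

test_that("planted expression effects are recovered with the right sign", {
  set.seed(18)
  n <- 500
  hits <- 0L; signs_ok <- 0L
  for (rep in 1:20) {
    e <- matrix(rnorm(n), 1, n, dimnames = list("g1", paste0("s", 1:n)))
    y <- setNames(0.5 * e[1, ] + rnorm(n), colnames(e))
    tab <- expression_trait_assoc(e, y, kinship = NULL)
    if (tab$beta > 0.4 && tab$beta < 0.6) hits <- hits + 1L
    if (sign(tab$beta) > 0) signs_ok <- signs_ok + 1L
  }
  expect_gte(hits, 17L)       # ~95% coverage of the planted value
  expect_equal(signs_ok, 20L) # |beta| sqrt(n)/sigma > 4: sign always right
})
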