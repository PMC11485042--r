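test_that("residualize matches the normal-equation oracle and is idempotent", {
  set.seed(11)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  r <- residualize(y, X)
  expect_equal(as.numeric(r), normal_equation_residuals(y, X), tolerance = 1e-10)
  # orthogonality to the design
  expect_lt(max(abs(crossprod(cbind(1, X), as.numeric(r)))), 1e-8 * n)
  # idempotence
  r2 <- residualize(as.numeric(r), X)
  expect_equal(as.numeric(r2), as.numeric(r), tolerance = 1e-10)
  # exact fit -> zero vector
  b <- rnorm(4)
  y_fit <- cbind(1, X) %*% b
  expect_lt(max(abs(residualize(as.numeric(y_fit), X))), 1e-10)
  # already-orthogonal response is unchanged
  y_orth <- as.numeric(r)
  expect_equal(as.numeric(residualize(y_orth, X)), y_orth, tolerance = 1e-10)
  # collinear columns dropped with a warning
  expect_warning(residualize(y, cbind(X, X[, 1])), "collinear")
})

test_that("forward stepwise retains exactly the associated PCs", {
  set.seed(21)
  n <- 200
  PCs <- qr.Q(qr(matrix(rnorm(n * 10), n, 10)))
  colnames(PCs) <- paste0("PC", 1:10)
  # pure-noise residual orthogonalized against all PCs: nothing retained
  res0 <- residualize(rnorm(n), PCs)
  out0 <- stepwise_pc_adjust(as.numeric(res0), PCs)
  expect_length(attr(out0, "retained"), 0)
  expect_equal(as.numeric(out0), as.numeric(res0))
  # planted effect on PC3
  y <- 2 * PCs[, 3] + rnorm(n, 0, 0.1)
  out1 <- stepwise_pc_adjust(y, PCs)
  expect_true(3 %in% attr(out1, "retained"))
  expect_lt(abs(cor(as.numeric(out1), PCs[, 3])), 0.05)
  # alpha = 1 retains everything
  out2 <- stepwise_pc_adjust(y, PCs, alpha = 1)
  expect_equal(attr(out2, "retained"), 1:10)
})

test_that("inverse normal transform follows the Blom formula", {
  expect_equal(inverse_normal_transform(c(5, 1, 9))[[1]], 0)
  v <- c(10, 20, 30, 40, 50)
  expect_equal(unname(inverse_normal_transform(v)),
               qnorm(((1:5) - 3 / 8) / 5.25))
  set.seed(4)
  x <- rgamma(40, 2)
  z <- inverse_normal_transform(x)
  expect_equal(cor(z, x, method = "spearman"), 1)
  # ties share the mean rank
  zt <- inverse_normal_transform(c(1, 2, 2, 5))
  expect_equal(zt[2], zt[3])
  expect_error(inverse_normal_transform(rep(1, 10)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
})

test_that("INT output passes a normality check in >= 18 of 20 seeded runs", {
  pass <- 0L
  for (s in 1:20) {
    set.seed(s)
    z <- inverse_normal_transform(rexp(100))
    if (stats::shapiro.test(z)$p.value > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 18L)
})

test_that("genomic inflation factor is 1 at p = 0.5 and scales with z^2", {
  expect_equal(genomic_inflation_factor(rep(0.5, 7)), 1.0)
  set.seed(5)
  p <- runif(10000)
  expect_gt(genomic_inflation_factor(p), 0.95)
  expect_lt(genomic_inflation_factor(p), 1.05)
  # doubling the chi-square (z * sqrt(2)) doubles lambda
  z <- qnorm(p / 2, lower.tail = FALSE)
  p2 <- 2 * pnorm(-abs(z * sqrt(2)))
  expect_equal(genomic_inflation_factor(p2), 2 * genomic_inflation_factor(p),
               tolerance = 0.02)
  expect_error(genomic_inflation_factor(numeric(0)), "no p-values")
})

test_that("empirical-null correction recovers bias and inflation", {
  # averaged over 10 seeded replicates so the check reflects the estimator,
  # not one draw
  fit_many <- function(gen) {
    t(sapply(1:10, function(s) {
      set.seed(s * 7 + 3)
      f <- suppressWarnings(empirical_null_correct(gen()))
      c(bias = f$null$bias, inflation = f$null$inflation,
        gif = genomic_inflation_factor(f$p_corrected))
    }))
  }
  r0 <- fit_many(function() rnorm(5000))
  expect_gt(mean(r0[, "inflation"]), 0.95)
  expect_lt(mean(r0[, "inflation"]), 1.05)
  expect_lt(abs(mean(r0[, "bias"])), 0.05)
  # corrected pure-null z has calibrated GIF
  expect_gt(mean(r0[, "gif"]), 0.95)
  expect_lt(mean(r0[, "gif"]), 1.05)

  r1 <- fit_many(function() rnorm(5000, 0, 1.5))
  expect_gt(mean(r1[, "inflation"]), 1.4)
  expect_lt(mean(r1[, "inflation"]), 1.6)

  r2 <- fit_many(function() rnorm(5000, 0.3, 1))
  expect_gt(mean(r2[, "bias"]), 0.25)
  expect_lt(mean(r2[, "bias"]), 0.35)

  # 10% heavy-tailed signal contamination barely moves the null estimate
  r3 <- fit_many(function() c(rnorm(4500), rnorm(500, 0, 3)))
  expect_lt(abs(mean(r3[, "bias"])), 0.05)
  expect_gt(mean(r3[, "inflation"]), 0.9)
  expect_lt(mean(r3[, "inflation"]), 1.1)
})

test_that("prepare_trait composes adjustment, stepwise PCs and INT", {
  set.seed(31)
  n <- 150
  X <- cbind(age = rnorm(n, 50, 8), sex = rbinom(n, 1, .5))
  PCs <- qr.Q(qr(matrix(rnorm(n * 10), n, 10)))
  y <- setNames(2 + 0.1 * X[, 1] + 3 * PCs[, 2] + rnorm(n), paste0("S", 1:n))
  out <- prepare_trait(y, X, PCs)
  expect_named(out, names(y))
  expect_true(2 %in% attr(out, "retained_pcs"))
  expect_equal(mean(out), 0, tolerance = 0.05)
  # log transform guards positivity
  expect_error(prepare_trait(c(a = -1, b = 2, c = 3), log_transform = TRUE),
               "positive")
})
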