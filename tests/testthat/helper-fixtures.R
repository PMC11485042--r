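# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small planted cohort exercising every stage
small_planted_cohort <- function() {
  fixture("small_planted", function() {
    cfg <- sim_config(n_samples = 300L, n_rna_samples = 150L, n_genes = 120L,
                      n_modules = 40L, n_go = 15L,
                      planted_multi = 2L, planted_gwas = 1L,
                      planted_twas = 1L, planted_rva = 1L)
    simulate_cohort(cfg, seed = 42L)
  })
}

# Monte-Carlo tail of sum(lambda_j chisq_1) by direct simulation
mc_quadform_tail <- function(T, lambda, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  k <- length(lambda)
  hits <- 0
  chunk <- 2e5
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    Q <- colSums(matrix(rchisq(m * k, df = 1), k) * lambda)
    hits <- hits + sum(Q > T)
    done <- done + m
  }
  p <- hits / n_draws
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# least-squares residuals via the normal equations (independent oracle)
normal_equation_residuals <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  as.numeric(y - X %*% solve(crossprod(X), crossprod(X, y)))
}
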