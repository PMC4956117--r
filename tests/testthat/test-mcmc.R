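test_that("log-likelihood: symmetric null, closed form, brute-force oracle", {
  expect_equal(log_likelihood(0L, matrix(0, 1, 7)), log(1 / 8))
  e <- matrix(0, 1, 7); e[1, 7] <- 2
  expect_equal(log_likelihood(7L, e), log(exp(2) / (7 + exp(2))))
  set.seed(14)
  k <- sample(0:7, 40, replace = TRUE)
  eta <- matrix(rnorm(40 * 7, 0, 2), 40, 7)
  expect_lt(abs(log_likelihood(k, eta) - loglik_oracle(k, eta)), 1e-10)
  # the stabilised form survives predictors that overflow naive exp()
  eta_big <- matrix(500, 2, 7)
  expect_true(is.finite(log_likelihood(c(1L, 0L), eta_big)))
  expect_error(log_likelihood(1L, matrix(Inf, 1, 7)), "finite")
})

test_that("block variance draw follows the conjugate inverse-gamma", {
  K <- crossprod(diff(diag(10), differences = 2))    # rank 8
  a <- 2; b <- 1.5
  set.seed(31)
  draws <- replicate(1e5, sample_block_variance(rep(0, 10), K, a, b))
  # coef = 0 => IG(a + rank/2, b); mean b/(a + rank/2 - 1) = 1.5/5 = 0.3
  m_true <- b / (a + 4 - 1)
  mcse <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_true), 3 * mcse)
  expect_true(all(draws > 0))
  expect_error(sample_block_variance(1, matrix(0, 1, 1)), "rank-0")
  expect_error(sample_block_variance(1:2, matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
  set.seed(7); d1 <- sample_block_variance(rnorm(10), K)
  set.seed(7); d2 <- sample_block_variance(rnorm(10), K)
  expect_identical(d1, d2)
})

test_that("chains are deterministic given spec and seed", {
  r1 <- fit_small(n = 600, n_iterations = 400, burn_in = 100, chain_seed = 5)
  r2 <- fit_small(n = 600, n_iterations = 400, burn_in = 100, chain_seed = 5)
  expect_identical(r1$fit$beta, r2$fit$beta)
})

test_that("spatial fits keep theta centred and variances positive", {
  r <- fit_small(n = 900, graph = path_graph(6), spatial_var = 0.4,
                 unstructured_var = 0.1, n_iterations = 600, burn_in = 200)
  fit <- r$fit
  for (cc in as.character(1:7)) {
    expect_lt(max(abs(rowSums(fit$theta[[cc]]))), 1e-8)
  }
  expect_true(all(fit$tau2_theta > 0))
  expect_true(all(fit$tau2_phi > 0))
  expect_equal(nrow(fit$beta[["1"]]), (600 - 200 + 3 - 1) %/% 3)
})

test_that("a much tighter fixed-effect prior shrinks the posterior toward 0", {
  b <- matrix(0, 3, 7); b[2, ] <- 1          # strong x1 effect everywhere
  loose <- fit_small(n = 1500, betas = b, eps = 1e-6,
                     n_iterations = 800, burn_in = 200, data_seed = 3)
  tight <- fit_small(n = 1500, betas = b, eps = 100,
                     n_iterations = 800, burn_in = 200, data_seed = 3)
  m_loose <- mean(sapply(loose$fit$beta, function(m) mean(m[, "x1b"])))
  m_tight <- mean(sapply(tight$fit$beta, function(m) mean(m[, "x1b"])))
  expect_gt(m_loose, m_tight)
  expect_gt(m_loose, 0.5)
  expect_lt(abs(m_tight), abs(m_loose) / 2)
})

test_that("without spatial terms the posterior mean tracks the MLE", {
  skip_if_not_installed("nnet")
  set.seed(6)
  b <- matrix(runif(21, -0.8, 0.8), 3, 7)
  r <- fit_small(n = 3000, betas = b, n_iterations = 1500, burn_in = 500,
                 data_seed = 6, chain_seed = 6)
  dat <- data.frame(k = factor(unclass(r$outcomes), levels = 0:7),
                    x1 = r$design$Z[, "x1b"], x2 = r$design$Z[, "x2b"])
  ml <- nnet::multinom(k ~ x1 + x2, data = dat, trace = FALSE)
  mle <- t(coef(ml))                        # p x 7, categories 1..7
  pm <- sapply(r$fit$beta, colMeans)
  psd <- sapply(r$fit$beta, function(m) apply(m, 2, sd))
  expect_true(all(abs(pm - mle) <= 2 * psd + 0.02))
})

test_that("two independent seeds agree within Monte-Carlo error", {
  b <- matrix(0.3, 3, 7)
  ra <- fit_small(n = 1200, betas = b, n_iterations = 1500, burn_in = 300,
                  thinning = 2, data_seed = 10, chain_seed = 101)
  rb <- fit_small(n = 1200, betas = b, n_iterations = 1500, burn_in = 300,
                  thinning = 2, data_seed = 10, chain_seed = 202)
  for (cc in as.character(1:7)) {
    A <- ra$fit$beta[[cc]]; B <- rb$fit$beta[[cc]]
    for (j in seq_len(ncol(A))) {
      essa <- max(nrow(A) / 20, morbidmap:::.ess(A[, j]))
      essb <- max(nrow(B) / 20, morbidmap:::.ess(B[, j]))
      mcse <- sqrt(sd(A[, j])^2 / essa + sd(B[, j])^2 / essb)
      expect_lt(abs(mean(A[, j]) - mean(B[, j])), 3.5 * mcse + 0.02)
    }
  }
})

test_that("model_spec enforces its invariants", {
  expect_error(model_spec(burn_in = 1000, n_iterations = 500), "burn_in")
  expect_error(model_spec(thinning = 0), "thinning")
  expect_error(model_spec(a = 0), "a, b")
  expect_error(run_mcmc(structure(list(), class = "design_bundle"),
                        outcomes = 9L), "design bundle")
})

test_that("smooth blocks fit without breaking the partition structure", {
  tr <- two_binary_truth(800, matrix(0, 3, 7), graph = path_graph(4),
                         seed = 22)
  sv <- generate_survey(tr)
  rec <- sv$records
  set.seed(23)
  rec$age <- runif(800, 0, 60)
  d <- build_design(rec, terms = c("x1", "x2"), smooth_terms = "age",
                    n_interior_knots = 8)
  k <- encode_outcome(rec$diarrhoea[d$rows], rec$fever[d$rows],
                      rec$cough[d$rows])
  fit <- suppressWarnings(run_mcmc(d, k, model_spec(n_iterations = 400,
                                                    burn_in = 100,
                                                    thinning = 2, seed = 2)))
  expect_equal(length(fit$smooth$age), 7L)
  expect_equal(ncol(fit$smooth$age[["1"]]), d$smooths$age$m)
  # centred smooth: fitted values average ~0 draw by draw
  fhat <- fit$smooth$age[["3"]] %*% t(d$smooths$age$B)
  expect_lt(max(abs(rowMeans(fhat))), 1e-6)
})
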