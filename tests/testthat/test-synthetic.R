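test_that("sample_icar degenerate and constraint cases", {
  g <- path_graph(3)
  expect_equal(unname(sample_icar(g, 0)), c(0, 0, 0))
  for (s in 1:20) {
    x <- sample_icar(egypt_graph(), 0.7, seed = s)
    expect_lt(abs(sum(x)), 1e-8)
  }
  gd <- adjacency_graph(rbind(c(1, 2), c(3, 4)))
  expect_error(sample_icar(gd, 1), "disconnected")
  xd <- sample_icar(gd, 1, seed = 1, per_component = TRUE)
  expect_lt(abs(sum(xd[1:2])), 1e-12)
  expect_lt(abs(sum(xd[3:4])), 1e-12)
})

test_that("sample_icar draws match the pseudo-inverse covariance", {
  g <- path_graph(3)
  Q <- unclass(build_icar_precision(g))
  Sigma <- pinv_eigen(Q)                      # oracle covariance, variance 1
  set.seed(81)
  draws <- t(replicate(10000, sample_icar(g, 1)))
  emp <- cov(draws)
  # Monte-Carlo error of a covariance entry at 10k draws is ~ 0.02
  expect_lt(max(abs(emp - Sigma)), 6 / sqrt(10000))
  expect_lt(max(abs(colMeans(draws))), 6 / sqrt(10000))
})

test_that("sample_icar is invariant under the path graph's reflection", {
  # relabelling 1<->3 is an automorphism of the 3-path: marginal variances
  # of the end nodes must agree and both end-middle covariances too
  g <- path_graph(3)
  set.seed(4)
  draws <- t(replicate(8000, sample_icar(g, 1)))
  v <- diag(cov(draws))
  expect_lt(abs(v[1] - v[3]), 8 / sqrt(8000))
  cv <- cov(draws)
  expect_lt(abs(cv[1, 2] - cv[3, 2]), 8 / sqrt(8000))
})

test_that("null generator gives uniform category frequencies", {
  tr <- two_binary_truth(80000, matrix(0, 3, 7), seed = 11)
  sv <- generate_survey(tr)
  k <- encode_outcome(sv$records$diarrhoea, sv$records$fever,
                      sv$records$cough)
  freq <- as.vector(table(factor(unclass(k), levels = 0:7))) / 80000
  mcse <- sqrt(0.125 * 0.875 / 80000)
  expect_true(all(abs(freq - 0.125) < 3 * mcse))
})

test_that("a lone intercept shifts one category per the logit closed form", {
  b <- matrix(0, 3, 7); b[1, 7] <- 2          # intercept of category 7 = +2
  tr <- two_binary_truth(80000, b, seed = 12)
  sv <- generate_survey(tr)
  k <- encode_outcome(sv$records$diarrhoea, sv$records$fever, sv$records$cough)
  p7 <- exp(2) / (7 + exp(2))
  freq7 <- mean(unclass(k) == 7L)
  expect_lt(abs(freq7 - p7), 3 * sqrt(p7 * (1 - p7) / 80000))
})

test_that("generator is deterministic and flags round-trip the category", {
  tr <- two_binary_truth(500, matrix(rnorm(21, 0, 0.5), 3, 7),
                         graph = path_graph(4), spatial_var = 0.2,
                         unstructured_var = 0.1, seed = 33)
  s1 <- generate_survey(tr)
  s2 <- generate_survey(tr)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$theta_true, s2$theta_true)
  # theta sums to zero per category
  expect_true(all(abs(colSums(s1$theta_true)) < 1e-8))
  # every region id exists in the graph
  expect_true(all(s1$records$region_id %in% tr$graph$ids))
  # back-filled flags re-encode to the sampled category: encode o decode = id
  k <- encode_outcome(s1$records$diarrhoea, s1$records$fever,
                      s1$records$cough)
  back <- decode_outcome(k)
  expect_equal(back$diarrhoea, s1$records$diarrhoea)
  expect_equal(back$fever, s1$records$fever)
  expect_equal(back$cough, s1$records$cough)
})

test_that("truth_config validates its invariants", {
  bad_spec <- list(list(name = "x", levels = c("a", "b"), probs = c(0.6, 0.5)))
  expect_error(truth_config(10, matrix(0, 2, 7), covariate_spec = bad_spec,
                            graph = path_graph(3)), "sum to 1")
  expect_error(two_binary_truth(10, matrix(0, 5, 7)), "rows")
  expect_error(two_binary_truth(10, matrix(0, 3, 6)), "7 columns")
  expect_error(truth_config(10, lapply(1:7, function(i) rep(0, i)),
                            covariate_spec = two_binary_spec(),
                            graph = path_graph(3)), "same length")
})

test_that("written survey and truth round-trip through CSV/YAML", {
  tr <- two_binary_truth(120, matrix(0.1, 3, 7), graph = path_graph(3),
                         seed = 5)
  sv <- generate_survey(tr)
  dir <- tempfile()
  paths <- write_survey(sv, dir)
  rec <- read.csv(paths[["records"]])
  expect_equal(nrow(rec), 120L)
  expect_true(all(c("diarrhoea", "fever", "cough", "region_id") %in%
                    names(rec)))
  truth_back <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth_back$n_children, 120L)
  expect_equal(truth_back$spatial_var, 0)
  expect_equal(length(truth_back$betas), 7L)
})
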