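# Shared fixtures and independent oracles for the test suite.

path_graph <- function(n = 3) {
  adjacency_graph(cbind(seq_len(n - 1), 2:n))
}

triangle_graph <- function() adjacency_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))

two_binary_spec <- function() {
  list(list(name = "x1", levels = c("a", "b"), probs = c(0.5, 0.5)),
       list(name = "x2", levels = c("a", "b"), probs = c(0.5, 0.5)))
}

# truth with intercept + two binary dummies per category
two_binary_truth <- function(n, betas, graph = path_graph(3),
                             spatial_var = 0, unstructured_var = 0,
                             seed = 1) {
  truth_config(n, betas, covariate_spec = two_binary_spec(),
               spatial_var = spatial_var, unstructured_var = unstructured_var,
               graph = graph, seed = seed)
}

# Moore-Penrose pseudo-inverse via eigen-decomposition (ICAR covariance oracle)
pinv_eigen <- function(M, tol = 1e-9) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values)
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

# textbook Pearson chi-squared oracle: sum (O - E)^2 / E
chi2_oracle <- function(counts) {
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

# independent Cox-de Boor recursion for a single B-spline basis function
# N_{i,d}(x) on knot vector t (1-based i over basis functions)
cox_de_boor <- function(x, i, d, t) {
  if (d == 0) return(as.numeric(t[i] <= x & x < t[i + 1]))
  a <- 0
  if (t[i + d] > t[i])
    a <- (x - t[i]) / (t[i + d] - t[i]) * cox_de_boor(x, i, d - 1, t)
  b <- 0
  if (t[i + d + 1] > t[i + 1])
    b <- b + (t[i + d + 1] - x) / (t[i + d + 1] - t[i + 1]) *
      cox_de_boor(x, i + 1, d - 1, t)
  a + b
}

# unstabilised multinomial-logit log-likelihood oracle
loglik_oracle <- function(k, eta) {
  p <- cbind(1, exp(eta))
  p <- p / rowSums(p)
  sum(log(p[cbind(seq_along(k), k + 1)]))
}

# fit a short chain on a small synthetic survey; shared by several tests
fit_small <- function(n = 1200, betas = matrix(0, 3, 7), graph = NULL,
                      spatial_var = 0, unstructured_var = 0,
                      data_seed = 1, chain_seed = 1,
                      n_iterations = 1200, burn_in = 300, thinning = 3,
                      eps = 1e-6) {
  g <- if (is.null(graph)) path_graph(6) else graph
  tr <- two_binary_truth(n, betas, graph = g, spatial_var = spatial_var,
                         unstructured_var = unstructured_var, seed = data_seed)
  sv <- generate_survey(tr)
  use_spatial <- spatial_var > 0 || unstructured_var > 0
  d <- build_design(sv$records, terms = c("x1", "x2"),
                    graph = if (use_spatial) g,
                    reference_levels = list(x1 = "a", x2 = "a"))
  k <- encode_outcome(sv$records$diarrhoea[d$rows],
                      sv$records$fever[d$rows], sv$records$cough[d$rows])
  fit <- suppressWarnings(run_mcmc(d, k, model_spec(
    n_iterations = n_iterations, burn_in = burn_in, thinning = thinning,
    seed = chain_seed, eps = eps)))
  list(fit = fit, survey = sv, design = d, outcomes = k)
}
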