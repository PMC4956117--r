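test_that("OR summary: constant chain and closed-form normal chain", {
  s0 <- summarize_or(rep(0, 500), "null", 1)
  expect_equal(s0$or, 1)
  expect_equal(c(s0$ci_low, s0$ci_high), c(1, 1))
  expect_false(s0$significant)

  set.seed(41)
  ch <- rnorm(1e5, 0.7, 0.1)
  s <- summarize_or(ch, "effect", 2)
  expect_equal(s$or, exp(0.7), tolerance = 0.01)
  expect_equal(s$ci_low, exp(0.7 + qnorm(0.025) * 0.1), tolerance = 0.01)
  expect_equal(s$ci_high, exp(0.7 + qnorm(0.975) * 0.1), tolerance = 0.01)
  expect_true(s$significant)
  expect_warning(summarize_or(rnorm(50), "short"), "only")
})

test_that("OR scale convention: exp after summarising, alternative behind flag", {
  set.seed(42)
  ch <- rnorm(5e4, 0.5, 0.6)
  coef_scale <- summarize_or(ch, "x", 1, scale = "coefficient")
  or_scale <- summarize_or(ch, "x", 1, scale = "or")
  expect_equal(coef_scale$or, exp(mean(ch)))
  # mean of exp > exp of mean (Jensen); the flag is recorded
  expect_gt(or_scale$or, coef_scale$or)
  expect_equal(coef_scale$scale, "coefficient")
  expect_equal(or_scale$scale, "or")
})

test_that("significance flags are stable under thinning that keeps >= 1000 draws", {
  set.seed(43)
  p <- 40
  chains <- matrix(rnorm(4000 * p, rep(c(0, 0.35), length.out = p), 0.12),
                   4000, p, byrow = TRUE)
  full <- apply(chains, 2, function(ch) summarize_or(ch)$significant)
  thinned <- apply(chains[seq(1, 4000, by = 4), ], 2,
                   function(ch) summarize_or(ch)$significant)
  expect_gte(mean(full == thinned), 0.95)
})

test_that("spatial effect table summarises theta per region", {
  r <- fit_small(n = 900, graph = path_graph(5), spatial_var = 0.4,
                 unstructured_var = 0.05, n_iterations = 600, burn_in = 200)
  tab <- spatial_effect_table(r$fit, 3)
  expect_s3_class(tab, "spatial_effect_table")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$region_id, 1:5)          # sorted by region id
  expect_equal(tab$or, exp(tab$mean))
  expect_error(spatial_effect_table(r$fit, 9), "unknown")
  # all-zero chains give flat table
  flat <- r$fit
  flat$theta[["2"]][] <- 0
  tf <- spatial_effect_table(flat, 2)
  expect_true(all(tf$or == 1))
  expect_false(any(tf$significant))
})

test_that("a strongly elevated region is recovered as the top region", {
  g <- path_graph(6)
  theta_shift <- function(n) {
    tr <- two_binary_truth(n, matrix(0, 3, 7), graph = g, seed = 55)
    sv <- generate_survey(tr)
    # impose the effect directly: region 5 elevated for category 1
    rec <- sv$records
    eta <- matrix(0, n, 7)
    eta[, 1] <- 1.5 * (rec$region_id == 5)
    pr <- cbind(1, exp(eta)); pr <- pr / rowSums(pr)
    set.seed(56)
    k <- apply(pr, 1, function(p) sample(0:7, 1, prob = p))
    flags <- decode_outcome(k)
    rec$diarrhoea <- flags$diarrhoea; rec$fever <- flags$fever
    rec$cough <- flags$cough
    rec
  }
  rec <- theta_shift(2500)
  d <- build_design(rec, terms = c("x1", "x2"), graph = g)
  k <- encode_outcome(rec$diarrhoea[d$rows], rec$fever[d$rows],
                      rec$cough[d$rows])
  fit <- suppressWarnings(run_mcmc(d, k, model_spec(n_iterations = 1200,
                                                    burn_in = 400,
                                                    thinning = 2, seed = 57)))
  tab <- spatial_effect_table(fit, 1)
  expect_equal(attr(tab, "top_region"), 5L)
  expect_equal(tab$mean[5], max(tab$mean))
})

test_that("write_results emits 7 + 7 CSVs and a round-tripping JSON", {
  r <- fit_small(n = 700, graph = path_graph(4), spatial_var = 0.3,
                 unstructured_var = 0.05, n_iterations = 500, burn_in = 150)
  dir <- tempfile()
  files <- write_results(r$fit, dir)
  expect_length(files, 7 + 7 + 1)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(file.path(dir, "results.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(names(js$or)), as.character(1:7))
  # JSON round-trips the OR table values
  ors <- or_table(r$fit)
  cat1 <- ors[ors$category == 1, ]
  expect_equal(js$or[["1"]]$or, cat1$or, tolerance = 1e-12)
  # spatial CSV joins against the region lookup with zero unmatched rows
  sp <- read.csv(grep("spatial_cat1", files, value = TRUE))
  expect_equal(nrow(sp), 4L)
  expect_true(all(sp$region_id %in% r$design$graph$ids))
})

test_that("or_table covers every non-intercept contrast for all categories", {
  r <- fit_small(n = 600, n_iterations = 400, burn_in = 100)
  tab <- or_table(r$fit)
  expect_equal(nrow(tab), 7 * 2)             # x1b, x2b per category
  expect_true(all(tab$ci_low <= tab$ci_high))
  expect_true(all((tab$ci_low > 1 | tab$ci_high < 1) == tab$significant))
  expect_equal(unname(tab$category_label[tab$category == 4][1]),
               "fever_cough")
})
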