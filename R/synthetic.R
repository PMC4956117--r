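#' Ground-truth configuration for the synthetic survey generator
#'
#' Bundles everything the generator needs to draw a DHS-style child-morbidity
#' survey with known parameters: per-category coefficient vectors for the
#' multinomial-logit predictor, the covariate dictionary, the spatial and
#' unstructured region-effect variances, the region adjacency graph and a
#' seed.
#'
#' The generator's linear predictor for category `k` (k = 1..7; the
#' no-illness category 0 is the reference with predictor 0) is
#' `eta_k = Z beta_k + theta_k[region] + phi_k[region]`, where `Z` is the
#' reference-cell design implied by `covariate_spec` (intercept, then
#' first-level-reference dummies for each categorical covariate, then each
#' metrical covariate rescaled to \[0,1\] over its range so coefficients are
#' comparable across covariates).
#'
#' @param n_children positive number of records to draw.
#' @param betas coefficient matrix (`p` x 7, one column per non-reference
#'   category) or a list of 7 equal-length vectors; `p` must match the
#'   design implied by `covariate_spec`.
#' @param covariate_spec list of covariate descriptors: categorical entries
#'   `list(name=, levels=, probs=)` with probabilities summing to 1 (within
#'   1e-12), metrical entries `list(name=, range=c(lo, hi))`.  Defaults to
#'   [default_covariate_spec()].
#' @param spatial_var variance of the structured (intrinsic CAR) region
#'   effect, >= 0.
#' @param unstructured_var variance of the exchangeable region effect, >= 0.
#' @param graph an `adjacency_graph`; defaults to [egypt_graph()].
#' @param seed integer seed; the generator is byte-reproducible given the
#'   full configuration.
#' @param region_weights optional sampling weights over regions (defaults to
#'   uniform).
#' @param covariate_sampler optional function `n -> data.frame` supplying a
#'   joint covariate draw; by default covariates are drawn independently
#'   from their stated marginals (the survey documents no dependence
#'   structure).
#' @return A validated `truth_config`.
#' @export
truth_config <- function(n_children, betas,
                         covariate_spec = default_covariate_spec(),
                         spatial_var = 0.3, unstructured_var = 0.1,
                         graph = egypt_graph(), seed = 1L,
                         region_weights = NULL, covariate_sampler = NULL) {
  stopifnot(n_children >= 1, spatial_var >= 0, unstructured_var >= 0,
            inherits(graph, "adjacency_graph"))
  for (cv in covariate_spec) {
    if (is.null(cv$name)) stop("every covariate needs a name")
    if (!is.null(cv$levels)) {
      if (length(cv$levels) != length(cv$probs))
        stop("covariate '", cv$name, "': levels and probs differ in length")
      if (abs(sum(cv$probs) - 1) > 1e-12)
        stop("covariate '", cv$name, "': marginal probabilities must sum to 1")
    } else if (is.null(cv$range) || length(cv$range) != 2L ||
               cv$range[1L] >= cv$range[2L]) {
      stop("covariate '", cv$name, "': need levels/probs or a valid range")
    }
  }
  p <- .truth_design_dim(covariate_spec)
  if (is.list(betas)) {
    if (length(betas) != 7L) stop("betas must cover the 7 non-reference categories")
    if (length(unique(lengths(betas))) != 1L)
      stop("beta vectors must all have the same length")
    betas <- do.call(cbind, betas)
  }
  betas <- as.matrix(betas)
  if (ncol(betas) != 7L) stop("betas must have 7 columns (categories 1..7)")
  if (nrow(betas) != p)
    stop("betas have ", nrow(betas), " rows but the design implied by ",
         "covariate_spec has ", p, " columns")
  rownames(betas) <- .truth_design_names(covariate_spec)
  colnames(betas) <- as.character(1:7)
  if (!is.null(region_weights)) {
    if (length(region_weights) != graph$n || any(region_weights < 0))
      stop("region_weights must be non-negative, one per region")
  }
  structure(list(n_children = as.integer(n_children), betas = betas,
                 covariate_spec = covariate_spec, spatial_var = spatial_var,
                 unstructured_var = unstructured_var, graph = graph,
                 seed = as.integer(seed), region_weights = region_weights,
                 covariate_sampler = covariate_sampler),
            class = "truth_config")
}

.truth_design_dim <- function(spec) {
  1L + sum(vapply(spec, function(cv)
    if (!is.null(cv$levels)) length(cv$levels) - 1L else 1L, integer(1)))
}

.truth_design_names <- function(spec) {
  nm <- "(Intercept)"
  for (cv in spec) {
    nm <- c(nm, if (!is.null(cv$levels))
      paste0(cv$name, cv$levels[-1L]) else cv$name)
  }
  nm
}

#' Default EDHS-style covariate dictionary
#'
#' Marginal distributions loosely calibrated to a national child-health
#' survey: sex near-balanced, a rural majority, equal wealth quintiles,
#' child age uniform over 0-60 months.  These are the generator's stated
#' study conditions, not estimates from any particular dataset.
#'
#' @return List of covariate descriptors accepted by [truth_config()].
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "sex", levels = c("male", "female"), probs = c(0.51, 0.49)),
    list(name = "residence", levels = c("urban", "rural"), probs = c(0.45, 0.55)),
    list(name = "antenatal_visits", levels = c("none", "some"), probs = c(0.4, 0.6)),
    list(name = "place_of_delivery",
         levels = c("public_or_private_hospital", "home_or_other"),
         probs = c(0.6, 0.4)),
    list(name = "working_status", levels = c("not_working", "working"),
         probs = c(0.8, 0.2)),
    list(name = "wealth_quintile",
         levels = c("poorest", "poorer", "middle", "richer", "richest"),
         probs = rep(0.2, 5)),
    list(name = "mother_education",
         levels = c("none_or_primary", "secondary_or_higher"),
         probs = c(0.5, 0.5)),
    list(name = "household_size", range = c(2, 12)),
    list(name = "child_age_months", range = c(0, 60)),
    list(name = "maternal_age_first_birth_years", range = c(15, 35)),
    list(name = "bmi", range = c(16, 40))
  )
}

#' Draw a structured spatial effect from the intrinsic CAR prior
#'
#' The intrinsic CAR distribution with precision `Q / variance` is improper
#' (flat along the constant vector on each component).  The draw is realised
#' as a proper Gaussian on the orthogonal complement of the null space via
#' the eigen-decomposition of `Q` -- exact for region graphs of this size --
#' and then centred to sum to zero (per component for disconnected graphs,
#' when `per_component = TRUE`).  `variance = 0` returns the zero vector.
#'
#' @param graph an `adjacency_graph`; must be connected unless
#'   `per_component = TRUE`.
#' @param variance marginal scaling variance, >= 0.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so the survey generator can consume one stream).
#' @param per_component centre each connected component separately (opt-in
#'   policy for disconnected graphs).
#' @return Numeric vector of per-region effects, named by region id,
#'   summing to zero (within machine precision).
#' @export
sample_icar <- function(graph, variance, seed = NULL, per_component = FALSE) {
  stopifnot(inherits(graph, "adjacency_graph"), variance >= 0)
  ncomp <- max(graph$component)
  if (ncomp > 1L && !per_component)
    stop("graph is disconnected; set per_component = TRUE to centre each ",
         "component separately")
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n
  out <- stats::setNames(numeric(n), graph$ids)
  if (variance == 0) return(out)
  Q <- build_icar_precision(graph)
  eg <- eigen(unclass(Q), symmetric = TRUE)
  tol <- 1e-9 * max(eg$values)
  pos <- eg$values > tol
  # zero mass on the null space; scale each positive eigendirection
  z <- stats::rnorm(sum(pos))
  x <- as.vector(eg$vectors[, pos, drop = FALSE] %*%
                   (z * sqrt(variance / eg$values[pos])))
  for (cc in seq_len(ncomp)) {
    sel <- graph$component == cc
    x[sel] <- x[sel] - mean(x[sel])
  }
  out[] <- x
  out
}

#' Generate a synthetic child-morbidity survey with known truth
#'
#' Draws covariates from their stated marginals (independently, unless a
#' joint sampler is supplied), assigns regions, draws per-category
#' structured (`theta`, intrinsic CAR) and unstructured (`phi`, iid
#' Gaussian) region effects, computes the multinomial-logit category
#' probabilities with the no-illness category as reference, samples each
#' child's co-morbidity category and back-fills the three binary illness
#' flags by the exact inverse of the outcome encoding.  The same
#' configuration and seed reproduce the survey byte for byte.
#'
#' @param truth a [truth_config()].
#' @return A `synthetic_survey`: list with `records` (data.frame, one row
#'   per child: id, illness flags, covariates, region_id, area7),
#'   `truth`, `theta_true` and `phi_true` (regions x 7 matrices; each
#'   `theta_true` column sums to zero), and `eta_names` (design column
#'   names the betas refer to).
#' @export
generate_survey <- function(truth) {
  stopifnot(inherits(truth, "truth_config"))
  set.seed(truth$seed)
  n <- truth$n_children
  g <- truth$graph
  nr <- g$n

  if (!is.null(truth$covariate_sampler)) {
    cov_df <- truth$covariate_sampler(n)
    if (!is.data.frame(cov_df) || nrow(cov_df) != n)
      stop("covariate_sampler must return a data.frame with n rows")
  } else {
    cov_df <- data.frame(row.names = seq_len(n))
    for (cv in truth$covariate_spec) {
      if (!is.null(cv$levels)) {
        cov_df[[cv$name]] <- sample(cv$levels, n, replace = TRUE, prob = cv$probs)
      } else {
        x <- stats::runif(n, cv$range[1L], cv$range[2L])
        if (cv$name == "household_size") x <- round(x)
        cov_df[[cv$name]] <- x
      }
    }
  }
  for (cv in truth$covariate_spec) {
    if (!is.null(cv$levels) && !all(cov_df[[cv$name]] %in% cv$levels))
      stop("unknown level in covariate '", cv$name, "'")
  }

  w <- truth$region_weights
  region <- if (is.null(w)) sample(g$ids, n, replace = TRUE)
            else sample(g$ids, n, replace = TRUE, prob = w / sum(w))
  ridx <- match(region, g$ids)

  theta <- vapply(1:7, function(k) sample_icar(g, truth$spatial_var),
                  numeric(nr))
  phi <- matrix(stats::rnorm(nr * 7, 0, sqrt(truth$unstructured_var)), nr, 7)
  dimnames(theta) <- dimnames(phi) <- list(g$ids, 1:7)

  Z <- .truth_design(cov_df, truth$covariate_spec)
  eta <- Z %*% truth$betas + theta[ridx, , drop = FALSE] +
    phi[ridx, , drop = FALSE]                      # n x 7, reference eta = 0
  expeta <- exp(eta)
  denom <- 1 + rowSums(expeta)
  probs <- cbind(1, expeta) / denom                # columns k = 0..7
  if (any(!is.finite(probs))) stop("category probabilities failed to normalise")
  cum <- t(apply(probs, 1L, cumsum))
  u <- stats::runif(n)
  k <- rowSums(u > cum)                            # 0..7
  flags <- decode_outcome(k)

  area_class <- attr(g, "area_class")
  area7 <- if (!is.null(area_class) && "residence" %in% names(cov_df)) {
    cls <- area_class[as.character(region)]
    ifelse(cls %in% c("urban_governorates", "frontier_governorates"), cls,
           paste0(cls, "_", cov_df$residence))
  } else NA_character_

  records <- data.frame(child_id = seq_len(n), flags, cov_df,
                        region_id = region, area7 = area7,
                        stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth,
                 theta_true = theta, phi_true = phi,
                 eta_names = colnames(Z)),
            class = "synthetic_survey")
}

# reference-cell design used by the generator: intercept, first-level
# reference dummies, metrical covariates rescaled to [0,1]
.truth_design <- function(cov_df, spec) {
  n <- nrow(cov_df)
  cols <- list("(Intercept)" = rep(1, n))
  for (cv in spec) {
    x <- cov_df[[cv$name]]
    if (!is.null(cv$levels)) {
      for (lv in cv$levels[-1L]) cols[[paste0(cv$name, lv)]] <- as.numeric(x == lv)
    } else {
      cols[[cv$name]] <- (x - cv$range[1L]) / diff(cv$range)
    }
  }
  do.call(cbind, cols)
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("<synthetic_survey>", nrow(x$records), "children,",
      x$truth$graph$n, "regions\n")
  invisible(x)
}

#' Write a synthetic survey to disk
#'
#' The record table goes out as CSV with the same column dictionary
#' [read_survey()] accepts; the ground truth (betas, covariate spec,
#' variances, seed, graph edge list) is saved as YAML alongside.
#'
#' @param survey a `synthetic_survey`.
#' @param dir output directory (created if needed).
#' @param stem file stem, default "synthetic_survey".
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, dir, stem = "synthetic_survey") {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  yml <- file.path(dir, paste0(stem, "_truth.yaml"))
  utils::write.csv(survey$records, csv, row.names = FALSE)
  tr <- survey$truth
  yaml::write_yaml(list(
    n_children = tr$n_children,
    betas = lapply(seq_len(ncol(tr$betas)), function(k)
      as.list(stats::setNames(tr$betas[, k], rownames(tr$betas)))),
    covariate_spec = lapply(tr$covariate_spec, function(cv)
      cv[!vapply(cv, is.null, logical(1))]),
    spatial_var = tr$spatial_var,
    unstructured_var = tr$unstructured_var,
    seed = tr$seed,
    graph_edges = apply(tr$graph$edges, 1L, paste, collapse = " "),
    theta_true = lapply(seq_len(ncol(survey$theta_true)), function(k)
      as.list(stats::setNames(survey$theta_true[, k],
                              rownames(survey$theta_true))))
  ), yml)
  invisible(c(records = csv, truth = yml))
}
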