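#' Equidistant B-spline basis with a difference penalty
#'
#' P-spline building block for the smooth terms: a cubic (by default)
#' B-spline basis on equidistant knots spanning the observed range of `x`,
#' with the knot grid extended by `degree` knots on each side so the basis
#' is a partition of unity on the whole data range, and the second-order
#' difference penalty `K = t(D) %*% D` whose null space (constant and
#' linear trends) carries the random-walk prior's improper directions.
#'
#' @param x metrical covariate values (min < max required).
#' @param n_interior_knots number of interior knots (default 20, the usual
#'   structured-additive-regression convention).
#' @param degree spline degree (default 3, cubic).
#' @param diff_order penalty difference order (default 2).
#' @return Object of class `spline_basis`: `B` (n x m basis matrix),
#'   `knots` (full extended knot vector), `degree`, `m` (coefficient
#'   count = n_interior_knots + degree + 1), `K` (penalty, rank `m -
#'   diff_order`), `penalty_rank`, `range`.
#' @export
build_spline_basis <- function(x, n_interior_knots = 20, degree = 3,
                               diff_order = 2) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x contains missing values")
  ux <- unique(x)
  if (length(ux) < degree + 2L)
    stop("need at least degree + 2 distinct x values (got ", length(ux), ")")
  lo <- min(x); hi <- max(x)
  if (lo >= hi) stop("x is degenerate: min == max")
  h <- (hi - lo) / (n_interior_knots + 1)
  knots <- lo + h * seq(-degree, n_interior_knots + 1 + degree)
  # nudge the knots sitting on the data boundary outward so min(x)/max(x)
  # stay strictly inside the supported interval despite fp rounding
  pad <- 1e-8 * (hi - lo)
  knots[degree + 1L] <- lo - pad
  knots[length(knots) - degree] <- hi + pad
  m <- n_interior_knots + degree + 1L
  B <- splines::splineDesign(knots, x, ord = degree + 1L)
  D <- diff(diag(m), differences = diff_order)
  K <- crossprod(D)
  structure(list(B = B, knots = knots, degree = degree, m = m, K = K,
                 penalty_rank = m - diff_order, diff_order = diff_order,
                 range = c(lo, hi)),
            class = "spline_basis")
}

#' Evaluate a spline basis at new points
#'
#' @param basis a `spline_basis`.
#' @param x points inside the basis range.
#' @return Matrix of basis values (length(x) x m).
#' @export
evaluate_spline_basis <- function(basis, x) {
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L)
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> degree", x$degree, "m =", x$m,
      "penalty rank", x$penalty_rank, "\n")
  invisible(x)
}

#' Build the design bundle for the geo-additive multinomial model
#'
#' Assembles every matrix the sampler needs from the (recoded) record
#' table: the reference-cell fixed-effect design `Z` (intercept plus
#' dummies, reference level = first level alphabetically unless overridden
#' -- every choice is logged in the bundle), optional P-spline blocks for
#' metrical covariates, the per-child region index, and the intrinsic CAR
#' precision from the adjacency graph.  Only complete cases on the used
#' columns enter the design (complete-case policy; the dropped row ids are
#' returned).  The default model uses linear effects only; smooth terms
#' attach when requested.
#'
#' @param records data.frame of child records (typically after
#'   [recode_covariates()]).  Rows flagged by ingestion are excluded.
#' @param terms character vector of covariate columns entering as
#'   fixed (categorical or numeric-linear) effects.
#' @param smooth_terms character vector of metrical covariate columns
#'   getting P-spline blocks (default none).
#' @param graph optional `adjacency_graph` for the spatial terms; `NULL`
#'   fits a non-spatial model.
#' @param reference_levels named list `covariate -> reference level`
#'   overriding the alphabetical default.
#' @param n_interior_knots,degree spline settings, see
#'   [build_spline_basis()].
#' @return Object of class `design_bundle`: `Z`, `smooths` (named list of
#'   `spline_basis`), `region_index` (1-based index into `graph$ids`, or
#'   `NULL`), `graph`, `Q` (`icar_precision`, or `NULL`), `rows` (kept row
#'   indices of `records`), `reference_levels`, `categories` (1..7,
#'   reference 0) and `n`.
#' @export
build_design <- function(records, terms, smooth_terms = character(),
                         graph = NULL, reference_levels = NULL,
                         n_interior_knots = 20, degree = 3) {
  stopifnot(is.data.frame(records), length(terms) >= 1)
  used <- unique(c(terms, smooth_terms,
                   if (!is.null(graph)) "region_id"))
  missing_terms <- setdiff(used, names(records))
  if (length(missing_terms))
    stop("term(s) not in records: ", paste(missing_terms, collapse = ", "))

  keep <- rep(TRUE, nrow(records))
  if (!is.null(records$flagged)) keep <- keep & !records$flagged
  for (v in used) keep <- keep & !is.na(records[[v]])
  if (!is.null(graph)) keep <- keep & records$region_id %in% graph$ids
  rows <- which(keep)
  if (length(rows) == 0L) stop("no complete cases left for the design")
  dat <- records[rows, , drop = FALSE]

  refs <- list()
  dropped <- character(0)
  for (v in terms) {
    x <- dat[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2L) {     # constant after filtering: nothing to fit
        dropped <- c(dropped, v)
        next
      }
      ref <- reference_levels[[v]]
      if (!is.null(ref)) {
        if (!ref %in% lev) stop("reference level '", ref,
                                "' not observed for ", v)
        lev <- c(ref, setdiff(lev, ref))
      }
      dat[[v]] <- factor(as.character(x), levels = lev)
      refs[[v]] <- lev[1L]
    }
  }
  if (length(dropped)) {
    message("dropping constant term(s): ", paste(dropped, collapse = ", "))
    terms <- setdiff(terms, dropped)
    if (length(terms) == 0L) terms <- "1"   # intercept-only design
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  Z <- stats::model.matrix(fml, data = dat)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    aliased <- colnames(Z)[qrz$pivot[(qrz$rank + 1L):ncol(Z)]]
    stop("design is rank-deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  smooths <- list()
  for (v in smooth_terms) {
    if (!is.numeric(dat[[v]]))
      stop("smooth term '", v, "' must be numeric")
    smooths[[v]] <- build_spline_basis(dat[[v]], n_interior_knots, degree)
  }

  region_index <- NULL; Q <- NULL
  if (!is.null(graph)) {
    region_index <- match(dat$region_id, graph$ids)
    Q <- build_icar_precision(graph)
  }
  structure(list(Z = Z, smooths = smooths, region_index = region_index,
                 graph = graph, Q = Q, rows = rows,
                 reference_levels = refs, categories = 1:7, n = nrow(Z)),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat("<design_bundle>", x$n, "children,", ncol(x$Z), "fixed-effect columns",
      if (length(x$smooths)) paste0(", ", length(x$smooths), " smooth(s)"),
      if (!is.null(x$graph)) paste0(", ", x$graph$n, " regions"), "\n")
  invisible(x)
}
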