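#' Posterior odds-ratio summary of one coefficient chain
#'
#' The "posterior OR" is `exp` of the posterior mean of the log-odds
#' coefficient; the 95% interval is `exp` of the 2.5%/97.5% empirical
#' quantiles of the coefficient chain (linear-interpolation quantiles,
#' `type = 7`), i.e. the chain is summarised on the log-odds scale and
#' exponentiated afterwards.  The alternative convention (summarising the
#' exponentiated draws) is available via `scale = "or"` and the choice is
#' recorded in the result.  An effect is flagged significant when the OR
#' interval excludes 1.
#'
#' @param chain numeric vector of post-burn-in draws for one coefficient.
#' @param label contrast label (e.g. `"child_age_group<20"`).
#' @param category category code 1..7 the coefficient belongs to.
#' @param level interval level, default 0.95 (equal-tailed).
#' @param scale `"coefficient"` (default) or `"or"`: which scale the mean
#'   and quantiles are taken on before/after exponentiation.
#' @return One-row data.frame of class `or_summary`: `category`, `label`,
#'   `posterior_mean_coef`, `or`, `ci_low`, `ci_high`, `significant`,
#'   `scale`.  A chain shorter than 100 draws attaches a warning.
#' @export
summarize_or <- function(chain, label = "coef", category = 1L, level = 0.95,
                         scale = c("coefficient", "or")) {
  scale <- match.arg(scale)
  chain <- as.numeric(chain)
  if (length(chain) == 0L) stop("empty chain")
  if (length(chain) < 100L)
    warning("chain has only ", length(chain), " draws; summaries are noisy")
  al <- (1 - level) / 2
  if (scale == "coefficient") {
    m <- mean(chain)
    q <- stats::quantile(chain, c(al, 1 - al), names = FALSE, type = 7)
    or <- exp(m); ci <- exp(q)
  } else {
    ec <- exp(chain)
    m <- mean(chain)
    or <- mean(ec)
    ci <- stats::quantile(ec, c(al, 1 - al), names = FALSE, type = 7)
  }
  out <- data.frame(category = as.integer(category), label = label,
                    posterior_mean_coef = m, or = or,
                    ci_low = ci[1L], ci_high = ci[2L],
                    significant = ci[1L] > 1 || ci[2L] < 1,
                    scale = scale, stringsAsFactors = FALSE)
  class(out) <- c("or_summary", "data.frame")
  out
}

#' Posterior odds-ratio table for all fixed effects
#'
#' One [summarize_or()] row per non-intercept coefficient per category
#' (the intercept is reported on the coefficient scale only in the chains;
#' ORs of intercepts are not contrasts).
#'
#' @param samples a `posterior_samples`.
#' @param level interval level.
#' @param scale see [summarize_or()].
#' @return data.frame with the `or_summary` columns plus `category_label`.
#' @export
or_table <- function(samples, level = 0.95, scale = "coefficient") {
  stopifnot(inherits(samples, "posterior_samples"))
  labs <- outcome_labels()
  rows <- list()
  for (cc in names(samples$beta)) {
    m <- samples$beta[[cc]]
    for (j in seq_len(ncol(m))) {
      if (colnames(m)[j] == "(Intercept)") next
      rows[[length(rows) + 1L]] <-
        summarize_or(m[, j], label = colnames(m)[j],
                     category = as.integer(cc), level = level, scale = scale)
    }
  }
  out <- do.call(rbind, rows)
  out$category_label <- labs[as.character(out$category)]
  rownames(out) <- NULL
  out
}

#' Per-region posterior spatial-effect table
#'
#' Summaries of the structured spatial effect `theta` for one category, on
#' both the coefficient and the exponential (odds-ratio) scale, one row
#' per region sorted by region id.  The total region effect `theta + phi`
#' is available via `component = "total"`.  A companion ranking attribute
#' identifies the highest-risk region.
#'
#' @param samples a `posterior_samples` fitted with spatial terms.
#' @param category category code 1..7.
#' @param level interval level, default 0.95.
#' @param component `"structured"` (default; what the maps show) or
#'   `"total"`.
#' @return data.frame of class `spatial_effect_table`: `region_id`,
#'   `region_name`, `mean`, `median`, `q_low`, `q_high` (coefficient
#'   scale), `or` (exp of posterior mean), `or_low`, `or_high`,
#'   `significant` (interval excludes 0).  Attribute `top_region` gives
#'   the region with the largest posterior mean.
#' @export
spatial_effect_table <- function(samples, category, level = 0.95,
                                 component = c("structured", "total")) {
  stopifnot(inherits(samples, "posterior_samples"))
  component <- match.arg(component)
  cc <- as.character(as.integer(category))
  if (!cc %in% names(samples$theta %||% list()))
    stop("unknown category or no spatial terms in the fit: ", category)
  m <- samples$theta[[cc]]
  if (component == "total") m <- m + samples$phi[[cc]]
  al <- (1 - level) / 2
  ids <- as.integer(colnames(m))
  ord <- order(ids)
  g <- samples$graph
  nm <- if (!is.null(g$names)) g$names[match(ids[ord], g$ids)] else NA_character_
  qs <- apply(m, 2L, stats::quantile, probs = c(al, 0.5, 1 - al),
              names = FALSE, type = 7)
  out <- data.frame(region_id = ids[ord], region_name = nm,
                    mean = colMeans(m)[ord], median = qs[2L, ord],
                    q_low = qs[1L, ord], q_high = qs[3L, ord],
                    or = exp(colMeans(m))[ord],
                    or_low = exp(qs[1L, ord]), or_high = exp(qs[3L, ord]),
                    stringsAsFactors = FALSE)
  out$significant <- out$q_low > 0 | out$q_high < 0
  rownames(out) <- NULL
  attr(out, "category") <- as.integer(category)
  attr(out, "component") <- component
  attr(out, "top_region") <- out$region_id[which.max(out$mean)]
  class(out) <- c("spatial_effect_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all result surfaces to disk
#'
#' One OR CSV and one spatial-effect CSV per non-reference category (7 of
#' each), plus a machine-readable JSON bundle of everything.  The spatial
#' CSVs are keyed by region id and name, ready to join against any
#' choropleth tool.
#'
#' @param samples a `posterior_samples`.
#' @param out_dir output directory (created if needed).
#' @param level interval level.
#' @param scale OR summarisation scale, see [summarize_or()].
#' @return Invisibly, a character vector of the files written (7 + 7 + 1).
#' @export
write_results <- function(samples, out_dir, level = 0.95,
                          scale = "coefficient") {
  stopifnot(inherits(samples, "posterior_samples"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ors <- or_table(samples, level = level, scale = scale)
  files <- character(0)
  bundle <- list(scale = scale, level = level, or = list(), spatial = list())
  for (cc in 1:7) {
    sub <- ors[ors$category == cc, , drop = FALSE]
    f <- file.path(out_dir, sprintf("or_cat%d_%s.csv", cc,
                                    outcome_labels()[as.character(cc)]))
    utils::write.csv(sub, f, row.names = FALSE)
    files <- c(files, f)
    bundle$or[[as.character(cc)]] <- sub
  }
  if (!is.null(samples$theta)) {
    for (cc in 1:7) {
      tab <- spatial_effect_table(samples, cc, level = level)
      f <- file.path(out_dir, sprintf("spatial_cat%d_%s.csv", cc,
                                      outcome_labels()[as.character(cc)]))
      utils::write.csv(tab, f, row.names = FALSE)
      files <- c(files, f)
      bundle$spatial[[as.character(cc)]] <- as.data.frame(tab)
    }
  }
  jf <- file.path(out_dir, "results.json")
  jsonlite::write_json(bundle, jf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, jf))
}
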