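#' Pearson chi-squared test on a contingency table
#'
#' Thin, validated wrapper around the Pearson statistic for the descriptive
#' association screen.  No continuity correction is applied by default (the
#' screen treats every table the same way; a documented switch enables the
#' Yates correction for 2x2 tables).  Cells with expected count below 5
#' raise a warning flag in the result rather than switching silently to an
#' exact test.
#'
#' @param counts matrix of non-negative counts, at least 2x2.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return List of class `chi_squared_test`: `chi2`, `df`, `p_value`,
#'   `significant` (at the 0.05 screen level), `expected`,
#'   `low_expected_cells` (count of cells with expected < 5).
#' @examples
#' chi_squared_test(matrix(c(10, 20, 20, 10), 2))$chi2  # 6.6667
#' @export
chi_squared_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0)) stop("degenerate table: row margin ",
                         which(rs == 0)[1L], " is zero")
  if (any(cs == 0)) stop("degenerate table: column margin ",
                         which(cs == 0)[1L], " is zero")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  low <- sum(ht$expected < 5)
  if (low > 0)
    warning(low, " cell(s) with expected count < 5; chi-squared ",
            "approximation may be poor")
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 significant = unname(ht$p.value) < 0.05,
                 expected = ht$expected, low_expected_cells = low),
            class = "chi_squared_test")
}

#' @export
print.chi_squared_test <- function(x, ...) {
  cat(sprintf("chi2 = %.4f, df = %d, p = %.4g%s\n", x$chi2, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Cross-tabulate a factor against a binary illness indicator
#'
#' One row of the descriptive screen: observed counts of factor level by
#' illness status, margins, and the Pearson chi-squared association test.
#'
#' @param records data.frame of child records.
#' @param factor_name column to tabulate (categorical).
#' @param illness one of `"diarrhoea"`, `"fever"`, `"cough"`.
#' @param correct passed to [chi_squared_test()].
#' @return Object of class `cross_tab`: factor name, level labels, observed
#'   count matrix, margins, and the test fields.
#' @export
cross_tab <- function(records, factor_name, illness, correct = FALSE) {
  stopifnot(factor_name %in% names(records),
            illness %in% c("diarrhoea", "fever", "cough"))
  f <- records[[factor_name]]
  y <- records[[illness]]
  keep <- !is.na(f) & !is.na(y)
  obs <- table(factor(f[keep]), factor(y[keep], levels = c(0, 1),
                                       labels = c("no", "yes")))
  obs <- unclass(obs)
  tst <- chi_squared_test(obs, correct = correct)
  structure(list(factor = factor_name, illness = illness,
                 levels = rownames(obs), observed = obs,
                 row_margin = rowSums(obs), col_margin = colSums(obs),
                 chi2 = tst$chi2, df = tst$df, p_value = tst$p_value,
                 significant = tst$significant,
                 low_expected_cells = tst$low_expected_cells),
            class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat(sprintf("<cross_tab> %s x %s: chi2 = %.3f (df %d), p = %.4g%s\n",
              x$factor, x$illness, x$chi2, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Distribution of the co-morbidity outcome categories
#'
#' @param outcomes vector of category codes 0..7 (e.g. from
#'   [encode_outcome()]); `NA` codes are dropped with a message.
#' @return data.frame with one row per category 0..7: `k`, `label`,
#'   `count`, `percent` (of non-missing records; sums to 100 within 1e-9)
#'   and `percent_fmt` (2 decimals, for the formatted table).
#' @export
category_distribution <- function(outcomes) {
  k <- as.integer(outcomes)
  if (length(k) == 0L) stop("empty outcome vector")
  if (anyNA(k)) {
    message(sum(is.na(k)), " record(s) with missing outcome dropped")
    k <- k[!is.na(k)]
  }
  if (length(k) == 0L) stop("no non-missing outcomes")
  tab <- table(factor(k, levels = 0:7))
  pct <- 100 * as.vector(tab) / sum(tab)
  data.frame(k = 0:7, label = unname(outcome_labels()),
             count = as.vector(tab), percent = pct,
             percent_fmt = sprintf("%.2f", pct))
}

#' Write the descriptive screen to CSV
#'
#' Emits two survey-report-style tables: a factor-by-illness association
#' table (counts per level with chi-squared columns) and the outcome
#' category distribution.  Cell percentages can condition on the factor
#' level (`"row"`) or on illness status (`"column"`); the orientation is
#' written into the file so tables are never ambiguous.
#'
#' @param records data.frame of child records (with outcome flags).
#' @param factors character vector of factor columns to screen.
#' @param out_dir output directory.
#' @param percent one of `"row"`, `"column"`: percentage orientation of the
#'   association table.
#' @return Invisibly, the two file paths.
#' @export
write_descriptives <- function(records, factors, out_dir, percent = c("row", "column")) {
  percent <- match.arg(percent)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (fac in factors) {
    for (ill in c("diarrhoea", "fever", "cough")) {
      ct <- cross_tab(records, fac, ill)
      pc <- if (percent == "row") 100 * ct$observed[, "yes"] / ct$row_margin
            else 100 * ct$observed[, "yes"] / ct$col_margin["yes"]
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fac, level = ct$levels, illness = ill,
        n_ill = ct$observed[, "yes"], n_well = ct$observed[, "no"],
        percent = round(pc, 2), percent_of = percent,
        chi2 = round(ct$chi2, 4), df = ct$df,
        p_value = signif(ct$p_value, 4), significant = ct$significant)
    }
  }
  assoc <- do.call(rbind, rows)
  f1 <- file.path(out_dir, "factor_illness_associations.csv")
  utils::write.csv(assoc, f1, row.names = FALSE)
  k <- encode_outcome(records$diarrhoea, records$fever, records$cough)
  f2 <- file.path(out_dir, "outcome_category_distribution.csv")
  utils::write.csv(category_distribution(k), f2, row.names = FALSE)
  invisible(c(associations = f1, categories = f2))
}
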