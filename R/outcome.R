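#' The eight co-morbidity categories
#'
#' Canonical labels for the categorical outcome formed from the three binary
#' illness indicators.  Category 0 (no illness) is the reference level of the
#' multinomial model; categories 1..7 are the seven illness combinations.
#'
#' @return Named character vector of length 8; names are the category codes
#'   "0".."7".
#' @export
outcome_labels <- function() {
  c("0" = "no_illness",
    "1" = "diarrhoea_fever_cough",
    "2" = "diarrhoea_fever",
    "3" = "diarrhoea_cough",
    "4" = "fever_cough",
    "5" = "diarrhoea_only",
    "6" = "fever_only",
    "7" = "cough_only")
}

# flag triples for k = 0..7, row k+1 = (diarrhoea, fever, cough)
.outcome_map <- matrix(
  c(0L, 0L, 0L,
    1L, 1L, 1L,
    1L, 1L, 0L,
    1L, 0L, 1L,
    0L, 1L, 1L,
    1L, 0L, 0L,
    0L, 1L, 0L,
    0L, 0L, 1L),
  ncol = 3, byrow = TRUE,
  dimnames = list(0:7, c("diarrhoea", "fever", "cough")))

#' Encode illness flags as the co-morbidity category
#'
#' Maps the three binary indicators to the eight-level outcome code `k`:
#' all three illnesses -> 1, diarrhoea & fever -> 2, diarrhoea & cough -> 3,
#' fever & cough -> 4, diarrhoea only -> 5, fever only -> 6, cough only -> 7,
#' none -> 0.  The map is a bijection between \{0,1\}^3 and \{0..7\}.
#'
#' @param diarrhoea,fever,cough binary vectors (0/1).  `NA` in any flag gives
#'   an `NA` code (the caller flags such records for exclusion rather than
#'   imputing them).
#' @return Integer vector of category codes in 0..7 with a `labels`
#'   attribute; class `comorbidity_outcome`.
#' @examples
#' encode_outcome(1, 1, 1)  # 1
#' encode_outcome(0, 0, 0)  # 0
#' encode_outcome(1, 0, 1)  # 3
#' @export
encode_outcome <- function(diarrhoea, fever, cough) {
  n <- max(length(diarrhoea), length(fever), length(cough))
  d <- rep_len(as.integer(diarrhoea), n)
  f <- rep_len(as.integer(fever), n)
  c_ <- rep_len(as.integer(cough), n)
  ok <- is.na(d) | d %in% c(0L, 1L)
  ok <- ok & (is.na(f) | f %in% c(0L, 1L))
  ok <- ok & (is.na(c_) | c_ %in% c(0L, 1L))
  if (!all(ok)) {
    stop("illness flags must be 0, 1 or NA (first bad row: ",
         which(!ok)[1L], ")")
  }
  # match each triple against the canonical map
  key <- d * 4L + f * 2L + c_
  lut <- integer(8L)
  lut[.outcome_map[, 1L] * 4L + .outcome_map[, 2L] * 2L +
        .outcome_map[, 3L] + 1L] <- 0:7
  k <- lut[key + 1L]
  k[is.na(key)] <- NA_integer_
  structure(k, labels = outcome_labels(), class = "comorbidity_outcome")
}

#' Decode a co-morbidity category back to illness flags
#'
#' Exact inverse of [encode_outcome()]; used by the synthetic-data generator
#' to back-fill the binary indicators from a sampled category.
#'
#' @param k integer vector of category codes in 0..7.
#' @return data.frame with integer columns `diarrhoea`, `fever`, `cough`.
#' @export
decode_outcome <- function(k) {
  k <- as.integer(k)
  if (any(!is.na(k) & (k < 0L | k > 7L))) stop("category codes must lie in 0..7")
  out <- .outcome_map[k + 1L, , drop = FALSE]
  data.frame(diarrhoea = out[, 1L], fever = out[, 2L], cough = out[, 3L],
             row.names = NULL)
}

#' @export
print.comorbidity_outcome <- function(x, ...) {
  cat("<comorbidity_outcome> n =", length(x), "\n")
  tab <- table(factor(unclass(x), levels = 0:7))
  names(tab) <- paste0(names(tab), ":", outcome_labels())
  print(tab)
  invisible(x)
}
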