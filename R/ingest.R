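#' Default column map for survey ingestion
#'
#' Maps source variable names to the package's canonical child-record
#' fields.  For CSV input the identity map is used; for an SPSS export the
#' DHS variable codes vary by release, so the map ships as an editable YAML
#' profile (see `system.file("extdata", "edhs_column_map.yaml",
#' package = "morbidmap")`) rather than being hard-coded.
#'
#' @param path optional YAML profile; `NULL` gives the identity map over the
#'   canonical field names.
#' @return Named character vector: canonical field -> source column.
#' @export
default_column_map <- function(path = NULL) {
  fields <- c("child_id", "diarrhoea", "fever", "cough", "child_age_months",
              "sex", "maternal_age_first_birth_years", "bmi", "residence",
              "household_size", "antenatal_visits", "place_of_delivery",
              "working_status", "wealth_quintile", "mother_education",
              "region_id", "area7")
  if (is.null(path)) return(stats::setNames(fields, fields))
  m <- yaml::read_yaml(path)
  out <- stats::setNames(fields, fields)
  out[names(m)] <- unlist(m)
  out
}

.mandatory_fields <- c("diarrhoea", "fever", "cough", "region_id")

#' Read and validate a child-morbidity survey
#'
#' Reads one row per child from CSV (the canonical interchange) or from an
#' SPSS SAV file (optional; requires the `foreign` package), renames source
#' columns to the canonical dictionary via `column_map`, and validates the
#' fields the model needs.  Rows with impossible or missing mandatory
#' values are *flagged*, not dropped or imputed -- complete-case filtering
#' for the model covariates is applied downstream, and every exclusion is
#' listed in the validation report.
#'
#' @param path input file.
#' @param dialect `"csv"` (default) or `"sav"`.
#' @param column_map named character vector, canonical field -> source
#'   column; see [default_column_map()].
#' @param graph optional `adjacency_graph`; when given, region ids are
#'   validated against it.
#' @return List with `records` (data.frame with canonical column names and
#'   a logical `flagged` column) and `report` (list: `n_read`, `n_flagged`,
#'   `exclusions` data.frame with row ids and reasons).
#' @export
read_survey <- function(path, dialect = c("csv", "sav"),
                        column_map = default_column_map(), graph = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("survey file not found: ", path)
  if (dialect == "csv") {
    raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) stop("unreadable survey file '", path,
                                             "': ", conditionMessage(e)))
  } else {
    if (!requireNamespace("foreign", quietly = TRUE))
      stop("reading SAV files requires the 'foreign' package; ",
           "convert to CSV for the dependency-free path")
    raw <- foreign::read.spss(path, to.data.frame = TRUE,
                              use.value.labels = TRUE)
    names(raw) <- trimws(names(raw))
  }
  if (nrow(raw) == 0L) stop("survey file is empty: ", path)

  missing_cols <- setdiff(unname(column_map[.mandatory_fields]), names(raw))
  if (length(missing_cols))
    stop("unmapped mandatory column(s): ", paste(missing_cols, collapse = ", "))

  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(column_map)) {
    src <- column_map[[field]]
    if (src %in% names(raw)) rec[[field]] <- raw[[src]]
  }
  if (is.null(rec$child_id)) rec$child_id <- seq_len(nrow(rec))

  exclusions <- data.frame(row = integer(), reason = character())
  note <- function(rows, reason) {
    if (length(rows))
      exclusions <<- rbind(exclusions, data.frame(row = rows, reason = reason))
  }
  for (fl in c("diarrhoea", "fever", "cough")) {
    v <- suppressWarnings(as.integer(rec[[fl]]))
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
    note(bad, paste0("missing or non-binary ", fl, " flag"))
    v[!(v %in% c(0L, 1L))] <- NA_integer_
    rec[[fl]] <- v
  }
  if (!is.null(rec$child_age_months)) {
    bad <- which(!is.na(rec$child_age_months) &
                   (rec$child_age_months < 0 | rec$child_age_months > 60))
    note(bad, "child_age_months outside [0, 60]")
  }
  if (!is.null(graph)) {
    bad <- which(!(rec$region_id %in% graph$ids))
    note(bad, "region_id not in adjacency graph")
  } else {
    note(which(is.na(rec$region_id)), "missing region_id")
  }

  flagged_rows <- sort(unique(exclusions$row))
  rec$flagged <- seq_len(nrow(rec)) %in% flagged_rows
  list(records = rec,
       report = list(n_read = nrow(rec), n_flagged = length(flagged_rows),
                     exclusions = exclusions))
}

#' Recode raw covariates into the analysis categories
#'
#' Produces the all-categorical analysis view used by the model: child age
#' binned into under-20, 20-40 and over-40 months (half-open, left-closed:
#' \[0,20), \[20,40), \[40,60\]); maternal age at first birth split at 20
#' years (closed left: 20 belongs to "<=20"); BMI dichotomised at
#' `bmi_threshold` (default 18.5 per WHO underweight cut-point; 18.0 is
#' supported because the source analysis is ambiguous between a plain 18.0 cut-off and
#' the WHO guideline value); wealth quintiles optionally collapsed to
#' poorest/poorer vs middle vs richer/richest.  Every bin choice is
#' recorded in the `recode_manifest` attribute.  The operation is
#' idempotent: recoding an already-coded table is a no-op.
#'
#' @param records data.frame of canonical child records (see
#'   [read_survey()]).
#' @param bmi_threshold BMI cut-point, default 18.5.
#' @param collapse_wealth collapse the five quintiles to three groups.
#' @return The records with factor columns `child_age_group`,
#'   `maternal_age_group`, `bmi_group` (plus `wealth_group` if collapsing)
#'   appended, and a `recode_manifest` attribute describing every rule
#'   applied.  Out-of-domain raw values yield `NA` plus an entry in the
#'   manifest's `validation` element (with row ids), never a silent recode.
#' @export
recode_covariates <- function(records, bmi_threshold = 18.5,
                              collapse_wealth = FALSE) {
  manifest <- list(
    child_age_bins = "[0,20) -> '<20'; [20,40) -> '20-40'; [40,60] -> '>40' (months)",
    maternal_age_rule = "age at first birth <= 20 years -> '<=20', else '>20'",
    bmi_threshold = bmi_threshold,
    wealth_collapsed = collapse_wealth,
    validation = list())
  done <- attr(records, "recode_manifest")
  if (!is.null(done) && all(c("child_age_group", "maternal_age_group")
                            %in% names(records)))
    return(records)                      # idempotent

  bad_rows <- function(x, lo, hi) which(!is.na(x) & (x < lo | x > hi))

  if (!is.null(records$child_age_months)) {
    x <- records$child_age_months
    bad <- bad_rows(x, 0, 60)
    if (length(bad)) {
      manifest$validation$child_age_months <- bad
      x[bad] <- NA_real_
    }
    records$child_age_group <- cut(x, breaks = c(0, 20, 40, 60.0001),
                                   labels = c("<20", "20-40", ">40"),
                                   right = FALSE, include.lowest = TRUE)
  }
  if (!is.null(records$maternal_age_first_birth_years)) {
    x <- records$maternal_age_first_birth_years
    bad <- bad_rows(x, 8, 49)
    if (length(bad)) {
      manifest$validation$maternal_age_first_birth_years <- bad
      x[bad] <- NA_real_
    }
    records$maternal_age_group <- factor(ifelse(x <= 20, "<=20", ">20"),
                                         levels = c("<=20", ">20"))
  }
  if (!is.null(records$bmi)) {
    x <- records$bmi
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      manifest$validation$bmi <- bad
      x[bad] <- NA_real_
    }
    records$bmi_group <- factor(
      ifelse(x <= bmi_threshold, paste0("<=", bmi_threshold),
             paste0(">", bmi_threshold)),
      levels = paste0(c("<=", ">"), bmi_threshold))
  }
  if (collapse_wealth && !is.null(records$wealth_quintile)) {
    map <- c(poorest = "poorest_poorer", poorer = "poorest_poorer",
             middle = "middle", richer = "richer_richest",
             richest = "richer_richest")
    records$wealth_group <- factor(map[as.character(records$wealth_quintile)],
                                   levels = unique(unname(map)))
  }
  attr(records, "recode_manifest") <- manifest
  records
}

#' Write a validation report as JSON
#'
#' @param report the `report` element returned by [read_survey()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
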