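.default_terms <- c("child_age_group", "sex", "residence",
                    "maternal_age_group", "bmi_group", "antenatal_visits",
                    "place_of_delivery", "working_status", "wealth_quintile",
                    "mother_education")

.known_config_keys <- c("input", "recode", "terms", "smooth_terms", "graph",
                        "mcmc", "out_dir", "seed")

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an R list; fills documented defaults,
#' rejects unknown keys by name, and checks every invariant (exactly one
#' input source; mandatory seed; chain-setting constraints).  All problems
#' are reported together, field by field.
#'
#' Schema (all except `seed` optional):
#' \describe{
#'   \item{input}{exactly one of `csv: <path>` (optionally `column_map:
#'     <yaml>`), `sav: <path>` (+ `column_map`), or `synthetic:
#'     \{n_children, spatial_var, unstructured_var, betas\}` (betas: list of
#'     7 vectors, default all zero).}
#'   \item{recode}{`bmi_threshold` (default 18.5), `collapse_wealth`
#'     (default FALSE).}
#'   \item{terms}{fixed-effect covariates (default: the all-categorical
#'     analysis view).}
#'   \item{smooth_terms}{metrical covariates given P-spline blocks
#'     (default none: linear-effects-only model).}
#'   \item{graph}{`"egypt"` (default) or `\{edges: <path>, lookup: <path>\}`.}
#'   \item{mcmc}{`n_iterations`, `burn_in`, `thinning`, `eps`, `a`, `b`
#'     (defaults as in [model_spec()]).}
#'   \item{out_dir}{output directory (default `"morbidmap_run"`).}
#'   \item{seed}{mandatory integer; governs every stochastic stage.}
#' }
#'
#' @param config file path (YAML or JSON) or list.
#' @return A normalised list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  errs <- character(0)
  bad <- setdiff(names(config), .known_config_keys)
  if (length(bad))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(bad, collapse = ", ")))
  if (is.null(config$seed) || !is.numeric(config$seed))
    errs <- c(errs, "seed: mandatory integer missing")

  input <- config$input %||% list()
  sources <- intersect(names(input), c("csv", "sav", "synthetic"))
  if (length(sources) != 1L)
    errs <- c(errs, paste0("input: exactly one of csv/sav/synthetic required",
                           " (got ", length(sources), ")"))
  bad_in <- setdiff(names(input), c("csv", "sav", "synthetic", "column_map"))
  if (length(bad_in))
    errs <- c(errs, paste0("input: unknown key(s) ",
                           paste(bad_in, collapse = ", ")))

  recode <- config$recode %||% list()
  recode$bmi_threshold <- recode$bmi_threshold %||% 18.5
  recode$collapse_wealth <- isTRUE(recode$collapse_wealth)
  if (!recode$bmi_threshold %in% c(18, 18.5) && !is.numeric(recode$bmi_threshold))
    errs <- c(errs, "recode$bmi_threshold: must be numeric")

  mc <- config$mcmc %||% list()
  bad_mc <- setdiff(names(mc), c("n_iterations", "burn_in", "thinning",
                                 "eps", "a", "b"))
  if (length(bad_mc))
    errs <- c(errs, paste0("mcmc: unknown key(s) ",
                           paste(bad_mc, collapse = ", ")))
  spec <- tryCatch(
    model_spec(n_iterations = mc$n_iterations %||% 12000,
               burn_in = mc$burn_in %||% 2000,
               thinning = mc$thinning %||% 10,
               seed = as.integer(config$seed %||% 1L),
               eps = mc$eps %||% 1e-6, a = mc$a %||% 0.001,
               b = mc$b %||% 0.001),
    error = function(e) { errs <<- c(errs, paste0("mcmc: ",
                                                  conditionMessage(e))); NULL })
  if (length(errs)) stop("invalid config:\n  - ",
                         paste(errs, collapse = "\n  - "))

  norm <- list(input = input,
               recode = recode,
               terms = config$terms %||% .default_terms,
               smooth_terms = config$smooth_terms %||% character(0),
               graph = config$graph %||% "egypt",
               spec = spec,
               out_dir = config$out_dir %||% "morbidmap_run",
               seed = as.integer(config$seed))
  class(norm) <- "run_config"
  norm
}

.load_graph <- function(gcfg) {
  if (identical(gcfg, "egypt")) return(egypt_graph())
  if (is.list(gcfg) && !is.null(gcfg$edges))
    return(read_adjacency(gcfg$edges, gcfg$lookup))
  stop("graph must be \"egypt\" or a list with an 'edges' path")
}

#' Run the full analysis pipeline
#'
#' Ingest (or simulate) -> recode -> descriptive screen -> design ->
#' MCMC -> posterior summaries, with every stage's inputs and outputs
#' hashed into a reproducibility manifest.  A stage failure stops the run
#' with the failing stage named.  The same configuration and seed give a
#' byte-identical results bundle.
#'
#' @param config a `run_config` from [validate_config()], or anything that
#'   function accepts.
#' @return Invisibly, the manifest (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logf("stage %-12s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  manifest <- list(config = list(
    terms = config$terms, smooth_terms = config$smooth_terms,
    recode = config$recode, spec = unclass(config$spec), seed = config$seed,
    input_source = intersect(names(config$input),
                             c("csv", "sav", "synthetic"))))
  timing <- list()

  graph <- stage("graph", .load_graph(config$graph))

  dat <- stage("ingest", {
    inp <- config$input
    if (!is.null(inp$synthetic)) {
      sy <- inp$synthetic
      p <- .truth_design_dim(default_covariate_spec())
      betas <- if (is.null(sy$betas)) matrix(0, p, 7)
               else do.call(cbind, lapply(sy$betas, unlist))
      tr <- truth_config(n_children = sy$n_children %||% 1000,
                         betas = betas,
                         spatial_var = sy$spatial_var %||% 0.3,
                         unstructured_var = sy$unstructured_var %||% 0.1,
                         graph = graph, seed = config$seed)
      sv <- generate_survey(tr)
      write_survey(sv, out_dir)
      list(records = sv$records,
           report = list(n_read = nrow(sv$records), n_flagged = 0L,
                         exclusions = data.frame()))
    } else {
      path <- inp$csv %||% inp$sav
      cm <- if (is.null(inp$column_map)) default_column_map()
            else default_column_map(inp$column_map)
      read_survey(path, dialect = if (is.null(inp$csv)) "sav" else "csv",
                  column_map = cm, graph = graph)
    }
  })
  manifest$ingest <- dat$report[c("n_read", "n_flagged")]

  records <- stage("recode", recode_covariates(
    dat$records, bmi_threshold = config$recode$bmi_threshold,
    collapse_wealth = config$recode$collapse_wealth))
  manifest$recode <- attr(records, "recode_manifest")[
    c("child_age_bins", "maternal_age_rule", "bmi_threshold",
      "wealth_collapsed")]

  stage("descriptives", {
    cat_terms <- config$terms[vapply(config$terms, function(v)
      !is.null(records[[v]]) && !is.numeric(records[[v]]), logical(1))]
    write_descriptives(records, cat_terms, file.path(out_dir, "descriptives"))
  })

  design <- stage("design", build_design(
    records, terms = config$terms, smooth_terms = config$smooth_terms,
    graph = graph))
  manifest$design <- list(n = design$n, p = ncol(design$Z),
                          n_excluded = nrow(records) - design$n,
                          reference_levels = design$reference_levels)

  outcomes <- encode_outcome(records$diarrhoea[design$rows],
                             records$fever[design$rows],
                             records$cough[design$rows])
  fit <- stage("mcmc", run_mcmc(design, outcomes, config$spec))
  manifest$mcmc <- list(acceptance = fit$acceptance,
                        ess_beta = fit$ess_beta,
                        warnings = fit$diagnostics_warnings)

  stage("summaries", {
    write_results(fit, file.path(out_dir, "results"))
    write_chains(fit, file.path(out_dir, "chains"))
  })

  out_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- setdiff(out_files, c(file.path(out_dir, "manifest.json"),
                                    log_file))
  rel <- sub(paste0("^", out_dir, "/?"), "", out_files)
  manifest$outputs <- lapply(stats::setNames(out_files, rel),
                             function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("pipeline complete: %s", out_dir)
  invisible(manifest)
}
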