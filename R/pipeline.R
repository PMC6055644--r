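# djb2-style rolling hash over the deparsed configuration, kept in double
# arithmetic below 2^31 so it is exact: a compact fingerprint embedded in
# every artifact so outputs can be matched to the configuration that
# produced them.
config_hash <- function(obj) {
  bytes <- utf8ToInt(paste(deparse(obj), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full model-development pipeline
#'
#' Chains the development stages on a cow record table: measurement-method
#' whitelist, complete-case filtering, region-wise IQR outlier screening,
#' VIF collinearity pruning, all-subsets BIC selection, the nested mixed
#' model fit on the selected predictors, leave-one-study-out
#' cross-validation, and scoped evaluation. Each stage's artifact is
#' written under `output_dir`: `kept.csv` (screened records),
#' `screen.json`, `selection.json`, `fit.json` and `metrics.json`; every
#' JSON artifact embeds the package version and a hash of the
#' configuration. Input files are never modified.
#'
#' @param records Cow record data frame, or path to a record CSV.
#' @param output_dir Directory for artifacts (created if needed).
#' @param response Response column (default `"ch4"`).
#' @param candidates Candidate predictors for selection.
#' @param required Complete-case field set (default: response + candidates).
#' @param scopes Evaluation scopes; each is `"intercontinental"` or a
#'   region code vector.
#' @param vif_threshold VIF above which predictors are pruned.
#' @param engine Subset-scoring engine passed to [all_subsets()].
#' @param k Outlier fence multiplier.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the per-stage results (`screen`,
#'   `selection`, `fit`, `cv`, `metrics`) and the artifact paths.
#' @export
run_pipeline <- function(records, output_dir,
                         response = "ch4",
                         candidates = c("dmi", "cp", "ee", "ndf", "ash",
                                        "my", "mf", "mp", "bw"),
                         required = NULL,
                         scopes = list("intercontinental"),
                         vif_threshold = 5, engine = "lmm", k = 1.5,
                         quiet = FALSE) {
  cfg <- list(response = response, candidates = candidates,
              required = required, scopes = scopes,
              vif_threshold = vif_threshold, engine = engine, k = k)
  hash <- config_hash(cfg)
  stamp <- list(tool = "entericCH4",
                version = as.character(utils::packageVersion("entericCH4")),
                config_hash = hash)
  if (is.character(records)) {
    pipeline_log(quiet, "load", "reading ", records)
    records <- read_cow_csv(records)
  }
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  paths <- list(kept = file.path(output_dir, "kept.csv"),
                screen = file.path(output_dir, "screen.json"),
                selection = file.path(output_dir, "selection.json"),
                fit = file.path(output_dir, "fit.json"),
                metrics = file.path(output_dir, "metrics.json"))
  with_stamp <- function(path, json_fun, obj) {
    js <- jsonlite::fromJSON(json_fun(obj), simplifyVector = FALSE)
    out <- c(stamp, js)
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), path)
  }

  pipeline_log(quiet, "method_filter", nrow(records), " records in")
  data <- method_filter(records)
  if (is.null(required)) required <- unique(c(response, candidates))
  pipeline_log(quiet, "complete_cases", nrow(data), " after method filter")
  data <- complete_records(data, required = required)
  pipeline_log(quiet, "screen", nrow(data), " complete records")
  scr <- screen_outliers(data, k = k)
  data <- scr$kept
  write_cow_csv(data, paths$kept)
  with_stamp(paths$screen, screen_report_json, scr$report)

  pipeline_log(quiet, "select", nrow(data), " records kept; ",
               length(candidates), " candidates")
  sel <- all_subsets(data, candidates, response, engine = engine,
                     vif_prune = TRUE, vif_threshold = vif_threshold)
  with_stamp(paths$selection, selection_json, sel)

  pipeline_log(quiet, "fit", "best subset {",
               paste(sel$best, collapse = ", "), "}")
  fit <- methane_lmm(stats::reformulate(sel$best, response), data)
  with_stamp(paths$fit, fit_json, fit)

  pipeline_log(quiet, "crossval", "leave-one-study-out over ",
               length(unique(data$study_id)), " studies")
  cv <- loso_cv(data, stats::reformulate(sel$best, response))

  metrics <- lapply(scopes, function(s) evaluate_by_scope(cv, s))
  names(metrics) <- vapply(scopes, paste, "", collapse = "+")
  obj <- c(stamp, lapply(metrics, function(m)
    jsonlite::fromJSON(metrics_json(m), simplifyVector = FALSE)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), paths$metrics)
  pipeline_log(quiet, "done", "artifacts in ", output_dir)

  invisible(list(screen = scr$report, selection = sel, fit = fit, cv = cv,
                 metrics = metrics, paths = paths, config_hash = hash))
}
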