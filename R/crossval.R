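#' Study-defined cross-validation folds
#'
#' One fold per distinct study: the revised k-fold layout in which k
#' equals the number of studies, so held-out records never share a study
#' with the training data.
#'
#' @param data Cow record data frame with `study_id`.
#' @return An object of class `"fold_assignment"`: list with `k`, `folds`
#'   (named list mapping study id to the row indices of its records) and
#'   `study_id` per record.
#' @export
study_folds <- function(data) {
  if (anyNA(data$study_id))
    stop("study_folds: missing study_id")
  ids <- as.character(data$study_id)
  folds <- split(seq_len(nrow(data)), ids)
  if (length(folds) == 1L)
    warning("only one study: leave-one-study-out CV is degenerate")
  structure(list(k = length(folds), folds = folds, study_id = ids),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Leave-one-study-out folds: k = %d studies, %d records\n",
              x$k, length(x$study_id)))
  sizes <- lengths(x$folds)
  cat(sprintf("  fold sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Leave-one-study-out cross-validation
#'
#' For each study in turn, fits the mixed model on all remaining studies
#' and predicts the held-out study's records with fixed effects only (a
#' new-study prediction: the held-out study's random effects are never
#' seen by its own model). Predictions from all folds are pooled, aligned
#' to the observations, for downstream evaluation.
#'
#' Folds whose REML fit fails fall back to ordinary least squares with a
#' warning; the returned object counts such folds rather than aborting
#' the cross-validation.
#'
#' @param data Complete-case cow record data frame.
#' @param formula Fixed-effects formula passed to [methane_lmm()].
#' @param group,study Grouping identifier columns.
#' @param re Random-effect reuse passed to [predict.methane_lmm()];
#'   default `"none"`.
#' @return An object of class `"methane_cv"`: list with aligned vectors
#'   `record_id`, `observed`, `predicted`, `study_id`, `group_id`,
#'   `region`, plus `k`, `n_fallback` (folds refitted by OLS) and
#'   `fold_diagnostics` (per-fold convergence and training size).
#' @export
loso_cv <- function(data, formula, group = "group_id", study = "study_id",
                    re = "none") {
  fa <- study_folds(stats::setNames(data.frame(data[[study]]), "study_id"))
  if (fa$k < 3L)
    stop("loso_cv: need at least 3 studies (got ", fa$k, ")")
  response <- all.vars(formula[[2]])
  predicted <- rep(NA_real_, nrow(data))
  diags <- vector("list", fa$k)
  n_fallback <- 0L
  for (i in seq_len(fa$k)) {
    sid <- names(fa$folds)[i]
    test_idx <- fa$folds[[i]]
    train <- data[-test_idx, , drop = FALSE]
    if (length(unique(train[[study]])) < 2L)
      stop("loso_cv: training complement of study '", sid,
           "' has fewer than 2 studies")
    fit <- withCallingHandlers(
      methane_lmm(formula, train, group = group, study = study),
      warning = function(w) invokeRestart("muffleWarning"))
    if (fit$engine == "ols") n_fallback <- n_fallback + 1L
    predicted[test_idx] <- predict(fit, data[test_idx, , drop = FALSE],
                                   re = re)
    diags[[i]] <- data.frame(fold = sid, n_train = nrow(train),
                             engine = fit$engine, converged = fit$converged,
                             stringsAsFactors = FALSE)
  }
  if (n_fallback > 0L)
    warning(n_fallback, " fold(s) fell back to OLS after REML failure")
  structure(list(
    record_id = data$record_id, observed = data[[response]],
    predicted = predicted, study_id = as.character(data[[study]]),
    group_id = as.character(data[[group]]),
    region = if ("region" %in% names(data)) data$region
             else rep(NA_character_, nrow(data)),
    k = fa$k, n_fallback = n_fallback,
    fold_diagnostics = do.call(rbind, diags),
    formula = formula),
    class = "methane_cv")
}

#' @export
print.methane_cv <- function(x, ...) {
  cat(sprintf("Leave-one-study-out CV: %d records, k = %d studies\n",
              length(x$observed), x$k))
  cat("  formula:", deparse(x$formula), "\n")
  if (x$n_fallback > 0)
    cat(sprintf("  %d fold(s) used the OLS fallback\n", x$n_fallback))
  print(evaluate_predictions(x$observed, x$predicted))
  invisible(x)
}

#' @export
plot.methane_cv <- function(x, ...) {
  plot_obs_pred(x$observed, x$predicted,
                main = "Held-out predictions vs observations", ...)
}

#' Evaluate pooled CV predictions on a regional scope
#'
#' Computes the metric suite on the subset of pooled held-out predictions
#' whose records fall in the requested scope: `"intercontinental"` keeps
#' every record, `"EU"` / `"US"` keep that region, and a character vector
#' of region codes keeps their union.
#'
#' @param cv A `"methane_cv"` result.
#' @param scope `"intercontinental"`, a single region code, or a vector
#'   of region codes.
#' @return A `"metric_report"` for the scoped subset.
#' @export
evaluate_by_scope <- function(cv, scope = "intercontinental") {
  keep <- if (identical(scope, "intercontinental")) {
    rep(TRUE, length(cv$observed))
  } else {
    !is.na(cv$region) & cv$region %in% scope
  }
  if (!any(keep))
    stop("evaluate_by_scope: no records in scope ",
         paste(scope, collapse = "+"))
  evaluate_predictions(cv$observed[keep], cv$predicted[keep])
}
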