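#' Fit the nested-random-intercept methane model
#'
#' Fits `y = b0 + b1*x1 + ... + bn*xn + S(study within group) + R(group) +
#' e` by restricted maximum likelihood: fixed covariate effects plus
#' random intercepts for research group and for study nested in research
#' group, the structure used to develop multi-study CH4 prediction
#' equations. Estimation is delegated to [lme4::lmer()]; the fit is
#' deterministic given the data and formula.
#'
#' @param formula Fixed-effects formula, e.g. `ch4 ~ dmi + ndf`. The
#'   random part is always `(1 | group) + (1 | group:study)` and is added
#'   internally.
#' @param data Cow record data frame; rows must be complete for all
#'   formula variables (run [complete_records()] first).
#' @param group,study Names of the research-group and study identifier
#'   columns.
#' @return An object of class `"methane_lmm"` with components `beta`
#'   (named vector of fixed-effect estimates), `se` (their standard
#'   errors), `var_group`, `var_study`, `var_resid` (variance
#'   components), `sse_conditional`, `log_likelihood` (REML criterion),
#'   `n_obs`, `n_studies`, `n_groups`, `converged`, `boundary`,
#'   `identifiable`, `engine` (`"reml"`, or `"ols"` after a fallback) and
#'   `ranef` (group and study random-intercept predictions).
#' @examples
#' herd <- generate_herd(sim_config(n_groups = 3, studies_per_group = 3,
#'                                  cows_per_study = 10, seed = 1))
#' fit <- methane_lmm(ch4 ~ dmi + ndf, herd$records)
#' coef(fit)
#' @export
methane_lmm <- function(formula, data, group = "group_id",
                        study = "study_id") {
  response <- all.vars(formula[[2]])
  predictors <- all.vars(formula[[3]])
  needed <- c(response, predictors, group, study)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("methane_lmm: column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(data[, c(response, predictors)]))
    stop("methane_lmm: missing values in model variables; ",
         "run complete_records() first")
  data <- as.data.frame(data)
  data[[group]] <- factor(data[[group]])
  study_key <- factor(paste(data[[group]], data[[study]], sep = ":"))
  n_studies <- nlevels(study_key)
  n_groups <- nlevels(data[[group]])
  if (n_studies < 2L)
    stop("methane_lmm: a single study cannot identify the random ",
         "structure; fit ordinary least squares (lm) instead")

  identifiable <- TRUE
  if (max(table(study_key)) == 1L) {
    warning("every study has exactly one record: study and residual ",
            "variances are not separately identifiable")
    identifiable <- FALSE
  }

  out <- list(formula = formula, response = response,
              predictors = predictors, group = group, study = study,
              n_obs = nrow(data), n_studies = n_studies,
              n_groups = n_groups, identifiable = identifiable)

  # degenerate response: nothing to estimate
  if (stats::sd(data[[response]]) == 0) {
    beta <- c(mean(data[[response]]), rep(0, length(predictors)))
    names(beta) <- c("(Intercept)", predictors)
    out <- c(out, list(
      beta = beta, se = setNames(rep(0, length(beta)), names(beta)),
      var_group = 0, var_study = 0, var_resid = 0,
      sse_conditional = 0, log_likelihood = NA_real_,
      converged = TRUE, boundary = TRUE, engine = "degenerate",
      ranef = NULL, lme4_fit = NULL,
      fitted = rep(mean(data[[response]]), nrow(data)),
      residuals = rep(0, nrow(data))))
    class(out) <- "methane_lmm"
    return(out)
  }

  data$.study_key <- study_key
  rand <- sprintf("(1 | %s) + (1 | .study_key)", group)
  full <- stats::as.formula(paste(
    response, "~",
    if (length(predictors)) paste(predictors, collapse = " + ") else "1",
    "+", rand))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(full, data = data, REML = TRUE,
                                control = ctrl)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    warning("REML fit failed (", conditionMessage(fit),
            "); falling back to ordinary least squares")
    ols <- stats::lm(stats::reformulate(
      if (length(predictors)) predictors else "1", response), data = data)
    sm <- summary(ols)$coefficients
    beta <- stats::coef(ols)
    se <- setNames(rep(NA_real_, length(beta)), names(beta))
    se[rownames(sm)] <- sm[, "Std. Error"]
    out <- c(out, list(
      beta = beta, se = se, var_group = 0, var_study = 0,
      var_resid = sum(stats::resid(ols)^2) / stats::df.residual(ols),
      sse_conditional = sum(stats::resid(ols)^2),
      log_likelihood = as.numeric(stats::logLik(ols)),
      converged = FALSE, boundary = FALSE, engine = "ols",
      ranef = NULL, lme4_fit = NULL,
      fitted = stats::fitted(ols), residuals = stats::resid(ols)))
    class(out) <- "methane_lmm"
    return(out)
  }

  sm <- summary(fit)$coefficients
  beta <- lme4::fixef(fit)
  se <- sm[names(beta), "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  vget <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  msgs <- fit@optinfo$conv$lme4$messages
  real_warnings <- if (is.null(msgs)) character(0)
  else msgs[!grepl("boundary", msgs, ignore.case = TRUE)]
  re <- lme4::ranef(fit)
  out <- c(out, list(
    beta = beta, se = se,
    var_group = vget(group), var_study = vget(".study_key"),
    var_resid = vget("Residual"),
    sse_conditional = sum(stats::resid(fit)^2),
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = fit@optinfo$conv$opt == 0 && length(real_warnings) == 0,
    boundary = lme4::isSingular(fit),
    engine = "reml",
    ranef = list(group = setNames(re[[group]][["(Intercept)"]],
                                  rownames(re[[group]])),
                 study = setNames(re[[".study_key"]][["(Intercept)"]],
                                  rownames(re[[".study_key"]]))),
    lme4_fit = fit,
    fitted = stats::fitted(fit), residuals = stats::resid(fit)))
  class(out) <- "methane_lmm"
  out
}

#' @export
print.methane_lmm <- function(x, ...) {
  cat("Nested-random-intercept methane model (", x$engine, ")\n", sep = "")
  cat("  ", deparse(x$formula), " + (1 | ", x$group, "/", x$study, ")\n",
      sep = "")
  cat(sprintf("  n = %d records, %d studies, %d groups\n",
              x$n_obs, x$n_studies, x$n_groups))
  cat("  fixed effects:\n")
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  cat(sprintf("  variance components: group %.3f, study %.3f, residual %.3f\n",
              x$var_group, x$var_study, x$var_resid))
  if (!x$converged) cat("  ** fit did not converge cleanly **\n")
  if (!x$identifiable) cat("  ** variance split not identifiable **\n")
  invisible(x)
}

#' @export
summary.methane_lmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.methane_lmm")
}

#' @export
print.summary.methane_lmm <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  tot <- f$var_group + f$var_study + f$var_resid
  if (tot > 0)
    cat(sprintf("  variance shares: group %.1f%%, study %.1f%%, residual %.1f%%\n",
                100 * f$var_group / tot, 100 * f$var_study / tot,
                100 * f$var_resid / tot))
  cat(sprintf("  REML criterion: %.2f; conditional SSE: %.2f\n",
              f$log_likelihood, f$sse_conditional))
  invisible(x)
}

#' @export
coef.methane_lmm <- function(object, ...) object$beta

#' @export
residuals.methane_lmm <- function(object, ...) object$residuals

#' @export
fitted.methane_lmm <- function(object, ...) object$fitted

#' @export
logLik.methane_lmm <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$beta) + 3L,
            class = "logLik")
}

#' Predict methane from a fitted model
#'
#' By default predicts with fixed effects only (`b0 + sum(b * x)`), so
#' random effects contribute zero — the new-study setting used in
#' leave-one-study-out evaluation. With `re = "group"` the fitted
#' research-group random intercept is added for groups present in the
#' training data (zero for unseen groups).
#'
#' @param object A `"methane_lmm"` fit.
#' @param newdata Data frame with the model's predictors (defaults to the
#'   fitted values' frame being unavailable, so `newdata` is required).
#' @param re Random-effect reuse: `"none"` (default) or `"group"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.methane_lmm <- function(object, newdata, re = c("none", "group"),
                                ...) {
  re <- match.arg(re)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols))
    stop("predict.methane_lmm: missing predictor(s): ",
         paste(missing_cols, collapse = ", "))
  for (p in object$predictors)
    if (anyNA(newdata[[p]]))
      stop("predict.methane_lmm: missing values in predictor '", p, "'")
  pred <- rep(unname(object$beta["(Intercept)"]), nrow(newdata))
  for (p in object$predictors)
    pred <- pred + unname(object$beta[p]) * newdata[[p]]
  if (re == "group" && !is.null(object$ranef)) {
    g <- as.character(newdata[[object$group]])
    b <- object$ranef$group[g]
    b[is.na(b)] <- 0
    pred <- pred + unname(b)
  }
  pred
}

#' Serialise a fit to JSON
#'
#' Writes the fixed coefficients, variance components and diagnostics of
#' a `"methane_lmm"` fit in a stable key order.
#'
#' @param fit A `"methane_lmm"` object.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_json <- function(fit, path = NULL) {
  obj <- list(
    formula = paste(deparse(fit$formula), collapse = " "),
    beta = as.list(fit$beta), se = as.list(fit$se),
    var_group = fit$var_group, var_study = fit$var_study,
    var_resid = fit$var_resid, n_obs = fit$n_obs,
    n_studies = fit$n_studies, n_groups = fit$n_groups,
    converged = fit$converged, boundary = fit$boundary,
    identifiable = fit$identifiable, engine = fit$engine,
    sse_conditional = fit$sse_conditional,
    log_likelihood = fit$log_likelihood)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
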