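# Population (denominator-n) standard deviation: the convention used
# throughout the error decomposition and CCC so that
# MSPE = MB + SB + (1 - r^2) * So^2 holds exactly.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Prediction-evaluation metric suite
#'
#' Computes the full agreement report between observed and predicted
#' values: mean square prediction error `MSPE = mean((Y - Yhat)^2)` and
#' its root (RMSPE, also as a percentage of the observed mean); mean
#' absolute error; `RSR = RMSPE / So` (error relative to the observed
#' spread); the decomposition of MSPE into mean bias `MB = (Pbar - Obar)^2`,
#' slope bias `SB = (Sp - r * So)^2` and random error `(1 - r^2) * So^2`;
#' and Lin's concordance correlation coefficient `CCC = r * Cb` with
#' `Cb = ((v + 1/v + u^2) / 2)^-1`, `v = So/Sp`,
#' `u = (Pbar - Obar) / sqrt(So * Sp)`. Standard deviations are population
#' (denominator n) so the decomposition identity is exact.
#'
#' When either vector is constant, `r`, `ccc`, `cb`, `v_scale`, `u_shift`
#' and (for constant observations) `rsr` are undefined: they are reported
#' as `NA` and named in the report's `undefined` field; the remaining
#' metrics are still computed.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2,
#'   finite).
#' @return An object of class `"metric_report"`: a list with fields `n`,
#'   `obs_mean`, `pred_mean`, `so`, `sp`, `r`, `mspe`, `rmspe`,
#'   `rmspe_pct`, `mae`, `rsr`, `mb`, `sb`, `random_error`, `mb_pct`,
#'   `sb_pct`, `ccc`, `cb`, `v_scale`, `u_shift`, `undefined`.
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(1.5, 2, 2.5))
#' @export
evaluate_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("evaluate_predictions: vectors must have equal length")
  if (length(observed) < 2L)
    stop("evaluate_predictions: need at least two observations")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("evaluate_predictions: values must be finite and non-missing")

  n <- length(observed)
  obar <- mean(observed)
  pbar <- mean(predicted)
  so <- sd_pop(observed)
  sp <- sd_pop(predicted)
  undefined <- character(0)

  mspe <- mean((observed - predicted)^2)
  rmspe <- sqrt(mspe)
  mae <- mean(abs(observed - predicted))
  mb <- (pbar - obar)^2

  if (so == 0 || sp == 0) {
    r <- NA_real_
    undefined <- c(undefined, "r")
  } else {
    r <- mean((observed - obar) * (predicted - pbar)) / (so * sp)
  }

  # with a constant vector the slope-bias split is taken at r = 0 so the
  # decomposition identity still closes: sb = sp^2, random = so^2
  sb <- if (is.na(r)) sp^2 else (sp - r * so)^2
  random_error <- mspe - mb - sb

  rsr <- if (so == 0) { undefined <- c(undefined, "rsr"); NA_real_ }
  else rmspe / so
  rmspe_pct <- if (obar == 0) { undefined <- c(undefined, "rmspe_pct"); NA_real_ }
  else 100 * rmspe / obar

  if (is.na(r)) {
    v <- u <- cb <- ccc <- NA_real_
    undefined <- c(undefined, "v_scale", "u_shift", "cb", "ccc")
  } else {
    v <- so / sp
    u <- (pbar - obar) / sqrt(so * sp)
    cb <- ((v + 1 / v + u^2) / 2)^-1
    ccc <- r * cb
  }

  if (mspe == 0) {
    mb_pct <- 0
    sb_pct <- 0
  } else {
    mb_pct <- 100 * mb / mspe
    sb_pct <- 100 * sb / mspe
  }

  structure(list(n = n, obs_mean = obar, pred_mean = pbar, so = so, sp = sp,
                 r = r, mspe = mspe, rmspe = rmspe, rmspe_pct = rmspe_pct,
                 mae = mae, rsr = rsr, mb = mb, sb = sb,
                 random_error = random_error, mb_pct = mb_pct,
                 sb_pct = sb_pct, ccc = ccc, cb = cb, v_scale = v,
                 u_shift = u, undefined = undefined),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(round(v, digits))
  cat(sprintf("Model evaluation (n = %d)\n", x$n))
  cat(sprintf("  observed mean %s, predicted mean %s\n",
              fmt(x$obs_mean), fmt(x$pred_mean)))
  cat(sprintf("  RMSPE %s (%s%% of observed mean), MAE %s, RSR %s\n",
              fmt(x$rmspe), fmt(x$rmspe_pct), fmt(x$mae), fmt(x$rsr)))
  cat(sprintf("  MSPE %s = MB %s (%s%%) + SB %s (%s%%) + random %s\n",
              fmt(x$mspe), fmt(x$mb), fmt(x$mb_pct), fmt(x$sb),
              fmt(x$sb_pct), fmt(x$random_error)))
  cat(sprintf("  r %s, Cb %s, CCC %s\n", fmt(x$r), fmt(x$cb), fmt(x$ccc)))
  invisible(x)
}

#' RMSPE as a percentage of the observed mean
#'
#' @param report A `"metric_report"`.
#' @return `100 * rmspe / obs_mean`, or `NA` when the observed mean is 0.
#' @export
rmspe_pct <- function(report) report$rmspe_pct

#' Mean- and slope-bias shares of MSPE
#'
#' @param report A `"metric_report"`.
#' @return Named vector `c(mb_pct, sb_pct)` in percent of MSPE; both zero
#'   by convention when MSPE is zero.
#' @export
decomposition_pct <- function(report) {
  c(mb_pct = report$mb_pct, sb_pct = report$sb_pct)
}

#' Serialise a metric report to JSON
#'
#' @param report A `"metric_report"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
metrics_json <- function(report, path = NULL) {
  obj <- unclass(report)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Observed-versus-predicted scatter plot
#'
#' Plots pooled cross-validation (or any) predictions against
#' observations with the identity line and the least-squares line of
#' predicted on observed, the standard visual check for mean and slope
#' bias.
#'
#' @param observed,predicted Numeric vectors.
#' @param xlab,ylab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `lm` fit of predicted on observed.
#' @export
plot_obs_pred <- function(observed, predicted,
                          xlab = "Observed", ylab = "Predicted",
                          main = "Observed vs predicted", ...) {
  graphics::plot(observed, predicted, xlab = xlab, ylab = ylab,
                 main = main, ...)
  graphics::abline(0, 1, lty = 2)
  fit <- stats::lm(predicted ~ observed)
  graphics::abline(fit, col = "red")
  invisible(fit)
}
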