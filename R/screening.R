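#' Tukey-style interquartile-range fences
#'
#' Quartiles are computed by linear interpolation between order statistics
#' at position `p * (n - 1)` (0-based; `stats::quantile` type 7), then
#' `lower = Q1 - k * IQR`, `upper = Q3 + k * IQR`.
#'
#' @param values Numeric vector, non-empty and finite.
#' @param k Fence multiplier; 1.5 flags extremes.
#' @return An object of class `"iqr_fences"`: list with `q1`, `q3`, `iqr`,
#'   `lower`, `upper`, `k`, `n`.
#' @examples
#' iqr_fences(c(10, 12, 14, 16, 18, 20, 22, 24))
#' @export
iqr_fences <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("iqr_fences: 'values' must be non-empty")
  if (any(!is.finite(values)))
    stop("iqr_fences: 'values' must be finite")
  q <- unname(stats::quantile(values, probs = c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = q[1] - k * iqr, upper = q[2] + k * iqr,
                 k = k, n = length(values)),
            class = "iqr_fences")
}

#' @export
print.iqr_fences <- function(x, ...) {
  cat(sprintf("IQR fences (k = %g, n = %d): Q1 = %g, Q3 = %g, IQR = %g\n",
              x$k, x$n, x$q1, x$q3, x$iqr))
  cat(sprintf("  lower = %g, upper = %g\n", x$lower, x$upper))
  invisible(x)
}

#' Region-wise IQR outlier screen on CH4 yield and intensity
#'
#' For each region, fences are computed separately for CH4 yield (g/kg
#' DMI) and CH4 intensity (g/kg ECM); a record is flagged when either
#' ratio falls strictly outside its fences (`rule = "union"`, the
#' default), or when it is flagged by a yield screen followed by an
#' intensity screen whose fences are recomputed on the yield-screened
#' survivors (`rule = "sequential"`). The screen is single-pass: fences
#' are not recomputed after removal. Regions contributing fewer than
#' `min_region_n` records are left unscreened with a warning.
#'
#' @param data Cow record data frame with `region` and the fields needed
#'   by [derive_ratios()].
#' @param k Fence multiplier passed to [iqr_fences()].
#' @param rule Combination rule for the two ratios.
#' @param min_region_n Minimum records per region for screening.
#' @return A list with `kept` (the unflagged records) and `report`, an
#'   object of class `"screen_report"` holding counts, per-region fences
#'   and the flagged record ids with reasons.
#' @export
screen_outliers <- function(data, k = 1.5, rule = c("union", "sequential"),
                            min_region_n = 4L) {
  rule <- match.arg(rule)
  ratios <- derive_ratios(data)
  flagged <- rep(FALSE, nrow(data))
  reason <- rep(NA_character_, nrow(data))
  fences <- list()
  outside <- function(x, f) !is.na(x) & (x < f$lower | x > f$upper)
  for (reg in unique(data$region)) {
    in_reg <- !is.na(data$region) & data$region == reg
    if (sum(in_reg) < min_region_n) {
      warning(sprintf("region '%s' has %d record(s) (< %d): not screened",
                      reg, sum(in_reg), min_region_n))
      next
    }
    fy <- iqr_fences(ratios$ch4_yield[in_reg], k = k)
    out_y <- in_reg & outside(ratios$ch4_yield, fy)
    if (rule == "union") {
      fi <- iqr_fences(ratios$ch4_intensity[in_reg], k = k)
      out_i <- in_reg & outside(ratios$ch4_intensity, fi)
    } else {
      keep_i <- in_reg & !out_y
      fi <- iqr_fences(ratios$ch4_intensity[keep_i], k = k)
      out_i <- keep_i & outside(ratios$ch4_intensity, fi)
    }
    fences[[reg]] <- list(yield = fy, intensity = fi)
    reason[out_y & !flagged] <- "yield"
    reason[out_i & !flagged & !out_y] <- "intensity"
    reason[out_y & out_i] <- "yield+intensity"
    flagged <- flagged | out_y | out_i
  }
  report <- structure(list(
    n_input = nrow(data), n_kept = sum(!flagged), n_flagged = sum(flagged),
    k = k, rule = rule, fences = fences,
    flagged = data.frame(record_id = data$record_id[flagged],
                         region = data$region[flagged],
                         reason = reason[flagged],
                         stringsAsFactors = FALSE)),
    class = "screen_report")
  list(kept = data[!flagged, , drop = FALSE], report = report)
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("IQR outlier screen (k = %g, rule = %s)\n", x$k, x$rule))
  cat(sprintf("  input %d, kept %d, flagged %d\n",
              x$n_input, x$n_kept, x$n_flagged))
  for (reg in names(x$fences)) {
    f <- x$fences[[reg]]
    cat(sprintf("  %s: yield fences (%.3f, %.3f), intensity fences (%.3f, %.3f)\n",
                reg, f$yield$lower, f$yield$upper,
                f$intensity$lower, f$intensity$upper))
  }
  invisible(x)
}

#' Serialise a screen report to JSON
#'
#' @param report A `"screen_report"` object.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to file.
#' @export
screen_report_json <- function(report, path = NULL) {
  strip <- function(f) f[c("q1", "q3", "iqr", "lower", "upper", "k", "n")]
  obj <- list(n_input = report$n_input, n_kept = report$n_kept,
              n_flagged = report$n_flagged, k = report$k, rule = report$rule,
              fences = lapply(report$fences, function(f)
                list(yield = strip(f$yield), intensity = strip(f$intensity))),
              flagged = report$flagged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Complete-case filter
#'
#' Keeps records with all `required` fields present, preserving order. The
#' default required set is the refined complete set used for variable
#' selection: CH4 plus every candidate predictor.
#'
#' @param data Cow record data frame.
#' @param required Character vector of field names that must be non-missing.
#' @return The filtered data frame.
#' @export
complete_records <- function(data, required = COMPLETE_SET_FIELDS) {
  if (length(required) == 0L)
    stop("complete_records: 'required' must be non-empty")
  unknown <- setdiff(required, names(data))
  if (length(unknown))
    stop("complete_records: unknown field(s): ",
         paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(data))
  for (f in required) keep <- keep & !is.na(data[[f]])
  data[keep, , drop = FALSE]
}

#' Measurement-method whitelist
#'
#' Retains records measured with respiration chambers, the GreenFeed
#' system, or the SF6 tracer technique; drops method `"other"`. Records
#' with a missing method are kept.
#'
#' @param data Cow record data frame.
#' @return The filtered data frame.
#' @export
method_filter <- function(data) {
  drop <- !is.na(data$ch4_method) & data$ch4_method == "other"
  data[!drop, , drop = FALSE]
}
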