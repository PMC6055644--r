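#' BIC from an error sum of squares
#'
#' `BIC = n * log(SSE/n) + log(n) * p` (natural logarithms), where `p`
#' counts the regression coefficients including the intercept. Smaller is
#' better: the score balances goodness of fit against model complexity.
#'
#' @param sse Error sum of squares (> 0).
#' @param n Sample size.
#' @param p Number of regression coefficients (intercept + slopes).
#' @return The BIC score.
#' @examples
#' bic_score(100, 100, 2)  # 2 * log(100)
#' @export
bic_score <- function(sse, n, p) {
  if (any(sse <= 0)) stop("bic_score: 'sse' must be positive")
  if (any(n <= 0) || any(p < 1)) stop("bic_score: need n > 0 and p >= 1")
  n * log(sse / n) + log(n) * p
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from regressing predictor `j`
#' on the remaining predictors (with intercept). Exactly collinear
#' predictors are reported as `Inf`, not raised as errors.
#'
#' @param data Data frame containing the predictors, complete cases.
#' @param predictors Character vector of at least two column names.
#' @return Named numeric vector of VIFs.
#' @export
vif_scores <- function(data, predictors) {
  if (length(predictors) < 2L)
    stop("vif_scores: need at least two predictors")
  if (nrow(data) <= length(predictors) + 1L)
    stop("vif_scores: need n > number of predictors + 1")
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (anyNA(X)) stop("vif_scores: missing values in predictors")
  out <- setNames(numeric(length(predictors)), predictors)
  for (j in seq_along(predictors)) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    tss <- sum((y - mean(y))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    out[j] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Iterative VIF collinearity pruning
#'
#' Repeatedly computes VIFs and removes the single predictor with the
#' largest VIF while it exceeds `threshold`, one at a time (so VIFs are
#' recomputed after each removal). Ties are broken by position in the
#' original candidate list: the earlier-listed predictor is retained.
#'
#' @param data Data frame with the predictors, complete cases.
#' @param predictors Candidate predictor names.
#' @param threshold VIF value above which a predictor is flagged; 5 by
#'   default.
#' @return A list with `retained` (surviving predictors, original order)
#'   and `removed` (data frame of `predictor`, `vif` at removal, in
#'   removal order).
#' @export
prune_collinear <- function(data, predictors, threshold = 5) {
  retained <- predictors
  removed <- data.frame(predictor = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  while (length(retained) >= 2L) {
    v <- vif_scores(data, retained)
    if (max(v) <= threshold) break
    # largest VIF; on ties drop the latest-listed involved predictor
    worst_val <- max(v)
    worst <- retained[v == worst_val]
    drop <- worst[length(worst)]
    removed <- rbind(removed,
                     data.frame(predictor = drop, vif = worst_val,
                                stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, removed = removed)
}

subset_sse_ols <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' All-subsets model search scored by BIC
#'
#' Fits every non-empty subset of the candidate predictors and ranks the
#' subsets by [bic_score()]. With the default `engine = "lmm"` each
#' subset is fitted with [methane_lmm()] and the BIC uses the conditional
#' residual sum of squares, so study- and group-level noise is absorbed
#' by the random intercepts instead of being attributed to chance
#' fixed-effect correlations; this matches how the multi-study equations
#' are developed. `engine = "ols"` scores each subset by an
#' ordinary-least-squares fit (fixed effects only) — much faster, but on
#' strongly clustered data the within-study correlation can buy spurious
#' predictors past the BIC penalty. A model with a smaller BIC is
#' preferred. Optionally VIF-prunes the candidate list first
#' (`vif_prune = TRUE`).
#'
#' @param data Complete-case data frame.
#' @param candidates Candidate predictor names (at most 12).
#' @param response Response column name.
#' @param engine `"lmm"` (default) or `"ols"`.
#' @param vif_prune Prune collinear candidates before the search?
#' @param vif_threshold Threshold passed to [prune_collinear()].
#' @param group,study Grouping columns, used when `engine = "lmm"`.
#' @return An object of class `"ch4_selection"`: list with `candidates`
#'   (data frame of `subset` label, `size`, `sse`, `bic`, ranked best
#'   first), `best` (character vector of predictors in the best subset),
#'   `removed_collinear`, `n`, `engine`.
#' @export
all_subsets <- function(data, candidates, response, engine = c("lmm", "ols"),
                        vif_prune = FALSE, vif_threshold = 5,
                        group = "group_id", study = "study_id") {
  engine <- match.arg(engine)
  if (length(candidates) > 12L)
    stop("all_subsets: more than 12 candidates (", length(candidates),
         "); prune the list first")
  cols <- c(response, candidates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("all_subsets: column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(data[, cols]))
    stop("all_subsets: missing values; run complete_records() first")

  removed <- data.frame(predictor = character(), vif = numeric())
  if (vif_prune && length(candidates) >= 2L) {
    pr <- prune_collinear(data, candidates, threshold = vif_threshold)
    candidates <- pr$retained
    removed <- pr$removed
  }

  n <- nrow(data)
  y <- data[[response]]
  Xall <- as.matrix(data[, candidates, drop = FALSE])
  k <- length(candidates)
  subsets <- vector("list", 2^k - 1)
  sse <- numeric(2^k - 1)
  idx <- 0L
  for (size in seq_len(k)) {
    for (combo in utils::combn(k, size, simplify = FALSE)) {
      idx <- idx + 1L
      subsets[[idx]] <- candidates[combo]
      if (engine == "ols") {
        sse[idx] <- subset_sse_ols(y, cbind(1, Xall[, combo, drop = FALSE]))
      } else {
        # subset fits are scored by SSE only; optimizer grumbles on
        # non-best subsets are not informative here
        fit <- suppressWarnings(
          methane_lmm(stats::reformulate(candidates[combo], response),
                      data, group = group, study = study))
        sse[idx] <- fit$sse_conditional
      }
    }
  }
  size <- lengths(subsets)
  bic <- bic_score(pmax(sse, .Machine$double.xmin), n, size + 1L)
  ord <- order(bic)
  result <- structure(list(
    candidates = data.frame(
      subset = vapply(subsets, paste, "", collapse = "+")[ord],
      size = size[ord], sse = sse[ord], bic = bic[ord],
      stringsAsFactors = FALSE),
    best = subsets[[ord[1]]],
    removed_collinear = removed,
    n = n, engine = engine, response = response),
    class = "ch4_selection")
  result
}

#' @export
print.ch4_selection <- function(x, ...) {
  cat(sprintf("All-subsets BIC selection (%s engine, n = %d, response %s)\n",
              x$engine, x$n, x$response))
  if (nrow(x$removed_collinear))
    cat("  removed for collinearity:",
        paste(sprintf("%s (VIF %.1f)", x$removed_collinear$predictor,
                      x$removed_collinear$vif), collapse = ", "), "\n")
  cat("  best subset: {", paste(x$best, collapse = ", "), "}\n")
  top <- utils::head(x$candidates, 5)
  cat("  top candidates:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Serialise a selection result to JSON
#'
#' @param sel A `"ch4_selection"` object.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
selection_json <- function(sel, path = NULL) {
  obj <- list(engine = sel$engine, n = sel$n, response = sel$response,
              best = sel$best, removed_collinear = sel$removed_collinear,
              candidates = sel$candidates)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
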