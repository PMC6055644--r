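# Registry of published CH4 prediction equations (responses: production in
# g/day, yield in g/kg DMI, intensity in g/kg ECM). Coefficients and
# standard errors are stored exactly at printed precision; the registry is
# a transcription layer, nothing is re-derived.

EQ_RESPONSES <- c("production_g_d", "yield_g_kgDMI", "intensity_g_kgECM")
EQ_SCOPES <- c("intercontinental", "EU", "US")
EQ_PREDICTORS <- c("dmi", "gei", "cp", "ee", "ndf", "ash", "my", "ecm",
                   "mf", "mp", "bw")

# Tie-break preference among equally sized candidate equations: animal-level
# models first, then intake-based, then milk-based, then diet-only.
CATEGORY_PREFERENCE <- c(
  "Animal_C", "DMI+Com_C", "DMI+NDF_C", "DMI+EE_C", "DMI_C", "GEI_C",
  "ECM+Com_C", "ECM_C", "MY_C", "Diet_Com_C", "Animal_no_DMI_C",
  "DMI+Com_Comp_C", "Milk_Com_C", "NDF_C", "EE_C", "IPCC_2006", "IPCC_1997")

new_equation <- function(eq_id, response, category, scope, intercept,
                         intercept_se, terms, energy_transform = FALSE,
                         source = "") {
  stopifnot(response %in% EQ_RESPONSES, scope %in% EQ_SCOPES)
  if (length(terms)) {
    preds <- vapply(terms, `[[`, "", "predictor")
    if (anyDuplicated(preds))
      stop("equation '", eq_id, "': duplicate predictor in terms")
    if (!all(preds %in% EQ_PREDICTORS))
      stop("equation '", eq_id, "': unknown predictor(s): ",
           paste(setdiff(preds, EQ_PREDICTORS), collapse = ", "))
    terms <- data.frame(
      predictor = preds,
      coef = vapply(terms, function(t) as.numeric(t$coef), 0),
      se = vapply(terms, function(t)
        if (is.null(t$se)) NA_real_ else as.numeric(t$se), 0),
      stringsAsFactors = FALSE)
  } else {
    terms <- data.frame(predictor = character(), coef = numeric(),
                        se = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(eq_id = eq_id, response = response, category = category,
                 scope = scope, intercept = intercept,
                 intercept_se = intercept_se, terms = terms,
                 energy_transform = isTRUE(energy_transform),
                 source = source),
            class = "ch4_equation")
}

#' @export
print.ch4_equation <- function(x, ...) {
  rhs <- if (nrow(x$terms))
    paste(sprintf("%+g x %s", x$terms$coef, toupper(x$terms$predictor)),
          collapse = " ")
  else ""
  body <- trimws(paste(format(x$intercept), rhs))
  if (x$energy_transform) body <- sprintf("[%s]/%.5f", body, 0.05565)
  cat(sprintf("<%s> %s (%s, %s)\n  %s\n", x$eq_id, x$category, x$scope,
              x$response, body))
  invisible(x)
}

tm <- function(predictor, coef, se) list(predictor = predictor, coef = coef,
                                         se = se)

build_bundled_registry <- function() {
  P <- "production_g_d"; Y <- "yield_g_kgDMI"; I <- "intensity_g_kgECM"
  IC <- "intercontinental"
  e <- list(
    # --- production, intercontinental ---
    new_equation("eq01", P, "GEI_C", IC, 7.13, 0.581,
                 list(tm("gei", 0.0391, 0.00095)), energy_transform = TRUE),
    new_equation("eq02", P, "DMI_C", IC, 124, 10.44,
                 list(tm("dmi", 13.3, 0.32))),
    new_equation("eq03", P, "DMI+NDF_C", IC, 33.2, 13.54,
                 list(tm("dmi", 13.6, 0.33), tm("ndf", 2.43, 0.245))),
    new_equation("eq04", P, "DMI+EE_C", IC, 163, 12.9,
                 list(tm("dmi", 13.3, 0.35), tm("ee", -11.0, 1.39))),
    new_equation("eq05", P, "DMI+Com_C", IC, 76.0, 16.14,
                 list(tm("dmi", 13.5, 0.35), tm("ee", -9.55, 1.390),
                      tm("ndf", 2.24, 0.268))),
    new_equation("eq06", P, "Diet_Com_C", IC, 369, 21.9,
                 list(tm("ee", -14.7, 1.73), tm("ndf", 1.67, 0.339))),
    new_equation("eq07", P, "MY_C", IC, 299, 12.1,
                 list(tm("my", 2.73, 0.171))),
    new_equation("eq08", P, "ECM_C", IC, 259, 11.1,
                 list(tm("ecm", 3.86, 0.167))),
    new_equation("eq09", P, "ECM+Com_C", IC, 150, 16.1,
                 list(tm("ecm", 4.31, 0.172), tm("mp", 28.3, 3.20))),
    new_equation("eq10", P, "Animal_C", IC, -60.5, 17.56,
                 list(tm("dmi", 12.4, 0.37), tm("ee", -8.78, 1.342),
                      tm("ndf", 2.10, 0.256), tm("mf", 16.1, 1.39),
                      tm("bw", 0.148, 0.0143))),
    new_equation("eq11", P, "Animal_no_DMI_C", IC, -37.0, 22.94,
                 list(tm("ee", -12.3, 1.49), tm("ndf", 2.24, 0.289),
                      tm("ecm", 3.68, 0.191), tm("mf", 7.81, 1.762),
                      tm("mp", 17.7, 3.78), tm("bw", 0.284, 0.0148))),
    new_equation("eq12", P, "IPCC_2006", IC, 0, NA_real_,
                 list(tm("gei", 0.065, NA_real_)), energy_transform = TRUE,
                 source = "IPCC Tier 2, 2006 guidelines (Ym = 6.5%)"),
    new_equation("eq13", P, "IPCC_1997", IC, 0, NA_real_,
                 list(tm("gei", 0.060, NA_real_)), energy_transform = TRUE,
                 source = "IPCC Tier 2, 1997 guidelines (Ym = 6.0%)"),
    # --- production, EU ---
    new_equation("eq14", P, "GEI_C", "EU", 6.20, 0.688,
                 list(tm("gei", 0.0425, 0.00118)), energy_transform = TRUE),
    new_equation("eq15", P, "DMI_C", "EU", 107, 12.6,
                 list(tm("dmi", 14.5, 0.39))),
    new_equation("eq16", P, "DMI+NDF_C", "EU", -26.0, 16.67,
                 list(tm("dmi", 15.3, 0.41), tm("ndf", 3.42, 0.309))),
    new_equation("eq17", P, "DMI+EE_C", "EU", 160, 14.7,
                 list(tm("dmi", 14.2, 0.44), tm("ee", -13.5, 1.46))),
    new_equation("eq18", P, "DMI+Com_C", "EU", 11.3, 22.62,
                 list(tm("dmi", 14.7, 0.44), tm("cp", 2.50, 0.670),
                      tm("ee", -10.8, 1.49), tm("ndf", 3.20, 0.361),
                      tm("ash", -2.87, 1.134))),
    new_equation("eq19", P, "Diet_Com_C", "EU", 435, 17.4,
                 list(tm("ee", -18.7, 1.92))),
    new_equation("eq20", P, "MY_C", "EU", 287, 14.1,
                 list(tm("my", 3.16, 0.224))),
    new_equation("eq21", P, "ECM_C", "EU", 247, 13.1,
                 list(tm("ecm", 4.30, 0.215))),
    new_equation("eq22", P, "ECM+Com_C", "EU", 141, 18.9,
                 list(tm("ecm", 4.75, 0.220), tm("mp", 27.4, 3.70))),
    new_equation("eq23", P, "Animal_C", "EU", -52.2, 21.73,
                 list(tm("dmi", 13.0, 0.49), tm("ee", -10.9, 1.50),
                      tm("ndf", 2.80, 0.349), tm("mf", 7.26, 1.590),
                      tm("bw", 0.154, 0.0167))),
    new_equation("eq24", P, "Animal_no_DMI_C", "EU", -44.7, 27.14,
                 list(tm("ee", -15.3, 1.63), tm("ndf", 2.62, 0.391),
                      tm("ecm", 4.34, 0.242), tm("mp", 21.5, 3.83),
                      tm("bw", 0.289, 0.0168))),
    # --- production, US ---
    new_equation("eq25", P, "GEI_C", "US", 7.30, 1.217,
                 list(tm("gei", 0.0358, 0.00163)), energy_transform = TRUE),
    new_equation("eq26", P, "DMI_C", "US", 125, 20.5,
                 list(tm("dmi", 12.2, 0.55))),
    new_equation("eq27", P, "DMI+NDF_C", "US", 49.5, 27.78,
                 list(tm("dmi", 12.1, 0.56), tm("ndf", 2.57, 0.450))),
    new_equation("eq28", P, "DMI+EE_C", "US", 136, 27.1,
                 list(tm("dmi", 12.3, 0.57), tm("ee", -2.96, 2.876))),
    # eq29 duplicates eq27 verbatim as printed; both ids retained.
    new_equation("eq29", P, "DMI+Com_C", "US", 49.5, 27.78,
                 list(tm("dmi", 12.1, 0.56), tm("ndf", 2.57, 0.450)),
                 source = "identical to eq27 as printed"),
    new_equation("eq30", P, "Diet_Com_C", "US", 279, 51.1,
                 list(tm("ndf", 3.53, 0.531))),
    new_equation("eq31", P, "MY_C", "US", 314, 33.4,
                 list(tm("my", 2.27, 0.278))),
    new_equation("eq32", P, "ECM_C", "US", 270, 28.9,
                 list(tm("ecm", 3.44, 0.278))),
    new_equation("eq33", P, "ECM+Com_C", "US", 157, 37.1,
                 list(tm("ecm", 3.53, 0.295), tm("mf", 16.1, 3.22),
                      tm("mp", 15.3, 6.83))),
    new_equation("eq34", P, "Animal_C", "US", -126, 32.7,
                 list(tm("dmi", 11.3, 0.59), tm("ndf", 2.30, 0.414),
                      tm("mf", 28.8, 2.53), tm("bw", 0.148, 0.0250))),
    new_equation("eq35", P, "Animal_no_DMI_C", "US", -72.4, 42.41,
                 list(tm("ndf", 3.15, 0.461), tm("ecm", 2.65, 0.270),
                      tm("mf", 23.9, 2.79), tm("bw", 0.290, 0.0257))),
    # --- yield (g/kg DMI), intercontinental ---
    new_equation("eq36", Y, "NDF_C", IC, 13.8, 0.63,
                 list(tm("ndf", 0.185, 0.0133))),
    new_equation("eq37", Y, "EE_C", IC, 21.8, 0.62,
                 list(tm("ee", -0.452, 0.0763))),
    new_equation("eq38", Y, "Diet_Com_C", IC, 15.4, 0.76,
                 list(tm("ee", -0.354, 0.0756), tm("ndf", 0.173, 0.0145))),
    new_equation("eq39", Y, "MY_C", IC, 23.5, 0.53,
                 list(tm("my", -0.123, 0.0076))),
    new_equation("eq40", Y, "ECM_C", IC, 22.6, 0.55,
                 list(tm("ecm", -0.082, 0.0079))),
    new_equation("eq41", Y, "ECM+Com_C", IC, 21.1, 0.77,
                 list(tm("ecm", -0.105, 0.0081), tm("mf", 1.30, 0.077),
                      tm("mp", -0.952, 0.1667))),
    new_equation("eq42", Y, "Animal_no_DMI_C", IC, 15.4, 1.08,
                 list(tm("ee", -0.291, 0.0733), tm("ndf", 0.144, 0.0141),
                      tm("ecm", -0.104, 0.0094), tm("mf", 1.34, 0.087),
                      tm("mp", -1.12, 0.187), tm("bw", 0.00330, 0.000729))),
    # --- intensity (g/kg ECM), intercontinental ---
    new_equation("eq43", I, "GEI_C", IC, 15.5, 0.45,
                 list(tm("gei", -0.00629, 0.000962))),
    new_equation("eq44", I, "DMI_C", IC, 15.5, 0.46,
                 list(tm("dmi", -0.116, 0.0179))),
    new_equation("eq45", I, "DMI+NDF_C", IC, 11.3, 0.73,
                 list(tm("dmi", -0.103, 0.0190), tm("ndf", 0.118, 0.0141))),
    new_equation("eq46", I, "DMI+EE_C", IC, 17.7, 0.61,
                 list(tm("dmi", -0.142, 0.0207), tm("ee", -0.462, 0.0820))),
    new_equation("eq47", I, "DMI+Com_C", IC, 13.2, 0.86,
                 list(tm("dmi", -0.127, 0.0207), tm("ee", -0.393, 0.0823),
                      tm("ndf", 0.114, 0.0156))),
    new_equation("eq48", I, "DMI+Com_Comp_C", IC, 10.5, 0.71,
                 list(tm("ee", -0.364, 0.0825), tm("ndf", 0.120, 0.0156))),
    new_equation("eq49", I, "ECM+Com_C", IC, 3.72, 0.602,
                 list(tm("mp", 2.87, 0.147))),
    new_equation("eq50", I, "Animal_C", IC, -0.101, 1.0980,
                 list(tm("dmi", -0.215, 0.0213), tm("cp", -0.118, 0.0301),
                      tm("ee", -0.323, 0.0760), tm("ndf", 0.120, 0.0142),
                      tm("mf", -0.253, 0.0901), tm("mp", 3.44, 0.183),
                      tm("bw", 0.00947, 0.000836))),
    new_equation("eq51", I, "Animal_no_DMI_C", IC, -2.85, 1.112,
                 list(tm("cp", -0.118, 0.0307), tm("ee", -0.289, 0.0784),
                      tm("ndf", 0.124, 0.0146), tm("mp", 3.32, 0.168),
                      tm("bw", 0.00605, 0.000762))))
  names(e) <- vapply(e, `[[`, "", "eq_id")
  structure(e, class = "ch4_registry")
}

# built once at load time
the_registry <- new.env(parent = emptyenv())

#' Bundled registry of published prediction equations
#'
#' Returns the full set of main-text CH4 production, yield and intensity
#' prediction equations (intercontinental, EU and US scopes) plus the two
#' IPCC Tier 2 comparator rows, with coefficients and standard errors at
#' printed precision.
#'
#' @return An object of class `"ch4_registry"`: a named list of
#'   `"ch4_equation"` objects keyed by equation id (`"eq01"` ... `"eq51"`).
#' @export
bundled_registry <- function() {
  if (is.null(the_registry$bundled))
    the_registry$bundled <- build_bundled_registry()
  the_registry$bundled
}

#' @export
print.ch4_registry <- function(x, ...) {
  cat(sprintf("CH4 equation registry: %d equations\n", length(x)))
  tab <- table(vapply(x, `[[`, "", "response"),
               vapply(x, `[[`, "", "scope"))
  print(tab)
  invisible(x)
}

#' Filter a registry by response and scope
#'
#' @param registry A `"ch4_registry"`.
#' @param response Optional response filter (see `EquationSpec` responses).
#' @param scope Optional scope filter.
#' @param include_ipcc Keep the IPCC comparator rows? Default `TRUE`.
#' @return The filtered `"ch4_registry"`.
#' @export
filter_registry <- function(registry, response = NULL, scope = NULL,
                            include_ipcc = TRUE) {
  keep <- rep(TRUE, length(registry))
  if (!is.null(response))
    keep <- keep & vapply(registry, `[[`, "", "response") == response
  if (!is.null(scope))
    keep <- keep & vapply(registry, `[[`, "", "scope") == scope
  if (!include_ipcc)
    keep <- keep & !grepl("^IPCC", vapply(registry, `[[`, "", "category"))
  structure(registry[keep], class = "ch4_registry")
}

#' Predict from a published equation
#'
#' Evaluates the linear combination `intercept + sum(coef * predictor)` on
#' each row of `newdata`; equations on the gross-energy scale (the GEI
#' category and IPCC rows) are divided by the methane energy density
#' 0.05565 MJ/g. The `ecm` predictor is computed on the fly from `my`,
#' `mf`, `mp` when not supplied as a column.
#'
#' @param object A `"ch4_equation"`.
#' @param newdata Data frame with the equation's predictors as columns.
#' @param ... Unused.
#' @return Numeric vector of predictions in the equation's response units.
#' @export
predict.ch4_equation <- function(object, newdata, ...) {
  needed <- object$terms$predictor
  data <- newdata
  if ("ecm" %in% needed && !("ecm" %in% names(data))) {
    if (all(c("my", "mf", "mp") %in% names(data)))
      data$ecm <- compute_ecm(data$my, data$mf, data$mp)
  }
  missing <- setdiff(needed, names(data))
  if (length(missing))
    stop("equation '", object$eq_id, "' needs missing predictor(s): ",
         paste(missing, collapse = ", "))
  incomplete <- needed[vapply(needed, function(p) anyNA(data[[p]]), TRUE)]
  if (length(incomplete))
    stop("equation '", object$eq_id, "' has missing values in: ",
         paste(incomplete, collapse = ", "))
  pred <- rep(object$intercept, nrow(data))
  for (i in seq_len(nrow(object$terms)))
    pred <- pred + object$terms$coef[i] * data[[object$terms$predictor[i]]]
  if (object$energy_transform) pred <- pred / CH4_ENERGY_MJ_PER_G
  pred
}

#' IPCC Tier 2 enteric methane prediction
#'
#' Inventory-style prediction from gross energy intake with a fixed
#' methane conversion factor: `CH4 (g/day) = (ym_fraction * gei) / 0.05565`.
#' The 2006 guidelines use `ym_fraction = 0.065`, the 1997 guidelines
#' `0.060`.
#'
#' @param gei Gross energy intake, MJ/day (non-negative).
#' @param ym_fraction Methane conversion factor as a fraction of GEI;
#'   must lie in (0, 0.15).
#' @return CH4 production, g/day.
#' @examples
#' ipcc_tier2(347, 0.060)
#' @export
ipcc_tier2 <- function(gei, ym_fraction = 0.065) {
  if (any(!is.na(gei) & gei < 0))
    stop("ipcc_tier2: 'gei' must be non-negative")
  if (ym_fraction <= 0 || ym_fraction >= 0.15)
    stop("ipcc_tier2: 'ym_fraction' outside plausible range (0, 0.15)")
  (ym_fraction * gei) / CH4_ENERGY_MJ_PER_G
}

#' Read and write equation registries as JSON
#'
#' The JSON schema is a list of objects with keys `eq_id`, `response`,
#' `category`, `scope`, `intercept`, `intercept_se`, `terms` (list of
#' `{predictor, coef, se}`), `energy_transform`, `source`. This lets users
#' supply equations not bundled with the package (for example regional
#' yield and intensity equations).
#'
#' @param path JSON file path.
#' @param registry A `"ch4_registry"` to serialise.
#' @return `load_registry` returns a `"ch4_registry"`; `write_registry`
#'   returns `path` invisibly.
#' @export
load_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  eqs <- lapply(raw, function(x) {
    for (key in c("eq_id", "response", "category", "scope", "intercept"))
      if (is.null(x[[key]]))
        stop("registry JSON: equation missing '", key, "'",
             if (!is.null(x$eq_id)) paste0(" (", x$eq_id, ")") else "")
    new_equation(x$eq_id, x$response, x$category, x$scope,
                 as.numeric(x$intercept),
                 if (is.null(x$intercept_se)) NA_real_
                 else as.numeric(x$intercept_se),
                 x$terms,
                 energy_transform = isTRUE(x$energy_transform),
                 source = if (is.null(x$source)) "" else x$source)
  })
  names(eqs) <- vapply(eqs, `[[`, "", "eq_id")
  structure(eqs, class = "ch4_registry")
}

#' @rdname load_registry
#' @export
write_registry <- function(registry, path) {
  obj <- lapply(unname(registry), function(e) {
    terms <- lapply(seq_len(nrow(e$terms)), function(i)
      list(predictor = e$terms$predictor[i], coef = e$terms$coef[i],
           se = e$terms$se[i]))
    list(eq_id = e$eq_id, response = e$response, category = e$category,
         scope = e$scope, intercept = e$intercept,
         intercept_se = e$intercept_se, terms = terms,
         energy_transform = e$energy_transform, source = e$source)
  })
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' Pick the most informative computable equation
#'
#' Among registry equations matching `response` and `scope` whose
#' predictors are all contained in `available`, returns the one using the
#' most predictors; ties are broken by a documented category preference
#' (animal-level models first, then intake-based, milk-based, diet-only,
#' IPCC comparators last).
#'
#' @param registry A `"ch4_registry"`.
#' @param available Character vector of predictor names on hand. Note
#'   `"ecm"` must be listed explicitly if energy-corrected milk is
#'   available (it can be computed from `my`, `mf`, `mp` with
#'   [compute_ecm()] at prediction time).
#' @param response,scope Filters applied before the search.
#' @return The selected `"ch4_equation"`.
#' @export
best_available <- function(registry, available,
                           response = "production_g_d",
                           scope = "intercontinental") {
  if (length(registry) == 0L) stop("best_available: empty registry")
  cand <- filter_registry(registry, response = response, scope = scope)
  feasible <- Filter(function(e) all(e$terms$predictor %in% available), cand)
  if (length(feasible) == 0L) {
    gaps <- vapply(cand, function(e)
      paste(setdiff(e$terms$predictor, available), collapse = "+"), "")
    min_gap <- gaps[order(nchar(gaps))][1]
    stop("no equation computable from {",
         paste(available, collapse = ", "), "}; smallest missing set: {",
         min_gap, "}")
  }
  np <- vapply(feasible, function(e) nrow(e$terms), 0L)
  pref <- match(vapply(feasible, `[[`, "", "category"), CATEGORY_PREFERENCE,
                nomatch = length(CATEGORY_PREFERENCE) + 1L)
  feasible[[order(-np, pref)[1]]]
}
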