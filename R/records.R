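#' @keywords internal
#' @importFrom stats setNames predict
"_PACKAGE"

# Energy density of methane, MJ per g CH4. Fixed physical constant used in
# the methane conversion factor (Ym) and in the energy-scale prediction
# equations; not user-configurable.
CH4_ENERGY_MJ_PER_G <- 0.05565

#' Energy density of methane
#'
#' Returns the fixed energy density of methane (0.05565 MJ per g CH4) used
#' throughout the package to convert between CH4 mass and CH4 energy.
#'
#' @return A single number, MJ per g CH4.
#' @export
ch4_energy_density <- function() CH4_ENERGY_MJ_PER_G

# Numeric covariate columns of a cow record table, in canonical order.
COW_NUMERIC_FIELDS <- c("dmi", "gei", "ge_diet", "cp", "ee", "ndf", "ash",
                        "my", "mf", "mp", "bw", "ch4")

COW_ID_FIELDS <- c("record_id", "group_id", "study_id")

COW_REGIONS <- c("EU", "US", "AU", "NZ", "CL")

CH4_METHODS <- c("chamber", "greenfeed", "sf6", "other")

# Default required set for the refined complete data set: the response plus
# every candidate predictor used in variable selection.
COMPLETE_SET_FIELDS <- c("ch4", "dmi", "gei", "ge_diet", "cp", "ee", "ndf",
                         "ash", "my", "mf", "mp", "bw")

#' Energy-corrected milk (3.5% fat)
#'
#' Standardises milk yield for fat and protein content:
#' `ECM (kg/day) = 12.95 * fat yield + 7.65 * true protein yield +
#' 0.327 * milk yield`, where fat yield is `my * mf / 100` (kg/day), and
#' true protein yield is crude protein yield scaled by 0.93
#' (`my * mp / 100 * 0.93`).
#'
#' @param my Milk yield, kg/day.
#' @param mf Milk fat concentration, percent.
#' @param mp Milk crude protein concentration, percent.
#' @return ECM in kg/day. Missing inputs propagate to missing output.
#' @examples
#' compute_ecm(27, 4.1, 3.4)
#' @export
compute_ecm <- function(my, mf, mp) {
  ok <- !is.na(my) & !is.na(mf) & !is.na(mp)
  if (any(ok & (my < 0 | mf < 0 | mp < 0)))
    stop("compute_ecm: 'my', 'mf' and 'mp' must be non-negative")
  12.95 * (my * mf / 100) + 7.65 * (my * mp / 100 * 0.93) + 0.327 * my
}

#' Methane conversion factor (Ym)
#'
#' CH4 energy as a percentage of gross energy intake:
#' `Ym = 100 * (ch4 * 0.05565) / gei`.
#'
#' @param ch4 CH4 production, g/day.
#' @param gei Gross energy intake, MJ/day. Must be positive.
#' @return Ym in percent of GEI.
#' @export
compute_ym <- function(ch4, gei) {
  if (any(!is.na(gei) & gei <= 0))
    stop("compute_ym: 'gei' must be positive")
  if (any(!is.na(ch4) & ch4 < 0))
    stop("compute_ym: 'ch4' must be non-negative")
  100 * (ch4 * CH4_ENERGY_MJ_PER_G) / gei
}

#' CH4 yield and intensity
#'
#' Adds `ch4_yield` (g CH4 per kg DMI) and `ch4_intensity` (g CH4 per kg
#' energy-corrected milk) columns to a cow record table. Missing
#' prerequisites (or non-positive denominators) propagate to missing
#' outputs rather than errors.
#'
#' @param data A cow record data frame (see [read_cow_csv()]).
#' @return `data` with `ch4_yield` and `ch4_intensity` columns appended.
#' @export
derive_ratios <- function(data) {
  yield <- ifelse(!is.na(data$ch4) & !is.na(data$dmi) & data$dmi > 0,
                  data$ch4 / data$dmi, NA_real_)
  ecm <- rep(NA_real_, nrow(data))
  ok <- !is.na(data$my) & !is.na(data$mf) & !is.na(data$mp)
  if (any(ok)) ecm[ok] <- compute_ecm(data$my[ok], data$mf[ok], data$mp[ok])
  intensity <- ifelse(!is.na(data$ch4) & !is.na(ecm) & ecm > 0,
                      data$ch4 / ecm, NA_real_)
  data$ch4_yield <- yield
  data$ch4_intensity <- intensity
  data
}

#' Validate cow records
#'
#' Checks a record table against the schema invariants: numeric fields
#' strictly positive when present, known region and CH4-method codes,
#' `study_id` nested in exactly one `group_id`, derived Ym within (0, 15)%
#' when computable, and the soft GEI consistency check
#' `|gei - dmi * ge_diet| / gei <= 0.25` (reported as a warning-severity
#' violation, since gross energy intake should roughly equal intake times
#' dietary energy density).
#'
#' @param data A cow record data frame.
#' @return A data frame of violations with columns `record_id`, `field`,
#'   `rule` and `severity` ("error" or "warning"); zero rows if the table
#'   is clean.
#' @export
validate_records <- function(data) {
  viol <- list()
  add <- function(record_id, field, rule, severity = "error") {
    viol[[length(viol) + 1L]] <<- data.frame(
      record_id = as.character(record_id), field = field, rule = rule,
      severity = severity, stringsAsFactors = FALSE)
  }
  for (f in intersect(COW_NUMERIC_FIELDS, names(data))) {
    bad <- !is.na(data[[f]]) & data[[f]] <= 0
    for (id in data$record_id[bad])
      add(id, f, sprintf("%s must be strictly positive when present", f))
  }
  if ("region" %in% names(data)) {
    bad <- !is.na(data$region) & !(data$region %in% COW_REGIONS)
    for (id in data$record_id[bad])
      add(id, "region", paste("region must be one of",
                              paste(COW_REGIONS, collapse = ", ")))
  }
  if ("ch4_method" %in% names(data)) {
    bad <- !is.na(data$ch4_method) & !(data$ch4_method %in% CH4_METHODS)
    for (id in data$record_id[bad])
      add(id, "ch4_method", paste("ch4_method must be one of",
                                  paste(CH4_METHODS, collapse = ", ")))
  }
  # study nested in exactly one research group
  if (all(c("study_id", "group_id") %in% names(data))) {
    tab <- unique(data[, c("study_id", "group_id")])
    dup <- tab$study_id[duplicated(tab$study_id)]
    for (s in unique(dup))
      add(s, "study_id",
          sprintf("study '%s' maps to more than one group_id", s))
  }
  # Ym plausibility when computable
  ok <- !is.na(data$ch4) & !is.na(data$gei) & data$gei > 0 & data$ch4 > 0
  if (any(ok)) {
    ym <- compute_ym(data$ch4[ok], data$gei[ok])
    bad <- ym <= 0 | ym >= 15
    for (id in data$record_id[ok][bad])
      add(id, "ch4", "derived Ym outside plausible range (0, 15)%",
          severity = "warning")
  }
  # soft GEI consistency: gei ~ dmi * ge_diet
  ok <- !is.na(data$gei) & !is.na(data$dmi) & !is.na(data$ge_diet) &
    data$gei > 0
  if (any(ok)) {
    rel <- abs(data$gei[ok] - data$dmi[ok] * data$ge_diet[ok]) / data$gei[ok]
    for (id in data$record_id[ok][rel > 0.25])
      add(id, "gei",
          "gei inconsistent with dmi * ge_diet (relative gap > 0.25)",
          severity = "warning")
  }
  if (length(viol) == 0L)
    return(data.frame(record_id = character(), field = character(),
                      rule = character(), severity = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

#' Read and write cow record CSV files
#'
#' The on-disk format is a plain comma-separated file with a mandatory
#' header row naming the record fields (`record_id`, `group_id`,
#' `study_id`, `region`, `breed`, `ch4_method`, `dmi`, `gei`, `ge_diet`,
#' `cp`, `ee`, `ndf`, `ash`, `my`, `mf`, `mp`, `bw`, `ch4`), UTF-8
#' encoded, decimal point, empty cells meaning missing.
#'
#' @param path File path.
#' @param data A cow record data frame.
#' @return `read_cow_csv` returns the record data frame; `write_cow_csv`
#'   returns `path` invisibly.
#' @export
read_cow_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_ids <- setdiff(COW_ID_FIELDS, names(data))
  if (length(missing_ids))
    stop("cow record CSV lacks identifier column(s): ",
         paste(missing_ids, collapse = ", "))
  for (f in intersect(COW_NUMERIC_FIELDS, names(data)))
    data[[f]] <- as.numeric(data[[f]])
  for (f in COW_ID_FIELDS) data[[f]] <- as.character(data[[f]])
  data
}

#' @rdname read_cow_csv
#' @export
write_cow_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
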