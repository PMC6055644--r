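# Covariate profiles per region: marginal mean / min / max / SD for each
# cow-level covariate, transcribed from the summary statistics of the
# refined multi-study data set. Covariates are drawn as truncated normals
# within [min, max]; only the dmi-my pair is correlated (knob below),
# since no joint structure beyond the marginals is available.

PROFILE_FIELDS <- c("dmi", "ge_diet", "cp", "ee", "ndf", "ash", "my", "mf",
                    "mp", "bw")

make_profile <- function(region, stats, reference) {
  stopifnot(identical(sort(rownames(stats)), sort(PROFILE_FIELDS)))
  bad <- stats[, "min"] > stats[, "mean"] | stats[, "mean"] > stats[, "max"]
  if (any(bad)) stop("profile '", region, "': mean outside [min, max]")
  structure(list(region = region, stats = stats, reference = reference),
            class = "region_profile")
}

profile_stats <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE,
              dimnames = list(PROFILE_FIELDS,
                              c("mean", "min", "max", "sd")))
  m
}

#' Region covariate profiles
#'
#' Marginal covariate distributions (mean, min, max, SD) for the EU, US
#' and intercontinental record pools, used by [generate_herd()] to draw
#' realistic cow records. Each profile also carries reference outcome
#' means (`gei`, `ecm`, `ch4`, `ch4_yield`, `ch4_intensity`, `ym`)
#' observed on the corresponding pool, useful for plausibility checks.
#'
#' @return Named list of `"region_profile"` objects (`intercontinental`,
#'   `EU`, `US`).
#' @export
default_profiles <- function() {
  list(
    intercontinental = make_profile(
      "intercontinental",
      profile_stats(
        18.5, 3.9, 35.4, 4.60,     # dmi (kg/day)
        18.7, 16.1, 22.8, 0.69,    # ge_diet (MJ/kg DM)
        16.5, 8.1, 25.3, 2.43,     # cp (% DM)
        3.5, 0.7, 7.7, 1.14,       # ee
        35.4, 13.4, 70.0, 7.66,    # ndf
        7.3, 3.4, 19.5, 1.76,      # ash
        27.0, 4.3, 62.7, 9.76,     # my (kg/day)
        4.1, 1.4, 9.0, 0.85,       # mf (%)
        3.4, 2.3, 5.3, 0.38,       # mp (%)
        611, 283, 939, 88.1),      # bw (kg)
      reference = c(gei = 347, ecm = 29.2, ch4 = 369, ch4_yield = 20.1,
                    ch4_intensity = 13.5, ym = 6.0)),
    EU = make_profile(
      "EU",
      profile_stats(
        18.5, 8.0, 33.5, 3.84,
        18.6, 16.1, 22.8, 0.75,
        16.5, 8.1, 25.3, 2.58,
        3.6, 1.5, 7.7, 1.06,
        36.6, 13.4, 57.0, 7.83,
        7.9, 3.7, 19.5, 1.89,
        26.4, 7.6, 51.4, 7.92,
        4.4, 1.8, 9.0, 0.80,
        3.4, 2.3, 4.9, 0.37,
        614, 283, 939, 89.3),
      reference = c(gei = 345, ecm = 29.8, ch4 = 392, ch4_yield = 21.4,
                    ch4_intensity = 13.6, ym = 6.4)),
    US = make_profile(
      "US",
      profile_stats(
        18.8, 3.9, 35.4, 5.48,
        18.8, 17.3, 20.7, 0.56,
        16.5, 9.8, 23.5, 2.18,
        3.3, 0.7, 7.0, 1.23,
        33.3, 14.9, 70.0, 6.77,
        6.4, 3.4, 12.1, 1.07,
        28.4, 4.3, 62.7, 11.50,
        3.6, 1.4, 7.6, 0.68,
        3.2, 2.3, 5.3, 0.35,
        611, 302, 854, 86.4),
      reference = c(gei = 354, ecm = 29.0, ch4 = 340, ch4_yield = 18.2,
                    ch4_intensity = 12.8, ym = 5.4)))
}

#' @export
print.region_profile <- function(x, ...) {
  cat(sprintf("Region profile '%s'\n", x$region))
  print(x$stats)
  invisible(x)
}

#' Ground truth for herd simulation
#'
#' Defines the data-generating emission equation and variance structure:
#' `ch4 = b0 + sum(b * x) + group effect + study effect + residual`. The
#' default coefficients are the published all-variable (Animal_C)
#' production equation; the default variance components (group SD 20,
#' study SD 25, residual SD 40 g/day) give region-level CH4 coefficients
#' of variation in the 23-33% range typical of multi-study databases.
#'
#' @param beta Named coefficient vector; must contain `"(Intercept)"`,
#'   other names must be covariates from the region profiles.
#' @param sd_group,sd_study,sd_resid Random-effect and residual SDs
#'   (g/day, non-negative).
#' @param corr_dmi_my Correlation between dry matter intake and milk
#'   yield, in (-1, 1).
#' @return A `"simulation_truth"` list.
#' @export
simulation_truth <- function(beta = c("(Intercept)" = -60.5, dmi = 12.4,
                                      ee = -8.78, ndf = 2.10, mf = 16.1,
                                      bw = 0.148),
                             sd_group = 20, sd_study = 25, sd_resid = 40,
                             corr_dmi_my = 0.6) {
  if (!"(Intercept)" %in% names(beta))
    stop("simulation_truth: beta must include '(Intercept)'")
  preds <- setdiff(names(beta), "(Intercept)")
  if (!all(preds %in% PROFILE_FIELDS))
    stop("simulation_truth: unknown covariate(s): ",
         paste(setdiff(preds, PROFILE_FIELDS), collapse = ", "))
  if (sd_group < 0 || sd_study < 0 || sd_resid < 0)
    stop("simulation_truth: SDs must be non-negative")
  if (abs(corr_dmi_my) >= 1)
    stop("simulation_truth: |corr_dmi_my| must be < 1")
  structure(list(beta = beta, sd_group = sd_group, sd_study = sd_study,
                 sd_resid = sd_resid, corr_dmi_my = corr_dmi_my),
            class = "simulation_truth")
}

#' Simulation configuration
#'
#' @param n_groups Number of research groups.
#' @param studies_per_group Studies contributed by each group.
#' @param cows_per_study Records per study.
#' @param region_mix Named probabilities for the region assigned to each
#'   study; regions without their own profile fall back to the
#'   intercontinental profile. The default approximates the EU/US/AU
#'   composition of the multi-study pool.
#' @param truth A `"simulation_truth"` object.
#' @param profiles Profile list as from [default_profiles()].
#' @param seed Integer seed; every random draw derives from it.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_groups = 6, studies_per_group = 10,
                       cows_per_study = 20,
                       region_mix = c(EU = 0.55, US = 0.42, AU = 0.03),
                       truth = simulation_truth(),
                       profiles = default_profiles(), seed = 1L) {
  if (n_groups < 1 || studies_per_group < 1 || cows_per_study < 1)
    stop("sim_config: all counts must be >= 1")
  if (abs(sum(region_mix) - 1) > 1e-8)
    stop("sim_config: region_mix must sum to 1")
  if (is.null(names(region_mix)) || !all(names(region_mix) %in% COW_REGIONS))
    stop("sim_config: region_mix names must be region codes")
  structure(list(n_groups = n_groups, studies_per_group = studies_per_group,
                 cows_per_study = cows_per_study, region_mix = region_mix,
                 truth = truth, profiles = profiles,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# truncated-normal draw by rejection within [lo, hi]
rtruncnorm_rej <- function(n, mean, sd, lo, hi) {
  mass <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  if (mass < 0.01)
    stop("infeasible truncation: N(", mean, ", ", sd, ") has mass ",
         signif(mass, 2), " on [", lo, ", ", hi, "]")
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# deterministic per-entity substream seeds, kept below 2^31 - 1
substream_seed <- function(seed, salt, index) {
  as.integer((as.numeric(seed) * 7919 + salt * 337 + index * 104729) %%
               2147483647)
}

#' Generate a synthetic multi-study herd
#'
#' Draws a balanced hierarchy of research groups, studies nested in
#' groups, and cow records within studies. Covariates come from the
#' study's region profile (truncated normals within the profile's
#' ranges); milk yield is linked to intake through the configured
#' `corr_dmi_my`; gross energy intake is `dmi * ge_diet`; and CH4
#' production follows the configured true equation plus group, study and
#' residual noise, floored at 1 g/day. Each study draws from its own
#' seeded substream, so enlarging one study does not perturb another's
#' records, and the whole data set is reproducible from the seed.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `records` (cow record data frame, including the
#'   realised `group_effect` and `study_effect` columns for diagnostics)
#'   and `truth` (the `"simulation_truth"` used, with the seed echoed).
#' @export
generate_herd <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- cfg$truth
  preds <- setdiff(names(truth$beta), "(Intercept)")
  out <- vector("list", cfg$n_groups * cfg$studies_per_group)
  idx <- 0L
  for (gi in seq_len(cfg$n_groups)) {
    group_id <- sprintf("G%02d", gi)
    set.seed(substream_seed(cfg$seed, salt = 1, index = gi))
    g_eff <- stats::rnorm(1, 0, truth$sd_group)
    for (si in seq_len(cfg$studies_per_group)) {
      idx <- idx + 1L
      study_id <- sprintf("%sS%02d", group_id, si)
      set.seed(substream_seed(cfg$seed, salt = 2,
                              index = (gi - 1L) * cfg$studies_per_group + si))
      region <- sample(names(cfg$region_mix), 1, prob = cfg$region_mix)
      prof <- if (region %in% names(cfg$profiles))
        cfg$profiles[[region]] else cfg$profiles$intercontinental
      st <- prof$stats
      n <- cfg$cows_per_study
      s_eff <- stats::rnorm(1, 0, truth$sd_study)
      rec <- data.frame(
        record_id = sprintf("%sC%03d", study_id, seq_len(n)),
        group_id = group_id, study_id = study_id, region = region,
        breed = NA_character_,
        ch4_method = sample(c("chamber", "greenfeed", "sf6"), 1),
        stringsAsFactors = FALSE)
      for (f in PROFILE_FIELDS)
        rec[[f]] <- rtruncnorm_rej(n, st[f, "mean"], st[f, "sd"],
                                   st[f, "min"], st[f, "max"])
      # re-draw milk yield tied to intake: my | dmi is normal with the
      # configured correlation, truncated to the profile range
      rho <- truth$corr_dmi_my
      z_dmi <- (rec$dmi - st["dmi", "mean"]) / st["dmi", "sd"]
      cond_mean <- st["my", "mean"] + rho * st["my", "sd"] * z_dmi
      cond_sd <- st["my", "sd"] * sqrt(1 - rho^2)
      my <- stats::rnorm(n, cond_mean, cond_sd)
      bad <- which(my < st["my", "min"] | my > st["my", "max"])
      guard <- 0L
      while (length(bad)) {
        my[bad] <- stats::rnorm(length(bad), cond_mean[bad], cond_sd)
        bad <- bad[my[bad] < st["my", "min"] | my[bad] > st["my", "max"]]
        guard <- guard + 1L
        if (guard > 1000L) {  # pathological conditional mean: clamp
          my[bad] <- pmin(pmax(my[bad], st["my", "min"]), st["my", "max"])
          break
        }
      }
      rec$my <- my
      rec$gei <- rec$dmi * rec$ge_diet
      mu <- rep(truth$beta[["(Intercept)"]], n)
      for (p in preds) mu <- mu + truth$beta[[p]] * rec[[p]]
      rec$ch4 <- pmax(mu + g_eff + s_eff +
                        stats::rnorm(n, 0, truth$sd_resid), 1)
      rec$group_effect <- g_eff
      rec$study_effect <- s_eff
      out[[idx]] <- rec
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  truth$seed <- cfg$seed
  list(records = records, truth = truth)
}
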