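test_that("region profiles carry the published summary statistics", {
  p <- default_profiles()
  expect_equal(p$EU$stats["ndf", "mean"], 36.6)
  expect_equal(p$EU$stats["ndf", "sd"], 7.83)
  expect_equal(p$US$stats["mf", "mean"], 3.6)
  expect_equal(p$intercontinental$stats["dmi", "mean"], 18.5)
  for (prof in p) {
    expect_true(all(prof$stats[, "min"] <= prof$stats[, "mean"]))
    expect_true(all(prof$stats[, "mean"] <= prof$stats[, "max"]))
    expect_true(all(prof$stats[, "sd"] > 0))
  }
})

test_that("generation is reproducible from the seed and studies are substream-stable", {
  cfg <- sim_config(n_groups = 2, studies_per_group = 3, cows_per_study = 5,
                    seed = 99)
  a <- generate_herd(cfg)
  b <- generate_herd(cfg)
  expect_identical(a$records, b$records)
  # enlarging one study leaves other studies' draws untouched
  cfg_big <- sim_config(n_groups = 2, studies_per_group = 3,
                        cows_per_study = 8, seed = 99)
  big <- generate_herd(cfg_big)
  # each study draws from its own substream: its region assignment and
  # leading intake draws are unchanged by the other studies growing
  for (s in unique(a$records$study_id)) {
    small_s <- a$records[a$records$study_id == s, ]
    big_s <- big$records[big$records$study_id == s, ][seq_len(5), ]
    expect_identical(big_s$region, small_s$region)
    expect_equal(big_s$dmi, small_s$dmi)
  }
})

test_that("the noise-free limit is exactly linear in the covariates", {
  h <- generate_herd(sim_config(
    n_groups = 2, studies_per_group = 3, cows_per_study = 10,
    truth = simulation_truth(sd_group = 0, sd_study = 0, sd_resid = 0),
    seed = 13))
  r <- h$records
  beta <- h$truth$beta
  mu <- beta[["(Intercept)"]] + beta[["dmi"]] * r$dmi +
    beta[["ee"]] * r$ee + beta[["ndf"]] * r$ndf + beta[["mf"]] * r$mf +
    beta[["bw"]] * r$bw
  expect_equal(r$ch4, pmax(mu, 1), tolerance = 1e-12)
  # refitting recovers the coefficients
  ols <- lm(ch4 ~ dmi + ee + ndf + mf + bw, r)
  expect_equal(unname(coef(ols)[-1]),
               unname(beta[c("dmi", "ee", "ndf", "mf", "bw")]),
               tolerance = 1e-6)
})

test_that("large samples match the EU profile marginals within truncation bias", {
  h <- generate_herd(sim_config(
    n_groups = 5, studies_per_group = 10, cows_per_study = 200,
    region_mix = c(EU = 1), seed = 14))
  d <- h$records
  expect_identical(nrow(d), 10000L)
  st <- default_profiles()$EU$stats
  expect_true(all(d$dmi >= st["dmi", "min"] & d$dmi <= st["dmi", "max"]))
  expect_true(all(d$my >= st["my", "min"] & d$my <= st["my", "max"]))
  # 3 SEs plus a small truncation-bias allowance
  tol <- 3 * st["dmi", "sd"] / sqrt(10000) + 0.05
  expect_lt(abs(mean(d$dmi) - st["dmi", "mean"]), tol)
  # the intake-milk correlation knob is honoured
  expect_gt(cor(d$dmi, d$my), 0.45)
  expect_lt(cor(d$dmi, d$my), 0.75)
  # gei is exactly dmi * ge_diet
  expect_equal(d$gei, d$dmi * d$ge_diet, tolerance = 1e-12)
})

test_that("realised CH4 dispersion sits in the multi-study range", {
  h <- generate_herd(sim_config(n_groups = 6, studies_per_group = 10,
                                cows_per_study = 20, seed = 15))
  cv_pct <- 100 * sd(h$records$ch4) / mean(h$records$ch4)
  expect_gt(cv_pct, 15)
  expect_lt(cv_pct, 40)
})

test_that("implanted extreme-yield records are all flagged by the screen", {
  h <- small_herd(seed = 16)
  d <- h$records
  reg <- d$region[1]
  in_reg <- d$region == reg
  f <- iqr_fences(d$ch4[in_reg] / d$dmi[in_reg])
  m <- 3
  implant <- d[which(in_reg)[seq_len(m)], ]
  implant$record_id <- sprintf("IMPLANT%d", seq_len(m))
  implant$ch4 <- 3 * f$upper * implant$dmi
  out <- screen_outliers(rbind(d, implant))
  expect_true(all(implant$record_id %in% out$report$flagged$record_id))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_groups = 0), ">= 1")
  expect_error(sim_config(region_mix = c(EU = 0.5, US = 0.4)), "sum to 1")
  expect_error(simulation_truth(sd_resid = -1), "non-negative")
  expect_error(simulation_truth(corr_dmi_my = 1), "< 1")
  expect_error(simulation_truth(beta = c(dmi = 1)), "Intercept")
  # infeasible truncation surfaces as a config error at generation time
  prof <- default_profiles()
  prof$EU$stats["dmi", "mean"] <- 100
  expect_error(generate_herd(sim_config(region_mix = c(EU = 1),
                                        profiles = prof, seed = 1)),
               "infeasible truncation")
})
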