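test_that("with no group or study variance the fixed effects match OLS", {
  h <- generate_herd(sim_config(
    n_groups = 5, studies_per_group = 8, cows_per_study = 50,
    truth = simulation_truth(sd_group = 0, sd_study = 0, sd_resid = 0),
    seed = 3))
  d <- h$records
  # noise projected orthogonal to the covariates and study indicators:
  # the study variance sits exactly on the zero boundary, the group
  # variance is a small boundary-adjacent REML artefact, and the fixed
  # effects coincide with OLS up to that residual shrinkage
  set.seed(33)
  eps <- rnorm(nrow(d), 0, 40)
  eps <- resid(lm(eps ~ dmi + ndf + ee + factor(study_id), data = d))
  d$ch4 <- d$ch4 + eps
  fit <- methane_lmm(ch4 ~ dmi + ndf + ee, d)
  expect_identical(fit$var_study, 0)
  expect_lt(fit$var_group / fit$var_resid, 0.01)
  ols <- lm(ch4 ~ dmi + ndf + ee, d)
  se_ols <- summary(ols)$coefficients[, "Std. Error"]
  expect_true(all(abs(coef(fit) - coef(ols)) < 0.5 * se_ols))
})

test_that("noise-free data is reproduced exactly", {
  h <- generate_herd(sim_config(
    n_groups = 3, studies_per_group = 4, cows_per_study = 10,
    truth = simulation_truth(sd_group = 0, sd_study = 0, sd_resid = 0),
    seed = 4))
  # optimizer grumbles are expected at an exactly-singular fit
  fit <- suppressWarnings(
    methane_lmm(ch4 ~ dmi + ee + ndf + mf + bw, h$records))
  expect_equal(unname(coef(fit)[c("dmi", "ee", "ndf", "mf", "bw")]),
               unname(h$truth$beta[c("dmi", "ee", "ndf", "mf", "bw")]),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]),
               h$truth$beta[["(Intercept)"]], tolerance = 1e-4)
})

test_that("response shift moves only the intercept; predictor scaling inverts the slope", {
  d <- multi_study_records()
  f1 <- methane_lmm(ch4 ~ dmi, d)
  d2 <- d; d2$ch4 <- d2$ch4 + 100
  f2 <- methane_lmm(ch4 ~ dmi, d2)
  expect_equal(unname(coef(f2)["(Intercept)"] - coef(f1)["(Intercept)"]),
               100, tolerance = 1e-6)
  expect_equal(coef(f2)["dmi"], coef(f1)["dmi"], tolerance = 1e-6)
  expect_equal(f2$var_resid, f1$var_resid, tolerance = 1e-6)
  expect_equal(f2$var_study, f1$var_study, tolerance = 1e-4)
  d3 <- d; d3$dmi <- d3$dmi * 4
  f3 <- methane_lmm(ch4 ~ dmi, d3)
  expect_equal(unname(coef(f3)["dmi"]), unname(coef(f1)["dmi"]) / 4,
               tolerance = 1e-6)
})

test_that("degenerate inputs are flagged, not silently fitted", {
  d <- multi_study_records()
  # single study cannot identify the random structure
  one <- d[d$study_id == "S1", ]
  expect_error(methane_lmm(ch4 ~ dmi, one), "single study")
  # constant response collapses to intercept-only
  dc <- d; dc$ch4 <- 369
  fit <- methane_lmm(ch4 ~ dmi + ndf, dc)
  expect_equal(unname(coef(fit)["(Intercept)"]), 369)
  expect_equal(unname(coef(fit)["dmi"]), 0)
  expect_equal(fit$var_group + fit$var_study + fit$var_resid, 0)
  # one record per study: variance split not identifiable
  singleton <- d[!duplicated(d$study_id), ]
  singleton <- rbind(singleton, singleton, singleton)
  singleton$study_id <- sprintf("S%02d", seq_len(nrow(singleton)))
  singleton$record_id <- singleton$study_id
  suppressWarnings(
    expect_warning(fit2 <- methane_lmm(ch4 ~ dmi, singleton),
                   "not separately identifiable"))
  expect_false(fit2$identifiable)
})

test_that("fixed-effects prediction matches the published-equation arithmetic", {
  d <- multi_study_records()
  fit <- methane_lmm(ch4 ~ dmi, d)
  # overwrite the coefficients with the printed intake-only equation: the
  # prediction path must reproduce the registry's arithmetic
  fit$beta <- c("(Intercept)" = 124, dmi = 13.3)
  expect_equal(predict(fit, data.frame(dmi = 18.5)), 370.05)
  expect_equal(predict(fit, data.frame(dmi = 0)), 124)
  # permutation invariance
  new <- data.frame(dmi = c(12, 25, 18.5))
  perm <- c(3, 1, 2)
  expect_equal(predict(fit, new)[perm], predict(fit, new[perm, , drop = FALSE]))
  expect_error(predict(fit, data.frame(ndf = 1)), "missing predictor")
})

test_that("group random effects can be reused for known groups only", {
  h <- small_herd(seed = 6)
  fit <- methane_lmm(ch4 ~ dmi, h$records)
  new <- h$records[1:5, ]
  p_fixed <- predict(fit, new)
  p_group <- predict(fit, new, re = "group")
  expect_equal(p_group - p_fixed,
               rep(unname(fit$ranef$group[new$group_id[1]]), 5))
  unseen <- new; unseen$group_id <- "G99"
  expect_equal(predict(fit, unseen, re = "group"), p_fixed)
})

test_that("fits serialise to JSON with coefficients and variances", {
  d <- multi_study_records()
  fit <- methane_lmm(ch4 ~ dmi, d)
  js <- jsonlite::fromJSON(fit_json(fit))
  expect_equal(js$beta$dmi, unname(coef(fit)["dmi"]))
  expect_equal(js$var_resid, fit$var_resid)
  expect_true(is.logical(js$converged))
})
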