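test_that("the BIC formula matches its closed forms", {
  expect_equal(bic_score(100, 100, 2), 2 * log(100))
  # sse = n makes the fit term vanish for any n
  for (n in c(10, 250, 5000))
    expect_equal(bic_score(n, n, 3), 3 * log(n))
  # each added coefficient costs log(n) at fixed sse
  expect_equal(bic_score(50, 200, 4) - bic_score(50, 200, 3), log(200))
  expect_error(bic_score(0, 10, 1), "positive")
})

test_that("VIFs equal brute-force auxiliary regressions", {
  set.seed(51)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- 0.7 * x1 + 0.5 * x2 + rnorm(n, 0, 0.4)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif_scores(d, c("x1", "x2", "x3"))
  for (j in c("x1", "x2", "x3")) {
    aux <- lm(reformulate(setdiff(c("x1", "x2", "x3"), j), j), d)
    expect_equal(unname(v[j]), 1 / (1 - summary(aux)$r.squared),
                 tolerance = 1e-8)
  }
  # orthogonal standardized predictors have VIF 1
  ortho <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
  expect_equal(unname(vif_scores(ortho, c("a", "b"))), c(1, 1))
  # exact duplicates are Inf, not an error
  dup <- data.frame(x1 = x1, x2 = x1)
  expect_equal(unname(vif_scores(dup, c("x1", "x2"))), c(Inf, Inf))
})

test_that("VIFs agree with the car package on correlated data", {
  skip_if_not_installed("car")
  set.seed(52)
  n <- 150
  d <- data.frame(x1 = rnorm(n))
  d$x2 <- 0.8 * d$x1 + rnorm(n, 0, 0.5)
  d$x3 <- rnorm(n)
  d$y <- d$x1 + d$x3 + rnorm(n)
  ours <- vif_scores(d, c("x1", "x2", "x3"))
  theirs <- car::vif(lm(y ~ x1 + x2 + x3, d))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})

test_that("collinearity pruning removes the largest-VIF predictor one at a time", {
  set.seed(53)
  n <- 100
  x1 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x1, x3 = rnorm(n))
  pr <- prune_collinear(d, c("x1", "x2", "x3"))
  expect_identical(pr$retained, c("x1", "x3"))  # first-listed copy kept
  expect_identical(pr$removed$predictor, "x2")
  # all VIF below threshold: nothing removed
  clean <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_identical(prune_collinear(clean, c("a", "b"))$retained, c("a", "b"))
  # removal order matches recomputation at each step
  d4 <- data.frame(x1 = x1, x2 = x1 + rnorm(n, 0, 0.05),
                   x3 = x1 + rnorm(n, 0, 0.1), x4 = rnorm(n))
  pr4 <- prune_collinear(d4, c("x1", "x2", "x3", "x4"))
  remaining <- c("x1", "x2", "x3", "x4")
  for (i in seq_len(nrow(pr4$removed))) {
    v <- vif_scores(d4, remaining)
    worst <- names(v)[v == max(v)]
    expect_identical(pr4$removed$predictor[i], worst[length(worst)])
    expect_equal(pr4$removed$vif[i], unname(max(v)))
    remaining <- setdiff(remaining, pr4$removed$predictor[i])
  }
  expect_lte(nrow(pr4$removed), 4)
})

test_that("all-subsets search ranks every subset and prefers the signal", {
  set.seed(54)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  group_id = "G1",
                  study_id = sample(sprintf("S%d", 1:5), n, replace = TRUE))
  d$y <- 2 * d$x1 + rnorm(n)
  sel <- all_subsets(d, c("x1", "x2", "x3"), "y", engine = "ols")
  expect_identical(nrow(sel$candidates), 7L)  # 2^3 - 1 subsets
  expect_identical(sel$best, "x1")
  # single candidate
  sel1 <- all_subsets(d, "x1", "y", engine = "ols")
  expect_identical(sel1$best, "x1")
  # best subset invariant to candidate permutation
  sel_perm <- all_subsets(d, c("x3", "x1", "x2"), "y", engine = "ols")
  expect_setequal(sel_perm$best, sel$best)
  expect_error(all_subsets(d, sprintf("x%d", 1:13), "y"), "12")
})

test_that("a pure-noise predictor raises BIC at large n", {
  set.seed(55)
  n <- 5000
  d <- data.frame(x1 = rnorm(n), noise = rnorm(n))
  d$y <- 1.5 * d$x1 + rnorm(n)
  sse1 <- sum(resid(lm(y ~ x1, d))^2)
  sse2 <- sum(resid(lm(y ~ x1 + noise, d))^2)
  expect_gt(bic_score(sse2, n, 3), bic_score(sse1, n, 2))
})

test_that("the mixed-model subset engine runs and agrees on strong signal", {
  h <- small_herd(seed = 8)
  d <- h$records
  sel_ols <- all_subsets(d, c("dmi", "mp"), "ch4", engine = "ols")
  sel_lmm <- all_subsets(d, c("dmi", "mp"), "ch4", engine = "lmm")
  expect_true("dmi" %in% sel_ols$best)
  expect_true("dmi" %in% sel_lmm$best)
})
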