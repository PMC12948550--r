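test_that("replicated-block data force a singular fit and reduction", {
  # identical residual pattern in every block: block variance estimate is 0
  base <- rep(c(-1, -0.5, 0, 0.5, 1, 1.5, -1.5, 0.25), 3)
  tab <- data.frame(
    treatment = rep(c("shade", "ambient", "supplemental"), each = 24),
    block = rep(rep(1:3, each = 8), 3),
    y = rep(c(0, 0.2, 0.4), each = 24) + rep(base, 3)
  )
  tf <- fit_treatment_model(tab, "y")
  expect_true(tf$singular_fit)
  expect_true(tf$reduced)
  expect_equal(tf$model_form, "simple_linear")
  res <- treatment_anova(tf)
  expect_equal(res$statistic_kind, "F")
})

test_that("strong block structure keeps the mixed form and recovers the variance", {
  ests <- vapply(1:200, function(s) {
    tab <- generate_seedling_experiment(calib_design(block_sd = 2, seed = s))
    tf <- fit_treatment_model(tab, "y")
    if (tf$model_form != "mixed") return(NA_real_)
    vc <- as.data.frame(lme4::VarCorr(tf$fit))
    vc$vcov[vc$grp == "block"]
  }, numeric(1))
  expect_gt(mean(!is.na(ests)), 0.9)       # mixed form retained
  m <- mean(ests, na.rm = TRUE)
  mc_se <- sd(ests, na.rm = TRUE) / sqrt(sum(!is.na(ests)))
  expect_lt(abs(m - 4), 2 * mc_se)         # block variance = 2^2
})

test_that("degenerate designs are refused", {
  tab <- data.frame(treatment = "shade", block = rep(1:3, 4), y = rnorm(12))
  expect_error(fit_treatment_model(tab, "y"), class = "lightphen_invalid_model")
  tab2 <- data.frame(treatment = rep(c("a", "b"), each = 4), block = 1,
                     y = NA_real_)
  expect_error(fit_treatment_model(tab2, "y"), class = "lightphen_invalid_model")
})

test_that("the two-group reduced model reproduces F = t^2", {
  # identical residual pattern per block keeps the block variance at zero,
  # so the fit reduces deterministically
  base <- c(-1.3, -0.4, 0.1, 0.9, 1.7)
  tab <- data.frame(treatment = rep(c("a", "b"), each = 10),
                    block = rep(rep(1:2, each = 5), 2),
                    y = rep(c(0, 1), each = 10) + rep(base, 4))
  tf <- fit_treatment_model(tab, "y")
  expect_equal(tf$model_form, "simple_linear")
  res <- treatment_anova(tf)
  tstat <- t.test(y ~ treatment, data = tab, var.equal = TRUE)$statistic
  expect_equal(res$statistic, unname(tstat^2), tolerance = 1e-10)
})

test_that("pairwise contrasts recover a constructed one-group shift", {
  # shade and ambient carry the exact same response pattern; supplemental is
  # shifted far away -- only its two contrasts can be significant
  set.seed(4)
  pattern <- rnorm(24)
  tab <- data.frame(
    treatment = factor(rep(c("shade", "ambient", "supplemental"), each = 24),
                       levels = c("shade", "ambient", "supplemental")),
    block = rep(rep(1:3, each = 8), 3),
    y = c(pattern, pattern, pattern + 3)
  )
  tf <- fit_treatment_model(tab, "y")
  pw <- tukey_pairwise(tf)
  key <- paste(pw$group_a, pw$group_b)
  expect_false(pw$significant[key == "shade ambient"])
  expect_true(pw$significant[key == "shade supplemental"])
  expect_true(pw$significant[key == "ambient supplemental"])
  lt <- attr(pw, "letters")
  expect_equal(lt[["shade"]], lt[["ambient"]])
  expect_false(lt[["supplemental"]] == lt[["shade"]])
})

test_that("identical groups yield non-significant contrasts sharing one letter", {
  tab <- generate_seedling_experiment(calib_design(seed = 31))
  tf <- fit_treatment_model(tab, "y")
  pw <- tukey_pairwise(tf)
  expect_true(all(pw$p_adj > 0.05))
  expect_equal(length(unique(attr(pw, "letters"))), 1L)
})

test_that("Tukey adjustment never lowers a p-value", {
  for (s in c(2, 12, 22)) {
    tab <- generate_seedling_experiment(calib_design(means = c(0, 0.3, 0.6),
                                                     seed = s))
    pw <- tukey_pairwise(fit_treatment_model(tab, "y"))
    expect_true(all(pw$p_adj >= pw$p_unadj - 1e-12))
  }
})

test_that("grouped survival LR test matches the closed-form deviance", {
  res <- survival_lr_test(c(22, 15, 19), c(24, 24, 24))
  expect_equal(res$statistic, 6.19, tolerance = 0.005)
  expect_equal(res$df1, 2)

  eq <- survival_lr_test(c(10, 5), c(20, 10))
  expect_equal(eq$statistic, 0, tolerance = 1e-10)

  # brute-force grouped-binomial deviance oracle on arbitrary 2-group counts
  y <- c(13, 4); n <- c(18, 11)
  p0 <- sum(y) / sum(n)
  oracle <- 2 * sum(y * log(y / (n * p0)) + (n - y) * log((n - y) / (n * (1 - p0))))
  got <- survival_lr_test(y, n)
  expect_equal(got$statistic, oracle, tolerance = 1e-10)
  expect_equal(got$p_value, pchisq(oracle, 1, lower.tail = FALSE))
})

test_that("survival test input validation", {
  expect_error(survival_lr_test(c(25, 3), c(24, 24)), class = "lightphen_invalid_model")
  expect_error(survival_lr_test(5, 10), class = "lightphen_invalid_model")
  expect_error(survival_lr_test(c(2, 3), c(0, 10)), class = "lightphen_invalid_model")
})

test_that("plant-level survival wrapper tabulates counts correctly", {
  tab <- generate_seedling_experiment(experiment_design(seed = 14))
  res <- survival_test(tab)
  counts <- tapply(tab$survived, tab$treatment, sum)
  direct <- survival_lr_test(as.integer(counts), rep(24L, 3))
  expect_equal(res$statistic, direct$statistic)
})

test_that("R:S allometry check is calibrated and powered", {
  # null: R:S independent of biomass; main-effect false-positive rate <= 7%
  hits <- vapply(1:1000, function(s) {
    set.seed(40000 + s)
    tab <- data.frame(
      rs = 0.22 + rnorm(60, 0, 0.04),
      total_biomass = runif(60, 1, 9),
      treatment = rep(c("shade", "ambient", "supplemental"), each = 20)
    )
    res <- rs_allometry_check(tab)
    res$p_value[res$response == "rs ~ total_biomass"] < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.93)

  # exact zero slope, no noise: estimated coefficient is 0
  tab0 <- data.frame(rs = rep(c(0.2, 0.25, 0.3), each = 8),
                     total_biomass = rep(seq(2, 9, 1), 3),
                     treatment = rep(c("shade", "ambient", "supplemental"), each = 8))
  fit0 <- lm(rs ~ total_biomass * treatment, data = tab0)
  expect_equal(unname(coef(fit0)["total_biomass"]), 0, tolerance = 1e-12)

  # strong constructed interaction is detected with power >= 0.8
  pow <- vapply(1:200, function(s) {
    set.seed(90000 + s)
    tb <- runif(72, 1, 8)
    trt <- factor(rep(c("shade", "ambient", "supplemental"), each = 24))
    slope <- c(shade = 0, ambient = 0, supplemental = 0.08)[as.integer(trt)]
    tab <- data.frame(rs = 0.22 + slope * tb + rnorm(72, 0, 0.05),
                      total_biomass = tb, treatment = trt)
    res <- rs_allometry_check(tab)
    res$p_value[res$response == "rs ~ total_biomass:treatment"] < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.8)
})
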