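test_that("equal values give F = 0 and p = 1 with a single letter", {
  out <- oneway_anova_tukey(rep(0.15, 12), rep(c("A", "B", "C"), each = 4))
  expect_equal(out$model$statistic, 0)
  expect_equal(out$model$p_value, 1)
  expect_equal(length(unique(attr(out$pairwise, "letters"))), 1L)
})

test_that("unbalanced one-way F matches a sums-of-squares oracle", {
  set.seed(19)
  groups <- factor(rep(c("GRF", "PSG", "HWK", "HI"), times = c(6, 4, 6, 6)))
  values <- rnorm(length(groups), mean = c(GRF = 0.1, PSG = 0.12, HWK = 0.2,
                                           HI = 0)[as.character(groups)], sd = 0.05)
  out <- oneway_anova_tukey(values, groups)
  n <- table(groups); gm <- tapply(values, groups, mean); grand <- mean(values)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum((values - gm[as.character(groups)])^2)
  k <- nlevels(groups); N <- length(values)
  oracle_F <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(out$model$statistic, oracle_F, tolerance = 1e-10)
  expect_equal(out$model$df1, k - 1)
  expect_equal(out$model$df2, N - k)
  expect_true(all(out$pairwise$p_adj >= out$pairwise$p_unadj - 1e-12))
})

test_that("two-group one-way ANOVA reproduces F = t^2", {
  set.seed(5)
  v <- c(rnorm(6, 0), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  out <- oneway_anova_tukey(v, g)
  tstat <- t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(out$model$statistic, unname(tstat^2), tolerance = 1e-10)
})

test_that("tiny provenance groups are refused", {
  expect_error(oneway_anova_tukey(c(1, 2, 3), c("a", "a", "b")),
               class = "lightphen_invalid_model")
  expect_error(oneway_anova_tukey(rep(1, 4), rep("a", 4)),
               class = "lightphen_invalid_model")
})

test_that("region test uses 1 and n-2 degrees of freedom", {
  means <- c(0.12, 0.13, 0.11, 0.02, 0.03, 0.01)
  regions <- rep(c("northern", "southern"), each = 3)
  res <- region_means_test(means, regions)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_lt(res$p_value, 0.05)

  flat <- region_means_test(rep(c(1, 1, 1, 1), times = c(2, 1, 2, 1)),
                            c("n", "n", "n", "s", "s", "s"))
  expect_equal(flat$statistic, 0)
  expect_error(region_means_test(means, rep("northern", 6)),
               class = "lightphen_invalid_model")
})

test_that("a separated region contrast is detected reliably", {
  hits <- vapply(1:500, function(s) {
    set.seed(70000 + s)
    m <- c(rnorm(3, 0.5, 0.1), rnorm(3, 0, 0.1))  # delta/sigma = 5
    region_means_test(m, rep(c("n", "s"), each = 3))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PCA handles the rank-1 case and conserves variance", {
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  p <- pca_climate(x)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)

  cl <- provenance_climate()
  clim <- cl[, c("solar_radiation", "elevation", "mat", "temp_seasonality",
                 "annual_precip", "precip_seasonality")]
  p2 <- pca_climate(clim)
  expect_equal(sum(p2$variance_fraction), 1, tolerance = 1e-8)
  expect_equal(crossprod(p2$loadings), diag(ncol(p2$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA matches an SVD oracle up to column sign", {
  cl <- provenance_climate()
  clim <- as.matrix(cl[, c("solar_radiation", "elevation", "mat",
                           "temp_seasonality", "annual_precip",
                           "precip_seasonality")])
  p <- pca_climate(clim)
  z <- scale(clim, center = TRUE, scale = TRUE)
  sv <- svd(z)
  k <- ncol(p$loadings)
  for (j in seq_len(k)) {
    s <- sign(sum(p$loadings[, j] * sv$v[, j]))
    expect_equal(p$loadings[, j], s * sv$v[, j], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(p$scores[, j], s * sv$u[, j] * sv$d[j], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(p$variance_fraction, sv$d[seq_len(k)]^2 / sum(sv$d^2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA is equivariant under row permutation", {
  cl <- provenance_climate()
  clim <- as.matrix(cl[, c("solar_radiation", "elevation", "mat",
                           "temp_seasonality", "annual_precip",
                           "precip_seasonality")])
  perm <- c(4, 1, 6, 2, 5, 3)
  p1 <- pca_climate(clim)
  p2 <- pca_climate(clim[perm, ])
  expect_equal(p2$variance_fraction, p1$variance_fraction, tolerance = 1e-10)
  for (j in seq_len(ncol(p1$scores))) {
    s <- sign(sum(p1$loadings[, j] * p2$loadings[, j]))
    expect_equal(p2$scores[, j], s * p1$scores[perm, j], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCA rejects constant columns by name and missing values", {
  x <- cbind(a = 1:5, flat = rep(2, 5))
  expect_error(pca_climate(x), "flat")
  x2 <- cbind(a = c(1, NA, 3), b = c(2, 1, 0))
  expect_error(pca_climate(x2), class = "lightphen_invalid_model")
})

test_that("correlations match the direct formula with exact diagonals", {
  cl <- provenance_climate()
  cm <- correlation_matrix(cl[, c("elevation", "mat", "solar_radiation",
                                  "annual_precip")])
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r, t(cm$r))
  x <- cl$elevation; y <- cl$mat
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(oracle, 0)
  expect_equal(cm$r["elevation", "mat"], oracle, tolerance = 1e-10)
  # p from the t transform on n - 2 df
  n <- 6; tstat <- oracle * sqrt((n - 2) / (1 - oracle^2))
  expect_equal(cm$p["elevation", "mat"], 2 * pt(-abs(tstat), n - 2),
               tolerance = 1e-12)
})

test_that("a perfect linear pair correlates at exactly 1", {
  d <- data.frame(x = 1:8, y = 2 * (1:8) + 1)
  cm <- correlation_matrix(d)
  expect_equal(cm$r["x", "y"], 1)
})

test_that("correlations are invariant to affine rescaling", {
  set.seed(27)
  d <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  d2 <- transform(d, b = 100 * b - 7)
  expect_equal(correlation_matrix(d)$r, correlation_matrix(d2)$r,
               tolerance = 1e-12)
})

test_that("zero-variance variables are flagged, not silently zeroed", {
  d <- data.frame(a = 1:5, flat = rep(3, 5))
  expect_warning(cm <- correlation_matrix(d), "flat")
  expect_true(is.na(cm$r["a", "flat"]))
  expect_error(correlation_matrix(data.frame(a = 1:2, b = 2:1)),
               class = "lightphen_invalid_model")
})

test_that("annual solar mean demands twelve months", {
  expect_equal(annual_solar_mean(rep(15000, 12)), 15000)
  expect_equal(annual_solar_mean(1:12), 6.5)
  expect_error(annual_solar_mean(1:11), class = "lightphen_invalid_spec")
})
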