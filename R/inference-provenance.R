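# Experiment-2 inference: provenance ANOVA with Tukey(-Kramer) HSD, the
# northern/southern region test, climate PCA, the Pearson correlation matrix,
# and the annual solar radiation mean.

#' One-way provenance ANOVA with Tukey HSD
#'
#' F test for a provenance effect on a pigment index across cuttings, followed
#' by all pairwise Tukey HSD comparisons (Tukey-Kramer for unequal group
#' sizes, as required by the 6-versus-4 cutting design). The degenerate case
#' of no between-group variance is defined as F = 0, p = 1.
#'
#' @param values Numeric response (one value per cutting).
#' @param groups Provenance labels, same length.
#' @param alpha Significance level for flags and letters.
#' @return List with `model` (one-row `ModelResult`) and `pairwise` (data
#'   frame with `group_a`, `group_b`, `estimate`, `p_adj`, `p_unadj`,
#'   `significant`; attribute `letters`).
#' @export
oneway_anova_tukey <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop_lightphen("need >= 2 groups with >= 2 values each",
                   "lightphen_invalid_model")
  }
  n <- table(groups)
  gm <- tapply(values, groups, mean)
  ss_between <- sum(n * (gm - mean(values))^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (ss_between == 0) {
    res <- model_result("index", "oneway_anova", "F", 0, df1, df2, 1)
    pw <- all_pairs(levels(groups))
    pw$estimate <- 0; pw$p_adj <- 1; pw$p_unadj <- 1; pw$significant <- FALSE
    attr(pw, "letters") <- letters_from_pairs(levels(groups), pw, alpha)
    return(list(model = res, pairwise = pw))
  }
  fit <- stats::aov(values ~ groups)
  a <- summary(fit)[[1]]
  res <- model_result("index", "oneway_anova", "F", a$`F value`[1],
                      a$Df[1], a$Df[2], a$`Pr(>F)`[1])
  tk <- stats::TukeyHSD(fit)$groups
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  sigma2 <- a$`Mean Sq`[2]
  pw <- data.frame(
    group_a = vapply(parts, `[`, "", 1L),
    group_b = vapply(parts, `[`, "", 2L),
    estimate = tk[, "diff"],
    p_adj = tk[, "p adj"]
  )
  se <- sqrt(sigma2 * (1 / n[pw$group_a] + 1 / n[pw$group_b]))
  pw$p_unadj <- 2 * stats::pt(-abs(pw$estimate / se), df2)
  pw$significant <- pw$p_adj < alpha
  rownames(pw) <- NULL
  attr(pw, "letters") <- letters_from_pairs(levels(groups), pw, alpha)
  list(model = res, pairwise = pw)
}

all_pairs <- function(lv) {
  idx <- utils::combn(length(lv), 2)
  data.frame(group_a = lv[idx[2, ]], group_b = lv[idx[1, ]])
}

#' Northern-versus-southern test on provenance means
#'
#' One-way ANOVA of per-provenance mean indices on the two-level region
#' factor (df = 1 and n - 2; 1 and 4 in the six-provenance design).
#'
#' @param means Per-provenance mean index values.
#' @param regions Region labels (exactly two levels, >= 2 provenances each).
#' @return One-row `ModelResult` data frame.
#' @export
region_means_test <- function(means, regions) {
  regions <- droplevels(as.factor(regions))
  if (nlevels(regions) != 2) {
    stop_lightphen("regions must have exactly 2 levels", "lightphen_invalid_model")
  }
  if (any(table(regions) < 2)) {
    stop_lightphen("need >= 2 provenances per region", "lightphen_invalid_model")
  }
  rm_ <- tapply(means, regions, mean)
  ss_between <- sum(table(regions) * (rm_ - mean(means))^2)
  df2 <- length(means) - 2L
  if (ss_between == 0) {
    return(model_result("region", "oneway_anova", "F", 0, 1, df2, 1))
  }
  a <- summary(stats::aov(means ~ regions))[[1]]
  model_result("region", "oneway_anova", "F", a$`F value`[1], a$Df[1],
               a$Df[2], a$`Pr(>F)`[1])
}

#' Scaled and centered PCA of provenance climate
#'
#' Column-standardized principal component analysis (each variable centered
#' and scaled to unit variance). Component count is `min(rows - 1, columns)`.
#'
#' @param x Numeric matrix or data frame, provenances x climate variables; no
#'   missing values, no constant columns.
#' @return Object of class `pca_result`: list with `loadings` (variables x
#'   components, orthonormal columns), `scores` (provenances x components),
#'   `variance_fraction`.
#' @export
pca_climate <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 2 || ncol(x) < 2) {
    stop_lightphen("need a numeric matrix with >= 2 rows and >= 2 columns",
                   "lightphen_invalid_model")
  }
  if (anyNA(x)) stop_lightphen("missing values not allowed", "lightphen_invalid_model")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop_lightphen(paste0("constant column(s): ", paste(nm, collapse = ", ")),
                   "lightphen_invalid_model")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(nrow(x) - 1L, ncol(x))
  total_var <- sum(p$sdev^2)
  structure(list(loadings = p$rotation[, seq_len(k), drop = FALSE],
                 scores = p$x[, seq_len(k), drop = FALSE],
                 variance_fraction = p$sdev[seq_len(k)]^2 / total_var),
            class = "pca_result")
}

#' Pearson correlation matrix with per-cell significance
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. No multiplicity adjustment is applied (significance is reported
#' per cell). A zero-variance variable yields missing correlations and a
#' warning rather than a silent zero.
#'
#' @param df Data frame or matrix of numeric variables (columns).
#' @return Object of class `correlation_matrix`: list with symmetric `r`
#'   (unit diagonal), `p` (diagonal `NA`), and `n` (pairs used).
#' @export
correlation_matrix <- function(df) {
  x <- as.matrix(df)
  stopifnot(is.numeric(x), ncol(x) >= 2)
  v <- ncol(x)
  nm <- colnames(x)
  r <- diag(1, v); pmat <- matrix(NA_real_, v, v); nmat <- matrix(NA_real_, v, v)
  dimnames(r) <- dimnames(pmat) <- dimnames(nmat) <- list(nm, nm)
  degenerate <- character(0)
  for (i in seq_len(v)) {
    for (j in seq_len(i - 1L)) {
      ok <- stats::complete.cases(x[, c(i, j)])
      n <- sum(ok)
      if (n < 3) stop_lightphen("need >= 3 complete pairs per variable pair",
                                "lightphen_invalid_model")
      xi <- x[ok, i]; xj <- x[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        degenerate <- union(degenerate,
                            nm[c(i, j)][c(stats::sd(xi) == 0, stats::sd(xj) == 0)])
        rij <- NA_real_; pij <- NA_real_
      } else {
        rij <- stats::cor(xi, xj)
        if (abs(rij) >= 1) {
          pij <- 0
        } else {
          tstat <- rij * sqrt((n - 2) / (1 - rij^2))
          pij <- 2 * stats::pt(-abs(tstat), n - 2)
        }
      }
      r[i, j] <- r[j, i] <- rij
      pmat[i, j] <- pmat[j, i] <- pij
      nmat[i, j] <- nmat[j, i] <- n
    }
    nmat[i, i] <- sum(!is.na(x[, i]))
  }
  if (length(degenerate) > 0) {
    warning("zero-variance variable(s): ", paste(degenerate, collapse = ", "),
            "; correlations set missing", call. = FALSE)
  }
  structure(list(r = r, p = pmat, n = nmat), class = "correlation_matrix")
}

#' Mean annual solar radiation from monthly values
#'
#' Arithmetic mean of exactly 12 monthly solar radiation values
#' (kJ m^-2 day^-1).
#'
#' @param monthly Numeric vector of length 12.
#' @return Scalar mean.
#' @export
annual_solar_mean <- function(monthly) {
  if (length(monthly) != 12L) {
    stop_lightphen("need exactly 12 monthly values", "lightphen_invalid_spec")
  }
  mean(monthly)
}
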