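# Experiment-1 inference: treatment models with a block random effect,
# singular-fit reduction, Type-II ANOVA, Tukey contrasts, and the survival GLM.

model_result <- function(response, model_form, statistic_kind, statistic,
                         df1, df2 = NA_real_, p_value, singular_fit = FALSE,
                         reduced = FALSE) {
  data.frame(response = response, model_form = model_form,
             statistic_kind = statistic_kind, statistic = statistic,
             df1 = df1, df2 = df2, p_value = p_value,
             singular_fit = singular_fit, reduced = reduced)
}

#' Fit the treatment model for one trait
#'
#' Fits a linear mixed model `response ~ treatment + (1 | block)` (REML). If
#' the block variance is estimated at (or within tolerance of) zero -- a
#' singular fit -- the model is reduced to the simple linear regression
#' `response ~ treatment` and flagged accordingly.
#'
#' @param data Seedling table with `treatment`, `block`, and the response.
#' @param response Name of the response trait column.
#' @param singular_tol Reduction triggers when the block variance is below
#'   `singular_tol` times the residual variance (or when the optimizer reports
#'   a boundary fit).
#' @return Object of class `treatment_fit`: list with the fitted model
#'   (`merMod` or `lm`), `model_form`, `singular_fit`, `reduced`, `response`,
#'   and the complete-case data used.
#' @export
fit_treatment_model <- function(data, response, singular_tol = 1e-8) {
  stopifnot(all(c("treatment", "block", response) %in% names(data)))
  dd <- data[!is.na(data[[response]]), , drop = FALSE]
  dd$treatment <- droplevels(as.factor(dd$treatment))
  dd$block <- as.factor(dd$block)
  if (nrow(dd) == 0) {
    stop_lightphen(paste0("all values of ", response, " are missing"),
                   "lightphen_invalid_model")
  }
  tab <- table(dd$treatment)
  if (length(tab) < 2 || sum(tab >= 2) < 2) {
    stop_lightphen("need >= 2 treatments with >= 2 observations each",
                   "lightphen_invalid_model")
  }
  f <- stats::as.formula(paste(response, "~ treatment + (1 | block)"))
  fit <- suppressMessages(lme4::lmer(f, data = dd))
  vc <- as.data.frame(lme4::VarCorr(fit))
  block_var <- vc$vcov[vc$grp == "block"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit) || block_var <= singular_tol * resid_var
  if (singular) {
    fit <- stats::lm(stats::as.formula(paste(response, "~ treatment")), data = dd)
    structure(list(fit = fit, model_form = "simple_linear", singular_fit = TRUE,
                   reduced = TRUE, response = response, data = dd),
              class = "treatment_fit")
  } else {
    structure(list(fit = fit, model_form = "mixed", singular_fit = FALSE,
                   reduced = FALSE, response = response, data = dd),
              class = "treatment_fit")
  }
}

#' Type-II ANOVA for the treatment effect
#'
#' Wald chi-square test for the mixed form, F test for the reduced simple
#' linear form (matching the convention that mixed-effects and generalized
#' linear models report chi-square and simple linear models report F).
#'
#' @param tf A [fit_treatment_model()] result.
#' @return One-row `ModelResult` data frame: `response`, `model_form`,
#'   `statistic_kind` (`"chisq"` or `"F"`), `statistic`, `df1`, `df2`,
#'   `p_value`, `singular_fit`, `reduced`.
#' @export
treatment_anova <- function(tf) {
  stopifnot(inherits(tf, "treatment_fit"))
  if (tf$model_form == "mixed") {
    a <- car::Anova(tf$fit, type = "II")
    i <- match("treatment", rownames(a))
    model_result(tf$response, "mixed", "chisq", a$Chisq[i], a$Df[i],
                 NA_real_, a$`Pr(>Chisq)`[i])
  } else {
    a <- car::Anova(tf$fit, type = "II")
    i <- match("treatment", rownames(a))
    r <- match("Residuals", rownames(a))
    model_result(tf$response, "simple_linear", "F", a$`F value`[i], a$Df[i],
                 a$Df[r], a$`Pr(>F)`[i], singular_fit = tf$singular_fit,
                 reduced = tf$reduced)
  }
}

#' Tukey-adjusted pairwise treatment contrasts
#'
#' All pairwise differences of adjusted (model-based) treatment means with
#' Tukey family-wise adjustment; Satterthwaite denominator degrees of freedom
#' for the mixed form. A compact letter display is attached as the
#' `"letters"` attribute (groups sharing a letter do not differ at `alpha`).
#'
#' @param tf A [fit_treatment_model()] result.
#' @param alpha Significance level for the `significant` flag and letters.
#' @return Data frame with `group_a`, `group_b`, `estimate`, `se`, `df`,
#'   `p_adj`, `p_unadj`, `significant`; attribute `letters`.
#' @export
tukey_pairwise <- function(tf, alpha = 0.05) {
  stopifnot(inherits(tf, "treatment_fit"))
  if (nlevels(tf$data$treatment) < 2) {
    stop_lightphen("need >= 2 groups for pairwise contrasts",
                   "lightphen_invalid_model")
  }
  emm <- if (tf$model_form == "mixed") {
    emmeans::emmeans(tf$fit, "treatment", lmer.df = "satterthwaite")
  } else {
    emmeans::emmeans(tf$fit, "treatment")
  }
  ctr <- emmeans::contrast(emm, method = "pairwise")
  adj <- as.data.frame(summary(ctr, adjust = "tukey"))
  una <- as.data.frame(summary(ctr, adjust = "none"))
  parts <- strsplit(as.character(adj$contrast), " - ", fixed = TRUE)
  out <- data.frame(
    group_a = vapply(parts, `[`, "", 1L),
    group_b = vapply(parts, `[`, "", 2L),
    estimate = adj$estimate, se = adj$SE, df = adj$df,
    p_adj = adj$p.value, p_unadj = una$p.value
  )
  out$significant <- out$p_adj < alpha
  attr(out, "letters") <- letters_from_pairs(levels(tf$data$treatment), out, alpha)
  out
}

letters_from_pairs <- function(groups, pairs, alpha) {
  differs <- matrix(FALSE, length(groups), length(groups),
                    dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    if (isTRUE(pairs$p_adj[i] < alpha)) {
      differs[pairs$group_a[i], pairs$group_b[i]] <- TRUE
      differs[pairs$group_b[i], pairs$group_a[i]] <- TRUE
    }
  }
  compact_letters(groups, differs)
}

#' Likelihood-ratio test for a treatment effect on survival
#'
#' Fits a logit-link binomial GLM to grouped survival counts and reports the
#' likelihood-ratio chi-square for the treatment factor (df = groups - 1).
#' Because the treatment model saturates grouped data, the statistic equals
#' the null deviance of the intercept-only model,
#' `2 * sum(y*log(y/yhat) + (n-y)*log((n-y)/(n-yhat)))`.
#'
#' @param survivors Integer vector of survivor counts per group.
#' @param totals Integer vector of group sizes.
#' @param labels Optional group labels.
#' @return One-row `ModelResult` data frame (`statistic_kind = "chisq"`).
#' @examples
#' survival_lr_test(c(22, 15, 19), c(24, 24, 24))  # chisq = 6.19, df = 2
#' @export
survival_lr_test <- function(survivors, totals,
                             labels = paste0("g", seq_along(survivors))) {
  stopifnot(length(survivors) == length(totals))
  if (length(survivors) < 2) stop_lightphen("need >= 2 groups",
                                            "lightphen_invalid_model")
  if (any(totals <= 0)) stop_lightphen("group totals must be > 0",
                                       "lightphen_invalid_model")
  if (any(survivors < 0) || any(survivors > totals)) {
    stop_lightphen("survivors must lie in [0, total] per group",
                   "lightphen_invalid_model")
  }
  grp <- factor(labels, levels = labels)
  fit <- stats::glm(cbind(survivors, totals - survivors) ~ grp,
                    family = stats::binomial())
  stat <- fit$null.deviance - fit$deviance  # deviance = 0: model saturates groups
  df <- length(survivors) - 1L
  model_result("survival", "glm_binomial", "chisq", stat, df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Plant-level survival test from a seedling table
#'
#' Convenience wrapper over [survival_lr_test()]: tabulates survivors per
#' treatment from a seedling table. `include_block = TRUE` instead fits a
#' logistic mixed model with a block random intercept and reports the LR test
#' for treatment from it (flagging a singular block fit); the reduced,
#' block-free model is the default report.
#'
#' @param data Seedling table with `treatment`, `block`, `survived`.
#' @param include_block Fit the block random intercept instead of the reduced
#'   model.
#' @return One-row `ModelResult` data frame.
#' @export
survival_test <- function(data, include_block = FALSE) {
  stopifnot(all(c("treatment", "survived") %in% names(data)))
  if (!include_block) {
    tab <- table(data$treatment, data$survived)
    tot <- rowSums(tab)
    surv <- tapply(data$survived, data$treatment, sum)
    return(survival_lr_test(as.integer(surv), as.integer(tot),
                            labels = names(surv)))
  }
  full <- lme4::glmer(survived ~ treatment + (1 | block), data = data,
                      family = stats::binomial())
  null <- lme4::glmer(survived ~ 1 + (1 | block), data = data,
                      family = stats::binomial())
  lrt <- stats::anova(null, full)
  res <- model_result("survival", "glm_binomial", "chisq",
                      lrt$Chisq[2], lrt$Df[2],
                      p_value = lrt$`Pr(>Chisq)`[2],
                      singular_fit = lme4::isSingular(full))
  res
}

#' Root:shoot allometry check
#'
#' Fits `rs ~ total_biomass * treatment` and reports Type-II tests for the
#' biomass main effect, the treatment main effect, and their interaction. A
#' non-significant biomass main effect and interaction indicate that
#' developmental stage did not differentially shift biomass partitioning
#' across treatments.
#'
#' @param data Seedling table with `rs`, `total_biomass`, `treatment`.
#' @return `ModelResult` data frame with one row per term.
#' @export
rs_allometry_check <- function(data) {
  stopifnot(all(c("rs", "total_biomass", "treatment") %in% names(data)))
  dd <- data[stats::complete.cases(data[c("rs", "total_biomass", "treatment")]), ]
  dd$treatment <- droplevels(as.factor(dd$treatment))
  if (any(table(dd$treatment) < 3)) {
    stop_lightphen("need >= 3 complete plants per treatment",
                   "lightphen_invalid_model")
  }
  fit <- stats::lm(rs ~ total_biomass * treatment, data = dd)
  a <- car::Anova(fit, type = "II")
  terms <- c("total_biomass", "treatment", "total_biomass:treatment")
  r <- match("Residuals", rownames(a))
  do.call(rbind, lapply(terms, function(tm) {
    i <- match(tm, rownames(a))
    model_result(paste0("rs ~ ", tm), "simple_linear", "F", a$`F value`[i],
                 a$Df[i], a$Df[r], a$`Pr(>F)`[i])
  }))
}
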