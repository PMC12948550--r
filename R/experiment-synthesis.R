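default_treatment_means <- function() {
  list(
    ndai = c(shade = -0.12, ambient = -0.10, supplemental = 0.02),
    ndvi = c(shade = 0.18, ambient = 0.17, supplemental = 0.17),
    delta_projected_area = c(shade = 0.00, ambient = -0.03, supplemental = -0.10),
    sla = c(shade = 0.25, ambient = 0.24, supplemental = 0.20),
    srl = c(shade = 30.51, ambient = 36.99, supplemental = 31.07),
    rs = c(shade = 0.22, ambient = 0.22, supplemental = 0.24),
    total_biomass = c(shade = 3.89, ambient = 4.78, supplemental = 4.75)
  )
}

default_residual_sd <- function() {
  c(ndai = 0.05, ndvi = 0.06, delta_projected_area = 0.05, sla = 0.06,
    srl = 16, rs = 0.18, total_biomass = 3.2)
}

# lower physical floors for strictly positive traits (balance / scanner
# resolution scale); additive-normal draws are truncated here
trait_floors <- c(sla = 0.01, srl = 0.5, rs = 0.01, total_biomass = 0.2)

#' Specify a blocked light-treatment seedling experiment
#'
#' Describes the stratified greenhouse design: `n_per_cell` seedlings in each
#' treatment x block cell (8 x 3 treatments x 3 blocks = 72 at defaults).
#' Each trait follows the additive model
#' `value = treatment mean + block effect + residual`, with block effects
#' `Normal(0, block_sd)` shared by all plants of a block (per trait) and
#' residuals `Normal(0, residual_sd)`. Survival is Bernoulli per plant with a
#' per-treatment probability; plants that die carry no end-of-experiment
#' measurements. Default trait targets and residual spreads follow the
#' greenhouse experiment's reported group means and standard errors; default
#' survival probabilities are 22/24, 15/24, 19/24.
#'
#' @param n_per_cell Seedlings per treatment x block cell.
#' @param n_blocks Number of blocks.
#' @param treatment_means Named list: one numeric vector per trait giving the
#'   per-treatment target means (length = number of treatments).
#' @param block_sd,residual_sd Per-trait standard deviations, recycled from a
#'   scalar or matched by trait name. `block_sd` defaults to half the residual
#'   sd (block variance is typically small relative to residual variance in
#'   this design).
#' @param survival_prob Per-treatment survival probabilities in `[0, 1]`.
#' @param treatments Treatment labels.
#' @param seed Integer seed.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(n_per_cell = 8L, n_blocks = 3L,
                              treatment_means = default_treatment_means(),
                              block_sd = NULL, residual_sd = NULL,
                              survival_prob = c(shade = 22 / 24, ambient = 15 / 24,
                                                supplemental = 19 / 24),
                              treatments = treatment_levels, seed = 1L) {
  k <- length(treatments)
  stopifnot(is.list(treatment_means), length(treatment_means) >= 1)
  if (!all(vapply(treatment_means, length, 1L) == k)) {
    stop_lightphen("each treatment_means entry needs one value per treatment",
                   "lightphen_invalid_spec")
  }
  traits <- names(treatment_means)
  expand_sd <- function(x, default) {
    if (is.null(x)) x <- default[traits]
    if (length(x) == 1L && is.null(names(x))) x <- rep(x, length(traits))
    if (is.null(names(x)) && length(x) == length(traits)) names(x) <- traits
    x <- x[traits]
    if (any(is.na(x))) stop_lightphen("sd missing for some trait",
                                      "lightphen_invalid_spec")
    if (any(x < 0)) stop_lightphen("standard deviations must be >= 0",
                                   "lightphen_invalid_spec")
    x
  }
  residual_sd <- expand_sd(residual_sd, default_residual_sd())
  block_sd <- expand_sd(block_sd, 0.5 * residual_sd)
  if (length(survival_prob) == 1L) survival_prob <- rep(survival_prob, k)
  if (is.null(names(survival_prob))) names(survival_prob) <- treatments
  survival_prob <- survival_prob[treatments]
  if (any(is.na(survival_prob)) || any(survival_prob < 0) || any(survival_prob > 1)) {
    stop_lightphen("survival_prob must be in [0, 1] per treatment",
                   "lightphen_invalid_spec")
  }
  structure(list(n_per_cell = as.integer(n_per_cell), n_blocks = as.integer(n_blocks),
                 treatments = treatments, treatment_means = treatment_means,
                 block_sd = block_sd, residual_sd = residual_sd,
                 survival_prob = survival_prob, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Generate a seedling trait table
#'
#' Draws one realization of an [experiment_design()]. When the canonical
#' analysis traits (`sla`, `srl`, `rs`, `total_biomass`,
#' `delta_projected_area`) are among the design's traits, a consistent set of
#' raw measurements is back-derived per plant -- component dry masses, leaf
#' area, root length, and the two projected areas -- so that
#' [derive_traits()] on the raw columns reproduces the generated trait values
#' exactly. Shoot mass is split 2:1 leaf:stem; strictly positive traits are
#' truncated at small physical floors before back-derivation.
#'
#' @param design An [experiment_design()].
#' @return Data frame with `plant_id`, `treatment` (factor), `block` (factor),
#'   `survived` (logical), raw measurement columns (when applicable), and one
#'   column per designed trait. Dead plants have missing measurements.
#' @export
generate_seedling_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  k <- length(design$treatments)
  n <- design$n_per_cell * design$n_blocks * k
  treatment <- factor(rep(design$treatments, each = design$n_per_cell * design$n_blocks),
                      levels = design$treatments)
  block <- factor(rep(rep(seq_len(design$n_blocks), each = design$n_per_cell), k))
  traits <- names(design$treatment_means)
  with_seed(design$seed, {
    survived <- stats::rbinom(n, 1L, design$survival_prob[as.integer(treatment)]) == 1L
    df <- data.frame(plant_id = sprintf("p%03d", seq_len(n)),
                     treatment = treatment, block = block, survived = survived)
    vals <- list()
    for (tr in traits) {
      mu <- design$treatment_means[[tr]][as.integer(treatment)]
      beff <- stats::rnorm(design$n_blocks, 0, design$block_sd[[tr]])[as.integer(block)]
      v <- mu + beff + stats::rnorm(n, 0, design$residual_sd[[tr]])
      if (tr %in% names(trait_floors)) v <- pmax(v, trait_floors[[tr]])
      if (tr %in% c("ndai", "ndvi")) v <- pmin(pmax(v, -1), 1)
      v[!survived] <- NA_real_
      vals[[tr]] <- v
    }
    # back-derive raw measurements consistent with the generated traits
    if (all(c("total_biomass", "rs") %in% traits)) {
      shoot <- vals$total_biomass / (1 + vals$rs)
      df$dry_leaf_mass <- 2 / 3 * shoot
      df$dry_stem_mass <- 1 / 3 * shoot
      df$dry_root_mass <- vals$total_biomass - shoot
      if ("sla" %in% traits) df$total_leaf_area <- vals$sla * df$dry_leaf_mass
      if ("srl" %in% traits) df$root_length <- vals$srl * df$dry_root_mass
      if ("delta_projected_area" %in% traits && "sla" %in% traits) {
        df$projected_area_initial <- 0.9 * df$total_leaf_area
        df$projected_area_final <- df$projected_area_initial +
          vals$delta_projected_area * df$total_leaf_area
      }
    }
    for (tr in traits) df[[tr]] <- vals[[tr]]
    df
  })
}
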