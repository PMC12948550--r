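#' Projected area from an aerial image
#'
#' Segments the plant (reusing [segment_plant()]) and converts the foreground
#' pixel count to cm^2 with a user-supplied calibration.
#'
#' @param image Single-channel matrix (or RGB array) of the aerial photograph.
#' @param scale Calibration, pixels per cm (> 0).
#' @param polarity Passed to [segment_plant()]; use `"dark"` for a dark plant
#'   photographed against bright cardstock.
#' @return Data frame with `area` (cm^2), `pixels`, `scale`.
#' @export
area_from_image <- function(image, scale, polarity = "bright") {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop_lightphen("scale must be a positive pixels-per-cm value",
                   "lightphen_invalid_spec")
  }
  mask <- segment_plant(image, polarity = polarity)
  px <- sum(mask$mask)
  data.frame(area = px / scale^2, pixels = px, scale = scale)
}

#' Normalized change in projected area
#'
#' `(a_final - a_initial) / total_leaf_area`: the change in plan-view
#' silhouette area between two timepoints, normalized by the plant's total
#' leaf area so plants of different sizes are comparable. Negative values mean
#' the projected surface decreased over time (e.g. leaves turning pendent);
#' the statistic itself is agnostic to whether change reflects movement or
#' growth.
#'
#' @param a_initial,a_final Projected areas, cm^2 (>= 0).
#' @param total_leaf_area One-sided total leaf area at harvest, cm^2 (> 0).
#' @return Signed dimensionless ratio.
#' @export
change_in_projected_area <- function(a_initial, a_final, total_leaf_area) {
  if (any(total_leaf_area <= 0, na.rm = TRUE)) {
    stop_lightphen("total_leaf_area must be > 0", "lightphen_invalid_spec")
  }
  stopifnot(all(a_initial >= 0, na.rm = TRUE), all(a_final >= 0, na.rm = TRUE))
  (a_final - a_initial) / total_leaf_area
}

#' Derive biomass and architecture traits
#'
#' Adds the derived traits to a seedling table holding the raw measurements:
#' \describe{
#'   \item{sla}{specific leaf area, `total_leaf_area / dry_leaf_mass` (cm^2 mg^-1)}
#'   \item{srl}{specific root length, `root_length / dry_root_mass` (cm mg^-1)}
#'   \item{rs}{root:shoot, `dry_root_mass / (dry_leaf_mass + dry_stem_mass)`}
#'   \item{total_biomass}{`dry_leaf_mass + dry_stem_mass + dry_root_mass` (mg)}
#'   \item{delta_projected_area}{normalized change in projected area}
#' }
#' Missing raw fields propagate to missing derived values (never zero); a zero
#' denominator yields a missing derived value with a warning, and the plant is
#' retained, so per-trait sample sizes can differ.
#'
#' @param df Data frame with (some of) the raw columns `total_leaf_area`,
#'   `dry_leaf_mass`, `dry_stem_mass`, `dry_root_mass`, `root_length`,
#'   `projected_area_initial`, `projected_area_final`.
#' @return `df` with the derived columns added/overwritten.
#' @export
derive_traits <- function(df) {
  stopifnot(is.data.frame(df))
  ratio <- function(num, den, what) {
    bad <- !is.na(den) & den == 0 & !is.na(num)
    if (any(bad)) {
      warning(sprintf("%d plant(s) with zero denominator for %s: derived value set missing",
                      sum(bad), what), call. = FALSE)
    }
    out <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
    out
  }
  has <- function(...) all(c(...) %in% names(df))
  if (has("total_leaf_area", "dry_leaf_mass")) {
    df$sla <- ratio(df$total_leaf_area, df$dry_leaf_mass, "SLA")
  }
  if (has("root_length", "dry_root_mass")) {
    df$srl <- ratio(df$root_length, df$dry_root_mass, "SRL")
  }
  if (has("dry_leaf_mass", "dry_stem_mass", "dry_root_mass")) {
    shoot <- df$dry_leaf_mass + df$dry_stem_mass
    df$rs <- ratio(df$dry_root_mass, shoot, "R:S")
    df$total_biomass <- df$dry_leaf_mass + df$dry_stem_mass + df$dry_root_mass
  }
  if (has("projected_area_initial", "projected_area_final", "total_leaf_area")) {
    df$delta_projected_area <- ratio(df$projected_area_final - df$projected_area_initial,
                                     df$total_leaf_area, "change in projected area")
  }
  df
}

#' Per-trait, per-treatment sample sizes
#'
#' Counts non-missing values of each trait within each treatment, the
#' bookkeeping needed when mortality and unmeasurable tissue make sample sizes
#' trait-specific.
#'
#' @param df Seedling table with a `treatment` column.
#' @param traits Character vector of trait columns to count.
#' @return Data frame, one row per treatment, one column per trait.
#' @export
trait_sample_sizes <- function(df, traits) {
  stopifnot("treatment" %in% names(df), all(traits %in% names(df)))
  counts <- sapply(traits, function(tr) {
    tapply(!is.na(df[[tr]]), df$treatment, sum)
  })
  data.frame(treatment = rownames(counts), counts, row.names = NULL)
}
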