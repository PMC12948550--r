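#' Daily light integral and maximum from a PPFD logger series
#'
#' Splits the series at local midnight into calendar days and, per day,
#' computes the daily light integral `DLI = sum(PPFD) * cadence * 1e-6`
#' (umol -> mol m^-2 d^-1), the daily maximum PPFD, and the number of samples
#' seen (so incomplete days can be filtered by the caller; no imputation is
#' done).
#'
#' @param series A `ppfd_series` or data frame with columns `timestamp`
#'   (seconds) and `ppfd_umol_m2_s`.
#' @param cadence Sampling interval in seconds; by default taken from the
#'   series attribute or inferred as the modal timestamp difference.
#' @return Data frame with columns `day` (0-based day index), `dli`,
#'   `max_ppfd`, `n_samples`.
#' @export
compute_daily_summaries <- function(series, cadence = NULL) {
  d <- as.data.frame(series)
  stopifnot(all(c("timestamp", "ppfd_umol_m2_s") %in% names(d)), nrow(d) > 0)
  if (is.unsorted(d$timestamp, strictly = TRUE)) {
    stop_lightphen("timestamps must be strictly increasing", "lightphen_invalid_series")
  }
  if (any(d$ppfd_umol_m2_s < 0)) {
    stop_lightphen("negative PPFD values", "lightphen_invalid_series")
  }
  if (is.null(cadence)) cadence <- attr(series, "cadence")
  if (is.null(cadence)) {
    if (nrow(d) < 2) stop_lightphen("cannot infer cadence from one sample",
                                    "lightphen_invalid_series")
    dt <- diff(d$timestamp)
    cadence <- as.numeric(names(sort(table(dt), decreasing = TRUE))[1])
  }
  day <- floor(d$timestamp / 86400)
  out <- do.call(rbind, lapply(split(d, day), function(g) {
    data.frame(day = floor(g$timestamp[1] / 86400),
               dli = sum(g$ppfd_umol_m2_s) * cadence * 1e-6,
               max_ppfd = max(g$ppfd_umol_m2_s),
               n_samples = nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Per-treatment summary of spot PPFD measurements
#'
#' Mean and standard error (`sd / sqrt(n)`) of hand-held spot PPFD readings
#' grouped by treatment.
#'
#' @param ppfd Numeric vector of spot readings, umol m^-2 s^-1.
#' @param treatment Grouping labels, same length.
#' @return Data frame with `treatment`, `mean_ppfd`, `se_ppfd`, `n`.
#' @export
spot_summary <- function(ppfd, treatment) {
  stopifnot(length(ppfd) == length(treatment))
  treatment <- as.factor(treatment)
  if (any(table(treatment) < 2)) {
    stop_lightphen("each treatment needs >= 2 spot measurements",
                   "lightphen_invalid_series")
  }
  out <- do.call(rbind, lapply(split(ppfd, treatment), function(v) {
    data.frame(mean_ppfd = mean(v), se_ppfd = stats::sd(v) / sqrt(length(v)),
               n = length(v))
  }))
  data.frame(treatment = rownames(out), out, row.names = NULL)
}

#' Fold ratio of two mean PPFD values
#'
#' `mean_a / mean_b`, rounded half-up to one decimal (matching how fold
#' differences between treatments are conventionally reported).
#'
#' @param mean_a,mean_b Mean PPFD values; `mean_b > 0`.
#' @return Ratio rounded to one decimal.
#' @examples
#' fold_ratio(207.10, 28.46)  # 7.3
#' @export
fold_ratio <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) stop_lightphen("fold_ratio divisor must be > 0",
                                       "lightphen_invalid_series")
  round_half_up(mean_a / mean_b, 1)
}
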