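#' Specify a diurnal PPFD logger profile
#'
#' Emulates a photosynthetically-active-radiation sensor logging PPFD on a
#' fixed cadence under one light treatment. The diurnal course is a half-sine
#' of amplitude `peak_ppfd` over `day_length` hours centred on solar noon,
#' zero at night, with additive Gaussian flicker on daylight samples clipped
#' at 0. Default peaks are calibrated analytically so the treatment mean daily
#' light integrals land on 2.27 (shade), 4.62 (ambient), and 17.24
#' (supplemental) mol m^-2 d^-1 via `DLI = peak * (2/pi) * day_length`.
#'
#' @param treatment `"shade"`, `"ambient"`, or `"supplemental"`.
#' @param peak_ppfd Peak of the half-sine, umol m^-2 s^-1; default by treatment
#'   (71, 144, 537).
#' @param day_length Daylight duration, hours.
#' @param flicker_sd Within-day noise sd, umol m^-2 s^-1; default 10% of peak.
#' @param n_days Number of days to simulate.
#' @param cadence Logging interval in seconds; must divide 86400 (288
#'   samples/day at the default 300 s).
#' @param seed Integer seed.
#' @return An object of class `light_profile`.
#' @export
light_profile <- function(treatment = c("shade", "ambient", "supplemental"),
                          peak_ppfd = NULL, day_length = 14, flicker_sd = NULL,
                          n_days = 30L, cadence = 300L, seed = 1L) {
  treatment <- match.arg(treatment)
  if (is.null(peak_ppfd)) {
    peak_ppfd <- c(shade = 71, ambient = 144, supplemental = 537)[[treatment]]
  }
  if (is.null(flicker_sd)) flicker_sd <- 0.1 * peak_ppfd
  if (peak_ppfd < 0 || flicker_sd < 0) {
    stop_lightphen("peak_ppfd and flicker_sd must be >= 0", "lightphen_invalid_spec")
  }
  if (cadence <= 0 || 86400 %% cadence != 0) {
    stop_lightphen("cadence must be a positive divisor of 86400 s",
                   "lightphen_invalid_spec")
  }
  if (day_length <= 0 || day_length > 24) {
    stop_lightphen("day_length must be in (0, 24] hours", "lightphen_invalid_spec")
  }
  structure(list(treatment = treatment, peak_ppfd = peak_ppfd,
                 day_length = day_length, flicker_sd = flicker_sd,
                 n_days = as.integer(n_days), cadence = as.integer(cadence),
                 seed = as.integer(seed)),
            class = "light_profile")
}

#' Generate a PPFD logger series
#'
#' @param profile A [light_profile()].
#' @return Data frame of class `ppfd_series` with columns `timestamp` (seconds
#'   from series start, at `cadence`) and `ppfd_umol_m2_s`; attributes
#'   `treatment` and `cadence`.
#' @examples
#' s <- generate_ppfd_series(light_profile("shade", flicker_sd = 0, n_days = 1))
#' max(s$ppfd_umol_m2_s)  # = peak
#' @export
generate_ppfd_series <- function(profile) {
  stopifnot(inherits(profile, "light_profile"))
  per_day <- 86400L %/% profile$cadence
  n <- per_day * profile$n_days
  ts <- (seq_len(n) - 1L) * profile$cadence
  tod <- ts %% 86400                       # seconds since local midnight
  half <- profile$day_length * 3600 / 2
  phase <- (tod - 43200 + half) / (profile$day_length * 3600)
  day_part <- phase >= 0 & phase <= 1
  ppfd <- numeric(n)
  ppfd[day_part] <- profile$peak_ppfd * sin(pi * phase[day_part])
  with_seed(profile$seed, {
    if (profile$flicker_sd > 0) {
      ppfd[day_part] <- ppfd[day_part] +
        stats::rnorm(sum(day_part), 0, profile$flicker_sd)
    }
    ppfd <- pmax(ppfd, 0)
  })
  structure(data.frame(timestamp = ts, ppfd_umol_m2_s = ppfd),
            treatment = profile$treatment, cadence = profile$cadence,
            class = c("ppfd_series", "data.frame"))
}

#' Read / write PPFD logger CSV
#'
#' Columns `timestamp,ppfd_umol_m2_s`.
#' @param path CSV path.
#' @param series A `ppfd_series` (or compatible data frame) to write.
#' @export
read_ppfd_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("timestamp", "ppfd_umol_m2_s") %in% names(d))) {
    stop_lightphen("PPFD CSV needs columns timestamp, ppfd_umol_m2_s",
                   "lightphen_io_error")
  }
  structure(d, class = c("ppfd_series", "data.frame"))
}

#' @rdname read_ppfd_csv
#' @export
write_ppfd_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("timestamp", "ppfd_umol_m2_s")],
                   path, row.names = FALSE)
  invisible(path)
}
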