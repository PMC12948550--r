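#' Provenance coordinates and climate summaries
#'
#' Loads the bundled table of the six seed-source provenances: geographic
#' coordinates, mean annual solar radiation (kJ m^-2 day^-1), elevation (m),
#' mean annual temperature (degC), temperature seasonality (sd x 100), annual
#' precipitation (mm), precipitation seasonality (CV), and the
#' northern/southern region assignment (GRF, PSG, HWK northern; SPB, PRV, HI
#' southern).
#'
#' @return Data frame, one row per provenance.
#' @export
provenance_climate <- function() {
  path <- system.file("extdata", "provenance_climate.csv", package = "lightphen",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$region <- factor(d$region, levels = c("northern", "southern"))
  d
}

#' Specify a climate-linked provenance pigment sample
#'
#' Describes the common-garden sampling: one genotype per provenance, several
#' rooted cuttings per genotype, one index value per cutting. The provenance
#' mean index is a linear function of one climate variable; cutting values
#' scatter around it with Gaussian between-cutting noise. Defaults emulate the
#' observed NDAI pattern (higher index at colder provenances) via a negative
#' slope on mean annual temperature, with six cuttings everywhere except four
#' at the designated provenance (PSG).
#'
#' @param variable Climate column of [provenance_climate()] driving the mean.
#' @param slope,intercept Linear link from the climate variable to the
#'   provenance mean index.
#' @param cutting_sd Between-cutting standard deviation (>= 0).
#' @param cuttings_per_provenance Cuttings per provenance (>= 2).
#' @param reduced_provenance,reduced_n One provenance sampled at a smaller
#'   size (default PSG at 4).
#' @param index_name Name of the generated index column.
#' @param seed Integer seed.
#' @return Object of class `climate_link`.
#' @export
climate_link <- function(variable = "mat", slope = -0.012, intercept = 0.08,
                         cutting_sd = 0.03, cuttings_per_provenance = 6L,
                         reduced_provenance = "PSG", reduced_n = 4L,
                         index_name = "ndai", seed = 1L) {
  if (cutting_sd < 0) stop_lightphen("cutting_sd must be >= 0",
                                     "lightphen_invalid_spec")
  if (cuttings_per_provenance < 2 || reduced_n < 2) {
    stop_lightphen("need >= 2 cuttings per provenance", "lightphen_invalid_spec")
  }
  structure(list(variable = variable, slope = slope, intercept = intercept,
                 cutting_sd = cutting_sd,
                 cuttings_per_provenance = as.integer(cuttings_per_provenance),
                 reduced_provenance = reduced_provenance,
                 reduced_n = as.integer(reduced_n),
                 index_name = index_name, seed = as.integer(seed)),
            class = "climate_link")
}

#' Generate per-cutting provenance pigment indices
#'
#' @param link A [climate_link()].
#' @param climate Provenance table (default [provenance_climate()]); needs the
#'   `variable` column named in `link`, plus `provenance` and optionally
#'   `region`.
#' @return Data frame with `provenance`, `region` (if available), `cutting`,
#'   and the index column named by `link$index_name`.
#' @export
generate_provenance_pigments <- function(link, climate = provenance_climate()) {
  stopifnot(inherits(link, "climate_link"))
  if (nrow(climate) < 2) {
    stop_lightphen("need >= 2 provenances", "lightphen_invalid_spec")
  }
  if (!link$variable %in% names(climate)) {
    stop_lightphen(paste0("unknown climate variable: ", link$variable),
                   "lightphen_invalid_spec")
  }
  means <- link$intercept + link$slope * climate[[link$variable]]
  n_i <- ifelse(climate$provenance == link$reduced_provenance,
                link$reduced_n, link$cuttings_per_provenance)
  with_seed(link$seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(climate)), function(i) {
      d <- data.frame(provenance = climate$provenance[i],
                      cutting = seq_len(n_i[i]))
      if ("region" %in% names(climate)) d$region <- climate$region[i]
      d[[link$index_name]] <- means[i] + stats::rnorm(n_i[i], 0, link$cutting_sd)
      d
    }))
    rownames(out) <- NULL
    out
  })
}
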