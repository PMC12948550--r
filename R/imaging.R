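#' Segment the plant from a natural-light image
#'
#' Thresholds the natural-light frame with Otsu's method, then cleans the
#' binary image by opening-based reconstruction: connected components of the
#' thresholded mask that survive a 3x3 morphological opening are retained in
#' full (specks vanish, true plant outlines are not eroded), holes are filled,
#' and the largest connected component is kept.
#'
#' @param x A `multispectral_capture` (its `natural` frame is used), a
#'   single-channel matrix in `[0, 255]`, or an H x W x 3 RGB array (reduced to
#'   an excess-green channel `2G - R - B` before thresholding).
#' @param polarity `"bright"` if the plant is brighter than the background in
#'   the masking channel (the default, matching captures taken against a dark
#'   tent), `"dark"` for a dark plant on a bright background (e.g. cardstock).
#' @return An object of class `plant_mask`: list with `mask` (logical matrix)
#'   and `foreground_fraction`.
#' @export
segment_plant <- function(x, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (inherits(x, "multispectral_capture")) x <- x$natural
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] < 3) x <- x[, , 1]
    else x <- 2 * x[, , 2] - x[, , 1] - x[, , 3]  # excess green
  }
  stopifnot(is.matrix(x))
  rng <- range(x)
  if (diff(rng) <= 0) {
    stop_lightphen("masking image is constant; cannot segment",
                   "lightphen_segmentation_failure")
  }
  z <- (x - rng[1]) / diff(rng)
  if (polarity == "dark") z <- 1 - z
  thr <- EBImage::otsu(EBImage::Image(z), range = c(0, 1))
  raw <- z > thr
  mode(raw) <- "integer"
  opened <- EBImage::opening(raw, EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(raw)
  seeds <- setdiff(unique(lab[opened > 0]), 0L)
  recon <- matrix(lab %in% seeds, nrow(x), ncol(x))
  mode(recon) <- "integer"
  filled <- EBImage::fillHull(recon)
  comp <- EBImage::bwlabel(filled)
  sizes <- tabulate(comp[comp > 0])
  if (length(sizes) == 0 || max(sizes) == 0) {
    stop_lightphen("no plant found after cleanup", "lightphen_no_plant")
  }
  mask <- matrix(comp == which.max(sizes), nrow(x), ncol(x))
  structure(list(mask = mask,
                 foreground_fraction = mean(mask)),
            class = "plant_mask")
}

#' Mean pixel intensity over a plant mask
#'
#' Arithmetic mean of the image over foreground pixels only.
#'
#' @param image Single-channel matrix.
#' @param mask A `plant_mask` or logical matrix of the same dimensions.
#' @return Scalar mean intensity.
#' @export
masked_mean_intensity <- function(image, mask) {
  if (inherits(mask, "plant_mask")) mask <- mask$mask
  stopifnot(is.matrix(image), is.logical(mask))
  if (!identical(dim(image), dim(mask))) {
    stop_lightphen("image and mask dimensions differ", "lightphen_dim_mismatch")
  }
  if (!any(mask)) stop_lightphen("mask is empty", "lightphen_no_plant")
  mean(image[mask])
}

#' Normalized difference anthocyanin index
#'
#' `(i_red - i_green) / (i_red + i_green)` on whole-plant masked mean
#' intensities; an anthocyanin proxy (red leaves reflect relatively more red
#' than green light).
#'
#' @param i_green,i_red Non-negative mean intensities.
#' @return Index in `[-1, 1]`.
#' @export
ndai <- function(i_green, i_red) {
  stopifnot(all(i_green >= 0), all(i_red >= 0))
  den <- i_red + i_green
  if (any(den == 0)) stop_lightphen("NDAI undefined: i_red + i_green = 0",
                                    "lightphen_undefined_index")
  (i_red - i_green) / den
}

#' Normalized difference vegetation index
#'
#' `(i_nir - i_red) / (i_nir + i_red)` on whole-plant masked mean intensities;
#' a chlorophyll proxy.
#'
#' @param i_red,i_nir Non-negative mean intensities.
#' @return Index in `[-1, 1]`.
#' @export
ndvi <- function(i_red, i_nir) {
  stopifnot(all(i_red >= 0), all(i_nir >= 0))
  den <- i_nir + i_red
  if (any(den == 0)) stop_lightphen("NDVI undefined: i_nir + i_red = 0",
                                    "lightphen_undefined_index")
  (i_nir - i_red) / den
}

#' Process one capture into pigment indices
#'
#' Segments the plant from the natural-light frame, computes the three masked
#' mean channel intensities, then both indices from those whole-plant means
#' (means first, indices second -- not per-pixel indices averaged).
#'
#' @param capture A `multispectral_capture`.
#' @param polarity Passed to [segment_plant()].
#' @return One-row data frame: `plant_id`, `i_green`, `i_red`, `i_nir`,
#'   `ndai`, `ndvi`.
#' @export
process_capture <- function(capture, polarity = "bright") {
  stopifnot(inherits(capture, "multispectral_capture"))
  mask <- tryCatch(segment_plant(capture, polarity = polarity),
                   lightphen_error = function(e) {
                     stop_lightphen(paste0(capture$plant_id, ": ", conditionMessage(e)),
                                    class(e)[1])
                   })
  ig <- masked_mean_intensity(capture$green, mask)
  ir <- masked_mean_intensity(capture$red, mask)
  inir <- masked_mean_intensity(capture$nir, mask)
  data.frame(plant_id = capture$plant_id, i_green = ig, i_red = ir,
             i_nir = inir, ndai = ndai(ig, ir), ndvi = ndvi(ir, inir))
}

#' @rdname process_capture
#' @param captures List of `multispectral_capture` objects.
#' @export
process_captures <- function(captures, polarity = "bright") {
  do.call(rbind, lapply(captures, process_capture, polarity = polarity))
}
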