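#' Specify a synthetic multispectral rosette scene
#'
#' Describes a single-plant scene imaged under green, red, and near-infrared
#' illumination plus a natural-light frame used for masking. The plant is an
#' overlapping union of ellipses ("leaves") around the frame centre; the union
#' has an analytically known pixel mask, so every scene carries exact ground
#' truth for segmentation and for the pigment indices computed from masked mean
#' intensities.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param n_leaves Number of elliptical leaves (>= 1). Ignored when
#'   `leaf_geometry` is supplied.
#' @param leaf_geometry Optional data frame with one row per leaf and columns
#'   `cx`, `cy` (centre, pixels), `a`, `b` (semi-axes, pixels), and `theta`
#'   (rotation, radians). When `NULL` a rosette layout is drawn from the seed.
#' @param foreground_intensity,background_intensity Named numeric vectors with
#'   elements `green`, `red`, `nir`; per-channel target mean intensities in
#'   `[0, 255]` for plant and background pixels.
#' @param natural_light_contrast Foreground minus background intensity in the
#'   natural-light masking frame (background sits at 40).
#' @param noise_sd Per-pixel Gaussian noise standard deviation, intensity units.
#' @param seed Integer seed; identical spec + seed gives bit-identical scenes.
#'
#' @return An object of class `scene_spec`.
#' @seealso [generate_multispectral_scene()]
#' @export
scene_spec <- function(image_height = 120L, image_width = 120L, n_leaves = 6L,
                       leaf_geometry = NULL,
                       foreground_intensity = c(green = 40, red = 60, nir = 150),
                       background_intensity = c(green = 12, red = 12, nir = 10),
                       natural_light_contrast = 120, noise_sd = 3, seed = 1L) {
  chan <- c("green", "red", "nir")
  if (!all(chan %in% names(foreground_intensity)) ||
      !all(chan %in% names(background_intensity))) {
    stop_lightphen("foreground/background intensities need green, red, nir elements",
                   "lightphen_invalid_spec")
  }
  fg <- foreground_intensity[chan]; bg <- background_intensity[chan]
  if (any(c(fg, bg) < 0) || any(c(fg, bg) > 255)) {
    stop_lightphen("intensities must lie in [0, 255]", "lightphen_invalid_spec")
  }
  if (!is_count(n_leaves) || n_leaves < 1) {
    stop_lightphen("n_leaves must be a count >= 1", "lightphen_invalid_spec")
  }
  if (noise_sd < 0) {
    stop_lightphen("noise_sd must be >= 0", "lightphen_invalid_spec")
  }
  if (natural_light_contrast <= 0 || natural_light_contrast > 215) {
    stop_lightphen("natural_light_contrast must be in (0, 215]",
                   "lightphen_invalid_spec")
  }
  if (!is.null(leaf_geometry)) {
    need <- c("cx", "cy", "a", "b", "theta")
    if (!all(need %in% names(leaf_geometry)) || nrow(leaf_geometry) < 1) {
      stop_lightphen("leaf_geometry needs columns cx, cy, a, b, theta",
                     "lightphen_invalid_spec")
    }
  }
  structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    n_leaves = as.integer(n_leaves), leaf_geometry = leaf_geometry,
    foreground_intensity = fg, background_intensity = bg,
    natural_light_contrast = natural_light_contrast,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "scene_spec")
}

# Rasterize the union of ellipses on the pixel grid (row-major, origin
# top-left, pixel centres at integer coordinates).
rasterize_leaves <- function(geom, h, w) {
  mask <- matrix(FALSE, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (k in seq_len(nrow(geom))) {
    dx <- xs - geom$cx[k]; dy <- ys - geom$cy[k]
    u <- (dx * cos(geom$theta[k]) + dy * sin(geom$theta[k])) / geom$a[k]
    v <- (-dx * sin(geom$theta[k]) + dy * cos(geom$theta[k])) / geom$b[k]
    mask <- mask | (u^2 + v^2 <= 1)
  }
  mask
}

default_rosette <- function(spec) {
  s <- min(spec$image_height, spec$image_width)
  ang <- 2 * pi * (seq_len(spec$n_leaves) - 1) / spec$n_leaves +
    stats::runif(spec$n_leaves, -0.2, 0.2)
  # each petal's semi-major axis exceeds its centre offset, so every petal
  # covers the frame centre: the union is connected and hole-free
  d <- s * stats::runif(spec$n_leaves, 0.08, 0.12)
  data.frame(
    cx = spec$image_width / 2 + d * cos(ang),
    cy = spec$image_height / 2 + d * sin(ang),
    a = s * stats::runif(spec$n_leaves, 0.15, 0.19),
    b = s * stats::runif(spec$n_leaves, 0.055, 0.075),
    theta = ang
  )
}

draw_channel <- function(mask, fg, bg, noise_sd) {
  x <- matrix(bg, nrow(mask), ncol(mask))
  x[mask] <- fg
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  pmin(pmax(x, 0), 255)
}

#' Generate a multispectral scene with ground truth
#'
#' Draws the four single-channel rasters described by a [scene_spec()]:
#' foreground pixels (the ellipse union) from
#' `Normal(foreground_intensity, noise_sd)` and background pixels analogously,
#' clipped to `[0, 255]`; the natural-light frame separates plant from
#' background by `natural_light_contrast`. Ground truth holds the exact mask,
#' the expected masked means, and the NDAI/NDVI implied by them.
#'
#' @param spec A [scene_spec()].
#' @param plant_id Identifier stored with the capture.
#' @return A list with elements `capture` (class `multispectral_capture`:
#'   `plant_id`, `green`, `red`, `nir`, `natural` matrices) and `truth` (class
#'   `scene_ground_truth`: `true_mask`, `true_i_green`, `true_i_red`,
#'   `true_i_nir`, `true_ndai`, `true_ndvi`).
#' @examples
#' sc <- generate_multispectral_scene(scene_spec(noise_sd = 0, seed = 7))
#' sc$truth$true_ndai  # (60 - 40) / (60 + 40) = 0.2
#' @export
generate_multispectral_scene <- function(spec, plant_id = "plant_1") {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_height; w <- spec$image_width
  with_seed(spec$seed, {
    geom <- if (is.null(spec$leaf_geometry)) default_rosette(spec) else spec$leaf_geometry
    mask <- rasterize_leaves(geom, h, w)
    if (!any(mask)) {
      stop_lightphen("leaf ellipses cover no in-frame pixels", "lightphen_invalid_spec")
    }
    # a real rosette has no see-through pin holes: close raster pockets left
    # between crossing petals so the plant region is the hole-filled union
    mask <- EBImage::fillHull(matrix(as.integer(mask), h, w)) > 0
    fg <- spec$foreground_intensity; bg <- spec$background_intensity
    nat_bg <- 40
    capture <- structure(list(
      plant_id = plant_id,
      green = draw_channel(mask, fg[["green"]], bg[["green"]], spec$noise_sd),
      red = draw_channel(mask, fg[["red"]], bg[["red"]], spec$noise_sd),
      nir = draw_channel(mask, fg[["nir"]], bg[["nir"]], spec$noise_sd),
      natural = draw_channel(mask, nat_bg + spec$natural_light_contrast, nat_bg,
                             spec$noise_sd)
    ), class = "multispectral_capture")
    truth <- structure(list(
      true_mask = mask,
      true_i_green = fg[["green"]], true_i_red = fg[["red"]],
      true_i_nir = fg[["nir"]],
      true_ndai = ndai(fg[["green"]], fg[["red"]]),
      true_ndvi = ndvi(fg[["red"]], fg[["nir"]])
    ), class = "scene_ground_truth")
    list(capture = capture, truth = truth)
  })
}

#' Write / read a capture as four PNG files
#'
#' Files are named `<plant_id>_green.png`, `_red.png`, `_nir.png`,
#' `_natural.png`, 8-bit grayscale.
#'
#' @param capture A `multispectral_capture`.
#' @param dir Directory to write into (created if needed).
#' @return `write_capture()` returns the four paths invisibly;
#'   `read_capture()` returns a `multispectral_capture`.
#' @export
write_capture <- function(capture, dir) {
  stopifnot(inherits(capture, "multispectral_capture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(4)
  ch <- c("green", "red", "nir", "natural")
  for (i in seq_along(ch)) {
    paths[i] <- file.path(dir, paste0(capture$plant_id, "_", ch[i], ".png"))
    png::writePNG(capture[[ch[i]]] / 255, paths[i])
  }
  invisible(paths)
}

#' @rdname write_capture
#' @param plant_id Basename prefix of the four files.
#' @export
read_capture <- function(dir, plant_id) {
  ch <- c("green", "red", "nir", "natural")
  imgs <- lapply(ch, function(cc) {
    p <- file.path(dir, paste0(plant_id, "_", cc, ".png"))
    if (!file.exists(p)) stop_lightphen(paste("missing channel file:", p),
                                        "lightphen_io_error")
    x <- png::readPNG(p)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x * 255
  })
  names(imgs) <- ch
  structure(c(list(plant_id = plant_id), imgs), class = "multispectral_capture")
}
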