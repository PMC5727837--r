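# Synthetic WCE-like fixture generator: pinkish mucosa background under a
# smooth nonuniform illumination field, dark-red lesion blobs with sharp
# contours, pixel-accurate ground-truth masks, and controlled noise
# injection.

#' Specification of a synthetic WCE fixture
#'
#' Describes a synthetic capsule-endoscopy-like frame: frame size, number and
#' size of dark-red bleeding lesions, mucosa and lesion colors, the amplitude
#' of a smooth radial illumination field, per-pixel texture noise, an
#' optional circular field-of-view vignette, and the random seed.
#'
#' @param height,width Frame dimensions in pixels (default 480).
#' @param n_lesions Number of lesions; `NULL` (default) draws 1-3 from the
#'   seed.
#' @param lesion_radius_range Numeric 2-vector: min/max lesion semi-axis in
#'   pixels (each >= 2).
#' @param lesion_color RGB triple in [0,1] of lesion tissue (dark red).
#' @param background_color RGB triple in [0,1] of mucosa (pink).
#' @param illumination_gradient Peak-to-trough fractional amplitude of the
#'   radial illumination field, in [0, 0.6].
#' @param texture_noise_sd Standard deviation of the additive Gaussian
#'   texture field on the background.
#' @param fov_vignette If `TRUE`, darken pixels outside the inscribed
#'   circular field of view.
#' @param seed Integer random seed; the fixture is deterministic given the
#'   spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(height = 480L, width = 480L, n_lesions = NULL,
                         lesion_radius_range = c(12, 36),
                         lesion_color = c(0.45, 0.05, 0.05),
                         background_color = c(0.80, 0.45, 0.40),
                         illumination_gradient = 0.3,
                         texture_noise_sd = 0.002,
                         fov_vignette = FALSE,
                         seed = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 8L, width >= 8L)
  if (!is.null(n_lesions)) {
    n_lesions <- as.integer(n_lesions)
    stopifnot(n_lesions >= 0L)
  }
  stopifnot(length(lesion_radius_range) == 2L,
            all(lesion_radius_range >= 2),
            lesion_radius_range[1] <= lesion_radius_range[2])
  stopifnot(length(lesion_color) == 3L, all(lesion_color >= 0),
            all(lesion_color <= 1))
  stopifnot(length(background_color) == 3L, all(background_color >= 0),
            all(background_color <= 1))
  stopifnot(illumination_gradient >= 0, illumination_gradient <= 0.6)
  stopifnot(texture_noise_sd >= 0)
  structure(
    list(height = height, width = width, n_lesions = n_lesions,
         lesion_radius_range = as.numeric(lesion_radius_range),
         lesion_color = as.numeric(lesion_color),
         background_color = as.numeric(background_color),
         illumination_gradient = illumination_gradient,
         texture_noise_sd = texture_noise_sd,
         fov_vignette = isTRUE(fov_vignette),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic WCE-like frame with ground truth
#'
#' Builds the frame described by a [fixture_spec()]: the mucosa base color is
#' modulated by a smooth radial illumination field (bright near a randomly
#' placed optical center, darker towards the periphery), lesions are
#' rendered as anti-aliased random ellipses of the lesion color with a sharp
#' 1.5 px edge, a shared Gaussian texture field is added to all channels, and
#' the ground-truth mask records the exact lesion support. Lesions are
#' rejection-sampled to fit inside the frame without touching each other;
#' generation fails after 1000 rejected placements.
#'
#' @param spec A [fixture_spec()] object.
#' @return An object of class `wce_fixture`: list with `image` (H x W x 3
#'   array in [0,1]), `gt_mask` (H x W logical), and `spec`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(height = 96, width = 96, seed = 3))
#' sum(fx$gt_mask)
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)

  # smooth linear illumination ramp in a random direction: peak 1 on the
  # bright side, 1 - amplitude on the dark side; its luminance histogram is
  # near-uniform, so illumination alone creates no rare gray levels
  ang <- stats::runif(1, 0, 2 * pi)
  proj <- (cc - 1) * cos(ang) + (rr - 1) * sin(ang)
  proj <- (proj - min(proj)) / max(proj - min(proj))
  illum <- 1 - spec$illumination_gradient * proj
  storage.mode(illum) <- "double"

  n_lesions <- if (is.null(spec$n_lesions)) sample(1:3, 1) else spec$n_lesions

  alpha <- matrix(0, h, w)      # lesion coverage in [0,1]
  gt <- matrix(FALSE, h, w)
  edge_px <- 1.5                # contour transition width in pixels
  attempts <- 0L
  placed <- 0L
  while (placed < n_lesions) {
    a <- stats::runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    b <- a * stats::runif(1, 0.8, 1)
    ang <- stats::runif(1, 0, pi)
    margin <- a + edge_px + 2
    feasible <- h > 2 * margin && w > 2 * margin
    cr <- if (feasible) stats::runif(1, margin, h - margin) else NA
    ccol <- if (feasible) stats::runif(1, margin, w - margin) else NA
    ok <- feasible
    if (ok) {
      dr <- rr - cr; dc <- cc - ccol
      u <- dc * cos(ang) + dr * sin(ang)
      v <- -dc * sin(ang) + dr * cos(ang)
      r_ell <- sqrt((u / a)^2 + (v / b)^2)
      # approximate signed distance (px) to the ellipse contour, positive
      # inside
      dist_px <- (1 - r_ell) * min(a, b)
      a_new <- pmin(1, pmax(0, 0.5 + dist_px / edge_px))
      ok <- !any(a_new > 0 & alpha > 0)   # no overlap with earlier lesions
    }
    if (ok) {
      alpha <- pmax(alpha, a_new)
      gt <- gt | (a_new >= 0.5)
      placed <- placed + 1L
    } else {
      attempts <- attempts + 1L
      if (attempts >= 1000L)
        stop("could not place lesions inside the frame (infeasible spec)",
             call. = FALSE)
    }
  }

  texture <- matrix(stats::rnorm(h * w, 0, spec$texture_noise_sd), h, w)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    base <- spec$background_color[ch] * (1 - alpha) +
      spec$lesion_color[ch] * alpha
    img[, , ch] <- base * illum + texture
  }
  if (spec$fov_vignette) {
    fov <- fov_circle_mask(h, w, margin = 2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * ifelse(fov, 1, 0.05)
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, gt_mask = gt, spec = spec),
            class = "wce_fixture")
}

#' @export
print.wce_fixture <- function(x, ...) {
  cat(sprintf("synthetic WCE fixture %d x %d, %d lesion pixel(s), seed %d\n",
              x$spec$height, x$spec$width, sum(x$gt_mask), x$spec$seed))
  invisible(x)
}

#' Corrupt an image with noise
#'
#' Salt-and-pepper noise replaces a fraction `level` of the pixels, half with
#' black and half with white, identically across the three channels.
#' Gaussian noise adds zero-mean noise of variance `level` (on the [0, 1]
#' scale) independently per channel. Output is clipped to [0, 1];
#' `level = 0` returns the input unchanged. Deterministic given `seed`.
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param kind `"salt_pepper"` or `"gaussian"`.
#' @param level Noise level: pixel fraction (salt-and-pepper) or variance
#'   (Gaussian); >= 0.
#' @param seed Integer seed.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
#' @examples
#' img <- array(0.5, c(8, 8, 3))
#' noisy <- add_noise(img, "salt_pepper", 0.5, seed = 1)
#' mean(noisy != img)
add_noise <- function(image, kind = c("salt_pepper", "gaussian"), level,
                      seed = 0L) {
  kind <- match.arg(kind)
  if (!is.finite(level) || level < 0)
    stop("`level` must be >= 0", call. = FALSE)
  if (level == 0) return(image)
  stopifnot(length(dim(image)) == 3L)
  set.seed(as.integer(seed))
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  if (kind == "salt_pepper") {
    hit <- stats::runif(h * w) < level
    val <- ifelse(stats::runif(h * w) < 0.5, 0, 1)
    idx <- which(hit)
    for (ch in seq_len(dim(image)[3])) {
      plane <- out[, , ch]
      plane[idx] <- val[idx]
      out[, , ch] <- plane
    }
  } else {
    out <- image + array(stats::rnorm(length(image), 0, sqrt(level)),
                         dim(image))
  }
  pmin(pmax(out, 0), 1)
}
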