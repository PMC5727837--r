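# End-to-end localization pipeline and its configuration.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the localization pipeline. Defaults
#' are the standard operating point: Log-Gabor bank with 5 scales and 6
#' orientations (min wavelength 6 px, octave spacing, sigma_rho 0.75,
#' sigma_theta 0.6, epsilon 0.01), 256 histogram bins with rarity threshold
#' 1/72 and decay 0.6, color stabilizer 1e-6, equal fusion weights, mean
#' thresholding, no field-of-view restriction, no minimum region area, and
#' 201 ROC thresholds.
#'
#' @param log_gabor A [log_gabor_params()] object.
#' @param intensity An [intensity_params()] object.
#' @param eps_color Stabilizer of the red-proportion denominator.
#' @param weights Fusion weights (edge, intensity, color), summing to 1.
#' @param use_fov If `TRUE`, threshold and evaluate within a circular
#'   field-of-view mask.
#' @param min_area Minimum region area in pixels kept by region extraction.
#' @param n_thresholds ROC threshold count.
#' @param seed Integer seed for operations with randomness (noise injection).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(log_gabor = log_gabor_params(),
                            intensity = intensity_params(),
                            eps_color = 1e-6,
                            weights = rep(1 / 3, 3),
                            use_fov = FALSE,
                            min_area = 1L,
                            n_thresholds = 201L,
                            seed = 0L) {
  stopifnot(inherits(log_gabor, "log_gabor_params"),
            inherits(intensity, "intensity_params"))
  if (!is.finite(eps_color) || eps_color <= 0)
    stop("`eps_color` must be > 0", call. = FALSE)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must be 3 nonnegative numbers summing to 1",
         call. = FALSE)
  structure(
    list(log_gabor = log_gabor, intensity = intensity,
         eps_color = eps_color, weights = weights,
         use_fov = isTRUE(use_fov), min_area = as.integer(min_area),
         n_thresholds = as.integer(n_thresholds), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("wcesaliency pipeline configuration\n")
  cat(sprintf("  Log-Gabor: %d scales x %d orientations, min_wave %.3g, mult %.3g, sigma_rho %.3g, sigma_theta %.3g, epsilon %.3g\n",
              x$log_gabor$n_scales, x$log_gabor$n_orientations,
              x$log_gabor$min_wave, x$log_gabor$mult, x$log_gabor$sigma_rho,
              x$log_gabor$sigma_theta, x$log_gabor$epsilon))
  cat(sprintf("  intensity: %d bins, p_bar %.4g, lambda %.3g\n",
              x$intensity$n_bins, x$intensity$p_bar, x$intensity$lam))
  cat(sprintf("  eps_color %.3g | weights %s | fov %s | min_area %d | roc thresholds %d\n",
              x$eps_color, paste(signif(x$weights, 4), collapse = "/"),
              x$use_fov, x$min_area, x$n_thresholds))
  invisible(x)
}

#' Circular field-of-view mask
#'
#' Logical mask that is `TRUE` inside the inscribed circle of the frame,
#' modelling the circular valid-imaging region of endoscopic optics (the
#' corners of a WCE frame are dark and carry no tissue signal).
#'
#' @param height,width Frame dimensions in pixels.
#' @param margin Pixels subtracted from the inscribed radius (default 0).
#' @return H x W logical matrix.
#' @export
fov_circle_mask <- function(height, width, margin = 0) {
  r0 <- (height + 1) / 2; c0 <- (width + 1) / 2
  rad <- min(height, width) / 2 - margin
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}

#' Compute the three saliency channels of an image
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param config A [pipeline_config()] object.
#' @return List with matrices `edge`, `intensity`, `color` and the luminance
#'   matrix `gray`.
#' @export
compute_saliency_maps <- function(image, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  gray <- rgb_to_gray(image)
  list(
    edge = edge_saliency(gray, config$log_gabor),
    intensity = intensity_saliency(gray, config$intensity),
    color = color_saliency(image, config$eps_color),
    gray = gray
  )
}

#' Localize bleeding regions in a WCE frame
#'
#' Runs the full pipeline: the three saliency channels, weighted fusion,
#' mean thresholding, and 8-connected region extraction.
#'
#' @param image H x W x 3 numeric array in [0, 1] (see [read_rgb_image()]).
#' @param config A [pipeline_config()] object.
#' @param fov_mask Optional logical field-of-view matrix; when `NULL` and
#'   `config$use_fov` is `TRUE`, the inscribed circle of the frame is used.
#' @return An object of class `wce_localization`: list with `maps` (the
#'   three channels + luminance), `fused` (`fused_saliency`), `mask`
#'   (logical matrix with attribute `"threshold"`), `threshold`, and
#'   `regions` (tibble from [extract_regions()]).
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(height = 96, width = 96, seed = 1))
#' loc <- localize_bleeding(fx$image)
#' loc$regions
localize_bleeding <- function(image, config = pipeline_config(),
                              fov_mask = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fov_mask) && config$use_fov)
    fov_mask <- fov_circle_mask(dim(image)[1], dim(image)[2])
  maps <- compute_saliency_maps(image, config)
  fused <- fuse_maps(maps$edge, maps$intensity, maps$color,
                     weights = config$weights)
  mask <- threshold_mask(fused, fov_mask)
  regions <- extract_regions(mask, config$min_area)
  structure(
    list(maps = maps, fused = fused, mask = mask,
         threshold = attr(mask, "threshold"), regions = regions),
    class = "wce_localization"
  )
}

#' @export
print.wce_localization <- function(x, ...) {
  cat(sprintf("bleeding localization: threshold %.4f, %d region(s), %d predicted pixel(s)\n",
              x$threshold, nrow(x$regions), sum(x$mask)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.wce_localization <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n_regions = nrow(x$regions),
                 predicted_pixels = sum(x$mask))
}
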