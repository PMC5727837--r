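# Intensity-rarity and red-proportion saliency channels.

#' Intensity saliency parameters
#'
#' Parameters of the histogram-rarity intensity channel: number of gray-level
#' bins, the probability threshold below which a gray level counts as rare,
#' and the geometric decay factor that grades rarity into saliency steps.
#'
#' @param n_bins Number of histogram bins (>= 2; default 256, one bin per
#'   8-bit gray level).
#' @param p_bar Rarity probability threshold in (0, 1) (default 1/72).
#' @param lam Decay factor in (0, 1) scaling successive interval boundaries
#'   (default 0.6).
#' @return An object of class `intensity_params`.
#' @export
intensity_params <- function(n_bins = 256L, p_bar = 1 / 72, lam = 0.6) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  if (!is.finite(p_bar) || p_bar <= 0 || p_bar >= 1)
    stop("`p_bar` must be in (0, 1)", call. = FALSE)
  if (!is.finite(lam) || lam <= 0 || lam >= 1)
    stop("`lam` must be in (0, 1)", call. = FALSE)
  structure(list(n_bins = n_bins, p_bar = p_bar, lam = lam),
            class = "intensity_params")
}

# Gray value in [0,1] -> integer level 0..n_bins-1, rounded half up.
quantize_gray <- function(image_gray, n_bins) {
  lev <- floor(image_gray * (n_bins - 1) + 0.5)
  pmin(pmax(lev, 0), n_bins - 1)
}

#' Normalized gray-level histogram
#'
#' Quantizes luminance to `n_bins` integer levels and returns per-bin
#' probabilities summing to 1.
#'
#' @param image_gray H x W numeric matrix in [0, 1].
#' @param params An [intensity_params()] object.
#' @return Numeric vector of length `n_bins`; element k+1 is the probability
#'   of gray level k.
#' @export
#' @examples
#' g <- matrix(c(0, 0, 128 / 255, 1), 2, 2)
#' h <- intensity_histogram(g, intensity_params())
#' h[c(1, 129, 256)]
intensity_histogram <- function(image_gray, params = intensity_params()) {
  if (length(image_gray) == 0L) stop("image is empty", call. = FALSE)
  stopifnot(inherits(params, "intensity_params"))
  lev <- quantize_gray(image_gray, params$n_bins)
  tabulate(as.integer(lev) + 1L, nbins = params$n_bins) / length(image_gray)
}

#' Saliency step level for a bin probability
#'
#' Maps a gray-level probability p to the five-step rarity scale:
#' 0 for p > p_bar, 0.25 for lam*p_bar < p <= p_bar, 0.5 for
#' lam^2*p_bar < p <= lam*p_bar, 0.75 for lam^3*p_bar < p <= lam^2*p_bar,
#' and 1 for p <= lam^3*p_bar. Rarer gray levels are more salient.
#'
#' @param p Numeric vector of bin probabilities.
#' @param params An [intensity_params()] object.
#' @return Numeric vector of step values in {0, 0.25, 0.5, 0.75, 1}.
#' @export
intensity_step <- function(p, params = intensity_params()) {
  pb <- params$p_bar; lam <- params$lam
  out <- numeric(length(p))
  out[p <= pb] <- 0.25
  out[p <= lam * pb] <- 0.5
  out[p <= lam^2 * pb] <- 0.75
  out[p <= lam^3 * pb] <- 1
  out
}

#' Intensity saliency map
#'
#' Assigns each pixel the rarity step of its gray-level histogram bin (see
#' [intensity_step()]): pixels whose gray level is common score 0; the rarer
#' the level, the higher the step, up to 1. Because the histogram ignores
#' spatial arrangement, the map is invariant to image rotation.
#'
#' @param image_gray H x W numeric matrix in [0, 1].
#' @param params An [intensity_params()] object.
#' @return H x W numeric matrix with values in {0, 0.25, 0.5, 0.75, 1}.
#' @export
#' @examples
#' g <- matrix(runif(64 * 64), 64, 64)
#' table(intensity_saliency(g))
intensity_saliency <- function(image_gray, params = intensity_params()) {
  probs <- intensity_histogram(image_gray, params)
  lev <- quantize_gray(image_gray, params$n_bins)
  p <- probs[as.integer(lev) + 1L]
  matrix(intensity_step(p, params), nrow(image_gray), ncol(image_gray))
}

#' Red-proportion color saliency map
#'
#' Per-pixel proportion of the red channel,
#' \deqn{S_3(x,y) = \frac{r}{r + g + b + \varepsilon},}
#' with a small stabilizer guarding black pixels. Bleeding tissue is dark
#' red, so its red proportion clearly exceeds that of pinkish mucosa.
#'
#' @param image_rgb H x W x 3 numeric array with channels in [0, 1].
#' @param eps_color Small positive stabilizing constant (default 1e-6).
#' @return H x W numeric matrix of values in [0, 1).
#' @export
#' @examples
#' px <- array(c(1, 0, 0), c(1, 1, 3))
#' color_saliency(px)           # ~1 for pure red
color_saliency <- function(image_rgb, eps_color = 1e-6) {
  stopifnot(length(dim(image_rgb)) == 3L, dim(image_rgb)[3] == 3L)
  if (!is.finite(eps_color) || eps_color <= 0)
    stop("`eps_color` must be > 0", call. = FALSE)
  if (min(image_rgb) < 0 || max(image_rgb) > 1)
    stop("channel values must lie in [0, 1]", call. = FALSE)
  d <- dim(image_rgb)[1:2]
  r <- array(image_rgb[, , 1], d); g <- array(image_rgb[, , 2], d)
  b <- array(image_rgb[, , 3], d)
  r / (r + g + b + eps_color)
}
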