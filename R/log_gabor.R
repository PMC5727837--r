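# Log-Gabor filter bank and phase-congruency edge saliency.
#
# Conventions used throughout the package: a grayscale image is an H x W
# numeric matrix with values in [0, 1], indexed (row, col) with row 1 at the
# top; frequencies are in cycles/pixel on the FFT grid.

#' Log-Gabor filter bank parameters
#'
#' Parameters of the Log-Gabor quadrature filter bank used for
#' phase-congruency edge detection. Defaults are the operating point used for
#' WCE frames: 5 scales, 6 orientations, smallest wavelength 6 px, octave
#' spacing, radial bandwidth 0.75, angular bandwidth 0.6 rad, and a
#' phase-congruency stabilizing constant of 0.01.
#'
#' @param n_scales Number of filter scales (>= 1).
#' @param n_orientations Number of filter orientations (>= 1).
#' @param min_wave Wavelength in pixels of the smallest-scale filter (> 2,
#'   i.e. above the Nyquist wavelength).
#' @param mult Wavelength scaling factor between successive scales (> 1).
#' @param sigma_rho Radial (log-frequency) bandwidth parameter (> 0).
#' @param sigma_theta Angular bandwidth parameter in radians (> 0).
#' @param epsilon Stabilizing constant in the phase-congruency denominator
#'   (> 0).
#' @return An object of class `log_gabor_params`.
#' @export
#' @examples
#' p <- log_gabor_params()
#' p$min_wave
log_gabor_params <- function(n_scales = 5L, n_orientations = 6L,
                             min_wave = 6, mult = 2,
                             sigma_rho = 0.75, sigma_theta = 0.6,
                             epsilon = 0.01) {
  n_scales <- as.integer(n_scales)
  n_orientations <- as.integer(n_orientations)
  if (is.na(n_scales) || n_scales < 1L)
    stop("`n_scales` must be an integer >= 1", call. = FALSE)
  if (is.na(n_orientations) || n_orientations < 1L)
    stop("`n_orientations` must be an integer >= 1", call. = FALSE)
  if (!is.finite(min_wave) || min_wave <= 2)
    stop("`min_wave` must be > 2 (above the Nyquist wavelength)", call. = FALSE)
  if (!is.finite(mult) || mult <= 1)
    stop("`mult` must be > 1", call. = FALSE)
  if (!is.finite(sigma_rho) || sigma_rho <= 0)
    stop("`sigma_rho` must be > 0", call. = FALSE)
  if (!is.finite(sigma_theta) || sigma_theta <= 0)
    stop("`sigma_theta` must be > 0", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("`epsilon` must be > 0", call. = FALSE)
  structure(
    list(n_scales = n_scales, n_orientations = n_orientations,
         min_wave = min_wave, mult = mult,
         sigma_rho = sigma_rho, sigma_theta = sigma_theta,
         epsilon = epsilon),
    class = "log_gabor_params"
  )
}

# FFT-convention normalized frequencies for an n-point axis, in cycles/pixel.
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  (((k + floor(n / 2)) %% n) - floor(n / 2)) / n
}

#' Analytic Log-Gabor transfer value
#'
#' Evaluates the Log-Gabor frequency response
#' \deqn{LG(\rho, \theta) = \exp\!\left(-\frac{\log^2(\rho/f_0)}{2\sigma_\rho^2}\right)
#'       \exp\!\left(-\frac{\Delta\theta^2}{2\sigma_\theta^2}\right)}
#' at polar frequency coordinates (`rho`, `theta`), where `f0` is the center
#' frequency of scale `scale` (the reciprocal of `min_wave * mult^(scale-1)`)
#' and \eqn{\Delta\theta} is the wrapped angular distance to the orientation
#' angle `theta0`. The response at `rho = 0` (DC) is 0 by convention.
#'
#' @param params A [log_gabor_params()] object.
#' @param scale 1-based scale index.
#' @param rho Radial frequency (cycles/pixel); vectorized.
#' @param theta Angular frequency coordinate in radians; vectorized.
#' @param theta0 Filter orientation angle in radians.
#' @return Numeric vector of transfer values in [0, 1].
#' @export
#' @examples
#' p <- log_gabor_params()
#' f0 <- 1 / (p$min_wave * p$mult^(3 - 1))
#' log_gabor_response(p, 3, f0, 0, 0)  # 1 at the filter center
log_gabor_response <- function(params, scale, rho, theta, theta0) {
  stopifnot(inherits(params, "log_gabor_params"))
  if (scale < 1 || scale > params$n_scales)
    stop("`scale` out of range", call. = FALSE)
  f0 <- 1 / (params$min_wave * params$mult^(scale - 1))
  radial <- ifelse(rho > 0,
                   exp(-(log(pmax(rho, .Machine$double.xmin) / f0))^2 /
                         (2 * params$sigma_rho^2)),
                   0)
  dtheta <- atan2(sin(theta - theta0), cos(theta - theta0))
  radial * exp(-dtheta^2 / (2 * params$sigma_theta^2))
}

#' Build a Log-Gabor filter bank on the FFT grid
#'
#' Constructs the frequency-domain transfer grids for all scales and
#' orientations. Orientation angles are \eqn{\theta_0 = k\pi/n} for
#' \eqn{k = 0, \dots, n-1}; the wavelength at scale \eqn{s} (1-based) is
#' `min_wave * mult^(s-1)` and the center frequency its reciprocal. The
#' wrapped angular Gaussian suppresses the reflected half-plane so the filter
#' is effectively one-sided (analytic): filtering a real image and taking
#' real/imaginary parts of the inverse transform yields the even and odd
#' quadrature responses.
#'
#' @param params A [log_gabor_params()] object.
#' @param height,width Grid dimensions in pixels (>= 8).
#' @return An object of class `log_gabor_bank`: a list with `transfer`
#'   (nested list, `transfer[[scale]][[orientation]]` an `height x width`
#'   matrix), `center_freqs` (cycles/pixel per scale), `orientations`
#'   (radians), `params`, and `dim`.
#' @export
#' @examples
#' bank <- build_log_gabor_bank(log_gabor_params(), 64, 64)
#' length(bank$transfer)        # scales
#' bank$center_freqs
build_log_gabor_bank <- function(params, height, width) {
  stopifnot(inherits(params, "log_gabor_params"))
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 8L || width < 8L)
    stop("`height` and `width` must be >= 8", call. = FALSE)

  fy <- fft_freqs(height)             # row frequencies
  fx <- fft_freqs(width)              # column frequencies
  FY <- matrix(fy, height, width)
  FX <- matrix(fx, height, width, byrow = TRUE)
  rho <- sqrt(FY^2 + FX^2)
  theta <- atan2(FY, FX)
  dc <- rho == 0

  orientations <- (seq_len(params$n_orientations) - 1) * pi /
    params$n_orientations
  center_freqs <- 1 / (params$min_wave * params$mult^(seq_len(params$n_scales) - 1))

  log_rho <- matrix(0, height, width)
  log_rho[!dc] <- log(rho[!dc])

  transfer <- vector("list", params$n_scales)
  for (s in seq_len(params$n_scales)) {
    radial <- exp(-(log_rho - log(center_freqs[s]))^2 /
                    (2 * params$sigma_rho^2))
    radial[dc] <- 0
    transfer[[s]] <- vector("list", params$n_orientations)
    for (o in seq_len(params$n_orientations)) {
      dtheta <- atan2(sin(theta - orientations[o]), cos(theta - orientations[o]))
      transfer[[s]][[o]] <- radial * exp(-dtheta^2 / (2 * params$sigma_theta^2))
    }
  }
  structure(
    list(transfer = transfer, center_freqs = center_freqs,
         orientations = orientations, params = params,
         dim = c(height, width)),
    class = "log_gabor_bank"
  )
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat("Log-Gabor filter bank:", x$params$n_scales, "scales x",
      x$params$n_orientations, "orientations on a",
      x$dim[1], "x", x$dim[2], "grid\n")
  cat("center frequencies (cycles/pixel):",
      paste(signif(x$center_freqs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Even and odd quadrature responses for one orientation
#'
#' Filters a grayscale image with every scale of the bank at one orientation
#' and returns the even (real part) and odd (imaginary part) responses of the
#' inverse Fourier transform — the quadrature pair from which local energy
#' and phase congruency are computed. The analytic filter is twice the
#' one-sided transfer grid, so that the even response's effective spectrum is
#' the two-lobed point-symmetric Log-Gabor \eqn{LG(u) + LG(-u)} (the
#' classical even/odd wavelet pair, with unit gain for a cosine at the filter
#' center).
#'
#' @param image_gray H x W numeric matrix in [0, 1].
#' @param bank A [build_log_gabor_bank()] object matching the image size.
#' @param orientation_index 1-based orientation index.
#' @param image_fft Optional precomputed `stats::fft(image_gray)` to avoid
#'   recomputation across orientations.
#' @return List with elements `even` and `odd`, each a list of H x W matrices,
#'   one per scale.
#' @export
quadrature_responses <- function(image_gray, bank, orientation_index,
                                 image_fft = NULL) {
  stopifnot(inherits(bank, "log_gabor_bank"))
  if (!all(dim(image_gray) == bank$dim))
    stop("image and filter bank dimensions disagree", call. = FALSE)
  o <- as.integer(orientation_index)
  if (is.na(o) || o < 1L || o > bank$params$n_orientations)
    stop("`orientation_index` out of range", call. = FALSE)
  if (is.null(image_fft)) image_fft <- stats::fft(image_gray)
  npix <- prod(bank$dim)
  even <- odd <- vector("list", bank$params$n_scales)
  for (s in seq_len(bank$params$n_scales)) {
    resp <- stats::fft(image_fft * (2 * bank$transfer[[s]][[o]]),
                       inverse = TRUE) / npix
    even[[s]] <- Re(resp)
    odd[[s]] <- Im(resp)
  }
  list(even = even, odd = odd)
}

#' Phase-congruency map for one orientation
#'
#' Combines the quadrature responses over all scales into a phase-congruency
#' map:
#' \deqn{PC(x,y) = \frac{\sqrt{(\sum_n e_n)^2 + (\sum_n o_n)^2}}
#'                     {\varepsilon + \sum_n \sqrt{e_n^2 + o_n^2}}}
#' where \eqn{e_n, o_n} are the even and odd responses at scale \eqn{n}.
#' PC is near 1 where frequency components are in phase (step edges, lines)
#' and near 0 in smooth regions; it is invariant to image contrast up to the
#' \eqn{\varepsilon} term. Output is clipped to [0, 1].
#'
#' @inheritParams quadrature_responses
#' @return H x W numeric matrix of phase-congruency values in [0, 1], with
#'   the orientation angle attached as attribute `"orientation"`.
#' @export
pc_orientation_map <- function(image_gray, bank, orientation_index,
                               image_fft = NULL) {
  qr <- quadrature_responses(image_gray, bank, orientation_index, image_fft)
  sum_e <- Reduce(`+`, qr$even)
  sum_o <- Reduce(`+`, qr$odd)
  amp_sum <- Reduce(`+`, Map(function(e, o) sqrt(e^2 + o^2), qr$even, qr$odd))
  pc <- sqrt(sum_e^2 + sum_o^2) / (bank$params$epsilon + amp_sum)
  pc <- pmin(pmax(pc, 0), 1)
  attr(pc, "orientation") <- bank$orientations[orientation_index]
  pc
}

# Symmetric (reflect-with-edge) padding of a matrix by `pad` pixels per side,
# capped at dim-1. Makes the periodic extension continuous so frequency-domain
# filtering does not manufacture edges at the frame border.
reflect_pad <- function(m, pad) {
  pr <- min(pad, nrow(m) - 1L); pc <- min(pad, ncol(m) - 1L)
  ridx <- c(rev(seq_len(pr)), seq_len(nrow(m)), nrow(m) - seq_len(pr) + 1L)
  cidx <- c(rev(seq_len(pc)), seq_len(ncol(m)), ncol(m) - seq_len(pc) + 1L)
  m[ridx, cidx, drop = FALSE]
}

#' Phase-congruency maps for all orientations
#'
#' Computes the per-orientation phase-congruency maps of an image. To avoid
#' spurious responses from the FFT's periodicity assumption, the image is
#' symmetrically extended by `pad` pixels per side before filtering and the
#' maps are cropped back afterwards.
#'
#' @param image_gray H x W numeric matrix in [0, 1].
#' @param params A [log_gabor_params()] object.
#' @param pad Reflect-padding width in pixels; the default, half the
#'   largest filter wavelength, suppresses the border wrap artifact of all
#'   scales. Use 0 for raw FFT-grid filtering.
#' @return List of H x W phase-congruency matrices, one per orientation,
#'   with the orientation angles attached as attribute `"orientations"`.
#' @export
pc_maps <- function(image_gray, params = log_gabor_params(), pad = NULL) {
  if (length(image_gray) == 0L) stop("image is empty", call. = FALSE)
  if (is.null(pad))
    pad <- ceiling(params$min_wave * params$mult^(params$n_scales - 1) / 2)
  padded <- if (pad > 0) reflect_pad(image_gray, pad) else image_gray
  bank <- build_log_gabor_bank(params, nrow(padded), ncol(padded))
  image_fft <- stats::fft(padded)
  pr <- nrow(padded) - nrow(image_gray)   # total padding actually applied
  pc_list <- vector("list", params$n_orientations)
  rows <- (pr / 2 + 1):(pr / 2 + nrow(image_gray))
  pcc <- ncol(padded) - ncol(image_gray)
  cols <- (pcc / 2 + 1):(pcc / 2 + ncol(image_gray))
  for (o in seq_len(params$n_orientations)) {
    pc <- pc_orientation_map(padded, bank, o, image_fft)
    pc_list[[o]] <- pc[rows, cols, drop = FALSE]
  }
  attr(pc_list, "orientations") <- bank$orientations
  pc_list
}

#' Maximum singular-value moment of orientation PC maps
#'
#' Given per-orientation phase-congruency maps, forms
#' \eqn{C_x = \sum_d (PC_d \sin\theta_d)^2},
#' \eqn{C_y = \sum_d (PC_d \cos\theta_d)^2},
#' \eqn{C_{xy} = \sum_d PC_d\cos\theta_d \cdot PC_d\sin\theta_d}
#' and returns the larger eigenvalue of \eqn{[[C_y, C_{xy}], [C_{xy}, C_x]]},
#' \eqn{\tfrac12(C_x + C_y + \sqrt{(C_x - C_y)^2 + 4C_{xy}^2})}, at every
#' pixel.
#'
#' @param pc_list List of H x W PC matrices with attribute `"orientations"`
#'   (from [pc_maps()]), or a plain list plus explicit `orientations`.
#' @param orientations Orientation angles in radians (defaults to the
#'   attribute).
#' @return H x W numeric matrix of raw (unnormalized) moment values.
#' @export
edge_moment <- function(pc_list, orientations = attr(pc_list, "orientations")) {
  stopifnot(length(pc_list) == length(orientations))
  d <- dim(pc_list[[1]])
  cx <- cy <- cxy <- matrix(0, d[1], d[2])
  for (o in seq_along(pc_list)) {
    pc <- pc_list[[o]]; th <- orientations[o]
    cx <- cx + (pc * sin(th))^2
    cy <- cy + (pc * cos(th))^2
    cxy <- cxy + (pc * cos(th)) * (pc * sin(th))
  }
  0.5 * (cx + cy + sqrt((cx - cy)^2 + 4 * cxy^2))
}

#' Phase-congruency edge saliency map
#'
#' Computes per-orientation phase-congruency maps, forms the 2 x 2
#' orientation-covariance entries
#' \eqn{C_x = \sum_d (PC_d \sin\theta_d)^2},
#' \eqn{C_y = \sum_d (PC_d \cos\theta_d)^2},
#' \eqn{C_{xy} = \sum_d PC_d\cos\theta_d \cdot PC_d\sin\theta_d},
#' and takes the maximum singular-value moment
#' \deqn{S_1 = \tfrac12\left(C_x + C_y + \sqrt{(C_x - C_y)^2 + 4C_{xy}^2}\right),}
#' the larger eigenvalue of \eqn{[[C_y, C_{xy}], [C_{xy}, C_x]]}, which is
#' large where edge energy concentrates along one direction. The map is then
#' rescaled to [0, 1] by its maximum (a constant-zero map is returned
#' unchanged).
#'
#' @param image_gray H x W numeric matrix in [0, 1].
#' @param params A [log_gabor_params()] object.
#' @param pad Reflect-padding width passed to [pc_maps()] (default half the
#'   largest filter wavelength).
#' @param normalize If `FALSE`, return the raw moment without per-image max
#'   rescaling (used for oracle checks).
#' @return H x W numeric matrix: the edge saliency map in [0, 1].
#' @export
#' @examples
#' img <- matrix(0.2, 32, 32); img[, 17:32] <- 0.8
#' s1 <- edge_saliency(img)
#' range(s1)
edge_saliency <- function(image_gray, params = log_gabor_params(),
                          pad = NULL, normalize = TRUE) {
  pcs <- pc_maps(image_gray, params, pad)
  s1 <- edge_moment(pcs)
  if (normalize) {
    m <- max(s1)
    # an (effectively) all-zero moment map is returned unrescaled; rescaling
    # by a floating-point residual would amplify numerical noise
    if (m > 1e-12) s1 <- s1 / m
  }
  s1
}

#' Convert an RGB image array to luminance
#'
#' Standard luma weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image_rgb H x W x 3 numeric array in [0, 1].
#' @return H x W numeric matrix in [0, 1].
#' @export
rgb_to_gray <- function(image_rgb) {
  stopifnot(length(dim(image_rgb)) == 3L, dim(image_rgb)[3] == 3L)
  g <- 0.299 * image_rgb[, , 1] + 0.587 * image_rgb[, , 2] +
    0.114 * image_rgb[, , 3]
  array(g, dim(image_rgb)[1:2])
}
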