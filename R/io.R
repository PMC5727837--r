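# Image/mask readers and writers, configuration serialization, and the
# artifact-writing pipeline runner.

#' Read an RGB image
#'
#' Reads a PNG/JPEG/TIFF file into an H x W x 3 array with channels in
#' [0, 1], indexed (row, col, channel) with row 1 at the top. Grayscale
#' files are replicated to three channels; an alpha channel is dropped.
#'
#' @param path Path to the image file.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("cannot decode image %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  dat <- EBImage::imageData(img)          # (x, y[, channel])
  if (length(dim(dat)) == 2L) {
    gray <- t(dat)
    dat <- array(rep(gray, 3), c(dim(gray), 3))
  } else {
    dat <- aperm(dat, c(2, 1, 3))
    if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
    if (dim(dat)[3] == 1L) dat <- array(rep(dat, 3), c(dim(dat)[1:2], 3))
  }
  pmin(pmax(dat, 0), 1)
}

#' Read a binary mask image
#'
#' Reads an image file and returns a logical matrix that is `TRUE` wherever
#' any channel is nonzero, so grayscale masks and RGB annotation overlays
#' both work.
#'
#' @param path Path to the mask image file.
#' @return H x W logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_rgb_image(path)
  img[, , 1] > 0 | img[, , 2] > 0 | img[, , 3] > 0
}

#' Write a saliency map or image as PNG
#'
#' Values are encoded as `round half-up(value * 255)` 8-bit samples;
#' grayscale for matrices, RGB for 3-channel arrays, pure black/white for
#' logical masks.
#'
#' @param x Numeric matrix in [0, 1], H x W x 3 array, or logical matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- ifelse(x, 1, 0)
  q <- floor(pmin(pmax(x, 0), 1) * 255 + 0.5) / 255
  dat <- if (length(dim(q)) == 3L) aperm(q, c(2, 1, 3)) else t(q)
  img <- EBImage::Image(dat,
                        colormode = if (length(dim(q)) == 3L) "Color"
                        else "Grayscale")
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

config_to_list <- function(config) {
  list(
    log_gabor = unclass(config$log_gabor),
    intensity = unclass(config$intensity),
    eps_color = config$eps_color,
    weights = as.numeric(config$weights),
    use_fov = config$use_fov,
    min_area = config$min_area,
    n_thresholds = config$n_thresholds,
    seed = config$seed
  )
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()] object.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to the defaults of [pipeline_config()]; every
#' field is re-validated against its owning type's invariants.
#'
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return A [pipeline_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  lg <- do.call(log_gabor_params, y$log_gabor %||% list())
  ip <- do.call(intensity_params, y$intensity %||% list())
  pipeline_config(
    log_gabor = lg, intensity = ip,
    eps_color = y$eps_color %||% 1e-6,
    weights = y$weights %||% rep(1 / 3, 3),
    use_fov = y$use_fov %||% FALSE,
    min_area = y$min_area %||% 1L,
    n_thresholds = y$n_thresholds %||% 201L,
    seed = y$seed %||% 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run localization and write all artifacts
#'
#' Runs [localize_bleeding()] on an image (path or array) and writes the
#' standard artifact set to `out_dir`: the four saliency PNGs (`edge.png`,
#' `intensity.png`, `color.png`, `fused.png`), the binary mask
#' (`mask.png`), the green-contour overlay (`overlay.png`), the region
#' table (`regions.csv`), and the configuration (`config.yaml`). The
#' computed mean threshold is reported via `message()`.
#'
#' @param image Path to an image file, or an H x W x 3 array in [0, 1].
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if absent).
#' @param dump_filters If `TRUE`, additionally write every Log-Gabor
#'   transfer grid as `filters/lg_s<scale>_o<orientation>.png` (each grid
#'   rescaled by its maximum for display).
#' @return Invisibly, the `wce_localization` result with an added `files`
#'   element naming the written artifacts.
#' @export
run_localize <- function(image, config = pipeline_config(), out_dir = ".",
                         dump_filters = FALSE) {
  if (is.character(image)) image <- read_rgb_image(image)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- localize_bleeding(image, config)
  message(sprintf("mean threshold on fused map: %.6f", res$threshold))

  files <- c(edge = "edge.png", intensity = "intensity.png",
             color = "color.png", fused = "fused.png", mask = "mask.png",
             overlay = "overlay.png", regions = "regions.csv",
             config = "config.yaml")
  files <- vapply(files, function(f) file.path(out_dir, f), character(1))
  write_image_png(res$maps$edge, files[["edge"]])
  write_image_png(res$maps$intensity, files[["intensity"]])
  write_image_png(res$maps$color, files[["color"]])
  write_image_png(res$fused$values, files[["fused"]])
  write_image_png(res$mask, files[["mask"]])
  write_image_png(overlay_mask(image, res$mask), files[["overlay"]])
  utils::write.csv(dplyr::select(res$regions, -"pixels"),
                   files[["regions"]], row.names = FALSE)
  write_config(config, files[["config"]])

  if (dump_filters) {
    fdir <- file.path(out_dir, "filters")
    dir.create(fdir, showWarnings = FALSE)
    bank <- build_log_gabor_bank(config$log_gabor, dim(image)[1],
                                 dim(image)[2])
    for (s in seq_len(config$log_gabor$n_scales))
      for (o in seq_len(config$log_gabor$n_orientations)) {
        g <- bank$transfer[[s]][[o]]
        if (max(g) > 0) g <- g / max(g)
        write_image_png(g, file.path(fdir, sprintf("lg_s%d_o%d.png", s, o)))
      }
  }
  res$files <- files
  invisible(res)
}
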