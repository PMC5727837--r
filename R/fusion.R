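# Saliency fusion, mean thresholding, region extraction, overlay.

#' Fuse saliency maps by weighted averaging
#'
#' Pixel-wise weighted mean of the edge, intensity, and color saliency maps.
#' The default equal weights give \eqn{S = \frac13 \sum_i S_i}; other weight
#' patterns (e.g. `c(0.5, 0.5, 0)`) realize the pairwise channel ablations.
#'
#' @param edge,intensity,color H x W numeric matrices in [0, 1], same shape.
#' @param weights Numeric 3-vector of nonnegative weights summing to 1
#'   (within 1e-9).
#' @return An object of class `fused_saliency`: list with `values` (H x W
#'   matrix in [0, 1]), `components` (the three input maps), and `weights`.
#' @export
#' @examples
#' m <- matrix(0.5, 4, 4)
#' f <- fuse_maps(m, m, m)
#' all(f$values == m)
fuse_maps <- function(edge, intensity, color, weights = rep(1 / 3, 3)) {
  maps <- list(edge = edge, intensity = intensity, color = color)
  d <- dim(edge)
  for (nm in names(maps)) {
    if (!is.numeric(maps[[nm]]) || !identical(dim(maps[[nm]]), d))
      stop("saliency maps must be numeric matrices of identical shape",
           call. = FALSE)
    if (min(maps[[nm]]) < 0 || max(maps[[nm]]) > 1)
      stop(sprintf("`%s` map has values outside [0, 1]", nm), call. = FALSE)
  }
  if (length(weights) != 3L || any(weights < 0))
    stop("`weights` must be 3 nonnegative numbers", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must sum to 1 (within 1e-9)", call. = FALSE)
  values <- weights[1] * edge + weights[2] * intensity + weights[3] * color
  structure(list(values = values, components = maps, weights = weights),
            class = "fused_saliency")
}

#' @export
print.fused_saliency <- function(x, ...) {
  cat("Fused saliency map", nrow(x$values), "x", ncol(x$values),
      "| weights (edge, intensity, color):",
      paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

# Accept either a fused_saliency object or a bare matrix.
saliency_values <- function(map) {
  if (inherits(map, "fused_saliency")) map$values
  else if (is.matrix(map) && is.numeric(map)) map
  else stop("`map` must be a numeric matrix or a fused_saliency object",
            call. = FALSE)
}

#' Threshold a saliency map at its mean
#'
#' Binarizes a saliency map with the adaptive threshold equal to the mean of
#' all map values (computed over the field-of-view pixels when `fov_mask` is
#' supplied). A pixel is predicted bleeding when its value strictly exceeds
#' the threshold, so a constant map yields an empty mask. Pixels outside the
#' field of view are always `FALSE`.
#'
#' @param map Saliency map: numeric matrix in [0, 1] or a `fused_saliency`
#'   object.
#' @param fov_mask Optional logical matrix marking the valid imaging region.
#' @return H x W logical matrix with the applied scalar threshold attached as
#'   attribute `"threshold"`.
#' @export
#' @examples
#' m <- matrix(c(0.1, 0.1, 0.1, 0.9), 2, 2)
#' mk <- threshold_mask(m)
#' sum(mk); attr(mk, "threshold")
threshold_mask <- function(map, fov_mask = NULL) {
  v <- saliency_values(map)
  if (length(v) == 0L) stop("map is empty", call. = FALSE)
  if (is.null(fov_mask)) {
    thr <- mean(v)
    mask <- v > thr
  } else {
    if (!identical(dim(fov_mask), dim(v)))
      stop("`fov_mask` shape disagrees with map", call. = FALSE)
    thr <- mean(v[fov_mask])
    mask <- (v > thr) & fov_mask
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Extract connected bleeding regions from a binary mask
#'
#' Labels 8-connected components of the mask and summarizes each as a region
#' record; components smaller than `min_area` are discarded.
#'
#' @param mask H x W logical matrix.
#' @param min_area Minimum component area in pixels to keep (default 1, i.e.
#'   no filtering).
#' @return A tibble with one row per region: `region`, `area`,
#'   `centroid_row`, `centroid_col`, `bbox_row_min`, `bbox_row_max`,
#'   `bbox_col_min`, `bbox_col_max`, and a list-column `pixels` holding an
#'   n x 2 matrix of (row, col) coordinates.
#' @export
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE; m[6:8, 6:8] <- TRUE
#' extract_regions(m)
extract_regions <- function(mask, min_area = 1) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- tibble::tibble(
    region = integer(), area = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    bbox_row_min = integer(), bbox_row_max = integer(),
    bbox_col_min = integer(), bbox_col_max = integer(),
    pixels = list()
  )
  idx <- which(mask)
  if (length(idx) == 0L) return(empty)

  h <- nrow(mask)
  pos <- arrayInd(idx, dim(mask))          # (row, col) of true pixels
  # 8-neighbourhood adjacency among true pixels via linear-index shifts.
  in_mask <- logical(length(mask))
  in_mask[idx] <- TRUE
  vid <- integer(length(mask))             # linear index -> vertex id
  vid[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (sft in shifts) {
    nr <- pos[, 1] + sft[1]; nc <- pos[, 2] + sft[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(mask)
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    keep <- in_mask[nidx]
    if (any(keep))
      edges[[length(edges) + 1L]] <-
        rbind(vid[idx[ok][keep]], vid[nidx[keep]])
  }
  g <- igraph::make_graph(edges = if (length(edges)) c(do.call(cbind, edges))
                          else integer(0),
                          n = length(idx), directed = FALSE)
  lab <- igraph::components(g)$membership

  rows <- split(seq_along(idx), lab)
  recs <- purrr::map(rows, function(i) {
    p <- pos[i, , drop = FALSE]
    tibble::tibble(
      area = length(i),
      centroid_row = mean(p[, 1]), centroid_col = mean(p[, 2]),
      bbox_row_min = min(p[, 1]), bbox_row_max = max(p[, 1]),
      bbox_col_min = min(p[, 2]), bbox_col_max = max(p[, 2]),
      pixels = list(p)
    )
  })
  out <- dplyr::bind_rows(recs)
  out <- dplyr::filter(out, .data$area >= min_area)
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::arrange(out, dplyr::desc(.data$area))
  dplyr::mutate(out, region = dplyr::row_number(), .before = 1)
}

# TRUE on mask pixels having at least one FALSE 8-neighbour (frame border
# counts as outside), i.e. the inner boundary of the mask.
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  interior <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    interior <- interior & padded[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
  }
  mask & !interior
}

#' Overlay a mask boundary on an image
#'
#' Paints the boundary pixels of the predicted bleeding mask green (0, 1, 0)
#' on a copy of the input image, for visual inspection of suspected regions.
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param mask H x W logical matrix.
#' @return H x W x 3 numeric array: the input with green region contours.
#' @export
overlay_mask <- function(image, mask) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask shapes disagree", call. = FALSE)
  out <- image
  b <- mask_boundary(mask)
  if (any(b)) {
    ch <- dim(image)[1] * dim(image)[2]
    ib <- which(b)
    out[ib] <- 0            # red channel
    out[ib + ch] <- 1       # green channel
    out[ib + 2L * ch] <- 0  # blue channel
  }
  out
}
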