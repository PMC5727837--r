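# Pixel-wise evaluation: confusion counts, sensitivity/specificity/accuracy,
# ROC curves, channel ablations, and the noise-robustness sweep.

#' Combine two ground-truth masks
#'
#' Pixel-to-pixel logical AND of two annotation masks, used to merge masks
#' drawn independently by two readers into a consensus ground truth.
#'
#' @param mask_a,mask_b H x W logical matrices of identical shape.
#' @return H x W logical matrix.
#' @export
combine_gt_masks <- function(mask_a, mask_b) {
  stopifnot(is.logical(mask_a), is.logical(mask_b))
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes disagree", call. = FALSE)
  mask_a & mask_b
}

#' Pixel-wise confusion counts
#'
#' Counts true/false positives and negatives of a predicted bleeding mask
#' against a ground-truth mask, over all pixels or over the field-of-view
#' pixels only.
#'
#' @param pred,gt H x W logical matrices (prediction and ground truth).
#' @param fov_mask Optional logical matrix restricting the evaluated pixels.
#' @return An object of class `wce_confusion`: list with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
#' @examples
#' gt <- matrix(FALSE, 10, 10); gt[1:5, 1:6] <- TRUE
#' confusion(gt, gt)
confusion <- function(pred, gt, fov_mask = NULL) {
  stopifnot(is.logical(pred), is.logical(gt))
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground-truth shapes disagree", call. = FALSE)
  if (!is.null(fov_mask)) {
    if (!identical(dim(fov_mask), dim(gt)))
      stop("`fov_mask` shape disagrees", call. = FALSE)
    pred <- pred[fov_mask]; gt <- gt[fov_mask]
  }
  structure(
    list(tp = sum(pred & gt), fp = sum(pred & !gt),
         tn = sum(!pred & !gt), fn = sum(!pred & gt)),
    class = "wce_confusion"
  )
}

#' @export
print.wce_confusion <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d (total %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Sensitivity, specificity, and accuracy from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(FP+TN), accuracy =
#' (TP+TN)/total. A ratio with zero denominator is reported as `NaN` rather
#' than raising an error or silently reporting 0.
#'
#' @param counts A [confusion()] object (or a list with fields tp, fp, tn,
#'   fn).
#' @return An object of class `wce_eval`: list with `counts`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
#' @examples
#' metrics(list(tp = 5, tn = 90, fp = 3, fn = 2))$accuracy
metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tot <- counts$tp + counts$fp + counts$tn + counts$fn
  structure(
    list(counts = counts,
         sensitivity = safe_ratio(counts$tp, counts$tp + counts$fn),
         specificity = safe_ratio(counts$tn, counts$fp + counts$tn),
         accuracy = safe_ratio(counts$tp + counts$tn, tot)),
    class = "wce_eval"
  )
}

#' @export
print.wce_eval <- function(x, ...) {
  cat(sprintf("sensitivity %.4f | specificity %.4f | accuracy %.4f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.wce_eval <- function(x, ...) {
  tibble::tibble(
    tp = x$counts$tp, fp = x$counts$fp, tn = x$counts$tn, fn = x$counts$fn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy
  )
}

#' Pixel-wise ROC curve and AUC of a saliency map
#'
#' Sweeps `n_thresholds` uniformly spaced thresholds over [0, 1]; at each, a
#' pixel is predicted bleeding when its saliency strictly exceeds the
#' threshold, giving one (1 - specificity, sensitivity) point. The AUC is the
#' trapezoidal area under the points sorted by false-positive rate, anchored
#' at (0, 0) and (1, 1). If the ground truth contains a single class the AUC
#' is `NaN`.
#'
#' @param map Saliency map: numeric matrix in [0, 1] or `fused_saliency`.
#' @param gt H x W logical ground-truth mask.
#' @param n_thresholds Number of thresholds (>= 2; default 201).
#' @param fov_mask Optional logical matrix restricting evaluated pixels.
#' @return An object of class `wce_roc`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
#' @examples
#' gt <- matrix(FALSE, 16, 16); gt[4:8, 4:8] <- TRUE
#' roc_curve(ifelse(gt, 1, 0), gt)$auc   # perfect predictor
roc_curve <- function(map, gt, n_thresholds = 201L, fov_mask = NULL) {
  v <- saliency_values(map)
  stopifnot(is.logical(gt))
  if (!identical(dim(v), dim(gt)))
    stop("map and ground-truth shapes disagree", call. = FALSE)
  n_thresholds <- as.integer(n_thresholds)
  if (is.na(n_thresholds) || n_thresholds < 2L)
    stop("`n_thresholds` must be >= 2", call. = FALSE)
  if (!is.null(fov_mask)) {
    v <- v[fov_mask]; gt <- gt[fov_mask]
  }
  pos <- sort(v[gt]); neg <- sort(v[!gt])
  np <- length(pos); nn <- length(neg)
  thr <- seq(0, 1, length.out = n_thresholds)
  # count of values strictly above each threshold
  tp <- np - findInterval(thr, pos)
  fp <- nn - findInterval(thr, neg)
  tpr <- if (np > 0) tp / np else rep(NaN, n_thresholds)
  fpr <- if (nn > 0) fp / nn else rep(NaN, n_thresholds)
  points <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- if (np == 0 || nn == 0) NaN else {
    x <- c(0, rev(fpr), 1); y <- c(0, rev(tpr), 1)
    ord <- order(x, y)
    x <- x[ord]; y <- y[ord]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  structure(list(points = points, auc = auc, n_thresholds = n_thresholds),
            class = "wce_roc")
}

#' @export
print.wce_roc <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds | AUC = %.4f\n", x$n_thresholds, x$auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wce_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.wce_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = x$n_thresholds)
}

# The seven channel combinations of the ablation study, as weight vectors
# (edge, intensity, color).
ablation_combinations <- function() {
  list(
    edge               = c(1, 0, 0),
    intensity          = c(0, 1, 0),
    color              = c(0, 0, 1),
    `edge+intensity`   = c(1 / 2, 1 / 2, 0),
    `edge+color`       = c(1 / 2, 0, 1 / 2),
    `intensity+color`  = c(0, 1 / 2, 1 / 2),
    fused              = c(1 / 3, 1 / 3, 1 / 3)
  )
}

#' Channel-ablation evaluation table
#'
#' Evaluates the seven combinations of the edge, intensity, and color
#' channels (three singletons, three equal-weight pairs, and the full
#' equal-weight fusion). Each combined map is thresholded at its own mean
#' and scored pixel-wise against the ground truth.
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param gt H x W logical ground-truth mask.
#' @param config A [pipeline_config()] object.
#' @param fov_mask Optional logical matrix restricting threshold and
#'   evaluation to the field of view.
#' @return A tibble with one row per combination: `combination`, the three
#'   weights, `threshold`, confusion counts, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
ablation_table <- function(image, gt, config = pipeline_config(),
                           fov_mask = NULL) {
  maps <- compute_saliency_maps(image, config)
  combos <- ablation_combinations()
  purrr::imap_dfr(combos, function(w, nm) {
    fused <- fuse_maps(maps$edge, maps$intensity, maps$color, weights = w)
    mask <- threshold_mask(fused, fov_mask)
    ev <- metrics(confusion(mask, gt, fov_mask))
    dplyr::bind_cols(
      tibble::tibble(combination = nm,
                     w_edge = w[1], w_intensity = w[2], w_color = w[3],
                     threshold = attr(mask, "threshold")),
      tidy(ev)
    )
  })
}

# The six noise settings of the robustness protocol.
noise_settings <- function() {
  tibble::tibble(
    kind = c("salt_pepper", "salt_pepper", "salt_pepper",
             "gaussian", "gaussian", "gaussian"),
    level = c(0.02, 0.04, 0.06, 0.005, 0.01, 0.015)
  )
}

#' Noise-robustness sweep
#'
#' Corrupts the image with each of the six standard noise settings
#' (salt-and-pepper densities 2/4/6%; zero-mean Gaussian with variance
#' 0.5/1/1.5% of the unit range), runs the full localization pipeline on each
#' corrupted copy, and reports pixel accuracy. A clean (`kind = "none"`,
#' level 0) row is included as the reference.
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param gt H x W logical ground-truth mask.
#' @param config A [pipeline_config()] object.
#' @param seed Integer seed for the noise injection.
#' @param fov_mask Optional logical field-of-view matrix.
#' @return A tibble with columns `kind`, `level`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
noise_sweep <- function(image, gt, config = pipeline_config(), seed = 0L,
                        fov_mask = NULL) {
  settings <- dplyr::bind_rows(
    tibble::tibble(kind = "none", level = 0),
    noise_settings()
  )
  purrr::pmap_dfr(settings, function(kind, level) {
    img <- if (kind == "none") image else add_noise(image, kind, level, seed)
    res <- localize_bleeding(img, config, fov_mask)
    ev <- metrics(confusion(res$mask, gt, fov_mask))
    tibble::tibble(kind = kind, level = level,
                   sensitivity = ev$sensitivity,
                   specificity = ev$specificity,
                   accuracy = ev$accuracy)
  })
}
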