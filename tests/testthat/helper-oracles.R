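# Shared oracles and small image builders, independent of the package's
# vectorized code paths.

# Per-pixel loop evaluation of the phase-congruency ratio from explicit
# even/odd responses (list of matrices per scale).
pc_loop_oracle <- function(even, odd, epsilon) {
  h <- nrow(even[[1]]); w <- ncol(even[[1]])
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    se <- 0; so <- 0; amp <- 0
    for (s in seq_along(even)) {
      e <- even[[s]][i, j]; o <- odd[[s]][i, j]
      se <- se + e; so <- so + o
      amp <- amp + sqrt(e^2 + o^2)
    }
    out[i, j] <- sqrt(se^2 + so^2) / (epsilon + amp)
  }
  pmin(pmax(out, 0), 1)
}

# Double-loop confusion-count oracle.
confusion_loop_oracle <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] && gt[i, j]) tp <- tp + 1L
    else if (pred[i, j] && !gt[i, j]) fp <- fp + 1L
    else if (!pred[i, j] && !gt[i, j]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Rank-statistic (Mann-Whitney) AUC oracle with tie correction.
auc_rank_oracle <- function(values, gt) {
  pos <- values[gt]; neg <- values[!gt]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Literal interval-membership evaluation of the five-step rarity rule.
step_oracle <- function(p, p_bar = 1 / 72, lam = 0.6) {
  vapply(p, function(pp) {
    if (pp > p_bar) 0
    else if (pp > lam * p_bar) 0.25
    else if (pp > lam^2 * p_bar) 0.5
    else if (pp > lam^3 * p_bar) 0.75
    else 1
  }, numeric(1))
}

# Flat-color RGB image builder.
flat_rgb <- function(h, w, col) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- col[ch]
  img
}

# Disc image: background color with a centered disc of another color;
# returns image, gray, and the disc mask.
disc_image <- function(h = 64, w = 64, radius = 20,
                       bg = c(0.80, 0.45, 0.40), fg = c(0.45, 0.05, 0.05)) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt((rr - (h + 1) / 2)^2 + (cc - (w + 1) / 2)^2)
  inside <- r <= radius
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- ifelse(inside, fg[ch], bg[ch])
  list(image = img, gray = rgb_to_gray(img), mask = inside, r = r)
}
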