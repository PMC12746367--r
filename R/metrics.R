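#' Mean absolute percentage error per ROI
#'
#' `100 * mean(|est - true| / true)` over the pixels of each labelled ROI
#' (label 0 = background is excluded).
#'
#' @param true_map,est_map Numeric matrices.
#' @param roi_labels Integer label matrix; 0 is background.
#' @return Tibble with `roi`, `n_pixels`, `mape_pct`.
#' @export
mape <- function(true_map, est_map, roi_labels) {
  stopifnot(all(dim(true_map) == dim(est_map)),
            all(dim(true_map) == dim(roi_labels)))
  rois <- sort(unique(roi_labels[roi_labels > 0L]))
  if (length(rois) == 0) abort("no labelled ROIs")
  purrr::map_dfr(rois, function(r) {
    pix <- roi_labels == r
    tv <- true_map[pix]
    if (any(tv == 0)) abort("true values must be non-zero inside every ROI")
    ev <- est_map[pix]
    tibble(roi = r, n_pixels = sum(pix),
           mape_pct = 100 * mean(abs(ev - tv) / abs(tv), na.rm = TRUE))
  })
}

#' Normalized root-mean-squared error
#'
#' RMSE over the masked pixels divided by the range (max - min) of the
#' reference map within the mask.
#'
#' @param reference_map,est_map Numeric matrices.
#' @param mask Logical matrix; default all pixels.
#' @return NRMSE as a fraction.
#' @export
nrmse <- function(reference_map, est_map, mask = NULL) {
  stopifnot(all(dim(reference_map) == dim(est_map)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(reference_map), ncol(reference_map))
  ref <- reference_map[mask]
  est <- est_map[mask]
  rng <- max(ref) - min(ref)
  if (rng <= 0) abort("reference map has zero range within the mask")
  sqrt(mean((ref - est)^2, na.rm = TRUE)) / rng
}

# Unbiased local means/variances over all fully-interior windows (equivalent
# to a uniform filter followed by cropping of the half-window border).
local_stats <- function(x, win) {
  n <- nrow(x); m <- ncol(x)
  out_r <- n - win + 1L; out_c <- m - win + 1L
  # 2-D sliding-window sums via cumulative sums (integral image)
  S <- apply(apply(x, 2, cumsum), 1, cumsum) # transposed cumsum matrix
  S <- t(S)
  pad <- matrix(0, n + 1L, m + 1L)
  pad[-1, -1] <- S
  i <- seq_len(out_r); j <- seq_len(out_c)
  win_sum <- pad[i + win, j + win, drop = FALSE] -
    pad[i, j + win, drop = FALSE] - pad[i + win, j, drop = FALSE] +
    pad[i, j, drop = FALSE]
  win_sum / (win * win)
}

#' Structural similarity and Pearson correlation of two maps
#'
#' SSIM with the standard constants (`K1 = 0.01`, `K2 = 0.03`), a 7 x 7
#' uniform window, unbiased covariance normalization and the data range taken
#' from the reference map; the SSIM map is averaged over windows that lie
#' fully inside the image (border of half a window cropped). Pearson's r is
#' computed over the masked pixels.
#'
#' @param reference_map,est_map Numeric matrices.
#' @param mask Logical matrix for the Pearson correlation; default all pixels.
#' @param win SSIM window size (odd).
#' @return List with `ssim` and `pearson_r`.
#' @export
ssim_and_pearson <- function(reference_map, est_map, mask = NULL, win = 7) {
  stopifnot(all(dim(reference_map) == dim(est_map)))
  if (min(dim(reference_map)) < win)
    abort("maps are smaller than the SSIM window")
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(reference_map), ncol(reference_map))
  if (sum(mask) < 2) abort("mask must contain at least 2 pixels")
  ref <- reference_map[mask]
  est <- est_map[mask]
  if (sd(ref) == 0 || sd(est) == 0)
    abort("zero variance: Pearson correlation undefined")
  r <- cor(ref, est)

  L <- max(reference_map) - min(reference_map)
  if (L <= 0) abort("reference map has zero range")
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  np <- win * win
  cov_norm <- np / (np - 1)
  ux <- local_stats(reference_map, win)
  uy <- local_stats(est_map, win)
  uxx <- local_stats(reference_map^2, win)
  uyy <- local_stats(est_map^2, win)
  uxy <- local_stats(reference_map * est_map, win)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)
  ssim_map <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  list(ssim = mean(ssim_map), pearson_r = r)
}

#' Paired two-tailed t-test with significance stars
#'
#' Stars follow the usual thresholds: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001. Identical inputs return `t = 0`, `p = 1` by convention;
#' constant non-zero differences (zero variance) are an error.
#'
#' @param metric_before,metric_after Paired samples (equal length, n >= 2).
#' @return List with `t`, `p`, `stars`.
#' @export
paired_ttest <- function(metric_before, metric_after) {
  if (length(metric_before) != length(metric_after))
    abort("paired samples must have equal length")
  if (length(metric_before) < 2) abort("need at least 2 pairs")
  d <- metric_before - metric_after
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, stars = "ns"))
    abort("differences have zero variance; t statistic undefined")
  }
  ht <- t.test(metric_before, metric_after, paired = TRUE)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), p = p, stars = stars)
}

#' Full evaluation report of reconstructed maps against a reference
#'
#' @param phantom The [make_phantom()] ground truth.
#' @param maps A `param_maps` reconstruction.
#' @return One-row tibble per parameter (`fs`, `ksw`) with MAPE mean and SD
#'   over ROIs, NRMSE, SSIM and Pearson's r.
#' @export
metric_report <- function(phantom, maps) {
  mask <- phantom$roi_labels > 0L
  one <- function(name, truth, est) {
    mp <- mape(truth, est, phantom$roi_labels)
    sp <- ssim_and_pearson(truth, ifelse(is.na(est), 0, est), mask)
    tibble(
      parameter = name,
      mape_mean_pct = mean(mp$mape_pct),
      mape_sd_pct = sd(mp$mape_pct),
      nrmse = nrmse(truth, ifelse(is.na(est), 0, est), mask),
      ssim = sp$ssim,
      pearson_r = sp$pearson_r
    )
  }
  dplyr::bind_rows(
    one("fs", phantom$fs_truth, maps$fs_map),
    one("ksw", phantom$ksw_truth, maps$ksw_map)
  )
}
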