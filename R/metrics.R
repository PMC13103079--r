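# Image-quality and overlap metrics: SSIM (global and Gaussian-windowed,
# 2D and 3D), PSNR, a pluggable LPIPS, CNR and per-region CNR-difference
# tables, Dice, and (average) Hausdorff surface distance.

as_img <- function(x) {
  if (is_volume(x)) x$data
  else if (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)) x
  else stop_lh("expected a 2D/3D array or lh_volume")
}

check_same_shape <- function(x, y, what) {
  if (!identical(dim(x), dim(y)))
    stop_lh("%s: shape mismatch (%s vs %s)", what,
            paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x"))
}

#' SSIM configuration
#'
#' Defaults follow the reference implementation of the index: stabilization
#' constants `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and an 11-point Gaussian
#' window with sd 1.5 in sliding mode. `window = "global"` computes a single
#' SSIM over whole-image statistics.
#'
#' @param L Data range (1 for normalized volumes).
#' @param window `"sliding"` or `"global"`.
#' @param size Window width (odd) in sliding mode.
#' @param sd Gaussian window standard deviation (pixels).
#' @param c1,c2 Stabilization constants (> 0).
#' @export
ssim_config <- function(L = 1, window = c("sliding", "global"), size = 11,
                        sd = 1.5, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2) {
  window <- match.arg(window)
  if (c1 <= 0 || c2 <= 0 || L <= 0) stop_lh("ssim constants and L must be > 0")
  if (size < 2 || size %% 2 != 1) stop_lh("ssim window size must be odd and > 1")
  list(L = L, window = window, size = as.integer(size), sd = sd, c1 = c1, c2 = c2)
}

gauss_kernel <- function(size, sd) {
  u <- seq_len(size) - (size + 1) / 2
  k <- exp(-u^2 / (2 * sd^2))
  k / sum(k)
}

gauss_filter_valid <- function(a, kern) {
  nd <- length(dim(a))
  for (d in seq_len(nd)) a <- .sepfilter_valid_cpp(a, kern, d)
  a
}

#' Structural similarity index
#'
#' Implements `(2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#' ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`. In sliding mode the
#' statistics are Gaussian-weighted over each fully interior window and the
#' mean of the SSIM map is returned; in global mode whole-image (population)
#' moments are used. Works on 2D slices and 3D volumes (the volume-wise mode
#' uses a 3D sliding window).
#'
#' @param x,y Equal-shaped images (arrays or `lh_volume`s).
#' @param config An [ssim_config()].
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, config = ssim_config()) {
  x <- as_img(x); y <- as_img(y)
  check_same_shape(x, y, "ssim")
  c1 <- config$c1; c2 <- config$c2
  if (config$window == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (any(dim(x) < config$size))
    stop_lh("ssim: image smaller than the %d-point window; use window='global'",
            config$size)
  k <- gauss_kernel(config$size, config$sd)
  mx <- gauss_filter_valid(x, k); my <- gauss_filter_valid(y, k)
  vx <- gauss_filter_valid(x * x, k) - mx^2
  vy <- gauss_filter_valid(y * y, k) - my^2
  cxy <- gauss_filter_valid(x * y, k) - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(L^2 / MSE)` in dB; for normalized inputs (`L = 1`) this equals
#' the `10 log10(L / MSE)` form. Identical inputs give `Inf`.
#'
#' @param x,y Equal-shaped images or volumes.
#' @param L Maximum possible intensity (> 0).
#' @export
psnr <- function(x, y, L = 1) {
  x <- as_img(x); y <- as_img(y)
  check_same_shape(x, y, "psnr")
  if (L <= 0) stop_lh("psnr: L must be > 0")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

#' Learned-perceptual-style feature distance (pluggable)
#'
#' `sum_l (1 / (H_l W_l)) sum_{h,w} || phi_l(x) - phi_l(y) ||_2^2` for an
#' injected feature extractor. Parity with published pretrained perceptual
#' weights is out of scope; the extractor is any deterministic function
#' returning a list of per-layer feature maps (`H x W` matrices or
#' `H x W x C` arrays).
#'
#' @param x,y Equal-shaped images.
#' @param extractor Function `image -> list of feature maps`.
#' @return Non-negative distance; 0 for identical inputs.
#' @export
lpips <- function(x, y, extractor) {
  x <- as_img(x); y <- as_img(y)
  check_same_shape(x, y, "lpips")
  fx <- extractor(x); fy <- extractor(y)
  if (length(fx) != length(fy)) stop_lh("lpips: extractor layer count mismatch")
  total <- 0
  for (l in seq_along(fx)) {
    a <- fx[[l]]; b <- fy[[l]]
    if (is.matrix(a)) { a <- array(a, c(dim(a), 1L)); b <- array(b, c(dim(b), 1L)) }
    check_same_shape(a, b, sprintf("lpips layer %d", l))
    if (!all(is.finite(a)) || !all(is.finite(b)))
      stop_lh("lpips: non-finite features at layer %d", l)
    total <- total + sum((a - b)^2) / (dim(a)[1] * dim(a)[2])
  }
  total
}

#' A small deterministic feature extractor for testing LPIPS plumbing
#'
#' Layer 1 is the image itself; layer 2 is the 2x2 block mean (half
#' resolution). Deterministic and weight-free, so LPIPS values computed with
#' it are reproducible but are NOT comparable to published LPIPS numbers.
#'
#' @return An extractor function for [lpips()].
#' @export
test_feature_extractor <- function() {
  function(img) {
    img <- as_img(img)
    h <- dim(img)[1] %/% 2L; w <- dim(img)[2] %/% 2L
    pooled <- 0.25 * (img[2 * seq_len(h) - 1, 2 * seq_len(w) - 1, drop = FALSE] +
                      img[2 * seq_len(h), 2 * seq_len(w) - 1, drop = FALSE] +
                      img[2 * seq_len(h) - 1, 2 * seq_len(w), drop = FALSE] +
                      img[2 * seq_len(h), 2 * seq_len(w), drop = FALSE])
    list(img, pooled)
  }
}

as_mask <- function(m, what = "mask") {
  m <- as_img(m)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop_lh("%s must be binary (0/1)", what)
  m > 0
}

#' Contrast-to-noise ratio
#'
#' `(mean(ROI) - mean(background)) / sd(background)` with the population
#' standard deviation over background voxels.
#'
#' @param volume Intensity image or `lh_volume`.
#' @param roi_mask,background_mask Non-empty binary masks on the same grid.
#' @export
cnr <- function(volume, roi_mask, background_mask) {
  v <- as_img(volume)
  roi <- as_mask(roi_mask, "roi_mask")
  bg <- as_mask(background_mask, "background_mask")
  check_same_shape(v, roi, "cnr"); check_same_shape(v, bg, "cnr")
  if (!any(roi) || !any(bg)) stop_lh("cnr: empty mask")
  b <- v[bg]
  s <- sqrt(mean((b - mean(b))^2))
  if (s == 0) stop_lh("cnr: constant background (zero sd)")
  (mean(v[roi]) - mean(b)) / s
}

#' Per-region CNR difference table
#'
#' For each named region mask, the absolute difference between the region's
#' CNR in the baseline and in the (original or harmonized) follow-up volume.
#'
#' @param bl,fu Volumes on one grid.
#' @param region_masks Named list of binary masks.
#' @param background_mask Binary mask used as the CNR noise reference.
#' @return `data.frame` with columns `region`, `cnr_bl`, `cnr_fu`,
#'   `cnr_abs_diff`.
#' @export
cnr_difference_table <- function(bl, fu, region_masks, background_mask) {
  if (is.null(names(region_masks)) || any(names(region_masks) == ""))
    stop_lh("region_masks must be a named list")
  rows <- lapply(names(region_masks), function(nm) {
    cb <- cnr(bl, region_masks[[nm]], background_mask)
    cf <- cnr(fu, region_masks[[nm]], background_mask)
    data.frame(region = nm, cnr_bl = cb, cnr_fu = cf,
               cnr_abs_diff = abs(cb - cf), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Region masks from a label volume
#'
#' Splits an integer label volume into a named list of binary masks, one per
#' distinct non-background label.
#'
#' @param label_volume Integer-labeled `lh_volume` or array.
#' @param exclude Labels to drop (default background 0).
#' @export
region_masks_from_labels <- function(label_volume, exclude = 0L) {
  lab <- as_img(label_volume)
  codes <- setdiff(sort(unique(as.integer(lab))), as.integer(exclude))
  names(codes) <- vapply(codes, function(k) {
    switch(as.character(k), "1" = "csf", "2" = "gm", "3" = "wm",
           "99" = "lesion", sprintf("region%d", k - 10L))
  }, character(1))
  lapply(codes, function(k) (lab == k) + 0)
}

#' Dice overlap coefficient
#'
#' `2 |A & B| / (|A| + |B|)`; two empty masks are defined as identical
#' (Dice 1).
#'
#' @param mask_a,mask_b Equal-shaped binary masks.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as_mask(mask_a, "mask_a"); b <- as_mask(mask_b, "mask_b")
  check_same_shape(a, b, "dice")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

boundary_points <- function(mask, spacing) {
  d <- dim(mask)
  if (length(d) == 2L) { mask <- array(mask, c(d, 1L)); d <- dim(mask); spacing <- c(spacing, 1) }
  shift_mask <- function(m, axis, by) {
    out <- array(FALSE, dim(m))
    n <- dim(m)[axis]
    if (abs(by) >= n) return(out)   # singleton axis: everything is boundary
    dst <- lapply(dim(m), seq_len); src <- dst
    if (by > 0) { dst[[axis]] <- seq.int(1 + by, n); src[[axis]] <- seq.int(1, n - by) }
    else        { dst[[axis]] <- seq.int(1, n + by); src[[axis]] <- seq.int(1 - by, n) }
    out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
    out
  }
  interior <- mask
  for (ax in 1:3)
    interior <- interior & shift_mask(mask, ax, 1) & shift_mask(mask, ax, -1)
  idx <- which(mask & !interior)
  ii <- arrayInd(idx, d)
  sweep(ii - 1, 2, spacing[1:3], `*`)
}

#' (Average) Hausdorff distance between mask surfaces
#'
#' Boundary voxels are mask voxels with a face neighbour outside the mask
#' (array edges count as outside). In the default average mode the result is
#' the mean of the two directed mean nearest-boundary distances, in physical
#' units; `mode = "max"` gives the classical symmetric Hausdorff distance.
#'
#' @param mask_a,mask_b Non-empty equal-shaped binary masks.
#' @param spacing mm per voxel (length 3, or 2 for 2D masks).
#' @param mode `"average"` (default) or `"max"`.
#' @export
average_hausdorff <- function(mask_a, mask_b, spacing = c(1, 1, 1),
                              mode = c("average", "max")) {
  mode <- match.arg(mode)
  a <- as_mask(mask_a, "mask_a"); b <- as_mask(mask_b, "mask_b")
  check_same_shape(a, b, "average_hausdorff")
  if (!any(a) || !any(b)) stop_lh("average_hausdorff: empty mask")
  pa <- boundary_points(a, spacing); pb <- boundary_points(b, spacing)
  use_max <- (mode == "max")
  d_ab <- .directed_surface_dist_cpp(pa, pb, use_max)
  d_ba <- .directed_surface_dist_cpp(pb, pa, use_max)
  if (use_max) max(d_ab, d_ba) else (d_ab + d_ba) / 2
}
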