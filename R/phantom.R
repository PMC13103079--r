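# Synthetic longitudinal two-scanner brain phantom.
#
# The phantom stands in for the clinical cohort: per subject, a baseline and
# a follow-up volume of the same procedural anatomy (nested ellipsoids for
# CSF/GM/WM plus seeded spherical subregions standing in for a parcellation
# and an enhancing lesion), rendered under two scanner "styles" (per-tissue
# mean intensities, gamma, degree-2 multiplicative bias field, Gaussian
# noise), with the follow-up lesion optionally rescaled and the follow-up
# volume pushed through a known rigid misalignment. Every applied quantity is
# returned as ground truth.
#
# Tissue label codes: 0 background, 1 CSF-like, 2 GM-like, 3 WM-like,
# 11..(10+n_regions) subregions, 99 lesion.

LABEL_BG <- 0L; LABEL_CSF <- 1L; LABEL_GM <- 2L; LABEL_WM <- 3L
LABEL_REGION0 <- 10L; LABEL_LESION <- 99L

#' Default scanner styles
#'
#' Style A emulates the baseline scanner: bright WM/GM contrast, no gamma
#' distortion, flat bias, low noise. Style B emulates a different scanner:
#' compressed tissue contrast, gamma 0.8, a spatially varying degree-2 bias
#' field and slightly higher noise. Magnitudes are package choices (the
#' interscanner difference is not quantified publicly); they are deliberately
#' large enough that baseline/follow-up pairs are visibly mismatched.
#'
#' @return A style parameter list with fields `means` (named: background,
#'   csf, gm, wm), `region_means`, `gamma`, `bias` (9 polynomial
#'   coefficients: x, y, z, x2, y2, z2, xy, xz, yz on [-1,1]^3 coordinates)
#'   and `noise_sd`.
#' @export
default_style_A <- function() {
  list(means = c(background = 0.02, csf = 0.15, gm = 0.45, wm = 0.70),
       region_means = NULL, gamma = 1.0, bias = rep(0, 9), noise_sd = 0.01,
       psf_sd = 0.6)
}

#' @rdname default_style_A
#' @export
default_style_B <- function() {
  list(means = c(background = 0.03, csf = 0.22, gm = 0.38, wm = 0.55),
       region_means = NULL, gamma = 0.8,
       bias = c(0.06, -0.04, 0.05, 0.03, -0.03, 0.02, 0.02, 0, -0.02),
       noise_sd = 0.015, psf_sd = 0.6)
}

#' Specify a longitudinal phantom
#'
#' @param grid_size Voxels per axis (default 64 for desk-scale runs; the
#'   full-scale pipeline uses 256).
#' @param voxel_spacing Isotropic spacing in mm.
#' @param n_regions Number of labeled subregions (>= 4).
#' @param lesion List: `center` (voxel coords, 1-based; `NULL` for the
#'   default site), `radius` (voxels, >= 0), `contrast` (added to the WM mean),
#'   `radius_change_fraction` (follow-up radius is `radius * (1 + fraction)`).
#' @param style_A,style_B Scanner styles, see [default_style_A()].
#' @param misalignment `lh_rigid` applied to the follow-up volume.
#' @param texture_amplitude Amplitude of the seeded anatomy-frame intensity
#'   texture (smooth sinusoidal modulation shared by both visits, standing in
#'   for within-tissue anatomical texture; 0 gives piecewise-constant
#'   tissues).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return A validated `lh_phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64, voxel_spacing = 1, n_regions = 4,
                         lesion = list(center = NULL, radius = 4,
                                       contrast = 0.25,
                                       radius_change_fraction = 0),
                         style_A = default_style_A(),
                         style_B = default_style_B(),
                         misalignment = rigid_transform(c(1.5, -1, 0.5),
                                                        c(2, -1.5, 1)),
                         texture_amplitude = 0.2,
                         seed = 1) {
  lesion <- modifyList(list(center = NULL, radius = 4, contrast = 0.25,
                            radius_change_fraction = 0), lesion)
  if (grid_size < 16) stop_lh("grid_size must be >= 16")
  if (n_regions < 4) stop_lh("n_regions must be >= 4")
  if (lesion$radius < 0) stop_lh("lesion radius must be non-negative")
  if (is.null(lesion$center))
    lesion$center <- round(grid_size * c(0.62, 0.58, 0.55))
  for (st in list(style_A, style_B)) {
    if (st$gamma <= 0) stop_lh("style gamma must be > 0")
    if (st$noise_sd < 0) stop_lh("style noise sd must be >= 0")
  }
  r_max <- lesion$radius * (1 + max(0, lesion$radius_change_fraction))
  if (any(lesion$center - r_max < 1) || any(lesion$center + r_max > grid_size))
    stop_lh("lesion (center %s, max radius %.1f) extends outside the %d^3 grid",
            paste(lesion$center, collapse = ","), r_max, grid_size)
  if (texture_amplitude < 0) stop_lh("texture_amplitude must be >= 0")
  structure(list(grid_size = as.integer(grid_size),
                 voxel_spacing = voxel_spacing, n_regions = as.integer(n_regions),
                 lesion = lesion, style_A = style_A, style_B = style_B,
                 misalignment = misalignment,
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "lh_phantom_spec")
}

# Normalized coordinates in [-1, 1] per axis for an n^3 grid.
norm_coords <- function(n) {
  u <- (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  list(x = array(rep(u, times = n * n), dim = c(n, n, n)),
       y = array(rep(rep(u, each = n), times = n), dim = c(n, n, n)),
       z = array(rep(u, each = n * n), dim = c(n, n, n)))
}

# Grid coordinates in anatomy-frame normalized units; when a pose is given,
# the grid point is pulled back through it first (normalized-unit version of
# the mm-space map used by apply_rigid: u' = R u + t / half field of view).
posed_coords <- function(spec, pose = NULL) {
  co <- norm_coords(spec$grid_size)
  if (is.null(pose) || is_identity_rigid(pose)) return(co)
  R <- rigid_matrix(pose)
  tt <- pose$translations / ((spec$grid_size - 1) / 2 * spec$voxel_spacing)
  list(x = R[1, 1] * co$x + R[1, 2] * co$y + R[1, 3] * co$z + tt[1],
       y = R[2, 1] * co$x + R[2, 2] * co$y + R[2, 3] * co$z + tt[2],
       z = R[3, 1] * co$x + R[3, 2] * co$y + R[3, 3] * co$z + tt[3])
}

#' Anatomy-frame intensity texture
#'
#' A smooth seeded sum of sinusoidal plane waves evaluated in anatomy
#' coordinates: it travels rigidly with the head, is identical for both
#' visits of a subject, and stands in for within-tissue anatomical texture
#' (without it the piecewise-constant phantom is nearly rotation-symmetric
#' to intensity-based registration).
#'
#' @param spec An `lh_phantom_spec`.
#' @param pose Optional `lh_rigid`, as in [make_anatomy()].
#' @return Multiplicative texture array (mean about 1).
#' @export
make_texture <- function(spec, pose = NULL) {
  n <- spec$grid_size
  if (spec$texture_amplitude <= 0) return(array(1, c(n, n, n)))
  co <- posed_coords(spec, pose)
  # Wavelengths span roughly gyral scale (a few voxels at 64^3) up to lobar
  # scale, so intensity registration has structure to lock onto.
  with_seed(derive_seed(spec$seed, 12L), {
    tex <- array(1, c(n, n, n))
    for (k in 1:12) {
      w <- rnorm(3); w <- w / sqrt(sum(w^2))
      f <- runif(1, 4, 16); ph <- runif(1, 0, 2 * pi)
      a <- spec$texture_amplitude * runif(1, 0.4, 1) / sqrt(12)
      tex <- tex + a * sin(pi * f * (w[1] * co$x + w[2] * co$y + w[3] * co$z) + ph)
    }
    tex
  })
}

in_ellipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

# Ellipsoid with a seeded angular ripple on its surface (folding-like
# boundary): inside iff the normalized radius is below 1 + ripple(direction).
# The ripple is a sum of plane waves on the unit direction vector, so it is a
# pure function of anatomy-frame geometry (pose-consistent) and of the seed.
in_rippled_ellipsoid <- function(co, center, semi, seed, amplitude, n_waves = 8) {
  ex <- (co$x - center[1]) / semi[1]
  ey <- (co$y - center[2]) / semi[2]
  ez <- (co$z - center[3]) / semi[3]
  r <- sqrt(ex^2 + ey^2 + ez^2)
  rs <- pmax(r, 1e-9)
  vx <- ex / rs; vy <- ey / rs; vz <- ez / rs
  ripple <- 0
  with_seed(seed, {
    for (k in seq_len(n_waves)) {
      w <- rnorm(3); w <- w / sqrt(sum(w^2))
      f <- runif(1, 3, 7); ph <- runif(1, 0, 2 * pi)
      a <- amplitude * runif(1, 0.4, 1) / sqrt(n_waves)
      ripple <- ripple + a * sin(f * (w[1] * vx + w[2] * vy + w[3] * vz) + ph)
    }
  })
  r <= 1 + ripple
}

#' Generate the phantom label volume
#'
#' Procedural anatomy: a GM-like head ellipsoid enclosing a WM-like
#' ellipsoid, CSF-like ventricles, `n_regions` seeded spherical subregions
#' carved out of WM, and (last, overwriting) the lesion sphere.
#'
#' When `pose` is given, the anatomy is evaluated analytically in that rigid
#' pose (the grid point is pulled back through the transform before the
#' geometry test). This is how the misaligned follow-up visit is produced:
#' the "scanner" samples the re-posed head directly on its own grid, so no
#' interpolation enters the generated data and edges stay as crisp as the
#' baseline's.
#'
#' @param spec An `lh_phantom_spec`.
#' @param lesion_radius Override of `spec$lesion$radius` (used internally for
#'   the follow-up visit).
#' @param pose Optional `lh_rigid`; same pull-back convention as
#'   [apply_rigid()], so registering the posed volume back to the unposed one
#'   should recover the inverse of `pose`.
#' @return An integer-labeled `lh_volume` (provenance `"label"`).
#' @export
make_anatomy <- function(spec, lesion_radius = spec$lesion$radius, pose = NULL) {
  n <- spec$grid_size
  co <- posed_coords(spec, pose)
  labels <- array(LABEL_BG, dim = c(n, n, n))
  # Distinct semi-axes per axis pair (head length > height > width) so the
  # anatomy carries rotation information about every axis; ventricles and an
  # off-centre cerebellum-like lobe break the remaining near-symmetries.
  labels[in_rippled_ellipsoid(co, c(0, 0.02, 0), c(0.88, 0.70, 0.76),
                              derive_seed(spec$seed, 13L), 0.05)] <- LABEL_GM
  labels[in_rippled_ellipsoid(co, c(0.02, 0, 0.02), c(0.64, 0.48, 0.52),
                              derive_seed(spec$seed, 14L), 0.10)] <- LABEL_WM
  labels[in_ellipsoid(co, c(-0.40, -0.22, -0.30), c(0.24, 0.18, 0.22)) &
           labels == LABEL_GM] <- LABEL_WM
  labels[in_ellipsoid(co, c(0.38, 0.10, 0.28), c(0.16, 0.20, 0.14)) &
           labels == LABEL_GM] <- LABEL_WM
  labels[in_ellipsoid(co, c(-0.12, 0.04, 0.08), c(0.09, 0.14, 0.22))] <- LABEL_CSF
  labels[in_ellipsoid(co, c(0.16, -0.02, 0.06), c(0.11, 0.17, 0.18))] <- LABEL_CSF
  # Seeded subregion blobs: accepted analytically (sphere inside the WM
  # ellipsoid, clear of ventricles and lesion site), so placement is a pure
  # function of the seed and identical for every pose and visit.
  les_cen_n <- (spec$lesion$center - (n + 1) / 2) / ((n - 1) / 2)
  les_rad_n <- lesion_radius / ((n - 1) / 2)
  with_seed(derive_seed(spec$seed, 11L), {
    placed <- 0L
    while (placed < spec$n_regions) {
      cen <- runif(3, -0.4, 0.4)
      rad <- runif(1, 0.10, 0.16)
      fits_wm <- sum(((cen - c(0.02, 0, 0.02)) /
                        (c(0.62, 0.48, 0.55) - rad))^2) <= 1
      clear_csf <- sqrt(sum((cen - c(-0.12, 0.04, 0.08))^2)) > rad + 0.24 &&
        sqrt(sum((cen - c(0.16, -0.02, 0.06))^2)) > rad + 0.24
      clear_lesion <- sqrt(sum((cen - les_cen_n)^2)) > rad + les_rad_n + 0.03
      if (fits_wm && clear_csf && clear_lesion) {
        placed <- placed + 1L
        sel <- in_ellipsoid(co, cen, rep(rad, 3)) & labels == LABEL_WM
        labels[sel] <- LABEL_REGION0 + placed
      }
    }
  })
  # Lesion sphere (anatomy-frame voxel units), overwrites whatever it covers
  # inside the head.
  if (lesion_radius > 0) {
    sel <- (co$x - les_cen_n[1])^2 + (co$y - les_cen_n[2])^2 +
      (co$z - les_cen_n[3])^2 <= les_rad_n^2
    sel <- sel & labels != LABEL_BG
    if (!any(sel))
      stop_lh("lesion at (%s) lies outside the head region",
              paste(spec$lesion$center, collapse = ","))
    labels[sel] <- LABEL_LESION
  }
  new_volume(labels, spacing = rep(spec$voxel_spacing, 3), provenance = "label")
}

style_mean_table <- function(style, n_regions, lesion_contrast) {
  rm <- style$region_means %||%
    seq(style$means[["gm"]] + 0.05, style$means[["wm"]] - 0.03,
        length.out = n_regions)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  means <- c(style$means[["background"]], style$means[["csf"]],
             style$means[["gm"]], style$means[["wm"]], rm,
             clamp01(style$means[["wm"]] + lesion_contrast))
  names(means) <- c(LABEL_BG, LABEL_CSF, LABEL_GM, LABEL_WM,
                    LABEL_REGION0 + seq_len(n_regions), LABEL_LESION)
  clamp01(means)^style$gamma
}

#' Render a label volume under a scanner style
#'
#' Per-tissue styled means (`clamp(mean)^gamma`), then a multiplicative
#' degree-2 polynomial bias field, then additive Gaussian noise; the result
#' is clamped to `[0, 1]`.
#'
#' @param labels Label `lh_volume` from [make_anatomy()].
#' @param style Style list, see [default_style_A()].
#' @param seed Integer seed for the noise draw.
#' @param n_regions,lesion_contrast Rendering context, as in the spec that
#'   produced `labels`.
#' @param texture Optional multiplicative anatomy-frame texture from
#'   [make_texture()] (applied before the bias field).
#' @return An intensity `lh_volume` in `[0, 1]`.
#' @export
render_style <- function(labels, style, seed = 1, n_regions = 4,
                         lesion_contrast = 0.25, texture = NULL) {
  if (style$gamma <= 0) stop_lh("style gamma must be > 0")
  lab <- labels$data
  means <- style_mean_table(style, n_regions, lesion_contrast)
  img <- array(means[as.character(as.integer(lab))], dim = dim(lab))
  if (!is.null(texture)) img <- img * texture
  if (any(style$bias != 0)) {
    co <- norm_coords(dim(lab)[1])
    b <- style$bias
    bias <- 1 + b[1] * co$x + b[2] * co$y + b[3] * co$z +
      b[4] * co$x^2 + b[5] * co$y^2 + b[6] * co$z^2 +
      b[7] * co$x * co$y + b[8] * co$x * co$z + b[9] * co$y * co$z
    img <- img * pmax(0.2, bias)
  }
  # Scanner point-spread function: band-limits the piecewise-constant
  # render (partial-volume-like edges) before noise; applied in the grid
  # (scanner) frame, like a real acquisition.
  img <- gauss_smooth_same(img, style$psf_sd %||% 0)
  if (style$noise_sd > 0)
    img <- img + with_seed(seed, array(rnorm(length(img), 0, style$noise_sd),
                                       dim = dim(img)))
  img <- array(pmin(1, pmax(0, img)), dim = dim(lab))
  new_volume(img, spacing = labels$spacing, provenance = "bl")
}

is_identity_rigid <- function(tf) all(tf$rotations == 0) && all(tf$translations == 0)

# Same-size separable Gaussian smoothing with replicate padding.
gauss_smooth_same <- function(a, sd) {
  if (sd <= 0) return(a)
  r <- max(1L, ceiling(2 * sd))
  k <- exp(-(-r:r)^2 / (2 * sd^2)); k <- k / sum(k)
  d <- dim(a)
  idx <- lapply(d, function(n) c(rep(1L, r), seq_len(n), rep(n, r)))
  ap <- a[idx[[1]], idx[[2]], idx[[3]]]
  for (ax in 1:3) ap <- .sepfilter_valid_cpp(ap, k, ax)
  ap
}

#' Generate one longitudinal baseline/follow-up phantom pair
#'
#' The baseline is the anatomy rendered with style A. The follow-up shares
#' the anatomy, with the lesion radius scaled by
#' `1 + radius_change_fraction`, rendered with style B, and then resampled
#' through the specified rigid misalignment. All applied quantities are
#' recorded in the returned ground truth.
#'
#' @param spec An `lh_phantom_spec`.
#' @return List `bl` (`lh_volume`), `fu` (`lh_volume`), `truth`
#'   (`lh_phantom_truth`: `region_label_volume` and `background_mask` in
#'   baseline space, `lesion_mask_bl`, `lesion_mask_fu` (follow-up space),
#'   `applied_transform`, `style_params`, `seed`).
#' @export
make_longitudinal_pair <- function(spec) {
  if (!inherits(spec, "lh_phantom_spec")) stop_lh("expected an lh_phantom_spec")
  labels_bl <- make_anatomy(spec)
  r_fu <- spec$lesion$radius * (1 + spec$lesion$radius_change_fraction)
  # Follow-up anatomy is sampled directly in the misaligned pose (see
  # make_anatomy): the generated data contain no resampling blur.
  labels_fu <- make_anatomy(spec, lesion_radius = r_fu,
                            pose = spec$misalignment)
  bl <- render_style(labels_bl, spec$style_A, seed = derive_seed(spec$seed, 1L),
                     n_regions = spec$n_regions,
                     lesion_contrast = spec$lesion$contrast,
                     texture = make_texture(spec))
  fu <- render_style(labels_fu, spec$style_B, seed = derive_seed(spec$seed, 2L),
                     n_regions = spec$n_regions,
                     lesion_contrast = spec$lesion$contrast,
                     texture = make_texture(spec, pose = spec$misalignment))
  lesion_fu <- new_volume((labels_fu$data == LABEL_LESION) + 0,
                          spacing = labels_fu$spacing, provenance = "mask")
  fu$provenance <- "fu"
  truth <- structure(list(
    region_label_volume = labels_bl,
    lesion_mask_bl = new_volume((labels_bl$data == LABEL_LESION) + 0,
                                spacing = labels_bl$spacing, provenance = "mask"),
    lesion_mask_fu = lesion_fu,
    background_mask = new_volume((labels_bl$data == LABEL_BG) + 0,
                                 spacing = labels_bl$spacing, provenance = "mask"),
    applied_transform = spec$misalignment,
    style_params = list(style_A = spec$style_A, style_B = spec$style_B),
    seed = spec$seed), class = "lh_phantom_truth")
  list(bl = bl, fu = fu, truth = truth)
}

#' Generate and save a phantom cohort
#'
#' Writes per-subject baseline/follow-up volumes plus ground-truth masks as
#' NIfTI and a manifest CSV (columns `subject_id`, `visit`, `style`, `file`,
#' `seed`); the applied misalignment is serialized as JSON per subject.
#'
#' @param n_subjects Number of subjects.
#' @param spec Template `lh_phantom_spec`; each subject uses a seed derived
#'   from `seed`.
#' @param seed Cohort seed.
#' @param out_dir Writable output directory (created if missing).
#' @return The manifest `data.frame`, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
make_dataset <- function(n_subjects, spec = phantom_spec(), seed = spec$seed,
                         out_dir) {
  if (missing(out_dir)) stop_lh("make_dataset requires an output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_lh("cannot create output directory '%s'", out_dir)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub%03d", i)
    sseed <- derive_seed(seed, i)
    spec_i <- spec; spec_i$seed <- sseed
    pair <- make_longitudinal_pair(spec_i)
    files <- c(bl = sprintf("%s_bl.nii.gz", sid),
               fu = sprintf("%s_fu.nii.gz", sid),
               lesion_bl = sprintf("%s_lesion_bl.nii.gz", sid),
               lesion_fu = sprintf("%s_lesion_fu.nii.gz", sid),
               regions = sprintf("%s_regions.nii.gz", sid),
               background = sprintf("%s_background.nii.gz", sid))
    paths <- file.path(out_dir, files)
    names(paths) <- names(files)
    write_nifti(pair$bl, paths[["bl"]])
    write_nifti(pair$fu, paths[["fu"]])
    write_nifti(pair$truth$lesion_mask_bl, paths[["lesion_bl"]], datatype = "uint8")
    write_nifti(pair$truth$lesion_mask_fu, paths[["lesion_fu"]], datatype = "uint8")
    write_nifti(pair$truth$region_label_volume, paths[["regions"]], datatype = "int16")
    write_nifti(pair$truth$background_mask, paths[["background"]], datatype = "uint8")
    write_rigid_json(pair$truth$applied_transform,
                     file.path(out_dir, sprintf("%s_misalignment.json", sid)))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid,
      visit = c("bl", "fu", "bl", "fu", "bl", "bl"),
      style = c("A", "B", rep(NA_character_, 4)),
      file = unname(files),
      seed = sseed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
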