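test_that("anatomy generation is deterministic and respects its contracts", {
  spec <- small_spec(seed = 4)
  a1 <- make_anatomy(spec)
  a2 <- make_anatomy(spec)
  expect_identical(a1$data, a2$data)
  labs <- sort(unique(as.vector(a1$data)))
  expect_length(intersect(labs, 11:14), 4)          # n_regions = 4 blobs
  # region labels + background partition the grid
  expect_true(all((a1$data > 0) | (a1$data == 0)))
  expect_equal(sum(a1$data > 0) + sum(a1$data == 0), length(a1$data))
  # lesion radius 0 -> no lesion voxels
  a0 <- make_anatomy(spec, lesion_radius = 0)
  expect_equal(sum(a0$data == 99), 0)
  expect_error(phantom_spec(grid_size = 32, lesion = list(center = c(2, 2, 2),
                                                          radius = 5)),
               "outside")
  expect_error(phantom_spec(n_regions = 3), "n_regions")
  expect_error(phantom_spec(lesion = list(radius = -1)), "non-negative")
})

test_that("lesion voxel counts match the lattice-sphere oracle", {
  # the lesion occupies every lattice point within its radius (it sits
  # entirely inside the head), so the exact count is enumerable
  lattice_count <- function(r) {
    g <- expand.grid(x = -ceiling(r):ceiling(r), y = -ceiling(r):ceiling(r),
                     z = -ceiling(r):ceiling(r))
    sum(g$x^2 + g$y^2 + g$z^2 <= r^2)
  }
  spec <- phantom_spec(seed = 5,
                       lesion = list(radius = 4, radius_change_fraction = 0.5))
  pair <- make_longitudinal_pair(spec)
  expect_equal(sum(pair$truth$lesion_mask_bl$data), lattice_count(4))
  # follow-up lesion is generated in the misaligned pose; its count matches
  # the scaled radius within voxelization error of the analytic sphere
  n_fu <- sum(pair$truth$lesion_mask_fu$data)
  expect_equal(n_fu / lattice_count(6), 1, tolerance = 0.05)
  expect_equal(n_fu / sum(pair$truth$lesion_mask_bl$data), 1.5^3,
               tolerance = 0.15)
})

test_that("rendering honors styled means, gamma monotonicity and geometry", {
  spec <- small_spec(seed = 6, style_A = quiet_style(), texture_amplitude = 0)
  labs <- make_anatomy(spec)
  img <- render_style(labs, quiet_style(), seed = 1)
  for (code_mean in list(c(0, 0.02), c(1, 0.15), c(2, 0.45), c(3, 0.70))) {
    sel <- labs$data == code_mean[1]
    expect_equal(unique(as.vector(img$data[sel])), code_mean[2],
                 tolerance = 1e-12)
  }
  expect_true(all(img$data >= 0 & img$data <= 1))
  # gamma transform preserves the rank order of class means
  img_g <- render_style(labs, quiet_style(gamma = 0.7), seed = 1)
  classes <- c(0, 1, 2, 3)
  m1 <- sapply(classes, function(k) mean(img$data[labs$data == k]))
  m2 <- sapply(classes, function(k) mean(img_g$data[labs$data == k]))
  expect_identical(order(m1), order(m2))
  # two styles share geometry: intensity is a pure function of the label
  img_b <- render_style(labs, quiet_style(means = c(background = 0.05,
                                                    csf = 0.3, gm = 0.5,
                                                    wm = 0.6)), seed = 2)
  for (k in classes)
    expect_length(unique(as.vector(img_b$data[labs$data == k])), 1)
  expect_error(render_style(labs, quiet_style(gamma = 0)), "gamma")
})

test_that("identity configuration gives a voxel-identical follow-up", {
  st <- quiet_style()
  spec <- small_spec(seed = 7, style_A = st, style_B = st,
                     misalignment = rigid_transform(),
                     lesion = list(radius = 3, radius_change_fraction = 0))
  pair <- make_longitudinal_pair(spec)
  expect_identical(pair$bl$data, pair$fu$data)
  expect_identical(pair$truth$applied_transform, spec$misalignment)
})

test_that("longitudinal pairs are deterministic with full ground truth", {
  spec <- small_spec(seed = 8)
  p1 <- make_longitudinal_pair(spec)
  p2 <- make_longitudinal_pair(spec)
  expect_identical(p1$bl$data, p2$bl$data)
  expect_identical(p1$fu$data, p2$fu$data)
  expect_identical(p1$truth$applied_transform, spec$misalignment)
  expect_identical(dim(p1$truth$region_label_volume$data), dim(p1$bl$data))
  # lesion masks are single connected spheres by construction: nonempty and
  # within the head
  expect_gt(sum(p1$truth$lesion_mask_bl$data), 0)
  expect_equal(sum(p1$truth$lesion_mask_bl$data *
                     p1$truth$background_mask$data), 0)
})

test_that("inverse misalignment recovers baseline anatomy (mask fidelity)", {
  spec <- phantom_spec(seed = 3)
  labs_bl <- make_anatomy(spec)
  labs_fu <- make_anatomy(spec, pose = spec$misalignment)
  back <- apply_rigid(new_volume(labs_fu$data + 0, provenance = "label"),
                      rigid_invert(spec$misalignment), method = "nearest")
  for (k in c(2, 3)) {     # GM-like and WM-like tissue masks
    d <- dice((back$data == k) + 0, (labs_bl$data == k) + 0)
    expect_gt(d, 0.95)
  }
})

test_that("make_dataset writes a reloadable cohort with a manifest", {
  out <- withr::local_tempdir()
  spec <- small_spec(seed = 10)
  mf <- make_dataset(3, spec, seed = 42, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_equal(length(unique(mf$subject_id)), 3)
  expect_true(all(file.exists(file.path(out, mf$file))))
  expect_named(mf, c("subject_id", "visit", "style", "file", "seed"))
  # round trip within float32
  spec1 <- spec; spec1$seed <- unique(mf$seed[mf$subject_id == "sub001"])
  pair <- make_longitudinal_pair(spec1)
  reread <- load_volume(file.path(out, "sub001_bl.nii.gz"))
  expect_lt(max(abs(reread$data - pair$bl$data)), 1e-6)
  # distinct subject seeds -> distinct baselines
  b1 <- load_volume(file.path(out, "sub001_bl.nii.gz"))
  b2 <- load_volume(file.path(out, "sub002_bl.nii.gz"))
  expect_false(identical(b1$data, b2$data))
  # recorded misalignment serializes faithfully
  tf <- read_rigid_json(file.path(out, "sub001_misalignment.json"))
  expect_equal(tf$rotations, spec$misalignment$rotations)
})
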