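test_that("ssim matches hand values and is 1 on identical inputs", {
  set.seed(11)
  x <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, x, ssim_config(window = "global")), 1, tolerance = 1e-12)
  # constant images, global mode: zero variances, hand-evaluated formula
  a <- matrix(0.2, 8, 8); b <- matrix(0.4, 8, 8)
  expect_equal(ssim(a, b, ssim_config(window = "global")),
               (2 * 0.08 + 1e-4) / (0.04 + 0.16 + 1e-4), tolerance = 1e-12)
  expect_equal(ssim(a, b, ssim_config(window = "global")), 0.80010,
               tolerance = 1e-5)
  expect_error(ssim(x, matrix(0, 16, 16)), "shape mismatch")
})

test_that("sliding ssim agrees with a brute-force windowed oracle (2D and 3D)", {
  set.seed(12)
  x <- matrix(runif(32 * 32), 32)
  y <- x + matrix(rnorm(32 * 32, 0, 0.1), 32)
  expect_equal(ssim(x, y), ssim_oracle(x, y), tolerance = 1e-6)
  xv <- array(runif(16^3), c(16, 16, 16))
  yv <- xv + array(rnorm(16^3, 0, 0.05), c(16, 16, 16))
  expect_equal(ssim(xv, yv), ssim_oracle(xv, yv), tolerance = 1e-6)
})

test_that("ssim is symmetric and degrades with growing noise", {
  set.seed(13)
  x <- matrix(runif(24 * 24), 24)
  y <- x + matrix(rnorm(24 * 24, 0, 0.05), 24)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  means <- sapply(c(0.02, 0.08, 0.25), function(s) {
    mean(sapply(1:5, function(k) {
      set.seed(100 + k)
      ssim(x, x + matrix(rnorm(24 * 24, 0, s), 24))
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("psnr matches hand values and basic properties", {
  x <- matrix(0, 8, 8)
  expect_identical(psnr(x, x), Inf)
  expect_equal(psnr(x, x + 0.1), 20, tolerance = 1e-10)
  expect_equal(psnr(x, x + 0.5), 10 * log10(1 / 0.25), tolerance = 1e-10)
  expect_equal(psnr(x, x + 0.5), 6.0206, tolerance = 1e-4)
  expect_error(psnr(x, matrix(0, 4, 4)), "shape mismatch")
  expect_error(psnr(x, x, L = 0), "L must be")
  # strictly decreasing in MSE
  vals <- sapply(c(0.01, 0.1, 0.2, 0.4), function(d) psnr(x, x + d))
  expect_true(all(diff(vals) < 0))
  # joint shift invariance within range
  expect_equal(psnr(x + 0.2, x + 0.3), psnr(x, x + 0.1), tolerance = 1e-12)
})

test_that("volume-wise psnr equals slice-wise value when per-slice MSE is equal", {
  v1 <- array(0, c(6, 6, 4))
  v2 <- v1
  for (k in 1:4) v2[, , k] <- matrix(c(0.2, -0.2), 6, 6)  # same MSE each slice
  per_slice <- sapply(1:4, function(k) psnr(v1[, , k], v2[, , k]))
  expect_equal(psnr(v1, v2), mean(per_slice), tolerance = 1e-10)
})

test_that("lpips implements the printed layer sum with an injected extractor", {
  identity_extractor <- function(img) list(img)
  x <- matrix(0.3, 2, 2)
  expect_equal(lpips(x, x, identity_extractor), 0)
  expect_equal(lpips(x, x + 1, identity_extractor), 1)  # (1/4) * 4 * 1
  set.seed(14)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  expect_equal(lpips(a, b, identity_extractor), lpips(b, a, identity_extractor))
  ex <- test_feature_extractor()
  expect_equal(lpips(a, b, ex), lpips(a, b, ex))   # deterministic
  expect_gte(lpips(a, b, ex), 0)
  # hand check of the two-layer sum
  expect_equal(lpips(a, b, ex),
               sum((a - b)^2) / 16 +
                 sum((ex(a)[[2]] - ex(b)[[2]])^2) / 4, tolerance = 1e-12)
})

test_that("cnr matches the printed definition and its invariances", {
  v <- array(0, c(4, 4, 4))
  roi <- array(0, c(4, 4, 4)); bg <- array(0, c(4, 4, 4))
  roi[1:2, , ] <- 1; bg[3:4, , ] <- 1
  v[roi > 0] <- 0.8
  v[bg > 0] <- rep(c(0.1, 0.3), 16)          # mean 0.2, population sd 0.1
  expect_equal(cnr(v, roi, bg), 6, tolerance = 1e-10)
  expect_equal(cnr(v + 0.13, roi, bg), 6, tolerance = 1e-10)   # shift invariant
  v2 <- v; v2[bg > 0] <- 0.2 + 2 * (v[bg > 0] - 0.2)           # sd doubled
  expect_equal(cnr(v2, roi, bg), 3, tolerance = 1e-10)
  v3 <- v; v3[roi > 0] <- v[bg > 0][1:sum(roi)]                # roi == bg stats
  v3[roi > 0] <- rep(c(0.1, 0.3), 16)
  expect_equal(cnr(v3, roi, bg), 0, tolerance = 1e-10)
  v4 <- v; v4[bg > 0] <- 0.2
  expect_error(cnr(v4, roi, bg), "zero sd")
  expect_error(cnr(v, array(0, c(4, 4, 4)), bg), "empty mask")
})

test_that("cnr_difference_table composes per-region cnr calls", {
  pair <- default_pair()
  truth <- pair$truth
  regions <- region_masks_from_labels(truth$region_label_volume)
  bg <- truth$background_mask
  tab0 <- cnr_difference_table(pair$bl, pair$bl, regions, bg)
  expect_equal(tab0$cnr_abs_diff, rep(0, length(regions)))
  tab <- cnr_difference_table(pair$bl, pair$fu, regions, bg)
  expect_equal(nrow(tab), length(regions))
  expect_setequal(tab$region, names(regions))
  for (r in sample(seq_len(nrow(tab)), 3)) {
    nm <- tab$region[r]
    expect_equal(tab$cnr_abs_diff[r],
                 abs(cnr(pair$bl, regions[[nm]], bg) -
                       cnr(pair$fu, regions[[nm]], bg)), tolerance = 1e-12)
  }
})

test_that("dice handles the printed cases", {
  a <- array(0, c(4, 4, 1)); b <- a
  a[1:2, , 1] <- 1
  expect_equal(dice(a, a), 1)
  b[3:4, , 1] <- 1
  expect_equal(dice(a, b), 0)
  expect_equal(dice(array(0, c(4, 4, 1)), array(0, c(4, 4, 1))), 1)
  a2 <- array(0, c(10, 10, 2)); b2 <- a2
  a2[1:50] <- 1; b2[26:75] <- 1                  # |A|=|B|=50, overlap 25
  expect_equal(dice(a2, b2), 0.5)
  expect_error(dice(a * 2, b), "binary")
})

test_that("average_hausdorff matches hand and brute-force values", {
  a <- array(0, c(8, 8, 8)); b <- a
  a[2, 2, 2] <- 1; b[5, 2, 2] <- 1
  expect_equal(average_hausdorff(a, a), 0)
  expect_equal(average_hausdorff(a, b), 3)
  expect_equal(average_hausdorff(a, b, spacing = c(2, 1, 1)), 6)
  # shifted 5x5 square against the all-pairs oracle
  sa <- array(0, c(12, 12, 1)); sb <- sa
  sa[3:7, 3:7, 1] <- 1; sb[5:9, 4:8, 1] <- 1
  expect_equal(average_hausdorff(sa, sb), hausdorff_oracle(sa, sb),
               tolerance = 1e-9)
  expect_equal(average_hausdorff(sa, sb), average_hausdorff(sb, sa))
  expect_gte(average_hausdorff(sa, sb, mode = "max"), average_hausdorff(sa, sb))
  expect_error(average_hausdorff(a, array(0, c(8, 8, 8))), "empty")
})
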