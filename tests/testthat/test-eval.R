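test_that("harmonize_volume with an identity generator is the identity pipeline", {
  pair <- default_pair()
  nf <- normalize_intensity(pair$fu)
  state <- list(record_fu = nf$record, record_bl = nf$record,
                exclude_fraction = 0.1,
                lo = floor(0.1 * 64), hi = 64 - floor(0.1 * 64))
  out <- harmonize_volume(nf$volume, identity, state)
  expect_lt(max(abs(out$data - pair$fu$data)) /
              diff(range(pair$fu$data)), 1e-4)
  expect_identical(dim(out$data), dim(pair$fu$data))
  expect_equal(out$spacing, pair$fu$spacing)
  expect_equal(out$provenance, "harmonized")
  bad_state <- state; bad_state$lo <- 10
  expect_error(harmonize_volume(nf$volume, identity, bad_state),
               "slice range mismatch")
})

test_that("reconstruct_volume composes the two generators", {
  pair <- default_pair()
  nb <- normalize_intensity(pair$bl)
  state <- list(record_bl = nb$record, exclude_fraction = 0.1)
  out <- reconstruct_volume(nb$volume, identity, identity, state)
  expect_lt(max(abs(out$data - pair$bl$data)) /
              diff(range(pair$bl$data)), 1e-4)
  expect_equal(out$provenance, "reconstructed")
  # non-trivial maps compose in the right order: g_bl(g_fu(x))
  halve <- function(s) s / 2
  plus <- function(s) s + 0.1
  out2 <- reconstruct_volume(nb$volume, halve, plus, state, denorm = FALSE)
  k <- 33                                   # a retained slice
  expect_equal(out2$data[, , k], nb$volume$data[, , k] / 2 + 0.1,
               tolerance = 1e-12)
  # excluded slices pass through unchanged
  expect_equal(out2$data[, , 1], nb$volume$data[, , 1])
})

test_that("histogram matching implements quantile mapping", {
  pair <- default_pair()
  src <- normalize_intensity(pair$fu)$volume
  ref <- normalize_intensity(pair$bl)$volume
  # source == reference -> output == source within quantization tolerance
  same <- histogram_match(src, src)
  expect_lt(max(abs(same$data - src$data)), 0.02)
  # shifted distribution maps back onto the reference within one bin
  shifted <- as_shift <- src
  shifted$data <- pmin(1, src$data + 0.2)
  shifted$data <- src$data + 0.2             # same-shape histogram, shifted
  mapped <- histogram_match(shifted, src)
  expect_lt(mean(abs(mapped$data[shifted$data > 0.2] -
                       src$data[shifted$data > 0.2])), 0.02)
  # Kolmogorov-Smirnov distance to the reference cannot increase
  ks <- function(a, b) {
    grid <- seq(0, 1, length.out = 201)
    max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
  }
  matched <- histogram_match(src, ref)
  expect_lte(ks(matched$data[matched$data > 0], ref$data[ref$data > 0]),
             ks(src$data[src$data > 0], ref$data[ref$data > 0]))
  # histogram matching improves volume-wise PSNR over the original follow-up
  expect_gt(psnr(ref, matched), psnr(ref, src))
  expect_error(histogram_match(new_volume(array(1, c(4, 4, 4))), ref),
               "constant")
})

test_that("evaluate_conditions composes the metrics module", {
  pair <- default_pair()
  truth <- pair$truth
  bl <- normalize_intensity(pair$bl)$volume
  regions <- region_masks_from_labels(truth$region_label_volume)
  bg <- truth$background_mask
  # degenerate perfect case: every condition is the baseline itself
  run0 <- evaluate_conditions(bl, bl, bl, bl, regions, bg,
                              lesion_masks = list(bl = truth$lesion_mask_bl,
                                                  fu = truth$lesion_mask_bl))
  s0 <- run0$summary
  expect_true(all(s0$mean[s0$metric == "ssim"] == 1))
  expect_true(all(run0$cnr$harmonized$cnr_abs_diff == 0))
  expect_equal(run0$lesion$dice, 1)
  expect_equal(run0$lesion$avg_hausdorff, 0)
  # volume rows carry the +Inf psnr sentinel per-item
  vol_psnr <- run0$metrics$value[run0$metrics$metric == "psnr" &
                                   run0$metrics$granularity == "volume"]
  expect_true(all(is.infinite(vol_psnr)))
  # real conditions: row counts and compositional agreement
  fu <- normalize_intensity(pair$fu)$volume
  run <- evaluate_conditions(bl, fu, fu, NULL, regions, bg,
                             extractor = test_feature_extractor())
  expect_setequal(unique(run$metrics$condition),
                  c("BL_vs_originalFU", "BL_vs_FU2BL"))
  n_slices <- 64 - 2 * floor(0.1 * 64)
  slice_rows <- run$metrics[run$metrics$granularity == "slice" &
                              run$metrics$condition == "BL_vs_originalFU" &
                              run$metrics$metric == "ssim", ]
  expect_equal(nrow(slice_rows), n_slices)
  expect_equal(run$metrics$value[run$metrics$metric == "ssim" &
                                   run$metrics$granularity == "volume" &
                                   run$metrics$condition == "BL_vs_originalFU"],
               ssim(bl, fu), tolerance = 1e-12)
  k <- 10                                    # spot-check one slice row
  st_b <- extract_axial_slices(bl, 0.1); st_f <- extract_axial_slices(fu, 0.1)
  expect_equal(slice_rows$value[k], ssim(st_b$slices[[k]], st_f$slices[[k]]),
               tolerance = 1e-12)
  # evaluation is a pure function of its inputs: repeated calls identical
  run_again <- evaluate_conditions(bl, fu, fu, NULL, regions, bg,
                                   extractor = test_feature_extractor())
  expect_identical(run_again$metrics, run$metrics)
})

test_that("write_report round-trips the evaluation tables", {
  pair <- default_pair()
  bl <- normalize_intensity(pair$bl)$volume
  fu <- normalize_intensity(pair$fu)$volume
  regions <- region_masks_from_labels(pair$truth$region_label_volume)
  run <- evaluate_conditions(bl, fu, fu, NULL, regions,
                             pair$truth$background_mask,
                             lesion_masks = list(bl = pair$truth$lesion_mask_bl,
                                                 fu = pair$truth$lesion_mask_fu))
  out <- withr::local_tempdir()
  paths <- write_report(run, out)
  expect_true(all(file.exists(paths)))
  summ <- read.csv(paths[["summary"]])
  expect_equal(summ$mean, run$summary$mean, tolerance = 1e-12)
  cnr_csv <- read.csv(paths[["cnr"]])
  expect_setequal(cnr_csv$region[cnr_csv$condition == "original"],
                  names(regions))
  lesion_csv <- read.csv(paths[["lesion"]])
  expect_true(all(lesion_csv$dice >= 0 & lesion_csv$dice <= 1))
  # paired condition-comparison stats carry valid p-values
  hm <- histogram_match(fu, bl)
  run2 <- evaluate_conditions(bl, fu, hm, NULL, regions,
                              pair$truth$background_mask)
  expect_true(!is.null(run2$stats))
  expect_true(all(run2$stats$p_value >= 0 & run2$stats$p_value <= 1))
  out2 <- withr::local_tempdir()
  paths2 <- write_report(run2, out2)
  expect_true(file.exists(paths2[["stats"]]))
})

test_that("wilcoxon signed-rank matches enumeration and the reference", {
  # n = 6, all positive: exact two-sided p = 2/2^6
  res <- wilcoxon_signed_rank(c(0.3, 1.2, 0.5, 2.2, 0.9, 1.7))
  expect_equal(res$p.value, 0.03125)
  expect_equal(res$method, "exact")
  # independent brute-force enumeration over all sign assignments
  d <- c(0.4, -1.1, 0.7, 2.0, -0.2, 1.5)
  r <- rank(abs(d)); V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  Vs <- signs %*% r
  p_brute <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  expect_equal(wilcoxon_signed_rank(d)$p.value, p_brute, tolerance = 1e-12)
  # sign flip leaves p unchanged
  expect_equal(wilcoxon_signed_rank(-d)$p.value,
               wilcoxon_signed_rank(d)$p.value)
  # reference implementation agreement on random tie-free samples
  set.seed(61)
  for (k in 1:40) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  # zeros are dropped; all-zero input is degenerate
  expect_warning(res0 <- wilcoxon_signed_rank(rep(0, 5)), "degenerate")
  expect_true(res0$degenerate)
  # large-sample normal approximation tracks the reference
  set.seed(62)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal-approximation")
  expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("paired t-test matches hand values and the reference", {
  res <- paired_t_test(c(1, 2, 3))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2L)
  ref <- t.test(c(1, 2, 3))
  expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-12)
  sym <- paired_t_test(c(-2, -1, 1, 2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  expect_error(paired_t_test(rep(1, 4)), "zero variance")
  expect_error(paired_t_test(1), "at least 2")
  set.seed(63)
  x <- rnorm(15); y <- rnorm(15, 0.4)
  expect_equal(paired_t_test(x, y)$p.value,
               unname(t.test(x, y, paired = TRUE)$p.value), tolerance = 1e-12)
})
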