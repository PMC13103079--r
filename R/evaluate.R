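# Volume-level inference (harmonization, round-trip reconstruction), the
# histogram-matching baseline, the three-condition evaluation harness and
# paired statistical tests.

#' Preprocess one baseline/follow-up pair for training or inference
#'
#' Runs the standard chain: optional resampling onto an isotropic cubic
#' grid, min-max normalization of both volumes (with invertible records),
#' rigid registration of the follow-up to the baseline, axial slice
#' extraction with symmetric exclusion, and slice pairing.
#'
#' @param bl,fu `lh_volume`s.
#' @param subject_id Carried onto each slice pair.
#' @param target_size Optional grid size for [resample_to_grid()] (`NULL`
#'   keeps the native grid).
#' @param target_spacing Spacing for resampling (mm).
#' @param exclude_fraction Axial exclusion per end (default 0.1).
#' @param register Run [rigid_register()] (default TRUE).
#' @param register_args Optional list of extra arguments for
#'   [rigid_register()] (e.g. a cheaper pyramid schedule for batch runs).
#' @return List: `pairs` (slice pairs of normalized volumes), `bl`, `fu`
#'   (preprocessed normalized volumes), `state` (records, slice range,
#'   registration transform) for [harmonize_volume()].
#' @export
preprocess_pair <- function(bl, fu, subject_id = "subject", target_size = NULL,
                            target_spacing = 1, exclude_fraction = 0.1,
                            register = TRUE, register_args = list()) {
  if (!is.null(target_size)) {
    bl <- resample_to_grid(bl, target_size, target_spacing)
    fu <- resample_to_grid(fu, target_size, target_spacing)
  }
  nb <- normalize_intensity(bl)
  nf <- normalize_intensity(fu)
  transform <- rigid_transform()
  fu_n <- nf$volume
  if (register) {
    reg <- do.call(rigid_register,
                   c(list(moving = fu_n, fixed = nb$volume), register_args))
    fu_n <- reg$registered
    transform <- reg$transform
  }
  bl_stack <- extract_axial_slices(nb$volume, exclude_fraction)
  fu_stack <- extract_axial_slices(fu_n, exclude_fraction)
  pairs <- pair_slices(bl_stack, fu_stack, subject_id)
  list(pairs = pairs, bl = nb$volume, fu = fu_n,
       state = list(record_bl = nb$record, record_fu = nf$record,
                    exclude_fraction = exclude_fraction,
                    lo = bl_stack$lo, hi = bl_stack$hi,
                    transform = transform))
}

as_slice_fn <- function(gen) {
  if (is.function(gen)) gen
  else function(s) generator_apply(gen, s)
}

#' Harmonize a follow-up volume into the baseline domain
#'
#' Each retained axial slice is translated FU->BL; slices are re-stacked
#' into the source grid (excluded top/bottom slices pass through unchanged)
#' and intensities restored through the recorded inverse normalization.
#'
#' @param fu Preprocessed, normalized (values in `[0,1]`) follow-up
#'   `lh_volume`.
#' @param generator_to_BL `lh_generator` or `function(matrix) matrix`.
#' @param state Preprocess state from [preprocess_pair()] (fields
#'   `record_fu`, `exclude_fraction`).
#' @param denorm Restore the original intensity range (default TRUE; FALSE
#'   keeps the `[0,1]` scale used by the metrics).
#' @return Harmonized `lh_volume` with `fu`'s grid and metadata.
#' @export
harmonize_volume <- function(fu, generator_to_BL, state, denorm = TRUE) {
  stack <- extract_axial_slices(fu, state$exclude_fraction)
  if (!is.null(state$lo) && (stack$lo != state$lo || stack$hi != state$hi))
    stop_lh("slice range mismatch: volume gives [%d,%d), state records [%d,%d)",
            stack$lo, stack$hi, state$lo, state$hi)
  g <- as_slice_fn(generator_to_BL)
  stack$slices <- lapply(stack$slices, g)
  out <- restack_slices(stack, fu, provenance = "harmonized")
  if (denorm) out <- denormalize(out, state$record_fu)
  out$provenance <- "harmonized"
  out
}

#' Round-trip reconstruct a baseline volume (BL->FU->BL)
#'
#' @param bl Preprocessed, normalized baseline `lh_volume`.
#' @param generator_to_FU,generator_to_BL Generators (or functions).
#' @param state Preprocess state (fields `record_bl`, `exclude_fraction`).
#' @param denorm As in [harmonize_volume()].
#' @return Reconstructed `lh_volume` (provenance `"reconstructed"`).
#' @export
reconstruct_volume <- function(bl, generator_to_FU, generator_to_BL, state,
                               denorm = TRUE) {
  stack <- extract_axial_slices(bl, state$exclude_fraction)
  g_fu <- as_slice_fn(generator_to_FU); g_bl <- as_slice_fn(generator_to_BL)
  stack$slices <- lapply(stack$slices, function(s) g_bl(g_fu(s)))
  out <- restack_slices(stack, bl, provenance = "reconstructed")
  if (denorm) out <- denormalize(out, state$record_bl)
  out$provenance <- "reconstructed"
  out
}

#' Histogram-matching baseline
#'
#' Monotone intensity remapping of the source volume so its empirical CDF
#' matches the reference's: 256-bin quantile mapping estimated over
#' above-zero voxels (the conventional non-learning harmonization baseline).
#'
#' @param source,reference `lh_volume`s.
#' @param n_bins Number of quantile bins (default 256).
#' @return Remapped `lh_volume` on `source`'s grid.
#' @export
histogram_match <- function(source, reference, n_bins = 256) {
  s <- as_img(source); r <- as_img(reference)
  sm <- s[s > 0]; rm <- r[r > 0]
  if (length(unique(sm)) < 2) stop_lh("histogram_match: constant source")
  probs <- seq(0, 1, length.out = n_bins + 1)
  qs <- quantile(sm, probs, names = FALSE, type = 7)
  qr <- quantile(rm, probs, names = FALSE, type = 7)
  keep <- !duplicated(qs)
  out <- approx(qs[keep], qr[keep], xout = s, rule = 2, ties = "ordered")$y
  out <- array(out, dim = dim(s))
  out[s <= 0] <- s[s <= 0]
  if (is_volume(source)) as_volume_like(out, source, provenance = "harmonized")
  else out
}

#' Evaluate the three comparison conditions
#'
#' Computes slice-wise and volume-wise SSIM and PSNR (plus LPIPS slice-wise
#' when an extractor is supplied) for BL vs original FU, BL vs harmonized FU
#' (FU->BL) and BL vs reconstructed BL (BL->FU->BL); per-region CNR
#' difference tables for the original and harmonized follow-up; and lesion
#' Dice / average Hausdorff when lesion masks are provided. All volumes must
#' be co-registered on one grid and on a common intensity scale.
#'
#' @param bl,fu_original,fu_harmonized `lh_volume`s; `bl_reconstructed`
#'   optional (`NULL` skips that condition).
#' @param region_masks Named list of binary masks (see
#'   [region_masks_from_labels()]).
#' @param background_mask Binary mask for the CNR noise reference.
#' @param lesion_masks Optional named list of binary lesion masks; each
#'   non-`bl` entry is compared against `lesion_masks$bl`.
#' @param extractor Optional LPIPS feature extractor.
#' @param exclude_fraction Axial range used for slice-wise metrics.
#' @param subject Subject label carried into the report.
#' @return An `lh_evaluation_run`: `metrics` (long data.frame: subject,
#'   condition, granularity, metric, item, value), `summary` (mean/sd),
#'   `cnr` (per-region tables), `lesion` (overlap table or `NULL`).
#' @export
evaluate_conditions <- function(bl, fu_original, fu_harmonized,
                                bl_reconstructed = NULL,
                                region_masks, background_mask,
                                lesion_masks = NULL, extractor = NULL,
                                exclude_fraction = 0.1, subject = "subject") {
  vols <- list("BL_vs_originalFU" = fu_original,
               "BL_vs_FU2BL" = fu_harmonized)
  if (!is.null(bl_reconstructed)) vols[["BL_vs_BL2FU2BL"]] <- bl_reconstructed
  for (v in vols) check_same_shape(as_img(bl), as_img(v), "evaluate_conditions")
  cfg2 <- ssim_config(); cfg3 <- ssim_config()
  rows <- list()
  add <- function(condition, granularity, metric, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject, condition = condition, granularity = granularity,
      metric = metric, item = seq_along(values) - 1L, value = values,
      stringsAsFactors = FALSE)
  }
  bl_stack <- extract_axial_slices(bl, exclude_fraction)
  for (cond in names(vols)) {
    other <- vols[[cond]]
    add(cond, "volume", "ssim", ssim(bl, other, cfg3))
    add(cond, "volume", "psnr", psnr(bl, other))
    st <- extract_axial_slices(other, exclude_fraction)
    sv <- vapply(seq_along(st$slices), function(i)
      ssim(bl_stack$slices[[i]], st$slices[[i]], cfg2), numeric(1))
    pv <- vapply(seq_along(st$slices), function(i)
      psnr(bl_stack$slices[[i]], st$slices[[i]]), numeric(1))
    add(cond, "slice", "ssim", sv)
    add(cond, "slice", "psnr", pv)
    if (!is.null(extractor)) {
      lv <- vapply(seq_along(st$slices), function(i)
        lpips(bl_stack$slices[[i]], st$slices[[i]], extractor), numeric(1))
      add(cond, "slice", "lpips", lv)
    }
  }
  metrics <- do.call(rbind, rows)
  fin <- metrics[is.finite(metrics$value), ]
  summary <- stats::aggregate(value ~ subject + condition + granularity + metric,
                              data = fin,
                              FUN = function(v) c(mean = mean(v), sd = sd(v)))
  summary <- cbind(summary[, 1:4],
                   mean = summary$value[, "mean"], sd = summary$value[, "sd"])
  # paired comparison of each harmonized condition against the original FU,
  # over the slice-wise values (mirrors the slice-wise condition tables)
  stats_rows <- list()
  for (cond in setdiff(names(vols), "BL_vs_originalFU")) {
    for (m in unique(metrics$metric)) {
      a <- metrics$value[metrics$condition == cond &
                           metrics$granularity == "slice" & metrics$metric == m]
      b <- metrics$value[metrics$condition == "BL_vs_originalFU" &
                           metrics$granularity == "slice" & metrics$metric == m]
      keep <- is.finite(a) & is.finite(b)
      if (sum(keep) < 2 || all(a[keep] == b[keep])) next
      w <- suppressWarnings(wilcoxon_signed_rank(a[keep], b[keep]))
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        subject = subject, comparison = paste0(cond, "_vs_original"),
        metric = m, test = "wilcoxon_signed_rank",
        statistic = w$statistic, p_value = w$p.value,
        stringsAsFactors = FALSE)
    }
  }
  stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  cnr_tables <- list(
    original = cnr_difference_table(bl, fu_original, region_masks, background_mask),
    harmonized = cnr_difference_table(bl, fu_harmonized, region_masks, background_mask))
  lesion <- NULL
  if (!is.null(lesion_masks)) {
    if (is.null(lesion_masks$bl)) stop_lh("lesion_masks must include a 'bl' entry")
    others <- setdiff(names(lesion_masks), "bl")
    lesion <- do.call(rbind, lapply(others, function(nm) {
      data.frame(subject = subject, comparison = nm,
                 dice = dice(lesion_masks$bl, lesion_masks[[nm]]),
                 avg_hausdorff = average_hausdorff(lesion_masks$bl,
                                                   lesion_masks[[nm]],
                                                   spacing = bl$spacing),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(metrics = metrics, summary = summary, cnr = cnr_tables,
                 stats = stats, lesion = lesion, subject = subject),
            class = "lh_evaluation_run")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences: zero differences are dropped, ties
#' of absolute differences are mid-ranked, the null distribution is exact
#' (by enumeration of sign assignments over the observed ranks) for up to 25
#' nonzero differences and a normal approximation with tie and continuity
#' corrections beyond that.
#'
#' @param x Paired differences, or the first sample if `y` is given.
#' @param y Optional second sample (`d = x - y`).
#' @param exact_max Largest n for the exact null (default 25).
#' @return List `statistic` (V, rank sum of positive differences),
#'   `p.value`, `n` (nonzero differences), `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("wilcoxon_signed_rank: all differences zero; degenerate")
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # Exact distribution of 2V over sign assignments: product of (1 + z^(2r_i)).
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(counts[seq_len(v2 + 1L)]) / total
    p_ge <- sum(counts[seq.int(v2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = V, p.value = p, n = n, method = method, degenerate = FALSE)
}

#' Paired t-test
#'
#' Standard two-sided paired t on the differences.
#'
#' @param x Paired differences, or first sample if `y` is given.
#' @param y Optional second sample.
#' @return List `statistic`, `p.value`, `df`.
#' @export
paired_t_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  if (n < 2) stop_lh("paired_t_test: need at least 2 differences")
  s <- sd(d)
  if (s == 0) stop_lh("paired_t_test: zero variance of differences")
  t_stat <- mean(d) / (s / sqrt(n))
  list(statistic = t_stat, p.value = 2 * pt(-abs(t_stat), n - 1), df = n - 1L)
}

#' Write an evaluation run to disk
#'
#' Emits `metrics.csv` (per-item values), `summary.csv` (mean/sd per
#' condition, granularity and metric), `cnr_differences.csv`, `stats.csv`
#' (paired condition comparisons: test, statistic, p-value), `lesion.csv`
#' (when lesion masks were evaluated) and `summary.json`.
#'
#' @param run An `lh_evaluation_run`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(run, out_dir) {
  if (!inherits(run, "lh_evaluation_run")) stop_lh("expected an lh_evaluation_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metrics = file.path(out_dir, "metrics.csv"),
             summary = file.path(out_dir, "summary.csv"),
             cnr = file.path(out_dir, "cnr_differences.csv"),
             json = file.path(out_dir, "summary.json"))
  write.csv(run$metrics, paths[["metrics"]], row.names = FALSE)
  write.csv(run$summary, paths[["summary"]], row.names = FALSE)
  cnr_all <- do.call(rbind, lapply(names(run$cnr), function(nm)
    cbind(condition = nm, run$cnr[[nm]])))
  write.csv(cnr_all, paths[["cnr"]], row.names = FALSE)
  if (!is.null(run$stats)) {
    paths[["stats"]] <- file.path(out_dir, "stats.csv")
    write.csv(run$stats, paths[["stats"]], row.names = FALSE)
  }
  if (!is.null(run$lesion)) {
    paths[["lesion"]] <- file.path(out_dir, "lesion.csv")
    write.csv(run$lesion, paths[["lesion"]], row.names = FALSE)
  }
  jsonlite::write_json(list(subject = run$subject, summary = run$summary,
                            cnr = run$cnr, stats = run$stats,
                            lesion = run$lesion),
                       paths[["json"]], dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(paths)
}
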