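# Paired training loop: Adam, the linear learning-rate ramp, the
# bidirectional simultaneous train step, subject-level 8:2 splitting,
# checkpointing, and the lambda_oml ablation runner.

#' Training configuration
#'
#' Defaults are the published full-scale settings: Adam with `beta1 = 0.5`,
#' `beta2 = 0.99`, learning rate `2e-4` decayed linearly to 0 over 250,000
#' iterations (50 epochs), batch size 16. Desk-scale runs override
#' `total_iterations`, `batch_size` and the network specs.
#'
#' @param learning_rate Initial learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param batch_size Slice pairs per iteration.
#' @param total_iterations Iterations over which the rate decays to 0.
#' @param epochs Nominal epoch count (bookkeeping; `total_iterations` is
#'   authoritative).
#' @param seed Run seed (initialisation, shuffling, batch sampling).
#' @param weights An [loss_weights()].
#' @param gen_spec,disc_spec Architecture specs.
#' @param checkpoint_every Iterations between checkpoints (0 = only final).
#' @param val_fraction Held-out fraction of subjects (default 0.2, the 8:2
#'   subject-level split).
#' @export
train_config <- function(learning_rate = 2e-4, adam_beta1 = 0.5,
                         adam_beta2 = 0.99, batch_size = 16,
                         total_iterations = 250000, epochs = 50, seed = 1,
                         weights = loss_weights(),
                         gen_spec = generator_spec(),
                         disc_spec = discriminator_spec(),
                         checkpoint_every = 0, val_fraction = 0.2) {
  if (learning_rate <= 0 || batch_size < 1 || total_iterations < 1)
    stop_lh("rates and sizes must be positive, iterations >= 1")
  if (val_fraction < 0 || val_fraction >= 1) stop_lh("val_fraction in [0, 1)")
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 total_iterations = as.integer(total_iterations),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 weights = weights, gen_spec = gen_spec, disc_spec = disc_spec,
                 checkpoint_every = as.integer(checkpoint_every),
                 val_fraction = val_fraction),
            class = "lh_train_config")
}

#' CI-scale training preset
#'
#' A configuration sized for single-CPU smoke and acceptance runs: 64x64
#' slices, tiny networks, small batches, and a learning rate of 1e-3 — the
#' published 2e-4 is coupled to a 250,000-iteration schedule and leaves a
#' few-hundred-iteration run essentially untrained.
#'
#' @param total_iterations,batch_size,seed Overrides.
#' @param weights An [loss_weights()].
#' @export
train_config_ci <- function(total_iterations = 400, batch_size = 4, seed = 1,
                            weights = loss_weights()) {
  train_config(learning_rate = 1e-3, total_iterations = total_iterations,
               batch_size = batch_size,
               epochs = 1, seed = seed, weights = weights,
               gen_spec = generator_spec(base_filters = 8, n_res_blocks = 1),
               disc_spec = discriminator_spec(base_filters = 8, n_layers = 3))
}

#' Linear learning-rate schedule
#'
#' Decays linearly from `config$learning_rate` at iteration 0 to 0 at
#' `config$total_iterations`.
#'
#' @param iteration Iteration in `[0, total_iterations]`.
#' @param config An [train_config()].
#' @export
lr_schedule <- function(iteration, config) {
  if (iteration < 0 || iteration > config$total_iterations)
    stop_lh("iteration %s outside [0, %d]", iteration, config$total_iterations)
  config$learning_rate * (1 - iteration / config$total_iterations)
}

adam_init <- function(params) {
  zeros <- rapply(params, function(a) a * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (layer in names(params)) {
    for (slot in names(params[[layer]])) {
      g <- grads[[layer]][[slot]]
      m <- beta1 * state$m[[layer]][[slot]] + (1 - beta1) * g
      v <- beta2 * state$v[[layer]][[slot]] + (1 - beta2) * g * g
      state$m[[layer]][[slot]] <- m
      state$v[[layer]][[slot]] <- v
      params[[layer]][[slot]] <- params[[layer]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (layer in names(b)) for (slot in names(b[[layer]]))
    a[[layer]][[slot]] <- a[[layer]][[slot]] + b[[layer]][[slot]]
  a
}

new_models <- function(config) {
  list(G_A = make_generator(config$gen_spec, derive_seed(config$seed, 1L)),
       G_B = make_generator(config$gen_spec, derive_seed(config$seed, 2L)),
       D_A = make_discriminator(config$disc_spec, derive_seed(config$seed, 3L)),
       D_B = make_discriminator(config$disc_spec, derive_seed(config$seed, 4L)))
}

new_optimizers <- function(models) lapply(models, function(m) adam_init(m$params))

mean_abs_grad <- function(x, y) sign(x - y) / length(x)

#' One bidirectional training iteration
#'
#' Runs the BL->FU and FU->BL passes simultaneously: translation, cycle and
#' same-domain outputs for both directions, adversarial + cycle + original
#' matching terms averaged across directions, one Adam update for the
#' generators and one for the discriminators.
#'
#' @param batch List with `x_A` (baseline) and `x_B` (follow-up) arrays of
#'   shape `(H, W, 1, N)`.
#' @param models List `G_A`, `G_B`, `D_A`, `D_B` (G_A maps into the baseline
#'   domain).
#' @param weights An [loss_weights()].
#' @param optimizers Adam states as from the internal initializer; pass the
#'   value returned by the previous call.
#' @param lr Learning rate for this iteration.
#' @param config An [train_config()].
#' @return List `models`, `optimizers`, `breakdown` (class
#'   `lh_loss_breakdown`: `adv_g`, `adv_d`, `ccl`, `oml`, `total`).
#' @export
train_step <- function(batch, models, weights, optimizers, lr, config) {
  x_A <- as_batch(batch$x_A); x_B <- as_batch(batch$x_B)
  check_same_shape(x_A, x_B, "train_step")
  la <- weights$lambda_adv; lc <- weights$lambda_ccl; lo <- weights$lambda_oml
  variant <- weights$variant

  fA <- gen_forward(models$G_A, x_B, keep_cache = TRUE)   # G_A(x_B) -> fake BL
  fB <- gen_forward(models$G_B, x_A, keep_cache = TRUE)   # G_B(x_A) -> fake FU
  rA <- gen_forward(models$G_A, fB$out, keep_cache = TRUE)
  rB <- gen_forward(models$G_B, fA$out, keep_cache = TRUE)
  # same-domain passes are only consumed by the OML/identity terms
  need_id <- variant %in% c("oml", "identity")
  iA <- if (need_id) gen_forward(models$G_A, x_A, keep_cache = TRUE)
  iB <- if (need_id) gen_forward(models$G_B, x_B, keep_cache = TRUE)
  dA_f <- disc_forward(models$D_A, fA$out, keep_cache = TRUE)
  dB_f <- disc_forward(models$D_B, fB$out, keep_cache = TRUE)
  dA_r <- disc_forward(models$D_A, x_A, keep_cache = TRUE)
  dB_r <- disc_forward(models$D_B, x_B, keep_cache = TRUE)

  advA <- adversarial_loss(dA_r$out, dA_f$out)
  advB <- adversarial_loss(dB_r$out, dB_f$out)
  adv_g <- (advA$generator + advB$generator) / 2
  adv_d <- (advA$discriminator + advB$discriminator) / 2
  ccl <- (cycle_consistency_loss(x_A, rA$out) +
            cycle_consistency_loss(x_B, rB$out)) / 2
  oml <- if (need_id)
    original_matching_loss(x_A, x_B, fA$out, iA$out, fB$out, iB$out,
                           variant = variant)
  else 0
  breakdown <- structure(
    list(adv_g = adv_g, adv_d = adv_d, ccl = ccl, oml = oml,
         total = la * adv_g + lc * ccl + lo * oml),
    class = "lh_loss_breakdown")
  for (term in c("adv_g", "adv_d", "ccl", "oml"))
    if (!is.finite(breakdown[[term]]))
      stop_lh("non-finite loss term '%s' in train_step", term)

  # ---- generator gradients ----
  gGA <- NULL; gGB <- NULL
  # cycle terms (each averaged over elements, directions averaged)
  bwrA <- gen_backward(models$G_A, rA$cache, lc * mean_abs_grad(rA$out, x_A) / 2)
  gGA <- add_grads(gGA, bwrA$grads)
  bwrB <- gen_backward(models$G_B, rB$cache, lc * mean_abs_grad(rB$out, x_B) / 2)
  gGB <- add_grads(gGB, bwrB$grads)
  # adversarial terms through the (frozen) discriminators
  sA <- pmin(1 - LOG_EPS, pmax(LOG_EPS, sigmoid_act(dA_f$out)))
  sB <- pmin(1 - LOG_EPS, pmax(LOG_EPS, sigmoid_act(dB_f$out)))
  dfakeA_adv <- disc_backward(models$D_A, dA_f$cache,
                              la * (-(1 - sA)) / length(sA) / 2)$dX
  dfakeB_adv <- disc_backward(models$D_B, dB_f$cache,
                              la * (-(1 - sB)) / length(sB) / 2)$dX
  # OML terms on fakes and same-domain outputs
  dfakeA <- dfakeA_adv + bwrB$dX
  dfakeB <- dfakeB_adv + bwrA$dX
  if (variant == "oml") {
    dfakeA <- dfakeA + lo * mean_abs_grad(fA$out, x_A)
    dfakeB <- dfakeB + lo * mean_abs_grad(fB$out, x_B)
  }
  bwfA <- gen_backward(models$G_A, fA$cache, dfakeA, want_dx = FALSE)
  gGA <- add_grads(gGA, bwfA$grads)
  bwfB <- gen_backward(models$G_B, fB$cache, dfakeB, want_dx = FALSE)
  gGB <- add_grads(gGB, bwfB$grads)
  if (variant %in% c("oml", "identity")) {
    bwiA <- gen_backward(models$G_A, iA$cache, lo * mean_abs_grad(iA$out, x_A),
                         want_dx = FALSE)
    gGA <- add_grads(gGA, bwiA$grads)
    bwiB <- gen_backward(models$G_B, iB$cache, lo * mean_abs_grad(iB$out, x_B),
                         want_dx = FALSE)
    gGB <- add_grads(gGB, bwiB$grads)
  }
  up <- adam_step(models$G_A$params, gGA, optimizers$G_A, lr,
                  config$adam_beta1, config$adam_beta2)
  models$G_A$params <- up$params; optimizers$G_A <- up$state
  up <- adam_step(models$G_B$params, gGB, optimizers$G_B, lr,
                  config$adam_beta1, config$adam_beta2)
  models$G_B$params <- up$params; optimizers$G_B <- up$state

  # ---- discriminator update (fakes detached; D params unchanged above) ----
  srA <- pmin(1 - LOG_EPS, pmax(LOG_EPS, sigmoid_act(dA_r$out)))
  srB <- pmin(1 - LOG_EPS, pmax(LOG_EPS, sigmoid_act(dB_r$out)))
  gDA <- add_grads(
    disc_backward(models$D_A, dA_r$cache, (-(1 - srA)) / length(srA) / 2,
                  want_dx = FALSE)$grads,
    disc_backward(models$D_A, dA_f$cache, sA / length(sA) / 2,
                  want_dx = FALSE)$grads)
  gDB <- add_grads(
    disc_backward(models$D_B, dB_r$cache, (-(1 - srB)) / length(srB) / 2,
                  want_dx = FALSE)$grads,
    disc_backward(models$D_B, dB_f$cache, sB / length(sB) / 2,
                  want_dx = FALSE)$grads)
  up <- adam_step(models$D_A$params, gDA, optimizers$D_A, lr,
                  config$adam_beta1, config$adam_beta2)
  models$D_A$params <- up$params; optimizers$D_A <- up$state
  up <- adam_step(models$D_B$params, gDB, optimizers$D_B, lr,
                  config$adam_beta1, config$adam_beta2)
  models$D_B$params <- up$params; optimizers$D_B <- up$state

  list(models = models, optimizers = optimizers, breakdown = breakdown)
}

#' Subject-level train/validation split
#'
#' Randomly splits subjects at the configured ratio (default 8:2) at the
#' subject level, so that slices from one subject never cross the split.
#'
#' @param subject_ids Character vector.
#' @param config An [train_config()].
#' @export
split_subjects <- function(subject_ids, config) {
  n <- length(subject_ids)
  n_val <- max(if (config$val_fraction > 0 && n > 1) 1L else 0L,
               floor(config$val_fraction * n))
  val <- with_seed(derive_seed(config$seed, 99L),
                   sample(subject_ids, n_val))
  list(train = setdiff(subject_ids, val), validation = val)
}

#' Train the paired harmonization model
#'
#' Iterates [train_step()] under the linear schedule over slice pairs from
#' the training subjects (shuffled each epoch with the run seed), logging a
#' per-iteration loss breakdown and writing checkpoints at the configured
#' cadence.
#'
#' @param config An [train_config()].
#' @param subjects Named list; each element has `pairs` (list of
#'   `lh_slice_pair` from [pair_slices()]).
#' @param out_dir Optional directory for checkpoints and the loss log CSV.
#' @param resume Optional checkpoint (path or object) to continue from; the
#'   iteration counter continues.
#' @return List `models`, `optimizers`, `log` (data.frame: iteration, lr,
#'   adv_g, adv_d, ccl, oml, total), `split`, `config`.
#' @export
train <- function(config, subjects, out_dir = NULL, resume = NULL) {
  if (length(subjects) == 0) stop_lh("empty dataset")
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("sub%03d", seq_along(subjects))
  split <- split_subjects(names(subjects), config)
  train_pairs <- unlist(lapply(subjects[split$train], `[[`, "pairs"),
                        recursive = FALSE)
  if (length(train_pairs) == 0) stop_lh("no training slice pairs")
  start_iter <- 0L
  if (!is.null(resume)) {
    ck <- if (is.character(resume)) load_checkpoint(resume) else resume
    models <- ck$models; optimizers <- ck$optimizers
    start_iter <- ck$iteration
  } else {
    models <- new_models(config)
    optimizers <- new_optimizers(models)
  }
  n_pairs <- length(train_pairs)
  sh <- dim(train_pairs[[1]]$bl_slice)
  log_rows <- vector("list", config$total_iterations - start_iter)
  order_state <- integer(0)
  epoch <- 0L
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (iter in seq.int(start_iter + 1L, config$total_iterations)) {
    if (length(order_state) < config$batch_size) {
      epoch <- epoch + 1L
      order_state <- c(order_state,
                       with_seed(derive_seed(config$seed, 1000L + epoch),
                                 sample.int(n_pairs)))
    }
    take <- order_state[seq_len(config$batch_size)]
    order_state <- order_state[-seq_len(config$batch_size)]
    x_A <- array(0, c(sh[1], sh[2], 1L, config$batch_size))
    x_B <- array(0, c(sh[1], sh[2], 1L, config$batch_size))
    for (j in seq_along(take)) {
      x_A[, , 1L, j] <- train_pairs[[take[j]]]$bl_slice
      x_B[, , 1L, j] <- train_pairs[[take[j]]]$fu_slice
    }
    lr <- lr_schedule(iter - 1L, config)
    step <- tryCatch(
      train_step(list(x_A = x_A, x_B = x_B), models, config$weights,
                 optimizers, lr, config),
      error = function(e) stop_lh("training aborted at iteration %d: %s",
                                  iter, conditionMessage(e)))
    models <- step$models; optimizers <- step$optimizers
    b <- step$breakdown
    log_rows[[iter - start_iter]] <- data.frame(
      iteration = iter, lr = lr, adv_g = b$adv_g, adv_d = b$adv_d,
      ccl = b$ccl, oml = b$oml, total = b$total)
    if (!is.null(out_dir) && config$checkpoint_every > 0 &&
        iter %% config$checkpoint_every == 0)
      save_checkpoint(models, optimizers, config, iter,
                      file.path(out_dir, sprintf("ckpt_%06d.rds", iter)))
  }
  log <- do.call(rbind, log_rows)
  if (!is.null(out_dir)) {
    write.csv(log, file.path(out_dir, "loss_log.csv"), row.names = FALSE)
    save_checkpoint(models, optimizers, config, config$total_iterations,
                    file.path(out_dir, "ckpt_final.rds"))
  }
  list(models = models, optimizers = optimizers, log = log, split = split,
       config = config)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned archive of the model weights, architecture
#' specs, loss weights, iteration counter and seed; loadable for inference
#' and for training resumption.
#'
#' @param models,optimizers,config,iteration Training state.
#' @param path Checkpoint file path (RDS).
#' @export
save_checkpoint <- function(models, optimizers, config, iteration, path) {
  saveRDS(list(version = 1L, models = models, optimizers = optimizers,
               config = config, weights = config$weights,
               iteration = as.integer(iteration), seed = config$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L)
    stop_lh("unsupported checkpoint version in '%s'", path)
  ck
}

#' Run the lambda_oml ablation
#'
#' Trains one model per coefficient value over shared data and seed, then
#' evaluates SSIM/PSNR (and LPIPS when an extractor is supplied) slice-wise
#' on the validation subjects for the two conditions BL vs FU->BL and
#' BL vs BL->FU->BL.
#'
#' @param lambda_values Coefficients of the original matching loss.
#' @param config Template [train_config()]; its `weights` are overridden
#'   per run (`variant = "none"` when the coefficient is 0).
#' @param subjects As for [train()].
#' @param extractor Optional LPIPS feature extractor.
#' @return `data.frame` (class `lh_ablation`): one row per lambda per
#'   condition with mean/sd per metric.
#' @export
run_ablation <- function(lambda_values = c(0, 1, 5, 10, 15), config, subjects,
                         extractor = NULL) {
  rows <- list()
  fits <- list()
  for (lam in lambda_values) {
    cfg <- config
    cfg$weights <- loss_weights(config$weights$lambda_adv,
                                config$weights$lambda_ccl, lam,
                                variant = if (lam == 0) "none" else "oml")
    fit <- train(cfg, subjects)
    fits[[as.character(lam)]] <- fit
    vals <- ablation_eval(fit, subjects, extractor)
    for (cond in names(vals)) {
      v <- vals[[cond]]
      row <- data.frame(lambda_oml = lam, condition = cond,
                        ssim_mean = mean(v$ssim), ssim_sd = sd(v$ssim),
                        psnr_mean = mean(v$psnr), psnr_sd = sd(v$psnr))
      if (!is.null(v$lpips)) {
        row$lpips_mean <- mean(v$lpips); row$lpips_sd <- sd(v$lpips)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lh_ablation", class(out))
  attr(out, "fits") <- fits       # trained models, for volume-level reuse
  out
}

# Slice-wise validation metrics for the two ablation conditions.
ablation_eval <- function(fit, subjects, extractor = NULL) {
  val_ids <- fit$split$validation
  if (length(val_ids) == 0) stop_lh("no validation subjects to evaluate")
  harm <- list(ssim = c(), psnr = c(), lpips = if (is.null(extractor)) NULL else c())
  rec <- harm
  cfgW <- ssim_config()
  for (sid in val_ids) {
    for (pr in subjects[[sid]]$pairs) {
      bl <- pr$bl_slice
      fu2bl <- generator_apply(fit$models$G_A, pr$fu_slice)
      bl2fu2bl <- generator_apply(fit$models$G_A,
                                  generator_apply(fit$models$G_B, bl))
      harm$ssim <- c(harm$ssim, ssim(bl, fu2bl, cfgW))
      harm$psnr <- c(harm$psnr, psnr(bl, fu2bl))
      rec$ssim <- c(rec$ssim, ssim(bl, bl2fu2bl, cfgW))
      rec$psnr <- c(rec$psnr, psnr(bl, bl2fu2bl))
      if (!is.null(extractor)) {
        harm$lpips <- c(harm$lpips, lpips(bl, fu2bl, extractor))
        rec$lpips <- c(rec$lpips, lpips(bl, bl2fu2bl, extractor))
      }
    }
  }
  list("FU2BL" = harm, "BL2FU2BL" = rec)
}

#' Serialize an ablation table to CSV
#'
#' @param ablation An `lh_ablation` from [run_ablation()].
#' @param path Output CSV path.
#' @export
write_ablation_csv <- function(ablation, path) {
  write.csv(ablation, path, row.names = FALSE)
  invisible(path)
}
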