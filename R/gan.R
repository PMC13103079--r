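# Translation model core: a residual-block generator and a patch-level
# convolutional discriminator with hand-rolled backpropagation (no deep
# learning framework is available in the target stack), plus the training
# objective: adversarial loss in the printed log (cross-entropy) form,
# cycle-consistency L1, the four-term original matching loss, and their
# weighted composition.
#
# Image batches are numeric arrays (H, W, C, N).

LOG_EPS <- 1e-7

relu <- function(x) pmax(x, 0)
lrelu <- function(x, alpha = 0.2) pmax(x, 0) + alpha * pmin(x, 0)
sigmoid_act <- function(x) 1 / (1 + exp(-x))

as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L))
  else if (is.array(x) && length(dim(x)) == 4L) x
  else stop_lh("expected a 2D matrix or 4D (H,W,C,N) batch array")
}

#' Generator / discriminator architecture specs
#'
#' The generator is a residual-block network operating at full resolution:
#' a 3x3 stem, `n_res_blocks` residual blocks, and a 3x3 output projection
#' squashed to `[0, 1]` by a sigmoid, following the canonical
#' cycle-consistent translator design (randomly initialised; an
#' identity-initialised residual variant was evaluated during development
#' and rejected because it prevents the plain cycle-consistent baseline
#' from exhibiting the structural drift the original matching loss exists
#' to correct). The discriminator is a
#' patch-level classifier: `n_layers` 4x4 convolutions (stride 2 except the
#' last) emitting a real/fake logit map. Depth and width are configuration,
#' with small defaults suitable for CPU-scale runs; `norm` accepts only
#' `"none"` in this implementation.
#'
#' @param base_filters Channel width of the first convolution.
#' @param n_res_blocks Number of residual blocks (generator).
#' @param n_layers Number of convolution layers (discriminator, >= 2).
#' @param norm Normalization kind; only `"none"` is supported.
#' @export
generator_spec <- function(base_filters = 8, n_res_blocks = 1, norm = "none") {
  if (base_filters < 1 || n_res_blocks < 0) stop_lh("invalid generator spec")
  if (!identical(norm, "none"))
    stop_lh("normalization kind '%s' is not implemented (only 'none')", norm)
  list(base_filters = as.integer(base_filters),
       n_res_blocks = as.integer(n_res_blocks), norm = norm)
}

#' @rdname generator_spec
#' @export
discriminator_spec <- function(base_filters = 8, n_layers = 3) {
  if (base_filters < 1 || n_layers < 2) stop_lh("invalid discriminator spec")
  list(base_filters = as.integer(base_filters), n_layers = as.integer(n_layers))
}

init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(W = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' Build a generator
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for weight initialisation (reproducible).
#' @return An `lh_generator` (fields `spec`, `params`).
#' @export
make_generator <- function(spec = generator_spec(), seed = 1) {
  nf <- spec$base_filters
  params <- with_seed(seed, {
    p <- list(head = init_conv(3, 3, 1, nf))
    for (i in seq_len(spec$n_res_blocks)) {
      p[[sprintf("res%d_c1", i)]] <- init_conv(3, 3, nf, nf)
      p[[sprintf("res%d_c2", i)]] <- init_conv(3, 3, nf, nf)
    }
    p$tail <- init_conv(3, 3, nf, 1)
    p
  })
  structure(list(spec = spec, params = params), class = "lh_generator")
}

#' Build a discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed.
#' @return An `lh_discriminator`.
#' @export
make_discriminator <- function(spec = discriminator_spec(), seed = 1) {
  nf <- spec$base_filters
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(spec$n_layers)) {
      cout <- if (i == spec$n_layers) 1L else nf * 2L^(i - 1L)
      p[[sprintf("d%d", i)]] <- init_conv(4, 4, cin, cout)
      cin <- cout
    }
    p
  })
  structure(list(spec = spec, params = params), class = "lh_discriminator")
}

gen_forward <- function(gen, X, keep_cache = FALSE) {
  X <- as_batch(X)
  p <- gen$params
  cache <- list(x = X)
  z0 <- .conv2d_fwd_cpp(X, p$head$W, p$head$b, 1L, 1L)
  h <- relu(z0)
  cache$z0 <- z0
  blocks <- list()
  for (i in seq_len(gen$spec$n_res_blocks)) {
    c1 <- p[[sprintf("res%d_c1", i)]]; c2 <- p[[sprintf("res%d_c2", i)]]
    z1 <- .conv2d_fwd_cpp(h, c1$W, c1$b, 1L, 1L)
    a1 <- relu(z1)
    z2 <- .conv2d_fwd_cpp(a1, c2$W, c2$b, 1L, 1L)
    blocks[[i]] <- list(hin = h, z1 = z1, a1 = a1)
    h <- h + z2
  }
  cache$blocks <- blocks
  cache$htail <- h
  zt <- .conv2d_fwd_cpp(h, p$tail$W, p$tail$b, 1L, 1L)
  out <- sigmoid_act(zt)
  cache$out <- out
  if (keep_cache) list(out = out, cache = cache) else out
}

# Backprop through the generator; returns parameter grads and (optionally)
# the input gradient.
gen_backward <- function(gen, cache, dOut, want_dx = TRUE) {
  p <- gen$params
  grads <- list()
  dzt <- dOut * cache$out * (1 - cache$out)
  bw <- .conv2d_bwd_cpp(cache$htail, p$tail$W, dzt, 1L, 1L)
  grads$tail <- list(W = bw$dW, b = bw$db)
  dh <- bw$dX
  for (i in rev(seq_len(gen$spec$n_res_blocks))) {
    blk <- cache$blocks[[i]]
    c1 <- p[[sprintf("res%d_c1", i)]]; c2 <- p[[sprintf("res%d_c2", i)]]
    # h_out = h_in + conv2(relu(conv1(h_in)))
    bw2 <- .conv2d_bwd_cpp(blk$a1, c2$W, dh, 1L, 1L)
    grads[[sprintf("res%d_c2", i)]] <- list(W = bw2$dW, b = bw2$db)
    dz1 <- bw2$dX * (blk$z1 > 0)
    bw1 <- .conv2d_bwd_cpp(blk$hin, c1$W, dz1, 1L, 1L)
    grads[[sprintf("res%d_c1", i)]] <- list(W = bw1$dW, b = bw1$db)
    dh <- dh + bw1$dX
  }
  dz0 <- dh * (cache$z0 > 0)
  bw0 <- .conv2d_bwd_cpp(cache$x, p$head$W, dz0, 1L, 1L, want_dx)
  grads$head <- list(W = bw0$dW, b = bw0$db)
  list(grads = grads, dX = if (want_dx) bw0$dX else NULL)
}

disc_forward <- function(disc, X, keep_cache = FALSE) {
  X <- as_batch(X)
  p <- disc$params
  n <- disc$spec$n_layers
  cache <- list(inputs = list(), z = list())
  h <- X
  for (i in seq_len(n)) {
    stride <- if (i == n) 1L else 2L
    cache$inputs[[i]] <- h
    z <- .conv2d_fwd_cpp(h, p[[sprintf("d%d", i)]]$W, p[[sprintf("d%d", i)]]$b,
                         stride, 1L)
    cache$z[[i]] <- z
    h <- if (i == n) z else lrelu(z)
  }
  if (keep_cache) list(out = h, cache = cache) else h
}

disc_backward <- function(disc, cache, dOut, want_dx = TRUE) {
  p <- disc$params
  n <- disc$spec$n_layers
  grads <- list()
  dh <- dOut
  for (i in rev(seq_len(n))) {
    stride <- if (i == n) 1L else 2L
    dz <- if (i == n) dh else dh * (0.2 + 0.8 * (cache$z[[i]] > 0))
    bw <- .conv2d_bwd_cpp(cache$inputs[[i]], p[[sprintf("d%d", i)]]$W, dz,
                          stride, 1L, want_dx || i > 1L)
    grads[[sprintf("d%d", i)]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dX
  }
  list(grads = grads, dX = if (want_dx) dh else NULL)
}

#' Apply a generator to a single 2D slice
#'
#' @param gen An `lh_generator` (or a plain `function(matrix) matrix`, which
#'   is applied directly — used to inject identity or reference mappings).
#' @param slice A 2D matrix.
#' @return The translated slice, same shape, values in `[0, 1]`.
#' @export
generator_apply <- function(gen, slice) {
  if (is.function(gen)) return(gen(slice))
  if (!inherits(gen, "lh_generator")) stop_lh("expected an lh_generator or function")
  out <- gen_forward(gen, as_batch(slice))
  matrix(out, nrow = dim(out)[1])
}

#' Loss weights for the final objective
#'
#' The defaults are the published operating point: `lambda_adv = 1`,
#' `lambda_ccl = 5`, `lambda_oml = 10`. The `variant` flag selects the active
#' structural-consistency term: `"oml"` (the four-term original matching
#' loss), `"identity"` (only the two same-domain terms, the classical
#' identity-mapping loss), or `"none"` (plain cycle-consistent objective;
#' requires `lambda_oml = 0`).
#'
#' @param lambda_adv,lambda_ccl,lambda_oml Non-negative weights.
#' @param variant `"oml"`, `"identity"` or `"none"`.
#' @export
loss_weights <- function(lambda_adv = 1, lambda_ccl = 5, lambda_oml = 10,
                         variant = c("oml", "identity", "none")) {
  variant <- match.arg(variant)
  if (any(c(lambda_adv, lambda_ccl, lambda_oml) < 0))
    stop_lh("loss weights must be non-negative")
  if (variant == "none" && lambda_oml != 0)
    stop_lh("variant 'none' requires lambda_oml = 0")
  structure(list(lambda_adv = lambda_adv, lambda_ccl = lambda_ccl,
                 lambda_oml = lambda_oml, variant = variant),
            class = "lh_loss_weights")
}

#' Adversarial loss (log form)
#'
#' Raw discriminator score maps are squashed through a sigmoid and clamped
#' away from 0/1 before the logs. The discriminator term is the negation of
#' the printed objective `E[log D(x)] + E[log(1 - D(G(x)))]` (so the
#' discriminator minimizes it); the generator term `-E[log D(G(x))]` drives
#' fakes toward the "real" label.
#'
#' @param real_scores,fake_scores Finite arrays of raw (pre-sigmoid) scores.
#' @return List with `generator` and `discriminator` loss values.
#' @export
adversarial_loss <- function(real_scores, fake_scores) {
  if (!all(is.finite(real_scores)) || !all(is.finite(fake_scores)))
    stop_lh("adversarial_loss: non-finite scores")
  sr <- pmin(1 - LOG_EPS, pmax(LOG_EPS, sigmoid_act(real_scores)))
  sf <- pmin(1 - LOG_EPS, pmax(LOG_EPS, sigmoid_act(fake_scores)))
  list(generator = -mean(log(sf)),
       discriminator = -(mean(log(sr)) + mean(log(1 - sf))))
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between an image and its round-trip
#' reconstruction through both generators.
#'
#' @param x,x_reconstructed Equal-shaped arrays.
#' @export
cycle_consistency_loss <- function(x, x_reconstructed) {
  check_same_shape(as_batch(x), as_batch(x_reconstructed), "cycle_consistency_loss")
  mean(abs(x - x_reconstructed))
}

#' Original matching loss
#'
#' The four-term L1 penalty tying every generator-domain combination of a
#' registered baseline/follow-up pair back to the originals:
#' `||x_A - G_A(x_B)||_1 + ||x_A - G_A(x_A)||_1 + ||x_B - G_B(x_A)||_1 +
#' ||x_B - G_B(x_B)||_1`, each an element-mean, summed with equal weight.
#' `variant = "identity"` keeps only the two same-domain terms (the
#' identity-mapping loss); `"none"` returns 0.
#'
#' @param x_A,x_B The registered pair.
#' @param g_A_of_xB,g_A_of_xA,g_B_of_xA,g_B_of_xB Generator outputs.
#' @param variant Term selection, see [loss_weights()].
#' @export
original_matching_loss <- function(x_A, x_B, g_A_of_xB, g_A_of_xA,
                                   g_B_of_xA, g_B_of_xB,
                                   variant = c("oml", "identity", "none")) {
  variant <- match.arg(variant)
  imgs <- lapply(list(x_A, x_B, g_A_of_xB, g_A_of_xA, g_B_of_xA, g_B_of_xB),
                 as_batch)
  for (i in 2:6) check_same_shape(imgs[[1]], imgs[[i]], "original_matching_loss")
  if (variant == "none") return(0)
  t2 <- mean(abs(x_A - g_A_of_xA))
  t4 <- mean(abs(x_B - g_B_of_xB))
  if (variant == "identity") return(t2 + t4)
  t1 <- mean(abs(x_A - g_A_of_xB))
  t3 <- mean(abs(x_B - g_B_of_xA))
  t1 + t2 + t3 + t4
}

#' Compose the final training objective
#'
#' `lambda_adv * L_adv + lambda_ccl * L_ccl + lambda_oml * L_oml`, with
#' `L_adv` the generator adversarial term.
#'
#' @param breakdown List with finite components `adv`, `ccl`, `oml` (an
#'   `lh_loss_breakdown` from [train_step()] also works, using its `adv_g`).
#' @param weights An [loss_weights()].
#' @export
total_loss <- function(breakdown, weights) {
  if (!inherits(weights, "lh_loss_weights")) stop_lh("expected lh_loss_weights")
  adv <- breakdown$adv %||% breakdown$adv_g
  comps <- c(adv, breakdown$ccl, breakdown$oml)
  if (!all(is.finite(comps))) stop_lh("total_loss: non-finite components")
  weights$lambda_adv * adv + weights$lambda_ccl * breakdown$ccl +
    weights$lambda_oml * breakdown$oml
}
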