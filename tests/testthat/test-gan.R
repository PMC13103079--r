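test_that("adversarial loss reproduces the printed objective", {
  z <- array(0, c(4, 4, 1, 2))          # sigmoid -> 0.5 everywhere
  al <- adversarial_loss(z, z)
  expect_equal(al$discriminator, 2 * log(2), tolerance = 1e-9)
  expect_equal(al$generator, log(2), tolerance = 1e-9)
  # perfect discriminator limit: D(x)->1, D(G(x))->0 under clamping
  big <- array(50, c(4, 4, 1, 1))
  al2 <- adversarial_loss(big, -big)
  expect_lt(al2$discriminator, 1e-6)
  expect_gt(al2$discriminator, 0)
  # generator term strictly decreases as D(G(x)) increases
  gvals <- sapply(seq(-3, 3, by = 0.5), function(s)
    adversarial_loss(z, array(s, c(4, 4, 1, 1)))$generator)
  expect_true(all(diff(gvals) < 0))
  expect_error(adversarial_loss(array(NaN, c(2, 2, 1, 1)), z), "non-finite")
})

test_that("cycle-consistency loss matches hand evaluations", {
  x <- array(0.5, c(2, 2, 1, 1))
  expect_equal(cycle_consistency_loss(x, x), 0)
  expect_equal(cycle_consistency_loss(x, x - 0.25), 0.25)
  a <- matrix(c(0, 0.5, 1, 0.5), 2)     # [0,1;0.5,0.5] in row-major reading
  b <- matrix(c(0.1, 0.5, 0.9, 0.5), 2)
  expect_equal(cycle_consistency_loss(a, b), 0.05)
  expect_error(cycle_consistency_loss(x, array(0, c(3, 3, 1, 1))),
               "shape mismatch")
})

test_that("original matching loss sums its four printed terms", {
  z <- matrix(0, 4, 4); o <- matrix(1, 4, 4)
  # identity generators and x_A == x_B
  expect_equal(original_matching_loss(z, z, z, z, z, z), 0)
  # x_A = 0, x_B = 1, both generators map everything to 0:
  # terms 0 + 0 + 1 + 1 = 2
  expect_equal(original_matching_loss(z, o, z, z, z, z), 2)
  set.seed(21)
  xa <- matrix(runif(16), 4); xb <- matrix(runif(16), 4)
  ga_xb <- matrix(runif(16), 4); ga_xa <- matrix(runif(16), 4)
  gb_xa <- matrix(runif(16), 4); gb_xb <- matrix(runif(16), 4)
  full <- original_matching_loss(xa, xb, ga_xb, ga_xa, gb_xa, gb_xb)
  idt <- original_matching_loss(xa, xb, ga_xb, ga_xa, gb_xa, gb_xb,
                                variant = "identity")
  # identity variant is exactly the two same-domain terms
  expect_equal(idt, mean(abs(xa - ga_xa)) + mean(abs(xb - gb_xb)),
               tolerance = 1e-12)
  expect_equal(full - idt, mean(abs(xa - ga_xb)) + mean(abs(xb - gb_xa)),
               tolerance = 1e-12)
  expect_equal(original_matching_loss(xa, xb, ga_xb, ga_xa, gb_xa, gb_xb,
                                      variant = "none"), 0)
  expect_gt(full, 0)
})

test_that("total loss recomposes linearly from the published weights", {
  w <- loss_weights(1, 5, 10)
  expect_equal(total_loss(list(adv = 0.2, ccl = 0.1, oml = 0.05), w), 1.2)
  expect_equal(total_loss(list(adv = 0, ccl = 0, oml = 0), w), 0)
  # linear in each lambda
  b <- list(adv = 0.3, ccl = 0.2, oml = 0.1)
  for (slot in c("lambda_adv", "lambda_ccl", "lambda_oml")) {
    w1 <- w; w1[[slot]] <- w[[slot]] + 1
    w2 <- w; w2[[slot]] <- w[[slot]] + 2
    d1 <- total_loss(b, w1) - total_loss(b, w)
    d2 <- total_loss(b, w2) - total_loss(b, w1)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
  expect_error(loss_weights(-1, 5, 10), "non-negative")
  expect_error(loss_weights(1, 5, 1, variant = "none"), "lambda_oml = 0")
})

test_that("generators and discriminators honor their shape/seed contracts", {
  g1 <- make_generator(generator_spec(4, 1), seed = 7)
  g2 <- make_generator(generator_spec(4, 1), seed = 7)
  expect_identical(g1$params, g2$params)
  x <- matrix(runif(64 * 64), 64)
  y <- generator_apply(g1, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= 1))
  d <- make_discriminator(discriminator_spec(4, 3), seed = 7)
  sc <- longiharm:::disc_forward(d, array(x, c(64, 64, 1, 1)))
  expect_identical(dim(sc), c(15L, 15L, 1L, 1L))   # patch score map
  expect_true(all(is.finite(sc)))
  expect_error(generator_spec(norm = "instance"), "not implemented")
})

test_that("a reduced-spec forward pass is fast enough for CPU batches", {
  g <- make_generator(generator_spec(base_filters = 16, n_res_blocks = 3),
                      seed = 1)
  x <- array(runif(64 * 64 * 16), c(64, 64, 1, 16))
  elapsed <- system.time(longiharm:::gen_forward(g, x))["elapsed"]
  expect_lt(elapsed, 1)
})

test_that("backprop gradients agree with finite differences", {
  set.seed(22)
  g <- make_generator(generator_spec(3, 1), seed = 5)
  X <- array(runif(12 * 12), c(12, 12, 1, 1))
  target <- array(runif(12 * 12), c(12, 12, 1, 1))
  fwd <- longiharm:::gen_forward(g, X, keep_cache = TRUE)
  bw <- longiharm:::gen_backward(g, fwd$cache, 2 * (fwd$out - target))
  loss <- function(gg) sum((longiharm:::gen_forward(gg, X) - target)^2)
  e <- 1e-6
  for (nm in names(g$params)) {
    gp <- g; gp$params[[nm]]$W[2] <- gp$params[[nm]]$W[2] + e
    gm <- g; gm$params[[nm]]$W[2] <- gm$params[[nm]]$W[2] - e
    expect_equal(bw$grads[[nm]]$W[2], (loss(gp) - loss(gm)) / (2 * e),
                 tolerance = 1e-5)
  }
  # input gradient (chains through residual block and sigmoid)
  Xp <- X; Xp[30] <- Xp[30] + e
  Xm <- X; Xm[30] <- Xm[30] - e
  num <- (sum((longiharm:::gen_forward(g, Xp) - target)^2) -
            sum((longiharm:::gen_forward(g, Xm) - target)^2)) / (2 * e)
  expect_equal(bw$dX[30], num, tolerance = 1e-5)
  # discriminator path, including stride-2 layers
  d <- make_discriminator(discriminator_spec(3, 3), seed = 6)
  df <- longiharm:::disc_forward(d, X, keep_cache = TRUE)
  dbw <- longiharm:::disc_backward(d, df$cache, 2 * df$out)
  dloss <- function(dd) sum(longiharm:::disc_forward(dd, X)^2)
  dp <- d; dp$params$d2$W[4] <- dp$params$d2$W[4] + e
  dm <- d; dm$params$d2$W[4] <- dm$params$d2$W[4] - e
  expect_equal(dbw$grads$d2$W[4], (dloss(dp) - dloss(dm)) / (2 * e),
               tolerance = 1e-5)
})
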