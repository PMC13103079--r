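# Shared fixtures: tiny phantom specs and a memoized default pair so slow
# objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# A quiet style: no noise, no bias, no gamma, no PSF — renders are exactly
# piecewise-constant, which the noiseless-limit examples rely on.
quiet_style <- function(means = c(background = 0.02, csf = 0.15,
                                  gm = 0.45, wm = 0.70), gamma = 1) {
  list(means = means, region_means = NULL, gamma = gamma, bias = rep(0, 9),
       noise_sd = 0, psf_sd = 0)
}

small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_size = 32, seed = seed, ...)
}

default_pair <- function() memo("default_pair", {
  make_longitudinal_pair(phantom_spec(seed = 3))
})

# Brute-force windowed SSIM oracle: explicit loops over valid windows with
# Gaussian weights; independent of the sepfilter-based implementation path.
ssim_oracle <- function(x, y, size = 11, sd = 1.5, c1 = 1e-4, c2 = 9e-4) {
  k1 <- exp(-((seq_len(size) - (size + 1) / 2)^2) / (2 * sd^2))
  k1 <- k1 / sum(k1)
  nd <- length(dim(x))
  w <- if (nd == 2) outer(k1, k1) else outer(outer(k1, k1), k1)
  dims <- dim(x)
  nw <- dims - size + 1
  total <- 0; count <- 0
  idx <- as.matrix(expand.grid(lapply(nw, seq_len)))
  for (r in seq_len(nrow(idx))) {
    sl <- lapply(seq_len(nd), function(d) idx[r, d] + 0:(size - 1))
    wx <- do.call(`[`, c(list(x), sl))
    wy <- do.call(`[`, c(list(y), sl))
    mx <- sum(w * wx); my <- sum(w * wy)
    vx <- sum(w * wx^2) - mx^2; vy <- sum(w * wy^2) - my^2
    cxy <- sum(w * wx * wy) - mx * my
    total <- total + ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
    count <- count + 1
  }
  total / count
}

# All-pairs average-Hausdorff oracle on boundary voxels.
hausdorff_oracle <- function(a, b, spacing = c(1, 1, 1)) {
  pts <- function(m) {
    m3 <- if (length(dim(m)) == 2) array(m, c(dim(m), 1)) else m
    bp <- longiharm:::boundary_points(m3 > 0, spacing)
    bp
  }
  pa <- pts(a); pb <- pts(b)
  dmat <- as.matrix(dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                         nrow(pa) + seq_len(nrow(pb)),
                                         drop = FALSE]
  (mean(apply(dmat, 1, min)) + mean(apply(dmat, 2, min))) / 2
}
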