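# SSIM, Clarkson similarity, sweep orchestration, masked dual fit, effect
# sizes and the strength-inhibition regression.

test_that("global SSIM has its fixed points and matches the scalar formula", {
  set.seed(4)
  a <- matrix(rnorm(64), 8); a <- (a + t(a)) / 2; diag(a) <- 0
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, a + 1), ssim(a + 1, a))  # symmetry
  # direct evaluation of the SSIM formula for a constant shift
  b <- a + 0.4
  L <- max(a, b) - min(a, b)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- mean(a); mu_b <- mean(b)
  v <- mean((a - mu_a)^2)
  want <- ((2 * mu_a * mu_b + C1) * (2 * v + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (2 * v + C2))
  expect_equal(ssim(a, b), want, tolerance = 1e-12)
  expect_lt(ssim(a, b), 1)
  # permuting one argument can only reduce the similarity
  perm <- a[sample(8), sample(8)]
  expect_lt(ssim(a, perm), ssim(a, a))
  expect_error(ssim(a, matrix(0, 4, 4)), "shape")
  expect_equal(ssim(matrix(2, 3, 3), matrix(2, 3, 3)), 1)
  # two different constant matrices still span a nonzero joint range
  expect_lt(ssim(matrix(2, 3, 3), matrix(3, 3, 3)), 1)
})

test_that("Clarkson similarity is scale-invariant with known values", {
  x <- c(0.2, 0.5, 0.3)
  expect_equal(clarkson_similarity(x, x), 1)
  expect_equal(clarkson_similarity(x, 17 * x), 1, tolerance = 1e-12)
  expect_equal(clarkson_similarity(c(1, 0), c(0, 1)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(clarkson_similarity(c(0, 0), x[1:2]), "zero")
  set.seed(1)
  for (i in 1:10) {
    u <- runif(4); v <- runif(4)
    s <- clarkson_similarity(u, v)
    expect_true(s >= 0 && s <= 1)
    expect_equal(s, clarkson_similarity(3 * u, 0.1 * v), tolerance = 1e-12)
  }
})

test_that("grid sweeps are order-invariant, resumable and record failures", {
  calls <- new.env(); calls$n <- 0L
  obj <- function(cell, seed) {
    calls$n <- calls$n + 1L
    c(score = cell$K + cell$r_alpha + 0 * seed)
  }
  axes <- list(K = c(0, 0.5, 1), r_alpha = c(0.2, 0.8))
  g1 <- grid_sweep(axes, obj, seeds = 1:2)
  expect_equal(nrow(g1), 12)
  expect_equal(g1$score, g1$K + g1$r_alpha)
  # order invariance: reversed axes give the same cell set
  g2 <- grid_sweep(list(K = rev(axes$K), r_alpha = rev(axes$r_alpha)), obj,
                   seeds = 1:2)
  o1 <- g1[order(g1$K, g1$r_alpha, g1$seed), c("K", "r_alpha", "score")]
  o2 <- g2[order(g2$K, g2$r_alpha, g2$seed), c("K", "r_alpha", "score")]
  expect_equal(o1, o2, ignore_attr = TRUE)
  # resumability: completed rows are not recomputed
  calls$n <- 0L
  g3 <- grid_sweep(axes, obj, seeds = 1:2, done = g1)
  expect_equal(calls$n, 0L)
  expect_equal(nrow(g3), 12)
  # single-cell sweep and failure capture
  g4 <- grid_sweep(list(K = 1), function(cell, seed) stop("boom"), seeds = 1)
  expect_equal(g4$error, "boom")
})

test_that("masked dual fit reduces to argmax under a trivial mask", {
  set.seed(8)
  grid <- expand.grid(K = seq(0, 1, 0.25), r_alpha = seq(0, 1, 0.25))
  grid$ssim <- runif(nrow(grid))
  grid$power_fit <- 1
  best <- masked_dual_fit(grid, threshold = 0.85)
  expect_true(best$feasible)
  expect_equal(best$best$ssim, max(grid$ssim))
  # threshold 0 degenerates to the unmasked argmax
  grid$power_fit <- runif(nrow(grid))
  b0 <- masked_dual_fit(grid, threshold = 0)
  expect_equal(b0$best$ssim, max(grid$ssim))
  # mask can exclude the global maximum
  grid$power_fit <- ifelse(grid$ssim == max(grid$ssim), 0.1, 0.9)
  bm <- masked_dual_fit(grid, threshold = 0.85)
  expect_lt(bm$best$ssim, max(grid$ssim))
  expect_equal(bm$best$ssim, max(grid$ssim[grid$power_fit >= 0.85]))
  # random grids against a brute-force filter + max oracle
  for (i in 1:10) {
    grid$ssim <- runif(nrow(grid)); grid$power_fit <- runif(nrow(grid))
    got <- masked_dual_fit(grid, threshold = 0.6)
    keep <- grid[grid$power_fit >= 0.6, ]
    if (!nrow(keep)) {
      expect_false(got$feasible)
    } else {
      expect_equal(got$best$ssim, max(keep$ssim))
      expect_equal(got$n_feasible, nrow(keep))
    }
  }
  # explicit no-feasible-cell result
  grid$power_fit <- 0
  expect_false(masked_dual_fit(grid, threshold = 0.85)$feasible)
})

test_that("Cohen's d uses the pooled SD and labels follow convention", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)
  # means one pooled SD apart give exactly 1
  y <- x + sd(x)
  expect_equal(cohens_d(y, x), 1, tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_equal(effect_size_label(1.5), "very large")
  expect_equal(effect_size_label(-1.5), "very large")
  expect_equal(effect_size_label(0.1), "very small")
  expect_equal(effect_size_label(2.4), "huge")
})

test_that("strength-inhibition regression matches closed-form least squares", {
  s <- c(1, 2, 3, 4)
  fit <- strength_inhibition_slope(s, 2 * s + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # hand data against the normal-equation oracle
  y <- c(0.3, 1.1, 0.9, 2.0)
  fit2 <- strength_inhibition_slope(s, y)
  X <- cbind(1, s)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)
  # uncorrelated vectors: slope near zero
  set.seed(10)
  n <- 4000
  fit3 <- strength_inhibition_slope(runif(n), runif(n))
  expect_lt(abs(fit3$slope), 0.1)
  expect_error(strength_inhibition_slope(rep(1, 5), rnorm(5)), "constant")
  expect_error(strength_inhibition_slope(1:2, 1:2), "3 nodes")
})
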