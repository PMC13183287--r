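# Connectome validation, homotopic reinforcement, synthetic generation,
# strength and coupling input.

test_that("connectome validation normalizes, zeroes the diagonal, rejects bad input", {
  m <- matrix(c(0, 2, 2, 0), 2)
  c <- connectome(m)
  expect_equal(max(c), 1)
  expect_equal(unclass(c), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  md <- matrix(c(5, 1, 1, 5), 2)
  expect_equal(diag(unclass(connectome(md))), c(0, 0), ignore_attr = TRUE)
  bad <- matrix(c(0, 1, 0.2, 0), 2)
  expect_error(connectome(bad), "asymmetry")
  expect_error(connectome(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  expect_error(connectome(matrix(c(0, NaN, NaN, 0), 2)), "NaN")
  expect_error(connectome(matrix(0, 2, 3)), "square")
})

test_that("homotopic reinforcement touches only the anti-diagonal", {
  set.seed(8)
  n <- 10
  base <- matrix(runif(n * n, 0, 0.6), n)
  base <- (base + t(base)) / 2; diag(base) <- 0
  c0 <- connectome(base)
  c1 <- reinforce_homotopic(c0, 0.9)
  anti <- row(c0) + col(c0) == n + 1
  expect_true(all(unclass(c1)[anti] >= 0.9 - 1e-12))
  expect_equal(unclass(c1)[!anti & row(c0) != col(c0)],
               unclass(c0)[!anti & row(c0) != col(c0)])
  # weight 0 is the identity transform
  expect_equal(unclass(reinforce_homotopic(c0, 0)), unclass(c0))
  # zero matrix with weight 1 gives the perfect pairing matrix
  zc <- connectome(matrix(0, 4, 4))
  pc <- unclass(reinforce_homotopic(zc, 1))
  expect_equal(pc, (row(pc) + col(pc) == 5) * 1, ignore_attr = TRUE)
  expect_error(reinforce_homotopic(connectome(matrix(0, 3, 3)), 0.5), "odd")
})

test_that("synthetic connectomes are reproducible, modular and mirror-symmetric", {
  c1 <- synthetic_connectome(20, seed = 5)
  c2 <- synthetic_connectome(20, seed = 5)
  expect_identical(unclass(c1), unclass(c2))
  expect_true(isSymmetric(unclass(c1)))
  expect_equal(diag(unclass(c1)), rep(0, 20), ignore_attr = TRUE)
  expect_equal(max(c1), 1)
  w <- unclass(c1)
  expect_equal(w, w[20:1, 20:1], ignore_attr = TRUE)  # hemispheric mirror
  # density 1 gives the complete graph minus the diagonal
  cf <- unclass(synthetic_connectome(8, seed = 2, density = 1))
  expect_true(all(cf[upper.tri(cf)] > 0))
  # within-module weights dominate between-module weights
  cm <- unclass(synthetic_connectome(20, seed = 3, modules = 2))[1:10, 1:10]
  mod <- sort(rep(1:2, 5))
  same <- outer(mod, mod, "==") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[!outer(mod, mod, "==") & upper.tri(cm)]))
  expect_error(synthetic_connectome(7, 1), "even")
  expect_error(synthetic_connectome(10, 1, density = 0), "density")
})

test_that("nodal strength is the row sum and matches column sums", {
  z <- connectome(matrix(0, 4, 4))
  expect_equal(unname(nodal_strength(z)), rep(0, 4))
  full <- connectome(matrix(1, 4, 4) - diag(4))
  expect_equal(unname(nodal_strength(full)), rep(3, 4))
  c1 <- synthetic_connectome(12, seed = 9)
  expect_equal(unname(nodal_strength(c1)), unname(colSums(unclass(c1))))
})

test_that("coupling input equals the naive double-loop oracle and is linear", {
  m <- matrix(c(0, 0.5, 0.2,
                0.5, 0, 1,
                0.2, 1, 0), 3, byrow = TRUE)
  c3 <- connectome(m)
  rates <- c(1, 2, 3)
  K <- 0.7; C <- 135
  oracle <- numeric(3)
  for (i in 1:3) for (j in 1:3) if (i != j)
    oracle[i] <- oracle[i] + K * C * unclass(c3)[i, j] * rates[j]
  expect_equal(coupling_input(rates, c3, K, C), oracle, tolerance = 1e-12)
  expect_equal(coupling_input(rates, c3, 0), rep(0, 3))
  expect_equal(coupling_input(rates, connectome(matrix(0, 3, 3)), 2),
               rep(0, 3))
  expect_error(coupling_input(c(1, 2), c3, 1), "length")
  # linearity in K and in the rate vector, on random instances
  set.seed(13)
  for (rep in 1:5) {
    cr <- synthetic_connectome(10, seed = rep)
    r1 <- runif(10); r2 <- runif(10)
    expect_equal(coupling_input(r1 + r2, cr, 0.3),
                 coupling_input(r1, cr, 0.3) + coupling_input(r2, cr, 0.3),
                 tolerance = 1e-10)
    expect_equal(coupling_input(r1, cr, 0.6), 2 * coupling_input(r1, cr, 0.3),
                 tolerance = 1e-10)
    # vectorized form vs per-node loop
    loop <- sapply(seq_len(10), function(i)
      0.3 * 135 * sum(unclass(cr)[i, -i] * r1[-i]))
    expect_equal(coupling_input(r1, cr, 0.3), loop, tolerance = 1e-10)
  }
})

test_that("connectome CSV round-trip preserves weights and labels", {
  c1 <- synthetic_connectome(8, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_connectome(c1, f)
  c2 <- read_connectome(f)
  expect_equal(unclass(c2), unclass(c1), tolerance = 1e-12)
  expect_equal(rownames(c2), rownames(c1))
})
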