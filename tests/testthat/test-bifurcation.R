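# Equilibria, Jacobians, continuation, event classification and Floquet
# analysis.

test_that("the degenerate (zeta_max -> 0) model has a unique equilibrium at 0", {
  m <- reduced_model(sigmoid = jr_sigmoid(zeta_max = 1e-300))
  eq <- find_equilibria(m, 0)
  expect_gte(nrow(eq), 1)
  expect_lt(max(abs(eq)), 1e-8)
  # linear damped blocks: eigenvalues -a (x4) and -b (x2)
  ev <- sort(Re(eigen(model_jacobian(rep(0, 6), 0, m))$values))
  expect_equal(ev, c(-120, -120, -120, -120, -60, -60), tolerance = 1e-8)
})

test_that("equilibria agree with the long-time limit of damped simulation", {
  m <- reduced_model()
  p <- 40  # below the oscillatory range: stable focus
  end <- jansenrit:::reduced_orbit_cpp(rep(0, 6), p, m$q, 1e-4, 400000L, 0L)$y
  eq <- find_equilibria(m, p, guesses = matrix(end, 1))
  expect_gte(nrow(eq), 1)
  i <- which.min(abs(eq[, 1] - end[1]))
  expect_equal(unname(eq[i, ]), end, tolerance = 1e-4)
  expect_lt(max(abs(model_rhs(eq[i, ], p, m))), 1e-10)
  # the focus is attracting: leading eigenvalue real part negative
  expect_lt(max(Re(eigen(model_jacobian(eq[i, ], p, m))$values)), 0)
})

test_that("with ISP the interior equilibrium pins the pyramidal rate at rho", {
  m <- reduced_model(plasticity = jr_plasticity(rho = 2.5))
  # interior root: solve from a seed with positive c4
  guess <- c(0.08, 0, 18, 0, 12, 0, 6)
  eq <- find_equilibria(m, 50, guesses = matrix(guess, 1))
  interior <- eq[eq[, 7] > 1e-6, , drop = FALSE]
  expect_gte(nrow(interior), 1)
  rate <- sigmoid_rate(interior[1, 3] - interior[1, 5])
  expect_equal(unname(rate), 2.5, tolerance = 1e-9)
})

test_that("analytic, finite-difference and complex-step Jacobians agree", {
  m <- reduced_model(plasticity = jr_plasticity())
  set.seed(3)
  x <- c(abs(rnorm(1, 0.05, 0.02)), rnorm(5), 25)
  p <- 150
  J_an <- model_jacobian(x, p, m)
  J_fd <- jansenrit:::fd_jacobian(function(z) model_rhs(z, p, m), x)
  # complex-step differentiation (machine-precision first derivatives)
  n <- length(x)
  J_cs <- matrix(0, n, n)
  h <- 1e-20
  for (j in seq_len(n)) {
    xc <- as.complex(x); xc[j] <- xc[j] + h * 1i
    J_cs[, j] <- Im(model_rhs(xc, p, m)) / h
  }
  scale <- max(abs(J_cs))
  expect_lt(max(abs(J_an - J_cs)) / scale, 1e-10)
  expect_lt(max(abs(J_fd - J_cs)) / scale, 1e-6)
})

test_that("continuation of a linear system yields a straight, event-free branch", {
  A <- matrix(c(-1, 0.5, 0, -2), 2)
  lin <- custom_model(function(x, p) as.numeric(A %*% x) + c(p, 0), n = 2)
  br <- continue_equilibria(lin, 0, x0 = c(0, 0), p_range = c(0, 10), ds0 = 1)
  expect_true(all(br$stable))
  expect_equal(nrow(classify_events(br)), 0)
  # the branch is the exact linear solution x = -A^{-1} (p, 0)
  sol <- t(vapply(br$p, function(p) as.numeric(solve(A, -c(p, 0))),
                  numeric(2)))
  expect_equal(unname(br$states), unname(sol), tolerance = 1e-8)
})

test_that("the Hopf normal form is classified with its frequency", {
  # dx = (mu - r^2) x - omega y, dy = omega x + (mu - r^2) y, omega = 2*2pi
  om <- 2 * 2 * pi
  nf <- custom_model(function(x, p) {
    r2 <- sum(x^2)
    c((p - r2) * x[1] - om * x[2], om * x[1] + (p - r2) * x[2])
  }, n = 2)
  br <- continue_equilibria(nf, -1, x0 = c(0, 0), p_range = c(-1, 1),
                            ds0 = 0.1, ds_max = 0.2)
  ev <- classify_events(br)
  hopf <- ev[ev$kind == "hopf", ]
  expect_equal(nrow(hopf), 1)
  expect_equal(hopf$p, 0, tolerance = 1e-3)
  expect_equal(hopf$diagnostic, 2, tolerance = 1e-3)  # frequency in Hz
})

test_that("the classical equilibrium branch folds and undergoes its known Hopfs", {
  m <- reduced_model()  # ISP off, c4 frozen
  br <- cached("classical_branch",
               continue_equilibria(m, 0, p_range = c(-500, 400), ds0 = 1,
                                   max_points = 3000))
  ev <- classify_events(br)
  folds <- ev[ev$kind == "saddle-node", ]
  expect_equal(nrow(folds), 2)
  # the knee of the S-curve: a fold in the 100-150 input range
  expect_equal(sum(folds$p > 100 & folds$p < 150), 1)
  # the two oscillation-bounding Hopf points of the classical model
  hp <- sort(ev$p[ev$kind == "hopf" & ev$p > 0])
  expect_equal(hp, c(89.83, 315.70), tolerance = 1e-3)
  # every reported equilibrium satisfies the residual bound
  expect_lt(max(br$residuals), 1e-9)
})

test_that("Hopf frequency matches the nearby simulated oscillation", {
  m <- reduced_model()
  br <- cached("classical_branch",
               continue_equilibria(m, 0, p_range = c(-500, 400), ds0 = 1,
                                   max_points = 3000))
  ev <- classify_events(br)
  hopf <- ev[ev$kind == "hopf" & ev$p > 200, ]
  expect_equal(nrow(hopf), 1)
  # simulate just inside the oscillatory side of the Hopf point
  p_sim <- hopf$p - 4
  cy <- cycle_from_simulation(m, p_sim, t_settle = 30)
  expect_equal(1 / cy$period, hopf$diagnostic,
               tolerance = 0.05 * hopf$diagnostic)
})

test_that("shooting refines the Hopf normal-form cycle with exact multipliers", {
  om <- 2 * 2 * pi
  nf <- custom_model(function(x, p) {
    r2 <- sum(x^2)
    c((p - r2) * x[1] - om * x[2], om * x[1] + (p - r2) * x[2])
  }, n = 2)
  mu <- 0.5
  lc <- find_limit_cycle(nf, mu, x0 = c(sqrt(mu) * 1.05, 0),
                         period = 2 * pi / om, n_orbit = 800L)
  expect_true(lc$converged)
  expect_equal(lc$period, 2 * pi / om, tolerance = 1e-8)
  mods <- sort(Mod(lc$multipliers))
  # trivial multiplier at 1 within 1e-4; the nontrivial one is exactly
  # exp(-2 mu T) for this normal form
  expect_equal(mods[2], 1, tolerance = 1e-4)
  expect_equal(mods[1], exp(-2 * mu * 2 * pi / om), tolerance = 1e-3)
})

test_that("the alpha-regime cycle period matches its simulated spectral peak", {
  m <- reduced_model()
  cy <- cycle_from_simulation(m, 220, t_settle = 30)
  lc <- find_limit_cycle(m, 220, cy$x0, cy$period, n_orbit = 3000L)
  expect_true(lc$converged)
  expect_lt(lc$residual, 1e-7)
  expect_equal(sort(Mod(lc$multipliers), decreasing = TRUE)[1], 1,
               tolerance = 1e-4)
  # the deterministic alpha cycle runs at ~13 Hz; Welch peak of an RK4
  # trajectory recorded at 200 Hz must match 1/period to the bin width
  tr <- jansenrit:::reduced_orbit_cpp(lc$x0, 220, m$q, 5e-5, 1200000L, 100L)$traj
  pk <- welch_peak_of(tr[, 3] - tr[, 5], 200)
  expect_equal(pk, 1 / lc$period, tolerance = 0.6)
})
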