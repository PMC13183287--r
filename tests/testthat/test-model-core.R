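# Elementary node operations: sigmoid, mixture, firing rates, derivative
# field, and equivalence with an independent classical Jansen-Rit integrator.

test_that("sigmoid hits its threshold, saturation and printed-formula values", {
  sp <- jr_sigmoid()
  expect_equal(sigmoid_rate(6, sp), 2.5)
  expect_equal(sigmoid_rate(1e4, sp), 5, tolerance = 1e-12)
  # direct scalar evaluation of the formula at v = 0
  expect_equal(sigmoid_rate(0, sp), 5 / (1 + exp(0.56 * 6)), tolerance = 1e-12)
  expect_error(sigmoid_rate(NaN, sp), "non-finite")
  expect_error(jr_sigmoid(zeta_max = -1))
})

test_that("sigmoid is monotone and bounded on a large random sample", {
  set.seed(11)
  v <- sort(runif(1e6, -30, 30))
  s <- sigmoid_rate(v)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s > 0 & s < 5))
})

test_that("mixture combination respects proportion and sign conventions", {
  a <- c(2, 2, 2); g <- c(1, 2, 3)
  expect_equal(combine_subpop(a, g, 1), a)
  # printed subtractive form at r_alpha = 0 negates the gamma triplet
  expect_equal(combine_subpop(c(0, 0, 0), g, 0, mixture_sign = -1),
               c(-1, -2, -3))
  expect_equal(combine_subpop(a, c(1, 1, 1), 0.5), c(1.5, 1.5, 1.5))
  expect_equal(combine_subpop(a, c(1, 1, 1), 0.5, mixture_sign = -1),
               c(0.5, 0.5, 0.5))
  expect_error(combine_subpop(a, g, 1.2), "r_alpha")
})

test_that("node firing rates follow the three sigmoid channels", {
  nd <- jr_node()
  expect_equal(firing_rates(c(0, 6, 0), nd)[["pyr"]], 2.5)
  r0 <- firing_rates(c(0, 0, 0), nd)
  expect_equal(unname(r0), rep(sigmoid_rate(0), 3))
  # pyramidal rate depends only on the difference x1 - x2
  expect_equal(firing_rates(c(0, 17.3, 17.3), nd)[["pyr"]], sigmoid_rate(0))
})

test_that("gamma preset gains are tied to its rate constants", {
  g <- jr_subpop("gamma")
  expect_equal(g$A, 32.5 * 660 / 1000)
  expect_equal(g$B, 440 * 330 / 1000)
  g2 <- jr_subpop("gamma", a = 1000, b = 500)
  expect_equal(g2$A, 32.5)
  expect_equal(g2$B, 220)
})

test_that("subpopulation derivatives reproduce printed scalar values", {
  nd <- jr_node()
  d <- subpop_derivatives(rep(0, 6), "alpha", u0 = 0, u_pyr = 0,
                          p_input = 0, node = nd)
  # dx_k/dt equal the y's, all zero here
  expect_equal(d[c(1, 3, 5)], c(0, 0, 0))
  expect_equal(d[4], 3.9 * 120 * 108 * sigmoid_rate(0), tolerance = 1e-12)
  # frozen sigmoid (zeta_max -> 0): damped linear oscillator block
  nd0 <- jr_node(sigmoid = jr_sigmoid(zeta_max = 1e-300))
  st <- c(0.3, -2, 0, 0, 0, 0)
  d0 <- subpop_derivatives(st, "alpha", 0, 0, 0, node = nd0)
  expect_equal(d0[2], -2 * 120 * (-2) - 120^2 * 0.3, tolerance = 1e-6)
})

test_that("dy1/dt is linear in external input and coupling (superposition)", {
  nd <- jr_node(r_alpha = 0.6)
  set.seed(2)
  st <- rnorm(12)
  base <- node_derivatives(st, nd, p_input = 0, coupling = 0)
  dp <- node_derivatives(st, nd, p_input = 7, coupling = 0) - base
  dc <- node_derivatives(st, nd, p_input = 0, coupling = 11) - base
  both <- node_derivatives(st, nd, p_input = 7, coupling = 11) - base
  expect_equal(both, dp + dc, tolerance = 1e-9)
  # doubling the inputs doubles their contribution
  expect_equal(node_derivatives(st, nd, p_input = 14, coupling = 0) - base,
               2 * dp, tolerance = 1e-9)
})

test_that("compiled Euler step agrees with the R derivative field", {
  nd <- jr_node(r_alpha = 0.4)
  pl <- jr_plasticity()
  pr <- jr_protocol(t_total = 0.01, t_discard = 0, noise = FALSE,
                    output_fs = 1000)
  s <- jr_simulate(NULL, nd, pl, pr)
  # state after one Euler step from zero initial conditions
  st0 <- c(rep(0, 12), nd$c4_init)
  d0 <- node_derivatives(st0, nd, p_input = 220, plasticity = pl)
  st1 <- st0 + pr$dt * d0
  eeg1 <- nd$r_alpha * st1[3] + (1 - nd$r_alpha) * st1[9] -
    (nd$r_alpha * st1[5] + (1 - nd$r_alpha) * st1[11])
  expect_equal(s$eeg[2, 1], eeg1, tolerance = 1e-10)
})

test_that("alpha-only node matches an independent classical Jansen-Rit oracle", {
  skip_if_not_installed("deSolve")
  nd <- jr_node(r_alpha = 1)
  pl <- jr_plasticity(enabled = FALSE)
  pr <- jr_protocol(t_total = 3, t_discard = 0, noise = FALSE,
                    output_fs = 1000)
  s <- jr_simulate(NULL, nd, pl, pr)
  # classical six-state JR integrated independently with deSolve's Euler
  S <- function(v) 5 / (1 + exp(-0.56 * (v - 6)))
  rhs <- function(t, y, parms) {
    with(as.list(parms), list(c(
      y[2], A * a * S(y[3] - y[5]) - 2 * a * y[2] - a^2 * y[1],
      y[4], A * a * (p + c2 * S(c1 * y[1])) - 2 * a * y[4] - a^2 * y[3],
      y[6], B * b * c4 * S(c3 * y[1]) - 2 * b * y[6] - b^2 * y[5])))
  }
  parms <- c(A = 3.9, B = 26.4, a = 120, b = 60, c1 = 135, c2 = 108,
             c3 = 33.75, c4 = 33.75, p = 220)
  out <- deSolve::ode(rep(0, 6), seq(0, 3, by = 1e-3), rhs, parms,
                      method = "euler")
  # traces are recorded at step starts: row k is the state after k - 1 steps
  oracle_eeg <- out[1:3000, 4] - out[1:3000, 6]
  expect_equal(s$eeg[, 1], unname(oracle_eeg), tolerance = 1e-8)
})
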