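# Numerical bifurcation toolkit for the single-node (reduced,
# one-subpopulation) model: equilibrium location, analytic/finite-difference
# Jacobians, pseudo-arclength continuation, codimension-1 event
# classification, and limit-cycle shooting with Floquet multipliers.

#' Reduced single-node model for bifurcation analysis
#'
#' The deterministic one-subpopulation node: six PSP states
#' (x0, y0, x1, y1, x2, y2), plus the plastic c4 as a seventh state when
#' `plasticity` is enabled (the full extended system is continued, so
#' equilibria with ISP satisfy either `zeta_pyr = rho` or `c4 = c4_min`).
#' With `r_alpha = 1` the network model reduces exactly to this system.
#'
#' @param subpop A [jr_subpop()] ("alpha" by default).
#' @param sigmoid A [jr_sigmoid()].
#' @param C,c1,c2,c3 Local connectivity constants.
#' @param c4_fixed Frozen feedback inhibition when ISP is off.
#' @param plasticity A [jr_plasticity()] with `enabled = TRUE`, or `NULL`
#'   for the classical (no-ISP) node.
#' @return An object of class `jr_model`.
#' @export
reduced_model <- function(subpop = jr_subpop("alpha"),
                          sigmoid = jr_sigmoid(), C = 135, c1 = C,
                          c2 = 0.8 * C, c3 = 0.25 * C, c4_fixed = 0.25 * C,
                          plasticity = NULL) {
  isp <- !is.null(plasticity) && isTRUE(plasticity$enabled)
  pp <- if (isp) plasticity else jr_plasticity(enabled = FALSE)
  q <- c(subpop$A, subpop$B, subpop$a, subpop$b, c1, c2, c3,
         sigmoid$zeta_max, sigmoid$slope, sigmoid$v_th, C,
         as.numeric(isp), pp$rho, pp$tau, pp$beta, pp$c4_min, c4_fixed)
  n <- if (isp) 7L else 6L
  structure(list(kind = "jr", q = q, n = n, isp = isp, subpop = subpop,
                 sigmoid = sigmoid, C = C, c1 = c1, c2 = c2, c3 = c3,
                 c4_fixed = c4_fixed, plasticity = pp,
                 labels = c("x0", "y0", "x1", "y1", "x2", "y2",
                            if (isp) "c4")),
            class = "jr_model")
}

#' Wrap an arbitrary ODE system for the continuation routines
#'
#' @param rhs `function(x, p)` returning the derivative vector.
#' @param n State dimension.
#' @param jac Optional `function(x, p)` returning the Jacobian; a central
#'   finite difference is used when absent.
#' @return An object of class `jr_model` with `kind = "custom"`.
#' @export
custom_model <- function(rhs, n, jac = NULL) {
  structure(list(kind = "custom", rhs_fun = rhs, jac_fun = jac, n = n,
                 isp = FALSE, labels = paste0("x", seq_len(n))),
            class = "jr_model")
}

#' Derivative field of a reduced model
#'
#' Pure-R evaluation (complex-step safe for `jr` models: the field is
#' composed of exp and polynomials only).
#'
#' @param state State vector (length `model$n`).
#' @param p External input.
#' @param model A [reduced_model()] or [custom_model()].
#' @return Derivative vector.
#' @export
model_rhs <- function(state, p, model) {
  if (model$kind == "custom") return(model$rhs_fun(state, p))
  q <- model$q
  S <- function(v) q[8] / (1 + exp(-q[9] * (v - q[10])))
  c4 <- if (model$isp) state[7] else q[17]
  u <- state[3] - state[5]
  f <- c(state[2],
         q[1] * q[3] * S(u) - 2 * q[3] * state[2] - q[3]^2 * state[1],
         state[4],
         q[1] * q[3] * (p + q[6] * S(q[5] * state[1])) -
           2 * q[3] * state[4] - q[3]^2 * state[3],
         state[6],
         q[2] * q[4] * c4 * S(q[7] * state[1]) - 2 * q[4] * state[6] -
           q[4]^2 * state[5])
  if (model$isp) {
    g <- ((c4 - q[16]) / q[11])^q[15]
    f <- c(f, S(q[7] * state[1]) * (S(u) - q[13]) * g / q[14])
  }
  f
}

#' Jacobian of a reduced model
#'
#' Analytic for `jr` models; for custom models uses the supplied Jacobian or
#' a central finite difference with adaptive step.
#'
#' @inheritParams model_rhs
#' @return `n x n` Jacobian matrix.
#' @export
model_jacobian <- function(state, p, model) {
  if (model$kind == "jr")
    return(reduced_jac_cpp(as.numeric(state), p, model$q))
  if (!is.null(model$jac_fun)) return(model$jac_fun(state, p))
  fd_jacobian(function(x) model$rhs_fun(x, p), state)
}

# central finite-difference Jacobian with per-component adaptive step
fd_jacobian <- function(f, x) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- max(1e-7, 1e-7 * abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- x[j] + h
    xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

model_dfdp <- function(state, p, model) {
  if (model$kind == "jr") {
    d <- numeric(model$n)
    d[4] <- model$q[1] * model$q[3]
    return(d)
  }
  h <- max(1e-6, 1e-6 * abs(p))
  (model$rhs_fun(state, p + h) - model$rhs_fun(state, p - h)) / (2 * h)
}

# Newton iteration for an equilibrium at fixed p
newton_equilibrium <- function(model, p, x0, tol = 1e-11, max_iter = 50) {
  x <- as.numeric(x0)
  for (i in seq_len(max_iter)) {
    f <- model_rhs(x, p, model)
    if (max(abs(f)) < tol) return(list(x = x, ok = TRUE, res = max(abs(f))))
    J <- model_jacobian(x, p, model)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, ok = FALSE, res = max(abs(f))))
    lam <- 1
    fn0 <- sum(f^2)
    repeat {
      xn <- x + lam * step
      fn <- sum(model_rhs(xn, p, model)^2)
      if (fn < fn0 || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
  }
  res <- max(abs(model_rhs(x, p, model)))
  list(x = x, ok = res < 1e-8, res = res)
}

#' Locate equilibria of the reduced model
#'
#' Newton refinement from the supplied guesses plus a set of default seeds
#' (the origin, the end state of a damped forward integration, and for ISP
#' models the same seeds restricted to the `c4 = c4_min` plane). Converged
#' roots with residual below `tol` are deduplicated.
#'
#' @param model A [reduced_model()].
#' @param p External input.
#' @param guesses Optional matrix (rows = initial guesses).
#' @param tol Residual tolerance (default 1e-10).
#' @return Matrix of equilibria (possibly zero rows), with attribute
#'   `"residuals"`.
#' @export
find_equilibria <- function(model, p, guesses = NULL, tol = 1e-10) {
  n <- model$n
  seeds <- list()
  if (!is.null(guesses)) {
    guesses <- as.matrix(guesses)
    for (i in seq_len(nrow(guesses))) seeds[[length(seeds) + 1L]] <-
        as.numeric(guesses[i, ])
  }
  seeds[[length(seeds) + 1L]] <- rep(0, n)
  if (model$kind == "jr") {
    y0 <- rep(0, n)
    if (model$isp) y0[7] <- max(model$plasticity$c4_min, model$c4_fixed)
    end <- reduced_orbit_cpp(y0, p, model$q, 1e-4, 50000L, 0L)$y
    seeds[[length(seeds) + 1L]] <- end
    if (model$isp) {
      for (s in seq_along(seeds)) {
        s2 <- seeds[[s]]
        s2[7] <- model$plasticity$c4_min
        seeds[[length(seeds) + 1L]] <- s2
      }
    }
  }
  roots <- list(); res <- numeric(0)
  for (s in seeds) {
    r <- newton_equilibrium(model, p, s)
    if (!r$ok || r$res > tol) next
    dup <- any(vapply(roots, function(z) max(abs(z - r$x)) < 1e-6,
                      logical(1)))
    if (!dup) {
      roots[[length(roots) + 1L]] <- r$x
      res <- c(res, r$res)
    }
  }
  out <- if (length(roots)) do.call(rbind, roots) else
    matrix(numeric(0), 0, n)
  colnames(out) <- model$labels
  attr(out, "residuals") <- res
  out
}

# bordered tangent: solve [J fp; t_ref] t = [0; 1], then normalize
branch_tangent <- function(model, x, p, t_ref) {
  n <- model$n
  A <- cbind(model_jacobian(x, p, model), model_dfdp(x, p, model))
  M <- rbind(A, t_ref)
  t_new <- tryCatch(solve(M, c(rep(0, n), 1)), error = function(e) NULL)
  if (is.null(t_new)) return(t_ref)
  t_new / sqrt(sum(t_new^2))
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Follows the equilibrium curve of `model` through folds, recomputing the
#' Jacobian spectrum at every accepted point. The continuation stops when
#' the parameter leaves `p_range`, the step collapses below `ds_min`
#' (truncated branch, flagged), or `max_points` is reached.
#'
#' @param model A [reduced_model()] or [custom_model()].
#' @param p_start Starting parameter value.
#' @param x0 Starting equilibrium (located with [find_equilibria()] when
#'   `NULL`).
#' @param p_range Parameter interval to explore.
#' @param ds0 Initial arclength step.
#' @param ds_min,ds_max Step bounds.
#' @param max_points Maximum number of branch points.
#' @param direction +1 to start toward increasing p, -1 decreasing.
#' @return An object of class `jr_branch`: per-point parameter values,
#'   states, eigenvalues, stability flags and the p-component of the unit
#'   tangent.
#' @export
continue_equilibria <- function(model, p_start, x0 = NULL,
                                p_range = c(p_start - 100, p_start + 400),
                                ds0 = 1, ds_min = 1e-8, ds_max = 5,
                                max_points = 1500, direction = 1) {
  n <- model$n
  if (is.null(x0)) {
    eq <- find_equilibria(model, p_start)
    if (!nrow(eq)) stop("no starting equilibrium found at p_start")
    x0 <- eq[1, ]
  }
  r <- newton_equilibrium(model, p_start, x0)
  if (!r$ok) stop("starting point did not converge to an equilibrium")
  x <- r$x; p <- p_start
  t_ref <- c(rep(0, n), direction)
  tt <- branch_tangent(model, x, p, t_ref)
  if (sign(tt[n + 1]) != direction && abs(tt[n + 1]) > 1e-12)
    tt <- -tt

  ps <- numeric(0); states <- NULL; eigs <- list(); tps <- numeric(0)
  resid <- numeric(0)
  add_point <- function(x, p, tt) {
    J <- model_jacobian(x, p, model)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    ps <<- c(ps, p)
    states <<- rbind(states, x)
    eigs[[length(eigs) + 1L]] <<- ev
    tps <<- c(tps, tt[n + 1])
    resid <<- c(resid, max(abs(model_rhs(x, p, model))))
  }
  add_point(x, p, tt)

  ds <- ds0
  truncated <- FALSE
  while (length(ps) < max_points) {
    u_pred <- c(x, p) + ds * tt
    # corrector
    u <- u_pred
    ok <- FALSE
    for (it in seq_len(12)) {
      f <- model_rhs(u[1:n], u[n + 1], model)
      g <- sum(tt * (u - u_pred))
      R <- c(f, g)
      if (max(abs(R)) < 1e-10) { ok <- TRUE; break }
      A <- rbind(cbind(model_jacobian(u[1:n], u[n + 1], model),
                       model_dfdp(u[1:n], u[n + 1], model)),
                 tt)
      du <- tryCatch(solve(A, -R), error = function(e) NULL)
      if (is.null(du)) break
      u <- u + du
      if (max(abs(du)) < 1e-12) { ok <- max(abs(model_rhs(u[1:n], u[n + 1],
                                                model))) < 1e-8; break }
    }
    if (ok) {
      # reject correctors that land far from the predictor (branch jumps)
      dist <- sqrt(sum((u - c(x, p))^2))
      t_new <- branch_tangent(model, u[1:n], u[n + 1], tt)
      if (sum(t_new * tt) < 0) t_new <- -t_new
      if (dist > 3 * abs(ds) || sum(t_new * tt) < 0.5) ok <- FALSE
    }
    if (!ok) {
      ds <- ds / 2
      if (ds < ds_min) { truncated <- TRUE; break }
      next
    }
    x <- u[1:n]; p <- u[n + 1]
    tt <- t_new
    add_point(x, p, tt)
    if (p < p_range[1] || p > p_range[2]) break
    ds <- min(ds * 1.2, ds_max)
  }

  stable <- vapply(eigs, function(ev) all(Re(ev) < 0), logical(1))
  structure(list(p = ps, states = states, eigvals = eigs, stable = stable,
                 tangent_p = tps, residuals = resid, truncated = truncated,
                 model = model),
            class = "jr_branch")
}

#' @export
print.jr_branch <- function(x, ...) {
  cat(sprintf("jr_branch: %d points, p in [%.4g, %.4g], %d stable\n",
              length(x$p), min(x$p), max(x$p), sum(x$stable)))
  if (x$truncated) cat("  (truncated: step collapsed)\n")
  invisible(x)
}

#' @export
plot.jr_branch <- function(x, component = 1, ...) {
  y <- x$states[, component]
  plot(x$p, y, type = "n", xlab = "p (1/s)",
       ylab = x$model$labels[component], ...)
  graphics::points(x$p[x$stable], y[x$stable], pch = 16, cex = 0.4,
                   col = "red")
  graphics::points(x$p[!x$stable], y[!x$stable], pch = 1, cex = 0.4)
  invisible(x)
}

# refine a fold: Newton on F(x, v, p) = [f; J v; |v|^2 - 1]
refine_fold <- function(model, x_init, p_init, v_init, tol = 1e-9,
                        max_iter = 40) {
  n <- model$n
  u <- c(x_init, v_init, p_init)
  Ffun <- function(u) {
    x <- u[1:n]; v <- u[(n + 1):(2 * n)]; p <- u[2 * n + 1]
    J <- model_jacobian(x, p, model)
    c(model_rhs(x, p, model), as.numeric(J %*% v), sum(v^2) - 1)
  }
  for (i in seq_len(max_iter)) {
    Fv <- Ffun(u)
    if (max(abs(Fv)) < tol) break
    J <- fd_jacobian(Ffun, u)
    du <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    u <- u + du
  }
  if (max(abs(Ffun(u))) > 1e-6) return(NULL)
  list(x = u[1:n], p = u[2 * n + 1], v = u[(n + 1):(2 * n)])
}

# bisection refinement of a Hopf point between two branch points
refine_hopf <- function(model, p_lo, x_lo, p_hi, x_hi, tol_p = 1e-3) {
  re_pair <- function(x, p) {
    ev <- eigen(model_jacobian(x, p, model), only.values = TRUE)$values
    cx <- ev[abs(Im(ev)) > 1e-8]
    if (!length(cx)) return(list(re = NA_real_, im = NA_real_))
    i <- which.max(Re(cx))
    list(re = Re(cx[i]), im = abs(Im(cx[i])))
  }
  s_lo <- re_pair(x_lo, p_lo)$re
  while (abs(p_hi - p_lo) > tol_p) {
    p_mid <- (p_lo + p_hi) / 2
    w <- (p_mid - p_lo) / (p_hi - p_lo)
    r <- newton_equilibrium(model, p_mid, (1 - w) * x_lo + w * x_hi)
    if (!r$ok) return(NULL)
    s_mid <- re_pair(r$x, p_mid)
    if (is.na(s_mid$re)) return(NULL)
    if (sign(s_mid$re) == sign(s_lo)) {
      p_lo <- p_mid; x_lo <- r$x; s_lo <- s_mid$re
    } else {
      p_hi <- p_mid; x_hi <- r$x
    }
  }
  fin <- re_pair(x_lo, p_lo)
  list(p = (p_lo + p_hi) / 2, x = x_lo, freq_hz = fin$im / (2 * pi))
}

#' Classify codimension-1 events along an equilibrium branch
#'
#' Detects folds (saddle-nodes, where the p-component of the tangent changes
#' sign and a real eigenvalue crosses zero) and Hopf points (a complex pair
#' crossing the imaginary axis), refining each to the requested parameter
#' tolerance (folds via an extended-system Newton, Hopf via bisection).
#'
#' @param branch A `jr_branch`.
#' @param tol_p Parameter tolerance for refined event locations.
#' @return A data.frame with columns `kind`, `p`, `diagnostic` (zero
#'   eigenvalue or Hopf frequency in Hz) plus the state columns.
#' @export
classify_events <- function(branch, tol_p = 1e-3) {
  model <- branch$model
  n <- model$n
  events <- list()
  add <- function(kind, p, diagnostic, x) {
    ev <- as.list(x); names(ev) <- model$labels
    events[[length(events) + 1L]] <<- cbind(
      data.frame(kind = kind, p = p, diagnostic = diagnostic),
      as.data.frame(ev))
  }
  np <- length(branch$p)
  for (i in seq_len(np - 1)) {
    # fold: tangent p-component sign change
    if (branch$tangent_p[i] * branch$tangent_p[i + 1] < 0) {
      j <- if (abs(branch$tangent_p[i]) < abs(branch$tangent_p[i + 1]))
        i else i + 1
      x0 <- branch$states[j, ]
      ev <- branch$eigvals[[j]]
      re <- Re(ev[abs(Im(ev)) < 1e-8])
      lam0 <- if (length(re)) re[which.min(abs(re))] else 0
      J <- model_jacobian(x0, branch$p[j], model)
      es <- eigen(J)
      k <- which.min(abs(es$values))
      v0 <- Re(es$vectors[, k])
      v0 <- v0 / sqrt(sum(v0^2))
      f <- refine_fold(model, x0, branch$p[j], v0)
      if (!is.null(f)) add("saddle-node", f$p, lam0, f$x)
      else add("saddle-node", branch$p[j], lam0, x0)
      next
    }
    # Hopf: leading complex pair crosses the imaginary axis
    cx_re <- function(ev) {
      cx <- ev[Im(ev) > 1e-8]
      if (!length(cx)) NA_real_ else max(Re(cx))
    }
    r1 <- cx_re(branch$eigvals[[i]])
    r2 <- cx_re(branch$eigvals[[i + 1]])
    if (!is.na(r1) && !is.na(r2) && r1 * r2 < 0) {
      h <- refine_hopf(model, branch$p[i], branch$states[i, ],
                       branch$p[i + 1], branch$states[i + 1, ], tol_p)
      if (!is.null(h)) add("hopf", h$p, h$freq_hz, h$x)
    }
  }
  if (!length(events))
    return(data.frame(kind = character(0), p = numeric(0),
                      diagnostic = numeric(0)))
  do.call(rbind, events)
}

# ---------------------------------------------------------------------------
# Limit cycles: shooting, Floquet multipliers, continuation.

# flow map with monodromy and parameter sensitivity
cycle_flow <- function(model, x0, p, T, n_orbit = 2000L) {
  if (model$kind == "jr")
    return(reduced_flow_cpp(as.numeric(x0), p, model$q, T, as.integer(n_orbit)))
  # R fallback for custom models: RK4 on state + variational + sensitivity
  n <- model$n
  dt <- T / n_orbit
  y <- as.numeric(x0)
  Phi <- diag(n)
  psi <- numeric(n)
  for (k in seq_len(n_orbit)) {
    step <- function(y, Phi, psi) {
      J <- model_jacobian(y, p, model)
      list(dy = model_rhs(y, p, model), dPhi = J %*% Phi,
           dpsi = as.numeric(J %*% psi) + model_dfdp(y, p, model))
    }
    k1 <- step(y, Phi, psi)
    k2 <- step(y + dt / 2 * k1$dy, Phi + dt / 2 * k1$dPhi,
               psi + dt / 2 * k1$dpsi)
    k3 <- step(y + dt / 2 * k2$dy, Phi + dt / 2 * k2$dPhi,
               psi + dt / 2 * k2$dpsi)
    k4 <- step(y + dt * k3$dy, Phi + dt * k3$dPhi, psi + dt * k3$dpsi)
    y <- y + dt / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
    Phi <- Phi + dt / 6 * (k1$dPhi + 2 * k2$dPhi + 2 * k3$dPhi + k4$dPhi)
    psi <- psi + dt / 6 * (k1$dpsi + 2 * k2$dpsi + 2 * k3$dpsi + k4$dpsi)
  }
  list(y = y, Phi = Phi, psi = psi, f = model_rhs(y, p, model))
}

#' Extract a limit-cycle guess from a forward simulation
#'
#' Integrates the deterministic reduced model to its attractor and estimates
#' the period from upward mean-crossings of the pyramidal potential
#' `x1 - x2`; the state at the last crossing is the initial-orbit guess.
#'
#' @param model A [reduced_model()].
#' @param p External input.
#' @param x_init Optional initial state for the settling run.
#' @param t_settle Settling time, s.
#' @param t_obs Observation window used for the period estimate, s.
#' @param dt Integration step, s.
#' @return List with `x0` (state on the cycle) and `period` (s).
#' @export
cycle_from_simulation <- function(model, p, x_init = NULL, t_settle = 40,
                                  t_obs = 4, dt = 1e-4) {
  n <- model$n
  if (is.null(x_init)) {
    x_init <- rep(0, n)
    if (model$isp) x_init[7] <- model$c4_fixed
  }
  y <- reduced_orbit_cpp(as.numeric(x_init), p, model$q, dt,
                         as.integer(round(t_settle / dt)), 0L)$y
  n_obs <- as.integer(round(t_obs / dt))
  tr <- reduced_orbit_cpp(y, p, model$q, dt, n_obs, 1L)$traj
  u <- tr[, 3] - tr[, 5]
  if (diff(range(u)) < 1e-6) stop("no sustained oscillation found at p = ", p)
  # primitive period from the first strong autocorrelation peak (robust for
  # multi-bump waveforms where zero crossings overcount)
  u0 <- u - mean(u)
  r <- stats::acf(u0, lag.max = floor(n_obs / 3), plot = FALSE)$acf[, 1, 1]
  lmax <- which(diff(sign(diff(r))) == -2) + 1L
  lmax <- lmax[r[lmax] > 0.5]
  if (!length(lmax)) stop("could not estimate an oscillation period at p = ",
                          p)
  period <- (lmax[1] - 1L) * dt
  up <- which(diff(sign(u0)) == 2)
  x0 <- if (length(up)) tr[up[length(up)], ] else tr[n_obs, ]
  list(x0 = x0, period = period)
}

#' Locate a periodic orbit by single shooting
#'
#' Newton iteration on the boundary-value problem `phi_T(x0) = x0` with an
#' anchor-plane phase condition, using monodromy and sensitivity information
#' from the variational equations. Returns the refined orbit and its Floquet
#' (monodromy) multipliers; the trivial multiplier should be within ~1e-4 of
#' 1 and is a built-in accuracy check.
#'
#' @param model A [reduced_model()] or [custom_model()].
#' @param p External input (fixed).
#' @param x0,period Initial guesses (e.g. from [cycle_from_simulation()]).
#' @param n_orbit RK4 steps per orbit.
#' @param tol Residual tolerance.
#' @param max_iter Newton iterations.
#' @return List with `x0`, `period`, `multipliers`, `p`, `converged`,
#'   `residual`.
#' @export
find_limit_cycle <- function(model, p, x0, period, n_orbit = 2000L,
                             tol = 1e-9, max_iter = 40) {
  n <- model$n
  x <- as.numeric(x0); T <- period
  anchor <- x
  fa <- model_rhs(anchor, p, model)
  res <- Inf
  resnorm <- function(x, T) {
    fl <- cycle_flow(model, x, p, T, n_orbit)
    R <- c(fl$y - x, sum(fa * (x - anchor)))
    if (!all(is.finite(R))) return(Inf)
    sqrt(sum(R^2))
  }
  for (i in seq_len(max_iter)) {
    fl <- cycle_flow(model, x, p, T, n_orbit)
    R <- c(fl$y - x, sum(fa * (x - anchor)))
    if (!all(is.finite(R))) break
    res <- max(abs(R))
    if (res < tol) break
    A <- rbind(cbind(fl$Phi - diag(n), fl$f), c(fa, 0))
    du <- tryCatch(solve(A, -R), error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) break
    # damped update: cap the period change at 30% per iteration (keeps the
    # shooting on the primitive orbit) and back-track on the residual norm
    lam <- 1
    if (abs(du[n + 1]) > 0.3 * T) lam <- 0.3 * T / abs(du[n + 1])
    r0 <- sqrt(sum(R^2))
    accepted <- FALSE
    for (h in seq_len(8)) {
      xn <- x + lam * du[1:n]
      Tn <- max(T + lam * du[n + 1], 1e-4)
      if (resnorm(xn, Tn) < r0) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) break
    x <- xn
    T <- Tn
  }
  fl <- cycle_flow(model, x, p, T, n_orbit)
  mult <- eigen(fl$Phi, only.values = TRUE)$values
  list(x0 = x, period = T, multipliers = mult, p = p,
       converged = res < max(tol, 1e-7), residual = res)
}

# nontrivial multipliers: drop the one closest to +1 (the trivial Floquet
# multiplier along the flow)
nontrivial_multipliers <- function(mult) {
  i <- which.min(Mod(mult - 1))
  mult[-i]
}

# modulus of the leading complex (non-real) multiplier pair, NA if none
complex_pair_modulus <- function(mult) {
  nm <- nontrivial_multipliers(mult)
  cx <- nm[abs(Im(nm)) > 1e-6 * pmax(Mod(nm), 1)]
  if (!length(cx)) return(NA_real_)
  max(Mod(cx))
}

#' Pseudo-arclength continuation of a limit-cycle branch
#'
#' Continues a periodic orbit in the parameter p by single shooting with
#' unknowns (x0, T, p), passing through folds of cycles. Floquet multipliers
#' are recorded at every accepted point.
#'
#' @param model A [reduced_model()] or [custom_model()].
#' @param cycle Starting orbit: list with `x0`, `period` (e.g. from
#'   [find_limit_cycle()] or [cycle_from_simulation()]).
#' @param p_start Starting parameter value.
#' @param p_range Interval of p to explore.
#' @param ds0,ds_min,ds_max Arclength step controls (the p-scale dominates,
#'   so steps are roughly in units of p).
#' @param max_points Maximum branch points.
#' @param direction Initial direction in p (+1 or -1).
#' @param n_orbit RK4 steps per orbit evaluation.
#' @return An object of class `jr_cycle_branch` with per-point `p`,
#'   `period`, `x0` rows, `multipliers` list and `tangent_p`.
#' @export
continue_cycles <- function(model, cycle, p_start, p_range, ds0 = 1,
                            ds_min = 1e-5, ds_max = 4, max_points = 400,
                            direction = 1, n_orbit = 2000L) {
  n <- model$n
  lc <- find_limit_cycle(model, p_start, cycle$x0, cycle$period,
                         n_orbit = n_orbit)
  if (!lc$converged) stop("starting cycle did not converge")
  x <- lc$x0; T <- lc$period; p <- p_start

  tangent <- function(x, T, p, t_ref) {
    fl <- cycle_flow(model, x, p, T, n_orbit)
    fa <- model_rhs(x, p, model)
    A <- rbind(cbind(fl$Phi - diag(n), fl$f, fl$psi),
               c(fa, 0, 0),
               t_ref)
    tt <- tryCatch(solve(A, c(rep(0, n + 1), 1)), error = function(e) NULL)
    if (is.null(tt)) return(t_ref)
    tt / sqrt(sum(tt^2))
  }
  t_ref <- c(rep(0, n + 1), direction)
  tt <- tangent(x, T, p, t_ref)
  if (sign(tt[n + 2]) != direction && abs(tt[n + 2]) > 1e-10) tt <- -tt

  ps <- numeric(0); Ts <- numeric(0); x0s <- NULL
  mults <- list(); tps <- numeric(0)
  add_point <- function(x, T, p, tt, mult) {
    ps <<- c(ps, p); Ts <<- c(Ts, T); x0s <<- rbind(x0s, x)
    mults[[length(mults) + 1L]] <<- mult
    tps <<- c(tps, tt[n + 2])
  }
  add_point(x, T, p, tt, lc$multipliers)

  ds <- ds0
  truncated <- FALSE
  while (length(ps) < max_points) {
    u_pred <- c(x, T, p) + ds * tt
    u <- u_pred
    ok <- FALSE
    fl <- NULL
    anchor <- x
    fa <- model_rhs(anchor, p, model)
    for (it in seq_len(10)) {
      fl <- cycle_flow(model, u[1:n], u[n + 2], u[n + 1], n_orbit)
      R <- c(fl$y - u[1:n],
             sum(fa * (u[1:n] - anchor)),
             sum(tt * (u - u_pred)))
      if (!all(is.finite(R))) break
      if (max(abs(R)) < 1e-8) { ok <- TRUE; break }
      A <- rbind(cbind(fl$Phi - diag(n), fl$f, fl$psi),
                 c(fa, 0, 0),
                 tt)
      du <- tryCatch(solve(A, -R), error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) break
      u <- u + du
      if (u[n + 1] <= 0) break
    }
    if (ok) {
      dist <- sqrt(sum((u - c(x, T, p))^2))
      t_new <- tangent(u[1:n], u[n + 1], u[n + 2], tt)
      if (sum(t_new * tt) < 0) t_new <- -t_new
      if (dist > 3 * abs(ds) || sum(t_new * tt) < 0.5) ok <- FALSE
    }
    if (!ok) {
      ds <- ds / 2
      if (ds < ds_min) { truncated <- TRUE; break }
      next
    }
    x <- u[1:n]; T <- u[n + 1]; p <- u[n + 2]
    tt <- t_new
    mult <- eigen(fl$Phi, only.values = TRUE)$values
    add_point(x, T, p, tt, mult)
    if (p < p_range[1] || p > p_range[2]) break
    ds <- min(ds * 1.2, ds_max)
  }

  structure(list(p = ps, period = Ts, x0 = x0s, multipliers = mults,
                 tangent_p = tps, truncated = truncated, model = model,
                 n_orbit = n_orbit),
            class = "jr_cycle_branch")
}

#' @export
print.jr_cycle_branch <- function(x, ...) {
  cat(sprintf(
    "jr_cycle_branch: %d points, p in [%.4g, %.4g], period %.4g-%.4g s\n",
    length(x$p), min(x$p), max(x$p), min(x$period), max(x$period)))
  invisible(x)
}

#' Classify codimension-1 events along a limit-cycle branch
#'
#' Detects folds of cycles (the p-tangent changes sign while a real
#' nontrivial multiplier sits near +1; located by quadratic interpolation of
#' p along the branch), torus (Neimark-Sacker) points (a nontrivial complex
#' multiplier pair crosses the unit circle; refined by bisection in p with
#' fixed-p shooting), and period doublings (a real multiplier crosses -1).
#'
#' @param branch A `jr_cycle_branch`.
#' @param tol_p Bisection tolerance for torus points.
#' @return Data.frame with `kind`, `p`, `diagnostic` (the relevant
#'   multiplier modulus or value) and `period`.
#' @export
classify_cycle_events <- function(branch, tol_p = 1e-3) {
  model <- branch$model
  np <- length(branch$p)
  events <- list()
  add <- function(kind, p, diagnostic, period)
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, p = p, diagnostic = diagnostic, period = period)

  cpm <- vapply(branch$multipliers, complex_pair_modulus, numeric(1))
  for (i in seq_len(np - 1)) {
    # fold of cycles
    if (branch$tangent_p[i] * branch$tangent_p[i + 1] < 0) {
      idx <- max(1, i - 1):min(np, i + 2)
      if (length(idx) >= 3) {
        s <- seq_along(idx)
        fit <- lm(branch$p[idx] ~ poly(s, 2, raw = TRUE))
        cf <- coef(fit)
        s_star <- -cf[2] / (2 * cf[3])
        p_fold <- unname(cf[1] + cf[2] * s_star + cf[3] * s_star^2)
      } else p_fold <- (branch$p[i] + branch$p[i + 1]) / 2
      nm <- nontrivial_multipliers(branch$multipliers[[i]])
      re <- Re(nm[abs(Im(nm)) < 1e-6])
      diag_m <- if (length(re)) re[which.min(abs(re - 1))] else NA_real_
      add("fold-of-cycles", p_fold, diag_m,
          (branch$period[i] + branch$period[i + 1]) / 2)
      next
    }
    # torus: complex pair modulus crosses 1
    if (!is.na(cpm[i]) && !is.na(cpm[i + 1]) &&
        (cpm[i] - 1) * (cpm[i + 1] - 1) < 0) {
      p_lo <- branch$p[i]; p_hi <- branch$p[i + 1]
      x_lo <- branch$x0[i, ]; x_hi <- branch$x0[i + 1, ]
      T_lo <- branch$period[i]; T_hi <- branch$period[i + 1]
      m_lo <- cpm[i]
      ok <- TRUE
      while (abs(p_hi - p_lo) > tol_p) {
        p_mid <- (p_lo + p_hi) / 2
        w <- (p_mid - p_lo) / (p_hi - p_lo + 1e-300)
        lc <- find_limit_cycle(model, p_mid, (1 - w) * x_lo + w * x_hi,
                               (1 - w) * T_lo + w * T_hi,
                               n_orbit = branch$n_orbit)
        if (!lc$converged) { ok <- FALSE; break }
        m_mid <- complex_pair_modulus(lc$multipliers)
        if (is.na(m_mid)) { ok <- FALSE; break }
        if (sign(m_mid - 1) == sign(m_lo - 1)) {
          p_lo <- p_mid; x_lo <- lc$x0; T_lo <- lc$period; m_lo <- m_mid
        } else {
          p_hi <- p_mid; x_hi <- lc$x0; T_hi <- lc$period
        }
      }
      p_t <- (p_lo + p_hi) / 2
      add("torus", p_t, if (ok) 1 else NA_real_, (T_lo + T_hi) / 2)
      next
    }
    # period doubling: real multiplier crosses -1
    rm_min <- function(m) {
      nm <- nontrivial_multipliers(m)
      re <- Re(nm[abs(Im(nm)) < 1e-6])
      if (!length(re)) NA_real_ else re[which.min(re)]
    }
    r1 <- rm_min(branch$multipliers[[i]])
    r2 <- rm_min(branch$multipliers[[i + 1]])
    if (!is.na(r1) && !is.na(r2) && (r1 + 1) * (r2 + 1) < 0)
      add("period-doubling", (branch$p[i] + branch$p[i + 1]) / 2, r1,
          branch$period[i])
  }
  if (!length(events))
    return(data.frame(kind = character(0), p = numeric(0),
                      diagnostic = numeric(0), period = numeric(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
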