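test_that("sigmoid firing rate has midpoint, saturation and symmetry", {
  p <- demoParams()
  expect_equal(sigmoidRate(p$mu_e, "e", p), p$S_e_max / 2)
  expect_equal(sigmoidRate(-1e4, "e", p), 0, tolerance = 1e-12)
  expect_equal(sigmoidRate(1e4, "e", p), p$S_e_max)
  for (d in c(0.5, 3, 12)) {
    expect_equal(sigmoidRate(p$mu_i + d, "i", p) +
                   sigmoidRate(p$mu_i - d, "i", p),
                 p$S_i_max)
  }
  h <- seq(-90, 0, by = 0.5)
  expect_true(all(diff(sigmoidRate(h, "e", p)) > 0))
  expect_true(all(sigmoidRate(h, "e", p) > 0 &
                    sigmoidRate(h, "e", p) < p$S_e_max))
  expect_error(sigmoidRate(NaN, "e", p), "non-finite")
})

test_that("synaptic weights are unit at rest and vanish at reversal", {
  p <- demoParams()
  expect_equal(synapticWeight(p$h_e_rest, "e", "e", p), 1)
  expect_equal(synapticWeight(p$h_e_rest, "i", "e", p), -1)
  expect_equal(synapticWeight(p$h_i_rest, "i", "i", p), -1)
  expect_equal(synapticWeight(p$h_e_eq, "e", "e", p), 0)
  expect_equal(synapticWeight(p$h_i_eq, "i", "e", p), 0)
  # sign flips exactly at the reversal potential
  expect_gt(synapticWeight(p$h_e_eq - 1, "e", "e", p), 0)
  expect_lt(synapticWeight(p$h_e_eq + 1, "e", "e", p), 0)
  pBad <- p
  pBad$h_e_eq <- p$h_e_rest
  expect_error(synapticWeight(-60, "e", "e", pBad), "degenerate")
})

test_that("decoupled model is exactly at rest and relaxes with tau", {
  p <- decoupledParams()
  rest <- setNames(c(p$h_e_rest, p$h_i_rest, rep(0, 8)), lileyStateNames())
  expect_equal(unname(lileyRHS(rest, p)), rep(0, 10))
  expect_equal(unname(findEquilibrium(p)), unname(rest))
  # eigenvalues of the decoupled Jacobian contain the membrane rates
  ev <- eigen(lileyJacobian(rest, p), only.values = TRUE)$values
  expect_true(any(abs(ev - (-1 / p$tau_e)) < 1e-12))
  expect_true(any(abs(ev - (-1 / p$tau_i)) < 1e-12))
  # e-folding: from a displaced start, h_e decays towards rest with tau_e
  y0 <- rest
  y0[1] <- p$h_e_rest + 10
  tr <- simulateLiley(p, y0 = y0, tEnd = p$tau_e, by = p$tau_e / 10)
  dev <- tr$states[nrow(tr$states), "h_e"] - p$h_e_rest
  expect_equal(unname(dev), 10 * exp(-1), tolerance = 0.01)
})

test_that("isolated synaptic impulse response peaks at Gamma after 1/gamma", {
  p <- decoupledParams()
  y0 <- setNames(c(p$h_e_rest, p$h_i_rest, rep(0, 8)), lileyStateNames())
  y0["J_ee"] <- exp(1) * p$Gamma_ee * p$gamma_ee
  tpk <- 1 / p$gamma_ee
  tr <- simulateLiley(p, y0 = y0, tEnd = 3 * tpk, by = tpk / 200,
                      rtol = 1e-10, atol = 1e-12)
  Imax <- max(tr$states[, "I_ee"])
  expect_equal(Imax, p$Gamma_ee, tolerance = 1e-3)
  tmax <- tr$times[which.max(tr$states[, "I_ee"])]
  expect_equal(tmax, tpk, tolerance = 0.01)
})

test_that("analytic Jacobian matches finite differences at random states", {
  skip_if_not_installed("pracma")
  p <- demoParams(p_ee = 5, p_ei = 2)
  set.seed(101)
  for (i in 1:100) {
    y <- c(runif(2, -80, -30), runif(8, -5, 25))
    J <- lileyJacobian(y, p)
    Jfd <- pracma::jacobian(function(z) unname(lileyRHS(z, p)), y)
    expect_lt(max(abs(J - Jfd) / (1 + abs(J))), 1e-6)
  }
  # definitional rows are exact
  expect_identical(unname(J["I_ee", "J_ee"]), 1)
  expect_identical(unname(J["I_ii", "J_ii"]), 1)
})

test_that("equilibrium satisfies its residual contract and moves continuously", {
  p <- demoParams(p_ee = 4, p_ei = 1)
  y <- findEquilibrium(p)
  expect_lt(max(abs(lileyRHS(y, p))), 1e-10)
  # closed-form synaptic levels at the fixed point
  se <- sigmoidRate(unname(y[1]), "e", p)
  expect_equal(unname(y["I_ee"]),
               exp(1) * p$Gamma_ee * (p$N_ee * se + p$p_ee) / p$gamma_ee)
  expect_true(all(y[c("J_ee", "J_ei", "J_ie", "J_ii")] == 0))
  # continuity under small input perturbations
  prev <- y
  for (d in c(1e-3, 1e-4, 1e-5)) {
    yd <- findEquilibrium(setLileyParameters(p, p_ee = p$p_ee + d))
    expect_lt(max(abs(yd - y)), 50 * d + 1e-9)
  }
})

test_that("simulation stays on an equilibrium and converges in tolerance", {
  p <- demoParams(p_ee = 4, p_ei = 1)
  y <- findEquilibrium(p)
  tr <- simulateLiley(p, y0 = y, tEnd = 1000, by = 10)
  expect_false(tr$diverged)
  expect_lt(max(abs(sweep(tr$states, 2, y))), 1e-6)
  # halving tolerances barely moves a short trajectory endpoint
  y0 <- y + c(0.5, -0.5, rep(0, 8))
  e1 <- simulateLiley(p, y0 = y0, tEnd = 100, by = 100, rtol = 1e-8,
                      atol = 1e-10)$states[2, ]
  e2 <- simulateLiley(p, y0 = y0, tEnd = 100, by = 100, rtol = 5e-9,
                      atol = 5e-11)$states[2, ]
  expect_lt(max(abs(e1 - e2) / (1 + abs(e1))), 1e-6)
})

test_that("compiled and R right-hand sides integrate to the same endpoint", {
  p <- demoParams(p_ee = 6, p_ei = 2)
  y0 <- unname(defaultInitialState(p, seed = 4, mag = 2))
  cmp <- simulateLiley(p, y0 = y0, tEnd = 50, by = 50)$states[2, ]
  rf <- function(t, y, parms) list(unname(lileyRHS(y, p)))
  ref <- deSolve::ode(y = y0, times = c(0, 50), func = rf, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)[2, -1]
  expect_equal(unname(cmp), unname(ref), tolerance = 1e-6)
})

test_that("divergence is flagged, not propagated", {
  p <- demoParams()
  y0 <- unname(findEquilibrium(p))
  tr <- simulateLiley(p, y0 = y0, tEnd = 100, divergenceBound = 1e-3)
  expect_true(tr$diverged)
  expect_true(all(is.finite(tr$states)))
})
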