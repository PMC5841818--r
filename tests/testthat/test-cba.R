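test_that("a zero boundary admits only the zero flux solution", {
  sol <- solve_timepoint(fx_net(), list(time = 0, JO2 = 0, JCO2 = 0,
                                        carb = 0, fa = 0))
  expect_true(startsWith(sol$status, "optimal"))
  expect_equal(max(abs(sol$J)), 0)
  expect_equal(sol$objective_value, 0)
})

test_that("pure-fuel boundaries reproduce textbook oxidation stoichiometry", {
  net <- fx_net()
  # glucose: 1 glc + 6 O2 -> 6 CO2, RQ = 1, PDH carries 2 per glucose
  g <- solve_timepoint(net, list(time = 0, JO2 = 6e-4, JCO2 = 6e-4,
                                 carb = 1e-4, fa = 0))
  expect_equal(solution_rq(g), 1.0, tolerance = 1e-9)
  expect_equal(unname(g$J["PDH"]), 2e-4, tolerance = 1e-9)
  expect_equal(unname(g$J["LDH"]), 0, tolerance = 1e-12)
  expect_equal(unname(abs(g$J["ACAD1"])), 0, tolerance = 1e-12)
  # palmitate: 1 fa + 23 O2 -> 16 CO2, RQ = 16/23; spiral carries 1 per round
  p <- solve_timepoint(net, list(time = 0, JO2 = 23e-5, JCO2 = 16e-5,
                                 carb = 0, fa = 1e-5))
  expect_equal(solution_rq(p), 16 / 23, tolerance = 1e-9)
  expect_equal(unname(p$J[sprintf("ACAD%d", 1:7)]), rep(1e-5, 7),
               tolerance = 1e-8)
  expect_equal(unname(p$J["CS"]), 8e-5, tolerance = 1e-9)
})

test_that("mass balance and looplessness hold at the resting solution", {
  net <- fx_net()
  rest <- fx_rest()
  expect_lt(rest$mass_balance_residual, 1e-9 * max(abs(rest$J)))
  expect_length(detect_loops(net, rest$J), 0L)
  expect_gt(rest$objective_value, 0)
})

test_that("boundary reconciliation projects noisy data onto consistency", {
  b <- fx_boundary_row(1e-3, 0.8)
  # noise-free data are a fixed point of the projection
  r <- fuelswitch:::.reconcile_boundary(b$JO2, b$JCO2, b$carb, b$fa)
  expect_equal(unname(r["JO2"]), b$JO2, tolerance = 1e-10)
  expect_equal(unname(r["carb"]), b$carb, tolerance = 1e-10)
  # noisy data get adjusted onto the stoichiometric subspace
  r2 <- fuelswitch:::.reconcile_boundary(b$JO2 * 1.05, b$JCO2 * 0.97,
                                         b$carb, b$fa)
  expect_equal(unname(r2["JO2"]), unname(6 * r2["carb"] + 23 * r2["fa"]),
               tolerance = 1e-12)
  expect_equal(unname(r2["JCO2"]), unname(6 * r2["carb"] + 16 * r2["fa"]),
               tolerance = 1e-12)
})

test_that("unreconciled carbon-infeasible boundaries raise an error", {
  expect_error(
    solve_timepoint(fx_net(), list(time = 0, JO2 = 1e-3, JCO2 = 1e-3,
                                   carb = 1e-5, fa = 0), reconcile = FALSE),
    class = "fuelswitch_infeasible")
})

test_that("small polytopes match exhaustive vertex enumeration", {
  # toy with a redundant parallel pair: maximize P1 subject to IN fixed
  net <- toy_parallel()
  n <- length(net$reaction_ids)
  Efix <- matrix(0, 1, n, dimnames = list("IN", net$reaction_ids))
  Efix["IN", "IN"] <- 1
  Aeq <- rbind(net$S, Efix)
  beq <- c(rep(0, nrow(net$S)), 1)
  lb <- setNames(rep(0, n), net$reaction_ids)
  ub <- setNames(rep(10, n), net$reaction_ids)
  for (target in c("P1", "P2", "OUT")) {
    cvec <- as.numeric(net$reaction_ids == target)
    lpres <- fuelswitch:::.lp_flux(cvec, Aeq, beq, lb, ub, maximize = TRUE)
    oracle <- lp_vertex_oracle(cvec, Aeq, beq, lb, ub)
    expect_equal(lpres$objective, oracle$objective, tolerance = 1e-8,
                 label = paste("objective for", target))
  }
  # randomized objectives on the same polytope
  set.seed(42)
  for (i in 1:5) {
    cvec <- rnorm(n)
    lpres <- fuelswitch:::.lp_flux(cvec, Aeq, beq, lb, ub, maximize = TRUE)
    oracle <- lp_vertex_oracle(cvec, Aeq, beq, lb, ub)
    expect_equal(lpres$objective, oracle$objective, tolerance = 1e-8)
  }
})

test_that("a two-point constant boundary series solves identically", {
  net <- fx_net()
  b <- fx_boundary_row(1e-3, 0.8)
  bs <- boundary_series(c(0, 10), rep(b$JO2, 2), rep(b$JCO2, 2),
                        rep(b$carb, 2), rep(b$fa, 2))
  ser <- solve_series(net, bs)
  expect_true(all(startsWith(ser$status, "optimal")))
  expect_equal(ser$J[1, ], ser$J[2, ], tolerance = 1e-9)
})

test_that("oxidative fluxes grow monotonically along a graded ramp", {
  net <- fx_net()
  bs <- make_boundary_series(protocol_spec("HCR_like", noise = 0))
  ser <- solve_series(net, bs[seq(1, nrow(bs), by = 5), ])
  expect_true(all(startsWith(ser$status, "optimal")))
  for (rx in c("CS", "C34", "ATPS", "ATPASE"))
    expect_true(all(diff(ser$J[, rx]) > -1e-12), label = rx)
})

test_that("the flux envelope is tight when the optimum is unique", {
  env <- flux_envelope(fx_net(), c(time = 0, fx_boundary_row(1e-3, 0.8)),
                       mode = "fva")
  width <- env$envelope_max - env$envelope_min
  expect_lte(max(width), 0.05 * max(abs(env$solution$J)))
  expect_true(all(env$envelope_min <= env$solution$J + 1e-9))
  expect_true(all(env$envelope_max >= env$solution$J - 1e-9))
})

test_that("the ATPase demand interpolant fits the solved series", {
  net <- fx_net()
  bs <- make_boundary_series(protocol_spec("HCR_like", noise = 0))
  idx <- seq(1, nrow(bs), by = 3)
  ser <- solve_series(net, bs[idx, ])
  f <- atpase_demand_curve(ser, degree = 3)
  pred <- f(ser$times)
  expect_true(all(pred >= 0))
  expect_lt(max(abs(pred - ser$J[, "ATPASE"]) / max(ser$J[, "ATPASE"])), 0.05)
  # a linear flux sequence is interpolated exactly at degree 1
  lin <- ser
  lin$J[, "ATPASE"] <- seq(1e-3, 2e-3, length.out = length(idx))
  f1 <- atpase_demand_curve(lin, degree = 1)
  expect_equal(f1(lin$times), unname(lin$J[, "ATPASE"]), tolerance = 1e-9)
  expect_error(atpase_demand_curve(ser, degree = length(idx)), "degree")
})
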