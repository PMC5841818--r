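test_that("the rate law obeys its analytic structure", {
  ctx <- thermo_context()
  RT <- ctx$RT
  # equilibrium: dG' = 0 -> J = 0 regardless of X and Ct
  net0 <- toy_ab()
  expect_equal(unname(reaction_flux(net0, c(a = 1e-3, b = 1e-3),
                                    c(AB = 7))), 0)
  # forward saturation: dG' -> -inf with finite dG'0 gives J -> X Ct
  path <- toy_network_file(list(toy_sp("a"), toy_sp("b", lb = 1e-30)),
                           list(toy_rx("AB", list(a = -1, b = 1), dg0 = -1)))
  netf <- load_network(path)
  J <- reaction_flux(netf, c(a = 1e-2, b = 1e-25), c(AB = 1), floor = 1e-30)
  Ct <- 1e-2 + 1e-25
  expect_equal(unname(J), Ct, tolerance = 1e-6)
  # worked example: X = 1, [A] = [B] = 1 M, dG'0 = -RT ln 2 -> J = 0.5
  path2 <- toy_network_file(
    list(toy_sp("a", ub = 2, conc = 1), toy_sp("b", ub = 2, conc = 1)),
    list(toy_rx("AB", list(a = -1, b = 1), dg0 = -RT * log(2))))
  net2 <- load_network(path2)
  expect_equal(unname(reaction_flux(net2, c(a = 1, b = 1), c(AB = 1))), 0.5,
               tolerance = 1e-12)
})

test_that("flux sign always opposes the free energy", {
  net <- fx_net()
  ctx <- thermo_context()
  set.seed(5)
  X <- setNames(runif(87, 0.1, 10), net$reaction_ids)
  for (i in 1:5) {
    conc <- resting_concentrations(net) * exp(runif(98, -2, 2))
    dg <- delta_g_prime(net, conc, ctx)
    J <- reaction_flux(net, conc, X, ctx)
    nz <- abs(dg) > 1e-9
    expect_true(all(sign(J[nz]) == -sign(dg[nz])))
  }
})

test_that("the partition matrix scales compartment derivatives", {
  # single reaction moving 1 unit from cytosol to mitochondrion:
  # |dB/dt| / |dA/dt| = 0.75 / 0.05 = 15
  path <- toy_network_file(
    list(toy_sp("a", comp = "cytosol"), toy_sp("b_m", comp = "mitochondrion")),
    list(toy_rx("T", list(a = -1, b_m = 1), dg0 = -10, reversible = FALSE)))
  net <- load_network(path)
  d <- ode_rhs(net, c(a = 1e-3, b_m = 1e-5), c(T = 1))
  expect_equal(unname(d["b_m"] / abs(d["a"])), 15, tolerance = 1e-12)
  # zero activities give a zero derivative
  expect_equal(max(abs(ode_rhs(net, c(a = 1e-3, b_m = 1e-5), c(T = 0)))), 0)
})

test_that("carbon is conserved in a closed toy system", {
  path <- toy_network_file(
    list(toy_sp("a", carbon = 2), toy_sp("b", carbon = 2)),
    list(toy_rx("AB", list(a = -1, b = 1), dg0 = -3)))
  net <- load_network(path)
  tr <- simulate_kinetics(net, c(a = 1e-3, b = 1e-4), c(AB = 1),
                          demand_constant(0), c(0, 10), dt = 1)
  vols <- 0.755 * 0.75
  total <- (tr$conc[, "a"] + tr$conc[, "b"]) * vols * 2
  expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
})

test_that("the packaged resting state is nearly steady at resting demand", {
  net <- fx_net()
  conc0 <- resting_concentrations(net)
  rest <- fx_rest()
  X <- initial_activities(net, conc0, rest$J)
  expect_length(X, 86L)
  expect_false("ATPASE" %in% names(X))
  # the rate law at the packaged state reproduces the resting fluxes
  J <- reaction_flux(net, conc0, X)
  nz <- setdiff(names(rest$J)[abs(rest$J) > 1e-12], "ATPASE")
  expect_lt(max(abs(J[nz] - rest$J[nz])) / max(abs(rest$J)), 1e-9)
  tr <- simulate_kinetics(net, conc0, X,
                          demand_constant(rest$J[["ATPASE"]]), c(0, 50),
                          dt = 10)
  expect_false(tr$crashed)
  n <- nrow(tr$conc)
  drift <- abs(tr$conc[n, ] - conc0[colnames(tr$conc)]) /
    pmax(conc0[colnames(tr$conc)], 1e-15)
  expect_lt(max(drift), 0.01)
})

test_that("activity transitions interpolate monoexponentially", {
  X_rest <- c(A = 1, B = 2)
  X_ex <- c(A = 3, B = 2)
  sp <- transition_spec(X_rest, X_ex, Tc = 0.15, vo2_rest = 10)
  expect_equal(transition_activities(sp, 10), X_rest)
  # one transition constant of intensity: weight 1/e
  expect_equal(unname(transition_activities(sp, 10 + 1 / 0.15)["A"]),
               3 + (1 - 3) * exp(-1), tolerance = 1e-12)
  # far above rest the exercise set is reached
  expect_equal(transition_activities(sp, 1e4), X_ex, tolerance = 1e-10)
  expect_error(transition_activities(sp, 5))
})

test_that("fuel fractions follow the indirect-calorimetry partition", {
  expect_equal(fuel_fractions(0.7)$fa, 100)
  expect_equal(fuel_fractions(1.0)$fa, 0)
  expect_equal(fuel_fractions(0.85), data.frame(fa = 50, cho = 50))
  expect_warning(ff <- fuel_fractions(1.2), "clipping")
  expect_equal(ff$fa, 0)
})

test_that("trajectory observables expose the measured quantities", {
  tr <- fx_hcr_traj()
  o <- tr$observables
  expect_true(all(c("JO2", "JCO2", "RQ", "lactate", "dpsi",
                    "nad_ratio_cyt", "carn_C16", "carn_acetyl",
                    "carn_free") %in% names(o)))
  expect_equal(o$RQ, o$JCO2 / o$JO2, tolerance = 1e-9)
  expect_true(all(o$carn_free > 0))
})
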