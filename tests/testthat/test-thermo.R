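test_that("transformed free energies follow dG' = dG'0 + RT ln Q", {
  net <- toy_ab()
  ctx <- thermo_context()
  # dG'0 = 0, both concentrations 1 M -> dG' = 0
  expect_equal(unname(delta_g_prime(net, c(a = 1, b = 1), ctx)), 0)
  # equal concentrations -> Q = 1 -> dG' = dG'0
  path <- toy_network_file(list(toy_sp("a"), toy_sp("b")),
                           list(toy_rx("AB", list(a = -1, b = 1), dg0 = -5)))
  net5 <- load_network(path)
  expect_equal(unname(delta_g_prime(net5, c(a = 1e-3, b = 1e-3), ctx)), -5)
  # [B]/[A] = e -> dG' = dG'0 + RT; RT = 2.478957 kJ/mol at 298.15 K
  expect_equal(unname(delta_g_prime(net, c(a = 1e-3, b = 1e-3 * exp(1)), ctx)),
               8.314462618e-3 * 298.15, tolerance = 1e-12)
  expect_error(delta_g_prime(net, c(a = 0, b = 1)), "strictly positive")
})

test_that("feasible samples satisfy the second law for carrying reactions", {
  net <- fx_net()
  rest <- fx_rest()
  conc <- sample_feasible_concentrations(net, rest$J, seed = 11,
                                         max_tries = 60000, eps = 0.05)
  dg <- delta_g_prime(net, conc)
  carrying <- abs(rest$J) > 1e-12
  # exact re-evaluation of the directional inequality
  expect_true(all(dg[carrying] * sign(rest$J[carrying]) < 0))
  # bounds respected
  expect_true(all(conc >= net$species$lb & conc <= net$species$ub))
  # determinism: identical seed reproduces the sample bit-for-bit
  conc2 <- sample_feasible_concentrations(net, rest$J, seed = 11,
                                          max_tries = 60000, eps = 0.05)
  expect_identical(unclass(conc), unclass(conc2))
})

test_that("zero-flux reactions impose no direction constraint", {
  net <- toy_ab()
  # with zero reference flux any in-bounds vector is acceptable
  conc <- sample_feasible_concentrations(net, c(AB = 0), seed = 1)
  expect_true(all(conc > 0))
  expect_identical(attr(conc, "attempts"), 1L)
})

test_that("sampling is log-uniform between the bounds", {
  net <- toy_ab()
  draws <- vapply(1:2000, function(s)
    sample_feasible_concentrations(net, c(AB = 0), seed = s)[["a"]], 0)
  lx <- log(draws)
  ks <- suppressWarnings(
    stats::ks.test(lx, "punif", log(1e-6), log(1e-2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("an infeasible problem reports the violated reactions", {
  # A -> B with dG'0 = +50: forward flux cannot be feasible within
  # one order of magnitude of concentration range
  path <- toy_network_file(
    list(toy_sp("a", lb = 1e-4, ub = 1e-3), toy_sp("b", lb = 1e-4, ub = 1e-3)),
    list(toy_rx("AB", list(a = -1, b = 1), dg0 = 50)))
  net <- load_network(path)
  err <- tryCatch(
    sample_feasible_concentrations(net, c(AB = 1), seed = 1, max_tries = 50),
    error = function(e) e)
  expect_s3_class(err, "fuelswitch_infeasible")
  expect_match(conditionMessage(err), "AB")
})

test_that("buffer poising moves side pools to equilibrium", {
  net <- fx_net()
  rest <- fx_rest()
  conc <- sample_feasible_concentrations(net, rest$J, seed = 3,
                                         max_tries = 60000, eps = 0.05)
  poised <- poise_buffers(net, conc)
  dg <- delta_g_prime(net, poised)
  expect_lt(abs(dg[["CK"]]), 0.5)
  expect_lt(abs(dg[["LDH"]]), 0.5)
  expect_lt(abs(dg[["CRAT"]]), 0.5)
})
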