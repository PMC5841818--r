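test_that("sensitivity ranks are a permutation with sensible signs", {
  net <- fx_net()
  truth <- fx_truth()
  subset <- c("CPT1", "FAT", "GLUT", "HK", "LDH", "CS", "C34", "ACRNT")
  sens <- sensitivity_coefficients(net, truth$hcr, reactions = subset,
                                   dt = 2)
  expect_setequal(sens$rank, seq_along(subset))
  # reducing fatty-acid entry raises RQ -> phi < 0 for the FA transporter;
  # glucose entry works the other way
  expect_lt(sens$phi[sens$reaction == "FAT"], 0)
  expect_gt(sens$phi[sens$reaction == "GLUT"], 0)
  # an equilibrative side pool has essentially no control over fuel mix
  expect_lt(abs(sens$phi[sens$reaction == "ACRNT"]),
            max(abs(sens$phi)) / 50)
})

test_that("sensitivity ranks are stable to halving the step", {
  net <- fx_net()
  truth <- fx_truth()
  subset <- c("CPT1", "FAT", "FACS", "GLUT", "HK", "PGI", "CS", "C34")
  # secant sensitivities over steps large enough to average out the local
  # curvature of the protocol-mean RQ response
  s1 <- sensitivity_coefficients(net, truth$hcr, perturbation = 0.10,
                                 reactions = subset, dt = 2)
  s2 <- sensitivity_coefficients(net, truth$hcr, perturbation = 0.05,
                                 reactions = subset, dt = 2)
  rho <- stats::cor(s1$rank, s2$rank, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("enzyme scores combine ratios and sensitivities", {
  rid <- c("R1", "R2")
  ens <- matrix(c(2, 2, 1, 1), 2, 2, dimnames = list(NULL, rid))
  ensB <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(NULL, rid))
  sens <- data.frame(reaction = rid, phi = c(1, 0.5), rank = 1:2)
  sc <- enzyme_score(ens, ensB, sens, sens, n_boot = 10)
  # ratio 2 with |phi| = 1 -> 2; ratio 1 with |phi| = 0.5 -> 0.5
  expect_equal(sc$score_hcr, c(2, 0.5))
  expect_equal(sc$score_lcr, c(0.5, 0.5))
  # identical ensembles with phi = 1 give unit scores
  sens1 <- data.frame(reaction = rid, phi = c(1, 1), rank = 1:2)
  sc1 <- enzyme_score(ens, ens, sens1, sens1, n_boot = 10)
  expect_equal(sc1$score_hcr, c(1, 1))
  # power mode: ratio^|phi|
  scp <- enzyme_score(ens, ensB, sens, sens, mode = "power", n_boot = 10)
  expect_equal(scp$score_hcr, c(2, 1))
})

test_that("the knockout capacity experiment detects ATP collapse", {
  net <- fx_net()
  truth <- fx_truth()
  cap <- fao_capacity(net, truth$hcr)
  expect_false(cap$unbounded)
  expect_gt(cap$max_sustainable_atpase, 0)
  expect_gt(cap$collapse_time, 1)
  # with the fatty-acid pathway also disabled, capacity is essentially zero
  X0 <- truth$hcr$X_exercise
  X0[intersect(names(X0), fao_reactions(net))] <- 0
  cap0 <- fao_capacity(net, X0, conc0 = truth$hcr$conc0,
                       basal = truth$hcr$basal)
  # the residual "capacity" is only the adenine/phosphagen pool drain
  # sustained during the early ramp
  expect_lt(cap0$max_sustainable_atpase,
            0.25 * cap$max_sustainable_atpase)
  expect_lt(cap0$collapse_time, 0.3 * cap$collapse_time)
})

test_that("ANT flux tracks the realized ATPase at sustained sub-capacity demand", {
  net <- fx_net()
  truth <- fx_truth()
  cap <- fx("capH", function() fao_capacity(net, truth$hcr))
  X <- truth$hcr$X_exercise
  gly <- intersect(names(X), pathway_members(net, "glycolysis"))
  X[gly] <- X[gly] * 1e-6
  X["CK"] <- 0
  tr <- simulate_kinetics(net, truth$hcr$conc0, X,
                          demand_constant(0.5 * cap$max_sustainable_atpase,
                                          basal = truth$hcr$basal),
                          c(0, 25), dt = 1)
  expect_false(tr$crashed)
  n <- nrow(tr$fluxes)
  # total ATPase flux includes the supra-basal term; ANT must supply it
  expect_lt(abs(tr$fluxes[n, "ANT"] / tr$fluxes[n, "ATPASE"] - 1), 0.05)
})

test_that("capacity grows with fatty-acid import activity", {
  net <- fx_net()
  truth <- fx_truth()
  caps <- vapply(c(0.05, 0.2, 1), function(f) {
    p2 <- truth$hcr
    p2$X_rest["CPT1"] <- p2$X_rest["CPT1"] * f
    p2$X_exercise["CPT1"] <- p2$X_exercise["CPT1"] * f
    fao_capacity(net, p2)$max_sustainable_atpase
  }, 0)
  expect_true(all(diff(caps) >= 0))
  expect_gt(caps[3], caps[1])
})
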