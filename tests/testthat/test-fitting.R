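test_that("the pooled error statistic computes standardized residual means", {
  # hand-built observation object with a constant model
  obs <- structure(list(
    series = data.frame(time = c(0, 1), JO2 = c(1, 1), JCO2 = c(1, 1),
                        lactate = c(1, 1), RQ = c(1, 1),
                        var_JO2 = c(1, 1), var_JCO2 = c(1, 1),
                        var_lactate = c(1, 1), var_RQ = c(1, 1)),
    biopsies = data.frame(time = numeric(), pool = character(),
                          value = numeric(), variance = numeric()),
    tspan = c(0, 1)), class = "observation_set")
  traj <- list(observables = data.frame(time = c(0, 1), JO2 = c(1, 1),
                                        JCO2 = c(1, 1), lactate = c(1, 1),
                                        RQ = c(1, 1)))
  # model identical to data -> 0
  expect_equal(error_function(traj, obs), 0)
  # one unit-variance residual of size sigma contributes 1
  traj$observables$JO2 <- c(2, 1)   # residual 1 at t = 0
  expect_equal(error_function(traj, obs), 1 / 8)
  # residuals sigma and 2*sigma pooled over two points -> mean(1, 4) = 2.5
  obs1 <- obs
  obs1$series <- data.frame(time = c(0, 1), JO2 = c(1, 2), var_JO2 = c(1, 1),
                            JCO2 = c(9, 9), var_JCO2 = c(1e12, 1e12),
                            lactate = c(9, 9), var_lactate = c(1e12, 1e12),
                            RQ = c(9, 9), var_RQ = c(1e12, 1e12))
  traj1 <- list(observables = data.frame(time = c(0, 1), JO2 = c(2, 4),
                                         JCO2 = c(9, 9), lactate = c(9, 9),
                                         RQ = c(9, 9)))
  expect_equal(error_function(traj1, obs1), mean(c(1, 4, rep(0, 6))))
  # missing coverage is an error naming the horizon
  traj2 <- traj
  traj2$observables <- traj2$observables[1, ]
  expect_error(error_function(traj2, obs), "does not cover")
})

test_that("hypothesis-mode parameterizations touch only their sets", {
  net <- fx_net()
  truth <- fx_truth()
  base <- truth$hcr
  mm <- fuelswitch:::.mode_activities(net, base, "mito_scale_only",
                                      list(mito_fraction = 0.5))
  m <- intersect(names(base$X_rest), mito_reactions(net))
  out <- setdiff(names(base$X_rest), m)
  expect_equal(mm$X_rest[m], base$X_rest[m] * 0.5)
  expect_equal(mm$X_rest[out], base$X_rest[out])
  ff <- fuelswitch:::.mode_activities(net, base, "fao_scale_only",
                                      list(fao_factor = 4))
  fset <- intersect(names(base$X_rest), fao_reactions(net))
  expect_equal(ff$X_exercise[fset], base$X_exercise[fset] / 4)
  cc <- fuelswitch:::.mode_activities(net, base, "minimal_combined",
                                      list(mito_fraction = 0.5,
                                           fa_transport_factor = 5,
                                           extra = NULL))
  expect_equal(unname(cc$X_rest[["CPT1"]]),
               unname(base$X_rest[["CPT1"]] * 0.5 / 5))
})

test_that("a small free fit from a perturbed start reduces the error", {
  net <- fx_net()
  truth <- fx_truth()
  obs <- fx_lcr_obs()
  # start from the truth mildly perturbed on two influential activities
  init <- truth$lcr
  init$X_rest[c("CPT1", "GLUT")] <- init$X_rest[c("CPT1", "GLUT")] * 1.5
  init$X_exercise[c("CPT1", "GLUT")] <- init$X_exercise[c("CPT1", "GLUT")] * 1.5
  e0 <- fuelswitch:::.candidate_error(net, obs, init$X_rest,
                                      init$X_exercise, dt = 1)$error
  fit <- fit_activities(net, obs, "free_fit", init = init,
                        hyperparams = list(sa_epochs = 2, proposals = 6,
                                           polish_evals = 20, dt = 1),
                        seed = 3)
  expect_lte(fit$error, e0)
  expect_identical(fit$mode, "free_fit")
  # determinism: same seed, same result
  fit2 <- fit_activities(net, obs, "free_fit", init = init,
                         hyperparams = list(sa_epochs = 2, proposals = 6,
                                            polish_evals = 20, dt = 1),
                         seed = 3)
  expect_equal(fit$error, fit2$error)
  expect_equal(fit$scale_factors$mult, fit2$scale_factors$mult)
})

test_that("ensembles accept everything at infinite threshold", {
  net <- fx_net()
  truth <- fx_truth()
  obs <- fx_lcr_obs()
  base <- structure(list(X_fit = truth$lcr$X_exercise,
                         X_rest = truth$lcr$X_rest, error = 1),
                    class = "fit_result")
  ens <- build_ensemble(net, obs, base, n_sets = 3, accept_threshold = Inf,
                        sigma = 0.01, seed = 2, dt = 2)
  expect_identical(nrow(ens), 3L)
  expect_equal(attr(ens, "acceptance_rate"), 1.0)
  # zero perturbation keeps copies of the base set
  ens0 <- build_ensemble(net, obs, base, n_sets = 2, accept_threshold = Inf,
                         sigma = 0, seed = 2, dt = 2)
  expect_equal(ens0[1, ], base$X_fit)
  expect_equal(ens0[2, ], base$X_fit)
})

test_that("pairwise ratio distributions count and summarize correctly", {
  A <- matrix(2, 3, 2, dimnames = list(NULL, c("R1", "R2")))
  B <- matrix(1, 4, 2, dimnames = list(NULL, c("R1", "R2")))
  rh <- activity_ratio_histograms(A, B)
  expect_length(rh$ratios$R1, 12L)
  expect_equal(rh$summary$median, c(2, 2))
  expect_equal(rh$summary$n, c(12, 12))
  # identical singleton ensembles give all-unit ratios
  one <- matrix(5, 1, 2, dimnames = list(NULL, c("R1", "R2")))
  rh1 <- activity_ratio_histograms(one, one)
  expect_equal(unname(unlist(rh1$ratios)), c(1, 1))
})
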