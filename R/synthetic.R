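# Synthetic-data generator: everything the original graded-treadmill rat
# experiments supplied, with known ground truth. The boundary-flux curves
# emulate indirect calorimetry during a speed-incremented run (2-min steps
# until exhaustion: ~50 min for the high-capacity genotype, ~14 min for the
# low-capacity one); fuel uptake series are derived from a prescribed RQ
# trajectory through the oxidation stoichiometry (glucose 6 O2 -> 6 CO2,
# palmitate 23 O2 -> 16 CO2), so the four series are exactly consistent at
# zero noise. Flux magnitudes are order-of-magnitude placeholders on the
# whole-body scale (resting JO2 1e-3 mol/min/kg).

#' Graded-exercise protocol specification
#'
#' @param genotype `"HCR_like"` (exhaustion ~50 min, RQ 0.80 to 0.87) or
#'   `"LCR_like"` (exhaustion ~14 min, RQ 0.85 to 1.0, lower peak JO2).
#' @param duration protocol duration (minutes); default the genotype's
#'   exhaustion time.
#' @param step_interval treadmill speed increment interval (minutes).
#' @param jo2_rest,jo2_peak oxygen uptake at rest / exhaustion
#'   (mol min^-1 kg^-1).
#' @param rq_rest,rq_peak respiratory quotient at rest / exhaustion.
#' @param noise relative SD of additive Gaussian noise per series.
#' @param seed RNG seed; every generator output is a pure function of
#'   (spec, seed).
#' @return a `protocol_spec`.
#' @export
protocol_spec <- function(genotype = c("HCR_like", "LCR_like"),
                          duration = NULL, step_interval = 2,
                          jo2_rest = 1e-3, jo2_peak = NULL,
                          rq_rest = NULL, rq_peak = NULL,
                          noise = 0.03, seed = 1L) {
  genotype <- match.arg(genotype)
  hcr <- genotype == "HCR_like"
  if (is.null(duration)) duration <- if (hcr) 50 else 14
  if (is.null(jo2_peak)) jo2_peak <- if (hcr) 3e-3 else 2e-3
  if (is.null(rq_rest)) rq_rest <- if (hcr) 0.80 else 0.85
  if (is.null(rq_peak)) rq_peak <- if (hcr) 0.87 else 1.00
  if (duration %% step_interval != 0)
    stop("step_interval must divide duration")
  if (noise < 0) stop("noise must be >= 0")
  structure(list(genotype = genotype, duration = duration,
                 step_interval = step_interval,
                 jo2_rest = jo2_rest, jo2_peak = jo2_peak,
                 rq_rest = rq_rest, rq_peak = rq_peak,
                 noise = noise, seed = as.integer(seed)),
            class = "protocol_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a boundary-flux series for a graded protocol
#'
#' JO2 follows a saturating ramp (monotone with a plateau near exhaustion);
#' the RQ trajectory is linear between its rest and peak values; glucose and
#' palmitate uptake are computed from (JO2, RQ) through the oxidation
#' stoichiometry, making the four series mutually consistent at zero noise.
#' Gaussian noise (relative SD `spec$noise`) is then added independently per
#' series, truncated at zero.
#'
#' @param spec a [protocol_spec()].
#' @param genotype optional override of `spec$genotype`.
#' @return a [boundary_series()] with `var_*` columns.
#' @export
make_boundary_series <- function(spec, genotype = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (!is.null(genotype) && genotype != spec$genotype)
    spec <- utils::modifyList(spec, list(genotype = genotype))
  times <- seq(0, spec$duration, by = spec$step_interval)
  tau <- spec$duration / 2.5   # saturating time constant: plateau near the end
  s <- (1 - exp(-times / tau)) / (1 - exp(-spec$duration / tau))
  JO2 <- spec$jo2_rest + (spec$jo2_peak - spec$jo2_rest) * s
  RQ <- spec$rq_rest + (spec$rq_peak - spec$rq_rest) * times / spec$duration
  JCO2 <- RQ * JO2
  fa <- (JO2 - JCO2) / 7
  carb <- (23 * JCO2 - 16 * JO2) / 42
  carb <- pmax(carb, 0); fa <- pmax(fa, 0)
  if (spec$noise > 0) {
    .with_seed(spec$seed, {
      JO2 <- pmax(JO2 * (1 + stats::rnorm(length(JO2), 0, spec$noise)), 0)
      JCO2 <- pmax(JCO2 * (1 + stats::rnorm(length(JCO2), 0, spec$noise)), 0)
      carb <- pmax(carb * (1 + stats::rnorm(length(carb), 0, spec$noise)), 0)
      fa <- pmax(fa * (1 + stats::rnorm(length(fa), 0, spec$noise)), 0)
    })
  }
  boundary_series(times, JO2, JCO2, carb, fa,
                  variance = list(JO2 = pmax(spec$noise * JO2, 1e-12)^2,
                                  JCO2 = pmax(spec$noise * JCO2, 1e-12)^2,
                                  carb = pmax(spec$noise * carb, 1e-12)^2,
                                  fa = pmax(spec$noise * fa, 1e-12)^2))
}

#' Ground-truth genotype parameterization pair
#'
#' The high-capacity truth is the canonical parameterization derived from a
#' noise-free high-capacity boundary series; the low-capacity truth applies
#' the genotype transform (mitochondrial activities x `mito_fraction`,
#' fatty-acid transport / `fa_transport_factor`, compounding on the
#' transport reactions) and is driven by its own lower, shorter demand
#' protocol. Exact ratio structure: FA-transport reactions
#' `1/(mito_fraction/fa_transport_factor)`, other mitochondrial reactions
#' `1/mito_fraction`, glycolytic reactions 1.
#'
#' @param net a `metabolic_network`.
#' @param conc0 resting concentrations.
#' @param seed generator seed (propagated to the protocol specs).
#' @param mito_fraction,fa_transport_factor the genotype transform.
#' @param extra optional named per-reaction extra divisors.
#' @return list with `hcr`, `lcr` (`fuel_parameterization`s, the latter
#'   carrying `$transform`), and the two noise-free boundary series.
#' @export
make_ground_truth_pair <- function(net, conc0 = resting_concentrations(net),
                                   seed = 1L, mito_fraction = 0.5,
                                   fa_transport_factor = 5, extra = NULL) {
  spec_h <- protocol_spec("HCR_like", noise = 0, seed = seed)
  spec_l <- protocol_spec("LCR_like", noise = 0, seed = seed)
  bh <- make_boundary_series(spec_h)
  bl <- make_boundary_series(spec_l)
  hcr <- derive_parameterization(net, bh, conc0 = conc0, Tc = 0.15)
  lcr_proto <- derive_parameterization(net, bl, conc0 = conc0, Tc = 0.1)
  lcr <- apply_genotype(hcr, net, mito_fraction = mito_fraction,
                        fa_transport_factor = fa_transport_factor,
                        extra = extra, protocol = lcr_proto$protocol,
                        Tc = 0.1, tspec_vo2_rest = lcr_proto$vo2_rest)
  lcr$boundary <- bl
  list(hcr = hcr, lcr = lcr, boundary_hcr = bh, boundary_lcr = bl,
       seed = seed)
}

#' Generate an observation set by forward simulation
#'
#' Simulates the kinetic model under the truth parameterization's own
#' protocol, samples the gas-exchange observables at every protocol step
#' time and the six total acyl-carnitine pools at the biopsy times, and adds
#' independent Gaussian noise (defaults: 3% gas fluxes, 10% lactate, 15%
#' carnitines — magnitudes consistent with between-animal error bars).
#' True variances are attached for the error function.
#'
#' @param net a `metabolic_network`.
#' @param truth a `fuel_parameterization` (the generating truth).
#' @param spec a [protocol_spec()] (defines step times and seed).
#' @param biopsy_times minutes at which carnitine pools are "biopsied"
#'   (0 and 10 for both genotypes, plus 45 for the high-capacity one).
#' @param noise_gas,noise_lac,noise_carn relative SDs.
#' @param conc0 initial concentrations.
#' @param ... passed to [simulate_kinetics()].
#' @return an `observation_set`: list with `series` (data.frame: time, JO2,
#'   JCO2, RQ, lactate + variances), `biopsies` (data.frame keyed by time x
#'   pool), `protocol`, `tspec`, `tspan`, `trajectory` (the noise-free
#'   truth trajectory).
#' @export
make_observations <- function(net, truth, spec, biopsy_times = c(0, 10),
                              noise_gas = 0.03, noise_lac = 0.10,
                              noise_carn = 0.15,
                              conc0 = NULL, ...) {
  stopifnot(inherits(truth, "fuel_parameterization"),
            inherits(spec, "protocol_spec"))
  if (is.null(conc0)) conc0 <- truth$conc0
  tspan <- c(0, spec$duration)
  tr <- simulate_kinetics(net, conc0, truth$tspec, truth$protocol, tspan,
                          dt = min(1, spec$step_interval / 2), ...)
  o <- tr$observables
  step_times <- seq(0, spec$duration, by = spec$step_interval)
  step_times <- step_times[step_times <= max(tr$times)]
  pick <- function(col, tt) stats::approx(o$time, o[[col]], xout = tt, rule = 2)$y
  ser <- data.frame(time = step_times,
                    JO2 = pick("JO2", step_times),
                    JCO2 = pick("JCO2", step_times),
                    lactate = pick("lactate", step_times))
  ser$RQ <- ser$JCO2 / pmax(ser$JO2, 1e-15)
  biopsy_times <- biopsy_times[biopsy_times <= max(tr$times)]
  pools <- c("carn_C16", "carn_C14", "carn_C8", "carn_C4",
             "carn_acetyl", "carn_free")
  bio <- do.call(rbind, lapply(biopsy_times, function(bt)
    data.frame(time = bt, pool = pools,
               value = vapply(pools, function(p) pick(p, bt), 0))))
  rownames(bio) <- NULL
  .with_seed(spec$seed + 1L, {
    nz <- function(x, rel) if (rel > 0) pmax(x * (1 + stats::rnorm(length(x), 0, rel)), 0) else x
    ser$JO2 <- nz(ser$JO2, noise_gas)
    ser$JCO2 <- nz(ser$JCO2, noise_gas)
    ser$lactate <- nz(ser$lactate, noise_lac)
    ser$RQ <- ser$JCO2 / pmax(ser$JO2, 1e-15)
    bio$value <- nz(bio$value, noise_carn)
  })
  ser$var_JO2 <- pmax(noise_gas * ser$JO2, 1e-4 * max(ser$JO2))^2
  ser$var_JCO2 <- pmax(noise_gas * ser$JCO2, 1e-4 * max(ser$JCO2))^2
  ser$var_lactate <- pmax(noise_lac * ser$lactate, 1e-4 * max(ser$lactate))^2
  # RQ variance by propagation of error from JCO2 and JO2
  ser$var_RQ <- ser$RQ^2 * (ser$var_JCO2 / ser$JCO2^2 + ser$var_JO2 / ser$JO2^2)
  ser$var_RQ <- pmax(ser$var_RQ, (1e-4 * max(ser$RQ))^2)
  bio$variance <- pmax(noise_carn * bio$value, 1e-4 * max(bio$value))^2
  structure(list(series = ser, biopsies = bio,
                 protocol = truth$protocol, tspec_template = truth$tspec,
                 Tc = truth$Tc, vo2_rest = truth$vo2_rest,
                 tspan = tspan, conc0 = conc0,
                 noise = c(gas = noise_gas, lactate = noise_lac,
                           carnitine = noise_carn),
                 seed = spec$seed), class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> ", nrow(x$series), " series points, ",
      nrow(x$biopsies), " biopsy values over [0, ",
      x$tspan[2], "] min\n", sep = "")
  invisible(x)
}
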