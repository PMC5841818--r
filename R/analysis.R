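#' Sensitivity of fuel selection to enzyme activities
#'
#' Normalized local sensitivity of the protocol-averaged respiratory
#' quotient to each adjustable activity:
#' `phi_i = d ln(mean RQ) / d ln(X_i)` by central finite difference
#' (default +/- 1%), perturbing the resting and exercise activity sets
#' jointly. Reactions are ranked by |phi| (descending; ties broken by
#' reaction id).
#'
#' @param net a `metabolic_network`.
#' @param par a `fuel_parameterization`.
#' @param perturbation relative step (0.01 = 1%).
#' @param reactions subset of reaction ids (default all adjustable).
#' @param t_span,dt simulation window and output step (defaults: the
#'   parameterization's protocol range at 1-min resolution).
#' @param ... passed to [simulate_kinetics()].
#' @return data.frame (`reaction`, `phi`, `rank`, `flagged` — TRUE when a
#'   perturbed simulation failed to meet demand and the difference is
#'   one-sided in spirit).
#' @export
sensitivity_coefficients <- function(net, par, perturbation = 0.01,
                                     reactions = NULL, t_span = NULL,
                                     dt = 1, ...) {
  stopifnot(inherits(par, "fuel_parameterization"))
  if (is.null(t_span)) t_span <- c(0, max(par$boundary$time))
  if (is.null(reactions)) reactions <- names(par$X_rest)
  rqbar <- function(XR, XE) {
    sp <- transition_spec(XR, XE, Tc = par$Tc, vo2_rest = par$vo2_rest)
    tr <- tryCatch(simulate_kinetics(net, par$conc0, sp, par$protocol,
                                     t_span, dt = dt, ...),
                   error = function(e) NULL)
    if (is.null(tr)) return(list(rq = NA_real_, crashed = TRUE))
    list(rq = mean(tr$observables$RQ, na.rm = TRUE), crashed = tr$crashed)
  }
  base <- rqbar(par$X_rest, par$X_exercise)
  if (is.na(base$rq)) stop("base simulation failed")
  up <- 1 + perturbation; dn <- 1 - perturbation
  phi <- flagged <- setNames(rep(NA_real_, length(reactions)), reactions)
  for (r in reactions) {
    XRu <- par$X_rest; XEu <- par$X_exercise
    XRu[r] <- XRu[r] * up; XEu[r] <- XEu[r] * up
    hi <- rqbar(XRu, XEu)
    XRd <- par$X_rest; XEd <- par$X_exercise
    XRd[r] <- XRd[r] * dn; XEd[r] <- XEd[r] * dn
    lo <- rqbar(XRd, XEd)
    flagged[r] <- isTRUE(hi$crashed) || isTRUE(lo$crashed)
    if (!is.na(hi$rq) && !is.na(lo$rq)) {
      phi[r] <- (log(hi$rq) - log(lo$rq)) / (log(up) - log(dn))
    } else if (!is.na(hi$rq)) {
      phi[r] <- (log(hi$rq) - log(base$rq)) / log(up)
    } else if (!is.na(lo$rq)) {
      phi[r] <- (log(base$rq) - log(lo$rq)) / (-log(dn))
    } else phi[r] <- 0
  }
  ord <- order(-abs(phi), reactions)
  rank <- integer(length(reactions))
  rank[ord] <- seq_along(ord)
  data.frame(reaction = reactions, phi = unname(phi), rank = rank,
             flagged = unname(flagged) > 0, row.names = NULL)
}

#' Normalized enzyme activity scores for two genotypes
#'
#' Combines ensemble activity ratios with sensitivity magnitudes:
#' `score_i(A) = (median X_i(A) / median X_i(B)) * |median phi_i(A)|`
#' (product form), and symmetrically for the other genotype. Standard
#' deviations come from a bootstrap over ensemble members.
#'
#' @param ens_HCR,ens_LCR `activity_ensemble` matrices over the same
#'   reactions.
#' @param sens_HCR,sens_LCR sensitivity data.frames from
#'   [sensitivity_coefficients()] (a single set stands in for the
#'   per-member median when only one is available).
#' @param mode `"product"` (default) or `"power"`
#'   (`ratio ^ |median phi|`).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: `reaction`, `score_hcr`, `score_lcr`, `sd_hcr`,
#'   `sd_lcr`.
#' @export
enzyme_score <- function(ens_HCR, ens_LCR, sens_HCR, sens_LCR,
                         mode = c("product", "power"), n_boot = 200,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(identical(colnames(ens_HCR), colnames(ens_LCR)))
  rid <- colnames(ens_HCR)
  ph <- setNames(abs(sens_HCR$phi), sens_HCR$reaction)[rid]
  pl <- setNames(abs(sens_LCR$phi), sens_LCR$reaction)[rid]
  calc <- function(A, B, p) {
    r <- apply(A, 2, stats::median) / apply(B, 2, stats::median)
    if (mode == "product") r * p else r^p
  }
  sh <- calc(ens_HCR, ens_LCR, ph)
  sl <- calc(ens_LCR, ens_HCR, pl)
  boot_h <- matrix(NA_real_, n_boot, length(rid))
  boot_l <- matrix(NA_real_, n_boot, length(rid))
  .with_seed(seed, {
    for (b in seq_len(n_boot)) {
      ia <- sample(nrow(ens_HCR), replace = TRUE)
      ib <- sample(nrow(ens_LCR), replace = TRUE)
      boot_h[b, ] <- calc(ens_HCR[ia, , drop = FALSE],
                          ens_LCR[ib, , drop = FALSE], ph)
      boot_l[b, ] <- calc(ens_LCR[ib, , drop = FALSE],
                          ens_HCR[ia, , drop = FALSE], pl)
    }
  })
  data.frame(reaction = rid, score_hcr = unname(sh), score_lcr = unname(sl),
             sd_hcr = apply(boot_h, 2, stats::sd),
             sd_lcr = apply(boot_l, 2, stats::sd), row.names = NULL)
}

#' Fatty-acid oxidation capacity by glycolysis knockout
#'
#' Knocks glycolytic activities down by a large factor and removes creatine
#' kinase buffering, then imposes a linearly increasing ATPase demand until
#' the ATP concentration collapses (below 25% of its initial value).
#' With glucose oxidation eliminated, the adenine nucleotide transporter
#' flux equals the fatty-acid-driven ATP synthesis delivered to the
#' cytosol. The capacity is the highest demand sustained for at least one
#' minute before collapse.
#'
#' @param net a `metabolic_network`.
#' @param par a `fuel_parameterization` (its exercise activity set is
#'   used), or a named activity vector.
#' @param glycolysis_knockdown_factor multiplier on glycolysis-tagged
#'   activities (default 1e-6).
#' @param ramp_slope demand increase (mol min^-1 kg^-1 per minute).
#' @param t_max ramp horizon (minutes).
#' @param collapse_frac ATP collapse threshold (fraction of initial).
#' @param dwell sustained time (minutes) required below collapse onset.
#' @param conc0 initial concentrations.
#' @param dt output step.
#' @param basal supra-basal ATP-turnover spec (see [demand_constant()]);
#'   defaults to the parameterization's own when `par` is a
#'   `fuel_parameterization`.
#' @param ... passed to [simulate_kinetics()].
#' @return a `capacity_result`: `max_sustainable_atpase`, `collapse_time`,
#'   `ant_flux_at_max`, `fao_flux_at_max`, `trajectory`. When no collapse
#'   occurs within the ramp, `max_sustainable_atpase` is the final demand
#'   and `collapse_time` is `NA` (unbounded within the ramp).
#' @export
fao_capacity <- function(net, par, glycolysis_knockdown_factor = 1e-6,
                         ramp_slope = 2e-4, t_max = 60,
                         collapse_frac = 0.25, dwell = 1,
                         conc0 = NULL, dt = 0.5, basal = NULL, ...) {
  is_par <- inherits(par, "fuel_parameterization")
  if (is.null(conc0))
    conc0 <- if (is_par) par$conc0 else resting_concentrations(net)
  knock <- function(X) {
    gly <- intersect(names(X), pathway_members(net, "glycolysis"))
    X[gly] <- X[gly] * glycolysis_knockdown_factor
    X["CK"] <- 0
    X
  }
  if (is_par) {
    # supply tracks the imposed ramp through the rest-to-exercise
    # transition (inverted from the parameterization's demand curve)
    if (is.null(basal)) basal <- par$basal
    XR <- knock(par$X_rest); XE <- knock(par$X_exercise)
    tsp <- transition_spec(XR, XE, Tc = par$Tc, vo2_rest = par$vo2_rest)
    dem0 <- par$rest$J[["ATPASE"]]
    rA <- par$peak$J[["ATPASE"]] / dem0
    dfun <- function(t) pmax(0.2 * dem0 + ramp_slope * t, 0)
    # activities transition to the exercise set over the portion of the
    # ramp that spans the parameterization's own demand range
    t90 <- (0.9 * dem0 * rA - 0.2 * dem0) / ramp_slope
    vfun <- function(t) par$vo2_rest +
      (100 - par$vo2_rest) * pmin(pmax(t, 0) / t90, 1)
    pr <- demand_interpolated(dfun, vo2 = vfun, basal = basal)
    tr <- simulate_kinetics(net, conc0, tsp, pr, c(0, t_max), dt = dt, ...)
  } else {
    X <- knock(par)
    pr <- demand_ramp(0, ramp_slope, basal = basal)
    tr <- simulate_kinetics(net, conc0, X, pr, c(0, t_max), dt = dt, ...)
  }
  atp <- tr$conc[, "atp"]
  below <- which(atp < collapse_frac * atp[1])
  if (!length(below)) {
    return(structure(list(max_sustainable_atpase = pr$fun(t_max),
                          collapse_time = NA_real_,
                          ant_flux_at_max = tr$fluxes[length(tr$times), "ANT"],
                          fao_flux_at_max = mean(tr$fluxes[length(tr$times),
                                                           sprintf("ACAD%d", 1:7)]),
                          unbounded = TRUE, trajectory = tr),
                     class = "capacity_result"))
  }
  t_collapse <- tr$times[below[1]]
  t_ref <- max(t_collapse - dwell, 0)
  # sustained-operation reference: before the ATP pool starts draining
  sus <- which(atp >= 0.75 * atp[1])
  i_sus <- if (length(sus)) max(sus) else 1L
  structure(list(max_sustainable_atpase = pr$fun(t_ref),
                 collapse_time = t_collapse,
                 ant_flux_at_max = tr$fluxes[i_sus, "ANT"],
                 fao_flux_at_max = mean(tr$fluxes[i_sus, sprintf("ACAD%d", 1:7)]),
                 atpase_at_sustained = tr$realized[i_sus],
                 unbounded = FALSE, trajectory = tr),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("<capacity_result> max sustainable ATPase:",
      signif(x$max_sustainable_atpase, 4), "mol/min/kg",
      if (x$unbounded) "(no collapse within ramp)" else
        paste0("(collapse at t = ", signif(x$collapse_time, 4), " min)"), "\n")
  invisible(x)
}
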