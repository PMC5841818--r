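#' Derive a rest-to-exercise kinetic parameterization from boundary data
#'
#' Builds the canonical kinetic parameterization of a genotype from its
#' boundary-flux series: solves the constraint-based problem at the resting
#' (first) and peak (last) time points, inverts the rate law at the packaged
#' resting concentrations for the resting activity set, scales each activity
#' by its peak/rest flux ratio for the exercise set, and constructs the
#' ATP-demand protocol. Demand and activities follow the same
#' monoexponential rest-to-exercise transition in normalized intensity
#' (%VO2max = 100 JO2/max JO2), so the supply side tracks the imposed load;
#' this is the transition the long-duration simulations require.
#'
#' @param net a `metabolic_network`.
#' @param boundary a [boundary_series()] for the genotype.
#' @param conc0 resting concentrations (default the packaged vector).
#' @param Tc transition constant (per %VO2max); 0.15 for the
#'   high-capacity-runner parameterization, 0.1 for low-capacity.
#' @param emergent_ratio exercise/rest activity ratio assigned to reactions
#'   that carry flux at peak but not at rest.
#' @param basal_gain gain of the supra-basal ATP-turnover term (see
#'   [demand_constant()]'s `basal`): demand is multiplied by
#'   `1 + gain * (atp/atp_ref - 1)` when ATP rises above its resting
#'   reference, dissipating transient supply surpluses.
#' @param capacity_margin safety factor on the exercise activity set:
#'   enzyme capacity over-tracks the imposed demand by this factor, so the
#'   parameterization tolerates moderate sustained loads and perturbations
#'   (the genotype contrasts cut far deeper than the margin).
#' @param ... passed to [solve_timepoint()].
#' @return a `fuel_parameterization`: list with `X_rest`, `X_exercise`,
#'   `tspec` ([transition_spec()]), `protocol` (demand), `rest`, `peak`
#'   (flux solutions), `vo2_rest`, `boundary`.
#' @export
derive_parameterization <- function(net, boundary, conc0 = resting_concentrations(net),
                                    Tc = 0.15, emergent_ratio = 3,
                                    capacity_margin = 1.0, basal_gain = 10, ...) {
  stopifnot(inherits(net, "metabolic_network"), nrow(boundary) >= 2)
  rest <- solve_timepoint(net, boundary[1, ], ...)
  peak <- solve_timepoint(net, boundary[nrow(boundary), ], ...)
  if (!startsWith(rest$status, "optimal") || !startsWith(peak$status, "optimal"))
    stop("constraint-based solve failed at rest or peak")
  X_rest <- initial_activities(net, conc0, rest$J)
  ratio <- rep(1, length(X_rest))
  names(ratio) <- names(X_rest)
  nz <- abs(rest$J[names(X_rest)]) > 1e-12
  ratio[nz] <- peak$J[names(X_rest)][nz] / rest$J[names(X_rest)][nz]
  ratio[!nz & abs(peak$J[names(X_rest)]) > 1e-12] <- emergent_ratio
  ratio <- pmax(ratio, 0)   # activities may down-regulate toward exercise
  X_ex <- X_rest * ratio * capacity_margin

  jo2max <- max(boundary$JO2)
  vo2_rest <- 100 * boundary$JO2[1] / jo2max
  tmax <- max(boundary$time)
  jo2_fun <- stats::approxfun(boundary$time, boundary$JO2, rule = 2)
  vo2 <- function(t) 100 * jo2_fun(pmin(pmax(t, 0), tmax)) / jo2max
  dem0 <- rest$J[["ATPASE"]]
  rA <- peak$J[["ATPASE"]] / dem0
  w <- function(t) exp(-pmax(vo2(t) - vo2_rest, 0) * Tc)
  demf <- function(t) dem0 * (rA + (1 - rA) * w(t))
  basal <- list(atp_ref = unname(conc0[["atp"]]), gain = basal_gain,
                rate = dem0)
  structure(list(
    X_rest = X_rest, X_exercise = X_ex,
    tspec = transition_spec(X_rest, X_ex, Tc = Tc, vo2_rest = vo2_rest),
    protocol = demand_interpolated(demf, vo2 = vo2, basal = basal),
    basal = basal,
    rest = rest, peak = peak, vo2_rest = vo2_rest, Tc = Tc,
    boundary = boundary, conc0 = conc0
  ), class = "fuel_parameterization")
}

#' Apply a genotype transform to a parameterization
#'
#' Scales mitochondrial-housed activities by `mito_fraction` and divides the
#' fatty-acid activation/transport activities by `fa_transport_factor`; on
#' the transport reactions the two compound (fraction 0.5 with factor 5
#' gives a 10-fold reduction). Optional per-reaction extra factors (e.g.
#' individual acyl-CoA dehydrogenases) are applied last. Both the resting
#' and exercise activity sets are transformed; the demand protocol can be
#' replaced (a genotype is driven by its own protocol).
#'
#' @param par a `fuel_parameterization`.
#' @param mito_fraction multiplier on mitochondrial-tagged activities.
#' @param fa_transport_factor divisor on fatty-acid transport activities.
#' @param extra named numeric vector of additional per-reaction divisors.
#' @param net the network (for the reaction sets).
#' @param protocol optional replacement demand protocol.
#' @param tspec_vo2_rest,Tc optional overrides for the transition.
#' @return transformed `fuel_parameterization`.
#' @export
apply_genotype <- function(par, net, mito_fraction = 0.5, fa_transport_factor = 5,
                           extra = NULL, protocol = NULL, Tc = NULL,
                           tspec_vo2_rest = NULL) {
  stopifnot(inherits(par, "fuel_parameterization"))
  tf <- function(X) {
    m <- intersect(names(X), mito_reactions(net))
    f <- intersect(names(X), fa_transport_reactions(net))
    X[m] <- X[m] * mito_fraction
    X[f] <- X[f] / fa_transport_factor
    if (!is.null(extra)) {
      e <- intersect(names(X), names(extra))
      X[e] <- X[e] / extra[e]
    }
    X
  }
  out <- par
  out$X_rest <- tf(par$X_rest)
  out$X_exercise <- tf(par$X_exercise)
  out$Tc <- if (is.null(Tc)) par$Tc else Tc
  vr <- if (is.null(tspec_vo2_rest)) par$vo2_rest else tspec_vo2_rest
  out$vo2_rest <- vr
  out$tspec <- transition_spec(out$X_rest, out$X_exercise, Tc = out$Tc,
                               vo2_rest = vr)
  if (!is.null(protocol)) out$protocol <- protocol
  out$transform <- list(mito_fraction = mito_fraction,
                        fa_transport_factor = fa_transport_factor,
                        extra = extra)
  out
}

#' Simulate a parameterized exercise protocol
#'
#' Convenience wrapper: integrates the kinetic model under a
#' `fuel_parameterization`'s transition spec and demand protocol.
#'
#' @param net a `metabolic_network`.
#' @param par a `fuel_parameterization`.
#' @param t_span time span (default the boundary series range plus 5 min).
#' @param conc0 initial concentrations (default the parameterization's).
#' @param ... passed to [simulate_kinetics()].
#' @return a `kinetic_trajectory`.
#' @export
simulate_protocol <- function(net, par, t_span = NULL, conc0 = NULL, ...) {
  stopifnot(inherits(par, "fuel_parameterization"))
  if (is.null(t_span)) t_span <- c(0, max(par$boundary$time) + 5)
  if (is.null(conc0)) conc0 <- par$conc0
  simulate_kinetics(net, conc0, par$tspec, par$protocol, t_span, ...)
}

#' Demand as a function of normalized intensity
#'
#' Returns the function mapping %VO2max to the ATPase demand rate implied
#' by a parameterization: the same monoexponential rest-to-exercise
#' interpolation that the activities follow, anchored at the resting and
#' peak constraint-based ATPase rates.
#'
#' @param par a `fuel_parameterization`.
#' @return function of %VO2max.
#' @export
normalized_demand <- function(par) {
  stopifnot(inherits(par, "fuel_parameterization"))
  dem0 <- par$rest$J[["ATPASE"]]
  rA <- par$peak$J[["ATPASE"]] / dem0
  function(v) dem0 * (rA + (1 - rA) * exp(-pmax(v - par$vo2_rest, 0) * par$Tc))
}

#' @export
print.fuel_parameterization <- function(x, ...) {
  cat("<fuel_parameterization> ", length(x$X_rest), " adjustable activities\n",
      "  resting ATPase demand: ", signif(x$rest$J[["ATPASE"]], 4),
      "  peak: ", signif(x$peak$J[["ATPASE"]], 4), " mol/min/kg\n",
      "  Tc: ", x$Tc, " per %VO2max; rest intensity ",
      signif(x$vo2_rest, 3), " %VO2max\n", sep = "")
  if (!is.null(x$transform))
    cat("  genotype transform: mito x", x$transform$mito_fraction,
        ", FA transport /", x$transform$fa_transport_factor, "\n", sep = "")
  invisible(x)
}
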