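#' Boundary flux time series
#'
#' Container for measured whole-body transport fluxes during a graded
#' exercise protocol: oxygen uptake, carbon dioxide output, carbohydrate
#' (glucose) uptake and fatty-acid (palmitate) uptake, all in
#' mol min^-1 kg^-1 body mass.
#'
#' @param times minutes, strictly increasing.
#' @param JO2,JCO2,carb,fa non-negative flux series of the same length.
#' @param variance optional list of per-series variances (same names).
#' @return a `boundary_series` data.frame.
#' @export
boundary_series <- function(times, JO2, JCO2, carb, fa, variance = NULL) {
  n <- length(times)
  stopifnot(length(JO2) == n, length(JCO2) == n, length(carb) == n,
            length(fa) == n)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(c(JO2, JCO2, carb, fa) < 0)) stop("boundary fluxes must be >= 0")
  out <- data.frame(time = times, JO2 = JO2, JCO2 = JCO2, carb = carb, fa = fa)
  if (!is.null(variance)) for (nm in names(variance))
    out[[paste0("var_", nm)]] <- variance[[nm]]
  class(out) <- c("boundary_series", "data.frame")
  out
}

# Stoichiometric reconciliation of one measured boundary row.
# Complete oxidation bookkeeping: glucose 6 O2 -> 6 CO2, palmitate
# 23 O2 -> 16 CO2. Finds fuel rates (u, v) >= 0 minimizing the
# variance-weighted squared adjustment of all four series; at noise zero the
# projection is the identity.
.reconcile_boundary <- function(JO2, JCO2, carb, fa, rel_sd = 0.03) {
  sig <- pmax(rel_sd * c(JO2, JCO2, carb, fa), 1e-12)
  w <- 1 / sig^2
  # quadratic in (u, v): rows of the design are the four predictions
  A <- rbind(c(6, 23), c(6, 16), c(1, 0), c(0, 1))
  y <- c(JO2, JCO2, carb, fa)
  M <- crossprod(A, A * w)
  rhs <- crossprod(A, y * w)
  uv <- drop(solve(M, rhs))
  if (uv[1] < 0) { uv[1] <- 0; uv[2] <- max(0, sum(A[, 2] * y * w) / sum(A[, 2]^2 * w)) }
  if (uv[2] < 0) { uv[2] <- 0; uv[1] <- max(0, sum(A[, 1] * y * w) / sum(A[, 1]^2 * w)) }
  c(carb = uv[1], fa = uv[2],
    JO2 = 6 * uv[1] + 23 * uv[2], JCO2 = 6 * uv[1] + 16 * uv[2])
}

.flux_bounds <- function(net, M = 10) {
  rev <- vapply(net$reactions, `[[`, TRUE, "reversible")
  lb <- ifelse(rev, -M, 0)
  ub <- rep(M, length(rev))
  names(lb) <- names(ub) <- net$reaction_ids
  list(lb = lb, ub = ub)
}

#' Solve the steady-state flux problem at one protocol time point
#'
#' Solves `S J = 0` for all internal fluxes with the six exchange columns
#' fixed to (reconciled) boundary data, maximizing mitochondrial ATP
#' production (flux through ATP synthase) subject to flux-direction bounds,
#' with an L1-parsimonious tie-break at the optimum that suppresses any
#' internal thermodynamically infeasible cycle flux.
#'
#' @param net a `metabolic_network`.
#' @param boundary a single row of a [boundary_series()] (or a list with
#'   elements `JO2`, `JCO2`, `carb`, `fa`, optionally `time`).
#' @param lactate one of `"free"` (exchange left free and non-negative, the
#'   default: plasma lactate is a fitted observation, not a constraint) or a
#'   numeric value fixing the lactate output flux.
#' @param reconcile project the four measured fluxes onto the
#'   glucose/palmitate oxidation stoichiometry before the solve (identity on
#'   noise-free data).
#' @param objective reaction id whose flux is maximized (`"ATPS"`).
#' @param parsimony apply the L1 tie-break at the optimum.
#' @param M box bound on unconstrained fluxes (mol min^-1 kg^-1).
#' @return a `flux_solution` with elements `J` (named flux vector),
#'   `objective_value`, `status`, `boundary` (values used), `time`.
#' @export
solve_timepoint <- function(net, boundary, lactate = "free",
                            reconcile = TRUE, objective = "ATPS",
                            parsimony = TRUE, M = 10) {
  stopifnot(inherits(net, "metabolic_network"))
  b <- as.list(boundary)
  vals <- c(JO2 = b$JO2, JCO2 = b$JCO2, carb = b$carb, fa = b$fa)
  if (any(!is.finite(vals))) stop("boundary fluxes must be finite")
  used <- if (reconcile)
    .reconcile_boundary(vals["JO2"], vals["JCO2"], vals["carb"], vals["fa"])
  else vals[c("carb", "fa", "JO2", "JCO2")][c(1, 2, 3, 4)]

  if (!reconcile) {
    carbon_in <- 6 * vals[["carb"]] + 16 * vals[["fa"]]
    if (vals[["JCO2"]] > carbon_in + 1e-12)
      stop(structure(class = c("fuelswitch_infeasible", "error", "condition"),
                     list(message = "CO2 output exceeds carbon input", call = NULL)))
    used <- c(carb = vals[["carb"]], fa = vals[["fa"]],
              JO2 = vals[["JO2"]], JCO2 = vals[["JCO2"]])
  }

  bounds <- .flux_bounds(net, M)
  lb <- bounds$lb; ub <- bounds$ub
  fixed <- c(EX_GLC = unname(used["carb"]), EX_FA = unname(used["fa"]),
             EX_O2 = unname(used["JO2"]), EX_CO2 = unname(used["JCO2"]))
  if (is.numeric(lactate)) fixed <- c(fixed, EX_LAC = unname(lactate))
  else { lb["EX_LAC"] <- 0; ub["EX_LAC"] <- M }
  lb["EX_H2O"] <- -M; ub["EX_H2O"] <- M

  n <- length(net$reaction_ids)
  Efix <- matrix(0, length(fixed), n,
                 dimnames = list(names(fixed), net$reaction_ids))
  for (nm in names(fixed)) Efix[nm, nm] <- 1
  Aeq <- rbind(net$S, Efix)
  beq <- c(rep(0, nrow(net$S)), unname(fixed))

  cvec <- as.numeric(net$reaction_ids == objective)
  sol <- .lp_flux(cvec, Aeq, beq, lb, ub, maximize = TRUE)
  if (sol$status == "infeasible" || sol$status == "solver_failed")
    return(structure(list(J = setNames(sol$J, net$reaction_ids),
                          objective_value = NA_real_, status = sol$status,
                          boundary = used, time = b$time),
                     class = "flux_solution"))
  if (parsimony && sol$status == "optimal")
    sol <- .lp_parsimony(sol, cvec, Aeq, beq, lb, ub, obj_value = sol$objective)
  J <- setNames(sol$J, net$reaction_ids)
  resid <- max(abs(net$S %*% J))
  structure(list(J = J, objective_value = sol$objective,
                 status = if (resid <= 1e-9 * max(1e-12, max(abs(J)))) sol$status
                          else "balance_violated",
                 mass_balance_residual = resid,
                 boundary = used, time = b$time),
            class = "flux_solution")
}

#' Solve a whole boundary-flux series
#'
#' Applies [solve_timepoint()] to each row; per-point failures are recorded
#' in `status` and skipped downstream rather than aborting the series.
#'
#' @param net a `metabolic_network`.
#' @param boundary a [boundary_series()].
#' @param ... passed to [solve_timepoint()].
#' @return a `flux_series`: list with `times`, `J` (time x reaction matrix),
#'   `objective_values`, `status` (per point).
#' @export
solve_series <- function(net, boundary, ...) {
  sols <- lapply(seq_len(nrow(boundary)), function(i)
    tryCatch(solve_timepoint(net, boundary[i, ], ...),
             fuelswitch_infeasible = function(e)
               structure(list(J = rep(NA_real_, length(net$reaction_ids)),
                              objective_value = NA_real_,
                              status = "infeasible",
                              boundary = NULL, time = boundary$time[i]),
                         class = "flux_solution")))
  Jmat <- do.call(rbind, lapply(sols, function(s) s$J))
  rownames(Jmat) <- boundary$time
  colnames(Jmat) <- net$reaction_ids
  structure(list(times = boundary$time, J = Jmat,
                 objective_values = vapply(sols, `[[`, 0, "objective_value"),
                 status = vapply(sols, `[[`, "", "status"),
                 solutions = sols),
            class = "flux_series")
}

#' Min/max flux envelope at one time point
#'
#' Deterministic mode (`"fva"`, default): flux variability analysis — each
#' reaction's flux is minimized and maximized subject to the objective held
#' at its optimum; this dominates any finite multi-start scheme. Stochastic
#' mode (`"multistart"`): `n_starts` re-solves with randomly weighted
#' parsimonious tie-breaks, emulating optimizer restarts from initial flux
#' vectors spanning the requested magnitude range; the envelope is the
#' componentwise min/max of the returned optima.
#'
#' @param net a `metabolic_network`.
#' @param boundary single boundary row (as in [solve_timepoint()]).
#' @param n_starts number of stochastic restarts (multistart mode).
#' @param flux_magnitude_range magnitude span for restart weights.
#' @param seed RNG seed (multistart mode).
#' @param mode `"fva"` or `"multistart"`.
#' @param ... passed to [solve_timepoint()].
#' @return list with `envelope_min`, `envelope_max` (named per reaction) and
#'   the central `solution`.
#' @export
flux_envelope <- function(net, boundary, n_starts = 100,
                          flux_magnitude_range = c(1e-9, 1e9), seed = 1L,
                          mode = c("fva", "multistart"), ...) {
  mode <- match.arg(mode)
  if (mode == "multistart" && n_starts < 2) stop("n_starts must be >= 2")
  centre <- solve_timepoint(net, boundary, ...)
  if (!startsWith(centre$status, "optimal"))
    stop("no optimal central solution (status ", centre$status, ")")
  obj <- centre$objective_value
  bounds <- .flux_bounds(net)
  lb <- bounds$lb; ub <- bounds$ub
  used <- centre$boundary
  fixed <- c(EX_GLC = unname(used["carb"]), EX_FA = unname(used["fa"]),
             EX_O2 = unname(used["JO2"]), EX_CO2 = unname(used["JCO2"]))
  lb["EX_LAC"] <- 0; lb["EX_H2O"] <- -10; ub["EX_H2O"] <- 10
  n <- length(net$reaction_ids)
  Efix <- matrix(0, length(fixed), n, dimnames = list(names(fixed), net$reaction_ids))
  for (nm in names(fixed)) Efix[nm, nm] <- 1
  Aeq <- rbind(net$S, Efix, matrix(as.numeric(net$reaction_ids == "ATPS"), 1))
  beq <- c(rep(0, nrow(net$S)), unname(fixed), obj)

  if (mode == "fva") {
    nsp <- .null_space_problem(Aeq, beq)
    emin <- emax <- setNames(nsp$Jp, net$reaction_ids)
    if (nsp$d > 0) {
      sup <- which(rowSums(abs(nsp$N)) > 1e-9)
      for (k in sup) {
        cv <- as.numeric(seq_len(n) == k)
        lo <- .lp_flux(cv, Aeq, beq, lb, ub, maximize = FALSE)
        hi <- .lp_flux(cv, Aeq, beq, lb, ub, maximize = TRUE)
        if (startsWith(lo$status, "optimal")) emin[k] <- lo$J[k]
        if (startsWith(hi$status, "optimal")) emax[k] <- hi$J[k]
      }
    }
    # numerical guard: the centre lies inside the envelope by construction
    emin <- pmin(emin, centre$J); emax <- pmax(emax, centre$J)
    return(list(envelope_min = emin, envelope_max = emax, solution = centre,
                mode = mode))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  lmag <- log10(flux_magnitude_range)
  Js <- matrix(NA_real_, n_starts, n)
  cvec <- as.numeric(net$reaction_ids == "ATPS")
  for (i in seq_len(n_starts)) {
    w <- 10^stats::runif(n, lmag[1], lmag[2])
    w <- w / max(w)
    base <- .lp_flux(cvec, Aeq, beq, lb, ub, maximize = TRUE)
    s <- .lp_parsimony(base, cvec, Aeq, beq, lb, ub, weights = w,
                       obj_value = obj)
    Js[i, ] <- s$J
  }
  list(envelope_min = setNames(apply(Js, 2, min), net$reaction_ids),
       envelope_max = setNames(apply(Js, 2, max), net$reaction_ids),
       solution = centre, mode = mode)
}

#' ATPase demand curve from a solved flux series
#'
#' Least-squares polynomial through the ATPase-reaction fluxes of a solved
#' series, clamped at zero; the returned interpolant drives the kinetic
#' model as the ATP-demand protocol.
#'
#' @param sol a `flux_series` from [solve_series()].
#' @param degree polynomial degree (default 3).
#' @return function mapping time (minutes) to ATPase rate
#'   (mol min^-1 kg^-1), with attribute `coefficients`.
#' @export
atpase_demand_curve <- function(sol, degree = 3) {
  ok <- startsWith(sol$status, "optimal")
  t <- sol$times[ok]; y <- sol$J[ok, "ATPASE"]
  if (length(t) < 3) stop("need at least 3 solved time points")
  if (degree >= length(t)) stop("polynomial degree must be < number of points")
  fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE))
  cf <- stats::coef(fit)
  f <- function(time) {
    X <- outer(time, 0:degree, `^`)
    pmax(drop(X %*% cf), 0)
  }
  attr(f, "coefficients") <- cf
  attr(f, "residuals") <- stats::resid(fit)
  f
}

#' Scan a flux vector for internal thermodynamically infeasible cycles
#'
#' Builds a null-space basis of the internal (non-exchange) submatrix of S
#' and flags any basis cycle whose support fluxes are sign-consistent with
#' the cycle — net flux around such a loop violates the loop law.
#'
#' @param net a `metabolic_network`.
#' @param J named flux vector.
#' @param tol fluxes below `tol` are treated as zero.
#' @return character vector of offending basis-cycle descriptions
#'   (empty when loopless).
#' @export
detect_loops <- function(net, J, tol = 1e-9) {
  internal <- !vapply(net$reactions, `[[`, TRUE, "boundary")
  Si <- net$S[, internal, drop = FALSE]
  ns <- pracma::nullspace(Si)
  if (is.null(ns) || !length(ns)) return(character(0))
  Jint <- J[internal]
  bad <- character(0)
  for (j in seq_len(ncol(ns))) {
    v <- ns[, j]
    sup <- which(abs(v) > 1e-9)
    if (!length(sup)) next
    active <- sup[abs(Jint[sup]) > tol]
    if (length(active) < length(sup)) next  # cycle not fully carrying flux
    sgn <- sign(v[active]) * sign(Jint[active])
    if (all(sgn > 0) || all(sgn < 0))
      bad <- c(bad, paste(colnames(Si)[sup], collapse = "+"))
  }
  bad
}

#' Respiratory quotient of a flux solution
#' @param sol a `flux_solution`.
#' @return JCO2 / JO2 from the exchange fluxes.
#' @export
solution_rq <- function(sol) unname(sol$J["EX_CO2"] / sol$J["EX_O2"])

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective (ATP synthase):", signif(x$objective_value, 4), "\n")
  cat("  RQ:", signif(solution_rq(x), 4), "\n")
  invisible(x)
}
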