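# Kinetic model: compartmentalized ODE system dC/dt = P^-1 S J(C) with the
# generalized thermodynamic rate law
#   J_k = X_k Ct_k (1 - exp(dG'/RT)) / (1 + exp((dG' - dG'0)/RT)),
#   Ct_k = prod substrates (C/1M)^mu + prod products (C/1M)^nu.
# The ATPase reaction is not given a rate law: its flux is the imposed
# ATP-demand protocol, attenuated by the same thermodynamic factor so the
# model "fails to meet demand" smoothly (and never violates the second law)
# when ATP potential collapses.

.kinetic_cache <- function(net, ctx = thermo_context()) {
  S <- net$S
  Msub <- pmax(-S, 0)
  Mprod <- pmax(S, 0)
  frac <- setNames(net$compartments$volume_fraction, net$compartments$id)
  vol <- net$water_volume_l_per_kg * frac[net$species$compartment] *
    net$species$volume_scale
  list(S = S, St = t(S), MsubT = t(Msub), MprodT = t(Mprod),
       Msub = Msub, Mprod = Mprod,
       dg0 = vapply(net$reactions, `[[`, 0, "dg0"),
       pinv = 1 / vol,
       RT = ctx$RT,
       i_atpase = match("ATPASE", net$reaction_ids),
       rid = net$reaction_ids, sid = net$species$id)
}

.clip_exp <- function(x) exp(pmin(x, 600))

# core rate-law evaluation on a (floored) concentration vector
.fluxes_core <- function(lnc, X, cache) {
  dg <- cache$dg0 + cache$RT * drop(cache$St %*% lnc)
  a <- dg / cache$RT
  b <- a - cache$dg0 / cache$RT
  Psub <- .clip_exp(drop(cache$MsubT %*% lnc))
  Pprod <- .clip_exp(drop(cache$MprodT %*% lnc))
  Ct <- Psub + Pprod
  F <- (1 - .clip_exp(a)) / (1 + .clip_exp(b))
  list(J = X * Ct * F, dg = dg, a = a, b = b, F = F, Ct = Ct,
       Psub = Psub, Pprod = Pprod)
}

#' Thermodynamic reaction fluxes
#'
#' Evaluates the generalized rate law for every reaction at the given
#' concentrations and enzyme activities. The flux always opposes the
#' transformed free energy (`sign(J) = -sign(dG')`), so every trajectory of
#' the kinetic model satisfies the second law pointwise.
#'
#' @param net a `metabolic_network`.
#' @param conc named molar concentration vector.
#' @param X named activity vector (reactions; missing entries treated as 0).
#' @param ctx a [thermo_context()].
#' @param floor concentrations are floored at this value for evaluation.
#' @return named flux vector (mol min^-1 kg^-1).
#' @export
reaction_flux <- function(net, conc, X, ctx = thermo_context(), floor = 1e-12) {
  cache <- .kinetic_cache(net, ctx)
  Xv <- setNames(numeric(length(cache$rid)), cache$rid)
  Xv[names(X)] <- X
  lnc <- log(pmax(conc[cache$sid], floor))
  setNames(.fluxes_core(lnc, Xv, cache)$J, cache$rid)
}

#' ODE right-hand side of the kinetic model
#'
#' `dC/dt = P^-1 S J(C)` with the ATPase flux overridden by the demanded
#' rate (attenuated by its own thermodynamic driving factor). The partition
#' matrix P converts whole-body molar fluxes into compartment concentration
#' changes using 0.755 L water per kg tissue and the compartment volume
#' fractions.
#'
#' @param net a `metabolic_network`.
#' @param conc named concentration vector.
#' @param X named activity vector.
#' @param demand ATPase demand rate (mol min^-1 kg^-1, scalar).
#' @param ctx a [thermo_context()].
#' @return named dC/dt vector (molar min^-1).
#' @export
ode_rhs <- function(net, conc, X, demand = 0, ctx = thermo_context()) {
  cache <- .kinetic_cache(net, ctx)
  Xv <- setNames(numeric(length(cache$rid)), cache$rid)
  Xv[names(X)] <- X
  lnc <- log(pmax(conc[cache$sid], 1e-12))
  fl <- .fluxes_core(lnc, Xv, cache)
  J <- fl$J
  if (!is.na(cache$i_atpase))
    J[cache$i_atpase] <- demand *
      min(1, max(0, 1 - .clip_exp(fl$a[cache$i_atpase])))
  setNames(cache$pinv * drop(cache$S %*% J), cache$sid)
}

# analytic Jacobian d(dC/dt)/dC for the stiff integrator
.ode_jac_factory <- function(cache, Xv, demand_fun, floor = 1e-12) {
  n_r <- length(cache$rid)
  function(t, y, parms) {
    cc <- pmax(y, floor)
    lnc <- log(cc)
    fl <- .fluxes_core(lnc, Xv, cache)
    ea <- .clip_exp(fl$a); eb <- .clip_exp(fl$b)
    dFda <- (-ea * (1 + eb) - (1 - ea) * eb) / (1 + eb)^2
    XF <- Xv * fl$F
    # dJ/dC = diag(X F Psub) MsubT + diag(X F Pprod) MprodT
    #       + diag(X Ct dFda) St, all column-scaled by 1/C
    dJdC <- XF * fl$Psub * cache$MsubT +
            XF * fl$Pprod * cache$MprodT +
            (Xv * fl$Ct * dFda) * cache$St
    # ATPase row: demand * d/dC clamp(1 - e^a)
    ia <- cache$i_atpase
    g <- 1 - ea[ia]
    dJdC[ia, ] <- if (g > 0 && g < 1)
      -demand_fun(t) * ea[ia] * cache$St[ia, ] else 0
    # clamped species contribute no derivative (rate law sees the floor)
    icl <- 1 / cc
    icl[y < floor] <- 0
    (cache$pinv * cache$S) %*% (dJdC * rep(icl, each = n_r))
  }
}

#' ATP-demand protocols
#'
#' Constructors for the demand protocols that drive the kinetic model:
#' a constant rate, a linear ramp, an interpolated curve (typically from
#' [atpase_demand_curve()]), or stepped normalized intensities.
#'
#' @param level,start,slope rates in mol min^-1 kg^-1 (slope per minute).
#' @param fun function of time returning the demand rate.
#' @param vo2 optional function of time returning normalized exercise
#'   intensity (%VO2max), used when simulating with a [transition_spec()].
#' @param basal optional list `(atp_ref, gain, rate)`: supra-basal ATP
#'   turnover. The demanded ATPase flux `d` becomes
#'   `d + (d + rate) * gain * max(atp/atp_ref - 1, 0)`. It vanishes at or below the reference ATP level (the
#'   resting fixed point is untouched) and dissipates transient
#'   overcapacity of the supply side, as non-contractile ATP turnover does.
#' @return a `demand_protocol` (list with `fun`, `vo2`, `mode`).
#' @export
demand_constant <- function(level, vo2 = NULL, basal = NULL) {
  stopifnot(level >= 0)
  structure(list(fun = function(t) rep(level, length(t)), vo2 = vo2,
                 basal = basal, mode = "constant"), class = "demand_protocol")
}

#' @rdname demand_constant
#' @export
demand_ramp <- function(start, slope, vo2 = NULL, basal = NULL) {
  structure(list(fun = function(t) pmax(start + slope * t, 0), vo2 = vo2,
                 basal = basal, mode = "linear_ramp"), class = "demand_protocol")
}

#' @rdname demand_constant
#' @export
demand_interpolated <- function(fun, vo2 = NULL, basal = NULL) {
  structure(list(fun = function(t) pmax(fun(t), 0), vo2 = vo2,
                 basal = basal, mode = "interpolated_curve"),
            class = "demand_protocol")
}

#' Activity transition between rest and exercise parameter sets
#'
#' Monoexponential interpolation of enzyme activities as a function of
#' normalized exercise intensity:
#' `X(v) = X_exercise + (X_rest - X_exercise) exp(-(v - v_rest) Tc)`.
#' At `v = v_rest` the rest activities are returned exactly; the transition
#' constant Tc (per %VO2max) is multiplicative, so large Tc switches
#' essentially instantly to the exercise set.
#'
#' @param X_rest,X_exercise named activity vectors over the same reactions.
#' @param Tc transition constant (> 0), per %VO2max.
#' @param vo2_rest resting intensity (%VO2max).
#' @return a `transition_spec`.
#' @export
transition_spec <- function(X_rest, X_exercise, Tc, vo2_rest = 10) {
  stopifnot(Tc > 0, setequal(names(X_rest), names(X_exercise)))
  structure(list(X_rest = X_rest, X_exercise = X_exercise[names(X_rest)],
                 Tc = Tc, vo2_rest = vo2_rest), class = "transition_spec")
}

#' @rdname transition_spec
#' @param spec a `transition_spec`.
#' @param vo2 intensity (%VO2max), `>= vo2_rest`.
#' @return `transition_activities()`: the interpolated activity vector.
#' @export
transition_activities <- function(spec, vo2) {
  stopifnot(inherits(spec, "transition_spec"), vo2 >= spec$vo2_rest)
  w <- exp(-(vo2 - spec$vo2_rest) * spec$Tc)
  spec$X_exercise + (spec$X_rest - spec$X_exercise) * w
}

#' Simulate the kinetic model under an ATP-demand protocol
#'
#' Integrates the 98-state stiff ODE system with `deSolve::lsoda` and an
#' analytic Jacobian. If the thermodynamic attenuation of the ATPase flux
#' makes the realized rate fall below the demanded rate, the failure ("the
#' model is unable to meet the ATP demand") is recorded as an outcome
#' (`crashed`, `crash_time`), not raised as an error.
#'
#' @param net a `metabolic_network`.
#' @param conc0 named initial concentration vector (typically
#'   [resting_concentrations()] or a [sample_feasible_concentrations()]
#'   draw).
#' @param X named activity vector, or a [transition_spec()] (requires
#'   `protocol$vo2`).
#' @param protocol a `demand_protocol`.
#' @param t_span `c(t0, t1)` minutes.
#' @param dt output resolution (minutes).
#' @param atol,rtol integrator tolerances on the log-concentration states;
#'   an absolute tolerance on log C is a relative tolerance on C, so the
#'   defaults correspond to the canonical 1e-12/1e-10 linear-space setting
#'   at unit concentration scale.
#' @param ctx a [thermo_context()].
#' @param crash_ratio realized/demanded ATPase ratio below which the state
#'   is flagged as failing to meet demand.
#' @return a `kinetic_trajectory`: list with `times`, `conc` (time x
#'   species), `fluxes` (time x reaction, ATPase = realized), `demand`,
#'   `realized`, `crashed`, `crash_time`, and `observables` (see
#'   [trajectory_observables()]).
#' @export
simulate_kinetics <- function(net, conc0, X, protocol, t_span, dt = 0.5,
                              atol = 1e-10, rtol = 1e-8,
                              ctx = thermo_context(), crash_ratio = 0.95,
                              maxsteps = 200000) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(protocol, "demand_protocol"))
  cache <- .kinetic_cache(net, ctx)
  transition <- inherits(X, "transition_spec")
  if (transition && is.null(protocol$vo2))
    stop("a transition_spec requires a protocol with a vo2(t) mapping")
  Xv <- setNames(numeric(length(cache$rid)), cache$rid)
  act_at <- function(t) {
    if (!transition) { Xv[names(X)] <- X; return(Xv) }
    xa <- transition_activities(X, max(protocol$vo2(t), X$vo2_rest))
    Xv[names(xa)] <- xa
    Xv
  }
  dfun <- protocol$fun
  basal <- protocol$basal
  i_atp <- match("atp", cache$sid)
  demand_tot <- function(t, atp) {
    d <- dfun(t)
    if (!is.null(basal)) {
      rel <- max(atp / basal$atp_ref - 1, 0)
      floor_rate <- if (is.null(basal$rate)) 0 else basal$rate
      d <- d + (d + floor_rate) * basal$gain * rel
    }
    d
  }
  # states are integrated in log space: positivity is guaranteed and the
  # wide dynamic range of metabolite pools is well conditioned
  has_atpase <- !is.na(cache$i_atpase)
  rhs_log <- function(t, y, parms) {
    y <- pmin(pmax(y, -60), 25)
    cc <- exp(y)
    Xt <- act_at(t)
    fl <- .fluxes_core(y, Xt, cache)
    J <- fl$J
    if (has_atpase)
      J[cache$i_atpase] <- demand_tot(t, cc[i_atp]) *
        min(1, max(0, 1 - .clip_exp(fl$a[cache$i_atpase])))
    list(cache$pinv * drop(cache$S %*% J) / cc)
  }
  jac_log <- function(t, y, parms) {
    y <- pmin(pmax(y, -60), 25)
    cc <- exp(y)
    Xt <- act_at(t)
    fl <- .fluxes_core(y, Xt, cache)
    ea <- .clip_exp(fl$a); eb <- .clip_exp(fl$b)
    dFda <- (-ea * (1 + eb) - (1 - ea) * eb) / (1 + eb)^2
    XF <- Xt * fl$F
    dJdlnC <- XF * fl$Psub * cache$MsubT +
              XF * fl$Pprod * cache$MprodT +
              (Xt * fl$Ct * dFda) * cache$St
    J <- fl$J
    if (has_atpase) {
      ia <- cache$i_atpase
      g <- 1 - ea[ia]
      dem <- demand_tot(t, cc[i_atp])
      J_atp_grad <- if (g > 0 && g < 1) -dem * ea[ia] * cache$St[ia, ] else
        rep(0, length(y))
      if (!is.null(basal) && cc[i_atp] > basal$atp_ref) {
        floor_rate <- if (is.null(basal$rate)) 0 else basal$rate
        J_atp_grad[i_atp] <- J_atp_grad[i_atp] +
          min(1, max(0, g)) * (dfun(t) + floor_rate) * basal$gain *
            cc[i_atp] / basal$atp_ref
      }
      dJdlnC[ia, ] <- J_atp_grad
      J[ia] <- dem * min(1, max(0, g))
    }
    f <- cache$pinv * drop(cache$S %*% J) / cc
    ((cache$pinv / cc) * cache$S) %*% dJdlnC - diag(f)
  }
  times <- seq(t_span[1], t_span[2], by = dt)
  y0 <- conc0[cache$sid]
  if (anyNA(y0)) stop("conc0 does not cover all species")
  if (any(y0 <= 0)) stop("initial concentrations must be strictly positive")
  out <- try(deSolve::lsoda(log(y0), times, rhs_log, parms = NULL,
                            jacfunc = jac_log, jactype = "fullusr",
                            atol = atol, rtol = rtol, maxsteps = maxsteps),
             silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integration failed: ", attr(out, "condition")$message)
  tt <- out[, 1]
  conc <- exp(out[, -1, drop = FALSE])
  if (anyNA(conc)) {
    last_ok <- max(which(stats::complete.cases(conc)))
    conc <- conc[seq_len(last_ok), , drop = FALSE]
    tt <- tt[seq_len(last_ok)]
  }
  # post-hoc fluxes and demand bookkeeping at output times
  nr <- length(cache$rid)
  fluxes <- matrix(NA_real_, length(tt), nr, dimnames = list(NULL, cache$rid))
  realized <- demanded <- numeric(length(tt))
  for (i in seq_along(tt)) {
    lnc <- log(pmax(conc[i, ], 1e-12))
    fl <- .fluxes_core(lnc, act_at(tt[i]), cache)
    J <- fl$J
    demanded[i] <- dfun(tt[i])
    g <- if (has_atpase)
      min(1, max(0, 1 - .clip_exp(fl$a[cache$i_atpase]))) else 1
    if (has_atpase) J[cache$i_atpase] <- demand_tot(tt[i], conc[i, i_atp]) * g
    realized[i] <- demanded[i] * g
    fluxes[i, ] <- J
  }
  ratio <- ifelse(demanded > 1e-12, realized / demanded, 1)
  crashed <- any(ratio < crash_ratio)
  traj <- structure(list(
    times = tt, conc = conc, fluxes = fluxes,
    demand = demanded, realized = realized,
    crashed = crashed,
    crash_time = if (crashed) tt[which(ratio < crash_ratio)[1]] else NA_real_,
    complete = abs(tt[length(tt)] - t_span[2]) < dt / 2,
    net_name = net$name), class = "kinetic_trajectory")
  traj$observables <- trajectory_observables(net, traj, ctx)
  traj
}

#' Derived observables along a kinetic trajectory
#'
#' Boundary gas fluxes, respiratory quotient, plasma lactate, redox ratios,
#' the proton-motive pseudo-species, acetyl-CoA/CoA, the transformed free
#' energy of cytosolic ATP hydrolysis, and the six measured total
#' (tissue-water volume-weighted) carnitine pools.
#'
#' @param net a `metabolic_network`.
#' @param traj a `kinetic_trajectory`.
#' @param ctx a [thermo_context()].
#' @return data.frame, one row per output time.
#' @export
trajectory_observables <- function(net, traj, ctx = thermo_context()) {
  conc <- traj$conc; fx <- traj$fluxes
  needed <- c("adp", "pi", "atp", "lac_e", "nad", "nadh", "nad_m", "nadh_m",
              "dpsi_m", "accoa_m", "coa_m")
  if (!all(needed %in% colnames(conc)) ||
      !all(c("EX_O2", "EX_CO2") %in% colnames(fx)))
    return(data.frame(time = traj$times, demand = traj$demand,
                      realized = traj$realized))
  frac <- setNames(net$compartments$volume_fraction, net$compartments$id)
  tot <- function(cyt, mito) {
    v <- numeric(nrow(conc))
    if (!is.null(cyt)) v <- v + conc[, cyt] * frac["cytosol"]
    if (!is.null(mito)) v <- v + conc[, mito] * frac["mitochondrion"]
    v
  }
  dg_atp <- vapply(seq_len(nrow(conc)), function(i) {
    -32 + ctx$RT * log(pmax(conc[i, "adp"], 1e-12) * pmax(conc[i, "pi"], 1e-12) /
                         pmax(conc[i, "atp"], 1e-12))
  }, 0)
  data.frame(
    time = traj$times,
    JO2 = fx[, "EX_O2"], JCO2 = fx[, "EX_CO2"],
    RQ = fx[, "EX_CO2"] / pmax(fx[, "EX_O2"], 1e-15),
    lactate = conc[, "lac_e"],
    atp = conc[, "atp"],
    dg_atp_hydrolysis = dg_atp,
    nad_ratio_cyt = conc[, "nad"] / pmax(conc[, "nadh"], 1e-15),
    nad_ratio_mito = conc[, "nad_m"] / pmax(conc[, "nadh_m"], 1e-15),
    dpsi = conc[, "dpsi_m"],
    accoa_coa_mito = conc[, "accoa_m"] / pmax(conc[, "coa_m"], 1e-15),
    carn_C16 = tot("c16crn", "c16crn_m"),
    carn_C14 = tot(NULL, "c14crn_m"),
    carn_C8 = tot(NULL, "c8crn_m"),
    carn_C4 = tot(NULL, "c4crn_m"),
    carn_acetyl = tot("accrn", "accrn_m"),
    carn_free = tot("carn", "carn_m"),
    demand = traj$demand, realized = traj$realized
  )
}

#' Initial enzyme activities from a resting flux solution
#'
#' Inverts the rate law at the resting state: `X_k = J_k / (Ct_k F_k)` for
#' every reaction carrying resting flux, so the resting concentrations and
#' fluxes form an exact fixed point of the ODE system before headroom is
#' applied. Reactions with zero resting flux (lactate branch, creatine
#' kinase, adenylate kinase, carnitine side pools) get capacity defaults
#' expressed as a reference flux over `Ct`. A uniform headroom factor then
#' scales all activities so the system withstands exercise-level ATPase
#' rates.
#'
#' @param net a `metabolic_network`.
#' @param conc0 resting concentrations.
#' @param J_rest named resting flux vector (from [solve_timepoint()]).
#' @param headroom uniform multiplier applied to all activities.
#' @param ref_buffer reference capacity (mol min^-1 kg^-1) for the creatine
#'   kinase / adenylate kinase phosphagen buffer (very fast in muscle).
#' @param ref_fast reference capacity for the lactate branch (LDH, lactate
#'   transport and export).
#' @param ref_side reference capacity for carnitine-ester side reactions.
#' @param ctx a [thermo_context()].
#' @return named activity vector over the 86 adjustable reactions (the
#'   driven ATPase is excluded).
#' @export
initial_activities <- function(net, conc0, J_rest, headroom = 1,
                               ref_buffer = 5e-2, ref_fast = 5e-3,
                               ref_side = 2e-4, ctx = thermo_context()) {
  cache <- .kinetic_cache(net, ctx)
  lnc <- log(pmax(conc0[cache$sid], 1e-12))
  fl <- .fluxes_core(lnc, rep(1, length(cache$rid)), cache)
  J <- setNames(numeric(length(cache$rid)), cache$rid)
  J[names(J_rest)] <- J_rest
  X <- setNames(numeric(length(cache$rid)), cache$rid)
  carrying <- abs(J) > 1e-12
  X[carrying] <- J[carrying] / (fl$Ct[carrying] * fl$F[carrying])
  if (any(X[carrying] < 0))
    stop("resting state thermodynamically inconsistent with resting fluxes: ",
         paste(cache$rid[carrying][X[carrying] < 0], collapse = ", "))
  buffer <- intersect(c("CK", "AK"), cache$rid[!carrying])
  fast <- intersect(c("LDH", "LACT", "EX_LAC"), cache$rid[!carrying])
  side <- intersect(c("CRAT", "ACT14", "ACT12", "ACT8", "ACT4", "ACRNT"),
                    cache$rid[!carrying])
  X[buffer] <- ref_buffer / fl$Ct[match(buffer, cache$rid)]
  X[fast] <- ref_fast / fl$Ct[match(fast, cache$rid)]
  X[side] <- ref_side / fl$Ct[match(side, cache$rid)]
  X <- X * headroom
  X[setdiff(cache$rid, "ATPASE")]
}

#' Poise zero-flux buffer pools at thermodynamic equilibrium
#'
#' The constraint-based resting solution leaves several reactions at zero
#' flux (the lactate branch, creatine kinase, the carnitine-ester side
#' pools). For the packaged resting state these reactions must sit exactly
#' at equilibrium, otherwise any appreciable buffer activity would inject
#' spurious fluxes at rest. This helper adjusts one species per reaction
#' (the paper's "slight adjustment" of the sampled vector): plasma and
#' cytosolic lactate to the export clamp, cytosolic NADH to lactate
#' dehydrogenase equilibrium, phosphocreatine to creatine kinase
#' equilibrium, and every carnitine ester to its transferase equilibrium.
#' Values are clipped into the species bounds.
#'
#' @param net a `metabolic_network`.
#' @param conc named concentration vector (e.g. a
#'   [sample_feasible_concentrations()] draw).
#' @param ctx a [thermo_context()].
#' @return adjusted concentration vector.
#' @export
poise_buffers <- function(net, conc, ctx = thermo_context()) {
  K <- function(rid) {
    r <- net$reactions[[match(rid, net$reaction_ids)]]
    exp(-r$dg0 / ctx$RT)
  }
  clip <- function(id, val) {
    i <- match(id, net$species$id)
    min(max(val, net$species$lb[i]), net$species$ub[i])
  }
  # lactate chain: export clamp -> transporter -> LDH
  conc["lac_e"] <- clip("lac_e", 1 / K("EX_LAC"))
  conc["lac"] <- clip("lac", conc[["lac_e"]] / K("LACT"))
  conc["nadh"] <- clip("nadh",
    conc[["lac"]] * conc[["nad"]] / (K("LDH") * conc[["pyr"]]))
  # creatine kinase: pcr + adp <-> cr + atp
  conc["pcr"] <- clip("pcr",
    conc[["cr"]] * conc[["atp"]] / (K("CK") * conc[["adp"]]))
  # carnitine ester side pools (transferase equilibria, K = 1 forms kept
  # general through dg0)
  conc["accrn_m"] <- clip("accrn_m",
    K("CRAT") * conc[["accoa_m"]] * conc[["carn_m"]] / conc[["coa_m"]])
  for (n in c(14, 12, 8, 4)) {
    rid <- paste0("ACT", n)
    acyl <- sprintf("c%dcoa_m", n); ester <- sprintf("c%dcrn_m", n)
    conc[ester] <- clip(ester,
      K(rid) * conc[[acyl]] * conc[[dQ <- "carn_m"]] / conc[["coa_m"]])
  }
  conc["accrn"] <- clip("accrn", conc[["accrn_m"]] * K("ACRNT"))
  conc
}

#' Fuel utilization percentages from the respiratory quotient
#'
#' Indirect-calorimetry partition: `%FA = 100 (1 - RQ) / (1 - 0.7)`,
#' `%carbohydrate = 100 - %FA`, clipped to [0, 100].
#'
#' @param RQ respiratory quotient(s); values outside [0.6, 1.1] are clipped
#'   with a warning.
#' @return data.frame with columns `fa` and `cho` (percent).
#' @export
fuel_fractions <- function(RQ) {
  if (any(RQ < 0.6 | RQ > 1.1, na.rm = TRUE))
    warning("RQ outside [0.6, 1.1]; clipping")
  RQ <- pmin(pmax(RQ, 0.6), 1.1)
  fa <- pmin(pmax(100 * (1 - RQ) / 0.3, 0), 100)
  data.frame(fa = fa, cho = 100 - fa)
}

#' Normalized-exercise protocol (transient or steady-state)
#'
#' Simulates a sequence of exercise intensities: at each %VO2max step the
#' activities come from the monoexponential rest-to-exercise transition and
#' the ATPase demand is proportional to intensity; the state is carried
#' from step to step and RQ is recorded at the end of each dwell. Dwell 2
#' min mimics the transient graded protocol, 60 min the steady state.
#'
#' @param net a `metabolic_network`.
#' @param conc0 initial concentrations.
#' @param spec a [transition_spec()].
#' @param steps numeric vector of %VO2max values.
#' @param dwell minutes per step.
#' @param demand_max ATPase rate at 100 %VO2max (demand linear in
#'   intensity when `demand_at` is not given).
#' @param carry carry the metabolic state from step to step (the
#'   continuous graded run); `FALSE` restarts each step from `conc0`.
#' @param basal optional basal ATP-turnover spec (see [demand_constant()]).
#' @param demand_at optional function mapping %VO2max to the ATPase rate
#'   (e.g. the matched rest-to-exercise interpolation of a
#'   `fuel_parameterization`; see [normalized_demand()]).
#' @param ... passed to [simulate_kinetics()].
#' @return data.frame with columns `vo2`, `RQ`, `crashed`, plus fuel
#'   percentages.
#' @export
run_normalized_protocol <- function(net, conc0, spec, steps, dwell = 2,
                                    demand_max = NULL, demand_at = NULL,
                                    carry = TRUE, basal = NULL, ...) {
  stopifnot(inherits(spec, "transition_spec"))
  if (is.null(demand_at)) {
    stopifnot(!is.null(demand_max))
    demand_at <- function(v) demand_max * v / 100
  }
  state <- conc0
  res <- data.frame(vo2 = steps, RQ = NA_real_, crashed = FALSE)
  for (i in seq_along(steps)) {
    v <- steps[i]
    Xv <- transition_activities(spec, max(v, spec$vo2_rest))
    pr <- demand_constant(demand_at(v), basal = basal)
    tr <- simulate_kinetics(net, if (carry) state else conc0, Xv, pr,
                            c(0, dwell), ...)
    n <- length(tr$times)
    res$RQ[i] <- tr$observables$RQ[n]
    res$crashed[i] <- tr$crashed
    if (carry) state <- setNames(tr$conc[n, ], colnames(tr$conc))
  }
  cbind(res, fuel_fractions(pmin(pmax(res$RQ, 0.6), 1.1)))
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("<kinetic_trajectory> ", n, " points over [",
      x$times[1], ", ", x$times[n], "] min\n", sep = "")
  cat("  final RQ: ", signif(x$observables$RQ[n], 4),
      "  crashed: ", x$crashed,
      if (x$crashed) paste0(" (t = ", signif(x$crash_time, 4), " min)"), "\n",
      sep = "")
  invisible(x)
}
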