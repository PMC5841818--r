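#' Standardized mean squared error between simulation and observations
#'
#' The pooled error statistic: the mean over all data points (gas-exchange
#' series, lactate, RQ, and acyl-carnitine biopsies) of the squared residual
#' divided by the point's variance. Model values are linearly interpolated
#' to the observation times. The RQ series is included even though it
#' derives from the gas fluxes; set `include_rq = FALSE` to drop it.
#'
#' @param traj a `kinetic_trajectory` covering the observation times.
#' @param obs an `observation_set`.
#' @param include_rq include the (derived) RQ series in the pool.
#' @return non-negative scalar.
#' @export
error_function <- function(traj, obs, include_rq = TRUE) {
  stopifnot(inherits(obs, "observation_set"))
  o <- traj$observables
  tmax <- max(o$time)
  need <- max(obs$series$time, obs$biopsies$time)
  if (need > tmax + 1e-6)
    stop("simulation does not cover observation times beyond t = ", tmax,
         " (needed ", need, ")")
  mi <- function(col, tt) stats::approx(o$time, o[[col]], xout = tt, rule = 2)$y
  s <- obs$series
  res <- c((mi("JO2", s$time) - s$JO2)^2 / s$var_JO2,
           (mi("JCO2", s$time) - s$JCO2)^2 / s$var_JCO2,
           (mi("lactate", s$time) - s$lactate)^2 / s$var_lactate)
  if (include_rq)
    res <- c(res, (mi("RQ", s$time) - s$RQ)^2 / s$var_RQ)
  b <- obs$biopsies
  if (nrow(b))
    res <- c(res, vapply(seq_len(nrow(b)), function(i)
      (mi(as.character(b$pool[i]), b$time[i]) - b$value[i])^2 / b$variance[i], 0))
  mean(res)
}

# simulate a candidate activity pair under the observation protocol
.simulate_candidate <- function(net, obs, X_rest, X_ex, dt = 1, ...) {
  sp <- transition_spec(X_rest, X_ex, Tc = obs$Tc, vo2_rest = obs$vo2_rest)
  simulate_kinetics(net, obs$conc0, sp, obs$protocol, obs$tspan, dt = dt, ...)
}

.candidate_error <- function(net, obs, X_rest, X_ex, include_rq = TRUE, ...) {
  tr <- tryCatch(.simulate_candidate(net, obs, X_rest, X_ex, ...),
                 error = function(e) NULL)
  if (is.null(tr)) return(list(error = 1e8, traj = NULL))
  list(error = error_function(tr, obs, include_rq = include_rq), traj = tr)
}

# apply a hypothesis-mode parameterization to a base activity pair
.mode_activities <- function(net, base, mode, pars) {
  XR <- base$X_rest; XE <- base$X_exercise
  scale_sets <- function(ids, mult) {
    ids <- intersect(ids, names(XR))
    XR[ids] <<- XR[ids] * mult
    XE[ids] <<- XE[ids] * mult
  }
  if (mode == "mito_scale_only") {
    scale_sets(mito_reactions(net), pars[["mito_fraction"]])
  } else if (mode == "fao_scale_only") {
    scale_sets(fao_reactions(net), 1 / pars[["fao_factor"]])
  } else if (mode == "minimal_combined") {
    scale_sets(mito_reactions(net), pars[["mito_fraction"]])
    scale_sets(fa_transport_reactions(net), 1 / pars[["fa_transport_factor"]])
    extra <- pars$extra
    if (!is.null(extra) && length(extra))
      for (nm in names(extra)) scale_sets(nm, 1 / extra[[nm]])
  } else if (mode == "free_fit") {
    mult <- pars$mult[names(XR)]
    XR <- XR * mult; XE <- XE * mult
  }
  list(X_rest = XR, X_exercise = XE)
}

#' Fit enzyme activities to an observation set
#'
#' Four hypothesis modes mirror the genotype analysis: `free_fit` adjusts
#' all 86 activities (one multiplicative factor per reaction, applied to the
#' resting and exercise sets jointly) by simulated annealing in log space
#' followed by a Nelder-Mead polish; `mito_scale_only` fits a single
#' multiplicative factor on all mitochondrial-tagged reactions
#' (`X = X_base * mito_fraction`); `fao_scale_only` fits a single divisor on
#' the fatty-acid transport plus beta-oxidation set; `minimal_combined`
#' fits the mitochondrial factor together with a separate divisor on the
#' fatty-acid transport reactions (compounding, as in the genotype
#' transform), optionally followed by forward selection of per-enzyme
#' factors over the FA pathway.
#'
#' @param net a `metabolic_network`.
#' @param obs an `observation_set`.
#' @param mode one of `"free_fit"`, `"mito_scale_only"`, `"fao_scale_only"`,
#'   `"minimal_combined"`.
#' @param init base `fuel_parameterization` (the high-capacity fit for the
#'   hypothesis modes; the perturbed start for `free_fit`).
#' @param hyperparams list: `sa_epochs` (12), `proposals` (20 per epoch),
#'   `cooling` (0.95), `sigma` (0.2 log-space proposal SD), `polish_evals`
#'   (200), `grid_n` (6), `forward_selection` (FALSE), `fs_candidates`,
#'   `fs_improve` (0.02), `dt` (simulation output step, 1 min),
#'   `include_rq` (TRUE).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return a `fit_result`: `X_fit` (fitted exercise activities), `X_rest`,
#'   `error`, `mode`, `scale_factors`, `seed`, `n_evals`, `trajectory`.
#' @export
fit_activities <- function(net, obs, mode = c("minimal_combined",
                                              "mito_scale_only",
                                              "fao_scale_only", "free_fit"),
                           init, hyperparams = list(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(obs, "observation_set"),
            inherits(init, "fuel_parameterization"))
  hp <- utils::modifyList(list(sa_epochs = 12, proposals = 20, cooling = 0.95,
                               sigma = 0.2, polish_evals = 60, grid_n = 6,
                               forward_selection = FALSE,
                               fs_candidates = c("CPT1", "PCT", "CPT2", "FAT",
                                                 "FACS", paste0("ACAD", 1:7)),
                               fs_improve = 0.02, dt = 1,
                               include_rq = TRUE), hyperparams)
  n_evals <- 0L
  evalmode <- function(pars) {
    n_evals <<- n_evals + 1L
    XX <- .mode_activities(net, init, mode, pars)
    .candidate_error(net, obs, XX$X_rest, XX$X_exercise,
                     include_rq = hp$include_rq, dt = hp$dt)$error
  }

  if (mode %in% c("mito_scale_only", "fao_scale_only")) {
    key <- if (mode == "mito_scale_only") "mito_fraction" else "fao_factor"
    grid <- if (mode == "mito_scale_only")
      exp(seq(log(0.2), log(1), length.out = hp$grid_n))
    else exp(seq(log(1), log(25), length.out = hp$grid_n))
    errs <- vapply(grid, function(g) evalmode(setNames(list(g), key)), 0)
    best <- grid[which.min(errs)]
    opt <- stats::optimize(function(lg) evalmode(setNames(list(exp(lg)), key)),
                           interval = log(best) + c(-0.6, 0.6), tol = 0.02)
    val <- exp(opt$minimum)
    if (opt$objective > min(errs)) { val <- best; opt$objective <- min(errs) }
    sf <- setNames(list(val), key)
    XX <- .mode_activities(net, init, mode, sf)
    fin <- .candidate_error(net, obs, XX$X_rest, XX$X_exercise,
                            include_rq = hp$include_rq, dt = hp$dt)
    return(structure(list(X_fit = XX$X_exercise, X_rest = XX$X_rest,
                          error = fin$error, mode = mode, scale_factors = sf,
                          seed = seed, n_evals = n_evals,
                          trajectory = fin$traj), class = "fit_result"))
  }

  if (mode == "minimal_combined") {
    # hypothesis scan over round physiological factors (fractional
    # mitochondrial-density reductions; fold-reductions of FA transport)
    mgrid <- c(0.3, 0.4, 0.5, 0.6, 0.75, 1)
    fgrid <- c(1, 2, 3.5, 5, 7.5, 12, 20)
    if (!is.null(hp$mgrid)) mgrid <- hp$mgrid
    if (!is.null(hp$fgrid)) fgrid <- hp$fgrid
    E <- matrix(NA_real_, length(mgrid), length(fgrid))
    for (i in seq_along(mgrid)) for (j in seq_along(fgrid))
      E[i, j] <- evalmode(list(mito_fraction = mgrid[i],
                               fa_transport_factor = fgrid[j]))
    ij <- which(E == min(E), arr.ind = TRUE)[1, ]
    start <- log(c(mgrid[ij[1]], fgrid[ij[2]]))
    clampm <- function(x) min(max(x, 0.2), 1)
    clampf <- function(x) min(max(x, 1), 25)
    opt <- stats::optim(start, function(lp)
      evalmode(list(mito_fraction = clampm(exp(lp[1])),
                    fa_transport_factor = clampf(exp(lp[2])))),
      method = "Nelder-Mead",
      control = list(maxit = min(hp$polish_evals, 40), reltol = 1e-2))
    sf <- list(mito_fraction = clampm(exp(opt$par[1])),
               fa_transport_factor = clampf(exp(opt$par[2])), extra = NULL)
    best_err <- min(opt$value, min(E))
    if (opt$value > min(E))
      sf <- list(mito_fraction = mgrid[ij[1]],
                 fa_transport_factor = fgrid[ij[2]], extra = NULL)
    if (isTRUE(hp$forward_selection)) {
      extra <- list()
      for (cand in hp$fs_candidates) {
        o1 <- stats::optimize(function(lg) {
          e <- extra; e[[cand]] <- exp(lg)
          evalmode(utils::modifyList(sf, list(extra = e)))
        }, interval = log(c(1, 20)), tol = 0.05)
        if (o1$objective < best_err * (1 - hp$fs_improve)) {
          extra[[cand]] <- exp(o1$minimum)
          best_err <- o1$objective
        }
      }
      sf$extra <- if (length(extra)) unlist(extra) else NULL
    }
    XX <- .mode_activities(net, init, mode, sf)
    fin <- .candidate_error(net, obs, XX$X_rest, XX$X_exercise,
                            include_rq = hp$include_rq, dt = hp$dt)
    return(structure(list(X_fit = XX$X_exercise, X_rest = XX$X_rest,
                          error = fin$error, mode = mode, scale_factors = sf,
                          seed = seed, n_evals = n_evals,
                          trajectory = fin$traj), class = "fit_result"))
  }

  ## free_fit: simulated annealing on per-reaction log multipliers
  rid <- names(init$X_rest)
  mult <- setNames(rep(1, length(rid)), rid)
  cur <- evalmode(list(mult = mult))
  best <- list(mult = mult, error = cur)
  Tfac <- max(cur, 1)
  .with_seed(seed, {
    for (ep in seq_len(hp$sa_epochs)) {
      for (pr in seq_len(hp$proposals)) {
        k <- sample(length(mult), 1)
        prop <- mult
        prop[k] <- prop[k] * exp(stats::rnorm(1, 0, hp$sigma))
        e <- evalmode(list(mult = prop))
        if (e < cur || stats::runif(1) < exp(-(e - cur) / Tfac)) {
          mult <- prop; cur <- e
          if (e < best$error) best <- list(mult = mult, error = e)
        }
      }
      Tfac <- Tfac * hp$cooling
    }
  })
  ## local polish: Nelder-Mead on the most-changed multipliers
  changed <- names(sort(abs(log(best$mult)), decreasing = TRUE))
  changed <- changed[seq_len(min(6, sum(abs(log(best$mult)) > 1e-9)))]
  if (length(changed) >= 1) {
    op <- stats::optim(log(best$mult[changed]), function(lp) {
      m <- best$mult; m[changed] <- exp(lp)
      evalmode(list(mult = m))
    }, method = "Nelder-Mead",
    control = list(maxit = hp$polish_evals, reltol = 1e-3))
    if (op$value <= best$error) {
      best$mult[changed] <- exp(op$par)
      best$error <- op$value
    }
  }
  XX <- .mode_activities(net, init, "free_fit", list(mult = best$mult))
  fin <- .candidate_error(net, obs, XX$X_rest, XX$X_exercise,
                          include_rq = hp$include_rq, dt = hp$dt)
  structure(list(X_fit = XX$X_exercise, X_rest = XX$X_rest,
                 error = fin$error, mode = "free_fit",
                 scale_factors = list(mult = best$mult), seed = seed,
                 n_evals = n_evals, trajectory = fin$traj),
            class = "fit_result")
}

#' Build an ensemble of acceptable activity sets
#'
#' Multiplicative log-normal perturbations of an accepted fit, retained when
#' the pooled error stays at or below `accept_threshold` (default 1.5x the
#' base error). The acceptance rate is recorded; per-activity spread across
#' the accepted sets quantifies parameter confidence (sensitive activities
#' admit less perturbation).
#'
#' @param net a `metabolic_network`.
#' @param obs an `observation_set`.
#' @param base_fit a `fit_result`.
#' @param n_sets number of accepted sets to collect.
#' @param accept_threshold absolute error threshold (default
#'   `1.5 * base_fit$error`).
#' @param sigma log-normal perturbation SD per activity.
#' @param seed RNG seed.
#' @param max_tries cap on total proposals.
#' @param dt simulation output step.
#' @return an `activity_ensemble`: matrix (set x reaction) of exercise
#'   activities with attributes `errors`, `acceptance_rate`.
#' @export
build_ensemble <- function(net, obs, base_fit, n_sets = 20,
                           accept_threshold = NULL, sigma = 0.05,
                           seed = 1L, max_tries = 50 * n_sets, dt = 1) {
  stopifnot(inherits(base_fit, "fit_result"))
  if (is.null(accept_threshold)) accept_threshold <- 1.5 * base_fit$error
  rid <- names(base_fit$X_fit)
  acc <- matrix(NA_real_, 0, length(rid), dimnames = list(NULL, rid))
  errs <- numeric(0)
  tries <- 0L
  .with_seed(seed, {
    while (nrow(acc) < n_sets && tries < max_tries) {
      tries <- tries + 1L
      pert <- exp(stats::rnorm(length(rid), 0, sigma))
      XR <- base_fit$X_rest * pert
      XE <- base_fit$X_fit * pert
      e <- .candidate_error(net, obs, XR, XE, dt = dt)$error
      if (e <= accept_threshold) {
        acc <- rbind(acc, XE)
        errs <- c(errs, e)
      }
    }
  })
  structure(acc, errors = errs, acceptance_rate = nrow(acc) / max(tries, 1),
            class = c("activity_ensemble", "matrix", "array"))
}

#' Pairwise activity-ratio distributions between two ensembles
#'
#' For each reaction, all |A| x |B| pairwise ratios `X_A / X_B` between the
#' two ensembles' activity sets, with a median and percentile interval
#' summary (the genotype-contrast histograms).
#'
#' @param ens_A,ens_B `activity_ensemble` matrices over the same reactions.
#' @param probs percentile interval (default 2.5/97.5).
#' @return list with `summary` (data.frame: reaction, median, lo, hi, n)
#'   and `ratios` (named list of numeric vectors).
#' @export
activity_ratio_histograms <- function(ens_A, ens_B, probs = c(0.025, 0.975)) {
  stopifnot(nrow(ens_A) >= 1, nrow(ens_B) >= 1,
            identical(colnames(ens_A), colnames(ens_B)))
  rid <- colnames(ens_A)
  ratios <- lapply(rid, function(r) as.vector(outer(ens_A[, r], ens_B[, r], `/`)))
  names(ratios) <- rid
  qs <- t(vapply(ratios, stats::quantile, numeric(2), probs = probs))
  summary <- data.frame(reaction = rid,
                        median = vapply(ratios, stats::median, 0),
                        lo = qs[, 1], hi = qs[, 2],
                        n = nrow(ens_A) * nrow(ens_B),
                        row.names = NULL)
  list(summary = summary, ratios = ratios)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> mode:", x$mode, " error:", signif(x$error, 4),
      " evals:", x$n_evals, "\n")
  if (x$mode != "free_fit") {
    sf <- x$scale_factors
    cat("  factors:", paste(sprintf("%s=%.3g",
        names(sf)[!vapply(sf, is.null, TRUE)],
        unlist(sf[!vapply(sf, is.null, TRUE)])), collapse = ", "), "\n")
  }
  invisible(x)
}
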