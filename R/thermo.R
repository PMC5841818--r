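#' Thermodynamic evaluation context
#'
#' @param T_K absolute temperature in kelvin; the canonical analysis uses
#'   298.15 K (25 C, matching the standard transformed free energies in the
#'   network file).
#' @param reference_conc reference concentration (molar) dividing every
#'   concentration in the mass-action ratio.
#' @return a `thermo_context` list with `R` (kJ/(mol K)), `T`, `RT` and
#'   `reference_conc`.
#' @export
thermo_context <- function(T_K = 298.15, reference_conc = 1.0) {
  R <- 8.314462618e-3
  structure(list(R = R, T = T_K, RT = R * T_K, reference_conc = reference_conc),
            class = "thermo_context")
}

#' Transformed reaction free energies at given concentrations
#'
#' Computes `dG' = dG'0 + RT ln Q` per reaction, with the mass-action ratio
#' `Q = prod(products^nu) / prod(substrates^mu)` (each concentration divided
#' by the reference concentration). Evaluated in log space as
#' `t(S) %*% log(conc)`.
#'
#' @param net a `metabolic_network`.
#' @param conc named molar concentration vector covering all species.
#' @param ctx a [thermo_context()].
#' @return named numeric vector of dG' (kJ/mol), one entry per reaction.
#' @export
delta_g_prime <- function(net, conc, ctx = thermo_context()) {
  stopifnot(inherits(net, "metabolic_network"))
  conc <- conc[net$species$id]
  if (anyNA(conc)) stop("concentration vector does not cover all species")
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  dg0 <- vapply(net$reactions, `[[`, 0, "dg0")
  lnq <- drop(crossprod(net$S, log(conc / ctx$reference_conc)))
  setNames(dg0 + ctx$RT * lnq, net$reaction_ids)
}

#' Sample a thermodynamically feasible concentration vector
#'
#' Monte Carlo search for a concentration vector that lies inside every
#' species' literature bounds and satisfies the second law,
#' `dG'_k * J_k < 0`, for every reaction carrying nonzero reference flux.
#' Flux directions come from the constraint-based solution at rest.
#' Sampling is log-uniform per species between its bounds; after an initial
#' all-at-once phase, a coordinate-wise repair phase resamples only the
#' species participating in violated reactions, and every returned vector is
#' re-checked in full.
#'
#' @param net a `metabolic_network`.
#' @param resting_fluxes named flux vector giving a sign for every reaction
#'   (zero-flux reactions impose no constraint).
#' @param ctx a [thermo_context()].
#' @param bounds optional two-column matrix/data.frame (`lb`, `ub`,
#'   rownames = species ids) overriding the network bounds.
#' @param seed integer seed; the sample is a pure function of
#'   (net, fluxes, bounds, seed).
#' @param max_tries maximum total resampling attempts.
#' @param eps strict-inequality margin in kJ/mol: feasibility requires
#'   `sign(J_k) * dG'_k <= -eps`, so razor-edge equilibria are not
#'   accepted.
#' @param flux_tol fluxes with `|J| <= flux_tol` impose no direction
#'   constraint (numerically zero solver output).
#' @return named concentration vector with attributes `seed` and `attempts`.
#'   If the search fails, an error of class `fuelswitch_infeasible` reports
#'   the most frequently violated reactions.
#' @export
sample_feasible_concentrations <- function(net, resting_fluxes,
                                           ctx = thermo_context(),
                                           bounds = NULL, seed = 1L,
                                           max_tries = 5000L, eps = 1e-9,
                                           flux_tol = 1e-12) {
  stopifnot(inherits(net, "metabolic_network"))
  ids <- net$species$id
  lb <- setNames(net$species$lb, ids)
  ub <- setNames(net$species$ub, ids)
  if (!is.null(bounds)) {
    lb[rownames(bounds)] <- bounds[, "lb"]
    ub[rownames(bounds)] <- bounds[, "ub"]
  }
  J <- setNames(numeric(length(net$reaction_ids)), net$reaction_ids)
  J[names(resting_fluxes)] <- resting_fluxes
  active <- which(abs(J) > flux_tol)

  dg0 <- vapply(net$reactions, `[[`, 0, "dg0")
  St <- t(net$S)
  llb <- log(lb); lub <- log(ub)

  sgn <- sign(J[active])
  violations <- function(conc) {
    dg <- dg0 + ctx$RT * drop(St %*% log(conc / ctx$reference_conc))
    active[dg[active] * sgn > -eps]
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  viol_count <- setNames(integer(length(J)), names(J))
  attempts <- 0L
  conc <- exp(llb + stats::runif(length(ids)) * (lub - llb))
  names(conc) <- ids
  repeat {
    attempts <- attempts + 1L
    bad <- violations(conc)
    if (!length(bad)) break
    viol_count[bad] <- viol_count[bad] + 1L
    if (attempts >= max_tries) {
      worst <- sort(viol_count[viol_count > 0], decreasing = TRUE)
      stop(structure(class = c("fuelswitch_infeasible", "error", "condition"),
        list(message = paste0(
          "no feasible concentration vector in ", max_tries,
          " attempts; most-violated reactions: ",
          paste(sprintf("%s (%d)", names(worst)[seq_len(min(5, length(worst)))],
                        worst[seq_len(min(5, length(worst)))]), collapse = ", ")),
          call = sys.call(-1))))
    }
    if (attempts <= max_tries %/% 10) {
      conc <- exp(llb + stats::runif(length(ids)) * (lub - llb))
      names(conc) <- ids
    } else {
      # repair mode: resample only species touching violated reactions
      touch <- unique(unlist(lapply(bad, function(k) names(which(net$S[, k] != 0)))))
      conc[touch] <- exp(llb[touch] +
                           stats::runif(length(touch)) * (lub[touch] - llb[touch]))
    }
  }
  structure(conc, seed = seed, attempts = attempts)
}
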