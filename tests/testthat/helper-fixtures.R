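# Shared fixtures, lazily computed once per test run.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_net <- function() fx("net", canonical_network)

fx_rest <- function() fx("rest", function() {
  b <- fx_boundary_row(1e-3, 0.80)
  solve_timepoint(fx_net(), c(time = 0, b))
})

fx_truth <- function() fx("truth", function()
  make_ground_truth_pair(fx_net(), seed = 1))

# a 50-min high-capacity graded-protocol trajectory (shared by several tests)
fx_hcr_traj <- function() fx("hcr_traj", function()
  simulate_protocol(fx_net(), fx_truth()$hcr, dt = 1))

fx_lcr_obs <- function() fx("lcr_obs", function()
  make_observations(fx_net(), fx_truth()$lcr,
                    protocol_spec("LCR_like", noise = 0.03, seed = 7)))

# consistent boundary row from (JO2, RQ) via oxidation stoichiometry
fx_boundary_row <- function(JO2, RQ) {
  list(JO2 = JO2, JCO2 = RQ * JO2,
       fa = JO2 * (1 - RQ) / 7, carb = JO2 * (23 * RQ - 16) / 42)
}

# --- toy network files -------------------------------------------------

toy_network_file <- function(species, reactions, name = "toy") {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = name,
    water_volume_l_per_kg = 0.755,
    compartments = list(
      list(id = "extracellular", volume_fraction = 0.2),
      list(id = "cytosol", volume_fraction = 0.75),
      list(id = "mitochondrion", volume_fraction = 0.05)),
    species = species, reactions = reactions),
    path, auto_unbox = TRUE, digits = NA)
  path
}

toy_sp <- function(id, comp = "cytosol", carbon = 1, lb = 1e-6, ub = 1e-2,
                   conc = 1e-4)
  list(id = id, name = id, compartment = comp, carbon = carbon,
       lb = lb, ub = ub, conc = conc)

toy_rx <- function(id, stoich, dg0 = 0, tag = "glycolysis",
                   boundary = FALSE, reversible = TRUE)
  list(id = id, name = id, stoich = stoich, dg0 = dg0, pathway = tag,
       boundary = boundary, reversible = reversible)

# A -> B (identity-case toy)
toy_ab <- function() {
  load_network(toy_network_file(
    list(toy_sp("a"), toy_sp("b")),
    list(toy_rx("AB", list(a = -1, b = 1)))))
}

# chain with exchanges and a redundant parallel pair:
#  in -> a ; a -> b (two parallel routes) ; b -> out
toy_parallel <- function() {
  load_network(toy_network_file(
    list(toy_sp("a"), toy_sp("b")),
    list(toy_rx("IN", list(a = 1), tag = "exchange", boundary = TRUE,
                reversible = FALSE),
         toy_rx("P1", list(a = -1, b = 1), reversible = FALSE),
         toy_rx("P2", list(a = -1, b = 1), reversible = FALSE),
         toy_rx("OUT", list(b = -1), tag = "exchange", boundary = TRUE,
                reversible = FALSE))))
}

# --- brute-force vertex enumeration oracle for box/equality LPs --------

# maximize c'J over {Aeq J = beq, lb <= J <= ub} by enumerating vertices
# (combinations of active bounds spanning the null space).
lp_vertex_oracle <- function(cvec, Aeq, beq, lb, ub) {
  red <- fuelswitch:::.reduce_equalities(Aeq, beq)
  A2 <- red$A; b2 <- red$b
  n <- ncol(Aeq); d <- n - red$rank
  Jp <- drop(crossprod(A2, solve(tcrossprod(A2), b2)))
  if (d == 0) return(list(J = Jp, objective = sum(cvec * Jp)))
  N <- qr.Q(qr(t(A2)), complete = TRUE)[, (red$rank + 1):n, drop = FALSE]
  best <- NULL
  idx <- utils::combn(n, d)
  for (j in seq_len(ncol(idx))) {
    rows <- idx[, j]
    Nk <- N[rows, , drop = FALSE]
    if (abs(det(Nk)) < 1e-10) next
    vals <- expand.grid(rep(list(c(1, 2)), d))
    for (v in seq_len(nrow(vals))) {
      target <- ifelse(unlist(vals[v, ]) == 1, lb[rows], ub[rows])
      if (any(!is.finite(target))) next
      z <- solve(Nk, target - Jp[rows])
      J <- Jp + drop(N %*% z)
      if (all(J >= lb - 1e-8) && all(J <= ub + 1e-8)) {
        obj <- sum(cvec * J)
        if (is.null(best) || obj > best$objective)
          best <- list(J = J, objective = obj)
      }
    }
  }
  best
}
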