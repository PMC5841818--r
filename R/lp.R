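# Internal linear-programming layer.
#
# All flux problems here have the form
#     optimize  c' J   s.t.  Aeq J = beq,  lb <= J <= ub
# with Aeq = stoichiometry plus rows fixing exchange fluxes. The equality
# system is first reduced to independent rows (QR with pivoting) and the
# problem re-expressed in null-space coordinates z (J = J_p + N z), which
# leaves an LP in only a handful of variables; pracma::linprog (implicit
# x >= 0) is called on shifted variables.

.reduce_equalities <- function(Aeq, beq, tol = 1e-10) {
  qa <- qr(t(Aeq), tol = tol)
  r <- qa$rank
  keep <- qa$pivot[seq_len(r)]
  A2 <- Aeq[keep, , drop = FALSE]
  b2 <- beq[keep]
  list(A = A2, b = b2, rank = r)
}

.null_space_problem <- function(Aeq, beq, tol = 1e-10) {
  red <- .reduce_equalities(Aeq, beq, tol)
  A2 <- red$A; b2 <- red$b; r <- red$rank; n <- ncol(Aeq)
  Jp <- drop(crossprod(A2, solve(tcrossprod(A2), b2)))  # min-norm particular solution
  # consistency of the dropped (dependent) rows
  resid <- max(abs(Aeq %*% Jp - beq))
  scale <- max(1, max(abs(beq)))
  if (resid > 1e-7 * scale)
    stop(structure(class = c("fuelswitch_infeasible", "error", "condition"),
                   list(message = paste0(
                     "equality constraints are inconsistent (residual ",
                     signif(resid, 3), "); boundary fluxes violate mass balance"),
                     call = NULL)))
  N <- if (r < n) qr.Q(qr(t(A2)), complete = TRUE)[, (r + 1):n, drop = FALSE]
       else matrix(0, n, 0)
  list(Jp = Jp, N = N, d = n - r)
}

# Solve optimize c'J over {Aeq J = beq, lb <= J <= ub}.
# Returns list(J, objective, status).
.lp_flux <- function(cvec, Aeq, beq, lb, ub, maximize = TRUE,
                     extra_eq = NULL, extra_beq = NULL, tol = 1e-10) {
  nsp <- .null_space_problem(Aeq, beq, tol)
  Jp <- nsp$Jp; N <- nsp$N; d <- nsp$d
  clamp_check <- function(J) {
    viol <- pmax(lb - J, J - ub, 0)
    max(viol)
  }
  if (d == 0L) {
    if (clamp_check(Jp) > 1e-7)
      return(list(J = Jp, objective = sum(cvec * Jp), status = "infeasible"))
    return(list(J = pmin(pmax(Jp, lb), ub), objective = sum(cvec * Jp),
                status = "optimal_unique"))
  }
  # inequality rows from finite bounds
  G <- rbind(N, -N)
  h <- c(ub - Jp, Jp - lb)
  fin <- is.finite(h)
  G <- G[fin, , drop = FALSE]; h <- h[fin]
  # extra equalities expressed in z
  Ez <- bz <- NULL
  if (!is.null(extra_eq)) {
    Ez <- extra_eq %*% N
    bz <- extra_beq - drop(extra_eq %*% Jp)
  }
  # shift z = y - s with y >= 0
  rng <- pmin(ub, 1e6) - pmax(lb, -1e6)
  Mz <- sqrt(sum(rng[is.finite(rng)]^2)) + 1
  s <- rep(Mz, d)
  cz <- drop(crossprod(N, cvec))
  res <- pracma::linprog(if (maximize) -cz else cz,
                         A = G, b = h + drop(G %*% s),
                         Aeq = Ez, beq = if (is.null(bz)) NULL else bz + drop(Ez %*% s),
                         maxiter = 2000)
  if (is.null(res$errno) || res$errno != 1 || anyNA(res$x))
    return(list(J = Jp, objective = NA_real_, status = "solver_failed"))
  z <- res$x - s
  J <- Jp + drop(N %*% z)
  list(J = pmin(pmax(J, lb), ub), objective = sum(cvec * J), status = "optimal",
       z = z, N = N, Jp = Jp)
}

# L1-parsimonious solution at a fixed objective value: minimize sum w|J|
# over the optimal face. Auxiliary variables are introduced only for
# reactions the null space can actually move.
.lp_parsimony <- function(sol, cvec, Aeq, beq, lb, ub, weights = NULL,
                          obj_value, tol = 1e-10) {
  nsp <- .null_space_problem(Aeq, beq, tol)
  Jp <- nsp$Jp; N <- nsp$N; d <- nsp$d
  if (d == 0L) return(sol)
  sup <- which(rowSums(abs(N)) > 1e-9)
  if (!length(sup)) return(sol)
  w <- if (is.null(weights)) rep(1, length(sup)) else weights[sup]
  m <- length(sup)
  # variables: y (= z + s, >= 0, length d), t (>= 0, length m)
  rng <- pmin(ub, 1e6) - pmax(lb, -1e6)
  Mz <- sqrt(sum(rng[is.finite(rng)]^2)) + 1
  s <- rep(Mz, d)
  Ns <- N[sup, , drop = FALSE]
  # t >= +-(Jp + N z):  +-Ns z - t <= -+Jp[sup]
  G1 <- cbind(Ns, -diag(m));  h1 <- -Jp[sup]
  G2 <- cbind(-Ns, -diag(m)); h2 <- Jp[sup]
  # bound rows on J
  Gb <- rbind(cbind(N, matrix(0, nrow(N), m)), cbind(-N, matrix(0, nrow(N), m)))
  hb <- c(ub - Jp, Jp - lb)
  fin <- is.finite(hb)
  G <- rbind(G1, G2, Gb[fin, , drop = FALSE])
  h <- c(h1, h2, hb[fin])
  cz <- drop(crossprod(N, cvec))
  Ez <- matrix(c(cz, rep(0, m)), 1)
  bz <- obj_value - sum(cvec * Jp)
  shift <- c(s, rep(0, m))
  obj <- c(rep(0, d), w)
  res <- pracma::linprog(obj, A = G, b = h + drop(G %*% shift),
                         Aeq = Ez, beq = bz + drop(Ez %*% shift),
                         maxiter = 2000)
  if (is.null(res$errno) || res$errno != 1 || anyNA(res$x)) return(sol)
  z <- res$x[seq_len(d)] - s
  J <- Jp + drop(N %*% z)
  list(J = pmin(pmax(J, lb), ub), objective = sum(cvec * J),
       status = "optimal_parsimonious", z = z, N = N, Jp = Jp)
}
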