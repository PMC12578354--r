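#' Initial/boundary-value problem specification
#'
#' Holds the initial nodal density, the solver time grid, and Dirichlet data
#' (prescribed density values on a set of boundary nodes at every solver
#' time). Nodes not listed as Dirichlet are treated as zero-flux (natural
#' Neumann, q = 0): the boundary integral vanishes and those nodes are free
#' unknowns. `dirichlet_nodes = integer(0)` gives a fully zero-flux problem.
#'
#' @param C0 initial nodal values (cells/um^2).
#' @param times solver time grid (hr), strictly increasing, `times[1]` the
#'   initial time.
#' @param dirichlet_nodes integer node indices where density is prescribed.
#' @param dirichlet_values `length(dirichlet_nodes) x length(times)` matrix
#'   of prescribed values (ignored when no Dirichlet nodes).
#' @return object of class `ibvp_spec`.
#' @export
ibvp_spec <- function(C0, times, dirichlet_nodes = integer(0),
                      dirichlet_values = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 entries")
  dirichlet_nodes <- as.integer(dirichlet_nodes)
  if (length(dirichlet_nodes)) {
    dirichlet_values <- matrix(dirichlet_values, nrow = length(dirichlet_nodes),
                               ncol = length(times))
  } else dirichlet_values <- matrix(0, 0, length(times))
  structure(list(C0 = as.numeric(C0), times = times,
                 dirichlet_nodes = dirichlet_nodes,
                 dirichlet_values = dirichlet_values),
            class = "ibvp_spec")
}

#' Build an IBVP from a data series (Dirichlet data trace)
#'
#' Uses the first frame as the initial condition and the (smoothed) data
#' values at the boundary nodes as Dirichlet data — the whole boundary is
#' Dirichlet, matching the inference setting. When `times` refines the data
#' frames, boundary values are linearly interpolated in time.
#'
#' @param series a [nodal_series()] of data.
#' @param times optional solver time grid (default: the data frames).
#' @return an [ibvp_spec()].
#' @export
ibvp_from_series <- function(series, times = NULL) {
  mesh <- series$mesh
  if (is.null(times)) times <- series$t
  bn <- mesh$boundary
  vals <- t(vapply(bn, function(k)
    stats::approx(series$t, series$d[k, ], xout = times, rule = 2)$y,
    numeric(length(times))))
  ibvp_spec(series$d[, 1], times, bn, vals)
}

#' Newton solver configuration
#'
#' Defaults follow the reference computational setup: absolute and relative
#' residual tolerances 1e-8 and 1e-9.
#'
#' @param atol absolute residual-norm tolerance.
#' @param rtol relative residual-norm tolerance.
#' @param max_iter maximum Newton iterations per time step.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(atol = 1e-8, rtol = 1e-9, max_iter = 30) {
  stopifnot(atol > 0, rtol > 0, max_iter >= 1)
  structure(list(atol = atol, rtol = rtol, max_iter = max_iter),
            class = "solver_config")
}

# residual and Jacobian of one backward-Euler step, all nodes:
#   R = M (d - dprev)/dt + Xi(d) theta        (rows = weighting functions)
#   J = M/dt + d[Xi(d) theta]/dd
assemble_step <- function(mesh, theta, v_unit, d, dprev, dt, jacobian = TRUE) {
  nel <- mesh$n_el; nloc <- mesh$n_loc
  de <- matrix(d[mesh$elements], nel, nloc)
  Cq <- de %*% t(mesh$Nq)                        # nel x nq
  Cte <- matrix(((d - dprev) / dt)[mesh$elements], nel, nloc)
  Ctq <- Cte %*% t(mesh$Nq)
  gradC <- vapply(seq_len(mesh$dim), function(k)
    rowSums(matrix(mesh$grads[, , k], nel) * de), numeric(nel))
  gdot <- matrix(0, nel, nloc)
  vdot <- matrix(0, nel, nloc)
  for (k in seq_len(mesh$dim)) {
    Gk <- matrix(mesh$grads[, , k], nel)
    gdot <- gdot + Gk * gradC[, k]
    vdot <- vdot + Gk * v_unit[k]
  }
  Dq <- ansatz_D(theta, Cq); vfq <- ansatz_vf(theta, Cq)
  rq <- ansatz_r(theta, Cq)
  me <- mesh$measure
  Rc <- me * (Ctq %*% mesh$wNq +
              as.vector(Dq %*% mesh$wq) * gdot -
              as.vector((Cq * vfq) %*% mesh$wq) * vdot -
              rq %*% mesh$wNq)
  R <- scatter_vec(mesh, Rc)
  J <- NULL
  if (jacobian) {
    Dpq <- ansatz_Dp(theta, Cq)
    vftq <- vfq + Cq * ansatz_vfp(theta, Cq)
    rpq <- ansatz_rp(theta, Cq)
    ia <- rep(seq_len(nloc), times = nloc)       # a index per ab column
    ib <- rep(seq_len(nloc), each = nloc)        # b index per ab column
    S2 <- Dpq %*% mesh$wNq                       # nel x nloc (per b)
    S4 <- vftq %*% mesh$wNq
    Jc <- outer(me / dt, as.vector(mesh$Mref)) +
      me * (gdot[, ia, drop = FALSE] * S2[, ib, drop = FALSE] +
            as.vector(Dq %*% mesh$wq) * mesh$GG -
            vdot[, ia, drop = FALSE] * S4[, ib, drop = FALSE] -
            rpq %*% mesh$NNw)
    J <- scatter_mat(mesh, Jc)
  }
  list(R = R, J = J)
}

#' Solve the nonlinear ADR equation forward in time
#'
#' Implicit backward-Euler stepping of the Galerkin weak form with a Newton
#' iteration per step (analytic Jacobian from the polynomial ansatz,
#' consistent non-lumped mass matrix, previous step as initial guess).
#' Dirichlet values are imposed exactly at every step. Negative intermediate
#' densities are permitted (and reported via the `negative_min` attribute),
#' not clipped, to keep the discrete adjoint consistent.
#'
#' @param model an [adr_model()].
#' @param ibvp an [ibvp_spec()].
#' @param mesh an [fe_mesh()].
#' @param cfg a [solver_config()].
#' @return a [nodal_series()] on the ibvp time grid (first column = C0).
#' @export
solve_forward <- function(model, ibvp, mesh, cfg = solver_config()) {
  theta <- model$theta
  v <- model$v_unit
  nt <- length(ibvp$times)
  n <- mesh$n_nodes
  free <- setdiff(seq_len(n), ibvp$dirichlet_nodes)
  D <- matrix(0, n, nt)
  D[, 1] <- ibvp$C0
  if (length(ibvp$dirichlet_nodes))
    D[ibvp$dirichlet_nodes, 1] <- ibvp$dirichlet_values[, 1]
  min_seen <- min(D[, 1])

  # Newton on the single-step residual from a given initial guess.
  # `damped` adds residual-norm backtracking (more cautious, but can stall
  # at local minima of |R|, so the plain iteration is tried first).
  newton <- function(dinit, dprev, dt, damped = FALSE) {
    d <- dinit
    r0 <- NULL
    rn <- Inf
    for (it in seq_len(cfg$max_iter)) {
      sys <- assemble_step(mesh, theta, v, d, dprev, dt)
      Rf <- sys$R[free]
      rn <- sqrt(sum(Rf^2))
      if (!is.finite(rn)) return(list(d = dinit, converged = FALSE, rn = rn))
      if (is.null(r0)) r0 <- rn
      if (rn <= max(cfg$atol, cfg$rtol * r0))
        return(list(d = d, converged = TRUE, rn = rn))
      if (rn > 1e8 * r0) return(list(d = dinit, converged = FALSE, rn = rn))
      delta <- tryCatch(solve(sys$J[free, free, drop = FALSE], -Rf),
                        error = function(e) NULL)
      if (is.null(delta)) return(list(d = dinit, converged = FALSE, rn = rn))
      if (damped) {
        alpha <- 1
        for (ls in 1:12) {
          dtry <- d
          dtry[free] <- d[free] + alpha * delta
          rtry <- sqrt(sum(assemble_step(mesh, theta, v, dtry, dprev, dt,
                                         jacobian = FALSE)$R[free]^2))
          if (is.finite(rtry) && rtry < rn) break
          alpha <- alpha / 2
        }
        d <- dtry
      } else {
        d[free] <- d[free] + delta
      }
    }
    list(d = d, converged = FALSE, rn = rn)
  }

  attempt <- function(dinit, dprev, dt) {
    res <- newton(dinit, dprev, dt)
    if (!res$converged) res <- newton(dinit, dprev, dt, damped = TRUE)
    res
  }

  # predictor by recursive half-stepping: used only to improve the initial
  # guess; the accepted state always solves the full single-step residual,
  # keeping the discrete adjoint consistent with the time grid
  predictor <- function(dprev, dval_prev, dval_next, dt, depth) {
    dmid_val <- (dval_prev + dval_next) / 2
    dmid_init <- dprev
    if (length(ibvp$dirichlet_nodes)) dmid_init[ibvp$dirichlet_nodes] <- dmid_val
    sub1 <- attempt(dmid_init, dprev, dt / 2)
    dmid <- if (sub1$converged) sub1$d
            else if (depth > 0) predictor(dprev, dval_prev, dmid_val, dt / 2, depth - 1)
            else sub1$d
    if (length(ibvp$dirichlet_nodes)) dmid[ibvp$dirichlet_nodes] <- dmid_val
    dend_init <- dmid
    if (length(ibvp$dirichlet_nodes)) dend_init[ibvp$dirichlet_nodes] <- dval_next
    sub2 <- attempt(dend_init, dmid, dt / 2)
    if (!sub2$converged && depth > 0)
      return(predictor(dmid, dmid_val, dval_next, dt / 2, depth - 1))
    sub2$d
  }

  for (j in 2:nt) {
    dt <- ibvp$times[j] - ibvp$times[j - 1]
    dval_prev <- if (length(ibvp$dirichlet_nodes)) ibvp$dirichlet_values[, j - 1] else numeric(0)
    dval_next <- if (length(ibvp$dirichlet_nodes)) ibvp$dirichlet_values[, j] else numeric(0)
    d <- D[, j - 1]
    if (length(ibvp$dirichlet_nodes)) d[ibvp$dirichlet_nodes] <- dval_next
    res <- attempt(d, D[, j - 1], dt)
    if (!res$converged) {
      dguess <- predictor(D[, j - 1], dval_prev, dval_next, dt, depth = 4)
      if (length(ibvp$dirichlet_nodes)) dguess[ibvp$dirichlet_nodes] <- dval_next
      res <- attempt(dguess, D[, j - 1], dt)
    }
    if (!res$converged)
      stop(sprintf("Newton did not converge at step %d (|R| = %.3g)",
                   j - 1, res$rn))
    D[, j] <- res$d
    min_seen <- min(min_seen, min(res$d))
  }
  out <- nodal_series(mesh, ibvp$times, D)
  attr(out, "negative_min") <- if (min_seen < 0) min_seen else NULL
  out
}

#' Total cell mass at a frame
#'
#' \eqn{\int_\Omega C^h \, dV} by element quadrature — a conservation
#' diagnostic: with no reaction and zero-flux boundaries the discrete scheme
#' conserves this exactly.
#'
#' @param series a [nodal_series()].
#' @param t_index frame index.
#' @return total number of cells (1D meshes: cells per um of strip width).
#' @export
total_mass <- function(series, t_index = 1) {
  mesh <- series$mesh
  d <- series$d[, t_index]
  s <- 0
  for (e in seq_len(mesh$n_el)) {
    Cq <- as.vector(mesh$Nq %*% d[mesh$elements[e, ]])
    s <- s + mesh$measure[e] * sum(mesh$wq * Cq)
  }
  s
}

#' Root-mean-squared error between two nodal series
#'
#' Root of the mean squared nodal difference over all nodes and frames,
#' requiring a shared mesh and time grid.
#'
#' @param pred,data [nodal_series()] objects with identical shapes.
#' @return RMSE in cells/um^2.
#' @export
rmse <- function(pred, data) {
  if (!identical(dim(pred$d), dim(data$d)) ||
      length(pred$t) != length(data$t))
    stop("series shapes do not match")
  sqrt(mean((pred$d - data$d)^2))
}
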