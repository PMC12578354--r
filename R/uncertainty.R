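#' Two-parameter loss-contour scan
#'
#' Evaluates the PDE-constrained misfit (or a caller-supplied objective) on
#' a grid over two active parameters while every other parameter stays fixed
#' at its inferred value, and normalizes by the grid minimum. Broad, shallow
#' valleys indicate low sensitivity (parameter degeneracy); sharp minima
#' indicate well-constrained parameters.
#'
#' @param model an [adr_model()] at the inferred point.
#' @param pair 0-based indices of the two varied terms (must be active).
#' @param data,ibvp,cfg forwarded to [misfit_loss()] (ignored when
#'   `objective` is given).
#' @param ranges list of two `c(lo, hi)` ranges; default +-50% around the
#'   inferred values.
#' @param grid_n grid points per axis (default 41).
#' @param objective optional function of the full theta 8-vector returning a
#'   scalar loss (e.g. the quadratic VSI loss), replacing the misfit.
#' @return object of class `contour_scan`: axes, raw `loss` matrix
#'   (failed evaluations recorded as `NA`), `norm_loss` (min = 1), the pair
#'   and the fixed theta.
#' @export
loss_contours <- function(model, pair, data = NULL, ibvp = NULL,
                          cfg = solver_config(), ranges = NULL, grid_n = 41,
                          objective = NULL) {
  stopifnot(length(pair) == 2, all(pair %in% model$active))
  th0 <- model$theta
  if (is.null(ranges))
    ranges <- lapply(pair, function(i) {
      v <- th0[i + 1]
      sort(c(0.5 * v, 1.5 * v))
    })
  ax1 <- seq(ranges[[1]][1], ranges[[1]][2], length.out = grid_n)
  ax2 <- seq(ranges[[2]][1], ranges[[2]][2], length.out = grid_n)
  if (is.null(objective))
    objective <- function(theta)
      as.numeric(misfit_loss(adr_model(theta, model$active, model$v_unit),
                             data, ibvp, cfg))
  L <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    th <- th0
    th[pair + 1] <- c(ax1[i], ax2[j])
    L[i, j] <- tryCatch(objective(th), error = function(e) NA_real_)
  }
  mn <- min(L, na.rm = TRUE)
  structure(list(pair = pair, ax1 = ax1, ax2 = ax2, loss = L,
                 norm_loss = L / mn, theta = th0),
            class = "contour_scan")
}

#' Local Gaussian (Laplace) approximation to the parameter posterior
#'
#' Approximates the posterior of the active parameters at a local minimum
#' theta* by a Gaussian with covariance `2 * sigma2 * H^{-1}`, where H is
#' the Hessian of the misfit at theta* (central finite differences of the
#' discrete-adjoint gradient) and the noise scale `sigma2` is estimated as
#' the final misfit divided by the residual degrees of freedom
#' (nodes x frames summed over replicates, minus the number of active
#' parameters). This Gaussian-likelihood convention is recorded in the
#' output. If H is not positive definite the pseudo-inverse is used, with
#' flat directions reported.
#'
#' @param model an [adr_model()] at the inferred minimum.
#' @param data,ibvp,cfg forwarded to [misfit_loss()] / [loss_gradient()]
#'   (ignored when `objective` is given).
#' @param objective optional function of the full theta 8-vector; the
#'   Hessian is then obtained by second-order central differences of it and
#'   `sigma2` must be supplied (default 1).
#' @param sigma2 optional noise-scale override.
#' @param h_rel relative finite-difference step.
#' @return object of class `laplace_summary`: `theta` (active point
#'   estimate), `covariance`, `sd`, `sigma2`, `hessian`, `flat`
#'   (near-null directions, if any) and `convention`.
#' @export
laplace_covariance <- function(model, data = NULL, ibvp = NULL,
                               cfg = solver_config(), objective = NULL,
                               sigma2 = NULL, h_rel = 1e-4) {
  active <- model$active
  p <- length(active)
  th0 <- model$theta
  steps <- vapply(active, function(i) h_rel * max(abs(th0[i + 1]), 1e-8),
                  numeric(1))
  H <- matrix(0, p, p)
  if (is.null(objective)) {
    datas <- as_series_list(data)
    gfun <- function(th)
      as.numeric(loss_gradient(adr_model(th, active, model$v_unit),
                               datas, ibvp, cfg))
    for (k in seq_len(p)) {
      up <- th0; up[active[k] + 1] <- up[active[k] + 1] + steps[k]
      dn <- th0; dn[active[k] + 1] <- dn[active[k] + 1] - steps[k]
      H[, k] <- (gfun(up) - gfun(dn)) / (2 * steps[k])
    }
    H <- (H + t(H)) / 2
    if (is.null(sigma2)) {
      loss <- as.numeric(misfit_loss(model, datas, ibvp, cfg))
      n_res <- sum(vapply(datas, function(s) length(s$d), numeric(1)))
      sigma2 <- loss / max(n_res - p, 1)
    }
  } else {
    f0 <- objective(th0)
    for (k in seq_len(p)) {
      for (l in seq_len(k)) {
        ik <- active[k] + 1; il <- active[l] + 1
        if (k == l) {
          up <- th0; up[ik] <- up[ik] + steps[k]
          dn <- th0; dn[ik] <- dn[ik] - steps[k]
          H[k, k] <- (objective(up) - 2 * f0 + objective(dn)) / steps[k]^2
        } else {
          pp <- th0; pp[ik] <- pp[ik] + steps[k]; pp[il] <- pp[il] + steps[l]
          pm <- th0; pm[ik] <- pm[ik] + steps[k]; pm[il] <- pm[il] - steps[l]
          mp <- th0; mp[ik] <- mp[ik] - steps[k]; mp[il] <- mp[il] + steps[l]
          mm <- th0; mm[ik] <- mm[ik] - steps[k]; mm[il] <- mm[il] - steps[l]
          H[k, l] <- H[l, k] <-
            (objective(pp) - objective(pm) - objective(mp) + objective(mm)) /
            (4 * steps[k] * steps[l])
        }
      }
    }
    if (is.null(sigma2)) sigma2 <- 1
  }
  eg <- eigen(H, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  flat <- which(eg$values <= tol)
  if (length(flat)) {
    warning("Hessian not positive definite: using pseudo-inverse; ",
            length(flat), " flat direction(s) reported")
    inv_vals <- ifelse(eg$values > tol, 1 / eg$values, 0)
  } else inv_vals <- 1 / eg$values
  Hinv <- eg$vectors %*% (inv_vals * t(eg$vectors))
  cov <- 2 * sigma2 * Hinv
  cov <- (cov + t(cov)) / 2
  lbl <- theta_labels[active + 1]
  dimnames(cov) <- list(lbl, lbl)
  structure(list(theta = stats::setNames(th0[active + 1], lbl),
                 covariance = cov,
                 sd = stats::setNames(sqrt(pmax(diag(cov), 0)), lbl),
                 sigma2 = sigma2, hessian = H,
                 flat = if (length(flat))
                   eg$vectors[, flat, drop = FALSE] else NULL,
                 convention = "covariance = 2 * sigma2 * H^-1; sigma2 = misfit / residual dof"),
            class = "laplace_summary")
}

#' @export
print.laplace_summary <- function(x, ...) {
  cat("<laplace_summary>", x$convention, "\n")
  for (nm in names(x$theta))
    cat(sprintf("  %s = %.5g +- %.3g\n", nm, x$theta[nm], x$sd[nm]))
  if (!is.null(x$flat)) cat("  flat directions present (degenerate parameters)\n")
  invisible(x)
}

#' Carrying capacity of the logistic-type reaction
#'
#' The density at which the reaction \eqn{r(C) = \theta_6 C + \theta_7 C^2}
#' vanishes: \eqn{K = -\theta_6/\theta_7} (cells/um^2), the positive root of
#' the logistic form \eqn{r = \lambda C (1 - C/K)}. In the three-term model
#' notation (`C1 = theta6`, `C2 = theta7`) this is `-C1/C2`; note that some
#' reports write the same quantity with the coefficients in the opposite
#' order, which dimensional analysis of r(C) does not support.
#'
#' @param model an [adr_model()] with `theta6 > 0` and `theta7 < 0`.
#' @return carrying capacity K in cells/um^2.
#' @export
carrying_capacity <- function(model) {
  th6 <- model$theta[7]; th7 <- model$theta[8]
  if (th7 >= 0) stop("no finite carrying capacity (theta7 must be negative)")
  if (th6 <= 0) stop("no positive carrying capacity (theta6 must be positive)")
  as.numeric(-th6 / th7)
}
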