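theta_labels <- paste0("theta", 0:7)

#' Advection-diffusion-reaction model
#'
#' Parameter vector for the quadratic-ansatz ADR equation
#' \deqn{\partial C/\partial t = \nabla\cdot(D(C)\nabla C)
#'       - \nabla\cdot(C\,v_f(C)\,v_{unit}) + r(C)}
#' with \eqn{D(C) = \theta_0 + \theta_1 C + \theta_2 C^2} (um^2/hr and per
#' power of C), \eqn{v_f(C) = \theta_3 + \theta_4 C + \theta_5 C^2} (um/hr),
#' and \eqn{r(C) = \theta_6 C + \theta_7 C^2} (1/hr). A constant reaction
#' term is excluded by construction: proliferation or death at zero density
#' is unphysical. In the three-term reaction-diffusion notation used for
#' sensitivity scans, `D0 = theta0`, `C1 = theta6`, `C2 = theta7`.
#'
#' @param theta numeric vector of length 8 (theta0..theta7); entries outside
#'   `active` are forced to exactly zero.
#' @param active integer vector of active term indices, 0-based subset of
#'   0..7. Defaults to the indices of nonzero `theta` entries.
#' @param v_unit advection direction, a unit vector perpendicular to the
#'   wound (scalar +-1 for 1D); normalized on input.
#' @return object of class `adr_model`.
#' @export
adr_model <- function(theta = numeric(8), active = NULL, v_unit = 1) {
  stopifnot(length(theta) == 8)
  theta <- as.numeric(theta)
  if (is.null(active)) active <- which(theta != 0) - 1L
  active <- sort(unique(as.integer(active)))
  stopifnot(all(active >= 0), all(active <= 7))
  theta[setdiff(0:7, active) + 1] <- 0
  names(theta) <- theta_labels
  nv <- sqrt(sum(v_unit^2))
  if (nv == 0) stop("v_unit must be nonzero")
  structure(list(theta = theta, active = active, v_unit = v_unit / nv),
            class = "adr_model")
}

#' @export
print.adr_model <- function(x, ...) {
  th <- x$theta
  fmt <- function(i) sprintf("%s=%.4g", theta_labels[i + 1], th[i + 1])
  cat("<adr_model> active terms:",
      if (length(x$active)) paste(vapply(x$active, fmt, ""), collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  D(C) = %.4g + %.4g C + %.4g C^2  [um^2/hr]\n", th[1], th[2], th[3]))
  cat(sprintf("  v_f(C) = %.4g + %.4g C + %.4g C^2  [um/hr]\n", th[4], th[5], th[6]))
  cat(sprintf("  r(C) = %.4g C + %.4g C^2  [1/hr]\n", th[7], th[8]))
  invisible(x)
}

# ansatz evaluations and derivatives w.r.t. C
ansatz_D <- function(theta, C) theta[1] + theta[2] * C + theta[3] * C^2
ansatz_Dp <- function(theta, C) theta[2] + 2 * theta[3] * C
ansatz_vf <- function(theta, C) theta[4] + theta[5] * C + theta[6] * C^2
ansatz_vfp <- function(theta, C) theta[5] + 2 * theta[6] * C
ansatz_r <- function(theta, C) theta[7] * C + theta[8] * C^2
ansatz_rp <- function(theta, C) theta[7] + 2 * theta[8] * C

#' Write / read an ADR model as JSON
#'
#' `model.json` stores theta (with term labels and units), the active set,
#' the advection direction, and optionally the stepwise-regression loss path
#' and refined coefficients.
#'
#' @param model an [adr_model()]; extra fields (e.g. `loss_path`,
#'   `theta_refined`) may be attached as attributes by callers.
#' @param path file path.
#' @param extra optional named list merged into the JSON document.
#' @return `read_model` returns an [adr_model()]; extras are attached as
#'   attributes.
#' @export
write_model <- function(model, path, extra = NULL) {
  obj <- list(theta = as.list(model$theta), active = model$active,
              v_unit = model$v_unit,
              units = list(theta0 = "um^2/hr", theta1 = "um^4/(hr cell)",
                           theta2 = "um^6/(hr cell^2)", theta3 = "um/hr",
                           theta4 = "um^3/(hr cell)", theta5 = "um^5/(hr cell^2)",
                           theta6 = "1/hr", theta7 = "um^2/(hr cell)"))
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- adr_model(unlist(obj$theta), active = obj$active, v_unit = obj$v_unit)
  for (nm in setdiff(names(obj), c("theta", "active", "v_unit", "units")))
    attr(m, nm) <- obj[[nm]]
  m
}
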