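#' Gauss-Legendre quadrature rules
#'
#' Reference-element quadrature: an n-point Gauss-Legendre rule on the unit
#' segment \[0, 1\] or a 6-point degree-4 rule on the reference triangle
#' (points in barycentric coordinates, weights summing to one; physical
#' integrals multiply by the element measure). The default rules integrate
#' polynomials up to degree 4 exactly, one degree above the highest integrand
#' the quadratic-ansatz library produces, so quadrature error is removed from
#' the inference comparisons.
#'
#' @param dim 1 (segment) or 2 (triangle).
#' @param n number of points for `dim = 1` (1..4 supported).
#' @return list with `points` (matrix, rows = quadrature points, columns =
#'   barycentric/reference coordinates) and `weights` (summing to 1).
#' @export
quadrature_rule <- function(dim = 1, n = 3) {
  if (dim == 1) {
    gl <- switch(as.character(n),
      "1" = list(x = 0.5, w = 1),
      "2" = list(x = 0.5 + c(-1, 1) / (2 * sqrt(3)), w = c(0.5, 0.5)),
      "3" = list(x = 0.5 + c(-1, 0, 1) * sqrt(3 / 5) / 2,
                 w = c(5, 8, 5) / 18),
      "4" = {
        a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
        b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
        wa <- (18 + sqrt(30)) / 72; wb <- (18 - sqrt(30)) / 72
        list(x = 0.5 + c(-b, -a, a, b) / 2, w = c(wb, wa, wa, wb))
      },
      stop("unsupported 1D rule order"))
    # barycentric (1-xi, xi) so points behave like shape-function values
    list(points = cbind(1 - gl$x, gl$x), weights = gl$w)
  } else {
    # 6-point degree-4 rule on the triangle (weights sum to 1)
    a1 <- 0.445948490915965; w1 <- 0.223381589678011
    a2 <- 0.091576213509771; w2 <- 0.109951743655322
    pts <- rbind(
      c(1 - 2 * a1, a1, a1), c(a1, 1 - 2 * a1, a1), c(a1, a1, 1 - 2 * a1),
      c(1 - 2 * a2, a2, a2), c(a2, 1 - 2 * a2, a2), c(a2, a2, 1 - 2 * a2))
    list(points = pts, weights = c(w1, w1, w1, w2, w2, w2))
  }
}

#' Piecewise-linear finite-element mesh
#'
#' Builds a P1 Galerkin mesh: 1D segments from sorted node coordinates, or a
#' structured triangulation of a tensor grid (each grid cell split along the
#' lower-left to upper-right diagonal). The same basis serves trial and
#' weighting functions (Galerkin). Element shape-function gradients (constant
#' per element) and measures are precomputed.
#'
#' @param x1 node coordinates along x1 (um).
#' @param x2 node coordinates along x2 (um) for a 2D mesh, `NULL` for 1D.
#' @param quad optional quadrature rule; default [quadrature_rule()] for the
#'   mesh dimension.
#' @return object of class `fe_mesh` with nodes, elements, boundary node set,
#'   per-element gradients/measures and reference shape values at quadrature
#'   points.
#' @export
fe_mesh <- function(x1, x2 = NULL, quad = NULL) {
  if (is.null(x2)) {
    x1 <- sort(as.numeric(x1))
    n <- length(x1)
    if (n < 2) stop("need at least 2 nodes")
    nodes <- matrix(x1, ncol = 1)
    elements <- cbind(seq_len(n - 1), seq(2, n))
    h <- diff(x1)
    if (any(h <= 0)) stop("degenerate 1D element")
    grads <- array(0, dim = c(n - 1, 2, 1))
    grads[, 1, 1] <- -1 / h
    grads[, 2, 1] <- 1 / h
    measure <- h
    boundary <- c(1L, n)
    dim <- 1L
    grid <- list(x1 = x1)
  } else {
    x1 <- sort(as.numeric(x1)); x2 <- sort(as.numeric(x2))
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) stop("need at least 2 nodes per dimension")
    id <- function(i, j) i + (j - 1L) * n1
    nodes <- cbind(rep(x1, times = n2), rep(x2, each = n1))
    elems <- vector("list", 2 * (n1 - 1) * (n2 - 1))
    k <- 0
    for (j in seq_len(n2 - 1)) for (i in seq_len(n1 - 1)) {
      a <- id(i, j); b <- id(i + 1L, j); cc <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
      elems[[k + 1]] <- c(a, b, cc)   # diagonal a -> cc (lower-left to upper-right)
      elems[[k + 2]] <- c(a, cc, d)
      k <- k + 2
    }
    elements <- do.call(rbind, elems)
    nel <- nrow(elements)
    grads <- array(0, dim = c(nel, 3, 2))
    measure <- numeric(nel)
    for (e in seq_len(nel)) {
      p <- nodes[elements[e, ], , drop = FALSE]
      d21 <- p[2, ] - p[1, ]; d31 <- p[3, ] - p[1, ]
      detJ <- d21[1] * d31[2] - d21[2] * d31[1]
      if (detJ <= 0) stop("degenerate or inverted triangle")
      measure[e] <- detJ / 2
      # gradients of barycentric coordinates
      grads[e, 1, ] <- c(p[2, 2] - p[3, 2], p[3, 1] - p[2, 1]) / detJ
      grads[e, 2, ] <- c(p[3, 2] - p[1, 2], p[1, 1] - p[3, 1]) / detJ
      grads[e, 3, ] <- c(p[1, 2] - p[2, 2], p[2, 1] - p[1, 1]) / detJ
    }
    ii <- rep(seq_len(n1), times = n2); jj <- rep(seq_len(n2), each = n1)
    boundary <- which(ii == 1L | ii == n1 | jj == 1L | jj == n2)
    dim <- 2L
    grid <- list(x1 = x1, x2 = x2)
  }
  if (is.null(quad)) quad <- quadrature_rule(dim)
  # precomputed structure for vectorized whole-mesh assembly
  n <- nrow(nodes); nel <- nrow(elements); nloc <- ncol(elements)
  Nq <- quad$points; wq <- quad$weights; nq <- length(wq)
  wNq <- wq * Nq                        # nq x nloc
  Mref <- t(Nq) %*% wNq                 # reference local mass (unit measure)
  NNw <- matrix(0, nq, nloc * nloc)     # wq * N_a * N_b, ab column-major
  for (b in seq_len(nloc)) for (a in seq_len(nloc))
    NNw[, (b - 1) * nloc + a] <- wq * Nq[, a] * Nq[, b]
  GG <- matrix(0, nel, nloc * nloc)     # grad N_a . grad N_b per element
  for (b in seq_len(nloc)) for (a in seq_len(nloc))
    GG[, (b - 1) * nloc + a] <-
      rowSums(matrix(grads[, a, ], nel) * matrix(grads[, b, ], nel))
  idxR <- as.vector(elements)
  idxJ <- integer(nel * nloc * nloc)
  for (b in seq_len(nloc)) for (a in seq_len(nloc))
    idxJ[((b - 1) * nloc + a - 1) * nel + seq_len(nel)] <-
      (elements[, b] - 1L) * n + elements[, a]
  mesh <- structure(list(dim = dim, nodes = nodes, elements = elements,
                 boundary = as.integer(boundary),
                 interior = setdiff(seq_len(n), boundary),
                 n_nodes = n, n_el = nel, n_loc = nloc,
                 grads = grads, measure = measure,
                 quad = quad, Nq = Nq, wq = wq, wNq = wNq,
                 Mref = Mref, NNw = NNw, GG = GG,
                 idxR = idxR, uR = sort(unique(idxR)),
                 idxJ = idxJ, uJ = sort(unique(idxJ)),
                 grid = grid),
            class = "fe_mesh")
  mesh$mass <- assemble_mass(mesh)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %dD, %d nodes, %d elements, %d boundary nodes\n",
              x$dim, x$n_nodes, x$n_el, length(x$boundary)))
  invisible(x)
}

#' Time-indexed nodal field
#'
#' Nodal coefficients \eqn{d_i(t_j)} on a mesh, defining the interpolant
#' \eqn{C^h(x, t_j) = \sum_i d_i(t_j) N_i(x)}.
#'
#' @param mesh an [fe_mesh()].
#' @param t frame times (hr), strictly increasing.
#' @param d `n_nodes x length(t)` matrix of nodal densities (cells/um^2).
#' @return object of class `nodal_series`.
#' @export
nodal_series <- function(mesh, t, d) {
  d <- matrix(d, nrow = mesh$n_nodes)
  stopifnot(ncol(d) == length(t), all(is.finite(d)))
  if (length(t) > 1 && is.unsorted(t, strictly = TRUE))
    stop("frame times must be strictly increasing")
  structure(list(mesh = mesh, t = as.numeric(t), d = d),
            class = "nodal_series")
}

#' Build a mesh and nodal field from a binned density field
#'
#' Places finite-element nodes at the bin centers so the nodal coefficients
#' equal the field values, `d_i(t) = C(x_i, t)`. 1D fields yield segment
#' meshes; 2D fields a structured triangulation (two triangles per grid
#' cell, consistent lower-left to upper-right diagonal).
#'
#' @param field a [density_field()].
#' @return list with `mesh` ([fe_mesh()]) and `series` ([nodal_series()]).
#' @export
build_mesh_from_field <- function(field) {
  if (is_1d_field(field)) {
    if (length(field$x1) < 3) stop("need at least 3 grid points")
    mesh <- fe_mesh(field$x1)
    d <- field$C
  } else {
    if (length(field$x1) < 3 || length(field$x2) < 3)
      stop("need at least 3 grid points per dimension")
    mesh <- fe_mesh(field$x1, field$x2)
    nt <- length(field$t)
    d <- matrix(0, mesh$n_nodes, nt)
    for (k in seq_len(nt)) d[, k] <- as.vector(field$C[, , k])
  }
  list(mesh = mesh, series = nodal_series(mesh, field$t, d))
}

# locate the element containing x; returns list(e, N) with shape values
locate_point <- function(mesh, x) {
  x <- as.numeric(x)
  if (mesh$dim == 1) {
    g <- mesh$grid$x1
    if (x < g[1] - 1e-9 || x > g[length(g)] + 1e-9) stop("point outside mesh")
    e <- min(max(findInterval(x, g, rightmost.closed = TRUE), 1), mesh$n_el)
    xi <- (x - g[e]) / (g[e + 1] - g[e])
    list(e = e, N = c(1 - xi, xi))
  } else {
    g1 <- mesh$grid$x1; g2 <- mesh$grid$x2
    n1 <- length(g1); n2 <- length(g2)
    if (x[1] < g1[1] - 1e-9 || x[1] > g1[n1] + 1e-9 ||
        x[2] < g2[1] - 1e-9 || x[2] > g2[n2] + 1e-9) stop("point outside mesh")
    i <- min(max(findInterval(x[1], g1, rightmost.closed = TRUE), 1), n1 - 1)
    j <- min(max(findInterval(x[2], g2, rightmost.closed = TRUE), 1), n2 - 1)
    xi <- (x[1] - g1[i]) / (g1[i + 1] - g1[i])
    eta <- (x[2] - g2[j]) / (g2[j + 1] - g2[j])
    cell <- 2 * ((j - 1) * (n1 - 1) + (i - 1))
    if (eta <= xi) {  # lower triangle (a, b, c)
      e <- cell + 1
      N <- c(1 - xi, xi - eta, eta)
    } else {          # upper triangle (a, c, d)
      e <- cell + 2
      N <- c(1 - eta, xi, eta - xi)
    }
    list(e = e, N = N)
  }
}

#' Evaluate a nodal field (and its gradient) at a point
#'
#' @param series a [nodal_series()].
#' @param x evaluation point (um); scalar for 1D, length-2 for 2D. Must lie
#'   inside the mesh.
#' @param t_index frame index.
#' @return list with `value` (cells/um^2) and `gradient` (constant per
#'   element for linear elements).
#' @export
eval_field <- function(series, x, t_index = 1) {
  mesh <- series$mesh
  loc <- locate_point(mesh, x)
  de <- series$d[mesh$elements[loc$e, ], t_index]
  ge <- matrix(mesh$grads[loc$e, , ], nrow = dim(mesh$grads)[2])  # nloc x dim
  grad <- as.vector(t(ge) %*% de)
  list(value = sum(loc$N * de), gradient = grad)
}

#' Integrate a function over one element by quadrature
#'
#' @param mesh an [fe_mesh()].
#' @param e element index.
#' @param f integrand: function of the physical coordinate (scalar for 1D,
#'   length-2 numeric for 2D) returning a scalar.
#' @param rule optional quadrature rule (default: the mesh rule).
#' @return the quadrature approximation of the element integral.
#' @export
element_integrate <- function(mesh, e, f, rule = NULL) {
  if (is.null(rule)) rule <- mesh$quad
  if (mesh$measure[e] <= 0) stop("degenerate element")
  p <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
  xq <- rule$points %*% p   # barycentric -> physical
  vals <- apply(xq, 1, function(row) f(as.numeric(row)))
  mesh$measure[e] * sum(rule$weights * vals)
}

#' Backward-Euler time derivative of a nodal field
#'
#' Per-node backward differences `(d(t_j) - d(t_{j-1})) / (t_j - t_{j-1})`,
#' defined at frames 2..M (the first frame has no predecessor).
#'
#' @param series a [nodal_series()] with at least 2 frames.
#' @return a `nodal_series` of derivative values with frame times `t[-1]`.
#' @export
time_derivative <- function(series) {
  t <- series$t
  if (length(t) < 2) stop("need at least 2 frames")
  dt <- diff(t)
  if (any(dt <= 0)) stop("frame times must be strictly increasing")
  dd <- sweep(series$d[, -1, drop = FALSE] - series$d[, -ncol(series$d), drop = FALSE],
              2, dt, "/")
  nodal_series(series$mesh, t[-1], dd)
}

# scatter element-wise contributions (nel x nloc flat) into a nodal vector
scatter_vec <- function(mesh, contrib) {
  n <- mesh$n_nodes
  if (mesh$dim == 1L) {
    # segment elements: column a touches nodes a..(n-2+a), no duplicates
    out <- numeric(n)
    out[seq_len(n - 1)] <- contrib[, 1]
    out[2:n] <- out[2:n] + contrib[, 2]
    return(out)
  }
  out <- numeric(n)
  acc <- rowsum(as.vector(contrib), mesh$idxR, reorder = TRUE)
  out[mesh$uR] <- acc
  out
}

# scatter element-wise pair contributions (nel x nloc^2 flat) into a matrix
scatter_mat <- function(mesh, contrib) {
  n <- mesh$n_nodes
  if (mesh$dim == 1L) {
    e <- seq_len(n - 1)
    out <- numeric(n * n)
    l11 <- (e - 1) * n + e
    l21 <- (e - 1) * n + e + 1
    l12 <- e * n + e
    l22 <- e * n + e + 1
    out[l11] <- contrib[, 1]
    out[l21] <- contrib[, 2]
    out[l12] <- contrib[, 3]
    out[l22] <- out[l22] + contrib[, 4]
    return(matrix(out, n, n))
  }
  out <- numeric(n^2)
  acc <- rowsum(as.vector(contrib), mesh$idxJ, reorder = TRUE)
  out[mesh$uJ] <- acc
  matrix(out, n, n)
}

# consistent (non-lumped) P1 mass matrix, dense (cached on the mesh)
assemble_mass <- function(mesh) {
  if (!is.null(mesh$mass)) return(mesh$mass)
  scatter_mat(mesh, outer(mesh$measure, as.vector(mesh$Mref)))
}
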