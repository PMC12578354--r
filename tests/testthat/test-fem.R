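test_that("meshes built from fields have the expected elements and reproduce nodal data", {
  f <- density_field((1:43 - 0.5) * 50, c(0, 12), matrix(1e-3, 43, 2),
                     bin_size = 50, strip_width = 100)
  mf <- build_mesh_from_field(f)
  expect_equal(mf$mesh$n_el, 42)
  expect_equal(mf$mesh$boundary, c(1L, 43L))

  f2 <- density_field((1:3 - 0.5) * 100, 0,
                      array(runif(9), c(3, 3, 1)), x2 = (1:3 - 0.5) * 100,
                      bin_size = 100)
  mf2 <- build_mesh_from_field(f2)
  expect_equal(mf2$mesh$n_el, 8)      # 2 triangles per grid cell
  expect_equal(sum(mf2$mesh$measure), 200 * 200)  # total area exact

  # interpolation identity: nodal values equal field values
  for (k in seq_len(mf2$mesh$n_nodes)) {
    v <- eval_field(mf2$series, mf2$mesh$nodes[k, ], 1)
    expect_equal(v$value, mf2$series$d[k, 1], tolerance = 1e-12)
  }
  expect_error(build_mesh_from_field(
    density_field(c(50, 150), 0, matrix(1, 2, 1), bin_size = 100)),
    "at least 3")
})

test_that("shape functions are a partition of unity and reproduce linear fields exactly", {
  set.seed(21)
  mesh1 <- fe_mesh(sort(runif(12, 0, 1000)))
  mesh2 <- fe_mesh(seq(0, 400, by = 100), seq(0, 300, by = 100))
  for (mesh in list(mesh1, mesh2)) {
    ones <- nodal_series(mesh, 0, matrix(1, mesh$n_nodes, 1))
    lin_coef <- c(0.3, -0.02, 0.05)
    lin <- function(x) lin_coef[1] + sum(lin_coef[1 + seq_along(x)] * x)
    linser <- nodal_series(mesh, 0,
                           matrix(apply(mesh$nodes, 1, lin), ncol = 1))
    for (i in 1:100) {
      x <- vapply(seq_len(mesh$dim), function(k)
        runif(1, min(mesh$nodes[, k]), max(mesh$nodes[, k])), numeric(1))
      u <- eval_field(ones, x, 1)
      expect_equal(u$value, 1, tolerance = 1e-12)
      expect_equal(max(abs(u$gradient)), 0, tolerance = 1e-12)
      v <- eval_field(linser, x, 1)
      expect_equal(v$value, lin(x), tolerance = 1e-10)
      expect_equal(v$gradient, lin_coef[1 + seq_len(mesh$dim)],
                   tolerance = 1e-10)
    }
  }
  # midpoint of a 1D element averages the end values
  m <- fe_mesh(c(0, 100))
  s <- nodal_series(m, 0, matrix(c(2, 6), 2, 1))
  expect_equal(eval_field(s, 50, 1)$value, 4)
  expect_error(eval_field(s, 120, 1), "outside")
})

test_that("element quadrature integrates to its declared degree", {
  mesh <- fe_mesh(c(0, 75, 200))
  expect_equal(element_integrate(mesh, 1, function(x) 1), 75)
  # 2-point Gauss integrates x exactly on [0, 1]
  m01 <- fe_mesh(c(0, 1))
  expect_equal(element_integrate(m01, 1, function(x) x,
                                 rule = quadrature_rule(1, 2)), 0.5)
  # random cubics on random triangles vs the barycentric monomial closed form
  # int L1^a L2^b L3^c dA = 2A a! b! c! / (a+b+c+2)!
  set.seed(31)
  for (rep in 1:5) {
    p <- matrix(runif(6, 0, 100), 3, 2)
    if ((p[2,1]-p[1,1])*(p[3,2]-p[1,2]) - (p[2,2]-p[1,2])*(p[3,1]-p[1,1]) < 0)
      p <- p[c(1, 3, 2), ]
    tri <- fe_mesh(c(0, 1), c(0, 1))  # container for the rule only
    rule <- quadrature_rule(2)
    A <- abs((p[2,1]-p[1,1])*(p[3,2]-p[1,2]) -
             (p[2,2]-p[1,2])*(p[3,1]-p[1,1])) / 2
    pow <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
    pow <- pow[rowSums(pow) <= 3, ]
    coef <- rnorm(nrow(pow))
    exact <- sum(coef * 2 * A * factorial(pow$a) * factorial(pow$b) *
                   factorial(pow$c) / factorial(pow$a + pow$b + pow$c + 2))
    quad <- A * sum(rule$weights * vapply(seq_along(rule$weights), function(q) {
      L <- rule$points[q, ]
      sum(coef * L[1]^pow$a * L[2]^pow$b * L[3]^pow$c)
    }, numeric(1)))
    expect_lt(abs(quad - exact), 1e-10 * max(1, abs(exact)))
  }
})

test_that("the local mass matrix matches its closed form", {
  mesh <- fe_mesh(c(0, 60))
  M <- scratchpde:::assemble_mass(mesh)
  h <- 60
  expect_lt(max(abs(M - h / 6 * matrix(c(2, 1, 1, 2), 2, 2))), 1e-12)
})

test_that("backward-Euler time derivatives are exact on linear data and first order otherwise", {
  mesh <- fe_mesh(c(0, 100, 200))
  t <- c(0, 2, 5, 9)
  d <- outer(c(1, 2, 3), t, function(a, tt) a + 0.5 * tt)
  dd <- time_derivative(nodal_series(mesh, t, d))
  expect_equal(dd$t, t[-1])
  expect_true(all(abs(dd$d - 0.5) < 1e-12))
  dc <- time_derivative(nodal_series(mesh, t, matrix(3, 3, 4)))
  expect_true(all(dc$d == 0))

  # d = t^2: error of the backward difference halves with the step
  err_at <- function(dt) {
    tt <- seq(0, 1, by = dt)
    s <- nodal_series(mesh, tt, matrix(rep(tt^2, each = 3), 3))
    max(abs(time_derivative(s)$d[1, ] - 2 * tt[-1]))
  }
  expect_equal(err_at(0.1) / err_at(0.05), 2, tolerance = 1e-8)
  expect_error(time_derivative(nodal_series(mesh, 5, matrix(1, 3, 1))),
               "at least 2")
})
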