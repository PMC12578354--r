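test_that("weak-form library entries vanish or reduce to hand-assembled values on constant fields", {
  h <- 100
  mesh <- fe_mesh(c(0, h, 2 * h))
  cval <- 1.3e-3
  # constant in space and time
  ser <- nodal_series(mesh, c(0, 12), matrix(cval, 3, 2))
  sys <- build_library(ser)
  expect_equal(nrow(sys$Xi), 1)          # one interior node, one frame pair
  expect_equal(unname(sys$Xi[1, 1:3]), c(0, 0, 0))        # grad C = 0
  expect_equal(unname(sys$Xi[1, 4]), 0)                   # symmetry
  expect_equal(unname(sys$Xi[1, 7]), -cval * h)           # -c int N_k
  expect_equal(sys$y, 0)                                  # time-constant
})

test_that("least squares solves exact, degenerate, and random systems correctly", {
  sys <- random_system(n = 200, seed = 42)
  # consistent system: y = Xi theta_true
  theta_true <- c(2, 0, 0, 0, 0, 0, -1, 0.5)
  sysc <- sys; sysc$y <- as.vector(sys$Xi[, c(1, 7, 8)] %*%
                                     theta_true[c(1, 7, 8)])
  fit <- solve_ls(sysc, c(0, 6, 7))
  expect_lt(fit$loss, 1e-20 * sum(sysc$y^2))
  expect_rel_equal(fit$theta[c(1, 7, 8)], theta_true[c(1, 7, 8)], 1e-8)

  # y orthogonal to the active columns -> zero fit, full loss
  A <- sys$Xi[, 1:3]
  yo <- residuals(lm.fit(A, rnorm(200)))
  syso <- sys; syso$y <- yo
  fito <- solve_ls(syso, 0:2)
  expect_lt(max(abs(fito$theta)), 1e-10)
  expect_equal(fito$loss, sum(yo^2), tolerance = 1e-10)

  # empty active set
  fe <- solve_ls(sys, integer(0))
  expect_equal(fe$loss, sum(sys$y^2))

  # rank-deficient columns fall back to the minimum-norm solution
  sysr <- sys; sysr$Xi[, 2] <- sysr$Xi[, 1]
  fr <- solve_ls(sysr, 0:1)
  expect_true(fr$rank_deficient)
  expect_equal(unname(fr$theta[1]), unname(fr$theta[2]), tolerance = 1e-8)

  # random systems against the explicit normal-equations oracle
  for (s in 1:5) {
    sy <- random_system(seed = 100 + s)
    fit <- solve_ls(sy, 0:7)
    oracle <- solve(crossprod(sy$Xi), crossprod(sy$Xi, sy$y))
    expect_rel_equal(unname(fit$theta), as.vector(oracle), 1e-8)
  }
})

test_that("column scaling leaves the loss unchanged and rescales the coefficient", {
  sys <- random_system(seed = 8)
  fit <- solve_ls(sys, 0:7)
  for (alpha in c(0.01, 3, 1e4)) {
    sys2 <- sys; sys2$Xi[, 4] <- alpha * sys$Xi[, 4]
    fit2 <- solve_ls(sys2, 0:7)
    expect_equal(fit2$loss, fit$loss, tolerance = 1e-10)
    expect_equal(unname(fit2$theta[4]), unname(fit$theta[4]) / alpha,
                 tolerance = 1e-8)
  }
})

test_that("stacking replicate systems equals minimizing the summed loss", {
  s1 <- random_system(seed = 1); s2 <- random_system(seed = 2)
  st <- stack_libraries(list(s1, s2))
  fit <- solve_ls(st, 0:7)
  # stacked loss at the optimum equals the sum of per-replicate losses there
  l1 <- sum((s1$y - s1$Xi %*% fit$theta)^2)
  l2 <- sum((s2$y - s2$Xi %*% fit$theta)^2)
  expect_equal(fit$loss, l1 + l2, tolerance = 1e-10)
  # and matches the normal equations of the concatenated system
  Xs <- rbind(s1$Xi, s2$Xi); ys <- c(s1$y, s2$y)
  oracle <- solve(crossprod(Xs), crossprod(Xs, ys))
  expect_rel_equal(unname(fit$theta), as.vector(oracle), 1e-8)
  expect_equal(unique(st$blocks$replicate), c(1L, 2L))
})

test_that("greedy elimination matches the exhaustive oracle with nondecreasing losses", {
  for (s in 1:6) {
    sys <- random_system(seed = 200 + s)
    res <- stepwise_regression(sys, tie_level = NULL)
    orc <- greedy_oracle(sys)
    for (k in seq_along(orc)) {
      expect_equal(res$path[[k]]$active, orc[[k]]$active)
      expect_equal(res$losses[k], orc[[k]]$loss, tolerance = 1e-9)
    }
    expect_true(all(diff(res$losses) >= -1e-10 * max(res$losses)))
    # eliminating any column never decreases the loss (nested LS), each step
    for (k in seq_len(length(res$path) - 1)) {
      act <- res$path[[k]]$active
      for (i in act)
        expect_gte(solve_ls(sys, setdiff(act, i))$loss,
                   res$losses[k] - 1e-10 * max(1, res$losses[k]))
    }
  }
})

test_that("stepwise regression recovers a planted sparse support", {
  set.seed(77)
  sys <- random_system(n = 300, seed = 77)
  theta_true <- numeric(8); theta_true[c(1, 7, 8)] <- c(3, -2, 1)
  sys$y <- as.vector(sys$Xi %*% theta_true) + rnorm(300, sd = 1e-6)
  res <- stepwise_regression(sys)
  expect_equal(res$path[[6]]$active, c(0, 6, 7))   # 3-term step
  expect_equal(select_model(res, 0.05), c(0, 6, 7))
})

test_that("elbow selection follows the loss-threshold contract", {
  fake <- structure(list(
    path = lapply(8:1, function(k) list(active = seq_len(k) - 1,
                                        theta = numeric(8), loss = NA)),
    n_terms = 8:1,
    losses = c(1, 1, 1, 1, 1, 1, 5, 40),
    ynorm2 = 1e6, sigma2 = 1 / 1e4, n_rows = 1e4),
    class = "vsi_result")
  expect_length(select_model(fake, 0.1), 3)
  expect_length(select_model(fake, 1e9), 1)
})

test_that("midpoint-scheme identification converges to the truth under time refinement", {
  # data resolution refined at a fixed 4-hr derivative span: the recovered
  # coefficients approach the generating values as the solver step shrinks
  mesh <- fe_mesh((seq_len(11) - 0.5) * 100)
  spec <- synthetic_spec(domain_length = 1100, bin_size = 100, seed = 2)
  ic <- scratch_initial_condition(spec, mesh)
  truth <- adr_model(spec$theta, spec$active)
  theta_true <- c(30, 0.05, -30)
  err_at <- function(h) {
    ser <- solve_forward(truth, ibvp_spec(ic$d[, 1], seq(0, 24, by = h)),
                         mesh)
    fit <- solve_ls(build_library(ser, stride = as.integer(4 / h),
                                  scheme = "midpoint"), c(0, 6, 7))
    max(abs(fit$theta[c(1, 7, 8)] - theta_true) / abs(theta_true))
  }
  e1 <- err_at(1); e2 <- err_at(0.5); e3 <- err_at(0.125)
  expect_lt(e2, e1)
  expect_lt(e3, e2)
  expect_lt(e3, 0.01)
})

test_that("backward-scheme library closes exactly on solver-generated data", {
  fx <- small_fixture()
  sys <- build_library(fx$series)
  fit <- solve_ls(sys, c(0, 6, 7))
  expect_rel_equal(fit$theta[c(1, 7, 8)], fx$theta_true[c(1, 7, 8)], 1e-6)
  res <- stepwise_regression(sys)
  expect_equal(select_model(res, 0.05), c(0, 6, 7))
  # loss-path CSV round trip
  p <- tempfile(fileext = ".csv")
  write_loss_path(res, p)
  df <- read.csv(p)
  expect_equal(df$n_terms, 8:1)
  expect_equal(df$loss, res$losses, tolerance = 1e-12)
})
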