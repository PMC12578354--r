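# shared fixtures, memoized across test files
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# noise-free closure fixture: truth {theta0=30, theta6=0.05, theta7=-30} on a
# 42-element 1D mesh, hourly frames over 48 h, generated by the implicit
# solver itself so the weak-form library closes exactly
closure_fixture <- function() {
  cached("closure", {
    spec <- synthetic_spec(domain_length = 2150, bin_size = 50, seed = 1)
    mesh <- fe_mesh((seq_len(43) - 0.5) * 50)
    ic <- scratch_initial_condition(spec, mesh)
    truth <- adr_model(spec$theta, spec$active)
    times <- seq(0, 48, by = 1)
    series <- solve_forward(truth, ibvp_spec(ic$d[, 1], times), mesh)
    list(spec = spec, mesh = mesh, truth = truth, series = series,
         theta_true = spec$theta)
  })
}

# small, fast self-consistent dataset for refinement/uncertainty unit tests
small_fixture <- function() {
  cached("small", {
    mesh <- fe_mesh((seq_len(11) - 0.5) * 100)
    spec <- synthetic_spec(domain_length = 1100, bin_size = 100, seed = 2)
    ic <- scratch_initial_condition(spec, mesh)
    truth <- adr_model(spec$theta, spec$active)
    times <- seq(0, 24, by = 2)
    series <- solve_forward(truth, ibvp_spec(ic$d[, 1], times), mesh)
    list(mesh = mesh, truth = truth, series = series,
         theta_true = spec$theta)
  })
}

# random well-conditioned regression system in library_system form
random_system <- function(n = 200, seed = 1, sd_y = 1) {
  set.seed(seed)
  Xi <- matrix(rnorm(n * 8), n, 8)
  colnames(Xi) <- paste0("Xi", 0:7)
  structure(list(y = rnorm(n, sd = sd_y), Xi = Xi,
                 blocks = data.frame(frame = 1L, node = seq_len(n),
                                     replicate = 1L),
                 v_unit = 1),
            class = "library_system")
}

# independent greedy backward-elimination oracle (numerical tie window only)
greedy_oracle <- function(system) {
  loss_of <- function(active) {
    if (!length(active)) return(sum(system$y^2))
    A <- system$Xi[, active + 1, drop = FALSE]
    sum(qr.resid(qr(A), system$y)^2)
  }
  active <- 0:7
  path <- list(list(active = active, loss = loss_of(active)))
  while (length(active) > 1) {
    ls <- vapply(active, function(i) loss_of(setdiff(active, i)), numeric(1))
    tied <- active[ls <= min(ls) + 1e-12 * max(min(ls), 1e-300)]
    active <- setdiff(active, max(tied))
    path[[length(path) + 1]] <- list(active = active, loss = loss_of(active))
  }
  path
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
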