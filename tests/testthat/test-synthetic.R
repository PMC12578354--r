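test_that("the scratch initial condition has the declared geometry", {
  spec <- synthetic_spec()
  mesh <- fe_mesh((seq_len(40) - 0.5) * 50)
  ic <- scratch_initial_condition(spec, mesh)
  x <- mesh$nodes[, 1]
  far <- ic$d[x < 200 | x > 1800, 1]
  expect_lt(max(abs(far - spec$plateau) / spec$plateau), 1e-6)
  expect_lt(ic$d[which.min(abs(x - 1000)), 1], 0.01 * spec$plateau)
  # full width at half plateau ~ scratch width (root-find on the profile)
  prof <- approxfun(x, ic$d[, 1] - spec$plateau / 2)
  left <- uniroot(prof, c(200, 1000))$root
  right <- uniroot(prof, c(1000, 1800))$root
  expect_lt(abs((right - left) - spec$scratch_width), 0.05 * spec$scratch_width)
})

test_that("dataset generation is deterministic and Poisson counts match their intensity", {
  spec <- synthetic_spec(seed = 9, n_replicates = 2, horizon = 2)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$centroids, d2$centroids)

  # expected count per bin = C * bin area (averaged over replicate draws)
  spec <- synthetic_spec(seed = 4, n_replicates = 60, horizon = 1 / 3)
  ds <- generate_dataset(spec)
  lam <- ds$field$C[, 1] * spec$bin_size * spec$strip_width
  counts <- sapply(ds$centroids, function(tab) {
    tab0 <- tab[tab$t == 0, ]
    tabulate(floor(tab0$x1 / spec$bin_size) + 1, nbins = 20)
  })
  mu <- rowMeans(counts)
  se <- sqrt(lam / ncol(counts))
  ok <- abs(mu - lam) <= 3 * se + 1e-9
  expect_gt(mean(ok), 0.95)

  # zero plateau -> empty tables
  z <- generate_dataset(synthetic_spec(plateau = 0, seed = 1, horizon = 2))
  expect_true(all(vapply(z$centroids, nrow, 0L) == 0))
})

test_that("gaussian observation mode perturbs fields without going negative", {
  spec <- synthetic_spec(seed = 2, n_replicates = 2, horizon = 2)
  ds <- generate_dataset(spec, noise = "gaussian", sigma = 2e-4)
  expect_length(ds$fields, 2)
  expect_true(all(ds$fields[[1]]$C >= 0))
  expect_gt(sd(ds$fields[[1]]$C - ds$field$C), 1e-4)
  expect_error(generate_dataset(spec, noise = "gaussian"), "sigma")
})

test_that("the seeding-density profile series matches its stated regime", {
  jset <- cached("jinset", jin_like_profile_set(seed = 1))
  plat <- vapply(jset, function(d) d$spec$plateau, numeric(1))
  expect_true(all(diff(plat) > 0))
  expect_equal(vapply(jset, function(d) d$spec$frame_interval, numeric(1)),
               rep(12, 6))
  # far-field growth of the first dataset follows exp(theta6 * t)
  d1 <- jset[[1]]
  ff <- d1$field$C[3, ]
  expect_equal(ff[5] / ff[1], exp(0.036 * 48), tolerance = 0.02)
  # densities stay in the observed experimental regime
  expect_true(all(vapply(jset, function(d) max(d$field$C), numeric(1)) <= 2e-3))
})

test_that("noise-free profile datasets identify their generating operators", {
  jset <- cached("jinset", jin_like_profile_set(seed = 1))
  for (ds in jset) {
    ser <- build_mesh_from_field(ds$field)$series
    sw <- stepwise_regression(build_library(ser))
    k <- length(ds$truth$active)
    expect_setequal(sw$path[[9 - k]]$active, ds$truth$active)
  }
})

test_that("the full pipeline on one noisy dataset recovers the generating model", {
  out <- cached("pipe1", scratch_pipeline(generate_dataset(synthetic_spec(seed = 1))))
  expect_true(all(c(0, 6, 7) %in% out$active))
  th <- out$refined$theta_refined
  expect_lt(abs(th[7] - 0.05) / 0.05, 0.15)
  expect_lt(abs(th[1] - 30) / 30, 0.5)
  expect_true(all(diff(out$refined$misfit_trajectory) <= 0))
  expect_lte(out$refined$final_loss, out$refined$initial_loss)
})

test_that("2D generation produces consistent fields, centroids, and libraries", {
  spec <- synthetic_spec(dims = 2, strip_width = 600, horizon = 4,
                         n_replicates = 2, seed = 3)
  ds <- generate_dataset(spec)
  expect_equal(dim(ds$field$C), c(20, 6, 13))
  tab <- ds$centroids[[1]]
  f <- bin_centroids(tab, 100, list(x1 = c(0, 2000), x2 = c(0, 600)),
                     dims = 2)
  # binning the sampled centroids recovers the frame-wise counts exactly
  for (k in c(1, 13))
    expect_equal(sum(f$C[, , k]) * 100^2, sum(tab$t == ds$field$t[k]))
  # collapsing commutes with replicate structure and keeps units
  f1 <- collapse_to_1d(f)
  expect_equal(dim(f1$C), c(20, 13))
  # 2D weak-form library assembles with interior rows only
  mf <- build_mesh_from_field(ds$field)
  sys <- build_library(mf$series, v_unit = c(1, 0))
  expect_equal(nrow(sys$Xi), length(mf$mesh$interior) * 12)
  expect_true(all(is.finite(sys$Xi)), all(is.finite(sys$y)))
})

test_that("models round-trip through model.json", {
  m <- adr_model(c(30, 0, 0, 0, 0, 0, 0.05, -30), c(0, 6, 7))
  p <- tempfile(fileext = ".json")
  write_model(m, p, extra = list(loss_path = c(1, 2, 3)))
  m2 <- read_model(p)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$active, m$active)
  expect_equal(attr(m2, "loss_path"), c(1, 2, 3))
})
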