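test_that("binning turns counts into densities and conserves cell counts", {
  domain <- list(x1 = c(0, 100), x2 = c(0, 100))
  tab <- data.frame(x1 = c(10, 20, 30, 40), x2 = c(10, 20, 30, 40),
                    t = 0, replicate = 1L)
  f <- bin_centroids(tab, 100, domain, dims = 2)
  expect_equal(as.numeric(f$C[1, 1, 1]), 4e-4)

  # empty bins stay zero; counts conserved exactly at each frame (2D)
  set.seed(7)
  domain <- list(x1 = c(0, 500), x2 = c(0, 300))
  tab <- data.frame(x1 = runif(137, 0, 500), x2 = runif(137, 0, 300),
                    t = rep(c(0, 12), c(70, 67)), replicate = 1L)
  f <- bin_centroids(tab, 100, domain, dims = 2)
  expect_equal(sum(f$C[, , 1]) * 100^2, 70)
  expect_equal(sum(f$C[, , 2]) * 100^2, 67)

  # 1D: count / (bin_size * strip width), conservation again exact
  f1 <- bin_centroids(tab, 100, domain, dims = 1)
  expect_equal(f1$strip_width, 300)
  expect_equal(sum(f1$C[, 1]) * 100 * 300, 70)

  expect_error(bin_centroids(data.frame(x1 = 600, x2 = 1, t = 0,
                                        replicate = 1L),
                             100, domain, dims = 1), "outside")
  expect_warning(
    fz <- bin_centroids(tab[0, ], 100, domain, dims = 1), "empty")
  expect_true(all(fz$C == 0))
})

test_that("homogeneous Poisson samples bin to their intensity", {
  lambda <- 1e-3
  means <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    n <- rpois(1, lambda * 1000 * 1000)
    tab <- data.frame(x1 = runif(n, 0, 1000), x2 = runif(n, 0, 1000),
                      t = 0, replicate = 1L)
    f <- bin_centroids(tab, 100, list(x1 = c(0, 1000), x2 = c(0, 1000)),
                       dims = 2)
    mean(f$C)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - lambda), 3 * se + 1e-12)
})

test_that("moving-average smoothing averages, shrinks at edges, and is inert below grid scale", {
  # constant field unchanged (exactly)
  f <- density_field(x1 = (1:20 - 0.5) * 50, t = c(0, 1, 2),
                     C = matrix(2e-3, 20, 3), bin_size = 50)
  fs <- smooth_field(f, 150, 5)
  expect_equal(fs$C, f$C)
  expect_equal(fs$smooth$spatial_um, 150)

  # interior unit spike divided by the window length (spatial only)
  C <- matrix(0, 20, 1); C[10, 1] <- 1
  f <- density_field((1:20 - 0.5) * 50, 0, C, bin_size = 50)
  fs <- suppressWarnings(smooth_field(f, 150, 1))  # 3-bin window, inert time
  expect_equal(fs$C[10, 1], 1 / 3)
  expect_equal(fs$C[9, 1], 1 / 3)
  expect_equal(fs$C[12, 1], 0)

  # window below one grid spacing -> identity with a warning
  w <- capture_warnings(fid <- smooth_field(f, 10, 1))
  expect_true(any(grepl("spatial window .* smaller than grid spacing", w)))
  expect_equal(fid$C, f$C)

  # i.i.d. noise variance shrinks by the product of window lengths
  set.seed(11)
  C <- matrix(abs(rnorm(200 * 50, 1, 0.2)), 200, 50)
  f <- density_field((1:200 - 0.5) * 50, 0:49, C, bin_size = 50)
  fs <- smooth_field(f, 150, 3)  # 3 x 3 windows
  interior <- fs$C[20:180, 10:40]
  ratio <- var(as.vector(interior)) / var(as.vector(C))
  expect_gt(ratio, 1 / 9 * 0.7)
  expect_lt(ratio, 1 / 9 * 1.5)
})

test_that("collapsing to 1D averages along the scratch direction", {
  set.seed(3)
  C <- array(runif(8 * 5 * 3), dim = c(8, 5, 3))
  f <- density_field((1:8 - 0.5) * 100, 0:2, C, x2 = (1:5 - 0.5) * 100,
                     bin_size = 100)
  f1 <- collapse_to_1d(f)
  expect_equal(f1$C, apply(C, c(1, 3), mean))
  expect_equal(f1$strip_width, 500)
  # two x2 rows -> arithmetic mean
  C2 <- array(c(1, 3), dim = c(1, 2, 1)) * 1e-3
  f2 <- collapse_to_1d(density_field(50, 0, C2, x2 = c(50, 150),
                                     bin_size = 100))
  expect_equal(as.numeric(f2$C), 2e-3)
  # already-1D field passes through unchanged
  expect_identical(collapse_to_1d(f1), f1)
})

test_that("wound edges are detected by interpolated threshold crossings", {
  x <- (1:50 - 0.5) * 20  # domain [0, 1000]
  P <- 1.5e-3
  # step trough on [300, 700]
  C <- ifelse(x < 300 | x > 700, P, 0)
  f <- density_field(x, 0, matrix(C), bin_size = 20)
  e <- detect_wound_edges(f, 0, 0.5)
  expect_false(e$closed)
  expect_lt(abs(e$left - 300), 20)
  expect_lt(abs(e$right - 700), 20)

  # uniform profile -> flagged closed, coincident edges
  fu <- density_field(x, 0, matrix(P, 50, 1), bin_size = 20)
  eu <- detect_wound_edges(fu, 0, 0.5)
  expect_true(eu$closed)
  expect_equal(eu$width, 0)

  # linear ramps with analytically known half-max crossings at 350 and 650
  Cr <- P * pmin(1, pmax(0, pmax((300 - x) / 100 + 1, (x - 600) / 100)))
  Cr[x <= 300 | x >= 700] <- P
  fr <- density_field(x, 0, matrix(Cr), bin_size = 20)
  er <- detect_wound_edges(fr, 0, 0.5)
  expect_lt(abs(er$left - 350), 1e-6)
  expect_lt(abs(er$right - 650), 1e-6)
})

test_that("wound closure is the normalized width change and is scale invariant", {
  expect_equal(wound_closure(400, 0), 1)
  expect_equal(wound_closure(400, 400), 0)
  expect_equal(wound_closure(400, 100), 0.75)
  expect_error(wound_closure(0, 10), "positive")
  for (alpha in c(0.1, 1, 7.5)) {
    expect_equal(wound_closure(alpha * 400, alpha * 130),
                 wound_closure(400, 130))
  }
})

test_that("density fields and centroid tables round-trip through their file formats", {
  set.seed(5)
  f <- density_field((1:6 - 0.5) * 100, c(0, 12, 24),
                     matrix(runif(18, 0, 2e-3), 6, 3),
                     bin_size = 100, strip_width = 100,
                     smooth = list(spatial_um = 150, temporal_hr = 11 / 3))
  p <- tempfile(fileext = ".json")
  write_density_field(f, p)
  g <- read_density_field(p)
  expect_equal(g$C, f$C)
  expect_equal(g$t, f$t)
  expect_equal(g$smooth$spatial_um, 150)

  tab <- data.frame(x1 = runif(10, 0, 100), x2 = runif(10, 0, 100),
                    t = rep(0, 10), replicate = 1L)
  pc <- tempfile(fileext = ".csv")
  write_centroids(tab, pc)
  tab2 <- read_centroids(pc)
  expect_equal(tab2$x1, tab$x1, tolerance = 1e-12)
})
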