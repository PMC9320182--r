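make_plane_sites <- function(n = 60, seed = 2) {
  set.seed(seed)
  x <- runif(n, 0, 40); y <- runif(n, 0, 25)
  data.frame(x = x, y = y, value = 0.3 * x - 0.5 * y + 2)
}

test_that("the trend network recovers an affine surface nearly exactly", {
  sites <- make_plane_sites()
  for (h in c(1L, 4L)) {
    m <- train_nn_pso(sites, h, n_particles = 30L, n_iterations = 300L, seed = 3L)
    expect_gte(m$report$r_validation, 0.999)
  }
})

test_that("training is deterministic, monotone, and round-trips standardisation", {
  sites <- make_plane_sites(50, seed = 4)
  m1 <- train_nn_pso(sites, 3L, n_iterations = 80L, seed = 11L)
  m2 <- train_nn_pso(sites, 3L, n_iterations = 80L, seed = 11L)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$report$mse_validation, m2$report$mse_validation)
  # best-so-far PSO trace never increases
  expect_true(all(diff(m1$trace) <= 0))
  # de-standardised predictions on training inputs match direct evaluation
  p <- predict(m1, sites)
  zx <- (sites$x - m1$scale_x$mean) / m1$scale_x$sd
  zy <- (sites$y - m1$scale_y$mean) / m1$scale_y$sd
  direct <- aquarisk:::.nn_forward(m1$weights, cbind(zx, zy), 3L) *
    m1$scale_v$sd + m1$scale_v$mean
  expect_equal(p, direct, tolerance = 1e-10)
  # constant field -> constant prediction, zero MSE
  const <- sites
  const$value <- 5
  mc <- train_nn_pso(const, 2L, n_iterations = 20L, seed = 1L)
  expect_equal(predict(mc, const), rep(5, nrow(const)), tolerance = 1e-9)
  expect_equal(mc$report$mse_train, 0, tolerance = 1e-18)
})

test_that("AIC selection penalises parameters and prefers small generators", {
  # independent arithmetic check of AIC = n ln(MSE) + 2k, k = 4h + 1
  sites <- make_plane_sites(80, seed = 6)
  m <- train_nn_pso(sites, 2L, n_iterations = 150L, seed = 5L)
  n_tr <- length(m$split$train)
  expect_equal(m$report$aic,
               n_tr * log(m$report$mse_train) + 2 * (4 * 2 + 1),
               tolerance = 1e-12)

  # data from a 1-hidden-unit generator + small noise -> small selected size,
  # AIC curve rises past its minimum
  set.seed(8)
  x <- runif(120, 0, 40); y <- runif(120, 0, 25)
  zx <- (x - 20) / 10; zy <- (y - 12.5) / 6
  val <- 2 * tanh(0.8 * zx - 0.4 * zy) + rnorm(120, 0, 0.05)
  gen1 <- data.frame(x = x, y = y, value = val)
  sel <- select_architecture(gen1, hidden_range = c(1:4, 8L, 16L),
                             n_particles = 25L, n_iterations = 150L, seed = 9L)
  expect_lte(sel$model$n_hidden, 5L)
  curve <- sel$aic_curve
  expect_gt(curve$aic[curve$n_hidden == 16L], min(curve$aic))

  expect_error(select_architecture(gen1, integer(0)), "empty")
  one <- select_architecture(gen1, 2L, n_particles = 10L,
                             n_iterations = 30L, seed = 1L)
  expect_equal(one$model$n_hidden, 2L)
})

test_that("ordinary kriging is exact at sites with zero nugget and handles nulls", {
  set.seed(12)
  n <- 40
  sites <- data.frame(x = runif(n, 0, 10), y = runif(n, 0, 10),
                      value = rnorm(n))
  vgm <- structure(list(nugget = 0, psill = 1, range = 3),
                   class = "variogram_exp")
  pred <- krige_residuals(sites, sites[, c("x", "y")], vgm = vgm)
  expect_equal(as.numeric(pred), sites$value, tolerance = 1e-6)

  zero <- sites
  zero$value <- 0
  pz <- krige_residuals(zero, data.frame(x = runif(20, 0, 10),
                                         y = runif(20, 0, 10)), vgm = vgm)
  expect_equal(as.numeric(pz), rep(0, 20), tolerance = 1e-10)
})

test_that("kriging a known exponential-variogram field beats inverse-distance weighting", {
  # simulate a Gaussian field with exponential covariance (range 5, sill 1)
  set.seed(33)
  n <- 200
  x <- runif(n, 0, 25); y <- runif(n, 0, 25)
  D <- as.matrix(dist(cbind(x, y)))
  C <- exp(-D / 5)
  L <- chol(C + diag(1e-10, n))
  val <- drop(t(L) %*% rnorm(n))
  sites <- data.frame(x = x, y = y, value = val)

  # leave-one-out cross-validation, kriging vs an independent IDW baseline
  idw <- function(train, px, py, power = 2) {
    d2 <- sqrt((train$x - px)^2 + (train$y - py)^2)^power
    w <- 1 / pmax(d2, 1e-12)
    sum(w * train$value) / sum(w)
  }
  hold <- seq(1, n, by = 4)
  vgm <- fit_variogram_exp(empirical_variogram(sites))
  krig_err <- idw_err <- numeric(length(hold))
  for (i in seq_along(hold)) {
    j <- hold[i]
    train <- sites[-j, ]
    krig_err[i] <- krige_residuals(train, sites[j, c("x", "y")], vgm = vgm) -
      sites$value[j]
    idw_err[i] <- idw(train, sites$x[j], sites$y[j]) - sites$value[j]
  }
  expect_lt(sqrt(mean(krig_err^2)), sqrt(mean(idw_err^2)))
})

test_that("surface composition is exact in degenerate cases and stores both layers", {
  sites <- make_plane_sites(60, seed = 13)
  # constant field -> constant surface
  const <- sites
  const$value <- 3
  surf <- build_surface(const, n_hidden = 2L, n_iterations = 30L, seed = 2L)
  expect_equal(surf$grid$value, rep(3, nrow(surf$grid)), tolerance = 1e-8)
  expect_true(all(c("value", "trend", "residual", "extrapolated") %in%
                    names(surf$grid)))
  # trend + residual decomposition reproduces site values at the sites
  # (zero-nugget exact interpolation)
  surf2 <- build_surface(sites, spec = grid_spec(c(0, 0), c(1, 1), c(5L, 5L)),
                         n_hidden = 2L, n_iterations = 60L, seed = 3L)
  vgm <- surf2$variogram
  if (!is.null(vgm) && vgm$nugget == 0) {
    res <- data.frame(x = sites$x, y = sites$y,
                      value = sites$value - predict(surf2$model, sites))
    back <- krige_residuals(res, sites[, c("x", "y")], vgm = vgm)
    expect_equal(predict(surf2$model, sites) + as.numeric(back), sites$value,
                 tolerance = 1e-6)
  }
  # corner cells of a grid larger than the hull are flagged extrapolated
  big <- build_surface(sites, spec = grid_spec(c(-10, -10), c(2, 2), c(10L, 10L)),
                       n_hidden = 2L, n_iterations = 30L, seed = 2L)
  expect_true(big$grid$extrapolated[1])
})

test_that("the full MLGI stack recovers a smooth synthetic field", {
  cc <- campaign_config(seed = 11L, spatial = TRUE)
  f <- latent_field(cc)
  set.seed(3)
  n <- 150
  x <- runif(n, 0, 40); y <- runif(n, 0, 25)
  sites <- data.frame(x = x, y = y, value = f(x, y))
  surf <- build_surface(sites, n_hidden = 6L, n_iterations = 150L, seed = 5L)
  g <- surf$grid
  truth <- f(g$x, g$y)
  inside <- !g$extrapolated
  expect_gte(cor(g$value[inside], truth[inside]), 0.9)
})

test_that("surface recovery improves with site density on average", {
  cc <- campaign_config(seed = 19L, spatial = TRUE)
  f <- latent_field(cc)
  rs <- vapply(c(50L, 150L), function(n) {
    mean(vapply(1:3, function(s) {
      set.seed(400 + s)
      x <- runif(n, 0, 40); y <- runif(n, 0, 25)
      sites <- data.frame(x = x, y = y, value = f(x, y))
      surf <- build_surface(sites, n_hidden = 4L, n_iterations = 100L,
                            seed = s)
      g <- surf$grid
      cor(g$value[!g$extrapolated], f(g$x, g$y)[!g$extrapolated])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(rs[2], rs[1])
})

test_that("lon/lat projection yields a metric plane around the centroid", {
  lon <- c(121.8, 121.9, 122.0); lat <- c(13.2, 13.4, 13.6)
  p <- project_lonlat(lon, lat)
  # 0.2 degrees of latitude is ~22.2 km
  expect_equal(p$y[3] - p$y[1], 6371 * 0.4 * pi / 180, tolerance = 1e-6)
  expect_equal(mean(p$x), 0, tolerance = 1e-9)
})

test_that("surfaces export to CSV and GeoJSON with both layers", {
  sites <- make_plane_sites(40, seed = 21)
  surf <- build_surface(sites, spec = grid_spec(c(0, 0), c(10, 8), c(4L, 4L)),
                        n_hidden = 2L, n_iterations = 40L, seed = 7L)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(surf, csv)
  d <- read.csv(csv)
  expect_equal(nrow(d), 16L)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_surface_geojson(surf, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 16L)
  expect_equal(parsed$features[[1]]$geometry$type, "Polygon")
})

test_that("bootstrap-averaged kriging is seeded and tracks plain kriging", {
  set.seed(17)
  n <- 60
  x <- runif(n, 0, 20); y <- runif(n, 0, 20)
  sites <- data.frame(x = x, y = y,
                      value = sin(x / 4) + cos(y / 5) + rnorm(n, 0, 0.1))
  grid <- data.frame(x = runif(25, 2, 18), y = runif(25, 2, 18))
  plain <- krige_residuals(sites, grid)
  b1 <- krige_residuals(sites, grid, ebk_B = 10L, seed = 4L)
  b2 <- krige_residuals(sites, grid, ebk_B = 10L, seed = 4L)
  expect_identical(as.numeric(b1), as.numeric(b2))
  # averaging over variogram refits stays close to the single-fit prediction
  expect_gt(cor(as.numeric(b1), as.numeric(plain)), 0.95)
})
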