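# Machine-learning geostatistical interpolation (MLGI): a single-hidden-layer
# network (2 -> h -> 1, tanh hidden, linear output) fitted to site coordinates
# by global-best particle swarm optimisation provides the spatial trend; the
# trend residuals are interpolated by ordinary kriging with a WLS-fitted
# exponential variogram, optionally bootstrap-averaged ("EBK-flavoured").
# Coordinates must be planar; lon/lat inputs can be projected with
# project_lonlat() first.

.nn_unpack <- function(w, h) {
  list(W1 = matrix(w[1:(2 * h)], nrow = 2),
       b1 = w[(2 * h + 1):(3 * h)],
       w2 = w[(3 * h + 1):(4 * h)],
       b2 = w[4 * h + 1])
}

.nn_forward <- function(w, X, h) {
  p <- .nn_unpack(w, h)
  A <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  drop(A %*% p$w2) + p$b2
}

.standardize <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Project lon/lat coordinates to a local planar frame
#'
#' Simple equirectangular projection about the domain centroid: x = R cos(lat0)
#' (lon - lon0), y = R (lat - lat0), in km. Adequate for island-scale domains
#' where kriging distances must live in a metric plane.
#'
#' @param lon,lat Coordinates in degrees.
#' @return Data frame with planar `x`, `y` (km) and the reference point as
#'   attributes.
#' @export
project_lonlat <- function(lon, lat) {
  R <- 6371
  lon0 <- mean(lon); lat0 <- mean(lat)
  out <- data.frame(
    x = R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
    y = R * (lat - lat0) * pi / 180)
  attr(out, "origin") <- c(lon = lon0, lat = lat0)
  out
}

#' Train the neural-network trend by particle swarm optimisation
#'
#' Standardises inputs and target, splits sites into train/validation/test
#' (default 70/15/15, seeded), and minimises training MSE over the `4h + 1`
#' network weights with a global-best PSO using constriction defaults
#' (inertia 0.729, cognitive = social = 1.494). The best-so-far training MSE
#' trace is recorded and is non-increasing by construction.
#'
#' @param sites Data frame with columns `x`, `y`, `value` (>= 5 rows).
#' @param n_hidden Hidden-layer size (1-30).
#' @param n_particles Swarm size.
#' @param n_iterations PSO iterations.
#' @param seed Integer seed; same seed and config give identical weights.
#' @param split Train/validation/test fractions (sum to 1).
#' @param inertia,cognitive,social PSO coefficients.
#' @return List of class `"nnpso_model"`: `weights`, `n_hidden`, scaling
#'   parameters, index `split`, `report` (a one-row data frame with
#'   `n_hidden, n_particles, n_iterations, elapsed_sec, mse_train,
#'   mse_validation, r_validation, r_testing, aic`), and `trace`.
#' @export
train_nn_pso <- function(sites, n_hidden, n_particles = 30L,
                         n_iterations = 200L, seed = 1L,
                         split = c(0.70, 0.15, 0.15),
                         inertia = 0.729, cognitive = 1.494, social = 1.494) {
  stopifnot(nrow(sites) >= 5L, n_hidden >= 1L, n_hidden <= 30L)
  t0 <- proc.time()[["elapsed"]]
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n <- nrow(sites)
  sx <- .standardize(sites$x); sy <- .standardize(sites$y)
  sv <- .standardize(sites$value)
  X <- cbind(sx$z, sy$z)
  z <- sv$z
  k <- 4L * n_hidden + 1L
  if (n < k) {
    warning("fewer sites (", n, ") than network parameters (", k,
            "); fit proceeds, AIC penalises")
  }
  constant_value <- stats::sd(sites$value) == 0
  idx <- sample.int(n)
  n_tr <- max(1L, round(split[1] * n))
  n_va <- round(split[2] * n)
  tr <- idx[seq_len(n_tr)]
  va <- if (n_va > 0 && n_tr < n) idx[(n_tr + 1):min(n, n_tr + n_va)] else tr
  te <- if (n_tr + length(va) < n && !identical(va, tr)) {
    idx[(n_tr + n_va + 1):n]
  } else va
  mse_of <- function(w, rows) mean((.nn_forward(w, X[rows, , drop = FALSE],
                                                n_hidden) - z[rows])^2)
  P <- matrix(stats::runif(n_particles * k, -2, 2), nrow = n_particles)
  V <- matrix(0, n_particles, k)
  if (constant_value) {
    # degenerate all-equal target: the zero-weight network already predicts
    # the (standardised) constant exactly; no search needed
    P[] <- 0
  }
  fit <- apply(P, 1, mse_of, rows = tr)
  pbest <- P; pbest_fit <- fit
  g <- which.min(fit)
  gbest <- P[g, ]; gbest_fit <- fit[g]
  trace <- rep(gbest_fit, n_iterations)
  for (it in seq_len(if (constant_value) 0L else n_iterations)) {
    r1 <- matrix(stats::runif(n_particles * k), n_particles)
    r2 <- matrix(stats::runif(n_particles * k), n_particles)
    V <- inertia * V + cognitive * r1 * (pbest - P) +
      social * r2 * sweep(-P, 2, gbest, "+")
    P <- P + V
    fit <- apply(P, 1, mse_of, rows = tr)
    imp <- fit < pbest_fit
    pbest[imp, ] <- P[imp, , drop = FALSE]
    pbest_fit[imp] <- fit[imp]
    g <- which.min(pbest_fit)
    if (pbest_fit[g] < gbest_fit) {
      gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
    }
    trace[it] <- gbest_fit
  }
  model <- structure(list(
    weights = gbest, n_hidden = n_hidden,
    scale_x = sx[c("mean", "sd")], scale_y = sy[c("mean", "sd")],
    scale_v = sv[c("mean", "sd")]
  ), class = "nnpso_model")
  pred_all <- predict(model, sites)
  mse_orig <- function(rows) mean((pred_all[rows] - sites$value[rows])^2)
  r_or_na <- function(rows) {
    if (stats::sd(pred_all[rows]) == 0 || stats::sd(sites$value[rows]) == 0) {
      NA_real_
    } else stats::cor(pred_all[rows], sites$value[rows])
  }
  mse_tr <- mse_orig(tr)
  aic <- length(tr) * log(max(mse_tr, .Machine$double.xmin)) + 2 * k
  report <- data.frame(
    n_hidden = n_hidden, n_particles = n_particles,
    n_iterations = n_iterations,
    elapsed_sec = proc.time()[["elapsed"]] - t0,
    mse_train = mse_tr, mse_validation = mse_orig(va),
    r_validation = r_or_na(va), r_testing = r_or_na(te),
    aic = aic
  )
  model$split <- list(train = tr, validation = va, test = te)
  model$report <- report
  model$trace <- trace
  model$seed <- as.integer(seed)
  model
}

#' Predict from a trained trend network
#'
#' @param object An `"nnpso_model"`.
#' @param newdata Data frame with columns `x`, `y`.
#' @param ... Unused.
#' @return Numeric predictions in original value units.
#' @export
predict.nnpso_model <- function(object, newdata, ...) {
  X <- cbind((newdata$x - object$scale_x$mean) / object$scale_x$sd,
             (newdata$y - object$scale_y$mean) / object$scale_y$sd)
  z <- .nn_forward(object$weights, X, object$n_hidden)
  z * object$scale_v$sd + object$scale_v$mean
}

#' Select the hidden-layer size by AIC
#'
#' Refits the trend network over a range of hidden-layer sizes and scores
#' each with `AIC = n ln(MSE_train) + 2k`, `k = 4h + 1`. Ties go to the
#' smallest architecture (the range is swept in increasing order).
#'
#' @param sites Data frame `x, y, value`.
#' @param hidden_range Integer vector of candidate sizes within 1-30.
#' @param n_particles,n_iterations,seed Passed to [train_nn_pso()]; each
#'   candidate trains with the same seed so the sweep is reproducible.
#' @return List with `model` (the minimum-AIC fit), `aic_curve` (data frame
#'   `n_hidden, aic, mse_train, mse_validation`), and `reports` (all rows).
#' @export
select_architecture <- function(sites, hidden_range = 1:10,
                                n_particles = 30L, n_iterations = 200L,
                                seed = 1L) {
  if (length(hidden_range) == 0L) stop("empty hidden-layer range", call. = FALSE)
  stopifnot(all(hidden_range >= 1L), all(hidden_range <= 30L))
  hidden_range <- sort(unique(as.integer(hidden_range)))
  fits <- lapply(hidden_range, function(h) {
    train_nn_pso(sites, h, n_particles, n_iterations, seed = seed)
  })
  reports <- do.call(rbind, lapply(fits, `[[`, "report"))
  best <- which.min(reports$aic)
  list(
    model = fits[[best]],
    aic_curve = reports[, c("n_hidden", "aic", "mse_train", "mse_validation")],
    reports = reports
  )
}

#' Empirical semivariogram
#'
#' @param sites Data frame `x, y, value`.
#' @param n_bins Number of distance bins.
#' @param cutoff Maximum pair distance considered; default half the maximum
#'   distance.
#' @return Data frame `dist, gamma, n_pairs` (empty bins dropped).
#' @export
empirical_variogram <- function(sites, n_bins = 12L, cutoff = NULL) {
  d <- as.matrix(stats::dist(sites[, c("x", "y")]))
  dv <- d[lower.tri(d)]
  r <- sites$value
  g <- 0.5 * outer(r, r, "-")^2
  gv <- g[lower.tri(g)]
  if (is.null(cutoff)) cutoff <- max(dv) / 2
  keep <- dv <= cutoff & dv > 0
  dv <- dv[keep]; gv <- gv[keep]
  bins <- cut(dv, breaks = seq(0, cutoff, length.out = n_bins + 1L),
              include.lowest = TRUE)
  out <- data.frame(
    dist = tapply(dv, bins, mean),
    gamma = tapply(gv, bins, mean),
    n_pairs = as.integer(table(bins))
  )
  out[!is.na(out$gamma), ]
}

#' Fit an exponential variogram by weighted least squares
#'
#' Model `gamma(h) = nugget + psill (1 - exp(-h / range))` for `h > 0`,
#' `gamma(0) = 0`. Bin weights are `N_j / h_j^2` (Cressie weighting), which
#' emphasises the short lags that drive kriging accuracy.
#'
#' @param emp Empirical variogram from [empirical_variogram()].
#' @return List `nugget, psill, range` (class `"variogram_exp"`).
#' @export
fit_variogram_exp <- function(emp) {
  s0 <- max(stats::quantile(emp$gamma, 0.9), 1e-10)
  r0 <- max(emp$dist) / 3
  w <- emp$n_pairs / emp$dist^2
  obj <- function(par) {
    m <- par[1] + par[2] * (1 - exp(-emp$dist / par[3]))
    sum(w * (emp$gamma - m)^2)
  }
  fit <- stats::optim(c(0, s0, r0), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12, 1e-6))
  structure(list(nugget = fit$par[1], psill = fit$par[2], range = fit$par[3]),
            class = "variogram_exp")
}

.vgm_gamma <- function(vgm, h) {
  ifelse(h > 0, vgm$nugget + vgm$psill * (1 - exp(-h / vgm$range)), 0)
}

.ok_predict <- function(sites, grid, vgm) {
  n <- nrow(sites)
  # kriging weights are invariant to a constant rescaling of the
  # semivariance, so solve in sill units to keep the system well conditioned
  # against the unit constraint row
  gscale <- max(vgm$nugget + vgm$psill, 1e-300)
  D <- as.matrix(stats::dist(sites[, c("x", "y")]))
  A <- rbind(cbind(.vgm_gamma(vgm, D) / gscale, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(sites$x, grid$x, "-")^2 + outer(sites$y, grid$y, "-")^2)
  B <- rbind(.vgm_gamma(vgm, d0) / gscale, 1)
  lambda <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(lambda)) {
    warning("singular kriging system; jittering the diagonal")
    scale <- max(vgm$nugget + vgm$psill, max(abs(A)), 1e-12)
    jitter <- 1e-10 * scale
    ii <- cbind(seq_len(n), seq_len(n))
    for (try in 1:8) {
      A2 <- A
      A2[ii] <- A2[ii] + jitter
      lambda <- tryCatch(solve(A2, B), error = function(e) NULL)
      if (!is.null(lambda)) break
      jitter <- jitter * 100
    }
    if (is.null(lambda)) stop("kriging system remains singular", call. = FALSE)
  }
  drop(crossprod(lambda[seq_len(n), , drop = FALSE], sites$value))
}

#' Ordinary kriging of trend residuals
#'
#' Interpolates site residuals onto prediction points with ordinary kriging
#' under a WLS-fitted exponential variogram. With a zero nugget the predictor
#' is exact at the data sites. The optional EBK-flavoured mode refits the
#' variogram on `ebk_B` bootstrap subsamples (80% of sites, without
#' replacement) and averages the predictions, emulating variogram-uncertainty
#' averaging with fully open math.
#'
#' @param sites Data frame `x, y, value` (the residuals; >= 5 rows).
#' @param grid Data frame of prediction points `x, y`.
#' @param vgm Optional `"variogram_exp"`; fitted from `sites` when `NULL`.
#' @param ebk_B Number of bootstrap refits (0 = plain ordinary kriging;
#'   default 20 when `ebk = TRUE`).
#' @param seed Seed for the bootstrap subsampling.
#' @return Numeric vector of predictions; the variogram used is attached as
#'   attribute `"variogram"`.
#' @export
krige_residuals <- function(sites, grid, vgm = NULL, ebk_B = 0L, seed = 1L) {
  stopifnot(nrow(sites) >= 5L)
  if (is.null(vgm)) vgm <- fit_variogram_exp(empirical_variogram(sites))
  if (ebk_B <= 0L) {
    out <- .ok_predict(sites, grid, vgm)
    attr(out, "variogram") <- vgm
    return(out)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  n <- nrow(sites)
  preds <- vapply(seq_len(ebk_B), function(b) {
    sub <- sort(sample.int(n, size = max(5L, floor(0.8 * n))))
    vb <- tryCatch(fit_variogram_exp(empirical_variogram(sites[sub, ])),
                   error = function(e) vgm)
    .ok_predict(sites, grid, vb)
  }, numeric(nrow(grid)))
  out <- rowMeans(preds)
  attr(out, "variogram") <- vgm
  out
}

#' Regular grid specification
#'
#' @param origin `c(x0, y0)`, the lower-left cell centre.
#' @param cell `c(dx, dy)` cell sizes.
#' @param n `c(n_cols, n_rows)`.
#' @return List of class `"grid_spec"`; [grid_points()] expands it.
#' @export
grid_spec <- function(origin, cell, n) {
  structure(list(origin = origin, cell = cell, n = as.integer(n)),
            class = "grid_spec")
}

#' Expand a grid specification to cell-centre points
#'
#' @param spec A [grid_spec()].
#' @return Data frame `x, y`, row-major from the origin.
#' @export
grid_points <- function(spec) {
  xs <- spec$origin[1] + spec$cell[1] * (seq_len(spec$n[1]) - 1)
  ys <- spec$origin[2] + spec$cell[2] * (seq_len(spec$n[2]) - 1)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Build an interpolated index surface (trend + kriged residual)
#'
#' The full MLGI composition: fit (or select by AIC) the NN-PSO trend on the
#' site values, krige the trend residuals onto the grid, and sum the two
#' layers. Cells outside the convex hull of the sites are flagged as
#' extrapolated.
#'
#' @param sites Data frame `x, y, value`.
#' @param spec A [grid_spec()]; `NULL` builds a 40 x 40 grid over the site
#'   bounding box.
#' @param n_hidden Hidden-layer size, or an integer vector to trigger AIC
#'   selection over that range.
#' @param n_particles,n_iterations,seed PSO settings.
#' @param ebk_B Bootstrap refits for the residual kriging (0 = plain).
#' @return List of class `"grid_surface"`: `grid` (data frame `x, y, value,
#'   trend, residual, extrapolated`), `spec`, `model`, `report`,
#'   `aic_curve` (when selection ran), `variogram`, `seed`.
#' @export
build_surface <- function(sites, spec = NULL, n_hidden = 6L,
                          n_particles = 30L, n_iterations = 200L,
                          seed = 1L, ebk_B = 0L) {
  if (is.null(spec)) {
    rx <- range(sites$x); ry <- range(sites$y)
    spec <- grid_spec(c(rx[1], ry[1]),
                      c(diff(rx) / 39, diff(ry) / 39), c(40L, 40L))
  }
  aic_curve <- NULL
  if (length(n_hidden) > 1L) {
    sel <- select_architecture(sites, n_hidden, n_particles, n_iterations, seed)
    model <- sel$model
    aic_curve <- sel$aic_curve
  } else {
    model <- train_nn_pso(sites, n_hidden, n_particles, n_iterations, seed)
  }
  grid <- grid_points(spec)
  trend_sites <- predict(model, sites)
  resid_sites <- sites$value - trend_sites
  res <- data.frame(x = sites$x, y = sites$y, value = resid_sites)
  if (all(resid_sites == 0)) {
    resid_grid <- rep(0, nrow(grid))
    vgm <- NULL
  } else {
    resid_grid <- krige_residuals(res, grid, ebk_B = ebk_B, seed = seed)
    vgm <- attr(resid_grid, "variogram")
  }
  trend_grid <- predict(model, grid)
  hull <- grDevices::chull(sites$x, sites$y)
  inside <- pracma::inpolygon(grid$x, grid$y,
                              sites$x[hull], sites$y[hull],
                              boundary = TRUE)
  grid$value <- trend_grid + as.numeric(resid_grid)
  grid$trend <- trend_grid
  grid$residual <- as.numeric(resid_grid)
  grid$extrapolated <- !inside
  structure(list(grid = grid, spec = spec, model = model,
                 report = model$report, aic_curve = aic_curve,
                 variogram = vgm, seed = as.integer(seed)),
            class = "grid_surface")
}

#' Write a grid surface as CSV
#'
#' @param surface A `"grid_surface"`.
#' @param path Output path (`x, y, value, trend, residual, extrapolated`).
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(surface$grid, path, row.names = FALSE)
  invisible(path)
}

#' Write a grid surface as GeoJSON cell polygons
#'
#' @param surface A `"grid_surface"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_geojson <- function(surface, path) {
  g <- surface$grid
  hx <- surface$spec$cell[1] / 2
  hy <- surface$spec$cell[2] / 2
  features <- lapply(seq_len(nrow(g)), function(i) {
    ring <- list(
      c(g$x[i] - hx, g$y[i] - hy), c(g$x[i] + hx, g$y[i] - hy),
      c(g$x[i] + hx, g$y[i] + hy), c(g$x[i] - hx, g$y[i] + hy),
      c(g$x[i] - hx, g$y[i] - hy))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(value = g$value[i], trend = g$trend[i],
                           residual = g$residual[i],
                           extrapolated = g$extrapolated[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
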