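test_that("distribution fitting recovers known lognormal moments and degenerates", {
  s <- tiny_campaign()
  # constant concentrations (zero spread) -> point mass at the mean
  s3 <- rbind(s, s, s)
  s3$sample_id <- sprintf("S-%d", 1:9)
  s3$As_mgL <- 0.5
  specs <- fit_input_distributions(s3, "As")
  expect_equal(specs$conc$family, "point")
  expect_equal(specs$conc$parameters$value, 0.5)

  # lognormal fit to data with known parameters, n = 10^4
  set.seed(31)
  n <- 10000L
  mu <- log(0.5); sg <- 0.8
  d <- s[rep(1, n), ]
  d$As_mgL <- rlnorm(n, mu, sg)
  sp <- fit_input_distributions(d, "As")
  expect_equal(sp$conc$family, "lognormal")
  m_true <- exp(mu + sg^2 / 2)
  s_true <- sqrt((exp(sg^2) - 1)) * m_true
  m_fit <- exp(sp$conc$parameters$meanlog + sp$conc$parameters$sdlog^2 / 2)
  s_fit <- sqrt(exp(sp$conc$parameters$sdlog^2) - 1) * m_fit
  expect_lt(abs(m_fit - m_true), 3 * s_true / sqrt(n))
  expect_lt(abs(s_fit - s_true) / s_true, 0.1)

  # zeros are excluded from the fit; all-zero degenerates with a warning
  z <- s
  for (m in hm_metals()) z[[paste0(m, "_mgL")]] <- 0
  expect_warning(fit_input_distributions(z, "As"), "zero")
  neg <- s
  neg$As_mgL[1] <- -0.1
  expect_error(fit_input_distributions(neg, "As"), "negative")
})

test_that("degenerate Monte Carlo equals the closed-form risk exactly", {
  conc <- study_mean_concentrations("TW")
  p <- exposure_params("adult")
  specs <- list(
    conc = dist_spec("conc", "point", value = conc[["As"]]),
    IR = dist_spec("IR", "point", value = p$ir),
    EF = dist_spec("EF", "point", value = p$ef),
    ED = dist_spec("ED", "point", value = p$ed),
    BW = dist_spec("BW", "point", value = p$bw),
    AT = dist_spec("AT", "point", value = p$at)
  )
  expect_warning(run_mc(specs, "As", n_iter = 500L, seed = 4L),
                 "zero-variance")
  mc <- suppressWarnings(run_mc(specs, "As", n_iter = 500L, seed = 4L))
  closed <- cr(cdi(conc[["As"]], p), get_toxicity("As")$sf_oral)
  expect_equal(mc$mean, closed, tolerance = 1e-12)
  expect_equal(mc$p5, closed, tolerance = 1e-12)
  expect_equal(mc$p95, closed, tolerance = 1e-12)
})

test_that("MC mean matches the analytic lognormal expectation and is seed-stable", {
  p <- exposure_params("adult")
  lp <- lognormal_from_moments(1.05, 3.84)
  specs <- list(
    conc = dist_spec("conc", "lognormal", meanlog = lp$meanlog, sdlog = lp$sdlog),
    IR = dist_spec("IR", "point", value = p$ir),
    EF = dist_spec("EF", "point", value = p$ef),
    ED = dist_spec("ED", "point", value = p$ed),
    BW = dist_spec("BW", "point", value = p$bw),
    AT = dist_spec("AT", "point", value = p$at)
  )
  n <- 10000L
  mc <- run_mc(specs, "As", n_iter = n, seed = 99L)
  # linearity: E[CR] = E[c] x IR x SF / BW; MC SE from the draw SD
  expected <- 1.05 * p$ir * get_toxicity("As")$sf_oral / p$bw
  mcse <- sd(mc$draws$CR) / sqrt(n)
  expect_lt(abs(mc$mean - expected), 3 * mcse)
  expect_true(mc$p5 <= mc$p50 && mc$p50 <= mc$p95)

  mc2 <- run_mc(specs, "As", n_iter = n, seed = 99L)
  expect_identical(mc$mean, mc2$mean)
  expect_identical(mc$sensitivity, mc2$sensitivity)
  expect_error(run_mc(specs, "Ba"), "not a carcinogen")
  expect_error(run_mc(specs, "As", n_iter = 10L))
})

test_that("MC mean error decays as 1/sqrt(n)", {
  p <- exposure_params("adult")
  lp <- lognormal_from_moments(1.0, 1.5)
  make_specs <- function() list(
    conc = dist_spec("conc", "lognormal", meanlog = lp$meanlog, sdlog = lp$sdlog),
    IR = dist_spec("IR", "point", value = p$ir),
    EF = dist_spec("EF", "point", value = p$ef),
    ED = dist_spec("ED", "point", value = p$ed),
    BW = dist_spec("BW", "point", value = p$bw),
    AT = dist_spec("AT", "point", value = p$at)
  )
  expected <- 1.0 * p$ir * get_toxicity("As")$sf_oral / p$bw
  ns <- c(100L, 1000L, 10000L)
  reps <- 60L
  err <- vapply(ns, function(n) {
    mean(vapply(seq_len(reps), function(r) {
      abs(run_mc(make_specs(), "As", n_iter = n, seed = 1000L * r + n)$mean -
            expected)
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(err) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("sensitivity contributions carry correct magnitudes and signs", {
  set.seed(55)
  n <- 2000L
  # only one varying input -> +/-100% for it, 0 elsewhere
  x <- rlnorm(n)
  inputs <- data.frame(conc = x, BW = rep(70, n))
  out <- x * 2.2 / 70
  sens <- mc_sensitivity(inputs, out)
  expect_equal(unname(sens["conc"]), 100)
  expect_equal(unname(sens["BW"]), 0)

  # numerator input positive, denominator input negative
  bw <- runif(n, 50, 90)
  inputs2 <- data.frame(conc = x, BW = bw)
  out2 <- x / bw
  sens2 <- mc_sensitivity(inputs2, out2)
  expect_gt(sens2[["conc"]], 0)
  expect_lt(sens2[["BW"]], 0)
  expect_equal(sum(abs(sens2)), 100, tolerance = 1e-9)

  # zero-variance output -> all zeros with a warning
  expect_warning(s0 <- mc_sensitivity(inputs2, rep(1, n)), "zero-variance")
  expect_true(all(s0 == 0))
})

test_that("two-input variance split approaches the analytic a-vs-b decomposition", {
  # oracle: output = a x1 + b x2 with independent standard normals splits
  # variance a^2 : b^2; squared rank correlations approach the same split
  set.seed(66)
  n <- 100000L
  x1 <- rnorm(n); x2 <- rnorm(n)
  a <- 3; b <- 1
  out <- a * x1 + b * x2
  sens <- mc_sensitivity(data.frame(x1 = x1, x2 = x2), out)
  expect_lt(abs(sens[["x1"]] - 100 * a^2 / (a^2 + b^2)), 2)
  expect_lt(abs(sens[["x2"]] - 100 * b^2 / (a^2 + b^2)), 2)
})

test_that("a full MC report round-trips to JSON with histogram export", {
  s <- generate_campaign(campaign_config(seed = 2L))
  specs <- fit_input_distributions(s, "As", "adult", "uncertain-exposure")
  mc <- run_mc(specs, "As", n_iter = 2000L, seed = 11L)
  expect_true(mc$p5 <= mc$p50 && mc$p50 <= mc$p95)
  # numerator variables non-negative, denominator non-positive
  expect_gte(mc$sensitivity[["conc"]], 0)
  expect_gte(mc$sensitivity[["IR"]], 0)
  expect_lte(mc$sensitivity[["BW"]], 0)
  expect_equal(sum(abs(mc$sensitivity)), 100, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".json")
  hpath <- withr::local_tempfile(fileext = ".csv")
  write_mc_report(mc, path, histogram_path = hpath)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$mean, mc$mean, tolerance = 1e-12)
  expect_equal(rep$n_iter, 2000L)
  h <- read.csv(hpath)
  expect_equal(sum(h$count), 2000L)
})

test_that("triangular and truncated draws respect their supports", {
  set.seed(3)
  tri <- mc_draw(dist_spec("IR", "triangular", min = 1, mode = 2, max = 4), 20000)
  expect_true(all(tri >= 1 & tri <= 4))
  expect_equal(mean(tri), (1 + 2 + 4) / 3, tolerance = 0.02)
  tn <- mc_draw(dist_spec("BW", "normal", mean = 1, sd = 2, lower = 0), 5000)
  expect_true(all(tn >= 0))
  expect_error(dist_spec("BW", "normal", mean = 1, sd = 1, lower = 2, upper = 1),
               "lower < upper")
  expect_error(dist_spec("BW", "normal", mean = 1), "missing parameter")
})
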