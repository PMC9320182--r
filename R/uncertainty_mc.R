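# Monte Carlo propagation of input uncertainty through the cancer-risk
# equation CR = C x IR x EF x ED / (BW x AT) x SF, with contribution-to-
# variance sensitivity analysis in the convention of spreadsheet risk tools:
# signed squared rank correlations, normalised to 100%.

#' Distribution specification for a Monte Carlo input
#'
#' @param variable Input name (e.g. `"conc"`, `"IR"`, `"BW"`, `"ED"`, `"EF"`,
#'   `"AT"`).
#' @param family One of `"point"`, `"lognormal"`, `"normal"`, `"uniform"`,
#'   `"triangular"`.
#' @param ... Family parameters: `value` (point); `meanlog`, `sdlog`
#'   (lognormal); `mean`, `sd` (normal); `min`, `max` (uniform); `min`,
#'   `mode`, `max` (triangular).
#' @param lower,upper Optional truncation bounds (applied by rejection).
#' @return List of class `"dist_spec"`.
#' @export
dist_spec <- function(variable, family = c("point", "lognormal", "normal",
                                           "uniform", "triangular"),
                      ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    point = "value", lognormal = c("meanlog", "sdlog"),
    normal = c("mean", "sd"), uniform = c("min", "max"),
    triangular = c("min", "mode", "max"))
  miss <- setdiff(need, names(pars))
  if (length(miss)) {
    stop("missing parameter(s) for ", family, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    stop("truncation bounds must satisfy lower < upper", call. = FALSE)
  }
  structure(list(variable = variable, family = family, parameters = pars,
                 lower = lower, upper = upper), class = "dist_spec")
}

.rtriangular <- function(n, min, mode, max) {
  u <- stats::runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
mc_draw <- function(spec, n) {
  p <- spec$parameters
  draw1 <- function(k) switch(spec$family,
    point = rep(p$value, k),
    lognormal = stats::rlnorm(k, p$meanlog, p$sdlog),
    normal = stats::rnorm(k, p$mean, p$sd),
    uniform = stats::runif(k, p$min, p$max),
    triangular = .rtriangular(k, p$min, p$mode, p$max))
  x <- draw1(n)
  lo <- spec$lower %||% -Inf
  hi <- spec$upper %||% Inf
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- draw1(length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1L
  }
  if (length(bad)) stop("truncation rejection did not converge", call. = FALSE)
  x
}

#' Fit Monte Carlo input distributions from a campaign
#'
#' Concentrations get a lognormal moment-matched to the positive observed
#' values of the chosen metal (zeros, i.e. below-detection records, are
#' excluded from the fit); a zero spread degenerates to a point mass. Exposure
#' variables default to point masses at the cohort values; the
#' `"uncertain-exposure"` profile instead treats body weight as normal
#' (CV 15%, truncated > 0) and ingestion rate as uniform (+/-30%), for
#' sensitivity studies.
#'
#' @param samples Campaign data frame.
#' @param metal Metal whose concentration is the uncertain input.
#' @param cohort `"adult"` or `"child"`.
#' @param profile `"point-exposure"` (default) or `"uncertain-exposure"`.
#' @return Named list of [dist_spec()] objects: `conc, IR, EF, ED, BW, AT`.
#' @export
fit_input_distributions <- function(samples, metal, cohort = "adult",
                                    profile = c("point-exposure",
                                                "uncertain-exposure")) {
  profile <- match.arg(profile)
  v <- samples[[paste0(metal, "_mgL")]]
  if (is.null(v)) stop("unknown metal: '", metal, "'", call. = FALSE)
  if (any(v < 0)) stop("negative concentration input", call. = FALSE)
  pos <- v[v > 0]
  if (length(pos) == 0L) {
    warning("all concentrations are zero; using a degenerate point distribution")
    conc <- dist_spec("conc", "point", value = 0)
  } else if (length(pos) < 3L || stats::sd(pos) == 0) {
    conc <- dist_spec("conc", "point", value = mean(pos))
  } else {
    lp <- lognormal_from_moments(mean(pos), stats::sd(pos))
    conc <- dist_spec("conc", "lognormal", meanlog = lp$meanlog, sdlog = lp$sdlog)
  }
  p <- exposure_params(cohort)
  if (profile == "point-exposure") {
    specs <- list(
      conc = conc,
      IR = dist_spec("IR", "point", value = p$ir),
      EF = dist_spec("EF", "point", value = p$ef),
      ED = dist_spec("ED", "point", value = p$ed),
      BW = dist_spec("BW", "point", value = p$bw),
      AT = dist_spec("AT", "point", value = p$at)
    )
  } else {
    specs <- list(
      conc = conc,
      IR = dist_spec("IR", "uniform", min = 0.7 * p$ir, max = 1.3 * p$ir),
      EF = dist_spec("EF", "point", value = p$ef),
      ED = dist_spec("ED", "point", value = p$ed),
      BW = dist_spec("BW", "normal", mean = p$bw, sd = 0.15 * p$bw, lower = 0),
      AT = dist_spec("AT", "point", value = p$at)
    )
  }
  specs
}

#' Contribution-to-variance sensitivity analysis
#'
#' For each varying input, the Spearman rank correlation `rho_i` with the
#' output is computed; the signed contribution is
#' `sign(rho_i) * rho_i^2 / sum_j rho_j^2 * 100`. Non-varying inputs report
#' 0. Absolute contributions sum to 100% whenever at least one input varies
#' and the output has spread.
#'
#' @param inputs Data frame of input draws (one column per variable).
#' @param output Numeric vector of output draws, same length.
#' @return Named numeric vector of signed contributions, percent.
#' @export
mc_sensitivity <- function(inputs, output) {
  stopifnot(nrow(inputs) == length(output), length(output) >= 100L)
  if (stats::sd(output) == 0) {
    warning("zero-variance output: contributions undefined, reported as 0")
    return(stats::setNames(rep(0, ncol(inputs)), names(inputs)))
  }
  rho <- vapply(inputs, function(x) {
    if (stats::sd(x) == 0) 0 else stats::cor(x, output, method = "spearman")
  }, numeric(1))
  denom <- sum(rho^2)
  if (denom == 0) return(stats::setNames(rep(0, ncol(inputs)), names(inputs)))
  sign(rho) * rho^2 / denom * 100
}

#' Monte Carlo cancer-risk simulation
#'
#' Draws all inputs independently (draw order fixed alphabetically by
#' variable name so a seed is portable), evaluates
#' `CR = conc x IR x EF x ED / (BW x AT) x SF` per iteration, and summarises
#' with the mean and linear-interpolation empirical percentiles (5th, 50th,
#' 95th), plus a contribution-to-variance sensitivity table.
#'
#' @param specs Named list of [dist_spec()]s with elements
#'   `conc, IR, EF, ED, BW, AT` (see [fit_input_distributions()]).
#' @param metal Carcinogen whose slope factor applies (As, Pb or Ni).
#' @param cohort Cohort label recorded in the summary.
#' @param n_iter Number of iterations (>= 100; the reference campaign uses
#'   10000).
#' @param seed Integer seed; the run is reproducible given (`specs`, `seed`).
#' @return List of class `"mc_summary"`: `target`, `n_iter`, `seed`, `mean`,
#'   `p5`, `p50`, `p95`, `sensitivity`, `draws` (data frame incl. `CR`),
#'   `specs`.
#' @export
run_mc <- function(specs, metal, cohort = "adult", n_iter = 10000L, seed = 1L) {
  stopifnot(n_iter >= 100L)
  sf <- get_toxicity(metal)$sf_oral
  if (is.na(sf)) {
    stop("no oral slope factor: '", metal, "' is not a carcinogen", call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  vars <- sort(names(specs))
  draws <- as.data.frame(lapply(stats::setNames(vars, vars), function(v) {
    mc_draw(specs[[v]], n_iter)
  }))
  cr_draws <- draws$conc * draws$IR * draws$EF * draws$ED /
    (draws$BW * draws$AT) * sf
  q <- stats::quantile(cr_draws, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  sens <- mc_sensitivity(draws, cr_draws)
  draws$CR <- cr_draws
  structure(list(
    target = list(metal = metal, cohort = cohort),
    n_iter = as.integer(n_iter), seed = as.integer(seed),
    mean = mean(cr_draws), p5 = q[1], p50 = q[2], p95 = q[3],
    sensitivity = sens, draws = draws, specs = specs
  ), class = "mc_summary")
}

#' Export a Monte Carlo report
#'
#' Writes the summary as JSON (specs echoed, mean, percentiles, sensitivity)
#' and optionally a histogram CSV (`bin_lo, bin_hi, count`) of the CR draws.
#'
#' @param summary An `"mc_summary"` from [run_mc()].
#' @param path JSON output path.
#' @param histogram_path Optional CSV path for the histogram.
#' @param bins Number of histogram bins.
#' @return `path`, invisibly.
#' @export
write_mc_report <- function(summary, path, histogram_path = NULL, bins = 40L) {
  spec_echo <- lapply(summary$specs, function(s) {
    list(variable = s$variable, family = s$family, parameters = s$parameters)
  })
  out <- list(
    target = summary$target, n_iter = summary$n_iter, seed = summary$seed,
    distributions = spec_echo,
    mean = summary$mean, p5 = summary$p5, p50 = summary$p50, p95 = summary$p95,
    sensitivity = as.list(summary$sensitivity)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(histogram_path)) {
    h <- graphics::hist(summary$draws$CR, breaks = bins, plot = FALSE)
    utils::write.csv(
      data.frame(bin_lo = utils::head(h$breaks, -1),
                 bin_hi = utils::tail(h$breaks, -1), count = h$counts),
      histogram_path, row.names = FALSE)
  }
  invisible(path)
}
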