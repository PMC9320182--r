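# Synthetic sampling campaigns with the statistical and spatial structure the
# downstream analysis assumes: per-metal lognormal concentrations moment-matched
# to target means/SDs, optional below-detection zeros, and a smooth latent
# spatial field (polynomial trend + random cosine modes) available as ground
# truth for interpolation tests.

#' Moment-matched lognormal parameters
#'
#' Given a target mean `m > 0` and SD `s >= 0`, returns the `(meanlog, sdlog)`
#' of the lognormal with exactly those first two moments:
#' `sdlog^2 = log(1 + s^2/m^2)`, `meanlog = log(m) - sdlog^2/2`.
#'
#' @param m Target mean (> 0).
#' @param s Target standard deviation (>= 0).
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_from_moments <- function(m, s) {
  stopifnot(m > 0, s >= 0)
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Configuration for a synthetic sampling campaign
#'
#' Defaults emulate the three-source-type survey the package targets: 25
#' water-refilling-station (WRS), 26 groundwater (GW) and 21 tap-water (TW)
#' samples, with per-metal lognormal concentration targets taken from
#' [study_summary()]. Coordinates are planar km over a rectangular domain.
#'
#' @param counts Named integer vector of sample counts per source type.
#' @param targets Data frame like [study_summary()] (columns `source_type`,
#'   `parameter`, `mean`, `sd`) supplying per-source, per-parameter targets.
#' @param p_lod Named numeric vector, probability that a metal reading falls
#'   below the detection limit and is recorded as 0. Default 0 for all metals.
#' @param lod_substitution `"zero"` (default) records censored values as 0;
#'   `"half_lod"` substitutes `lod/2` using `lod` below.
#' @param lod Named vector of detection limits (mg/L), only used by
#'   `"half_lod"` substitution. Defaults to the PNSDW limit / 10.
#' @param domain Numeric `c(xmin, xmax, ymin, ymax)`, km.
#' @param spatial `TRUE` to couple one metal's concentrations to a smooth
#'   latent spatial field.
#' @param spatial_metal Metal driven by the field when `spatial = TRUE`.
#' @param trend_amplitude Amplitude of the low-order polynomial trend of the
#'   latent field (in standardised field units).
#' @param correlation_length Correlation length (km) of the cosine modes.
#' @param n_modes Number of random cosine modes.
#' @param coupling Coefficient applied to the standardised field on the log
#'   scale of the driven metal.
#' @param seed Integer seed; every draw the generator makes derives from it.
#' @return A list of class `"campaign_config"`.
#' @export
campaign_config <- function(counts = c(WRS = 25L, GW = 26L, TW = 21L),
                            targets = study_summary(),
                            p_lod = NULL,
                            lod_substitution = c("zero", "half_lod"),
                            lod = NULL,
                            domain = c(0, 40, 0, 25),
                            spatial = FALSE,
                            spatial_metal = "As",
                            trend_amplitude = 1,
                            correlation_length = 12,
                            n_modes = 12L,
                            coupling = 1,
                            seed = 1L) {
  lod_substitution <- match.arg(lod_substitution)
  if (any(counts < 0)) stop("negative sample counts", call. = FALSE)
  if (any(targets$sd < 0)) stop("negative target SDs", call. = FALSE)
  if (any(targets$mean < 0)) stop("negative target means", call. = FALSE)
  if (correlation_length <= 0) stop("correlation length must be > 0", call. = FALSE)
  if (is.null(p_lod)) p_lod <- stats::setNames(rep(0, 8), hm_metals())
  if (is.null(lod)) lod <- standard_limits("PNSDW") / 10
  structure(list(
    counts = counts, targets = targets, p_lod = p_lod,
    lod_substitution = lod_substitution, lod = lod, domain = domain,
    spatial = spatial, spatial_metal = spatial_metal,
    trend_amplitude = trend_amplitude,
    correlation_length = correlation_length, n_modes = as.integer(n_modes),
    coupling = coupling, seed = as.integer(seed)
  ), class = "campaign_config")
}

#' Latent spatial field of a campaign configuration
#'
#' The smooth ground-truth field: a first-order polynomial trend plus
#' `n_modes` random cosine modes with wavelength equal to the configured
#' correlation length, normalised by `sqrt(n_modes)` so the stochastic part
#' has unit variance. Deterministic given `config$seed`; exposed so surface
#' recovery tests can compare an interpolated map against the truth.
#'
#' @param config A [campaign_config()].
#' @return `function(x, y)` returning the field value, vectorised.
#' @export
latent_field <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed + 7919L) # field draws decoupled from sample draws
  K <- config$n_modes
  theta <- stats::runif(K, 0, 2 * pi)
  u <- cos(theta); v <- sin(theta)
  amp <- stats::rnorm(K)
  phase <- stats::runif(K, 0, 2 * pi)
  L <- config$correlation_length
  d <- config$domain
  cx <- mean(d[1:2]); cy <- mean(d[3:4])
  beta <- config$trend_amplitude * c(0, 1 / (d[2] - d[1]), -1 / (d[4] - d[3]))
  function(x, y) {
    tr <- beta[1] + beta[2] * (x - cx) + beta[3] * (y - cy)
    modes <- vapply(seq_len(K), function(k) {
      amp[k] * cos(2 * pi * (x * u[k] + y * v[k]) / L + phase[k])
    }, numeric(length(x)))
    if (length(x) == 1L) modes <- matrix(modes, nrow = 1L)
    tr + rowSums(modes) / sqrt(K)
  }
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic sampling campaign
#'
#' Draws exact per-source-type sample counts with concentrations from
#' moment-matched lognormals (degenerating to the target mean when the target
#' SD is 0), physicochemical fields from truncated normals, uniform planar
#' coordinates, and optional below-detection censoring. When spatial mode is
#' on, the configured metal's log-concentration is shifted by the standardised
#' latent field at the sample location.
#'
#' @param config A [campaign_config()].
#' @return Data frame with one row per sample and columns
#'   `sample_id, source_type, x, y, temperature_C, pH, EC_uScm, TDS_ppm` and
#'   `<metal>_mgL` for the eight metals. Attributes `seed` and `coords`
#'   record provenance.
#' @export
generate_campaign <- function(config = campaign_config()) {
  stopifnot(inherits(config, "campaign_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  metals <- hm_metals()
  phys <- c("temperature_C", "pH", "EC_uScm", "TDS_ppm")
  field <- if (config$spatial) latent_field(config) else NULL
  rows <- list()
  for (st in names(config$counts)) {
    n <- config$counts[[st]]
    if (n == 0L) next
    tg <- config$targets[config$targets$source_type == st, ]
    tgt <- function(p) tg[tg$parameter == p, , drop = FALSE]
    x <- stats::runif(n, config$domain[1], config$domain[2])
    y <- stats::runif(n, config$domain[3], config$domain[4])
    d <- data.frame(
      sample_id = sprintf("%s-%03d", st, seq_len(n)),
      source_type = st, x = x, y = y, stringsAsFactors = FALSE
    )
    for (p in phys) {
      t <- tgt(p)
      v <- stats::rnorm(n, t$mean, t$sd)
      lo <- if (p == "pH") 0 else 0
      hi <- if (p == "pH") 14 else Inf
      d[[p]] <- pmin(pmax(v, lo), hi)
    }
    for (m in metals) {
      t <- tgt(m)
      if (t$sd == 0) {
        v <- rep(t$mean, n)
      } else if (t$mean == 0) {
        v <- rep(0, n)
      } else {
        lp <- lognormal_from_moments(t$mean, t$sd)
        meanlog <- lp$meanlog
        if (config$spatial && m == config$spatial_metal) {
          meanlog <- meanlog + config$coupling * field(x, y)
        }
        v <- stats::rlnorm(n, meanlog, lp$sdlog)
      }
      p_cens <- config$p_lod[[m]]
      if (!is.null(p_cens) && p_cens > 0) {
        cens <- stats::runif(n) < p_cens
        v[cens] <- if (config$lod_substitution == "zero") 0 else config$lod[[m]] / 2
      }
      d[[paste0(m, "_mgL")]] <- v
    }
    rows[[st]] <- d
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  attr(out, "seed") <- config$seed
  attr(out, "coords") <- "planar_km"
  out
}

.campaign_columns <- function() {
  c("sample_id", "source_type", "x", "y", "temperature_C", "pH",
    "EC_uScm", "TDS_ppm", paste0(hm_metals(), "_mgL"))
}

#' Write a campaign table to CSV (with a metadata sidecar)
#'
#' @param samples Campaign data frame (schema of [generate_campaign()]).
#' @param path CSV output path; a JSON sidecar `<path>.meta.json` records the
#'   coordinate convention and seed.
#' @return `path`, invisibly.
#' @export
write_campaign <- function(samples, path) {
  cols <- .campaign_columns()
  stopifnot(all(cols %in% names(samples)))
  utils::write.csv(samples[, cols], path, row.names = FALSE, quote = FALSE)
  meta <- list(
    coords = attr(samples, "coords") %||% "planar_km",
    seed = attr(samples, "seed"),
    n = nrow(samples)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a campaign CSV
#'
#' Enforces the campaign schema: all required columns present, no negative
#' concentrations, source types in the WRS/GW/TW set. Violations raise an
#' error naming the offending column and row.
#'
#' @param path CSV path written by [write_campaign()] (or hand-built to the
#'   same schema).
#' @return Campaign data frame; metadata sidecar fields attached as
#'   attributes when present.
#' @export
read_campaign <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.campaign_columns(), names(d))
  if (length(missing)) {
    stop("campaign schema error: missing column(s) ",
         paste0("`", missing, "`", collapse = ", "), call. = FALSE)
  }
  bad_st <- which(!d$source_type %in% c("WRS", "GW", "TW"))
  if (length(bad_st)) {
    stop("campaign schema error: unknown source_type '", d$source_type[bad_st[1]],
         "' at row ", bad_st[1], call. = FALSE)
  }
  for (m in paste0(hm_metals(), "_mgL")) {
    neg <- which(d[[m]] < 0)
    if (length(neg)) {
      stop("campaign schema error: negative concentration in `", m,
           "` at row ", neg[1], call. = FALSE)
    }
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(d, "coords") <- meta$coords
    attr(d, "seed") <- meta$seed
  }
  d
}

#' Concentration matrix of a campaign
#'
#' @param samples Campaign data frame.
#' @return Numeric matrix, rows = samples, columns = [hm_metals()], mg/L.
#' @export
concentration_matrix <- function(samples) {
  m <- as.matrix(samples[, paste0(hm_metals(), "_mgL")])
  colnames(m) <- hm_metals()
  m
}
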