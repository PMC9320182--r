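#' @keywords internal
"_PACKAGE"

#' Metals covered by the assessment
#'
#' The eight heavy metals and metalloids the package assesses, in the fixed
#' order used throughout: As, Ba, Cu, Fe, Pb, Mn, Ni, Zn.
#'
#' @return Character vector of element symbols.
#' @export
hm_metals <- function() c("As", "Ba", "Cu", "Fe", "Pb", "Mn", "Ni", "Zn")

# permissible limits, mg/L, per authority
.standards <- data.frame(
  metal = rep(c("As", "Ba", "Cu", "Fe", "Pb", "Mn", "Ni", "Zn"), times = 2),
  authority = rep(c("PNSDW", "WHO"), each = 8),
  s_i = c(
    # PNSDW 2017
    0.01, 0.70, 1.00, 1.00, 0.01, 0.40, 0.07, 5.00,
    # WHO guideline values
    0.01, 0.70, 2.00, 0.30, 0.01, 0.40, 0.07, 3.00
  ),
  stringsAsFactors = FALSE
)

# oral reference doses (mg/kg/day) and oral slope factors ((mg/kg/day)^-1);
# slope factors exist only for the three carcinogens As, Pb, Ni
.toxicity <- data.frame(
  metal = c("As", "Ba", "Cu", "Fe", "Pb", "Mn", "Ni", "Zn"),
  rfd_oral = c(3e-4, 0.2, 0.04, 0.7, 0.0014, 0.14, 0.02, 0.3),
  sf_oral = c(1.5, NA, NA, NA, 8.5e-3, NA, 0.84, NA),
  stringsAsFactors = FALSE
)

.exposure <- list(
  adult = list(cohort = "adult", ir = 2.2, ef = 365, ed = 70, bw = 70, at = 25550),
  child = list(cohort = "child", ir = 1.0, ef = 365, ed = 10, bw = 25, at = 3650)
)

# Classification scales. `breaks` are the interior thresholds; `upper_at_break`
# says, for each threshold, whether a value exactly on it falls in the interval
# above (TRUE) or below (FALSE). Where the printed inequality signs leave a
# boundary ambiguous or doubly claimed, the more-polluted (upper) label wins.
.scales <- list(
  MPI = list(
    breaks = c(90, 180),
    labels = c("Low", "Medium", "High"),
    upper_at_break = c(TRUE, FALSE) # 90-180 is printed closed on both ends
  ),
  NPI = list(
    breaks = c(1.0, 2.5, 7.0),
    labels = c("Unpolluted", "Slightly polluted", "Moderately polluted",
               "Heavily polluted"),
    upper_at_break = c(TRUE, TRUE, TRUE)
  ),
  TCR = list(
    breaks = c(1e-6, 1e-5, 1e-4, 1e-3),
    labels = c("Very low", "Low", "Medium", "High", "Very high"),
    upper_at_break = c(TRUE, TRUE, TRUE, TRUE)
  ),
  CV = list(
    breaks = c(15, 35),
    labels = c("low", "intermediate", "high"),
    upper_at_break = c(FALSE, TRUE) # CV = 15 is low; CV = 35 is high
  )
)

#' Regulatory concentration limit for a metal
#'
#' Looks up the stored permissible limit (mg/L) for one of the eight study
#' metals under a given drinking-water authority.
#'
#' @param metal Element symbol (one of [hm_metals()]).
#' @param authority `"PNSDW"` (default, Philippine National Standards for
#'   Drinking Water 2017) or `"WHO"`.
#' @return One-row data frame with columns `metal`, `authority`, `s_i` (mg/L).
#' @examples
#' get_standard("As")           # 0.01 mg/L
#' get_standard("Zn", "PNSDW")  # 5.00 mg/L
#' @export
get_standard <- function(metal, authority = "PNSDW") {
  if (!authority %in% c("PNSDW", "WHO")) {
    stop("unknown authority: '", authority, "'", call. = FALSE)
  }
  row <- .standards[.standards$metal == metal & .standards$authority == authority, ]
  if (nrow(row) != 1L) {
    stop("unknown metal: '", metal, "'", call. = FALSE)
  }
  row.names(row) <- NULL
  row
}

#' All limits for an authority as a named vector
#'
#' @inheritParams get_standard
#' @return Named numeric vector (mg/L) over [hm_metals()], in canonical order.
#' @export
standard_limits <- function(authority = "PNSDW") {
  vapply(hm_metals(), function(m) get_standard(m, authority)$s_i, numeric(1))
}

#' Oral toxicity values for a metal
#'
#' @param metal Element symbol.
#' @return List with `metal`, `rfd_oral` (mg/kg/day) and `sf_oral`
#'   ((mg/kg/day)^-1, `NA` for the five non-carcinogens).
#' @export
get_toxicity <- function(metal) {
  row <- .toxicity[.toxicity$metal == metal, ]
  if (nrow(row) != 1L) stop("unknown metal: '", metal, "'", call. = FALSE)
  list(metal = row$metal, rfd_oral = row$rfd_oral, sf_oral = row$sf_oral)
}

#' The carcinogenic subset of the study metals
#'
#' @return Character vector: metals with an oral slope factor (As, Pb, Ni).
#' @export
carcinogens <- function() .toxicity$metal[!is.na(.toxicity$sf_oral)]

#' Cohort ingestion-exposure parameters
#'
#' Default ingestion rate (IR, L/day), exposure frequency (EF, days/year),
#' exposure duration (ED, years), body weight (BW, kg) and averaging time
#' (AT, days) for the adult and child cohorts. Note EF x ED = AT for both
#' cohorts, so the chronic daily intake collapses to C x IR / BW.
#'
#' @param cohort `"adult"` or `"child"`.
#' @return List with fields `cohort`, `ir`, `ef`, `ed`, `bw`, `at`.
#' @export
exposure_params <- function(cohort = c("adult", "child")) {
  cohort <- match.arg(cohort)
  .exposure[[cohort]]
}

#' Classify an index value on a named scale
#'
#' Maps a finite non-negative value to exactly one category of the MPI, NPI,
#' TCR or CV scale. Boundary values follow the printed inequality signs of the
#' source classifications; where a boundary is ambiguous the more-polluted
#' label wins (e.g. CV = 35 is "high", TCR = 1e-3 is "Very high").
#'
#' @param scale One of `"MPI"`, `"NPI"`, `"TCR"`, `"CV"`.
#' @param value Numeric vector, finite and >= 0.
#' @return Character vector of category labels.
#' @examples
#' classify("MPI", 200)     # "High"
#' classify("NPI", 0.5)     # "Unpolluted"
#' classify("TCR", 5.53e-2) # "Very high"
#' @export
classify <- function(scale, value) {
  sc <- .scales[[scale]]
  if (is.null(sc)) stop("unknown scale: '", scale, "'", call. = FALSE)
  stopifnot(all(is.finite(value)), all(value >= 0))
  vapply(value, function(v) {
    idx <- 1L
    for (j in seq_along(sc$breaks)) {
      b <- sc$breaks[j]
      if (v > b || (v == b && sc$upper_at_break[j])) idx <- j + 1L
    }
    sc$labels[idx]
  }, character(1))
}

#' Classification scale definition
#'
#' @param scale Scale name.
#' @return List with `breaks`, `labels`, `upper_at_break`.
#' @export
get_scale <- function(scale) {
  sc <- .scales[[scale]]
  if (is.null(sc)) stop("unknown scale: '", scale, "'", call. = FALSE)
  sc
}

#' Coefficient of variation from moments
#'
#' @param mean Mean (> 0 for a defined CV).
#' @param sd Standard deviation (>= 0).
#' @return CV in percent, `NA` when `mean <= 0`.
#' @export
coef_variation <- function(mean, sd) {
  ifelse(mean > 0, sd / mean * 100, NA_real_)
}

#' Campaign summary statistics used as package defaults
#'
#' Per source type (WRS: water refilling station, GW: groundwater, TW: tap
#' water), the mean and standard deviation of each physicochemical parameter
#' and metal concentration from the Marinduque domestic-water survey that the
#' synthetic generator emulates. Concentrations in mg/L; temperature degC,
#' EC uS/cm, TDS ppm.
#'
#' @return Data frame with columns `source_type`, `parameter`, `mean`, `sd`.
#' @export
study_summary <- function() {
  pars <- c("temperature_C", "pH", "EC_uScm", "TDS_ppm",
            "As", "Ba", "Cu", "Fe", "Pb", "Mn", "Ni", "Zn")
  wrs <- c(26.6, 6.74, 51.6, 19.2,
           0.515, 0.027, 0.038, 0.178, 0.371, 0.009, 0.082, 0.029)
  wrs_sd <- c(3.69, 0.89, 84.6, 38.8,
              1.86, 0.02, 0.08, 0.31, 0.59, 0.004, 0.02, 0.01)
  gw <- c(29.3, 7.03, 680, 328,
          0.106, 0.025, 0.025, 0.901, 1.23, 0.009, 0.077, 0.035)
  gw_sd <- c(1.99, 0.48, 735, 367,
             0.19, 0.02, 0.06, 2.93, 3.03, 0.01, 0.04, 0.03)
  tw <- c(29.4, 6.91, 378, 180,
          1.05, 0.023, 0.027, 0.138, 0.432, 0.010, 0.208, 0.030)
  tw_sd <- c(1.61, 1.03, 286, 143,
             3.84, 0.02, 0.09, 0.31, 0.80, 0.01, 0.58, 0.02)
  data.frame(
    source_type = rep(c("WRS", "GW", "TW"), each = length(pars)),
    parameter = rep(pars, times = 3),
    mean = c(wrs, gw, tw),
    sd = c(wrs_sd, gw_sd, tw_sd),
    stringsAsFactors = FALSE
  )
}

#' Mean metal concentrations for one source type
#'
#' Convenience accessor over [study_summary()]: the mean concentration vector
#' (mg/L) for the eight metals, named and in canonical order.
#'
#' @param source_type `"WRS"`, `"GW"` or `"TW"`.
#' @return Named numeric vector over [hm_metals()].
#' @export
study_mean_concentrations <- function(source_type) {
  ss <- study_summary()
  rows <- ss[ss$source_type == source_type & ss$parameter %in% hm_metals(), ]
  if (nrow(rows) == 0L) stop("unknown source_type: '", source_type, "'", call. = FALSE)
  stats::setNames(rows$mean, rows$parameter)[hm_metals()]
}

#' Export the package constants to an editable YAML config
#'
#' Writes sections `standards`, `toxicity`, `exposure.adult`, `exposure.child`
#' and `scales` so other jurisdictions' limits can be swapped in. Numbers are
#' written with full precision so a round-trip through
#' [read_reference_config()] is bit-exact.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_config <- function(path) {
  cfg <- list(
    standards = lapply(split(.standards, .standards$authority), function(d) {
      as.list(stats::setNames(d$s_i, d$metal))
    }),
    toxicity = lapply(seq_len(nrow(.toxicity)), function(i) {
      list(metal = .toxicity$metal[i],
           rfd_oral = .toxicity$rfd_oral[i],
           sf_oral = if (is.na(.toxicity$sf_oral[i])) NULL else .toxicity$sf_oral[i])
    }),
    exposure = .exposure,
    scales = .scales
  )
  writeLines(yaml::as.yaml(cfg, precision = 17L), path)
  invisible(path)
}

#' Read a reference config written by [write_reference_config()]
#'
#' @param path YAML file path.
#' @return The constants list (sections `standards`, `toxicity`, `exposure`,
#'   `scales`).
#' @export
read_reference_config <- function(path) {
  yaml::read_yaml(path)
}
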