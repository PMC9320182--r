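# Deterministic ingestion-pathway exposure and risk (USEPA framework):
# CDI = C x IR x EF x ED / (BW x AT), HQ = CDI/RfD, HI = sum(HQ),
# CR = CDI x SF over the carcinogens As, Pb, Ni, TCR = sum(CR).
# Internal computation is full precision; any rounding is presentation-only.

#' Chronic daily intake from water ingestion
#'
#' `CDI = C x IR x EF x ED / (BW x AT)` in mg/kg-day. With the default
#' cohort parameters EF x ED equals AT, so this collapses algebraically to
#' `C x IR / BW`.
#'
#' @param c_i Concentration in water, mg/L (>= 0). Vectorised.
#' @param params Cohort parameters, see [exposure_params()].
#' @return Intake(s), mg/kg-day.
#' @export
cdi <- function(c_i, params = exposure_params("adult")) {
  if (params$bw <= 0 || params$at <= 0) {
    stop("body weight and averaging time must be > 0", call. = FALSE)
  }
  if (any(c_i < 0)) stop("concentration must be >= 0", call. = FALSE)
  c_i * params$ir * params$ef * params$ed / (params$bw * params$at)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD`; values above 1 flag potential non-carcinogenic effects.
#'
#' @param cdi_val Chronic daily intake, mg/kg-day. Vectorised.
#' @param rfd Oral reference dose, mg/kg/day (> 0).
#' @return Hazard quotient(s), unitless.
#' @export
hq <- function(cdi_val, rfd) {
  if (any(rfd <= 0)) stop("reference dose must be > 0", call. = FALSE)
  cdi_val / rfd
}

#' Hazard index
#'
#' Sum of hazard quotients across substances.
#'
#' @param hq_values Numeric vector of hazard quotients.
#' @return List with `hi` (the sum) and `exceeds_one` flag.
#' @export
hi <- function(hq_values) {
  h <- sum(hq_values)
  list(hi = h, exceeds_one = h > 1)
}

#' Carcinogenic risk for one metal
#'
#' `CR = CDI x SF`, an incremental lifetime cancer risk. Only metals with an
#' oral slope factor (As, Pb, Ni) are admissible.
#'
#' @param cdi_val Chronic daily intake, mg/kg-day. Vectorised.
#' @param sf Oral slope factor, (mg/kg/day)^-1; `NA` (non-carcinogen) errors.
#' @return Lifetime risk(s), unitless.
#' @export
cr <- function(cdi_val, sf) {
  if (any(is.na(sf))) {
    stop("no oral slope factor: metal is not in the carcinogen set", call. = FALSE)
  }
  cdi_val * sf
}

#' Total carcinogenic risk with classification and shares
#'
#' Sums per-carcinogen risks, classifies the total on the TCR scale, and
#' reports each carcinogen's percentage share of the total.
#'
#' @param cr_values Named numeric vector of per-carcinogen risks.
#' @return List with `tcr`, `label`, and `shares` (percent, summing to 100
#'   when `tcr > 0`).
#' @export
tcr <- function(cr_values) {
  total <- sum(cr_values)
  shares <- if (total > 0) cr_values / total * 100 else cr_values * NA_real_
  list(tcr = total, label = classify("TCR", total), shares = shares)
}

.risk_row <- function(conc, subject, cohort) {
  p <- exposure_params(cohort)
  metals <- hm_metals()
  cdis <- cdi(conc[metals], p)
  rfds <- vapply(metals, function(m) get_toxicity(m)$rfd_oral, numeric(1))
  hqs <- hq(cdis, rfds)
  h <- hi(hqs)
  carc <- carcinogens()
  sfs <- vapply(carc, function(m) get_toxicity(m)$sf_oral, numeric(1))
  crs <- cr(cdis[carc], sfs)
  t <- tcr(crs)
  row <- data.frame(subject = subject, cohort = cohort, stringsAsFactors = FALSE)
  for (m in metals) row[[paste0("cdi_", m)]] <- unname(cdis[m])
  for (m in metals) row[[paste0("hq_", m)]] <- unname(hqs[m])
  row$hi <- h$hi
  for (m in carc) row[[paste0("cr_", m)]] <- unname(crs[m])
  row$tcr <- t$tcr
  row$tcr_label <- t$label
  for (m in carc) row[[paste0("share_", m)]] <- unname(t$shares[m])
  row
}

#' Exposure and risk table
#'
#' Computes the full CDI/HQ/HI/CR/TCR chain for a cohort. In group mode
#' (default) concentrations are first averaged within each group and the risk
#' equations are applied to the group means, matching the convention of
#' computing risk from mean concentrations; in per-sample mode each sample
#' gets its own row.
#'
#' @param samples Campaign data frame, or a named concentration vector
#'   (mg/L over [hm_metals()]) for a single subject.
#' @param cohort `"adult"` or `"child"` (or both).
#' @param mode `"group"` (average concentrations within `by`, then assess) or
#'   `"sample"` (assess each sample).
#' @param by Grouping column for group mode.
#' @return Data frame, one row per subject x cohort, columns
#'   `subject, cohort, cdi_<metal>..., hq_<metal>..., hi, cr_As, cr_Pb, cr_Ni,
#'   tcr, tcr_label, share_As, share_Pb, share_Ni`.
#' @export
risk_table <- function(samples, cohort = c("adult", "child"),
                       mode = c("group", "sample"), by = "source_type") {
  mode <- match.arg(mode)
  cohorts <- match.arg(cohort, several.ok = TRUE)
  if (is.numeric(samples)) {
    rows <- lapply(cohorts, function(co) .risk_row(samples, "subject", co))
    return(do.call(rbind, rows))
  }
  rows <- list()
  if (mode == "group") {
    groups <- split(seq_len(nrow(samples)), samples[[by]])
    if (any(vapply(groups, length, integer(1)) == 0L)) {
      stop("empty group", call. = FALSE)
    }
    for (g in names(groups)) {
      cmean <- colMeans(concentration_matrix(samples[groups[[g]], , drop = FALSE]))
      for (co in cohorts) rows[[paste(g, co)]] <- .risk_row(cmean, g, co)
    }
  } else {
    cm <- concentration_matrix(samples)
    for (i in seq_len(nrow(samples))) {
      for (co in cohorts) {
        rows[[paste(i, co)]] <- .risk_row(cm[i, ], samples$sample_id[i], co)
      }
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
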