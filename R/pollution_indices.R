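# Composite pollution indices. All three indices compare concentrations
# (mg/L) to permissible limits (mg/L) from a single authority; mixing
# authorities inside one computation is rejected upstream by taking limits
# from a single standard_limits() call.

#' Quality rating of a metal
#'
#' `Q_i = (C_i / S_i) * 100`: the concentration as a percentage of the
#' permissible limit.
#'
#' @param c_i Concentration, mg/L (>= 0). Vectorised.
#' @param s_i Permissible limit, mg/L (> 0).
#' @return Quality rating(s), unitless.
#' @export
quality_rating <- function(c_i, s_i) {
  if (any(s_i <= 0)) stop("permissible limit must be > 0", call. = FALSE)
  if (any(c_i < 0)) stop("concentration must be >= 0", call. = FALSE)
  c_i / s_i * 100
}

#' Single-factor pollution index
#'
#' `SFPI = C_i / S_i`; a value above 1 means the metal exceeds its standard.
#' Identical to [quality_rating()] / 100.
#'
#' @inheritParams quality_rating
#' @return Index value(s), unitless.
#' @export
sfpi <- function(c_i, s_i) {
  quality_rating(c_i, s_i) / 100
}

#' Heavy-metal pollution index of one sample
#'
#' Weighted arithmetic mean of the per-metal quality ratings with weights
#' `W_i = 1/S_i`: `MPI = sum(Q_i W_i) / sum(W_i)`. Metals recorded as 0
#' (below detection) are kept with `Q_i = 0`; dropping them would change the
#' weight normalisation.
#'
#' @param conc Named concentration vector (mg/L); names are metal symbols.
#' @param standards Named vector of permissible limits covering every metal in
#'   `conc`, e.g. [standard_limits()].
#' @return MPI value, unitless.
#' @export
mpi <- function(conc, standards = standard_limits()) {
  miss <- setdiff(names(conc), names(standards))
  if (length(miss)) {
    stop("no standard for metal(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  s <- standards[names(conc)]
  w <- 1 / s
  sum(quality_rating(conc, s) * w) / sum(w)
}

#' Nemerow pollution index
#'
#' Root-mean-square of the maximum and mean single-factor indices:
#' `NPI = sqrt((SFPI_max^2 + SFPI_ave^2) / 2)`, emphasising the worst
#' pollutant. Always lies in `[SFPI_max / sqrt(2), SFPI_max]`.
#'
#' @param sfpi_values Non-empty numeric vector of single-factor indices.
#' @return NPI value, unitless.
#' @export
npi <- function(sfpi_values) {
  if (length(sfpi_values) == 0L) stop("empty SFPI collection", call. = FALSE)
  mx <- max(sfpi_values)
  av <- mean(sfpi_values)
  sqrt((mx^2 + av^2) / 2)
}

#' Per-sample pollution index table
#'
#' Computes MPI, NPI (with category labels) and the per-metal SFPI for each
#' sample of a campaign.
#'
#' @param samples Campaign data frame ([generate_campaign()] schema).
#' @param authority Standards authority, `"PNSDW"` (default) or `"WHO"`.
#' @return Data frame: `sample_id, mpi, mpi_label, npi, npi_label,
#'   sfpi_<metal>...`.
#' @export
index_table <- function(samples, authority = "PNSDW") {
  s <- standard_limits(authority)
  cm <- concentration_matrix(samples)
  sf <- sweep(cm, 2, s, "/")
  colnames(sf) <- paste0("sfpi_", hm_metals())
  mpi_v <- apply(cm, 1, mpi, standards = s)
  npi_v <- apply(sf, 1, npi)
  out <- data.frame(
    sample_id = samples$sample_id,
    mpi = mpi_v, mpi_label = classify("MPI", mpi_v),
    npi = npi_v, npi_label = classify("NPI", npi_v),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(sf))
}

#' Group-level pollution indices, both aggregation orders
#'
#' "Average MPI of a group" is ambiguous between the index of the group-mean
#' concentrations and the mean of per-sample indices; both are reported.
#'
#' @param samples Campaign data frame.
#' @param by Grouping column, default `"source_type"`.
#' @inheritParams index_table
#' @return Data frame with one row per group: `group, n, mpi_of_means,
#'   mean_mpi, npi_of_means, mean_npi` plus labels for the index-of-means.
#' @export
group_indices <- function(samples, by = "source_type", authority = "PNSDW") {
  s <- standard_limits(authority)
  per <- index_table(samples, authority)
  groups <- split(seq_len(nrow(samples)), samples[[by]])
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    cmean <- colMeans(concentration_matrix(samples[idx, , drop = FALSE]))
    m_of_means <- mpi(cmean, s)
    n_of_means <- npi(sfpi(cmean, s[names(cmean)]))
    data.frame(
      group = g, n = length(idx),
      mpi_of_means = m_of_means,
      mpi_of_means_label = classify("MPI", m_of_means),
      mean_mpi = mean(per$mpi[idx]),
      npi_of_means = n_of_means,
      npi_of_means_label = classify("NPI", n_of_means),
      mean_npi = mean(per$npi[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
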