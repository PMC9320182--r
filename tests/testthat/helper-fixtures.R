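# Shared fixtures, all generated in code.

# a tiny deterministic campaign (three samples, one per source type)
tiny_campaign <- function() {
  d <- data.frame(
    sample_id = c("WRS-001", "GW-001", "TW-001"),
    source_type = c("WRS", "GW", "TW"),
    x = c(1, 2, 3), y = c(1, 2, 3),
    temperature_C = c(26, 29, 29), pH = c(6.7, 7.0, 6.9),
    EC_uScm = c(52, 680, 378), TDS_ppm = c(19, 328, 180),
    stringsAsFactors = FALSE
  )
  conc <- rbind(
    c(0.515, 0.027, 0.038, 0.178, 0.371, 0.009, 0.082, 0.029),
    c(0.106, 0.025, 0.025, 0.901, 1.230, 0.009, 0.077, 0.035),
    c(1.050, 0.023, 0.027, 0.138, 0.432, 0.010, 0.208, 0.030)
  )
  for (i in seq_along(hm_metals())) d[[paste0(hm_metals()[i], "_mgL")]] <- conc[, i]
  d
}

# random positive 8-metal concentration vector
random_conc <- function() {
  stats::setNames(stats::rlnorm(8, -3, 2), hm_metals())
}

# independent two-pass summation oracle for the weighted-mean pollution index
mpi_oracle <- function(conc, standards) {
  num <- 0
  den <- 0
  for (m in names(conc)) {
    q <- conc[[m]] / standards[[m]] * 100
    w <- 1 / standards[[m]]
    num <- num + q * w
    den <- den + w
  }
  num / den
}
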