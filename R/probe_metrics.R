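#' Per-site summary of a methylation value vector
#'
#' Reports the mean, sample SD (n-1 denominator), and the range of the middle
#' 80% of values (q90 - q10). Quantiles use linear interpolation of order
#' statistics with quantile p at rank `1 + (n-1)p` (R's default type 7).
#' Missing values are excluded.
#'
#' @param values numeric vector of proportions, missing allowed.
#' @return list(`mean`, `sd`, `mid80_range`, `n_used`).
#' @export
summarize_probe <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stopf("summarize_probe needs >= 2 non-missing values (got %d)", length(v))
  q <- quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  list(mean = mean(v), sd = sd(v), mid80_range = q[2] - q[1], n_used = length(v))
}

#' Classify probes as variable / intermediate
#'
#' A probe is "variable" when its middle-80% range of beta values is strictly
#' greater than `variable_threshold` (default 5%), and has "intermediate"
#' methylation when its mean lies in the closed interval
#' \[`intermediate_low`, `intermediate_high`\] (default \[20%, 80%\]).
#'
#' @param betas a [beta_matrix()].
#' @param variable_threshold strict lower bound on the middle-80% range.
#' @param intermediate_low,intermediate_high closed bounds on the mean.
#' @param stratum_samples optional character vector of sample ids restricting
#'   the computation (e.g. one sex for X-chromosome work).
#' @param stratum label recorded in the output (`all`, `male`, `female`, ...).
#' @return data.frame (`ProbeClass`): `probe_id`, `mean`, `sd`,
#'   `mid80_range`, `n_used`, `is_variable`, `is_intermediate`, `stratum`.
#' @export
classify_probes <- function(betas, variable_threshold = 0.05,
                            intermediate_low = 0.20, intermediate_high = 0.80,
                            stratum_samples = NULL, stratum = "all") {
  stopifnot(variable_threshold > 0, variable_threshold < 1,
    intermediate_low > 0, intermediate_high < 1,
    intermediate_low < intermediate_high)
  m <- unclass(betas)
  if (!is.null(stratum_samples)) {
    keep <- intersect(colnames(m), stratum_samples)
    if (!length(keep)) stopf("empty stratum: no samples of '%s' in matrix", stratum)
    m <- m[, keep, drop = FALSE]
  }
  n_used <- rowSums(!is.na(m))
  if (any(n_used < 2))
    stopf("probe %s has < 2 non-missing values", rownames(m)[n_used < 2][1])
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, sd, na.rm = TRUE)
  qr_ <- t(apply(m, 1, quantile, probs = c(0.1, 0.9), na.rm = TRUE,
    names = FALSE, type = 7))
  mid80 <- qr_[, 2] - qr_[, 1]
  data.frame(probe_id = rownames(m), mean = mu, sd = sdv, mid80_range = mid80,
    n_used = as.integer(n_used),
    is_variable = mid80 > variable_threshold,
    is_intermediate = mu >= intermediate_low & mu <= intermediate_high,
    stratum = stratum, row.names = NULL)
}
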