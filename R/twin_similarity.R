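# extract per-pair value matrices for one zygosity (sites x pairs, twin1/twin2)
pair_value_matrices <- function(betas, manifest, zygosity = NULL) {
  mf <- manifest
  if (!is.null(zygosity)) mf <- mf[mf$zygosity %in% zygosity, , drop = FALSE]
  keep <- mf$sample_id_a %in% colnames(betas) & mf$sample_id_b %in% colnames(betas)
  mf <- mf[keep, , drop = FALSE]
  m <- unclass(betas)
  list(Y1 = m[, mf$sample_id_a, drop = FALSE],
       Y2 = m[, mf$sample_id_b, drop = FALSE],
       manifest = mf)
}

# row-wise Pearson r between two matrices with pairwise-complete masking
rowwise_pearson <- function(X, Y) {
  ok <- !is.na(X) & !is.na(Y)
  X[!ok] <- NA; Y[!ok] <- NA
  n <- rowSums(ok)
  sx <- rowSums(X, na.rm = TRUE); sy <- rowSums(Y, na.rm = TRUE)
  sxx <- rowSums(X * X, na.rm = TRUE); syy <- rowSums(Y * Y, na.rm = TRUE)
  sxy <- rowSums(X * Y, na.rm = TRUE)
  num <- n * sxy - sx * sy
  den2 <- (n * sxx - sx^2) * (n * syy - sy^2)
  r <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  list(r = r, n = n)
}

#' Per-site double-entry twin correlation
#'
#' The pair list is mirrored ((y1,y2) and (y2,y1)) before computing the
#' Pearson correlation, making the statistic invariant to within-pair member
#' ordering (an intraclass-correlation analogue). Pairs with a missing member
#' are dropped for that site; at least 2 complete non-constant pairs are
#' required here, while the genome-wide table ([twin_correlations()]) masks
#' correlations based on fewer than 3 pairs.
#'
#' @param site_values numeric vector of beta values named by sample id.
#' @param manifest a [pair_manifest()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param double_entry mirror pairs before correlating (default TRUE); FALSE
#'   gives the single-ordering Pearson correlation as listed in the manifest.
#' @return list(`r`, `n_pairs`).
#' @export
site_twin_correlation <- function(site_values, manifest, zygosity,
                                  double_entry = TRUE) {
  mf <- manifest[manifest$zygosity == zygosity, , drop = FALSE]
  y1 <- site_values[mf$sample_id_a]
  y2 <- site_values[mf$sample_id_b]
  ok <- !is.na(y1) & !is.na(y2)
  y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(y1)
  if (n < 2) return(list(r = NA_real_, n_pairs = n))
  x <- if (double_entry) c(y1, y2) else y1
  y <- if (double_entry) c(y2, y1) else y2
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, n_pairs = n))
  list(r = cor(x, y), n_pairs = n)
}

#' Genome-wide per-site MZ and DZ twin correlations
#'
#' Vectorized [site_twin_correlation()] across all probes of a beta matrix.
#'
#' @param betas a [beta_matrix()].
#' @param manifest a [pair_manifest()].
#' @param double_entry mirror pairs before correlating (default TRUE).
#' @return data.frame (`TwinCorrelations`): `probe_id`, `r_MZ`, `n_MZ_pairs`,
#'   `r_DZ`, `n_DZ_pairs`; correlations are `NA` when fewer than 3 complete
#'   pairs or zero variance.
#' @export
twin_correlations <- function(betas, manifest, double_entry = TRUE) {
  res <- lapply(c("MZ", "DZ"), function(z) {
    pv <- pair_value_matrices(betas, manifest, z)
    if (double_entry) {
      rr <- rowwise_pearson(cbind(pv$Y1, pv$Y2), cbind(pv$Y2, pv$Y1))
      rr$n <- rr$n / 2
    } else {
      rr <- rowwise_pearson(pv$Y1, pv$Y2)
    }
    rr$r[rr$n < 3] <- NA_real_
    rr
  })
  data.frame(probe_id = rownames(betas),
    r_MZ = res[[1]]$r, n_MZ_pairs = as.integer(res[[1]]$n),
    r_DZ = res[[2]]$r, n_DZ_pairs = as.integer(res[[2]]$n),
    row.names = NULL)
}

#' Whole-profile correlation within each twin pair
#'
#' Pearson correlation across sites between the two members' methylation
#' profiles, per pair. Pairs with fewer than `min_sites` shared non-missing
#' sites get `NA` with the reason recorded. Optionally also computes a
#' baseline of randomly matched individuals from different families (drawn
#' without replacement, seeded).
#'
#' @param betas a [beta_matrix()].
#' @param manifest a [pair_manifest()].
#' @param probe_subset optional character vector of probe ids.
#' @param min_sites minimum shared non-missing sites per pair (default 10).
#' @param n_unrelated number of unrelated baseline pairs to draw (default 0).
#' @param seed seed for the unrelated draw.
#' @return data.frame: `pair_id`, `zygosity` (`MZ`/`DZ`/`unrelated`), `r`,
#'   `n_sites`, `reason` (`NA` unless the correlation is missing).
#' @export
pair_profile_correlation <- function(betas, manifest, probe_subset = NULL,
                                     min_sites = 10, n_unrelated = 0,
                                     seed = 1L) {
  m <- unclass(betas)
  if (!is.null(probe_subset)) m <- m[intersect(rownames(m), probe_subset), , drop = FALSE]
  one <- function(a, b) {
    x <- m[, a]; y <- m[, b]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_sites)
      return(list(r = NA_real_, n = n, reason = sprintf("only %d shared sites", n)))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(list(r = NA_real_, n = n, reason = "zero variance"))
    list(r = cor(x[ok], y[ok]), n = n, reason = NA_character_)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i)
    c(list(pair_id = manifest$pair_id[i], zygosity = manifest$zygosity[i]),
      one(manifest$sample_id_a[i], manifest$sample_id_b[i])))
  if (n_unrelated > 0) {
    set.seed(derive_seed(seed, "unrelated"))
    fam <- manifest$family_id[match(sub("_[12]$", "", colnames(m)), manifest$pair_id)]
    ids <- sample(colnames(m))
    used <- logical(length(ids))
    k <- 0L
    for (i in seq_along(ids)) {
      if (used[i] || k >= n_unrelated) next
      j <- which(!used & fam != fam[match(ids[i], colnames(m))] &
        seq_along(ids) > i)[1]
      if (is.na(j)) next
      used[i] <- used[j] <- TRUE
      k <- k + 1L
      rows[[length(rows) + 1L]] <- c(list(pair_id = sprintf("UR%04d", k),
        zygosity = "unrelated"), one(ids[i], ids[j]))
    }
  }
  data.frame(pair_id = vapply(rows, `[[`, "", "pair_id"),
    zygosity = vapply(rows, `[[`, "", "zygosity"),
    r = vapply(rows, `[[`, 0, "r"),
    n_sites = vapply(rows, function(x) as.integer(x$n), 0L),
    reason = vapply(rows, `[[`, "", "reason"), row.names = NULL)
}

#' Exact two-sided binomial sign test with log-space tails
#'
#' Tests `k` successes in `m` fair-coin trials: two-sided p-value
#' `min(1, 2 * min(P(X <= k), P(X >= k)))`, with tail sums accumulated in log
#' space so `log10_p` stays exact to at least 6 significant digits even when
#' the p-value underflows a double (the 1e-323-scale values printed by most
#' software are underflow artifacts).
#'
#' @param k number of successes (0 <= k <= m).
#' @param m number of trials (>= 1).
#' @return list (`SignTestResult`): `k_success`, `m_trials`, `p_two_sided`
#'   (0 when underflowed), `log10_p` (always finite), `p_printed` (exact
#'   scientific string built from `log10_p`).
#' @export
exact_sign_test <- function(k, m) {
  stopifnot(length(k) == 1, length(m) == 1, m >= 1, k >= 0, k <= m)
  k <- as.numeric(k); m <- as.numeric(m)
  log_tail <- function(kk) {
    # log P(X <= kk); sum over the smaller tail by symmetry
    if (kk >= m) return(0)
    if (kk < 0) return(-Inf)
    logsumexp(lchoose(m, 0:kk)) - m * log(2)
  }
  lo <- log_tail(k)
  hi <- log_tail(m - k)  # P(X >= k) = P(X <= m - k) by symmetry of Binom(m, 1/2)
  lp <- min(lo, hi) + log(2)
  lp <- min(lp, 0)
  log10_p <- lp / log(10)
  p <- exp(lp)
  p_printed <- if (p > 0 && p >= 1e-300) sprintf("%.3g", p) else
    sprintf("%.3fe%d", 10^(log10_p - floor(log10_p)), as.integer(floor(log10_p)))
  structure(list(k_success = k, m_trials = m, p_two_sided = p,
    log10_p = log10_p, p_printed = p_printed), class = "SignTestResult")
}

#' @export
print.SignTestResult <- function(x, ...) {
  cat(sprintf("Exact sign test: k = %g of m = %g, two-sided p = %s (log10 p = %.4f)\n",
    x$k_success, x$m_trials,
    if (x$p_two_sided < 1e-300) paste0("<1e-300 (exact ", x$p_printed, ")") else x$p_printed,
    x$log10_p))
  invisible(x)
}

#' Compare mean twin-pair similarity between two groups
#'
#' Welch two-sample t-test on Fisher z-transformed correlations; group means
#' are reported back on the correlation scale. Correlations with |r| = 1 are
#' clamped to 1 - 1e-12 before the transform (count reported).
#'
#' @param r_group1,r_group2 numeric vectors of correlations (>= 2 each).
#' @return list(`mean1`, `mean2`, `p`, `t`, `df`, `n_clamped`).
#' @export
compare_group_similarity <- function(r_group1, r_group2) {
  r1 <- r_group1[!is.na(r_group1)]; r2 <- r_group2[!is.na(r_group2)]
  if (length(r1) < 2 || length(r2) < 2) stopf("need >= 2 correlations per group")
  clamp <- function(r) pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  n_clamped <- sum(abs(c(r1, r2)) >= 1)
  z1 <- atanh(clamp(r1)); z2 <- atanh(clamp(r2))
  v1 <- var(z1) / length(z1); v2 <- var(z2) / length(z2)
  tstat <- (mean(z1) - mean(z2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(z1) - 1) + v2^2 / (length(z2) - 1))
  p <- if (!is.finite(tstat)) 1 else 2 * pt(-abs(tstat), df)
  list(mean1 = mean(r1), mean2 = mean(r2), p = p, t = tstat, df = df,
    n_clamped = n_clamped)
}
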