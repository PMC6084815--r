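# exact two-sided Mann-Whitney p by enumerating the permutation distribution
# of U (handles ties via midranks); only used for small samples
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- utils::combn(n1 + n2, n1, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  list(U = u_obs, p = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

#' Compare A/C/E distributions between two probe strata
#'
#' Two-sided Mann-Whitney U test per variance component; for small samples
#' (combined n <= 16) the exact permutation distribution of U is enumerated
#' (ties handled by midranks), otherwise the normal approximation with tie
#' correction is used. Means and SDs are reported on the percent scale.
#'
#' @param decomp a `VarianceDecomposition` data.frame.
#' @param membership logical vector (or probe-id character vector) defining
#'   stratum 1; the complement is stratum 2.
#' @param components which of A/C/E to compare.
#' @param labels length-2 stratum labels.
#' @return data.frame (`StratumComparison`): `component`, `stratum1`,
#'   `stratum2`, `n1`, `n2`, `mean1`, `sd1`, `mean2`, `sd2`, `U`, `p`.
#' @export
compare_strata <- function(decomp, membership,
                           components = c("A", "C", "E"),
                           labels = c("in", "out")) {
  if (is.character(membership)) membership <- decomp$probe_id %in% membership
  stopifnot(length(membership) == nrow(decomp))
  if (!any(membership, na.rm = TRUE) || !any(!membership, na.rm = TRUE))
    stopf("both strata must be non-empty")
  rows <- lapply(components, function(cmp) {
    x <- decomp[[cmp]][membership]; y <- decomp[[cmp]][!membership]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) + length(y) <= 16) {
      mw <- mw_exact_p(x, y)
      U <- mw$U; p <- mw$p
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
        exact = FALSE, correct = FALSE))
      U <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(component = cmp, stratum1 = labels[1], stratum2 = labels[2],
      n1 = length(x), n2 = length(y),
      mean1 = 100 * mean(x), sd1 = 100 * sd(x),
      mean2 = 100 * mean(y), sd2 = 100 * sd(y),
      U = U, p = p)
  })
  do.call(rbind, rows)
}

# shared moving-window engine: mean of y over windows in x
moving_window <- function(x, y, centers, half_width, min_n, band = FALSE) {
  rows <- lapply(centers, function(cc) {
    sel <- x >= cc - half_width & x < cc + half_width & !is.na(y)
    n <- sum(sel)
    if (n < min_n)
      return(data.frame(center = cc, mean = NA_real_, n = n,
        q2.5 = NA_real_, q97.5 = NA_real_))
    qs <- if (band) quantile(y[sel], c(0.025, 0.975), names = FALSE) else c(NA, NA)
    data.frame(center = cc, mean = mean(y[sel]), n = n, q2.5 = qs[1], q97.5 = qs[2])
  })
  do.call(rbind, rows)
}

#' Sliding-window positional profile of variance components
#'
#' Mean A/C/E in windows of anchored signed distance (strand-aware TSS or TES
#' distance from the annotation), advancing by `step_bp`. Windows cover
#' `[center - window_bp/2, center + window_bp/2)`; windows with fewer than
#' `min_n` probes are emitted as missing, not zero.
#'
#' @param decomp `VarianceDecomposition` data.frame.
#' @param annotation [probe_annotation()] carrying the distance column.
#' @param window_bp,step_bp window width and step, both positive.
#' @param anchor distance column basename: `"TSS"` uses `tss_distance`,
#'   `"TES"` uses `tes_distance`.
#' @param min_n minimum probes per emitted window (default 50).
#' @param max_distance probes farther than this from the anchor are excluded
#'   (default 100 kb).
#' @return data.frame: `center`, `mean_A`, `mean_C`, `mean_E`, `n`.
#' @export
positional_profile <- function(decomp, annotation, window_bp = 500,
                               step_bp = 100, anchor = c("TSS", "TES"),
                               min_n = 50, max_distance = 1e5) {
  anchor <- match.arg(anchor)
  if (window_bp <= 0 || step_bp <= 0) stopf("window_bp and step_bp must be positive")
  dcol <- if (anchor == "TSS") "tss_distance" else "tes_distance"
  if (!dcol %in% names(annotation)) stopf("annotation lacks column %s", dcol)
  d <- annotation[[dcol]][match(decomp$probe_id, annotation$probe_id)]
  keep <- !is.na(d) & abs(d) <= max_distance
  d <- d[keep]; dc <- decomp[keep, , drop = FALSE]
  if (!length(d)) stopf("no probes with anchored distances")
  centers <- seq(floor(min(d) / step_bp) * step_bp,
    ceiling(max(d) / step_bp) * step_bp, by = step_bp)
  prof <- lapply(c("A", "C", "E"), function(cmp)
    moving_window(d, dc[[cmp]], centers, window_bp / 2, min_n)$mean)
  n <- moving_window(d, dc$A, centers, window_bp / 2, 0)$n
  data.frame(center = centers, mean_A = prof[[1]], mean_C = prof[[2]],
    mean_E = prof[[3]], n = n)
}

#' Moving-mean level profile with 95% interquantile band
#'
#' Moving mean of `y` over windows in `x` (e.g. a variance component or mQTL
#' effect against mean methylation level), with a band given by the 2.5 and
#' 97.5 percentiles of `y` within each window.
#'
#' @param x,y per-probe numeric vectors of equal length.
#' @param window_width,step window width and step on the `x` scale.
#' @param min_n minimum probes per emitted window.
#' @return data.frame: `center`, `mean`, `q2.5`, `q97.5`, `n`.
#' @export
level_profile <- function(x, y, window_width = 0.1, step = 0.02, min_n = 50) {
  stopifnot(length(x) == length(y))
  if (window_width <= 0 || step <= 0) stopf("window_width and step must be positive")
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stopf("no usable probes")
  centers <- seq(min(x), max(x), by = step)
  moving_window(x, y, centers, window_width / 2, min_n, band = TRUE)
}

# two-sided Fisher exact p in log space: sum of hypergeometric outcomes with
# probability <= that of the observed table (relative tolerance 1e-7)
fisher_log_p <- function(k, K, n, N) {
  # k flagged in set of n, K flagged total, N total
  lo <- max(0, n + K - N); hi <- min(n, K)
  supp <- lo:hi
  lp <- dhyper(supp, K, N - K, n, log = TRUE)
  obs <- lp[supp == k]
  sel <- lp <= obs + 1e-7
  list(log_p = min(logsumexp(lp[sel]), 0),
    log10_p = min(logsumexp(lp[sel]), 0) / log(10))
}

#' Enrichment of mQTL-flagged probes among highly heritable sites
#'
#' Builds the 2x2 table of (A > `a_threshold`) x (has mQTL) and tests it with
#' a two-sided Fisher exact test computed in log space. Probes without an
#' mQTL flag entry are excluded (count reported). The odds ratio is the
#' sample cross-product ratio; empty margins give an infinite/flagged OR.
#'
#' @param decomp `VarianceDecomposition` data.frame.
#' @param mqtl_flags logical vector named by probe id, or character vector of
#'   flagged probe ids.
#' @param a_threshold heritability cutoff defining the high-A set
#'   (default 0.8).
#' @return list (`EnrichmentResult`): `table` (2x2 counts), `prop_high`,
#'   `prop_low` (flagged fraction in/outside the high-A set), `odds_ratio`,
#'   `or_degenerate`, `p`, `log10_p`, `n_unflagged_excluded`.
#' @export
mqtl_enrichment <- function(decomp, mqtl_flags, a_threshold = 0.8) {
  if (is.character(mqtl_flags))
    mqtl_flags <- setNames(decomp$probe_id %in% mqtl_flags, decomp$probe_id)
  flag <- mqtl_flags[decomp$probe_id]
  excl <- sum(is.na(flag))
  keep <- !is.na(flag) & !is.na(decomp$A)
  flag <- as.logical(flag[keep])
  high <- decomp$A[keep] > a_threshold
  tab <- matrix(c(sum(high & flag), sum(high & !flag),
    sum(!high & flag), sum(!high & !flag)), 2, byrow = TRUE,
    dimnames = list(c("A_high", "A_low"), c("mQTL", "no_mQTL")))
  or_deg <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  fp <- fisher_log_p(tab[1, 1], sum(tab[, 1]), sum(tab[1, ]), sum(tab))
  structure(list(table = tab,
    prop_high = tab[1, 1] / max(sum(tab[1, ]), 1),
    prop_low = tab[2, 1] / max(sum(tab[2, ]), 1),
    odds_ratio = or, or_degenerate = or_deg,
    p = exp(fp$log_p), log10_p = fp$log10_p,
    n_unflagged_excluded = excl), class = "EnrichmentResult")
}

#' Heritability stratified by cross-tissue covariation
#'
#' Splits probes at a covariation cutoff (e.g. blood-brain correlation of
#' inter-individual variation), compares the A distributions above vs below
#' by Mann-Whitney, and reports the overall Pearson correlation between A and
#' the covariation score.
#'
#' @param decomp `VarianceDecomposition` data.frame.
#' @param covariation_r numeric vector named by probe id (or aligned with
#'   `decomp` rows).
#' @param cutoff covariation threshold (default 0.5).
#' @param min_per_side minimum probes required on each side (default 10).
#' @return list: `median_A_above`, `median_A_below`, `n_above`, `n_below`,
#'   `p` (Mann-Whitney), `pearson_r`.
#' @export
covariation_stratified_heritability <- function(decomp, covariation_r,
                                                cutoff = 0.5,
                                                min_per_side = 10) {
  cv <- if (!is.null(names(covariation_r)))
    covariation_r[decomp$probe_id] else covariation_r
  keep <- !is.na(cv) & !is.na(decomp$A)
  cv <- cv[keep]; A <- decomp$A[keep]
  above <- cv > cutoff
  if (sum(above) < min_per_side || sum(!above) < min_per_side)
    stopf("need >= %d probes on each side of the covariation cutoff", min_per_side)
  wt <- suppressWarnings(wilcox.test(A[above], A[!above]))
  list(median_A_above = stats::median(A[above]),
    median_A_below = stats::median(A[!above]),
    n_above = sum(above), n_below = sum(!above),
    p = wt$p.value, pearson_r = cor(A, cv))
}
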