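#' Ordinary least squares with cluster-robust (sandwich) standard errors
#'
#' Coefficients are plain OLS; the covariance is the cluster-robust sandwich
#' `(X'X)^-1 (sum_g X_g' u_g u_g' X_g) (X'X)^-1` with the CR1 small-sample
#' factor `G/(G-1) * (n-1)/(n-k)`, and Wald t statistics are referred to a
#' t distribution with `G - 1` degrees of freedom. With every cluster a
#' singleton this reduces to the HC1-style heteroskedasticity-robust
#' covariance.
#'
#' @param y response vector.
#' @param X design matrix including the intercept column.
#' @param cluster_ids cluster (family) label per observation.
#' @return list: `coefficients`, `vcov` (robust), `se`, `t`, `p`, `df`
#'   (`G - 1`), `n`, `n_clusters`, `residuals`.
#' @export
fit_clustered_ols <- function(y, X, cluster_ids) {
  X <- as.matrix(X)
  n <- length(y); k <- ncol(X)
  stopifnot(nrow(X) == n, length(cluster_ids) == n)
  cluster_ids <- as.character(cluster_ids)
  G <- length(unique(cluster_ids))
  if (G < 2) stopf("need >= 2 clusters (a single cluster contains all samples)")
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):k]] %||% "unnamed"
    stopf("singular design; collinear column(s): %s", paste(bad, collapse = ", "))
  }
  if (n <= k) stopf("need more observations than design columns")
  beta <- qr.coef(qx, y)
  u <- y - X %*% beta
  bread <- chol2inv(qr.R(qx))          # (X'X)^-1 via the QR factor
  B <- rowsum(X * as.numeric(u), cluster_ids)   # G x k cluster score sums
  meat <- crossprod(B)
  cr1 <- G / (G - 1) * (n - 1) / (n - k)
  V <- cr1 * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  tstat <- as.numeric(beta) / se
  p <- 2 * pt(-abs(tstat), df = G - 1)
  list(coefficients = setNames(as.numeric(beta), colnames(X)), vcov = V,
    se = se, t = tstat, p = p, df = G - 1, n = n, n_clusters = G,
    residuals = as.numeric(u))
}

# build the EWAS design matrix: exposure contrast + adjustment covariates
ewas_design <- function(covariates, samples, exposure, adjust) {
  cd <- as.data.frame(covariates)
  cd <- cd[match(samples, cd$sample_id), , drop = FALSE]
  ev <- cd[[exposure]]
  if (is.null(ev)) stopf("exposure column '%s' not in covariates", exposure)
  x_exp <- if (is.numeric(ev)) ev else as.numeric(ev == "current")
  if (length(unique(x_exp)) < 2) stopf("exposure is constant across included samples")
  X <- cbind("(Intercept)" = 1, exposure = x_exp)
  if (length(adjust)) {
    ad <- cd[, adjust, drop = FALSE]
    Xa <- stats::model.matrix(~ ., data = ad)[, -1, drop = FALSE]
    X <- cbind(X, Xa)
  }
  X
}

#' Site-wise exposure EWAS with cluster-robust standard errors
#'
#' Per site, fits `beta ~ exposure + adjustments` by OLS over all samples
#' with complete data (twin pairs and singletons alike), with standard
#' errors clustered on the family id to absorb twin relatedness. The default
#' exposure contrast codes `smoking_status == "current"` as 1 against former
#' and never smokers as 0.
#'
#' @param betas a [beta_matrix()].
#' @param covariates a [sample_covariates()] carrying the exposure, the
#'   cluster column and any adjustment covariates.
#' @param exposure covariate column holding the exposure (default
#'   `smoking_status`; a numeric column is used as-is).
#' @param adjust character vector of adjustment covariate columns.
#' @param cluster covariate column with the cluster label (default
#'   `family_id`).
#' @param dmp_threshold significance threshold defining DMPs (default 1e-7).
#' @return data.frame (`EwasResult`) sorted by p: `probe_id`, `effect`,
#'   `robust_se`, `t`, `p`, `n_samples`, `n_clusters`, `is_dmp`.
#' @export
run_ewas <- function(betas, covariates, exposure = "smoking_status",
                     adjust = character(), cluster = "family_id",
                     dmp_threshold = 1e-7) {
  cd <- as.data.frame(covariates)
  if (!cluster %in% names(cd)) stopf("cluster column '%s' not in covariates", cluster)
  samples <- intersect(colnames(betas), cd$sample_id)
  need <- c(exposure, adjust, cluster)
  cc <- samples[stats::complete.cases(cd[match(samples, cd$sample_id), need, drop = FALSE])]
  if (length(cc) < 3) stopf("too few samples with complete exposure/covariates")
  X <- ewas_design(covariates, cc, exposure, adjust)
  cl <- cd[[cluster]][match(cc, cd$sample_id)]
  G <- length(unique(cl))
  Y <- t(unclass(betas)[, cc, drop = FALSE])     # samples x sites

  complete <- !apply(Y, 2, anyNA)
  n <- nrow(Y); k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k)
    stopf("singular design; collinear column(s): %s",
      paste(colnames(X)[qx$pivot[(qx$rank + 1):k]], collapse = ", "))
  eff <- se <- rep(NA_real_, ncol(Y))
  # fast vectorized path for sites with no missing values
  if (any(complete)) {
    Yc <- Y[, complete, drop = FALSE]
    Bhat <- qr.coef(qx, Yc)
    U <- Yc - X %*% Bhat
    bread <- chol2inv(qr.R(qx))
    j <- 2L                                      # exposure coefficient
    # W = sum_l bread[j, l] * rowsum(X[, l] * U, cluster): G x sites
    W <- 0
    for (l in seq_len(k)) W <- W + bread[j, l] * rowsum(X[, l] * U, cl)
    cr1 <- G / (G - 1) * (n - 1) / (n - k)
    eff[complete] <- Bhat[j, ]
    se[complete] <- sqrt(cr1 * colSums(W^2))
  }
  # per-site fallback where betas are missing
  for (i in which(!complete)) {
    ok <- !is.na(Y[, i])
    f <- tryCatch(fit_clustered_ols(Y[ok, i], X[ok, , drop = FALSE], cl[ok]),
      error = function(e) NULL)
    if (!is.null(f)) { eff[i] <- f$coefficients[2]; se[i] <- f$se[2] }
  }
  tstat <- eff / se
  p <- 2 * pt(-abs(tstat), df = G - 1)
  out <- data.frame(probe_id = colnames(Y), effect = eff, robust_se = se,
    t = tstat, p = p, n_samples = n, n_clusters = G,
    is_dmp = !is.na(p) & p < dmp_threshold, row.names = NULL)
  out[order(out$p), ]
}

# per-site double-entry correlations restricted to a subset of pairs
subset_twin_correlations <- function(betas, manifest, pair_ids) {
  twin_correlations(betas, manifest[manifest$pair_id %in% pair_ids, , drop = FALSE])
}

#' Heritability profile of exposure-associated DMPs
#'
#' Three linked analyses of a DMP set against the twin structure:
#' (i) A/C/E distributions at DMPs versus background probes
#' ([compare_strata()]); (ii) per-site MZ vs DZ correlations restricted to
#' exposure-concordant-unexposed pairs, with the count of sites where
#' `r_MZ > r_DZ` tested by [exact_sign_test()] — heritability detected there
#' cannot be driven by the exposure; (iii) Falconer estimates per DMP within
#' each exposure-concordance class (concordant-unexposed / discordant /
#' concordant-exposed).
#'
#' @param dmp_set character vector of DMP probe ids.
#' @param decomp `VarianceDecomposition` table covering DMPs and background.
#' @param betas a [beta_matrix()].
#' @param manifest a [pair_manifest()].
#' @param covariates a [sample_covariates()] with the exposure column.
#' @param exposure exposure column name (default `smoking_status`; "never" /
#'   0 is treated as unexposed, anything else exposed).
#' @param background_probes probe ids for the comparison background (default:
#'   all non-DMP probes in `decomp`).
#' @return list: `strata_comparison`, `sign_test` (with `k`, `m`),
#'   `concordance_counts`, `falconer_by_class` (named list of data.frames),
#'   `skipped` (named reasons for sections that could not run).
#' @export
dmp_heritability_report <- function(dmp_set, decomp, betas, manifest,
                                    covariates, exposure = "smoking_status",
                                    background_probes = NULL) {
  if (!length(dmp_set)) stopf("DMP set is empty")
  cd <- as.data.frame(covariates)
  ev <- cd[[exposure]]
  if (is.null(ev)) stopf("exposure column '%s' not in covariates", exposure)
  unexposed <- if (is.numeric(ev)) ev == 0 else ev == "never"
  names(unexposed) <- cd$sample_id

  bg <- background_probes %||% setdiff(decomp$probe_id, dmp_set)
  sub <- decomp[decomp$probe_id %in% c(dmp_set, bg), , drop = FALSE]
  strata_cmp <- compare_strata(sub, sub$probe_id %in% dmp_set,
    labels = c("DMP", "background"))

  ua <- unexposed[manifest$sample_id_a]; ub <- unexposed[manifest$sample_id_b]
  cls <- ifelse(ua & ub, "concordant_unexposed",
    ifelse(!ua & !ub, "concordant_exposed", "discordant"))
  cls[is.na(ua) | is.na(ub)] <- NA
  counts <- table(factor(cls, levels = c("concordant_unexposed", "discordant",
    "concordant_exposed")), manifest$zygosity)

  skipped <- list()
  sign_test <- NULL
  dmp_in <- intersect(dmp_set, rownames(betas))
  cu_pairs <- manifest$pair_id[!is.na(cls) & cls == "concordant_unexposed"]
  cu_mf <- manifest[manifest$pair_id %in% cu_pairs, , drop = FALSE]
  if (sum(cu_mf$zygosity == "MZ") < 3 || sum(cu_mf$zygosity == "DZ") < 3) {
    skipped$sign_test <- "fewer than 3 concordant-unexposed pairs in a zygosity group"
  } else {
    tc <- subset_twin_correlations(betas[dmp_in, , drop = FALSE], manifest, cu_pairs)
    ok <- !is.na(tc$r_MZ) & !is.na(tc$r_DZ)
    k <- sum(tc$r_MZ[ok] > tc$r_DZ[ok]); m <- sum(ok)
    sign_test <- exact_sign_test(k, m)
  }

  falconer_by_class <- list()
  for (cl_name in c("concordant_unexposed", "discordant", "concordant_exposed")) {
    pid <- manifest$pair_id[!is.na(cls) & cls == cl_name]
    mf <- manifest[manifest$pair_id %in% pid, , drop = FALSE]
    if (sum(mf$zygosity == "MZ") < 3 || sum(mf$zygosity == "DZ") < 3) {
      skipped[[cl_name]] <- "fewer than 3 pairs in a zygosity group"
      next
    }
    tc <- subset_twin_correlations(betas[dmp_in, , drop = FALSE], manifest, pid)
    falconer_by_class[[cl_name]] <- cbind(probe_id = tc$probe_id,
      falconer_estimates(tc$r_MZ, tc$r_DZ),
      n_MZ = tc$n_MZ_pairs, n_DZ = tc$n_DZ_pairs)
  }

  list(strata_comparison = strata_cmp, sign_test = sign_test,
    concordance_counts = counts, falconer_by_class = falconer_by_class,
    skipped = skipped)
}
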