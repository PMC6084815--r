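# --- sufficient statistics -------------------------------------------------
# With a common mean and variance across twin order and zygosity groups, the
# pair-level bivariate normal log-likelihood depends on the data only through
# per-group moments: n pairs, s = sum(y1 + y2), q = sum(y1^2 + y2^2),
# x = sum(y1 * y2). Complete pairs only.
pair_moments <- function(pairs) {
  p <- as.matrix(pairs)
  if (ncol(p) != 2) stopf("pairs must have two columns")
  p <- p[complete.cases(p), , drop = FALSE]
  list(n = nrow(p), s = sum(p[, 1] + p[, 2]),
    q = sum(p[, 1]^2 + p[, 2]^2), x = sum(p[, 1] * p[, 2]))
}

# double-entry Pearson correlation from pair moments
moments_r <- function(m) {
  if (m$n < 1) return(NA_real_)
  mu <- m$s / (2 * m$n)
  v <- m$q / (2 * m$n) - mu^2
  k <- m$x / m$n - mu * m$s / m$n + mu^2
  if (v <= 0) return(NA_real_)
  k / v
}

# bivariate-normal log-likelihood for one group with covariance [[v,k],[k,v]]
ace_group_loglik <- function(mu, v, k, m) {
  det2 <- v^2 - k^2
  if (det2 <= 0 || v <= 0) return(-Inf)
  Q <- (v * (m$q - 2 * mu * m$s + 2 * m$n * mu^2) -
        2 * k * (m$x - mu * m$s + m$n * mu^2)) / det2
  -m$n * log(2 * pi) - m$n / 2 * log(det2) - Q / 2
}

ace_negloglik <- function(par, momMZ, momDZ, e_floor2) {
  mu <- par[1]; a2 <- par[2]^2; c2 <- par[3]^2; e2 <- par[4]^2 + e_floor2
  v <- a2 + c2 + e2
  -(ace_group_loglik(mu, v, a2 + c2, momMZ) +
    ace_group_loglik(mu, v, a2 / 2 + c2, momDZ))
}

# --- FIML fit --------------------------------------------------------------

#' Fit the ACE model by full-information maximum likelihood
#'
#' Maximizes the sum over twin pairs of the bivariate-normal log-likelihood
#' with a common mean and total variance across zygosity groups and twin
#' order, and the classical ACE covariance structure: the MZ within-pair
#' covariance is `a^2 + c^2`, the DZ covariance `a^2/2 + c^2`, the variance
#' `a^2 + c^2 + e^2`. The model is parameterized by path coefficients
#' `(a, c, e)` so the variance components are nonnegative by construction;
#' `e` is floored at `1e-6` of the total sample SD. Optimization is
#' deterministic multi-start (Falconer-based and equal-thirds starts), best
#' fit kept.
#'
#' @param pairs_MZ,pairs_DZ two-column matrices of twin values (one row per
#'   pair); rows with a missing member are dropped. At least 3 complete
#'   pairs per group.
#' @param options list; recognised: `e_floor_frac` (default 1e-6),
#'   `boundary_tol_frac` (path coefficient below this fraction of the total
#'   SD flags a boundary solution, default 1e-5), `grad_tol` (gradient-norm
#'   convergence check, default 1e-4).
#' @return one-row data.frame (`VarianceDecomposition`): standardized `A`,
#'   `C`, `E`; raw components `A_raw`, `C_raw`, `E_raw` (variance units);
#'   `sigma2`, `mu`, `r_MZ`, `r_DZ`, `n_MZ`, `n_DZ`, `loglik`, `converged`,
#'   `boundary` (comma-joined subset of "A","C"), `method = "fiml"`.
#' @export
fit_ace_fiml <- function(pairs_MZ, pairs_DZ, options = list()) {
  momMZ <- pair_moments(pairs_MZ)
  momDZ <- pair_moments(pairs_DZ)
  if (momMZ$n < 3 || momDZ$n < 3)
    stopf("need >= 3 complete pairs per zygosity (have %d MZ, %d DZ)", momMZ$n, momDZ$n)
  fit_ace_from_moments(momMZ, momDZ, options)
}

fit_ace_from_moments <- function(momMZ, momDZ, options = list(),
                                 probe_id = NA_character_, stratum = "all") {
  opt <- modifyList(list(e_floor_frac = 1e-6, boundary_tol_frac = 1e-5,
    grad_tol = 1e-5), options)
  n2 <- 2 * (momMZ$n + momDZ$n)
  mu0 <- (momMZ$s + momDZ$s) / n2
  var0 <- (momMZ$q + momDZ$q) / n2 - mu0^2
  if (var0 <= 0) stopf("zero total variance; ACE model undefined")
  sd0 <- sqrt(var0)

  # standardize so all parameters are O(1): y' = (y - mu0) / sd0
  std <- function(m) list(n = m$n,
    s = (m$s - 2 * m$n * mu0) / sd0,
    q = (m$q - 2 * mu0 * m$s + 2 * m$n * mu0^2) / var0,
    x = (m$x - mu0 * m$s + m$n * mu0^2) / var0)
  sMZ <- std(momMZ); sDZ <- std(momDZ)
  e_floor2 <- (opt$e_floor_frac)^2  # standardized scale, total SD ~ 1

  rMZ <- moments_r(momMZ); rDZ <- moments_r(momDZ)
  fal_A <- min(max(2 * (rMZ - rDZ), 0.02), 0.96)
  fal_C <- min(max(2 * rDZ - rMZ, 0.02), 1 - fal_A - 0.02)
  starts <- list(
    c(0, sqrt(fal_A), sqrt(fal_C), sqrt(max(1 - fal_A - fal_C, 0.02))),
    c(0, 1, 1, 1) / sqrt(3))

  run1 <- function(st, fixed = NULL) {
    # fixed: indices among (a, c) pinned to zero, optimizing the remainder
    free <- setdiff(seq_len(4), fixed)
    obj <- function(p) {
      par <- numeric(4); par[free] <- p
      ace_negloglik(par, sMZ, sDZ, e_floor2)
    }
    fit <- tryCatch(optim(st[free], obj, method = "BFGS",
      control = list(maxit = 1000, reltol = 1e-14)), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    par <- numeric(4); par[free] <- fit$par
    list(par = par, value = fit$value, convergence = fit$convergence,
      fixed = fixed, free = free)
  }

  fits <- Filter(Negate(is.null), lapply(starts, run1))
  if (!length(fits)) stopf("ACE optimization failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]

  # boundary polish: when a path coefficient ends near zero, refit with it
  # pinned at exactly zero and keep the pinned solution unless it is worse
  pin <- c(if (best$par[2]^2 < 0.01) 2L, if (best$par[3]^2 < 0.01) 3L)
  if (length(pin)) {
    for (fx in if (length(pin) == 2) list(pin[1], pin[2], pin) else list(pin)) {
      pf <- run1(best$par, fixed = fx)
      if (!is.null(pf) && pf$value <= best$value + 1e-8) best <- pf
    }
  }

  g <- vapply(best$free, function(i) {
    h <- 1e-6 * max(1, abs(best$par[i]))
    pp <- best$par; pp[i] <- pp[i] + h
    pm <- best$par; pm[i] <- pm[i] - h
    (ace_negloglik(pp, sMZ, sDZ, e_floor2) -
     ace_negloglik(pm, sMZ, sDZ, e_floor2)) / (2 * h)
  }, 0)
  converged <- best$convergence == 0 &&
    sqrt(sum(g^2)) < opt$grad_tol * (1 + abs(best$value))

  a2 <- best$par[2]^2; c2 <- best$par[3]^2; e2 <- best$par[4]^2 + e_floor2
  v_std <- a2 + c2 + e2
  btol <- opt$boundary_tol_frac
  boundary <- c(if (abs(best$par[2]) < btol) "A", if (abs(best$par[3]) < btol) "C")
  mu <- mu0 + sd0 * best$par[1]
  sigma2 <- v_std * var0
  # log-likelihood on the original scale: subtract the Jacobian of the
  # standardization (2n observations scaled by sd0)
  loglik <- -best$value - n2 * log(sd0)

  vd_row(probe_id = probe_id, A = a2 / v_std, C = c2 / v_std, E = e2 / v_std,
    sigma2 = sigma2, mu = mu, r_MZ = rMZ, r_DZ = rDZ,
    n_MZ = momMZ$n, n_DZ = momDZ$n, loglik = loglik,
    converged = converged, boundary = paste(boundary, collapse = ","),
    method = "fiml", stratum = stratum)
}

vd_row <- function(probe_id, A, C, E, sigma2, mu, r_MZ, r_DZ, n_MZ, n_DZ,
                   loglik, converged, boundary, method, stratum = "all") {
  df <- data.frame(probe_id = probe_id, A = A, C = C, E = E,
    A_raw = A * sigma2, C_raw = C * sigma2, E_raw = E * sigma2,
    sigma2 = sigma2, mu = mu, r_MZ = r_MZ, r_DZ = r_DZ,
    n_MZ = n_MZ, n_DZ = n_DZ, loglik = loglik, converged = converged,
    boundary = boundary, method = method, stratum = stratum,
    row.names = NULL, stringsAsFactors = FALSE)
  class(df) <- c("VarianceDecomposition", "data.frame")
  df
}

# --- summary-statistic fit -------------------------------------------------

# negative log-likelihood of two unit-variance correlation matrices with
# model correlations rho_MZ, rho_DZ against sample correlations r with the
# stated pair counts
corr_negloglik <- function(rho, r, n) {
  sum(n * (log(2 * pi) + 0.5 * log(1 - rho^2) + (1 - rho * r) / (1 - rho^2)))
}

#' Fit the ACE model from twin correlations (summary statistics)
#'
#' Maximizes the two-group likelihood implied by unit-variance bivariate
#' correlation matrices with the stated pair counts, under `a^2, c^2 >= 0`.
#' The unconstrained interior solution is the Falconer closed form
#' `A = 2(r_MZ - r_DZ)`, `C = 2 r_DZ - r_MZ`, `E = 1 - r_MZ` (the model is
#' saturated); when a closed-form component is negative the likelihood is
#' re-maximized with that component pinned to zero, weighting the two groups
#' by their pair counts.
#'
#' @param r_MZ,r_DZ within-pair correlations, |r| < 1.
#' @param n_MZ,n_DZ pair counts (>= 3).
#' @return one-row `VarianceDecomposition` data.frame (`method = "summary"`,
#'   `sigma2 = 1`, `mu = 0` by convention).
#' @export
fit_ace_summary <- function(r_MZ, r_DZ, n_MZ, n_DZ) {
  stopifnot(abs(r_MZ) < 1, abs(r_DZ) < 1, n_MZ >= 3, n_DZ >= 3)
  A <- 2 * (r_MZ - r_DZ); C <- 2 * r_DZ - r_MZ
  boundary <- character()
  if (A >= 0 && C >= 0) {
    E <- 1 - r_MZ
    rhoMZ <- r_MZ; rhoDZ <- r_DZ
  } else if (A < 0) {
    # common correlation model: rho = c^2 in both groups
    o <- optimize(function(rho) corr_negloglik(c(rho, rho), c(r_MZ, r_DZ), c(n_MZ, n_DZ)),
      c(0, 1 - 1e-9))
    A <- 0; C <- o$minimum; E <- 1 - C
    rhoMZ <- rhoDZ <- C
    boundary <- "A"
    if (C < 1e-12) { C <- 0; E <- 1; boundary <- c("A", "C") }
  } else {
    # C pinned at zero: rho_MZ = a^2, rho_DZ = a^2 / 2
    o <- optimize(function(a2) corr_negloglik(c(a2, a2 / 2), c(r_MZ, r_DZ), c(n_MZ, n_DZ)),
      c(0, 1 - 1e-9))
    A <- o$minimum; C <- 0; E <- 1 - A
    rhoMZ <- A; rhoDZ <- A / 2
    boundary <- "C"
    if (A < 1e-12) { A <- 0; E <- 1; boundary <- c("A", "C") }
  }
  ll <- -corr_negloglik(c(rhoMZ, rhoDZ), c(r_MZ, r_DZ), c(n_MZ, n_DZ))
  vd_row(probe_id = NA_character_, A = A, C = C, E = E, sigma2 = 1, mu = 0,
    r_MZ = r_MZ, r_DZ = r_DZ, n_MZ = n_MZ, n_DZ = n_DZ, loglik = ll,
    converged = TRUE, boundary = paste(boundary, collapse = ","),
    method = "summary")
}

#' Falconer closed-form estimates from twin correlations
#'
#' `h2 = 2 (r_MZ - r_DZ)`, `c2 = 2 r_DZ - r_MZ`, `e2 = 1 - r_MZ`; each is
#' also returned truncated to \[0, 1\]. Vectorized.
#'
#' @param r_MZ,r_DZ twin correlations (finite).
#' @return data.frame: `h2`, `c2`, `e2` (truncated) and `h2_raw`, `c2_raw`,
#'   `e2_raw`.
#' @export
falconer_estimates <- function(r_MZ, r_DZ) {
  h2_raw <- 2 * (r_MZ - r_DZ); c2_raw <- 2 * r_DZ - r_MZ; e2_raw <- 1 - r_MZ
  tr <- function(x) pmin(pmax(x, 0), 1)
  data.frame(h2 = tr(h2_raw), c2 = tr(c2_raw), e2 = tr(e2_raw),
    h2_raw = h2_raw, c2_raw = c2_raw, e2_raw = e2_raw)
}

# --- covariate residualization --------------------------------------------

#' Residualize a beta matrix on sample covariates
#'
#' Per site, values are replaced by ordinary least-squares residuals on the
#' named covariates (plus intercept), with the site mean added back so values
#' stay near the original scale. Factor covariates are expanded to dummies.
#'
#' @param betas a [beta_matrix()].
#' @param covariates a [sample_covariates()] data.frame covering every sample
#'   in `betas` with no missing values in the used columns.
#' @param covariate_names columns of `covariates` to regress out.
#' @return residualized matrix (plain numeric; may leave \[0, 1\]).
#' @export
residualize_covariates <- function(betas, covariates, covariate_names) {
  idx <- match(colnames(betas), covariates$sample_id)
  if (anyNA(idx))
    stopf("covariates missing for sample %s", colnames(betas)[is.na(idx)][1])
  cd <- as.data.frame(covariates)[idx, covariate_names, drop = FALSE]
  if (anyNA(cd)) stopf("missing covariate values for used samples")
  X <- stats::model.matrix(~ ., data = cd)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("covariate design is rank deficient; collinear column(s): %s",
      paste(drop_cols, collapse = ", "))
  }
  Y <- t(unclass(betas))                       # samples x sites
  res <- Y - X %*% qr.coef(qx, Y)
  out <- t(res) + rowMeans(unclass(betas))
  rownames(out) <- rownames(betas); colnames(out) <- colnames(betas)
  out
}

# --- genome-wide driver ----------------------------------------------------

# vectorized per-site moments for one zygosity group
site_moments <- function(betas, manifest, zygosity) {
  pv <- pair_value_matrices(betas, manifest, zygosity)
  Y1 <- pv$Y1; Y2 <- pv$Y2
  ok <- !is.na(Y1) & !is.na(Y2)
  Y1[!ok] <- 0; Y2[!ok] <- 0
  list(n = rowSums(ok), s = rowSums(Y1 + Y2), q = rowSums(Y1^2 + Y2^2),
    x = rowSums(Y1 * Y2))
}

#' Genome-wide per-site ACE decomposition
#'
#' Fits [fit_ace_fiml()] at every probe. Autosomal probes use all pairs
#' (stratum `"all"`); X-chromosome probes are fitted twice, on female-only
#' and male-only pairs (strata `"female"`, `"male"`); Y-linked probes are
#' skipped with a logged count. Per-site failures are recorded
#' (`converged = NA` row), never fatal.
#'
#' @param betas a [beta_matrix()] (or any numeric matrix of phenotypes by
#'   sample, e.g. DNAmAge or cell proportions as rows).
#' @param manifest a [pair_manifest()].
#' @param annotation optional [probe_annotation()]; when `NULL` all rows are
#'   treated as autosomal.
#' @param options passed to the per-site fit; see [fit_ace_fiml()].
#' @return `VarianceDecomposition` data.frame, one row per probe x stratum,
#'   with `chrom` and `position` attached when annotation is given; attribute
#'   `n_skipped_chrY` counts dropped Y-linked probes.
#' @export
run_ace_genomewide <- function(betas, manifest, annotation = NULL,
                               options = list()) {
  probes <- rownames(betas)
  chrom <- rep("autosome", length(probes))
  position <- rep(NA_integer_, length(probes))
  if (!is.null(annotation)) {
    ai <- match(probes, annotation$probe_id)
    chrom <- ifelse(is.na(ai), "autosome", annotation$chrom[ai])
    position <- annotation$position[ai]
  }
  n_y <- sum(is_chrY(chrom))
  if (n_y > 0) message(sprintf("skipping %d Y-linked probe(s)", n_y))

  fit_block <- function(idx, mf, stratum) {
    if (!length(idx)) return(NULL)
    momMZ <- site_moments(betas[idx, , drop = FALSE], mf, "MZ")
    momDZ <- site_moments(betas[idx, , drop = FALSE], mf, "DZ")
    if (max(momMZ$n) < 3 || max(momDZ$n) < 3)
      stopf("no usable pairs for stratum '%s'", stratum)
    rows <- lapply(seq_along(idx), function(i) {
      mMZ <- lapply(momMZ, `[`, i); mDZ <- lapply(momDZ, `[`, i)
      tryCatch(
        fit_ace_from_moments(mMZ, mDZ, options, probe_id = probes[idx[i]],
          stratum = stratum),
        error = function(e) vd_row(probes[idx[i]], NA, NA, NA, NA, NA,
          moments_r(mMZ), moments_r(mDZ), mMZ$n, mDZ$n, NA, NA,
          boundary = "", method = "fiml", stratum = stratum))
    })
    out <- do.call(rbind, rows)
    out$chrom <- chrom[idx]; out$position <- position[idx]
    out
  }

  auto_idx <- which(!is_chrX(chrom) & !is_chrY(chrom))
  x_idx <- which(is_chrX(chrom))
  blocks <- list(fit_block(auto_idx, manifest, "all"))
  if (length(x_idx)) {
    for (sx in c("F", "M")) {
      mf <- manifest[manifest$sex == sx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <-
        fit_block(x_idx, mf, if (sx == "F") "female" else "male")
    }
  }
  out <- do.call(rbind, blocks)
  if (is.null(out)) stopf("no usable probes")
  class(out) <- c("VarianceDecomposition", "data.frame")
  attr(out, "n_skipped_chrY") <- n_y
  out
}

#' ACE decomposition of derived phenotypes
#'
#' Applies the same twin model to arbitrary per-sample continuous phenotypes
#' (DNAmAge acceleration, estimated cell proportions, ...), one row of output
#' per phenotype.
#'
#' @param phenotypes data.frame with `sample_id` plus numeric phenotype
#'   columns.
#' @param manifest a [pair_manifest()].
#' @param options see [fit_ace_fiml()].
#' @return `VarianceDecomposition` data.frame with `probe_id` holding the
#'   phenotype name.
#' @export
run_ace_phenotypes <- function(phenotypes, manifest, options = list()) {
  stopifnot("sample_id" %in% names(phenotypes))
  num <- vapply(phenotypes, is.numeric, logical(1))
  m <- t(as.matrix(phenotypes[, num, drop = FALSE]))
  colnames(m) <- phenotypes$sample_id
  run_ace_genomewide(m, manifest, annotation = NULL, options = options)
}
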