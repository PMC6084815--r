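test_that("independent pairs with equal variances give A = C = 0, E = 1", {
  # sample covariance exactly 0, variances equal, in both zygosity groups
  pts <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  fit <- fit_ace_fiml(pts, pts)
  expect_equal(fit$A, 0, tolerance = 1e-8)
  expect_equal(fit$C, 0, tolerance = 1e-8)
  expect_equal(fit$E, 1, tolerance = 1e-8)
  expect_setequal(strsplit(fit$boundary, ",")[[1]], c("A", "C"))
})

test_that("FIML equals the summary fit on moment-matched data", {
  # datasets built so the ML sample moments are exactly mean 0, variance 1,
  # and the stated double-entry correlations
  for (rr in list(c(0.882, 0.484), c(0.6, 0.35), c(0.2, 0.15))) {
    dMZ <- moment_matched_pairs(426, rr[1], seed = 101)
    dDZ <- moment_matched_pairs(306, rr[2], seed = 102)
    fi <- fit_ace_fiml(dMZ, dDZ)
    su <- fit_ace_summary(rr[1], rr[2], nrow(dMZ), nrow(dDZ))
    fa <- falconer_estimates(rr[1], rr[2])
    expect_equal(fi$A, su$A, tolerance = 1e-6)
    expect_equal(fi$C, su$C, tolerance = 1e-6)
    expect_equal(fi$E, su$E, tolerance = 1e-6)
    expect_equal(su$A, fa$h2, tolerance = 1e-9)   # interior: closed form
    expect_equal(fi$sigma2, 1, tolerance = 1e-6)
    expect_equal(fi$mu, 0, tolerance = 1e-8)
  }
})

test_that("summary fit reproduces the worked high- and low-heritability sites", {
  hi <- fit_ace_summary(0.882, 0.484, 426, 306)
  expect_equal(hi$A, 0.796, tolerance = 1e-9)   # closed form 2(rMZ - rDZ)
  expect_equal(hi$C, 0.086, tolerance = 1e-9)
  expect_equal(hi$E, 0.118, tolerance = 1e-9)
  expect_identical(hi$boundary, "")

  lo <- fit_ace_summary(0.363, 0.449, 426, 306)
  expect_identical(lo$A, 0)                     # pinned at the boundary
  expect_identical(lo$boundary, "A")
  expect_gt(lo$C, 0.35); expect_lt(lo$C, 0.45)
  expect_equal(lo$C + lo$E, 1, tolerance = 1e-9)

  eq <- fit_ace_summary(0.4, 0.4, 100, 100)
  expect_identical(eq$A, 0)
  expect_equal(eq$C, 0.4, tolerance = 1e-6)
  expect_equal(eq$E, 0.6, tolerance = 1e-6)
})

test_that("constrained summary fit never beats the likelihood of the pin", {
  # C pinned: rDZ > rMZ/2 fails -> direct check of the branch
  fit <- fit_ace_summary(0.6, 0.1, 50, 50)
  expect_identical(fit$boundary, "C")
  expect_equal(fit$C, 0)
  expect_true(fit$A > 0.3 && fit$A < 0.7)
})

test_that("Falconer closed form and truncation", {
  f <- falconer_estimates(0.882, 0.484)
  expect_equal(f$h2, 0.796, tolerance = 1e-12)
  expect_equal(falconer_estimates(0.5, 0.5)$h2, 0)
  f <- falconer_estimates(0.3, 0.45)
  expect_equal(f$h2_raw, -0.3, tolerance = 1e-12)
  expect_identical(f$h2, 0)
  # vectorized
  f <- falconer_estimates(c(0.8, 0.2), c(0.3, 0.4))
  expect_equal(f$h2, c(1, 0))
  expect_equal(f$h2_raw, c(1, -0.4))
})

test_that("generator truth is recovered at 2000/2000 pairs", {
  sim <- simulate_twin_cohort(simulation_config(n_MZ = 2000, n_DZ = 2000,
    n_sites = 3, A_true = 0.4, C_true = 0.2, E_true = 0.4, seed = 55))
  d <- run_ace_genomewide(sim$betas, sim$manifest)
  expect_true(all(abs(d$A - 0.4) < 0.05))
  expect_true(all(abs(d$C - 0.2) < 0.05))
  expect_true(all(d$converged))
})

test_that("estimates are invariant to member order and affine rescaling", {
  sim <- tiny_cohort(n_MZ = 80, n_DZ = 60, n_sites = 1, seed = 66)
  pMZ <- probe_pairs(sim, "cg00000001", "MZ")
  pDZ <- probe_pairs(sim, "cg00000001", "DZ")
  f0 <- fit_ace_fiml(pMZ, pDZ)

  swap <- seq(1, nrow(pMZ), by = 2)
  pMZs <- pMZ; pMZs[swap, ] <- pMZ[swap, 2:1]
  f1 <- fit_ace_fiml(pMZs, pDZ)
  expect_equal(f1$A, f0$A, tolerance = 1e-7)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-7)

  f2 <- fit_ace_fiml(3 * pMZ + 2, 3 * pDZ + 2)
  expect_equal(f2$A, f0$A, tolerance = 1e-6)
  expect_equal(f2$C, f0$C, tolerance = 1e-6)
  expect_equal(f2$A_raw, 9 * f0$A_raw, tolerance = 1e-5)
  expect_equal(f2$mu, 3 * f0$mu + 2, tolerance = 1e-6)
})

test_that("pairs with a missing member are dropped site-wise", {
  sim <- tiny_cohort(n_MZ = 40, n_DZ = 30, n_sites = 1, seed = 71)
  pMZ <- probe_pairs(sim, "cg00000001", "MZ")
  pDZ <- probe_pairs(sim, "cg00000001", "DZ")
  pMZna <- rbind(pMZ, c(NA, 0.5), c(0.2, NA))
  f0 <- fit_ace_fiml(pMZ, pDZ); f1 <- fit_ace_fiml(pMZna, pDZ)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-9)
  expect_identical(f1$n_MZ, f0$n_MZ)
})

test_that("residualization removes exactly the linear covariate signal", {
  sim <- tiny_cohort(n_MZ = 30, n_DZ = 25, n_sites = 4, seed = 81)
  n <- ncol(sim$betas)
  set.seed(1)
  x <- rnorm(n)
  m <- unclass(sim$betas)
  xc <- (x - mean(x)) / max(abs(x - mean(x)))
  m[1, ] <- 0.5 + 0.3 * xc
  bm <- beta_matrix(m)
  cv <- sample_covariates(data.frame(sample_id = colnames(m), x = xc))
  res <- residualize_covariates(bm, cv, "x")
  expect_equal(unname(res[1, ]), rep(0.5, n), tolerance = 1e-10)
  # residuals are uncorrelated with the covariate at every site (site 1 is
  # constant after removal, so test the covariance)
  expect_true(all(abs(apply(res, 1, function(v) cov(v, xc))) < 1e-10))

  # orthogonal covariate leaves values untouched
  for (i in 2:4) {
    y <- m[i, ]
    ortho <- rnorm(n)
    ortho <- ortho - mean(ortho)
    ortho <- ortho - sum(ortho * (y - mean(y))) / sum((y - mean(y))^2) * (y - mean(y))
    cv2 <- sample_covariates(data.frame(sample_id = colnames(m), z = ortho))
    res2 <- residualize_covariates(beta_matrix(m[i, , drop = FALSE]), cv2, "z")
    expect_equal(unname(res2[1, ]), unname(y), tolerance = 1e-10)
  }

  cvc <- sample_covariates(data.frame(sample_id = colnames(m), x = xc, x2 = 2 * xc))
  expect_error(residualize_covariates(bm, cvc, c("x", "x2")), "collinear")
})

test_that("genome-wide driver stratifies chrX by sex and skips chrY", {
  sim <- simulate_twin_cohort(simulation_config(n_MZ = 40, n_DZ = 35,
    n_sites = 12, n_sites_chrX = 5, seed = 91))
  ann <- sim$annotation
  ann$chrom[3] <- "chrY"
  expect_message(d <- run_ace_genomewide(sim$betas, sim$manifest, ann),
    "skipping 1 Y-linked")
  expect_identical(sum(d$stratum == "all"), 11L)
  expect_identical(sum(d$stratum == "female"), 5L)
  expect_identical(sum(d$stratum == "male"), 5L)
  expect_identical(attr(d, "n_skipped_chrY"), 1L)
  expect_false("chrY" %in% d$chrom)
})

test_that("arbitrary phenotypes decompose like sites", {
  sim <- tiny_cohort(n_MZ = 300, n_DZ = 250, n_sites = 1, A = 0.5, C = 0.2,
    seed = 95)
  ph <- data.frame(sample_id = colnames(sim$betas),
    DNAmAge = unclass(sim$betas)[1, ] * 40 + 10)
  d <- run_ace_phenotypes(ph, sim$manifest)
  expect_identical(d$probe_id, "DNAmAge")
  expect_lt(abs(d$A - 0.5), 0.15)
  expect_equal(d$mu, mean(ph$DNAmAge), tolerance = 0.05)
})

test_that("zero-variance input errors out", {
  pts <- cbind(rep(0.5, 5), rep(0.5, 5))
  expect_error(fit_ace_fiml(pts, pts), "zero total variance")
  expect_error(fit_ace_fiml(cbind(1:2, 2:3), cbind(1:5, 2:6)), ">= 3 complete pairs")
})
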