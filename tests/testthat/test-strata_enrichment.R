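mk_decomp <- function(A, probe_id = sprintf("cg%04d", seq_along(A))) {
  d <- data.frame(probe_id = probe_id, A = A, C = pmin(1 - A, 0.2),
    E = 1 - A - pmin(1 - A, 0.2))
  class(d) <- c("VarianceDecomposition", "data.frame")
  d
}

# brute-force two-sided Mann-Whitney p by enumerating all rank allocations
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

test_that("Mann-Whitney agrees with rank enumeration for n <= 8", {
  set.seed(12)
  for (rep in 1:8) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- runif(n1); y <- runif(n2)
    d <- mk_decomp(c(x, y))
    res <- compare_strata(d, c(rep(TRUE, n1), rep(FALSE, n2)), components = "A")
    expect_equal(res$p, mw_enum_p(x, y), tolerance = 1e-12,
      label = sprintf("rep %d", rep))
  }
})

test_that("separated strata give the extreme U and its exact p", {
  d <- mk_decomp(c(rep(0.1, 6), rep(0.9, 6)))
  res <- compare_strata(d, rep(c(TRUE, FALSE), each = 6), components = "A")
  expect_true(res$U %in% c(0, 36))
  expect_equal(res$p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(res$mean1, 10)   # percent scale
  expect_equal(res$mean2, 90)
})

test_that("compare_strata is symmetric and near 1 for identical strata", {
  set.seed(7)
  vals <- runif(40, 0.1, 0.9)
  d <- mk_decomp(c(vals, vals))
  memb <- rep(c(TRUE, FALSE), each = 40)
  res <- compare_strata(d, memb, components = "A")
  expect_gt(res$p, 0.95)

  d2 <- mk_decomp(runif(60))
  memb2 <- seq_len(60) <= 25
  a <- compare_strata(d2, memb2, components = "A")
  b <- compare_strata(d2, !memb2, components = "A")
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$mean1, b$mean2)
  expect_error(compare_strata(d2, rep(TRUE, 60)), "non-empty")
})

test_that("strata simulated with different A separate significantly", {
  sim <- simulate_twin_cohort(simulation_config(n_MZ = 150, n_DZ = 120,
    n_sites = 120, A_true = rep(c(0.4, 0.1), each = 60), C_true = 0.2,
    E_true = rep(c(0.4, 0.7), each = 60), seed = 33))
  d <- run_ace_genomewide(sim$betas, sim$manifest)
  memb <- sim$truth$sites$A_true == 0.4
  res <- compare_strata(d, memb, components = "A")
  expect_gt(res$mean1, res$mean2)
  expect_lt(res$p, 0.01)
})

test_that("positional profile: flat field, step transition, empty windows", {
  n <- 400
  ann <- probe_annotation(data.frame(probe_id = sprintf("cg%04d", 1:n),
    chrom = "chr1", position = 1:n,
    tss_distance = seq(-2000, 1999, length.out = n)))
  d <- mk_decomp(rep(0.3, n), probe_id = ann$probe_id)
  prof <- positional_profile(d, ann, window_bp = 500, step_bp = 100, min_n = 5)
  expect_true(all(abs(prof$mean_A[!is.na(prof$mean_A)] - 0.3) < 1e-12))

  d2 <- mk_decomp(ifelse(ann$tss_distance < 0, 0.1, 0.5), probe_id = ann$probe_id)
  prof2 <- positional_profile(d2, ann, window_bp = 200, step_bp = 100, min_n = 5)
  far_up <- prof2$mean_A[prof2$center <= -300]
  far_dn <- prof2$mean_A[prof2$center >= 300]
  expect_true(all(abs(far_up[!is.na(far_up)] - 0.1) < 1e-12))
  expect_true(all(abs(far_dn[!is.na(far_dn)] - 0.5) < 1e-12))

  # sparse region -> NA, never 0
  ann3 <- ann; ann3$tss_distance[ann$tss_distance > 0] <- 10000
  prof3 <- positional_profile(d, ann3, window_bp = 200, step_bp = 200, min_n = 5)
  gap <- prof3$mean_A[prof3$center > 2500 & prof3$center < 9000]
  expect_true(all(is.na(gap)))
  expect_error(positional_profile(d, ann, window_bp = -5), "positive")
})

test_that("level profile: constant, identity, inverted U", {
  x <- seq(0, 1, length.out = 500)
  lp <- level_profile(x, rep(0.25, 500), window_width = 0.1, step = 0.05, min_n = 5)
  ok <- !is.na(lp$mean)
  expect_true(all(abs(lp$mean[ok] - 0.25) < 1e-12))
  expect_true(all(lp$q97.5[ok] - lp$q2.5[ok] == 0))

  lp <- level_profile(x, x, window_width = 0.1, step = 0.05, min_n = 5)
  mid <- lp$center > 0.1 & lp$center < 0.9 & !is.na(lp$mean)
  expect_true(all(abs(lp$mean[mid] - lp$center[mid]) < 0.01))

  y <- x * (1 - x)  # maximal near 0.5
  lp <- level_profile(x, y, window_width = 0.1, step = 0.02, min_n = 5)
  peak <- lp$center[which.max(lp$mean)]
  expect_lt(abs(peak - 0.5), 0.06)
})

test_that("Fisher enrichment matches fisher.test over random small tables", {
  set.seed(9)
  for (rep in 1:20) {
    N <- sample(8:60, 1)
    n_high <- sample(2:(N - 2), 1)
    flags <- sample(c(TRUE, FALSE), N, replace = TRUE)
    A <- numeric(N); A[seq_len(n_high)] <- 0.9
    d <- mk_decomp(A)
    er <- mqtl_enrichment(d, setNames(flags, d$probe_id))
    ft <- fisher.test(matrix(c(er$table), 2, byrow = FALSE))
    expect_equal(er$p, ft$p.value, tolerance = 1e-7, label = sprintf("rep %d", rep))
  }
})

test_that("mqtl enrichment on the toy table and degenerate margins", {
  A <- c(rep(0.9, 10), rep(0.1, 100))
  flags <- c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 10), rep(FALSE, 90))
  d <- mk_decomp(A)
  er <- mqtl_enrichment(d, setNames(flags, d$probe_id))
  expect_identical(unname(er$table[1, ]), c(8L, 2L))
  expect_identical(unname(er$table[2, ]), c(10L, 90L))
  expect_equal(er$p,
    fisher.test(matrix(c(8, 2, 10, 90), 2, byrow = TRUE))$p.value,
    tolerance = 1e-9)
  expect_equal(er$prop_high, 0.8)

  er2 <- mqtl_enrichment(d, setNames(rep(TRUE, 110), d$probe_id))
  expect_equal(er2$p, 1)
  expect_true(er2$or_degenerate)
  expect_equal(er2$prop_high, 1); expect_equal(er2$prop_low, 1)
})

test_that("flags independent of A give null-ish enrichment", {
  set.seed(14)
  ors <- ps <- numeric(10)
  for (i in 1:10) {
    d <- mk_decomp(runif(400))
    er <- mqtl_enrichment(d, setNames(runif(400) < 0.3, d$probe_id))
    ors[i] <- er$odds_ratio; ps[i] <- er$p
  }
  expect_lt(abs(mean(log(ors))), 0.4)
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("covariation stratification recovers constructed heritability split", {
  d <- mk_decomp(c(runif(300, 0.5, 0.7), runif(300, 0, 0.2)))
  cv <- setNames(c(runif(300, 0.6, 0.9), runif(300, 0, 0.4)), d$probe_id)
  res <- covariation_stratified_heritability(d, cv)
  expect_gt(res$median_A_above - res$median_A_below, 0.3)
  expect_lt(res$p, 1e-4)
  expect_gt(res$pearson_r, 0.5)

  res2 <- covariation_stratified_heritability(d, setNames(d$A, d$probe_id),
    cutoff = 0.3)
  expect_equal(res2$pearson_r, 1)
  expect_error(covariation_stratified_heritability(d, cv, cutoff = 0.95),
    "each side")
})

test_that("profiles are invariant to probe order", {
  set.seed(20)
  x <- runif(300); y <- runif(300)
  lp1 <- level_profile(x, y, min_n = 5)
  o <- sample(300)
  lp2 <- level_profile(x[o], y[o], min_n = 5)
  expect_equal(lp1, lp2)
})
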