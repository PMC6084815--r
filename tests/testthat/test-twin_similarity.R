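mk_manifest <- function(n, zyg = "MZ") {
  pair_manifest(data.frame(pair_id = paste0("p", 1:n),
    sample_id_a = paste0("a", 1:n), sample_id_b = paste0("b", 1:n),
    zygosity = zyg, sex = "F", family_id = paste0("f", 1:n)))
}

test_that("double-entry correlation matches hand calculations", {
  mf <- mk_manifest(2)
  v <- c(a1 = 0, b1 = 1, a2 = 1, b2 = 0)
  expect_equal(site_twin_correlation(v, mf, "MZ")$r, -1)

  mf <- mk_manifest(3)
  v <- c(a1 = 0, b1 = 0, a2 = 1, b2 = 1, a3 = 0, b3 = 1)
  # doubled points: (0,0),(1,1),(0,1),(0,0),(1,1),(1,0) -> r = 1/3
  expect_equal(site_twin_correlation(v, mf, "MZ")$r, 1 / 3, tolerance = 1e-12)
})

test_that("double-entry correlation is invariant to member order", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    mf <- mk_manifest(n)
    v <- runif(2 * n)
    names(v) <- c(rbind(paste0("a", 1:n), paste0("b", 1:n)))
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    mfs <- mf
    mfs$sample_id_a[swap] <- mf$sample_id_b[swap]
    mfs$sample_id_b[swap] <- mf$sample_id_a[swap]
    expect_equal(site_twin_correlation(v, mf, "MZ")$r,
      site_twin_correlation(v, pair_manifest(mfs), "MZ")$r, tolerance = 1e-12)
  }
})

test_that("vectorized twin_correlations agrees with the per-site path", {
  sim <- tiny_cohort(n_MZ = 25, n_DZ = 20, n_sites = 12, seed = 9)
  m <- unclass(sim$betas)
  m[1, 3] <- NA; m[5, 10:14] <- NA    # exercise the missing-pair path
  bm <- beta_matrix(m)
  tc <- twin_correlations(bm, sim$manifest)
  for (i in c(1, 5, 12)) {
    sMZ <- site_twin_correlation(m[i, ], sim$manifest, "MZ")
    sDZ <- site_twin_correlation(m[i, ], sim$manifest, "DZ")
    expect_equal(tc$r_MZ[i], sMZ$r, tolerance = 1e-12)
    expect_equal(tc$n_MZ_pairs[i], as.integer(sMZ$n_pairs))
    expect_equal(tc$r_DZ[i], sDZ$r, tolerance = 1e-12)
  }
  # < 3 complete pairs or zero variance -> NA
  few <- m[1:2, 1:5]
  few[1, ] <- c(0.1, 0.2, 0.3, 0.4, NA)
  few[2, ] <- 0.5
  mf <- sim$manifest[sim$manifest$sample_id_a %in% colnames(few) |
    sim$manifest$sample_id_b %in% colnames(few), ]
  tc2 <- twin_correlations(beta_matrix(few), sim$manifest)
  expect_true(all(is.na(tc2$r_MZ)))
})

test_that("pair profile correlations: identity, inversion, hand Pearson", {
  mf <- mk_manifest(3)
  m <- matrix(NA_real_, 12, 6, dimnames = list(sprintf("cg%02d", 1:12),
    c("a1", "b1", "a2", "b2", "a3", "b3")))
  base <- seq(0.1, 0.9, length.out = 12)
  m[, "a1"] <- base; m[, "b1"] <- base                  # identical -> r = 1
  m[, "a2"] <- base; m[, "b2"] <- 1 - base              # mirrored -> r = -1
  m[, "a3"] <- base; m[, "b3"] <- base; m[10:12, "b3"] <- NA  # too few sites
  pp <- pair_profile_correlation(beta_matrix(m), mf, min_sites = 10)
  expect_equal(pp$r[1], 1)
  expect_equal(pp$r[2], -1)
  expect_true(is.na(pp$r[3]) && grepl("9 shared sites", pp$reason[3]))

  v1 <- c(0.1, 0.2, 0.3); v2 <- c(0.1, 0.25, 0.3)
  m3 <- rbind(cg1 = c(v1[1], v2[1]), cg2 = c(v1[2], v2[2]), cg3 = c(v1[3], v2[3]))
  colnames(m3) <- c("a1", "b1")
  pp <- pair_profile_correlation(beta_matrix(m3), mk_manifest(1), min_sites = 3)
  expect_equal(pp$r, cor(v1, v2), tolerance = 1e-12)
  expect_equal(pp$r, sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2)), tolerance = 1e-12)
})

test_that("unrelated baseline draws cross-family pairs, deterministically", {
  sim <- tiny_cohort(n_MZ = 30, n_DZ = 20, n_sites = 15, seed = 19)
  pp1 <- pair_profile_correlation(sim$betas, sim$manifest, n_unrelated = 10, seed = 3)
  pp2 <- pair_profile_correlation(sim$betas, sim$manifest, n_unrelated = 10, seed = 3)
  expect_identical(pp1, pp2)
  expect_identical(sum(pp1$zygosity == "unrelated"), 10L)
})

test_that("exact sign test: small closed forms and symmetry", {
  expect_equal(exact_sign_test(5, 5)$p_two_sided, 0.0625)  # 2 * 1/32
  expect_equal(exact_sign_test(6, 12)$p_two_sided, 1)
  for (m in c(7, 12, 30)) for (k in c(0, 3, m %/% 2, m)) {
    a <- exact_sign_test(k, m); b <- exact_sign_test(m - k, m)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-14)
    expect_equal(a$log10_p, b$log10_p, tolerance = 1e-12)
  }
})

test_that("sign test matches full 2^m enumeration for m <= 12", {
  for (m in c(1, 4, 9, 12)) {
    # enumerate every coin-flip sequence, group by number of successes
    outcomes <- rowSums(as.matrix(expand.grid(rep(list(0:1), m))))
    for (k in 0:m) {
      lo <- mean(outcomes <= k); hi <- mean(outcomes >= k)
      expect_equal(exact_sign_test(k, m)$p_two_sided,
        min(1, 2 * min(lo, hi)), tolerance = 1e-12,
        label = sprintf("k=%d m=%d", k, m))
    }
  }
})

test_that("log10_p stays finite and exact beyond double underflow", {
  st <- exact_sign_test(277077, 420857)
  expect_identical(st$p_two_sided, 0)          # underflows a double
  expect_true(is.finite(st$log10_p) && st$log10_p < -5000)
  expect_match(st$p_printed, "e-")
  # cross-check a representable case against pbinom
  st <- exact_sign_test(700, 1000)
  expect_equal(st$p_two_sided,
    2 * pbinom(300, 1000, 0.5), tolerance = 1e-10)
})

test_that("group similarity comparison behaves at the edges and matches Welch", {
  g <- c(0.5, 0.6, 0.7)
  expect_equal(compare_group_similarity(g, g)$p, 1, tolerance = 1e-9)

  set.seed(2)
  r1 <- 0.9 + rnorm(50, sd = 1e-4); r2 <- 0.1 + rnorm(50, sd = 1e-4)
  expect_lt(compare_group_similarity(r1, r2)$p, 1e-10)

  a <- c(0.1, 0.3, 0.5, 0.2); b <- c(0.6, 0.7, 0.65)
  res <- compare_group_similarity(a, b)
  za <- atanh(a); zb <- atanh(b)
  tt <- t.test(za, zb)  # Welch reference
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$mean1, mean(a))

  res <- compare_group_similarity(c(1, 0.5, 0.7), c(0.2, 0.3, 0.1))
  expect_identical(res$n_clamped, 1L)
  expect_true(res$p < 1)
})
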