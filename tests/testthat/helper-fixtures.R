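# shared fixtures, built in code at test time

tiny_cohort <- function(n_MZ = 60, n_DZ = 50, n_sites = 20, A = 0.4, C = 0.2,
                        seed = 11, ...) {
  simulate_twin_cohort(simulation_config(n_MZ = n_MZ, n_DZ = n_DZ,
    n_sites = n_sites, A_true = A, C_true = C, E_true = 1 - A - C,
    seed = seed, ...))
}

# raw MZ/DZ pair matrices for one probe of a simulated cohort
probe_pairs <- function(sim, probe, zygosity) {
  mf <- sim$manifest[sim$manifest$zygosity == zygosity, ]
  cbind(unclass(sim$betas)[probe, mf$sample_id_a],
        unclass(sim$betas)[probe, mf$sample_id_b])
}

# build a doubled (swap-symmetric) two-column dataset whose maximum-likelihood
# moments are exactly mean 0, variance 1, correlation r
moment_matched_pairs <- function(n, r, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(2 * n), n, 2)
  D <- rbind(Z, Z[, 2:1])
  D <- sweep(D, 2, colMeans(D))
  S <- crossprod(D) / nrow(D)
  R <- matrix(c(1, r, r, 1), 2)
  D <- D %*% solve(chol(S)) %*% chol(R)
  sweep(D, 2, colMeans(D))
}
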