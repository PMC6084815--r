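#' Configuration for the synthetic twin-cohort generator
#'
#' Defaults mirror the target cohort design: 426 MZ and 306 same-sex DZ pairs
#' (48.5% / 49.2% female), with per-site variance structure given as
#' standardized A/C/E proportions on the beta scale. Per-site arguments are
#' recycled across `n_sites`.
#'
#' @param n_MZ,n_DZ numbers of MZ and DZ twin pairs.
#' @param n_sites number of autosomal CpG sites to simulate.
#' @param A_true,C_true,E_true per-site standardized variance proportions;
#'   must sum to 1 per site.
#' @param mu_beta per-site mean methylation, strictly inside (0, 1).
#' @param total_sd per-site total SD on the beta scale.
#' @param scale_mode `"linear-clip"` (latent Gaussian mapped to beta by
#'   clipping; components exact on the observed scale when clipping is
#'   negligible) or `"logistic"` (deviations applied on the logit scale, which
#'   emulates realistic boundary-compressed beta distributions but distorts
#'   variance components; only the MZ > DZ ordering is guaranteed there).
#' @param n_sites_chrX number of additional X-chromosome sites (same variance
#'   model, used to exercise sex-stratified fitting).
#' @param frac_female_MZ,frac_female_DZ expected proportion of female pairs.
#' @param mqtl_spec optional list(`fraction`, `maf`, `effect`): fraction of
#'   sites given a biallelic cis SNP with the stated minor-allele frequency
#'   and additive effect (beta units per allele).
#' @param exposure_spec optional list(`p_exposed`, `concordance`, `n_sites`
#'   or `sites`, `effect`) passed to [spike_exposure_effects()].
#' @param seed master integer seed; all draws flow from named sub-streams so
#'   e.g. genotype draws do not shift when `n_sites` changes.
#' @return a list with class `SimulationConfig`.
#' @export
simulation_config <- function(n_MZ = 426, n_DZ = 306, n_sites = 1000,
                              A_true = 0.159, C_true = 0.167, E_true = 0.674,
                              mu_beta = 0.5, total_sd = 0.05,
                              scale_mode = c("linear-clip", "logistic"),
                              n_sites_chrX = 0,
                              frac_female_MZ = 0.485, frac_female_DZ = 0.492,
                              mqtl_spec = NULL, exposure_spec = NULL,
                              seed = 1L) {
  scale_mode <- match.arg(scale_mode)
  n_tot <- n_sites + n_sites_chrX
  rec <- function(x) rep_len(x, n_tot)
  A_true <- rec(A_true); C_true <- rec(C_true); E_true <- rec(E_true)
  mu_beta <- rec(mu_beta); total_sd <- rec(total_sd)
  s <- A_true + C_true + E_true
  if (any(abs(s - 1) > 1e-12))
    stopf("A_true + C_true + E_true must equal 1 (site %d sums to %.15g)",
      which(abs(s - 1) > 1e-12)[1], s[which(abs(s - 1) > 1e-12)[1]])
  if (any(A_true < 0 | C_true < 0 | E_true < 0))
    stopf("variance proportions must be nonnegative")
  if (any(mu_beta <= 0 | mu_beta >= 1)) stopf("mu_beta must be inside (0,1)")
  if (any(total_sd <= 0)) stopf("total_sd must be positive")
  if (!is.null(mqtl_spec)) {
    maf <- mqtl_spec$maf %||% 0.25
    if (maf <= 0 || maf > 0.5) stopf("mQTL MAF must be in (0, 0.5]")
  }
  structure(list(n_MZ = n_MZ, n_DZ = n_DZ, n_sites = n_sites,
    n_sites_chrX = n_sites_chrX, A_true = A_true, C_true = C_true,
    E_true = E_true, mu_beta = mu_beta, total_sd = total_sd,
    scale_mode = scale_mode, frac_female_MZ = frac_female_MZ,
    frac_female_DZ = frac_female_DZ, mqtl_spec = mqtl_spec,
    exposure_spec = exposure_spec, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Simulate sibling genotype pairs at one biallelic SNP
#'
#' Parental haplotypes are drawn Bernoulli(`maf`); MZ co-twins share both
#' transmitted alleles, DZ co-twins receive independent transmissions from
#' the same two parents. Marginal genotype frequencies are Hardy-Weinberg;
#' the expected DZ sibling genotype correlation is 0.5.
#'
#' @param n_pairs number of twin pairs.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param maf minor-allele frequency, in (0, 0.5].
#' @param seed integer seed.
#' @return integer matrix `n_pairs` x 2 of allele counts (0/1/2).
#' @export
simulate_sibling_genotypes <- function(n_pairs, zygosity = c("MZ", "DZ"),
                                       maf, seed = 1L) {
  zygosity <- match.arg(zygosity)
  if (maf <= 0 || maf > 0.5) stopf("maf must be in (0, 0.5]")
  set.seed(as.integer(seed))
  hm <- matrix(rbinom(2L * n_pairs, 1L, maf), n_pairs, 2)  # maternal haplotypes
  hf <- matrix(rbinom(2L * n_pairs, 1L, maf), n_pairs, 2)  # paternal haplotypes
  pick <- function() cbind(seq_len(n_pairs), sample(c(1L, 2L), n_pairs, replace = TRUE))
  mi1 <- pick(); fi1 <- pick()
  g1 <- hm[mi1] + hf[fi1]
  if (zygosity == "MZ") {
    g2 <- g1
  } else {
    mi2 <- pick(); fi2 <- pick()
    g2 <- hm[mi2] + hf[fi2]
  }
  cbind(twin1 = as.integer(g1), twin2 = as.integer(g2))
}

# latent bivariate Gaussian ACE draw for one zygosity group:
# sites x pairs matrices for each twin, genetic correlation 1 (MZ) / 0.5 (DZ)
ace_latent_draw <- function(n_sites, n_pairs, A, C, E, total_sd, zygosity) {
  dim2 <- c(n_sites, n_pairs)
  G1 <- matrix(rnorm(n_sites * n_pairs), n_sites, n_pairs)
  G2 <- if (zygosity == "MZ") G1 else
    0.5 * G1 + sqrt(0.75) * matrix(rnorm(n_sites * n_pairs), n_sites, n_pairs)
  S <- matrix(rnorm(n_sites * n_pairs), n_sites, n_pairs)
  U1 <- matrix(rnorm(n_sites * n_pairs), n_sites, n_pairs)
  U2 <- matrix(rnorm(n_sites * n_pairs), n_sites, n_pairs)
  a <- sqrt(A) * total_sd; c_ <- sqrt(C) * total_sd; e <- sqrt(E) * total_sd
  list(y1 = a * G1 + c_ * S + e * U1, y2 = a * G2 + c_ * S + e * U2)
}

#' Simulate a twin cohort with known per-site ACE structure
#'
#' For each site, pair values are built as `mu + a*(g1,g2) + c*(s,s) +
#' e*(u1,u2)` with standard-normal factors, `corr(g1,g2) = 1` for MZ pairs
#' and `0.5` for DZ pairs, and `a^2 = A_true * total_sd^2` (etc.). In
#' `linear-clip` mode the latent value is clipped to \[0, 1\]; in `logistic`
#' mode deviations are applied on the logit scale (delta-method scaling) and
#' mapped back by the inverse logit.
#'
#' @param config a [simulation_config()].
#' @return list with elements `betas` ([beta_matrix()]), `manifest`
#'   ([pair_manifest()]), `covariates` ([sample_covariates()]), `truth`
#'   (`SimulationTruth`: per-site generating parameters, genotypes at mQTL
#'   sites, exposure labels, clipping diagnostics) and `annotation`
#'   ([probe_annotation()]).
#' @export
simulate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n_tot <- config$n_sites + config$n_sites_chrX
  n_pairs <- config$n_MZ + config$n_DZ
  zyg <- rep(c("MZ", "DZ"), c(config$n_MZ, config$n_DZ))
  pair_id <- sprintf("P%05d", seq_len(n_pairs))
  manifest <- pair_manifest(data.frame(
    pair_id = pair_id,
    sample_id_a = paste0(pair_id, "_1"),
    sample_id_b = paste0(pair_id, "_2"),
    zygosity = zyg,
    sex = "F",  # overwritten below
    family_id = sub("^P", "F", pair_id)))

  set.seed(derive_seed(config$seed, "sex"))
  pf <- ifelse(zyg == "MZ", config$frac_female_MZ, config$frac_female_DZ)
  manifest$sex <- ifelse(runif(n_pairs) < pf, "F", "M")

  probe_id <- sprintf("cg%08d", seq_len(n_tot))
  chrom <- rep(c("chr1", "chrX"), c(config$n_sites, config$n_sites_chrX))
  annotation <- probe_annotation(data.frame(
    probe_id = probe_id, chrom = chrom,
    position = 1000000L + 1000L * seq_len(n_tot)))

  set.seed(derive_seed(config$seed, "latent"))
  mz <- ace_latent_draw(n_tot, config$n_MZ, config$A_true, config$C_true,
    config$E_true, config$total_sd, "MZ")
  dz <- ace_latent_draw(n_tot, config$n_DZ, config$A_true, config$C_true,
    config$E_true, config$total_sd, "DZ")
  dev1 <- cbind(mz$y1, dz$y1); dev2 <- cbind(mz$y2, dz$y2)

  truth <- data.frame(probe_id = probe_id, chrom = chrom,
    position = annotation$position, A_true = config$A_true,
    C_true = config$C_true, E_true = config$E_true, mu_beta = config$mu_beta,
    total_sd = config$total_sd, is_mqtl = FALSE, mqtl_effect = 0,
    is_affected = FALSE)
  genotypes <- NULL

  if (!is.null(config$mqtl_spec)) {
    sp <- config$mqtl_spec
    frac <- sp$fraction %||% 0.1; maf <- sp$maf %||% 0.25
    eff <- sp$effect %||% 0.05
    gseed <- derive_seed(config$seed, "mqtl")
    set.seed(gseed)
    n_mq <- max(1L, round(frac * n_tot))
    mq_sites <- sort(sample.int(n_tot, n_mq))
    gmz <- simulate_sibling_genotypes(config$n_MZ * n_mq, "MZ", maf, gseed + 1L)
    gdz <- simulate_sibling_genotypes(config$n_DZ * n_mq, "DZ", maf, gseed + 2L)
    G1 <- matrix(0L, n_tot, n_pairs); G2 <- matrix(0L, n_tot, n_pairs)
    G1[mq_sites, zyg == "MZ"] <- matrix(gmz[, 1], n_mq, config$n_MZ)
    G2[mq_sites, zyg == "MZ"] <- matrix(gmz[, 2], n_mq, config$n_MZ)
    G1[mq_sites, zyg == "DZ"] <- matrix(gdz[, 1], n_mq, config$n_DZ)
    G2[mq_sites, zyg == "DZ"] <- matrix(gdz[, 2], n_mq, config$n_DZ)
    effv <- numeric(n_tot); effv[mq_sites] <- rep_len(eff, n_mq)
    dev1 <- dev1 + effv * (G1 - 2 * maf)  # centered so mu_beta stays the mean
    dev2 <- dev2 + effv * (G2 - 2 * maf)
    truth$is_mqtl[mq_sites] <- TRUE
    truth$mqtl_effect[mq_sites] <- rep_len(eff, n_mq)
    genotypes <- list(sites = probe_id[mq_sites], twin1 = G1[mq_sites, , drop = FALSE],
      twin2 = G2[mq_sites, , drop = FALSE])
  }

  clip_frac <- 0
  if (config$scale_mode == "linear-clip") {
    b1 <- config$mu_beta + dev1; b2 <- config$mu_beta + dev2
    n_clip <- sum(b1 < 0 | b1 > 1) + sum(b2 < 0 | b2 > 1)
    clip_frac <- n_clip / (2 * n_tot * n_pairs)
    b1 <- pmin(pmax(b1, 0), 1); b2 <- pmin(pmax(b2, 0), 1)
  } else {
    # delta-method scale factor so small deviations keep approximate SD
    sc <- 1 / (config$mu_beta * (1 - config$mu_beta))
    b1 <- plogis(qlogis(config$mu_beta) + sc * dev1)
    b2 <- plogis(qlogis(config$mu_beta) + sc * dev2)
  }

  betas <- matrix(0, n_tot, 2L * n_pairs)
  betas[, 2L * seq_len(n_pairs) - 1L] <- b1
  betas[, 2L * seq_len(n_pairs)] <- b2
  rownames(betas) <- probe_id
  cn <- character(2L * n_pairs)
  cn[2L * seq_len(n_pairs) - 1L] <- manifest$sample_id_a
  cn[2L * seq_len(n_pairs)] <- manifest$sample_id_b
  colnames(betas) <- cn
  betas <- beta_matrix(betas)

  pair_of <- match(sub("_[12]$", "", colnames(betas)), manifest$pair_id)
  covariates <- sample_covariates(data.frame(
    sample_id = colnames(betas),
    family_id = manifest$family_id[pair_of],
    sex = manifest$sex[pair_of]))

  warnings <- character()
  if (config$scale_mode == "linear-clip" && clip_frac > 0.01) {
    warnings <- sprintf("%.2f%% of beta values clipped at [0,1]", 100 * clip_frac)
    warnf("%s", warnings)
  }

  out <- list(betas = betas, manifest = manifest, covariates = covariates,
    truth = structure(list(sites = truth, genotypes = genotypes,
      exposure = NULL, clip_fraction = clip_frac, warnings = warnings,
      config = config), class = "SimulationTruth"),
    annotation = annotation)

  if (!is.null(config$exposure_spec)) {
    sp <- config$exposure_spec
    sp$sites <- sp$sites %||% head(probe_id, sp$n_sites %||% 10L)
    sk <- spike_exposure_effects(out$betas, out$manifest, sp,
      seed = derive_seed(config$seed, "exposure"))
    out$betas <- sk$betas
    out$covariates$smoking_status <- sk$covariates$smoking_status[
      match(out$covariates$sample_id, sk$covariates$sample_id)]
    out$truth$exposure <- sk$covariates
    out$truth$sites$is_affected <- probe_id %in% sp$sites
  }
  out
}

#' Spike an exposure effect into a beta matrix
#'
#' Exposure status is assigned per individual with a family-level concordance
#' parameter: with probability `concordance` both co-twins share a single
#' Bernoulli(`p_exposed`) draw, otherwise they draw independently (the
#' marginal exposure probability is `p_exposed` either way). Affected sites
#' are shifted additively by `effect` for exposed individuals and re-clipped
#' to \[0, 1\].
#'
#' @param betas a [beta_matrix()].
#' @param manifest a [pair_manifest()].
#' @param exposure_spec list with `p_exposed` (default 0.25), `concordance`
#'   (default 0.7), `sites` (probe ids to affect), `effect` (beta-scale shift
#'   per exposed individual; scalar or per-site).
#' @param seed integer seed.
#' @return list(`betas`, `covariates`) where covariates carry
#'   `smoking_status` ("current"/"never") as the exposure label.
#' @export
spike_exposure_effects <- function(betas, manifest, exposure_spec, seed = 1L) {
  sites <- exposure_spec$sites
  if (length(sites) && !all(sites %in% rownames(betas)))
    stopf("affected site not in matrix: %s", setdiff(sites, rownames(betas))[1])
  p <- exposure_spec$p_exposed %||% 0.25
  conc <- exposure_spec$concordance %||% 0.7
  eff <- exposure_spec$effect %||% -0.1
  set.seed(as.integer(seed))
  n_pairs <- nrow(manifest)
  shared <- runif(n_pairs) < conc
  fam_draw <- runif(n_pairs) < p
  e1 <- ifelse(shared, fam_draw, runif(n_pairs) < p)
  e2 <- ifelse(shared, fam_draw, runif(n_pairs) < p)
  exposed <- setNames(logical(ncol(betas)), colnames(betas))
  exposed[manifest$sample_id_a] <- e1
  exposed[manifest$sample_id_b] <- e2

  out <- unclass(betas)
  if (length(sites)) {
    effv <- rep_len(eff, length(sites))
    shift <- outer(effv, as.numeric(exposed[colnames(betas)]))
    out[sites, ] <- out[sites, , drop = FALSE] + shift
    n_bound <- sum(out[sites, ] < 0 | out[sites, ] > 1)
    if (n_bound > 0.05 * length(sites) * ncol(betas))
      warnf("exposure effect pushed %.1f%% of affected-site values past a clip boundary",
        100 * n_bound / (length(sites) * ncol(betas)))
    out[sites, ] <- pmin(pmax(out[sites, , drop = FALSE], 0), 1)
  }
  covs <- sample_covariates(data.frame(
    sample_id = colnames(betas),
    smoking_status = ifelse(exposed[colnames(betas)], "current", "never"),
    family_id = manifest$family_id[match(sub("_[12]$", "", colnames(betas)),
      manifest$pair_id)]))
  list(betas = beta_matrix(out), covariates = covs)
}
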