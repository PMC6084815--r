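#' @importFrom stats coef cor dhyper lm lm.fit optim optimize pbinom plogis
#'   pnorm pt qlogis quantile rbinom rnorm runif sd setNames var wilcox.test
#'   complete.cases
#' @importFrom utils head modifyList
NULL

# log(sum(exp(x))) without overflow; returns -Inf for empty input
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# natural chromosome ordering: chr1..chr22 < chrX < chrY < chrM < others
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  n <- suppressWarnings(as.integer(x))
  r <- ifelse(!is.na(n), n,
    ifelse(toupper(x) == "X", 23L,
      ifelse(toupper(x) == "Y", 24L,
        ifelse(toupper(x) %in% c("M", "MT"), 25L, NA_integer_))))
  # unknown labels sort after the canonical set, alphabetically
  unk <- is.na(r)
  if (any(unk)) r[unk] <- 26L + as.integer(factor(x[unk], levels = sort(unique(x[unk]))))
  r
}

is_chrX <- function(chrom) toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE)) == "X"
is_chrY <- function(chrom) toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE)) == "Y"

# deterministic per-component sub-seed from a single master seed (< 2^31)
derive_seed <- function(seed, component) {
  offs <- c(latent = 101L, genotype = 211L, exposure = 307L, sex = 401L,
    mqtl = 503L, unrelated = 601L, sites = 701L)
  if (!component %in% names(offs)) stop("unknown seed component: ", component)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[component]]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
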