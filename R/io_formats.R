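#' Construct a validated beta-value matrix
#'
#' A `BetaMatrix` is a numeric matrix of methylation proportions (beta values)
#' with probes in rows and samples in columns. Values must lie in \[0, 1\];
#' missing values are allowed. Row and column names are the authoritative
#' probe and sample identifiers and must be unique.
#'
#' @param values numeric matrix with unique rownames (probe ids) and unique
#'   colnames (sample ids); entries in \[0, 1\] or `NA`.
#' @return the matrix with class `BetaMatrix` prepended.
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("beta matrix must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stopf("beta matrix requires probe rownames and sample colnames")
  if (anyDuplicated(pid))
    stopf("duplicate probe id: %s", pid[duplicated(pid)][1])
  if (anyDuplicated(sid))
    stopf("duplicate sample id: %s", sid[duplicated(sid)][1])
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      pid[bad[1, 1]], sid[bad[1, 2]], values[bad[1, , drop = FALSE]])
  class(values) <- c("BetaMatrix", class(values))
  values
}

#' Read a beta-value matrix from delimited text
#'
#' First column holds probe ids, header row holds sample ids. Tab- and
#' comma-delimited files are both accepted (delimiter sniffed from the header
#' unless `sep` is given). Empty cells and `NA` are read as missing.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects `\t` vs `,`.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, sep = sep %||% "auto", header = TRUE,
    na.strings = c("", "NA"), data.table = FALSE, colClasses = list(character = 1))
  if (ncol(dt) < 2) stopf("beta matrix file needs a probe id column plus samples: %s", path)
  ids <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  beta_matrix(m)
}

#' Write a beta-value matrix as tab-delimited text
#'
#' Missing values are written as `NA`. Full `%.17g` precision is used so
#' write-then-read round-trips exactly.
#'
#' @param betas a [beta_matrix()].
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  m <- unclass(betas)
  vals <- data.table::as.data.table(
    lapply(seq_len(ncol(m)), function(j)
      ifelse(is.na(m[, j]), NA_character_, sprintf("%.17g", m[, j]))))
  data.table::setnames(vals, colnames(m))
  out <- cbind(data.table::data.table(probe_id = rownames(m)), vals)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Construct a validated twin-pair manifest
#'
#' Each row pairs two sample ids with a zygosity (`MZ`/`DZ`), a shared sex
#' (`F`/`M`; the design is same-sex pairs) and a family id. A sample may
#' belong to at most one pair.
#'
#' @param df data.frame with columns `pair_id`, `sample_id_a`, `sample_id_b`,
#'   `zygosity`, `sex`, `family_id`.
#' @return the data.frame with class `PairManifest`.
#' @export
pair_manifest <- function(df) {
  need <- c("pair_id", "sample_id_a", "sample_id_b", "zygosity", "sex", "family_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("pair manifest missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (j in need) df[[j]] <- as.character(df[[j]])
  if (anyDuplicated(df$pair_id))
    stopf("duplicate pair_id: %s", df$pair_id[duplicated(df$pair_id)][1])
  ids <- c(df$sample_id_a, df$sample_id_b)
  if (anyDuplicated(ids))
    stopf("sample listed in more than one pair: %s", ids[duplicated(ids)][1])
  badz <- setdiff(unique(df$zygosity), c("MZ", "DZ"))
  if (length(badz)) stopf("unknown zygosity code: %s", badz[1])
  bads <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bads)) stopf("unknown sex code: %s", bads[1])
  class(df) <- c("PairManifest", "data.frame")
  df
}

#' Read a twin-pair manifest from delimited text
#'
#' Samples present in the manifest but absent from a companion beta matrix are
#' reported via a `flagged_missing` attribute (never dropped silently).
#'
#' @param path file path.
#' @param betas optional [beta_matrix()] to cross-check sample ids against.
#' @param sep delimiter, auto-detected by default.
#' @return a [pair_manifest()]; attribute `flagged_missing` lists manifest
#'   samples not found in `betas` (if supplied).
#' @export
read_pair_manifest <- function(path, betas = NULL, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- data.table::fread(path, sep = sep %||% "auto", header = TRUE,
    data.table = FALSE, colClasses = "character")
  mf <- pair_manifest(df)
  if (!is.null(betas)) {
    missing_ids <- setdiff(c(mf$sample_id_a, mf$sample_id_b), colnames(betas))
    attr(mf, "flagged_missing") <- missing_ids
    if (length(missing_ids))
      warnf("%d manifest sample(s) absent from beta matrix (see attr 'flagged_missing')",
        length(missing_ids))
  }
  mf
}

#' Write a twin-pair manifest
#' @param manifest a [pair_manifest()].
#' @param path output path.
#' @export
write_pair_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a validated probe annotation table
#'
#' @param df data.frame with at least `probe_id`, `chrom`, `position`;
#'   optionally `strand`, `gene_features` (comma-separated subset of TSS200,
#'   TSS1500, 5'UTR, 1stExon, Body, 3'UTR, intergenic), `island_relation`
#'   (Island/Shore/Shelf/OpenSea), `tss_distance` (signed bp, strand-aware,
#'   negative = upstream), and arbitrary numeric per-probe score columns
#'   (mQTL effect per allele, cross-tissue covariation r, chromatin state).
#' @return data.frame with class `ProbeAnnotation`.
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chrom", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("probe annotation missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$probe_id <- as.character(df$probe_id)
  df$chrom <- as.character(df$chrom)
  df$position <- as.integer(df$position)
  if (anyDuplicated(df$probe_id))
    stopf("duplicate probe_id in annotation: %s", df$probe_id[duplicated(df$probe_id)][1])
  if (any(!nzchar(df$chrom))) stopf("empty chrom for probe %s", df$probe_id[!nzchar(df$chrom)][1])
  if (any(!is.na(df$position) & df$position < 1))
    stopf("position < 1 for probe %s", df$probe_id[which(df$position < 1)][1])
  if ("island_relation" %in% names(df)) {
    badi <- setdiff(unique(df$island_relation), c("Island", "Shore", "Shelf", "OpenSea", NA))
    if (length(badi)) stopf("unknown island_relation: %s", badi[1])
  }
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Read a probe annotation table
#'
#' Accepts either native column names (`probe_id`, `chrom`, `position`, ...)
#' or the Illumina HumanMethylation450 manifest schema, mapped as: `IlmnID`
#' -> `probe_id`, `CHR` -> `chrom` (a `chr` prefix is added when absent),
#' `MAPINFO` -> `position` (1-based, the interrogated CpG's C),
#' `UCSC_RefGene_Group` -> `gene_features`, `Relation_to_UCSC_CpG_Island` ->
#' `island_relation` (N/S shore and shelf variants collapsed).
#'
#' @param path file path.
#' @param sep delimiter, auto-detected by default.
#' @return a [probe_annotation()].
#' @export
read_probe_annotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- data.table::fread(path, sep = sep %||% "auto", header = TRUE, data.table = FALSE)
  ilmn <- c(IlmnID = "probe_id", CHR = "chrom", MAPINFO = "position",
    UCSC_RefGene_Group = "gene_features",
    Relation_to_UCSC_CpG_Island = "island_relation", STRAND = "strand")
  hit <- intersect(names(ilmn), names(df))
  if (length(hit)) {
    names(df)[match(hit, names(df))] <- ilmn[hit]
    if (!any(grepl("^chr", df$chrom))) df$chrom <- paste0("chr", df$chrom)
    if ("island_relation" %in% names(df)) {
      ir <- df$island_relation
      ir[grepl("Shore$", ir)] <- "Shore"
      ir[grepl("Shelf$", ir)] <- "Shelf"
      ir[ir == "" | is.na(ir)] <- "OpenSea"
      df$island_relation <- ir
    }
    if ("gene_features" %in% names(df)) {
      # the manifest repeats a feature per transcript; keep the unique set
      df$gene_features <- vapply(strsplit(as.character(df$gene_features), ";"),
        function(x) paste(unique(x[nzchar(x)]), collapse = ","), character(1))
      df$gene_features[!nzchar(df$gene_features)] <- "intergenic"
    }
  }
  probe_annotation(df)
}

#' Write per-site variance decomposition results
#'
#' Emits a tab-delimited table with a fixed header (`probe_id`, `chrom`,
#' `position`, `n_MZ`, `n_DZ`, `r_MZ`, `r_DZ`, `A`, `C`, `E`, `A_raw`,
#' `C_raw`, `E_raw`, `loglik`, `converged`, `boundary`, `method`), floats at
#' 6 significant digits, rows in deterministic genomic order (natural
#' chromosome order, then position, then probe id).
#'
#' @param decomp a `VarianceDecomposition` data.frame, e.g. from
#'   [run_ace_genomewide()], optionally carrying `chrom`/`position` columns
#'   (absent columns are written as `NA`).
#' @param path output path.
#' @export
write_results_table <- function(decomp, path) {
  df <- as.data.frame(decomp)
  cols <- c("probe_id", "chrom", "position", "n_MZ", "n_DZ", "r_MZ", "r_DZ",
    "A", "C", "E", "A_raw", "C_raw", "E_raw", "loglik", "converged",
    "boundary", "method")
  for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
  # raw variance components: standardized proportion x total variance
  if (all(c("A", "sigma2") %in% names(decomp)) && !"A_raw" %in% names(decomp)) {
    df$A_raw <- df$A * df$sigma2; df$C_raw <- df$C * df$sigma2; df$E_raw <- df$E * df$sigma2
  }
  df <- df[order(chrom_rank(df$chrom), df$position, df$probe_id), cols]
  num <- vapply(df, is.numeric, logical(1)) & !names(df) %in% c("position")
  for (j in names(df)[num]) df[[j]] <- signif(df[[j]], 6)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path file path.
#' @return data.frame with the documented columns.
#' @export
read_results_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
    na.strings = "NA")
}

#' Construct a per-sample covariate table
#'
#' @param df data.frame keyed by `sample_id`; recognised optional columns:
#'   `smoking_status` (current/former/never), cell-proportion columns (each in
#'   \[0, 1\]), `batch`, `family_id`, and arbitrary continuous phenotypes.
#' @param cell_columns names of columns holding cell proportions, checked to
#'   lie in \[0, 1\].
#' @return data.frame with class `SampleCovariates`.
#' @export
sample_covariates <- function(df, cell_columns = character()) {
  if (!"sample_id" %in% names(df)) stopf("covariates require a sample_id column")
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id in covariates: %s", df$sample_id[duplicated(df$sample_id)][1])
  if ("smoking_status" %in% names(df)) {
    bad <- setdiff(unique(df$smoking_status), c("current", "former", "never", NA))
    if (length(bad)) stopf("unknown smoking_status: %s", bad[1])
  }
  for (j in cell_columns) {
    v <- df[[j]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stopf("cell proportion out of [0,1] in column %s", j)
  }
  class(df) <- c("SampleCovariates", "data.frame")
  df
}
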