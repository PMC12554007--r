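# Readers/writers for the standard interchange formats and LD pruning.
#
# Methylation counts travel as long-format TSV with header columns
# sample_id, position, meth_reads, total_reads (positions 1-based bp, as in
# VCF). Genotypes travel as a samples x SNPs TSV (first column sample_id) or
# as VCF with GT fields.

#' Read long-format methylation counts
#'
#' Rows with `total_reads = 0` carry no likelihood information and are
#' dropped with a message reporting the count.
#'
#' @param path TSV file with columns `sample_id`, `position`, `meth_reads`,
#'   `total_reads`.
#' @return data.frame of validated records (zero-coverage rows removed).
#' @export
read_methylation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "position", "meth_reads", "total_reads")
  if (!all(need %in% names(df))) {
    stop("methylation file must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$meth_reads != round(df$meth_reads)) ||
      any(df$total_reads != round(df$total_reads))) {
    stop("non-integer read counts in ", path)
  }
  bad <- which(df$meth_reads > df$total_reads)
  if (length(bad)) {
    stop("meth_reads > total_reads at row ", bad[1], " of ", path)
  }
  zero <- df$total_reads == 0
  if (any(zero)) {
    message("dropped ", sum(zero), " zero-coverage record(s) from ", basename(path))
    df <- df[!zero, , drop = FALSE]
  }
  df
}

#' Write long-format methylation counts
#'
#' @param records data.frame with the four standard columns (or a
#'   `region_dataset`).
#' @param path output TSV path.
#' @export
write_methylation <- function(records, path) {
  if (inherits(records, "region_dataset")) {
    records <- data.frame(
      sample_id = records$sample_ids[records$records$sample_idx],
      position = records$records$position,
      meth_reads = records$records$Y,
      total_reads = records$records$X
    )
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' TSV input is samples x SNPs with a leading `sample_id` column. VCF input
#' is parsed with the vcfR package; the GT field is coded as the count of
#' alternate alleles (`0/1` -> 1, `1/1` -> 2). Missing genotypes (`./.` or
#' NA) are mean-imputed per SNP with a message reporting the count.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (guessed from the extension by default).
#' @return numeric N x P matrix with sample ids as rownames and SNP ids as
#'   colnames.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "sample_id") {
      stop("genotype TSV must have a leading sample_id column")
    }
    Z <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(Z) <- "double"
    rownames(Z) <- as.character(df$sample_id)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
    }
    Z <- t(apply(gt, 1, count_alt))
    dimnames(Z) <- dimnames(gt)
    Z <- t(Z)  # samples x SNPs
  }
  n_missing <- sum(is.na(Z))
  if (n_missing) {
    message("mean-imputed ", n_missing, " missing genotype(s)")
    for (j in seq_len(ncol(Z))) {
      miss <- is.na(Z[, j])
      if (any(miss)) Z[miss, j] <- mean(Z[!miss, j])
    }
  }
  if (any(Z < 0 | Z > 2)) stop("genotype dosages outside [0, 2] in ", path)
  Z
}

#' Write a genotype dosage matrix as TSV
#'
#' @param Z N x P matrix with sample rownames.
#' @param path output path.
#' @export
write_genotypes <- function(Z, path) {
  df <- data.frame(sample_id = rownames(Z), Z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a `region_dataset` from files
#'
#' Sample order is reconciled between the two files by id; a mismatch in
#' either direction is an error listing the symmetric difference.
#'
#' @param meth_path methylation TSV path.
#' @param geno_path genotype TSV/VCF path.
#' @param format genotype format passed to [read_genotypes()].
#' @export
read_region <- function(meth_path, geno_path, format = "auto") {
  meth <- read_methylation(meth_path)
  Z <- read_genotypes(geno_path, format)
  meth_samples <- unique(as.character(meth$sample_id))
  geno_samples <- rownames(Z)
  only_meth <- setdiff(meth_samples, geno_samples)
  only_geno <- setdiff(geno_samples, meth_samples)
  if (length(only_meth) || length(only_geno)) {
    stop("sample-id mismatch between files; only in methylation: [",
         paste(only_meth, collapse = ", "), "]; only in genotypes: [",
         paste(only_geno, collapse = ", "), "]")
  }
  Z <- Z[meth_samples, , drop = FALSE]
  region_dataset(meth$sample_id, meth$position, meth$meth_reads,
                 meth$total_reads, Z)
}

#' Greedy LD pruning
#'
#' Left-to-right pass in genomic order: a SNP is kept iff its squared
#' Pearson correlation with every previously kept SNP is below the
#' threshold. Constant columns have undefined correlation, which is treated
#' as 0 (they are kept, with a message). Deterministic.
#'
#' @param Z N x P dosage matrix in genomic column order.
#' @param r2_threshold squared-correlation threshold in `(0, 1]` (the study
#'   default for genome-wide scans is 0.2).
#' @return integer vector of kept column indices.
#' @export
ld_prune <- function(Z, r2_threshold = 0.2) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]")
  }
  P <- ncol(Z)
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) {
    message("constant SNP column(s) kept trivially (r^2 treated as 0): ",
            paste(which(sds == 0), collapse = ", "))
  }
  kept <- integer(0)
  for (j in seq_len(P)) {
    ok <- TRUE
    if (sds[j] > 0) {
      for (k in kept) {
        if (sds[k] == 0) next
        r <- stats::cor(Z[, j], Z[, k])
        if (r^2 >= r2_threshold) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

#' Export a cross-validation surface as TSV
#'
#' @param cv a `cv_result`.
#' @param path output path.
#' @export
write_cv_surface <- function(cv, path) {
  df <- data.frame(
    alpha = rep(cv$alpha_grid, times = ncol(cv$lambda)),
    lambda = as.vector(cv$lambda),
    mean_error = as.vector(cv$mean),
    se = as.vector(cv$se)
  )
  df <- df[order(df$alpha, -df$lambda), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a fit summary as JSON
#'
#' @param result a list as returned by [ssp_cv()] or [fit_adaptive()].
#' @param dataset the fitted `region_dataset`.
#' @param path output path.
#' @export
write_selection_json <- function(result, dataset, path) {
  fit <- result$fit
  out <- list(
    variant = result$variant,
    rule = result$rule,
    lambda = fit$lambda,
    alpha = fit$alpha,
    converged = fit$converged,
    selected = as.list(dataset$snp_ids[fit$selected])
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export fitted coefficient curves as TSV
#'
#' @param fit a `fit_result`.
#' @param dataset the fitted `region_dataset`.
#' @param grid positions at which to evaluate (defaults to the distinct
#'   observed positions).
#' @param path output path.
#' @export
write_curves <- function(fit, dataset, path, grid = NULL) {
  if (is.null(grid)) grid <- sort(unique(dataset$records$position))
  df <- curves_long(fit$coefs, fit$coefs$basis, grid, snp_ids = dataset$snp_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
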