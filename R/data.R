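#' Regional methylation dataset
#'
#' Bundles per-CpG bisulfite read counts with the sample-by-SNP genotype
#' matrix. Each record is one (sample, position) observation with methylated
#' reads `Y` out of `X` total reads; the binomial denominator must be at
#' least 1 (zero-coverage records carry no likelihood information and are
#' rejected here; file readers drop them before construction).
#'
#' @param sample_id vector of sample identifiers, one per record.
#' @param position numeric genomic positions (bp), one per record.
#' @param meth_reads integer methylated read counts \eqn{Y_{ij} \ge 0}.
#' @param total_reads integer total read counts \eqn{X_{ij} \ge 1}.
#' @param genotypes N x P numeric dosage matrix with entries in `[0, 2]`
#'   (real-valued imputed dosages are accepted); rownames, if present, must
#'   cover every sample id.
#' @param snp_ids optional SNP identifiers (defaults to colnames or snp1..P).
#' @return a `region_dataset` with fields `records` (data.frame:
#'   `sample_idx`, `position`, `Y`, `X`), `Z`, `sample_ids`, `snp_ids`,
#'   `N`, `P`, `M`.
#' @export
region_dataset <- function(sample_id, position, meth_reads, total_reads,
                           genotypes, snp_ids = NULL) {
  n <- length(sample_id)
  stopifnot(length(position) == n, length(meth_reads) == n,
            length(total_reads) == n)
  if (any(!is.finite(position))) stop("non-finite positions")
  if (any(meth_reads < 0) || any(meth_reads != round(meth_reads)) ||
      any(total_reads != round(total_reads))) {
    stop("read counts must be nonnegative integers")
  }
  if (any(total_reads < 1)) {
    stop("records with total_reads = 0 are not allowed; drop them at ingestion")
  }
  if (any(meth_reads > total_reads)) {
    bad <- which(meth_reads > total_reads)[1]
    stop(sprintf("meth_reads > total_reads at record %d (sample %s, position %s)",
                 bad, sample_id[bad], format(position[bad])))
  }
  genotypes <- as.matrix(genotypes)
  if (any(!is.finite(genotypes)) || any(genotypes < 0) || any(genotypes > 2)) {
    stop("genotype dosages must be finite values in [0, 2]")
  }
  sample_ids <- if (!is.null(rownames(genotypes))) rownames(genotypes) else
    as.character(sort(unique(sample_id)))
  if (is.null(rownames(genotypes))) {
    if (nrow(genotypes) != length(sample_ids)) {
      stop("genotype matrix has ", nrow(genotypes), " rows but data contain ",
           length(sample_ids), " samples")
    }
    rownames(genotypes) <- sample_ids
  }
  sample_idx <- match(as.character(sample_id), sample_ids)
  if (anyNA(sample_idx)) {
    missing <- unique(as.character(sample_id)[is.na(sample_idx)])
    stop("samples without a genotype row: ", paste(missing, collapse = ", "))
  }
  if (is.null(snp_ids)) {
    snp_ids <- if (!is.null(colnames(genotypes))) colnames(genotypes) else
      paste0("snp", seq_len(ncol(genotypes)))
  }
  colnames(genotypes) <- snp_ids
  structure(
    list(records = data.frame(sample_idx = sample_idx, position = position,
                              Y = as.integer(meth_reads),
                              X = as.integer(total_reads)),
         Z = genotypes, sample_ids = sample_ids, snp_ids = snp_ids,
         N = length(sample_ids), P = ncol(genotypes), M = n),
    class = "region_dataset"
  )
}

#' Restrict a dataset to a subset of samples
#'
#' @param dataset a `region_dataset`.
#' @param samples integer sample indices (rows of `Z`) to keep.
#' @export
subset_samples <- function(dataset, samples) {
  keep <- dataset$records$sample_idx %in% samples
  rec <- dataset$records[keep, , drop = FALSE]
  region_dataset(dataset$sample_ids[rec$sample_idx], rec$position, rec$Y, rec$X,
                 dataset$Z[samples, , drop = FALSE], snp_ids = dataset$snp_ids)
}

#' Assemble design matrices for a region fit
#'
#' The model design has one M x K block per covariate group,
#' \eqn{[X_p]_{(ij),k} = b_k(t_{ij}) Z_{ip}} with \eqn{Z_{i0} \equiv 1} for
#' the intercept. The blocks are stored in factorized form (basis rows plus
#' the augmented genotype matrix) and materialized on demand with
#' [design_block()]; penalized groups additionally carry the reparameterized
#' version \eqn{\tilde X_p = X_p L_p^{-1}}.
#'
#' @param dataset a `region_dataset`.
#' @param basis a `spline_basis` built on the dataset's positions.
#' @param penalty a `penalty_operator` for P covariate groups.
#' @return a `design_matrices` object with fields `B` (M x K basis rows),
#'   `Zaug` (N x (P+1), first column 1), `sample_idx`, `basis`, `penalty`,
#'   `zero_block` (covariates whose genotype column is all zero).
#' @export
assemble_design <- function(dataset, basis, penalty) {
  stopifnot(inherits(dataset, "region_dataset"),
            inherits(basis, "spline_basis"),
            inherits(penalty, "penalty_operator"))
  if (penalty$P != dataset$P) {
    stop("penalty composed for ", penalty$P, " covariates but dataset has ",
         dataset$P)
  }
  B <- evaluate_basis(basis, dataset$records$position)
  Zaug <- cbind(intercept = 1, dataset$Z)
  zero_block <- which(apply(dataset$Z, 2, function(z) all(z == 0)))
  if (length(zero_block)) {
    message("genotype column(s) constant zero (selectable but inert): ",
            paste(dataset$snp_ids[zero_block], collapse = ", "))
  }
  structure(
    list(B = B, Zaug = Zaug, sample_idx = dataset$records$sample_idx,
         basis = basis, penalty = penalty, zero_block = zero_block,
         M = dataset$M, K = basis$K, P = dataset$P),
    class = "design_matrices"
  )
}

#' Materialize one design block
#'
#' @param design a `design_matrices` object.
#' @param p covariate index 0..P (0 = intercept).
#' @param transformed if TRUE return \eqn{\tilde X_p = X_p L_p^{-1}}
#'   (penalized groups only).
#' @return M x K matrix.
#' @export
design_block <- function(design, p, transformed = FALSE) {
  stopifnot(p >= 0, p <= design$P)
  Xp <- design$B * design$Zaug[design$sample_idx, p + 1]
  if (!transformed || p == 0) return(Xp)
  Xp %*% penalty_Linv(design$penalty, p)
}

#' Coefficient set for a region fit
#'
#' @param theta (P+1) x K matrix of basis coefficients, row 1 = intercept.
#' @param basis the `spline_basis` the coefficients refer to.
#' @param penalty optional `penalty_operator` (enables eta conversion).
#' @export
coefficient_set <- function(theta, basis, penalty = NULL) {
  stopifnot(is.matrix(theta), ncol(theta) == basis$K)
  structure(list(theta = theta, basis = basis, penalty = penalty),
            class = "coefficient_set")
}

#' Convert between original and reparameterized coefficients
#'
#' The reparameterization is \eqn{\eta_p = L_p \theta_p} per penalized group
#' (intercept unchanged), under which the group penalty becomes the plain
#' Euclidean norm \eqn{\|\eta_p\|_2}.
#'
#' @param theta,eta (P+1) x K matrices.
#' @param penalty a `penalty_operator`.
#' @export
theta_to_eta <- function(theta, penalty) {
  eta <- theta
  for (p in seq_len(nrow(theta) - 1)) {
    if (p %in% penalty$excluded) next
    eta[p + 1, ] <- drop(penalty_L(penalty, p) %*% theta[p + 1, ])
  }
  eta
}

#' @rdname theta_to_eta
#' @export
eta_to_theta <- function(eta, penalty) {
  theta <- eta
  for (p in seq_len(nrow(eta) - 1)) {
    if (p %in% penalty$excluded) next
    theta[p + 1, ] <- drop(penalty_Linv(penalty, p) %*% eta[p + 1, ])
  }
  theta
}
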