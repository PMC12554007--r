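#' Compose the sparsity-smoothness penalty operator
#'
#' Builds, for each penalized covariate group p, the matrix
#' \deqn{H_p = w_{1p}(1-\alpha)\Omega^{(1)} + w_{2p}\,\alpha\,\Omega^{(2)}}
#' and its upper-triangular Cholesky factor \eqn{L_p} (with positive
#' diagonal, \eqn{L_p^T L_p = H_p}). The penalty applied to the coefficient
#' functions is \eqn{\lambda \sum_p \sqrt{\theta_p^T H_p \theta_p}}, a
#' generalized group lasso that zeroes whole functions. The intercept group
#' is never penalized.
#'
#' `alpha = 1` is rejected: a pure-curvature penalty does not penalize
#' constant or linear components and can lead to non-unique, unbounded
#' solutions.
#'
#' With `identity = TRUE` the matrices are replaced by the identity, which
#' turns the problem into an ordinary group LASSO on the raw basis
#' coefficients (the gLASSO special case). With `alpha = 0` and unit weights
#' the penalty reduces to the function-L2-norm-only variant (SSP0).
#'
#' @param matrices output of [penalty_matrices()].
#' @param alpha mixing weight in `[0, 1)`.
#' @param lambda overall penalty level, >= 0.
#' @param P number of penalized covariate groups (SNPs).
#' @param w1,w2 per-covariate positive weights (length P or scalar;
#'   default 1). An infinite weight excludes the covariate from the model.
#' @param identity if TRUE use H = I (group LASSO special case).
#' @return a `penalty_operator`: fields `alpha`, `lambda`, `w1`, `w2`,
#'   `excluded` (covariate indices with infinite weight), `shared` (TRUE when
#'   one H serves all groups), `H`, `L`, `Linv` (lists of per-group matrices,
#'   length 1 when shared), `K`, `P`, `identity`.
#' @export
compose_penalty <- function(matrices, alpha, lambda, P,
                            w1 = 1, w2 = 1, identity = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    stop("alpha must lie in [0, 1); alpha = 1 gives a curvature-only penalty ",
         "that can lead to non-unique, unbounded solutions")
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a nonnegative scalar")
  }
  P <- as.integer(P)
  w1 <- rep_len(as.numeric(w1), P)
  w2 <- rep_len(as.numeric(w2), P)
  if (any(is.nan(w1)) || any(is.nan(w2))) stop("weights must not be NaN")
  bad <- (is.finite(w1) & w1 <= 0) | (is.finite(w2) & w2 <= 0)
  if (any(bad)) {
    stop("nonpositive finite penalty weight for covariate(s): ",
         paste(which(bad), collapse = ", "))
  }
  excluded <- which(!is.finite(w1) | !is.finite(w2))
  K <- matrices$K

  shared <- identity || (all(w1 == 1) && all(w2 == 1))
  make_H <- function(a1, a2) {
    if (identity) diag(K) else a1 * (1 - alpha) * matrices$omega1 +
      a2 * alpha * matrices$omega2
  }
  groups <- if (shared) 1L else setdiff(seq_len(P), excluded)
  H <- L <- Linv <- vector("list", if (shared) 1L else P)
  for (g in groups) {
    Hg <- if (shared) make_H(1, 1) else make_H(w1[g], w2[g])
    Lg <- tryCatch(chol(Hg), error = function(e) {
      chol(Hg + diag(1e-10 * sum(diag(Hg)) / K, K))
    })
    H[[g]] <- Hg
    L[[g]] <- Lg
    Linv[[g]] <- backsolve(Lg, diag(K))
  }
  structure(
    list(alpha = alpha, lambda = lambda, w1 = w1, w2 = w2,
         excluded = excluded, shared = shared, H = H, L = L, Linv = Linv,
         K = K, P = P, identity = identity, matrices = matrices),
    class = "penalty_operator"
  )
}

# Index into the per-group matrix lists for covariate p (1..P).
penalty_group_index <- function(penalty, p) {
  if (penalty$shared) 1L else as.integer(p)
}

#' Per-group penalty matrix accessors
#'
#' @param penalty a `penalty_operator`.
#' @param p covariate index in 1..P.
#' @return the K x K matrix for group `p`.
#' @export
penalty_H <- function(penalty, p) penalty$H[[penalty_group_index(penalty, p)]]

#' @rdname penalty_H
#' @export
penalty_L <- function(penalty, p) penalty$L[[penalty_group_index(penalty, p)]]

#' @rdname penalty_H
#' @export
penalty_Linv <- function(penalty, p) penalty$Linv[[penalty_group_index(penalty, p)]]

#' Penalty value for a coefficient matrix
#'
#' Evaluates \eqn{\lambda \sum_{p\ge 1} \sqrt{\theta_p^T H_p \theta_p}}.
#' Excluded covariates must have zero rows.
#'
#' @param penalty a `penalty_operator`.
#' @param theta (P+1) x K coefficient matrix (row 1 = intercept).
#' @export
penalty_value <- function(penalty, theta) {
  val <- 0
  for (p in seq_len(penalty$P)) {
    th <- theta[p + 1, ]
    if (p %in% penalty$excluded) {
      if (any(th != 0)) stop("excluded covariate ", p, " has nonzero coefficients")
      next
    }
    val <- val + sqrt(max(0, drop(th %*% penalty_H(penalty, p) %*% th)))
  }
  penalty$lambda * val
}
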