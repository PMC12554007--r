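# Binomial likelihood for the varying-coefficient model.
#
# The linear predictor for record (i, j) is
#   logit(pi_ij) = beta_0(t_ij) + sum_p beta_p(t_ij) Z_ip
#                = B(t_ij)' (Theta' zaug_i),
# so all M predictors are obtained from the N x K matrix Zaug %*% Theta
# without materializing the M x (P+1)K design.

PI_CLIP <- 1e-10

# Linear predictor for all records given (P+1) x K theta.
linear_predictor <- function(theta, design) {
  U <- design$Zaug %*% theta                      # N x K
  rowSums(design$B * U[design$sample_idx, , drop = FALSE])
}

#' Twice-negative binomial log-likelihood
#'
#' Evaluates \eqn{-2\sum_{ij} [Y_{ij}\log\pi_{ij} + (X_{ij}-Y_{ij})
#' \log(1-\pi_{ij})]} for the varying-coefficient model. Probabilities are
#' clipped to `[1e-10, 1 - 1e-10]` before taking logs so the value is finite
#' for any finite coefficients. The additive binomial-coefficient term is
#' omitted (constant in the parameters), so deviance-style differences are
#' unaffected.
#'
#' @param coefs a `coefficient_set` or a (P+1) x K theta matrix.
#' @param design a `design_matrices` object.
#' @param dataset the `region_dataset` the design was assembled from.
#' @return nonnegative scalar.
#' @export
neg2_loglik <- function(coefs, design, dataset) {
  theta <- if (inherits(coefs, "coefficient_set")) coefs$theta else coefs
  if (any(!is.finite(theta))) stop("non-finite coefficients")
  pi <- plogis(linear_predictor(theta, design))
  pi <- pmin(pmax(pi, PI_CLIP), 1 - PI_CLIP)
  y <- dataset$records$Y
  x <- dataset$records$X
  -2 * sum(y * log(pi) + (x - y) * log(1 - pi))
}

#' Gradient of the twice-negative log-likelihood
#'
#' In the original space the block-p gradient is
#' \eqn{-2 X_p^T (Y - X \odot \pi)}; in the reparameterized space each
#' penalized block is premultiplied by \eqn{L_p^{-T}}.
#'
#' @inheritParams neg2_loglik
#' @param space `"original"` (with respect to theta) or `"reparameterized"`
#'   (with respect to eta).
#' @return (P+1) x K gradient matrix.
#' @export
vc_gradient <- function(coefs, design, dataset,
                        space = c("original", "reparameterized")) {
  space <- match.arg(space)
  theta <- if (inherits(coefs, "coefficient_set")) coefs$theta else coefs
  if (any(!is.finite(theta))) stop("non-finite coefficients")
  pi <- plogis(linear_predictor(theta, design))
  pi <- pmin(pmax(pi, PI_CLIP), 1 - PI_CLIP)
  resid <- dataset$records$Y - dataset$records$X * pi
  S <- rowsum(design$B * resid, design$sample_idx,
              reorder = FALSE)                       # one row per sample seen
  ord <- as.integer(rownames(S))
  Sfull <- matrix(0, dataset$N, design$K)
  Sfull[ord, ] <- S
  G <- -2 * t(design$Zaug) %*% Sfull                 # (P+1) x K
  if (space == "reparameterized") {
    pen <- design$penalty
    for (p in seq_len(design$P)) {
      if (p %in% pen$excluded) next
      G[p + 1, ] <- drop(t(penalty_Linv(pen, p)) %*% G[p + 1, ])
    }
  }
  unname(G)
}

#' Predicted methylation probabilities
#'
#' \eqn{\pi_{ij} = \mathrm{logistic}(\beta_0(t_{ij}) + \sum_p
#' \beta_p(t_{ij}) Z_{ip})} per record. Positions outside the basis range are
#' clamped to it with a warning.
#'
#' @param coefs a `coefficient_set` or theta matrix.
#' @param dataset a `region_dataset`.
#' @param basis the `spline_basis` (taken from `coefs` if absent).
#' @return vector of probabilities in (0, 1), one per record.
#' @export
predict_pi <- function(coefs, dataset, basis = NULL) {
  theta <- if (inherits(coefs, "coefficient_set")) coefs$theta else coefs
  if (is.null(basis) && inherits(coefs, "coefficient_set")) basis <- coefs$basis
  pos <- dataset$records$position
  out_of_range <- pos < basis$raw_range[1] | pos > basis$raw_range[2]
  if (any(out_of_range)) {
    warning(sum(out_of_range), " position(s) outside the basis range were clamped")
    pos <- pmin(pmax(pos, basis$raw_range[1]), basis$raw_range[2])
  }
  B <- evaluate_basis(basis, pos)
  U <- cbind(1, dataset$Z) %*% theta
  unname(plogis(rowSums(B * U[dataset$records$sample_idx, , drop = FALSE])))
}

#' Fitted coefficient functions on a position grid
#'
#' Evaluates \eqn{\beta_p(t) = \theta_p^T B(t)} for every covariate
#' (including the intercept) on a grid of raw positions.
#'
#' @param coefs a `coefficient_set` or theta matrix.
#' @param basis the `spline_basis`.
#' @param grid numeric positions (bp).
#' @return (P+1) x length(grid) matrix of curve values; rows named
#'   "intercept", then covariates.
#' @export
coefficient_functions <- function(coefs, basis, grid) {
  theta <- if (inherits(coefs, "coefficient_set")) coefs$theta else coefs
  B <- evaluate_basis(basis, grid)
  out <- theta %*% t(B)
  rownames(out) <- c("intercept", paste0("cov", seq_len(nrow(theta) - 1)))
  out
}

#' Export fitted curves as a long-format data frame
#'
#' @inheritParams coefficient_functions
#' @param snp_ids optional covariate names.
#' @return data.frame with columns `position`, `covariate`, `estimate`.
#' @export
curves_long <- function(coefs, basis, grid, snp_ids = NULL) {
  cf <- coefficient_functions(coefs, basis, grid)
  if (!is.null(snp_ids)) rownames(cf) <- c("intercept", snp_ids)
  data.frame(
    position = rep(grid, each = nrow(cf)),
    covariate = rep(rownames(cf), times = length(grid)),
    estimate = as.vector(cf)
  )
}
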