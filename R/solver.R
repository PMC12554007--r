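#' Solver configuration for proximal gradient descent
#'
#' @param t_init initial step size for the backtracking line search (> 0).
#'   Reset at every iteration.
#' @param shrink backtracking shrinkage factor \eqn{\delta \in (0,1)}.
#' @param tol convergence threshold on the relative change of the penalized
#'   objective between iterations.
#' @param max_iter iteration cap; hitting it flags the fit as not converged.
#' @param reset_step if TRUE the line search restarts at `t_init` every
#'   iteration; the default carries the last accepted step forward (with one
#'   growth attempt), which saves most objective evaluations while the
#'   acceptance condition still guarantees descent.
#' @export
solver_config <- function(t_init = 1, shrink = 0.5, tol = 1e-8,
                          max_iter = 5000L, reset_step = FALSE) {
  stopifnot(t_init > 0, shrink > 0, shrink < 1, tol > 0, max_iter >= 1)
  structure(list(t_init = t_init, shrink = shrink, tol = tol,
                 max_iter = as.integer(max_iter),
                 reset_step = isTRUE(reset_step)), class = "solver_config")
}

#' Group-wise proximal operator of the group-norm penalty
#'
#' Solves \eqn{\arg\min_\eta \frac{1}{2t}\|u - \eta\|^2 + \lambda
#' \sum_p \|\eta_p\|_2}: each penalized group is scaled by
#' \eqn{(1 - t\lambda/\|u_p\|_2)_+}; the intercept group is returned
#' unchanged (it is never penalized).
#'
#' @param u K x (P+1) matrix of reparameterized coefficients (column 1 =
#'   intercept) or a list of group vectors.
#' @param threshold nonnegative scalar \eqn{t\lambda}.
#' @param penalized indices (1..P) of groups subject to the penalty.
#' @return object of the same shape as `u`.
#' @export
prox_group <- function(u, threshold, penalized = seq_len(ncol(u) - 1)) {
  if (threshold < 0) stop("negative proximal threshold")
  for (p in penalized) {
    nrm <- sqrt(sum(u[, p + 1]^2))
    u[, p + 1] <- if (nrm <= threshold) 0 else (1 - threshold / nrm) * u[, p + 1]
  }
  u
}

#' One backtracking line-search step of proximal gradient descent
#'
#' Starting from `t_init`, the candidate step is shrunk by `shrink` until the
#' generalized-gradient majorization condition
#' \deqn{\ell(\eta - t G_t) \le \ell(\eta) - t \nabla\ell(\eta)^T G_t +
#' \frac{t}{2}\|G_t\|^2}
#' holds, where \eqn{G_t(\eta) = [\eta - \mathrm{prox}_{t}(\eta -
#' t\nabla\ell(\eta))]/t}. Returns the accepted step and the updated point.
#'
#' @param eta current K x (P+1) coefficient matrix (reparameterized).
#' @param config a [solver_config()].
#' @param objective function(eta) -> smooth loss \eqn{\ell}.
#' @param gradient function(eta) -> gradient matrix of \eqn{\ell}.
#' @param lambda penalty level.
#' @param penalized penalized group indices (1..P).
#' @return list with `t` (accepted step), `eta` (new point), `G`
#'   (generalized gradient at the accepted step).
#' @export
backtracking_step <- function(eta, config, objective, gradient, lambda,
                              penalized = seq_len(ncol(eta) - 1)) {
  g <- gradient(eta)
  if (any(!is.finite(g))) stop("non-finite gradient in line search")
  f0 <- objective(eta)
  t <- config$t_init
  for (m in 0:100) {
    cand <- prox_group(eta - t * g, t * lambda, penalized)
    G <- (eta - cand) / t
    if (all(G == 0)) return(list(t = t, eta = eta, G = G))
    lhs <- objective(cand)
    rhs <- f0 - t * sum(g * G) + (t / 2) * sum(G^2)
    if (lhs <= rhs + 1e-10 * (abs(f0) + 1)) {
      return(list(t = t, eta = cand, G = G))
    }
    t <- t * config$shrink
  }
  stop("backtracking line search failed after 100 shrinkages (gradient norm ",
       format(sqrt(sum(g^2))), ")")
}

# Build the eta -> theta transform cube and group bookkeeping for a design.
solver_groups <- function(design) {
  pen <- design$penalty
  K <- design$K
  P <- design$P
  locked <- sort(union(pen$excluded, design$zero_block))
  penalized <- setdiff(seq_len(P), locked)
  if (pen$shared) {
    Tmat <- array(0, dim = c(K, K, 2))
    Tmat[, , 1] <- diag(K)
    Tmat[, , 2] <- pen$Linv[[1]]
    tindex <- c(0L, rep(1L, P))
    tindex[1 + locked] <- 0L
  } else {
    Tmat <- array(0, dim = c(K, K, 1 + length(penalized)))
    Tmat[, , 1] <- diag(K)
    tindex <- integer(P + 1)
    for (i in seq_along(penalized)) {
      Tmat[, , 1 + i] <- pen$Linv[[penalized[i]]]
      tindex[1 + penalized[i]] <- i
    }
  }
  list(Tmat = Tmat, tindex = tindex, penalized = penalized, locked = locked)
}

#' Fit the penalized model at fixed (lambda, alpha)
#'
#' Minimizes \eqn{\ell(\theta) + \lambda\sum_p\sqrt{\theta_p^T H_p \theta_p}}
#' by proximal gradient descent with backtracking, iterating
#' \eqn{\eta^{(s)} \leftarrow \mathrm{prox}_{t_s}[\eta^{(s-1)} -
#' t_s\nabla\ell(\eta^{(s-1)})]} until the relative objective change falls
#' below `config$tol`. Groups whose design block is identically zero
#' (monomorphic SNPs) and covariates excluded by infinite adaptive weights
#' are held at exactly zero.
#'
#' @param dataset a `region_dataset`.
#' @param design the matching `design_matrices`.
#' @param lambda penalty level (defaults to the one stored in the penalty).
#' @param init optional initial `coefficient_set` or theta matrix (zero
#'   initialization when NULL).
#' @param config a [solver_config()].
#' @param keep_trace record the per-iteration penalized objective.
#' @return a `fit_result`: `coefs` (a `coefficient_set`), `eta`, `selected`
#'   (covariates with nonzero group norm), `objective`, `objective_trace`,
#'   `lambda`, `alpha`, `weights`, `converged`, `n_iter`.
#' @export
fit_penalized <- function(dataset, design, lambda = NULL, init = NULL,
                          config = solver_config(), keep_trace = TRUE) {
  pen <- design$penalty
  if (is.null(lambda)) lambda <- pen$lambda
  grp <- solver_groups(design)
  K <- design$K
  P <- design$P
  if (is.null(init)) {
    eta0 <- matrix(0, K, P + 1)
  } else {
    theta0 <- if (inherits(init, "coefficient_set")) init$theta else init
    if (!is.matrix(theta0) || any(dim(theta0) != c(P + 1, K))) {
      stop("init has dimensions ", paste(dim(theta0), collapse = "x"),
           " but (P+1) x K = ", P + 1, "x", K, " is required")
    }
    eta0 <- t(theta_to_eta(theta0, pen))
    eta0[, 1 + grp$locked] <- 0
  }
  res <- pgd_fit_cpp(
    design$B, design$Zaug, as.integer(dataset$records$sample_idx) - 1L,
    as.numeric(dataset$records$Y), as.numeric(dataset$records$X),
    grp$Tmat, as.integer(grp$tindex), as.integer(grp$penalized),
    as.integer(grp$locked), eta0, lambda,
    config$t_init, config$shrink, config$tol, config$max_iter, keep_trace,
    config$reset_step
  )
  eta <- t(res$eta)                                # (P+1) x K
  theta <- eta_to_theta(eta, pen)
  theta[1 + grp$locked, ] <- 0
  selected <- which(vapply(seq_len(P), function(p) {
    sqrt(sum(eta[p + 1, ]^2)) > 0
  }, logical(1)))
  structure(
    list(coefs = coefficient_set(theta, design$basis, pen), eta = eta,
         selected = selected, objective = res$objective,
         objective_trace = res$trace, lambda = lambda, alpha = pen$alpha,
         weights = list(w1 = pen$w1, w2 = pen$w2),
         converged = res$converged, n_iter = res$n_iter),
    class = "fit_result"
  )
}

#' Unpenalized intercept-only spline fit
#'
#' Fits the binomial varying-intercept model
#' \eqn{\mathrm{logit}(\pi_{ij}) = \beta_0(t_{ij})} by iteratively
#' reweighted least squares (with the step-halving safeguard of
#' [stats::glm.fit()]), leaving every SNP row at zero.
#'
#' @param dataset a `region_dataset`.
#' @param basis a `spline_basis`.
#' @return a `coefficient_set` with nonzero intercept row only.
#' @export
fit_intercept_only <- function(dataset, basis) {
  B <- evaluate_basis(basis, dataset$records$position)
  y <- dataset$records$Y / dataset$records$X
  fit <- suppressWarnings(stats::glm.fit(
    x = B, y = y, weights = dataset$records$X,
    family = stats::binomial(), control = stats::glm.control(maxit = 100)
  ))
  if (!fit$converged) stop("intercept-only IRLS did not converge in 100 iterations")
  theta <- matrix(0, dataset$P + 1, basis$K)
  theta[1, ] <- fit$coefficients
  coefficient_set(theta, basis)
}

#' Analytic upper end of the regularization path
#'
#' The smallest \eqn{\lambda} at which every penalized group is exactly zero
#' follows from the KKT conditions at the intercept-only fit:
#' \deqn{\lambda_{\max} = \max_p \sqrt{b_p^T H_p^{-1} b_p}, \quad
#' b_p = 2 X_p^T (Y - \Lambda_X \pi_0),}
#' with \eqn{\pi_0} the intercept-only fitted probabilities. Groups with an
#' adaptive (per-covariate) penalty use their own \eqn{H_p}; excluded and
#' zero-block groups are skipped.
#'
#' @param dataset a `region_dataset`.
#' @param design the matching `design_matrices`.
#' @param intercept_fit a `coefficient_set` from [fit_intercept_only()]
#'   (computed on the fly when NULL).
#' @return nonnegative scalar; also carries the per-group KKT norms as
#'   attribute `"group_norms"`.
#' @export
compute_lambda_max <- function(dataset, design, intercept_fit = NULL) {
  pen <- design$penalty
  if (is.null(intercept_fit)) {
    intercept_fit <- fit_intercept_only(dataset, design$basis)
  }
  pi0 <- plogis(linear_predictor(intercept_fit$theta, design))
  resid <- dataset$records$Y - dataset$records$X * pi0
  S <- rowsum(design$B * resid, design$sample_idx, reorder = FALSE)
  Sfull <- matrix(0, dataset$N, design$K)
  Sfull[as.integer(rownames(S)), ] <- S
  bmat <- 2 * t(dataset$Z) %*% Sfull                   # P x K
  norms <- numeric(dataset$P)
  skip <- union(pen$excluded, design$zero_block)
  for (p in seq_len(dataset$P)) {
    if (p %in% skip) next
    # b' H^{-1} b = ||L^{-T} b||^2, L upper triangular with H = L'L
    v <- forwardsolve(t(penalty_L(pen, p)), bmat[p, ])
    norms[p] <- sqrt(sum(v^2))
  }
  structure(max(0, norms), group_norms = norms)
}

#' Default lower-end fraction of the lambda path
#'
#' `0.01` in the under-determined regime (`M < (P+1)K`), `0.001` otherwise.
#'
#' @param M total observation count.
#' @param P number of covariates.
#' @param K basis dimension.
#' @export
default_path_tau <- function(M, P, K) if (M < (P + 1) * K) 0.01 else 0.001

#' Warm-started regularization path
#'
#' Fits the model along `L` log-spaced penalty levels decreasing from
#' \eqn{\lambda_{\max}} to \eqn{\tau\lambda_{\max}}, initializing each fit at
#' the previous solution (warm start). The path starts at the intercept-only
#' fit (SNP rows zero), where the KKT conditions at \eqn{\lambda_{\max}}
#' keep every penalized group exactly zero, so the first fit selects no
#' covariates by construction.
#'
#' @param dataset a `region_dataset`.
#' @param design the matching `design_matrices`.
#' @param config a [solver_config()].
#' @param L path length (default 100).
#' @param tau lower end as a fraction of `lambda_max`; defaults per
#'   [default_path_tau()].
#' @param lambda_max precomputed value (from [compute_lambda_max()]); when
#'   NULL it is computed from this dataset.
#' @param intercept_fit optional precomputed [fit_intercept_only()] result,
#'   used to anchor the path start.
#' @param keep_fits return the full `fit_result` list (otherwise only
#'   coefficients and selections are retained).
#' @return a `path_result`: `lambda` (decreasing), `fits`, `tau`, `L`,
#'   `lambda_max`.
#' @export
solve_path <- function(dataset, design, config = solver_config(), L = 100L,
                       tau = NULL, lambda_max = NULL, intercept_fit = NULL,
                       keep_fits = TRUE) {
  if (L < 2) stop("path length L must be at least 2")
  if (is.null(tau)) tau <- default_path_tau(dataset$M, dataset$P, design$K)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (is.null(intercept_fit)) {
    intercept_fit <- fit_intercept_only(dataset, design$basis)
  }
  if (is.null(lambda_max)) {
    lambda_max <- compute_lambda_max(dataset, design, intercept_fit)
  }
  lambda_max <- as.numeric(lambda_max)
  if (lambda_max <= 0) {
    stop("lambda_max is zero (no informative penalized group); nothing to path over")
  }
  lambdas <- exp(seq(log(lambda_max), log(tau * lambda_max), length.out = L))
  fits <- vector("list", L)
  pen <- design$penalty
  # At lambda_max the intercept-only fit satisfies the KKT conditions with
  # every penalized group exactly zero; record it directly rather than
  # resolving a boundary case numerically.
  obj1 <- neg2_loglik(intercept_fit$theta, design, dataset)
  fits[[1]] <- structure(
    list(coefs = coefficient_set(intercept_fit$theta, design$basis, pen),
         eta = theta_to_eta(intercept_fit$theta, pen), selected = integer(0),
         objective = obj1, objective_trace = obj1, lambda = lambdas[1],
         alpha = pen$alpha, weights = list(w1 = pen$w1, w2 = pen$w2),
         converged = TRUE, n_iter = 0L),
    class = "fit_result"
  )
  init <- intercept_fit
  for (l in seq_len(L)[-1]) {
    fit <- tryCatch(
      fit_penalized(dataset, design, lambda = lambdas[l], init = init,
                    config = config, keep_trace = FALSE),
      error = function(e) {
        stop("path fit failed at lambda index ", l, " (lambda = ",
             format(lambdas[l]), "): ", conditionMessage(e), call. = FALSE)
      }
    )
    init <- fit$coefs
    fits[[l]] <- fit
  }
  structure(list(lambda = lambdas, fits = fits, tau = tau, L = L,
                 lambda_max = lambda_max),
            class = "path_result")
}
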