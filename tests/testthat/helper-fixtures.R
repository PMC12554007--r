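# Shared fixtures and independent oracles.

# Small simulated region for solver/likelihood tests.
tiny_region <- function(N = 12, P = 3, P_true = 2, n_cpgs = 25, seed = 11,
                        effect_scale = 1.2, rho = 0, depth_mean = 30) {
  scen <- sim_scenario(N = N, P = P, P_true = P_true, rho = rho,
                       n_cpgs = n_cpgs,
                       shapes = c("bimodal", "linear", "quadratic_like"),
                       effect_scale = effect_scale, depth_mean = depth_mean,
                       seed = seed)
  generate_scenario(scen)
}

# Basis + penalty + design bundle for a region dataset.
build_setup <- function(region, K = 6, alpha = 0.5, identity = FALSE,
                        w1 = 1, w2 = 1) {
  ds <- region$dataset
  basis <- build_basis(ds$records$position, K)
  mats <- penalty_matrices(basis, ds$M)
  pen <- compose_penalty(mats, alpha, 0, ds$P, w1 = w1, w2 = w2,
                         identity = identity)
  design <- suppressMessages(assemble_design(ds, basis, pen))
  list(ds = ds, basis = basis, mats = mats, pen = pen, design = design)
}

# Materialized M x (P+1)K design (optionally reparameterized blocks).
full_design_matrix <- function(design, transformed = TRUE) {
  do.call(cbind, lapply(0:design$P, function(p) {
    design_block(design, p, transformed = transformed)
  }))
}

# Record-level -2 loglik from an eta vector, written independently of the
# package's evaluation path (explicit loop over records).
oracle_neg2ll_eta <- function(eta_vec, Xt, y, x, clip = 1e-10) {
  lp <- as.vector(Xt %*% eta_vec)
  val <- 0
  for (r in seq_along(lp)) {
    p <- 1 / (1 + exp(-lp[r]))
    p <- min(max(p, clip), 1 - clip)
    val <- val - 2 * (y[r] * log(p) + (x[r] - y[r]) * log(1 - p))
  }
  val
}

# Generic convex-solver oracle for the penalized problem in eta coordinates:
# minimizes ell(eta) + lambda * sum_p sqrt(eta_p'eta_p + eps) by BFGS from
# several starts and returns the best (unsmoothed) penalized objective.
convex_oracle_objective <- function(design, ds, lambda, eps = 1e-12,
                                    n_restarts = 2, seed = 99) {
  Xt <- full_design_matrix(design, transformed = TRUE)
  y <- ds$records$Y
  x <- ds$records$X
  K <- design$K
  P <- design$P
  groups <- lapply(seq_len(P), function(p) p * K + seq_len(K))
  fn <- function(v) {
    lp <- as.vector(Xt %*% v)
    p <- pmin(pmax(plogis(lp), 1e-10), 1 - 1e-10)
    ll <- -2 * sum(y * log(p) + (x - y) * log(1 - p))
    pen <- sum(vapply(groups, function(g) sqrt(sum(v[g]^2) + eps), numeric(1)))
    ll + lambda * pen
  }
  gr <- function(v) {
    p <- plogis(as.vector(Xt %*% v))
    g <- -2 * as.vector(crossprod(Xt, y - x * p))
    for (gi in groups) {
      g[gi] <- g[gi] + lambda * v[gi] / sqrt(sum(v[gi]^2) + eps)
    }
    g
  }
  d <- (P + 1) * K
  starts <- list(rep(0, d))
  set.seed(seed)
  for (i in seq_len(n_restarts)) starts <- c(starts, list(rnorm(d, sd = 0.1)))
  best <- Inf
  best_par <- NULL
  for (s in starts) {
    o <- stats::optim(s, fn, gr, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    if (o$value < best) { best <- o$value; best_par <- o$par }
  }
  # evaluate the exact (unsmoothed) objective at the smoothed optimum
  lp <- as.vector(Xt %*% best_par)
  p <- pmin(pmax(plogis(lp), 1e-10), 1 - 1e-10)
  ll <- -2 * sum(y * log(p) + (x - y) * log(1 - p))
  pen <- sum(vapply(groups, function(g) sqrt(sum(best_par[g]^2)), numeric(1)))
  list(objective = ll + lambda * pen, par = best_par)
}

# Penalized objective of a fit_result, recomputed from its theta.
fit_objective <- function(fit, design, ds) {
  pen <- design$penalty
  neg2_loglik(fit$coefs, design, ds) +
    penalty_value(modifyList(pen, list(lambda = fit$lambda)), fit$coefs$theta)
}

# Evaluate a basis on the rescaled [0, 1] axis.
ncs_eval_scaled_test <- function(basis, u, deriv = 0) {
  evaluate_basis(basis, basis$raw_range[1] + u * diff(basis$raw_range),
                 deriv = deriv)
}

# Dense trapezoid-rule integral of f over [0, 1].
trapz01 <- function(fvals, grid) {
  sum(diff(grid) * (fvals[-1] + fvals[-length(fvals)]) / 2)
}
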