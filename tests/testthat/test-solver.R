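# Proximal operator, line search, penalized fits, lambda_max and paths.

test_that("group proximal operator matches its closed form", {
  u <- cbind(c(3, 1), c(2, 0), c(0.5, 0.5))   # K=2, intercept + 2 groups
  out <- prox_group(u, threshold = 1)
  expect_equal(out[, 1], c(3, 1))             # intercept untouched
  expect_equal(out[, 2], c(1, 0))             # (1 - 1/2) * (2, 0)
  expect_equal(out[, 3], c(0, 0))             # norm <= threshold -> zero
  expect_error(prox_group(u, -0.1), "negative")
  # numeric minimizer oracle on a 2-group toy: argmin 1/(2t)||u-e||^2 + lam*sum||e_p||
  t <- 0.7; lam <- 0.9
  obj <- function(v) {
    e <- matrix(v, 2, 3)  # tiny smoothing so BFGS can reach the kink at zero
    sum((u - e)^2) / (2 * t) +
      lam * (sqrt(sum(e[, 2]^2) + 1e-18) + sqrt(sum(e[, 3]^2) + 1e-18))
  }
  gr <- function(v) {
    e <- matrix(v, 2, 3)
    g <- (e - u) / t
    g[, 2] <- g[, 2] + lam * e[, 2] / sqrt(sum(e[, 2]^2) + 1e-18)
    g[, 3] <- g[, 3] + lam * e[, 3] / sqrt(sum(e[, 3]^2) + 1e-18)
    as.vector(g)
  }
  best <- NULL
  for (s in list(as.vector(u), as.vector(u) / 2, as.vector(u) / 10)) {
    o <- optim(s, obj, gr, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-16))
    if (is.null(best) || o$value < best$value) best <- o
  }
  num <- best$par
  expect_lt(max(abs(as.vector(prox_group(u, t * lam)) - num)), 1e-6)
})

test_that("backtracking accepts steps satisfying the majorization condition", {
  # 1-d quadratic surrogate with curvature c: any t <= 1/c accepted at once
  cc <- 4
  objective <- function(eta) 0.5 * cc * sum(eta^2)
  gradient <- function(eta) cc * eta
  eta <- matrix(c(2, 0), 1, 2)  # 1 intercept + 1 group, K = 1
  st <- backtracking_step(eta, solver_config(t_init = 1 / cc, shrink = 0.5),
                          objective, gradient, lambda = 0.1)
  expect_equal(st$t, 1 / cc)
  # fixed point: zero gradient and zero groups -> eta unchanged, first t kept
  st0 <- backtracking_step(matrix(0, 1, 2), solver_config(),
                           function(e) 0, function(e) matrix(0, 1, 2),
                           lambda = 1)
  expect_equal(st0$eta, matrix(0, 1, 2))
  expect_equal(st0$t, 1)
  # on a real instance the accepted step satisfies the printed inequality
  region <- tiny_region(N = 8, P = 2, n_cpgs = 12, seed = 3)
  stp <- build_setup(region, K = 4, alpha = 0.5)
  Xt <- full_design_matrix(stp$design, transformed = TRUE)
  y <- stp$ds$records$Y; x <- stp$ds$records$X
  obj <- function(eta) oracle_neg2ll_eta(as.vector(t(eta)), Xt, y, x)
  grad <- function(eta) {
    p <- plogis(as.vector(Xt %*% as.vector(t(eta))))
    matrix(-2 * as.vector(crossprod(Xt, y - x * p)), nrow(eta), ncol(eta),
           byrow = TRUE)
  }
  set.seed(4)
  eta <- matrix(rnorm(3 * 4, sd = 0.2), 4, 3)   # K x (P+1)
  lam <- 50
  res <- backtracking_step(eta, solver_config(), function(e) obj(t(e)),
                           function(e) t(grad(t(e))), lambda = lam)
  G <- res$G
  lhs <- obj(t(eta - res$t * G))
  rhs <- obj(t(eta)) - res$t * sum(t(grad(t(eta))) * G) + res$t / 2 * sum(G^2)
  expect_lte(lhs, rhs + 1e-8 * abs(rhs))
})

test_that("penalized fit matches a generic convex solver on a tiny instance", {
  region <- tiny_region(N = 10, P = 2, n_cpgs = 14, seed = 7)
  st <- build_setup(region, K = 4, alpha = 0.5)
  lmax <- as.numeric(compute_lambda_max(region$dataset, st$design))
  lam <- lmax / 10
  fit <- fit_penalized(region$dataset, st$design, lambda = lam,
                       config = solver_config(tol = 1e-10))
  expect_true(fit$converged)
  oracle <- convex_oracle_objective(st$design, region$dataset, lam)
  expect_equal(fit_objective(fit, st$design, region$dataset),
               oracle$objective, tolerance = 1e-4)
  # objective trace is monotone nonincreasing
  expect_true(all(diff(fit$objective_trace) <= 1e-9 *
                    (abs(fit$objective_trace[-length(fit$objective_trace)]) + 1)))
})

test_that("lambda = 0 recovers the unpenalized MLE of a small identifiable model", {
  region <- tiny_region(N = 30, P = 1, P_true = 1, n_cpgs = 12, seed = 19,
                        depth_mean = 60)
  st <- build_setup(region, K = 4, alpha = 0)
  fit <- fit_penalized(region$dataset, st$design, lambda = 0,
                       config = solver_config(tol = 1e-12, max_iter = 20000))
  # reference: BFGS quasi-Newton on the same smooth objective
  Xt <- full_design_matrix(st$design, transformed = FALSE)
  y <- region$dataset$records$Y; x <- region$dataset$records$X
  fn <- function(v) {
    p <- pmin(pmax(plogis(as.vector(Xt %*% v)), 1e-10), 1 - 1e-10)
    -2 * sum(y * log(p) + (x - y) * log(1 - p))
  }
  gr <- function(v) {
    p <- plogis(as.vector(Xt %*% v))
    -2 * as.vector(crossprod(Xt, y - x * p))
  }
  ref <- optim(rep(0, 2 * 4), fn, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(fit$objective, ref$value, tolerance = 1e-5)
})

test_that("intercept-only fit is deterministic and matches a reference optimizer", {
  region <- tiny_region(N = 15, P = 2, n_cpgs = 12, seed = 23)
  basis <- build_basis(region$dataset$records$position, 5)
  f1 <- fit_intercept_only(region$dataset, basis)
  f2 <- fit_intercept_only(region$dataset, basis)
  expect_identical(f1$theta, f2$theta)
  expect_true(all(f1$theta[-1, ] == 0))
  # reference optimizer route on the intercept block only
  B <- evaluate_basis(basis, region$dataset$records$position)
  y <- region$dataset$records$Y; x <- region$dataset$records$X
  fn <- function(v) {
    p <- pmin(pmax(plogis(as.vector(B %*% v)), 1e-10), 1 - 1e-10)
    -2 * sum(y * log(p) + (x - y) * log(1 - p))
  }
  ref <- optim(rep(0, 5), fn, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  p_ref <- plogis(as.vector(B %*% ref$par))
  p_fit <- plogis(as.vector(B %*% f1$theta[1, ]))
  expect_lt(max(abs(p_ref - p_fit)), 1e-5)
  # symmetric null: Y/X = 0.5 everywhere gives a flat zero intercept
  Z <- matrix(1, 2, 1, dimnames = list(c("s1", "s2"), NULL))
  pos <- seq(10, 100, by = 10)
  dsn <- region_dataset(rep(c("s1", "s2"), each = 10), rep(pos, 2),
                        rep(2, 20), rep(4, 20), Z)
  bn <- build_basis(pos, 4)
  fn0 <- fit_intercept_only(dsn, bn)
  expect_lt(max(abs(fn0$theta[1, ] %*% t(evaluate_basis(bn, pos)))), 1e-4)
})

test_that("lambda_max brackets the selection boundary (KKT)", {
  region <- tiny_region(N = 25, P = 3, P_true = 2, n_cpgs = 20, seed = 29,
                        effect_scale = 1.5)
  st <- build_setup(region, K = 5, alpha = 0.5)
  lmax <- as.numeric(compute_lambda_max(region$dataset, st$design))
  expect_gt(lmax, 0)
  cfg <- solver_config(tol = 1e-10)
  above <- fit_penalized(region$dataset, st$design, lambda = 1.001 * lmax,
                         config = cfg)
  expect_length(above$selected, 0)
  below <- fit_penalized(region$dataset, st$design, lambda = 0.95 * lmax,
                         config = cfg)
  expect_gte(length(below$selected), 1)
  # at lambda above lambda_max the intercept agrees with the intercept-only
  # fit in function values
  icept <- fit_intercept_only(region$dataset, st$basis)
  grid <- seq(min(region$positions), max(region$positions), length.out = 60)
  c1 <- coefficient_functions(above$coefs, st$basis, grid)[1, ]
  c0 <- coefficient_functions(icept, st$basis, grid)[1, ]
  expect_lt(max(abs(c1 - c0)), 1e-4)
  # H = identity: lambda_max = max_p ||b_p||
  stI <- build_setup(region, K = 5, identity = TRUE)
  lmaxI <- compute_lambda_max(region$dataset, stI$design, icept)
  pi0 <- predict_pi(icept, region$dataset, st$basis)
  norms <- sapply(1:3, function(p) {
    Xp <- design_block(stI$design, p)
    sqrt(sum((2 * crossprod(Xp, region$dataset$records$Y -
                              region$dataset$records$X * pi0))^2))
  })
  expect_equal(as.numeric(lmaxI), max(norms), tolerance = 1e-8)
  # all-zero genotypes give lambda_max = 0
  Z0 <- matrix(0, region$dataset$N, 2,
               dimnames = list(region$dataset$sample_ids, NULL))
  ds0 <- region_dataset(
    region$dataset$sample_ids[region$dataset$records$sample_idx],
    region$dataset$records$position, region$dataset$records$Y,
    region$dataset$records$X, Z0
  )
  pen0 <- compose_penalty(st$mats, 0.5, 0, 2)
  des0 <- suppressMessages(assemble_design(ds0, st$basis, pen0))
  expect_equal(as.numeric(compute_lambda_max(ds0, des0)), 0)
})

test_that("KKT conditions hold at convergence", {
  region <- tiny_region(N = 20, P = 3, P_true = 2, n_cpgs = 16, seed = 37)
  st <- build_setup(region, K = 4, alpha = 0.3)
  lmax <- as.numeric(compute_lambda_max(region$dataset, st$design))
  lam <- lmax / 4
  fit <- fit_penalized(region$dataset, st$design, lambda = lam,
                       config = solver_config(tol = 1e-12, max_iter = 20000))
  ge <- vc_gradient(fit$coefs, st$design, region$dataset,
                    space = "reparameterized")
  eta <- theta_to_eta(fit$coefs$theta, st$pen)
  for (p in 1:3) {
    gn <- sqrt(sum(ge[p + 1, ]^2))
    if (sqrt(sum(eta[p + 1, ]^2)) == 0) {
      expect_lte(gn, lam * (1 + 1e-3))   # subgradient condition at zero
    } else {
      resid <- ge[p + 1, ] + lam * eta[p + 1, ] / sqrt(sum(eta[p + 1, ]^2))
      expect_lte(sqrt(sum(resid^2)), 1e-3 * lam)
    }
  }
})

test_that("special-case penalties match the convex oracle (SSP0, gLASSO)", {
  region <- tiny_region(N = 10, P = 2, n_cpgs = 14, seed = 43)
  for (setup in list(build_setup(region, K = 4, alpha = 0),
                     build_setup(region, K = 4, identity = TRUE))) {
    lmax <- as.numeric(compute_lambda_max(region$dataset, setup$design))
    lam <- lmax / 5
    fit <- fit_penalized(region$dataset, setup$design, lambda = lam,
                         config = solver_config(tol = 1e-10))
    oracle <- convex_oracle_objective(setup$design, region$dataset, lam)
    expect_equal(fit_objective(fit, setup$design, region$dataset),
                 oracle$objective, tolerance = 1e-4)
  }
})

test_that("warm-started paths are log-spaced, start empty, and match cold fits", {
  region <- tiny_region(N = 15, P = 3, P_true = 2, n_cpgs = 16, seed = 47)
  st <- build_setup(region, K = 4, alpha = 0.5)
  path <- solve_path(region$dataset, st$design, L = 12, tau = 0.05,
                     config = solver_config(tol = 1e-9))
  expect_length(path$fits[[1]]$selected, 0)
  expect_true(all(diff(path$lambda) < 0))
  ratios <- diff(log(path$lambda))
  expect_lt(max(abs(ratios - ratios[1])), 1e-12)
  expect_equal(path$lambda[1], path$lambda_max)
  expect_equal(path$lambda[12], 0.05 * path$lambda_max)
  # warm vs cold at a mid-path lambda
  l <- 7
  cold <- fit_penalized(region$dataset, st$design, lambda = path$lambda[l],
                        config = solver_config(tol = 1e-10))
  warm_obj <- fit_objective(path$fits[[l]], st$design, region$dataset)
  cold_obj <- fit_objective(cold, st$design, region$dataset)
  expect_equal(warm_obj, cold_obj, tolerance = 1e-6)
  # group norms evolve continuously along the path
  norms <- sapply(path$fits, function(f) {
    sqrt(colSums(matrix(f$eta[-1, ], nrow = st$basis$K, byrow = TRUE)^2))
  })
  expect_lt(max(abs(diff(t(norms)))), 1.5 * max(norms))
  # default tau rule
  expect_equal(default_path_tau(30, 3, 10), 0.01)   # M < (P+1)K
  expect_equal(default_path_tau(1000, 3, 10), 0.001)
})

test_that("monomorphic SNPs stay locked at zero along fits", {
  region <- tiny_region(N = 10, P = 3, n_cpgs = 12, seed = 53)
  ds <- region$dataset
  ds$Z[, 2] <- 0
  ds2 <- region_dataset(ds$sample_ids[ds$records$sample_idx],
                        ds$records$position, ds$records$Y, ds$records$X, ds$Z)
  basis <- build_basis(ds2$records$position, 4)
  pen <- compose_penalty(penalty_matrices(basis, ds2$M), 0.5, 0, 3)
  design <- suppressMessages(assemble_design(ds2, basis, pen))
  fit <- fit_penalized(ds2, design, lambda = 1e-4 *
                         as.numeric(compute_lambda_max(ds2, design)))
  expect_false(2 %in% fit$selected)
  expect_true(all(fit$coefs$theta[3, ] == 0))
})
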