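# Region data, design assembly and the binomial likelihood.

test_that("dataset construction enforces count invariants", {
  Z <- matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(
    region_dataset(c("a", "b"), c(10, 20), c(3, 1), c(2, 5), Z),
    "meth_reads > total_reads"
  )
  expect_error(
    region_dataset(c("a", "b"), c(10, 20), c(0, 1), c(0, 5), Z),
    "total_reads = 0"
  )
  expect_error(
    region_dataset(c("a", "c"), c(10, 20), c(0, 1), c(1, 5), Z),
    "without a genotype row"
  )
  ds <- region_dataset(c("a", "b", "a"), c(10, 20, 30), c(0, 1, 2),
                       c(1, 5, 4), Z)
  expect_equal(ds$M, 3L)
  expect_equal(ds$N, 2L)
})

test_that("design blocks follow the b_k(t) * Z structure", {
  Z <- matrix(c(0, 1, 2, 0, 1, 1), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("snpA", "snpB")))
  pos <- c(10, 20, 30, 40, 50)
  sid <- rep(c("s1", "s2", "s3"), times = c(2, 2, 1))
  ds <- region_dataset(sid, pos, c(1, 0, 2, 3, 1), c(2, 1, 4, 5, 3), Z)
  basis <- build_basis(pos, 4)
  pen <- compose_penalty(penalty_matrices(basis, ds$M), 0.4, 0, 2)
  design <- assemble_design(ds, basis, pen)
  B <- evaluate_basis(basis, pos)
  expect_equal(design_block(design, 0), B)              # intercept: Z == 1
  expect_equal(design_block(design, 1), B * Z[ds$records$sample_idx, 1])
  # reconstruction: transformed block times L gives the original
  X1 <- design_block(design, 1)
  X1t <- design_block(design, 1, transformed = TRUE)
  expect_lt(max(abs(X1t %*% penalty_L(pen, 1) - X1)), 1e-10)
})

test_that("all-zero genotype column yields an inert zero block with a message", {
  Z <- matrix(c(0, 0, 0, 1, 2, 0), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), NULL))
  ds <- region_dataset(rep(c("s1", "s2", "s3"), each = 4),
                       rep(c(5, 10, 15, 20), 3), rep(1, 12), rep(2, 12), Z)
  basis <- build_basis(c(5, 10, 15, 20), 4)
  pen <- compose_penalty(penalty_matrices(basis, ds$M), 0.4, 0, 2)
  expect_message(design <- assemble_design(ds, basis, pen), "constant zero")
  expect_true(all(design_block(design, 1) == 0))
})

test_that("neg2_loglik matches closed forms and an independent oracle", {
  Z <- matrix(0.5, 1, 1, dimnames = list("s1", NULL))
  ds <- region_dataset(rep("s1", 4), c(1, 4, 7, 9), c(1, 0, 1, 1),
                       c(2, 1, 1, 2), Z)
  basis <- build_basis(c(1, 4, 7, 9), 4)
  pen <- compose_penalty(penalty_matrices(basis, ds$M), 0, 0, 1)
  design <- assemble_design(ds, basis, pen)
  theta0 <- matrix(0, 2, 4)
  # one record with Y=1, X=2 at pi = 0.5 contributes -2*2*log(0.5)
  ds1 <- region_dataset("s1", 4, 1, 2, Z)
  d1 <- assemble_design(ds1, basis, pen)
  expect_equal(neg2_loglik(theta0, d1, ds1), 2.772589, tolerance = 1e-6)
  expect_error(neg2_loglik(theta0 * NA, d1, ds1), "non-finite")

  # clipping keeps the value finite at extreme coefficients
  theta_big <- matrix(40, 2, 4)
  ds0 <- region_dataset("s1", 4, 0, 5, Z)
  expect_true(is.finite(neg2_loglik(theta_big, d1, ds0)))

  # random instance vs record-level oracle through materialized design
  region <- tiny_region(N = 10, P = 2, n_cpgs = 12, seed = 5)
  st <- build_setup(region, K = 5, alpha = 0.3)
  set.seed(8)
  theta <- matrix(rnorm(3 * 5, sd = 0.4), 3, 5)
  eta <- theta_to_eta(theta, st$pen)
  Xt <- full_design_matrix(st$design, transformed = TRUE)
  oracle <- oracle_neg2ll_eta(as.vector(t(eta)), Xt,
                              st$ds$records$Y, st$ds$records$X)
  expect_equal(neg2_loglik(theta, st$design, st$ds), oracle,
               tolerance = 1e-9)
})

test_that("objective is invariant under the eta reparameterization and convex", {
  region <- tiny_region(N = 8, P = 3, n_cpgs = 15, seed = 21)
  st <- build_setup(region, K = 5, alpha = 0.7)
  set.seed(13)
  for (i in 1:5) {
    th1 <- matrix(rnorm(4 * 5, sd = 0.5), 4, 5)
    th2 <- matrix(rnorm(4 * 5, sd = 0.5), 4, 5)
    eta1 <- theta_to_eta(th1, st$pen)
    back <- eta_to_theta(eta1, st$pen)
    expect_lt(max(abs(back - th1)), 1e-10)
    cc <- runif(1)
    v1 <- neg2_loglik(th1, st$design, st$ds)
    v2 <- neg2_loglik(th2, st$design, st$ds)
    vm <- neg2_loglik(cc * th1 + (1 - cc) * th2, st$design, st$ds)
    expect_lte(vm, cc * v1 + (1 - cc) * v2 + 1e-8)
  }
})

test_that("gradient matches finite differences and the chain rule", {
  region <- tiny_region(N = 6, P = 2, n_cpgs = 10, seed = 31)
  st <- build_setup(region, K = 4, alpha = 0.5)
  set.seed(17)
  theta <- matrix(rnorm(3 * 4, sd = 0.3), 3, 4)
  g <- vc_gradient(theta, st$design, st$ds)
  h <- 1e-5
  for (idx in list(c(1, 1), c(2, 3), c(3, 4))) {
    tp <- theta; tm <- theta
    tp[idx[1], idx[2]] <- tp[idx[1], idx[2]] + h
    tm[idx[1], idx[2]] <- tm[idx[1], idx[2]] - h
    fd <- (neg2_loglik(tp, st$design, st$ds) -
             neg2_loglik(tm, st$design, st$ds)) / (2 * h)
    expect_equal(g[idx[1], idx[2]], fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
  # reparameterized gradient = L^{-T} block gradient
  ge <- vc_gradient(theta, st$design, st$ds, space = "reparameterized")
  for (p in 1:2) {
    Linv <- penalty_Linv(st$pen, p)
    expect_lt(max(abs(ge[p + 1, ] - drop(t(Linv) %*% g[p + 1, ]))), 1e-9)
  }
  # zero gradient at the saturated point (pi = Y/X) on a 1-sample design
  Z <- matrix(1, 1, 1, dimnames = list("s1", NULL))
  pos <- c(2, 5, 8, 11)
  dsat <- region_dataset(rep("s1", 4), pos, c(1, 2, 1, 3), c(2, 4, 2, 6), Z)
  bsat <- build_basis(pos, 4)
  psat <- compose_penalty(penalty_matrices(bsat, 4), 0, 0, 1)
  desat <- assemble_design(dsat, bsat, psat)
  # logit(Y/X) = 0 everywhere here, so theta = 0 saturates the model
  gsat <- vc_gradient(matrix(0, 2, 4), desat, dsat)
  expect_lt(max(abs(gsat)), 1e-8)
})

test_that("predict_pi and coefficient_functions follow the model equation", {
  region <- tiny_region(N = 5, P = 2, n_cpgs = 9, seed = 41)
  st <- build_setup(region, K = 4)
  theta0 <- matrix(0, 3, 4)
  expect_equal(predict_pi(theta0, st$ds, st$basis),
               rep(0.5, st$ds$M))
  theta_i <- theta0
  theta_i[1, ] <- linear_coefficients(st$basis, log(3), 0)
  expect_equal(predict_pi(theta_i, st$ds, st$basis),
               rep(0.75, st$ds$M), tolerance = 1e-8)
  # doubling dosages adds the SNP contribution to the logit again
  set.seed(6)
  theta <- matrix(rnorm(3 * 4, sd = 0.3), 3, 4)
  ds2 <- region$dataset
  ds2$Z <- pmin(ds2$Z * 2, 2) # keep within [0,2]: use half dosages instead
  lp1 <- qlogis(predict_pi(theta, st$ds, st$basis))
  B <- evaluate_basis(st$basis, st$ds$records$position)
  snp_contrib <- rowSums((st$ds$Z[st$ds$records$sample_idx, , drop = FALSE] %*%
                            theta[-1, , drop = FALSE]) * B)
  lp0 <- drop(B %*% theta[1, ])
  expect_equal(lp1, unname(lp0 + snp_contrib), tolerance = 1e-8)

  grid <- seq(min(region$positions), max(region$positions), length.out = 50)
  cf <- coefficient_functions(theta, st$basis, grid)
  expect_equal(dim(cf), c(3L, 50L))
  theta_z <- theta; theta_z[2, ] <- 0
  expect_true(all(coefficient_functions(theta_z, st$basis, grid)[2, ] == 0))
  # curve interpolates its knot values
  knots_raw <- st$basis$raw_range[1] + st$basis$knots * diff(st$basis$raw_range)
  expect_equal(drop(coefficient_functions(theta, st$basis, knots_raw)[1, ]),
               drop(theta[1, ] %*% t(evaluate_basis(st$basis, knots_raw))),
               tolerance = 1e-10)
  # continuity on a dense grid
  dense <- seq(min(grid), max(grid), length.out = 2000)
  cfd <- coefficient_functions(theta, st$basis, dense)
  expect_lt(max(abs(diff(cfd[2, ]))), 0.05)
})
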