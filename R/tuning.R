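# Cross-validation over the (lambda, alpha) grid and selection rules.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Assign samples to cross-validation folds
#'
#' Individuals (not records) are randomly partitioned into folds of sizes
#' differing by at most one, so that all records of a sample share one fold:
#' records within an individual share the genotype and are dependent, and a
#' record-level split would leak information between training and
#' validation.
#'
#' @param dataset a `region_dataset` (or an integer N).
#' @param n_folds number of folds, between 2 and N.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return integer vector of fold labels (1..n_folds), one per sample.
#' @export
make_folds <- function(dataset, n_folds, seed) {
  N <- if (inherits(dataset, "region_dataset")) dataset$N else as.integer(dataset)
  if (n_folds < 2) stop("need at least 2 folds")
  if (n_folds > N) stop("n_folds = ", n_folds, " exceeds the number of samples (", N, ")")
  folds <- integer(N)
  with_local_seed(seed, {
    folds[sample.int(N)] <- rep(seq_len(n_folds), length.out = N)
  })
  folds
}

#' Cross-validate the penalized fit over a (lambda, alpha) grid
#'
#' For each `alpha`, a lambda path is anchored at the full-data
#' \eqn{\lambda_{\max}} (shared across folds for comparability) and fitted on
#' each training split with warm starts. Validation error is the mean
#' deviance \eqn{(1/M_o)\sum_{ij\in V_o} -2[Y\log\hat\pi +
#' (X-Y)\log(1-\hat\pi)]} at the validation records; the grid mean is the
#' average over folds and its SE the across-fold standard deviation divided
#' by \eqn{\sqrt{n_{folds}}}.
#'
#' A SNP that is monomorphic (all-zero column) within a training split is
#' held at zero for that fold's fits.
#'
#' @param dataset a `region_dataset`.
#' @param basis a `spline_basis` built on the dataset positions.
#' @param alpha_grid numeric vector of mixing weights in `[0, 1)`. The grid
#'   used in the simulation study of record is
#'   `c(0, 0.1, ..., 0.9, 0.95, 0.99)` (see [default_alpha_grid()]).
#' @param folds fold labels from [make_folds()]; built from `n_folds` and
#'   `seed` when NULL.
#' @param n_folds,seed used when `folds` is NULL.
#' @param L lambda path length.
#' @param tau path lower-end fraction (defaults per [default_path_tau()]).
#' @param config a [solver_config()].
#' @param identity use the identity penalty matrix (group LASSO variant).
#' @param w1,w2 optional adaptive weights (length P; Inf excludes).
#' @return a `cv_result` with `alpha_grid`, `lambda` (n_alpha x L matrix),
#'   `mean` and `se` (same shape), `chosen_min`, `chosen_1se`, `folds`,
#'   `seed`.
#' @export
cross_validate <- function(dataset, basis, alpha_grid = default_alpha_grid(),
                           folds = NULL, n_folds = 5L, seed = 1L,
                           L = 100L, tau = NULL, config = solver_config(),
                           identity = FALSE, w1 = 1, w2 = 1) {
  if (any(alpha_grid < 0 | alpha_grid >= 1)) stop("alpha grid must lie in [0, 1)")
  if (is.null(folds)) folds <- make_folds(dataset, n_folds, seed)
  n_folds <- max(folds)
  if (is.null(tau)) tau <- default_path_tau(dataset$M, dataset$P, basis$K)
  mats <- penalty_matrices(basis, dataset$M)
  n_alpha <- length(alpha_grid)
  lambda_grid <- matrix(NA_real_, n_alpha, L)
  cv_mean <- cv_se <- matrix(NA_real_, n_alpha, L)
  fold_dev <- array(NA_real_, dim = c(n_alpha, L, n_folds))
  intercept_full <- fit_intercept_only(dataset, basis)

  # Per-fold structures do not depend on alpha: build them once.
  pen0 <- compose_penalty(mats, alpha_grid[1], 0, dataset$P,
                          w1 = w1, w2 = w2, identity = identity)
  design_full <- assemble_design(dataset, basis, pen0)
  fold_pre <- lapply(seq_len(n_folds), function(o) {
    train <- which(folds != o)
    val <- which(folds == o)
    ds_train <- subset_samples(dataset, train)
    design_train <- suppressMessages(assemble_design(ds_train, basis, pen0))
    dropped <- setdiff(design_train$zero_block, design_full$zero_block)
    if (length(dropped)) {
      message("fold ", o, ": SNP(s) monomorphic in training split, ",
              "unselectable there: ",
              paste(dataset$snp_ids[dropped], collapse = ", "))
    }
    val_keep <- dataset$records$sample_idx %in% val
    list(ds_train = ds_train, design_train = design_train,
         icept = fit_intercept_only(ds_train, basis),
         B_val = design_full$B[val_keep, , drop = FALSE],
         sidx_val = match(dataset$records$sample_idx[val_keep], val),
         Zaug_val = cbind(1, dataset$Z[val, , drop = FALSE]),
         Y_val = as.numeric(dataset$records$Y[val_keep]),
         X_val = as.numeric(dataset$records$X[val_keep]))
  })

  for (a in seq_len(n_alpha)) {
    pen <- compose_penalty(mats, alpha_grid[a], 0, dataset$P,
                           w1 = w1, w2 = w2, identity = identity)
    design_full$penalty <- pen
    lmax <- as.numeric(compute_lambda_max(dataset, design_full, intercept_full))
    if (lmax <= 0) stop("lambda_max is zero; cross-validation is undefined")
    lambda_grid[a, ] <- exp(seq(log(lmax), log(tau * lmax), length.out = L))
    for (o in seq_len(n_folds)) {
      fp <- fold_pre[[o]]
      design_train <- fp$design_train
      design_train$penalty <- pen
      thetas <- array(0, dim = c(basis$K, dataset$P + 1, L))
      init <- fp$icept
      for (l in seq_len(L)) {
        fit <- fit_penalized(fp$ds_train, design_train,
                             lambda = lambda_grid[a, l],
                             init = init, config = config, keep_trace = FALSE)
        init <- fit$coefs
        thetas[, , l] <- t(fit$coefs$theta)
      }
      fold_dev[a, , o] <- mean_deviance_cpp(
        fp$B_val, fp$Zaug_val, as.integer(fp$sidx_val) - 1L,
        fp$Y_val, fp$X_val, thetas
      )
    }
    cv_mean[a, ] <- apply(fold_dev[a, , , drop = FALSE], 2, mean)
    cv_se[a, ] <- apply(fold_dev[a, , , drop = FALSE], 2, stats::sd) / sqrt(n_folds)
  }

  res <- structure(
    list(alpha_grid = alpha_grid, lambda = lambda_grid, mean = cv_mean,
         se = cv_se, fold_deviance = fold_dev, folds = folds, seed = seed,
         n_folds = n_folds, L = L, tau = tau, identity = identity,
         weights = list(w1 = w1, w2 = w2)),
    class = "cv_result"
  )
  res$chosen_min <- select_lambda(res, "min")
  res$chosen_1se <- select_lambda(res, "one_se")
  res
}

#' Alpha grid of the simulation study
#'
#' Twelve mixing values spanning no smoothness control to near-pure
#' curvature penalization.
#'
#' @export
default_alpha_grid <- function() c(seq(0, 0.9, by = 0.1), 0.95, 0.99)

#' Select tuning parameters from a cross-validation surface
#'
#' The `"min"` rule returns the global minimizer of the mean CV error. The
#' `"one_se"` rule stays at the minimizing `alpha` and takes the largest
#' `lambda` whose mean error is within one standard error of the minimum,
#' favoring parsimony.
#'
#' @param cv a `cv_result`.
#' @param rule `"min"` or `"one_se"`.
#' @return list with `alpha`, `lambda`, `a_idx`, `l_idx`.
#' @export
select_lambda <- function(cv, rule = c("min", "one_se")) {
  rule <- match.arg(rule)
  if (length(cv$mean) == 0 || all(!is.finite(cv$mean))) stop("empty CV grid")
  idx <- which(cv$mean == min(cv$mean), arr.ind = TRUE)
  # ties: prefer the largest lambda (smallest path index), then smallest alpha
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  a_min <- idx[1, 1]
  l_min <- idx[1, 2]
  if (rule == "min") {
    return(list(alpha = cv$alpha_grid[a_min], lambda = cv$lambda[a_min, l_min],
                a_idx = a_min, l_idx = l_min))
  }
  thr <- cv$mean[a_min, l_min] + cv$se[a_min, l_min]
  l_1se <- min(which(cv$mean[a_min, ] <= thr))   # lambda decreasing in index
  list(alpha = cv$alpha_grid[a_min], lambda = cv$lambda[a_min, l_1se],
       a_idx = a_min, l_idx = l_1se)
}

#' Basis dimension rule for real regions
#'
#' SNP effect functions use \eqn{K = \min(10, \lfloor n_{CpG}/10 \rfloor)}
#' basis functions, clamped below at 4 (the natural cubic minimum); the
#' intercept function always uses K = 10.
#'
#' @param n_cpgs number of CpG sites in the region.
#' @return list with `K_snp` and `K_intercept`.
#' @export
basis_dimension_rule <- function(n_cpgs) {
  if (n_cpgs < 1) stop("n_cpgs must be positive")
  list(K_snp = max(4L, min(10L, as.integer(floor(n_cpgs / 10)))),
       K_intercept = 10L)
}

#' Fit the model with cross-validated tuning
#'
#' End-to-end regional fit: build the penalty, cross-validate over the
#' `(lambda, alpha)` grid, then refit on the full data at the selected pair.
#' `variant` chooses between the full sparsity-smoothness penalty (`"ssp"`),
#' its no-smoothness special case (`"ssp0"`, fixes `alpha = 0`) and the
#' group LASSO (`"glasso"`, identity penalty matrix).
#'
#' @inheritParams cross_validate
#' @param rule selection rule passed to [select_lambda()].
#' @param variant `"ssp"`, `"ssp0"` or `"glasso"`.
#' @return list with `fit` (a `fit_result` at the selected tuning), `cv`
#'   (the `cv_result`), `basis`, `rule`, `variant`, `selected` snp ids.
#' @export
ssp_cv <- function(dataset, basis, alpha_grid = default_alpha_grid(),
                   folds = NULL, n_folds = 5L, seed = 1L, L = 100L,
                   tau = NULL, config = solver_config(),
                   rule = c("one_se", "min"), variant = c("ssp", "ssp0", "glasso"),
                   w1 = 1, w2 = 1) {
  rule <- match.arg(rule)
  variant <- match.arg(variant)
  identity <- variant == "glasso"
  if (variant %in% c("ssp0", "glasso")) alpha_grid <- 0
  cv <- cross_validate(dataset, basis, alpha_grid, folds = folds,
                       n_folds = n_folds, seed = seed, L = L, tau = tau,
                       config = config, identity = identity, w1 = w1, w2 = w2)
  sel <- select_lambda(cv, ifelse(rule == "one_se", "one_se", "min"))
  mats <- penalty_matrices(basis, dataset$M)
  pen <- compose_penalty(mats, sel$alpha, sel$lambda, dataset$P,
                         w1 = w1, w2 = w2, identity = identity)
  design <- suppressMessages(assemble_design(dataset, basis, pen))
  # refit along the path down to the selected lambda for a warm final fit
  lambdas <- cv$lambda[sel$a_idx, seq_len(sel$l_idx)]
  init <- fit_intercept_only(dataset, basis)
  for (l in seq_along(lambdas)) {
    fit <- fit_penalized(dataset, design, lambda = lambdas[l], init = init,
                         config = config, keep_trace = FALSE)
    init <- fit$coefs
  }
  list(fit = fit, cv = cv, basis = basis, rule = rule, variant = variant,
       selected = dataset$snp_ids[fit$selected])
}
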