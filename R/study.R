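# Monte-Carlo simulation-study driver: replicate regions, fit each method
# variant with cross-validated tuning, and aggregate the evaluation measures.

#' Run a replicated simulation study
#'
#' For each of `R` replicate regions (shared CpG grid and true curves, fresh
#' genotypes and read counts), fits the requested method variants with
#' cross-validated tuning and records fitted coefficient curves, selected
#' sets and held-out prediction measures. Variants: `"ssp"` (full penalty,
#' tuned over `alpha_grid`; also records the 1-SE-rule fit), `"ssp0"`
#' (`alpha = 0`), `"glasso"` (identity penalty matrix) and `"adaptive"`
#' (adaptive weights from the run's ordinary min-rule fit, then the full
#' pipeline again).
#'
#' @param scenario a `sim_scenario`; its `seed` anchors the study and its
#'   `position_seed` is fixed internally so all runs share one region.
#' @param R number of simulation runs.
#' @param K basis dimension used for fitting (the generating model does not
#'   depend on it).
#' @param variants subset of `c("ssp", "ssp0", "glasso", "adaptive")`.
#' @param alpha_grid mixing grid for the `ssp`/`adaptive` variants.
#' @param L,n_folds,tau tuning-path and cross-validation settings.
#' @param config a [solver_config()].
#' @param with_test also simulate a same-size held-out region per run and
#'   record prediction metrics.
#' @return a `sim_study` list: `scenario`, `positions`, `true_beta`, `R`,
#'   and `runs[[variant]]` holding per-run `curves` (min rule),
#'   `selected_min`, `selected_1se`, `prediction` lists.
#' @export
run_simulation_study <- function(scenario, R = 20L, K = 10L,
                                 variants = c("ssp", "ssp0", "glasso"),
                                 alpha_grid = c(0, 0.5, 0.99), L = 30L,
                                 n_folds = 5L, tau = NULL,
                                 config = solver_config(tol = 1e-6,
                                                        max_iter = 2000L),
                                 with_test = TRUE) {
  variants <- match.arg(variants, c("ssp", "ssp0", "glasso", "adaptive"),
                        several.ok = TRUE)
  base_seed <- scenario$seed
  runs <- lapply(variants, function(v) list())
  names(runs) <- variants
  positions <- NULL
  true_beta <- NULL

  for (r in seq_len(R)) {
    scen_r <- scenario
    scen_r$seed <- base_seed + 101L * r
    scen_r$position_seed <- base_seed
    region <- generate_scenario(scen_r)
    if (is.null(positions)) {
      positions <- region$positions
      true_beta <- region$true_beta
    }
    ds <- region$dataset
    basis <- build_basis(ds$records$position, K)
    mats <- penalty_matrices(basis, ds$M)
    folds <- make_folds(ds, n_folds, seed = scen_r$seed + 7L)
    test_region <- NULL
    if (with_test) {
      scen_t <- scen_r
      scen_t$seed <- scen_r$seed + 53L
      scen_t$position_seed <- base_seed
      test_region <- generate_scenario(scen_t)
    }

    fit_variant <- function(identity, grid, w1 = 1, w2 = 1) {
      cv <- suppressMessages(cross_validate(
        ds, basis, alpha_grid = grid, folds = folds, L = L, tau = tau,
        config = config, identity = identity, w1 = w1, w2 = w2,
        seed = scen_r$seed + 7L
      ))
      refit <- function(sel) {
        pen <- compose_penalty(mats, sel$alpha, sel$lambda, ds$P,
                               w1 = w1, w2 = w2, identity = identity)
        design <- suppressMessages(assemble_design(ds, basis, pen))
        lambdas <- cv$lambda[sel$a_idx, seq_len(sel$l_idx)]
        init <- fit_intercept_only(ds, basis)
        for (lam in lambdas) {
          fit <- fit_penalized(ds, design, lambda = lam, init = init,
                               config = config, keep_trace = FALSE)
          init <- fit$coefs
        }
        fit
      }
      fit_min <- refit(cv$chosen_min)
      fit_1se <- refit(cv$chosen_1se)
      list(cv = cv, fit_min = fit_min, fit_1se = fit_1se)
    }

    record <- function(res) {
      pred <- NULL
      if (!is.null(test_region)) {
        pp <- predict_pi(res$fit_min$coefs, test_region$dataset, basis)
        pred <- suppressWarnings(prediction_metrics(
          pp, test_region$dataset, test_region$true_pi))
      }
      list(
        curves = coefficient_functions(res$fit_min$coefs, basis, positions),
        selected_min = res$fit_min$selected,
        selected_1se = res$fit_1se$selected,
        alpha_min = res$fit_min$alpha,
        prediction = pred
      )
    }

    ssp_res <- NULL
    for (v in variants) {
      res <- switch(v,
        ssp = {
          ssp_res <- fit_variant(FALSE, alpha_grid)
          ssp_res
        },
        ssp0 = fit_variant(FALSE, 0),
        glasso = fit_variant(TRUE, 0),
        adaptive = {
          if (is.null(ssp_res)) ssp_res <- fit_variant(FALSE, alpha_grid)
          w <- adaptive_weights(ssp_res$fit_min, mats)
          if (length(w$excluded) == ds$P) {
            # nothing survives the initial fit: adaptive model is intercept-only
            icept <- fit_intercept_only(ds, basis)
            f0 <- structure(list(coefs = icept, selected = integer(0),
                                 alpha = NA_real_, lambda = NA_real_),
                            class = "fit_result")
            list(fit_min = f0, fit_1se = f0, cv = NULL)
          } else {
            fit_variant(FALSE, alpha_grid, w1 = w$w1, w2 = w$w2)
          }
        })
      runs[[v]][[r]] <- record(res)
    }
  }

  structure(
    list(scenario = scenario, positions = positions, true_beta = true_beta,
         R = R, K = K, alpha_grid = alpha_grid, L = L, n_folds = n_folds,
         runs = runs),
    class = "sim_study"
  )
}

#' Aggregate a simulation study into the standard report
#'
#' @param study a `sim_study`.
#' @param variant which variant to summarize.
#' @param rule `"min"` or `"one_se"` (selection counts; estimation curves
#'   are recorded under the min rule).
#' @return list with `estimation` (per-SNP-covariate data.frame from
#'   [estimation_report()], totals over the P varying coefficients),
#'   `tp`, `fp` (per-run vectors), `mean_tp`, `mean_fp`,
#'   `deviance_error` (per-run), `mean_deviance_error`.
#' @export
summarize_study <- function(study, variant = "ssp",
                            rule = c("min", "one_se")) {
  rule <- match.arg(rule)
  runs <- study$runs[[variant]]
  if (is.null(runs)) stop("variant not present in study: ", variant)
  P <- nrow(study$true_beta) - 1
  G <- length(study$positions)
  est_by_cov <- lapply(seq_len(P), function(p) {
    do.call(rbind, lapply(runs, function(rr) rr$curves[p + 1, ]))
  })
  names(est_by_cov) <- rownames(study$true_beta)[-1]
  est <- estimation_report(est_by_cov, study$true_beta[-1, , drop = FALSE])
  sel_field <- if (rule == "min") "selected_min" else "selected_1se"
  sm <- lapply(runs, function(rr) {
    selection_metrics(rr[[sel_field]], seq_len(study$scenario$P_true), P)
  })
  tp <- vapply(sm, `[[`, numeric(1), "tp")
  fp <- vapply(sm, `[[`, numeric(1), "fp")
  dev <- vapply(runs, function(rr) {
    if (is.null(rr$prediction)) NA_real_ else rr$prediction$deviance_error
  }, numeric(1))
  list(estimation = est, tp = tp, fp = fp,
       mean_tp = mean(tp), mean_fp = mean(fp),
       deviance_error = dev, mean_deviance_error = mean(dev),
       imse_total = est$imse[est$covariate == "total"],
       ibias2_total = est$ibias2[est$covariate == "total"],
       ivar_total = est$ivar[est$covariate == "total"])
}
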