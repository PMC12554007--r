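# Evaluation measures for the simulation study: estimation (IBIAS^2, IVAR,
# IMSE), prediction (deviance error, arcsine RMSE, correlations) and
# selection (TP/FP).

#' Integrated estimation-accuracy measures over simulation runs
#'
#' Given per-run estimated curves and the true curve on a common position
#' grid, computes the Monte-Carlo integrated squared bias, variance and mean
#' squared error as plain sums over the grid:
#' \deqn{\mathrm{IBIAS}^2 = \sum_t [\hat E(t) - \beta(t)]^2,\quad
#'   \mathrm{IVAR} = \sum_t \frac1R \sum_r [\hat\beta^{(r)}(t) - \hat E(t)]^2,}
#' \deqn{\mathrm{IMSE} = \sum_t \frac1R \sum_r [\hat\beta^{(r)}(t) - \beta(t)]^2,}
#' with \eqn{\hat E(t)} the across-run mean. The identity
#' IMSE = IBIAS^2 + IVAR holds exactly.
#'
#' @param estimates R x G matrix (rows = simulation runs) or a list of
#'   length-G vectors.
#' @param truth length-G true curve on the same grid.
#' @return list with `ibias2`, `ivar`, `imse`, `R`.
#' @export
estimation_metrics <- function(estimates, truth) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  if (ncol(estimates) != length(truth)) {
    stop("estimate grid (", ncol(estimates), ") does not match truth grid (",
         length(truth), ")")
  }
  R <- nrow(estimates)
  Ehat <- colMeans(estimates)
  ibias2 <- sum((Ehat - truth)^2)
  ivar <- sum(colMeans((estimates - rep(Ehat, each = R))^2))
  imse <- sum(colMeans((estimates - rep(truth, each = R))^2))
  list(ibias2 = ibias2, ivar = ivar, imse = imse, R = R)
}

#' Estimation report across covariates
#'
#' @param estimates_by_cov list over covariates, each an R x G matrix of
#'   per-run estimated curves.
#' @param truth_by_cov list (or matrix with covariates in rows) of true
#'   curves on the same grid.
#' @return data.frame with one row per covariate plus a `total` row.
#' @export
estimation_report <- function(estimates_by_cov, truth_by_cov) {
  if (is.matrix(truth_by_cov)) {
    truth_by_cov <- lapply(seq_len(nrow(truth_by_cov)),
                           function(i) truth_by_cov[i, ])
  }
  stopifnot(length(estimates_by_cov) == length(truth_by_cov))
  rows <- mapply(function(est, tr) {
    m <- estimation_metrics(est, tr)
    c(ibias2 = m$ibias2, ivar = m$ivar, imse = m$imse)
  }, estimates_by_cov, truth_by_cov)
  out <- as.data.frame(t(rows))
  out$covariate <- if (!is.null(names(estimates_by_cov)))
    names(estimates_by_cov) else paste0("beta", seq_along(estimates_by_cov))
  total <- data.frame(ibias2 = sum(out$ibias2), ivar = sum(out$ivar),
                      imse = sum(out$imse), covariate = "total")
  rbind(out[, c("covariate", "ibias2", "ivar", "imse")],
        total[, c("covariate", "ibias2", "ivar", "imse")])
}

#' Arcsine variance-stabilizing transform for binomial proportions
#'
#' \eqn{h(\pi) = \arcsin(2\pi - 1)}; \eqn{h(0.5) = 0}, \eqn{h(1) = \pi/2}.
#'
#' @param p proportions in `[0, 1]`.
#' @export
arcsine_transform <- function(p) asin(pmin(pmax(2 * p - 1, -1), 1))

#' Prediction-accuracy measures on held-out records
#'
#' Computes the mean deviance error relative to the true probabilities,
#' \eqn{(1/M)\sum [\ell(\hat\pi; Y, X) - \ell(\pi; Y, X)]} with
#' \eqn{\ell(\pi;Y,X) = -2[Y\log\pi + (X-Y)\log(1-\pi)]}; the RMSE of the
#' arcsine-transformed predictions against observed proportions; and Pearson
#' correlations between predicted and observed proportions on the raw
#' (`cor_raw`) and transformed (`cor_trans`) scales. Zero-variance
#' correlation cases return `NA` with a warning.
#'
#' @param pred_pi predicted probabilities, one per record.
#' @param dataset the `region_dataset` holding the observed counts.
#' @param true_pi true probabilities (simulation truth); when NULL the
#'   deviance error is omitted.
#' @return list with `deviance_error`, `rmse`, `cor_raw`, `cor_trans`.
#' @export
prediction_metrics <- function(pred_pi, dataset, true_pi = NULL) {
  y <- dataset$records$Y
  x <- dataset$records$X
  stopifnot(length(pred_pi) == length(y))
  clip <- function(p) pmin(pmax(p, PI_CLIP), 1 - PI_CLIP)
  ell <- function(p) -2 * (y * log(clip(p)) + (x - y) * log(1 - clip(p)))
  dev_err <- if (is.null(true_pi)) NA_real_ else
    mean(ell(pred_pi) - ell(true_pi))
  obs <- y / x
  h_pred <- arcsine_transform(pred_pi)
  h_obs <- arcsine_transform(obs)
  rmse <- sqrt(mean((h_pred - h_obs)^2))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance input; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  list(deviance_error = dev_err, rmse = rmse,
       cor_raw = safe_cor(pred_pi, obs),
       cor_trans = safe_cor(h_pred, h_obs))
}

#' Variable-selection counts
#'
#' @param selected integer indices of selected covariates (subset of 1..P).
#' @param causal integer indices of truly causal covariates.
#' @param P total number of candidate covariates.
#' @return list with `tp` and `fp`.
#' @export
selection_metrics <- function(selected, causal, P) {
  selected <- as.integer(selected)
  causal <- as.integer(causal)
  if (length(selected) && (min(selected) < 1 || max(selected) > P)) {
    stop("selected indices outside 1..P")
  }
  if (length(causal) && (min(causal) < 1 || max(causal) > P)) {
    stop("causal indices outside 1..P")
  }
  list(tp = length(intersect(selected, causal)),
       fp = length(setdiff(selected, causal)))
}
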