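# Synthetic regional methylation data with block-correlated genotypes.
#
# The generator reproduces the structure of the simulation study the package
# is benchmarked on: a 123-CpG region, SNPs in linkage-disequilibrium blocks
# of 20 with exchangeable within-block correlation rho, a small causal set
# with smooth (or deliberately nonsmooth) position-varying effects on the
# logit scale, and binomial read counts with Poisson read depth.

#' Simulation scenario description
#'
#' @param N number of samples.
#' @param P number of candidate SNPs.
#' @param P_true number of causal SNPs (placed in the first LD block, so
#'   they share pairwise correlation `rho` when `rho > 0`; requires
#'   `P_true <= block_size`).
#' @param rho within-block genotype correlation in `[0, 1)` (study settings:
#'   0, 0.3, 0.7).
#' @param block_size SNPs per LD block (default 20).
#' @param n_cpgs number of CpG sites in the region (default 123).
#' @param shapes character vector of causal effect shapes, recycled to
#'   `P_true`; names from `constant`, `linear`, `quadratic_like`, `bimodal`,
#'   `nonsmooth_sharp`.
#' @param effect_scale peak magnitude of the causal curves on the logit
#'   scale.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param depth_mean mean read depth (Poisson, truncated to >= 1).
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param position_seed optional separate seed for the CpG position draw, so
#'   that replicate runs (different `seed`) can share one region grid.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(N = 50L, P = 100L, P_true = 5L, rho = 0,
                         block_size = 20L, n_cpgs = 123L,
                         shapes = c("bimodal", "quadratic_like", "linear",
                                    "constant", "bimodal"),
                         effect_scale = 1.2, maf = 0.3, depth_mean = 30,
                         seed = 1L, position_seed = NULL) {
  if (P_true > P) stop("P_true must not exceed P")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (rho > 0 && P_true > block_size) {
    stop("causal SNPs are co-located in one LD block; P_true must be <= block_size")
  }
  structure(
    list(N = as.integer(N), P = as.integer(P), P_true = as.integer(P_true),
         rho = rho, block_size = as.integer(block_size),
         n_cpgs = as.integer(n_cpgs),
         shapes = rep_len(shapes, P_true), effect_scale = effect_scale,
         maf = maf, depth_mean = depth_mean, seed = as.integer(seed),
         position_seed = if (is.null(position_seed)) NULL else
           as.integer(position_seed)),
    class = "sim_scenario"
  )
}

#' Preset scenarios of the simulation study
#'
#' `example1` uses smooth causal effects of varied shapes spanning the full
#' region; `example2` uses piecewise-constant effects with sharp interior
#' transitions, to probe robustness when the smoothness assumption is
#' violated.
#'
#' @param name `"example1"` or `"example2"`.
#' @param ... overrides passed to [sim_scenario()].
#' @export
scenario_preset <- function(name = c("example1", "example2"), ...) {
  name <- match.arg(name)
  shapes <- if (name == "example1") {
    c("bimodal", "quadratic_like", "linear", "constant", "bimodal")
  } else {
    "nonsmooth_sharp"
  }
  args <- list(...)
  if (is.null(args$shapes)) args$shapes <- shapes
  do.call(sim_scenario, args)
}

#' Simulate LD-blocked genotype dosages
#'
#' Each of the two haplotypes per sample is generated from a latent Gaussian
#' vector with block-diagonal exchangeable correlation `rho`, thresholded at
#' the `1 - maf` quantile to an allele indicator; the dosage is the sum of
#' the two independent haplotypes, giving values in `{0, 1, 2}` with
#' marginal allele frequency `maf` and tunable within-block LD.
#'
#' @param N,P samples and SNPs.
#' @param rho within-block latent correlation in `[0, 1)`.
#' @param block_size SNPs per block.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param seed integer seed.
#' @return N x P integer dosage matrix.
#' @export
simulate_genotypes <- function(N, P, rho, block_size = 20L, maf = 0.3,
                               seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  thr <- stats::qnorm(1 - maf)
  blocks <- split(seq_len(P), ceiling(seq_len(P) / block_size))
  with_local_seed(seed, {
    hap <- function() {
      Z <- matrix(stats::rnorm(N * P), N, P)
      if (rho > 0) {
        for (b in blocks) {
          shared <- stats::rnorm(N)
          Z[, b] <- sqrt(rho) * shared + sqrt(1 - rho) * Z[, b]
        }
      }
      (Z > thr) + 0L
    }
    G <- hap() + hap()
    storage.mode(G) <- "integer"
    colnames(G) <- paste0("snp", seq_len(P))
    G
  })
}

# Closed-form effect shapes on the rescaled axis t in [0, 1], peak height 1.
effect_shape <- function(name, t) {
  switch(name,
    constant = rep(1, length(t)),
    linear = 2 * t - 1,
    quadratic_like = 4 * t * (1 - t),
    bimodal = {
      g <- exp(-(t - 0.3)^2 / (2 * 0.1^2)) + 0.9 * exp(-(t - 0.75)^2 / (2 * 0.08^2))
      g / max(g)
    },
    nonsmooth_sharp = as.numeric(t >= 0.2 & t < 0.4) - as.numeric(t >= 0.6 & t < 0.7),
    stop("unknown effect shape: ", name)
  )
}

#' True coefficient functions for a scenario
#'
#' Returns the (P+1) x n_cpgs matrix of true curves on the CpG grid: row 1
#' is the intercept \eqn{\beta_0(t) = 0.3 + 0.8\sin(2\pi t)}, rows 2..
#' (P_true+1) the causal effect curves (shape library scaled to
#' `effect_scale`, with alternating sign so that positive and negative
#' effects both occur), remaining rows identically zero.
#'
#' @param scenario a `sim_scenario`.
#' @param t rescaled positions in `[0, 1]` (defaults to an equispaced grid
#'   of `n_cpgs` points).
#' @export
true_effect_functions <- function(scenario, t = NULL) {
  if (is.null(t)) t <- seq(0, 1, length.out = scenario$n_cpgs)
  curves <- matrix(0, scenario$P + 1, length(t))
  curves[1, ] <- 0.3 + 0.8 * sin(2 * pi * t)
  sgn <- rep(c(1, -1), length.out = scenario$P_true)
  for (p in seq_len(scenario$P_true)) {
    curves[p + 1, ] <- sgn[p] * scenario$effect_scale *
      effect_shape(scenario$shapes[p], t)
  }
  rownames(curves) <- c("intercept", paste0("snp", seq_len(scenario$P)))
  curves
}

#' Simulate methylation read counts given genotypes and true curves
#'
#' Read depths are Poisson(`depth_mean`) truncated to at least one read;
#' methylated counts are Binomial(X, pi) with
#' \eqn{\mathrm{logit}(\pi_{ij}) = \beta_0(t_j) + \sum_p \beta_p(t_j)Z_{ip}}.
#'
#' @param Z N x P dosage matrix.
#' @param curves (P+1) x n_cpgs matrix of true coefficient curves.
#' @param positions bp coordinates of the CpG sites (length n_cpgs).
#' @param depth_mean mean read depth.
#' @param seed integer seed.
#' @return list with `dataset` (a `region_dataset`), `true_pi` (per-record)
#'   and `depths`.
#' @export
simulate_methylation <- function(Z, curves, positions, depth_mean, seed = 1L) {
  N <- nrow(Z)
  G <- length(positions)
  stopifnot(ncol(curves) == G, nrow(curves) == ncol(Z) + 1)
  logit <- cbind(1, Z) %*% curves                  # N x G
  pi <- stats::plogis(logit)
  with_local_seed(seed, {
    # zero-truncated Poisson depths via inverse-cdf sampling
    u <- stats::runif(N * G, min = stats::ppois(0, depth_mean), max = 1)
    X <- stats::qpois(u, depth_mean)
    Y <- stats::rbinom(N * G, size = X, prob = as.vector(pi))
    dataset <- region_dataset(
      sample_id = rep(paste0("s", seq_len(N)), times = G),
      position = rep(positions, each = N),
      meth_reads = Y, total_reads = X,
      genotypes = `rownames<-`(Z, paste0("s", seq_len(N)))
    )
    list(dataset = dataset, true_pi = as.vector(pi), depths = X)
  })
}

#' Generate a complete simulated region
#'
#' Composes [simulate_genotypes()], [true_effect_functions()] and
#' [simulate_methylation()] deterministically from the scenario seed. CpG
#' positions are drawn once from the seed as irregular gaps (1 + Poisson),
#' emulating the uneven CpG spacing of real regions.
#'
#' @param scenario a `sim_scenario` (or preset from [scenario_preset()]).
#' @return a `simulated_region`: `dataset`, `true_beta` ((P+1) x n_cpgs),
#'   `true_pi`, `causal_set`, `positions`, `scenario`.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  pos_seed <- if (is.null(scenario$position_seed)) scenario$seed + 1L else
    scenario$position_seed
  positions <- with_local_seed(pos_seed, {
    10000 + cumsum(c(0, 1 + stats::rpois(scenario$n_cpgs - 1, 9)))
  })
  t <- (positions - min(positions)) / diff(range(positions))
  Z <- simulate_genotypes(scenario$N, scenario$P, scenario$rho,
                          scenario$block_size, scenario$maf,
                          seed = scenario$seed + 2L)
  curves <- true_effect_functions(scenario, t)
  sim <- simulate_methylation(Z, curves, positions, scenario$depth_mean,
                              seed = scenario$seed + 3L)
  structure(
    list(dataset = sim$dataset, true_beta = curves, true_pi = sim$true_pi,
         causal_set = seq_len(scenario$P_true), positions = positions,
         scenario = scenario),
    class = "simulated_region"
  )
}
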