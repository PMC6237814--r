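# Synthetic observables: the model's own forward map from ground-truth
# parameters to the three ratio observables, with optional multiplicative
# lognormal measurement noise, and parameter-recovery experiments built on
# it. This makes estimation and dynamics testable with no external data.

#' Ground-truth parameter set for synthetic-data generation
#'
#' @param params A \code{\link{thermoParams}} object (with \code{f},
#'   \code{g}, \code{alpha_tilde} strictly positive and \code{beta} > 0, so
#'   the implied observables are feasible for estimation).
#' @param trans A \code{\link{translationParams}} object.
#' @return A \code{ground_truth} list with the implied equilibrium C level
#'   \code{p_c_eq} (computed from the steady-state fixed point, not free).
#' @export
groundTruth <- function(params, trans = translationParams()) {
  .check_params(params)
  .check_trans(trans)
  if (params$f <= 0 || params$g <= 0 || params$alpha_tilde <= 0)
    stop("ground truth requires strictly positive f, g, alpha_tilde",
         call. = FALSE)
  p_c_eq <- steadyState(params, trans)[["p_C"]]
  structure(list(params = params, trans = trans, p_c_eq = p_c_eq),
            class = "ground_truth")
}

#' Forward map from parameters to the ratio observables
#'
#' Computes the equilibrium C level from the steady-state fixed point, then
#' evaluates the three observables the estimation consumes: the M-promoter
#' repression ratio (C-free over equilibrium activity), the C-promoter
#' initiation ratio, and the elongation-completion fraction at equilibrium.
#' Composed with \code{\link{estimateParameters}} this is the identity in
#' both directions (to solver tolerance).
#'
#' @param truth A \code{\link{groundTruth}} object.
#' @return An \code{\link{observedRatios}} object.
#' @examples
#' est <- estimateParameters(observedRatios())
#' forwardRatios(groundTruth(est$params))   # recovers the inputs
#' @export
forwardRatios <- function(truth) {
  if (!inherits(truth, "ground_truth"))
    stop("'truth' must be a ground_truth object", call. = FALSE)
  p <- truth$p_c_eq
  params <- truth$params
  observedRatios(
    r_M = activityM(params, 0) / activityM(params, p),
    r_C = initiationRateC(params, 0) / initiationRateC(params, p),
    r_block = elongationProbability(params, p))
}

#' Generate noisy replicate observables
#'
#' Each of the three ratios is multiplied by independent lognormal noise
#' with unit median (\code{meanlog = 0},
#' \code{sdlog = sqrt(log(1 + cv^2))}), modeling multiplicative
#' band-intensity quantification error; \code{cv = 0} returns exact copies.
#' The read-through fraction is clipped to (0, 1]. Draws are reproducible
#' under a fixed seed and do not disturb the caller's RNG state.
#'
#' @param truth A \code{\link{groundTruth}} object.
#' @param cv Coefficient of variation of the noise, >= 0.
#' @param n Number of replicates, >= 1.
#' @param seed Integer seed for the generator.
#' @return Data frame with columns \code{replicate}, \code{r_M},
#'   \code{r_C}, \code{r_block}.
#' @export
generateNoisyRatios <- function(truth, cv = 0.05, n = 100L, seed = 1L) {
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  base <- forwardRatios(truth)
  noise <- if (cv == 0) {
    matrix(1, nrow = n, ncol = 3)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    .with_seed(seed, matrix(stats::rlnorm(3L * n, meanlog = 0,
                                          sdlog = sdlog), ncol = 3))
  }
  out <- data.frame(
    replicate = seq_len(n),
    r_M = base$r_M * noise[, 1],
    r_C = base$r_C * noise[, 2],
    r_block = pmin(base$r_block * noise[, 3], 1))
  out
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameter-recovery experiment on noisy synthetic observables
#'
#' Generates \code{n} noisy replicates of the ground-truth observables,
#' runs \code{\link{estimateParameters}} on each feasible replicate
#' (infeasible draws, e.g. an implied read-through probability outside
#' (0, 1], are rejected and counted, not resampled), and aggregates the
#' per-parameter recovery errors against the truth.
#'
#' @inheritParams generateNoisyRatios
#' @return A \code{recovery_report} list: \code{n}, \code{cv}, \code{seed},
#'   \code{n_rejected}, \code{n_failed}, and per-parameter
#'   \code{median_rel_error} and \code{rmse} for \code{f}, \code{g},
#'   \code{alpha_tilde}, \code{beta}.
#' @examples
#' est <- estimateParameters(observedRatios())
#' recoveryExperiment(groundTruth(est$params), cv = 0.02, n = 20, seed = 7)
#' @export
recoveryExperiment <- function(truth, cv = 0.05, n = 200L, seed = 1L) {
  reps <- generateNoisyRatios(truth, cv = cv, n = n, seed = seed)
  true <- unlist(truth$params)
  pars <- c("f", "g", "alpha_tilde", "beta")
  est <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, pars))
  n_rejected <- 0L
  n_failed <- 0L
  for (i in seq_len(n)) {
    ratios <- tryCatch(
      observedRatios(reps$r_M[i], reps$r_C[i], reps$r_block[i]),
      error = function(e) NULL)
    feasible <- !is.null(ratios) &&
      ratios$r_block * ratios$r_M > 1 &&
      (ratios$r_block * ratios$r_M - 1) / (ratios$r_M - 1) <= 1
    if (!feasible) { n_rejected <- n_rejected + 1L; next }
    fit <- tryCatch(estimateParameters(ratios, truth$trans),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    est[i, ] <- unlist(fit$params)[pars]
  }
  ok <- !is.na(est[, 1])
  rel_err <- abs(sweep(est[ok, , drop = FALSE], 2, true[pars], "-")) /
    rep(abs(true[pars]), each = sum(ok))
  structure(list(
    n = n, cv = cv, seed = seed,
    n_rejected = n_rejected, n_failed = n_failed,
    median_rel_error = apply(rel_err, 2, stats::median),
    rmse = sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2,
                               true[pars], "-")^2))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: n = %d replicates, cv = %g, seed = %d\n",
              x$n, x$cv, x$seed))
  cat(sprintf("  rejected (infeasible draws): %d; solver failures: %d\n",
              x$n_rejected, x$n_failed))
  tab <- rbind(`median rel. error` = x$median_rel_error, RMSE = x$rmse)
  print(signif(tab, 4))
  invisible(x)
}
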