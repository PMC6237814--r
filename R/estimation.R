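# Estimation of the regulatory constants (f, g, alpha_tilde, beta) and the
# equilibrium C-protein level from three measured transcript-ratio
# observables. The five constraints are: the M-promoter repression ratio,
# the C-promoter activation ratio, the roadblock read-through fraction, the
# equality of M and C steady-state activities, and the protein balance at
# equilibrium. The system is exactly determined (five equations, five
# unknowns) and triangularizable, so the sequential elimination in
# seedEstimate() is an exact closed-form solution; estimateParameters()
# additionally polishes it through a damped least-squares root solve on
# transformed variables.

#' Measured ratio observables constraining the model
#'
#' Three dimensionless ratios extracted from band intensities of in vitro /
#' in vivo transcription experiments. Defaults are the measured values for
#' the Kpn2I system.
#'
#' @param r_M Fold-change of M-promoter transcript amount, absence over
#'   presence of C-protein; must exceed 1 (the promoter is repressed).
#' @param r_C Ratio of C-promoter initiation, absence over presence of
#'   C-protein; > 0 (below 1 for an activated promoter) and < \code{r_M}.
#' @param r_block Fraction of initiated C transcripts reaching full length
#'   in the presence of the roadblock; in (0, 1].
#'
#' @return An object of class \code{observed_ratios}.
#' @examples
#' observedRatios()                      # the measured Kpn2I values
#' observedRatios(50, 0.5, 0.6)
#' @export
observedRatios <- function(r_M = 86.229, r_C = 0.263, r_block = 0.44) {
  vals <- c(r_M = r_M, r_C = r_C, r_block = r_block)
  if (any(!is.finite(vals)))
    stop("observed ratios must be finite", call. = FALSE)
  if (r_M <= 1)
    stop("r_M must exceed 1 (M promoter must be repressed)", call. = FALSE)
  if (r_C <= 0)
    stop("r_C must be positive", call. = FALSE)
  if (r_M / r_C <= 1)
    stop("infeasible ratios: r_M/r_C must exceed 1", call. = FALSE)
  if (r_block <= 0 || r_block > 1)
    stop("r_block must lie in (0, 1]", call. = FALSE)
  structure(list(r_M = r_M, r_C = r_C, r_block = r_block),
            class = "observed_ratios")
}

#' Translation and degradation constants
#'
#' @param k_tilde Translations per transcript lifetime; default 3.
#' @param x Protein-to-transcript degradation-rate ratio; default 1/6
#'   (proteins degraded six times slower than transcripts).
#' @return An object of class \code{translation_params}.
#' @export
translationParams <- function(k_tilde = 3, x = 1/6) {
  if (!is.finite(k_tilde) || k_tilde <= 0 || !is.finite(x) || x <= 0)
    stop("k_tilde and x must be finite and positive", call. = FALSE)
  structure(list(k_tilde = k_tilde, x = x), class = "translation_params")
}

.check_ratios <- function(ratios) {
  if (!inherits(ratios, "observed_ratios"))
    stop("'ratios' must be an observed_ratios object", call. = FALSE)
  invisible(ratios)
}

.check_trans <- function(trans) {
  if (!inherits(trans, "translation_params"))
    stop("'trans' must be a translation_params object", call. = FALSE)
  invisible(trans)
}

.estimation_result <- function(params, p_c_eq, residual_norm, iterations) {
  structure(list(params = params, p_c_eq = p_c_eq,
                 residual_norm = residual_norm, iterations = iterations),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("Parameter estimate from ratio observables\n")
  print(x$params)
  cat(sprintf("  p_c_eq (equilibrium C level)  : %.6g\n", x$p_c_eq))
  cat(sprintf("  max |residual|                : %.3g\n", x$residual_norm))
  cat(sprintf("  solver iterations             : %d\n", x$iterations))
  invisible(x)
}

#' Closed-form sequential-elimination estimate
#'
#' Solves the five-constraint system by algebraic elimination:
#' the quotient of the two initiation-ratio constraints gives
#' \eqn{p_{eq}^4 = r_M/r_C - 1}; combining the read-through constraint with
#' the M-repression constraint gives
#' \eqn{\beta = (r_{block} r_M - 1)/(r_M - 1)}; the steady-state activity
#' equality then fixes \eqn{f/g = (r_M/r_C)\, r_{block}}, the M-repression
#' constraint becomes linear in \eqn{g}, and the protein-balance condition
#' yields \eqn{\tilde\alpha}. Because the system triangularizes, the result
#' is an exact root (up to floating point); it serves as the initializer and
#' independent cross-check for \code{\link{estimateParameters}}.
#'
#' @param ratios An \code{\link{observedRatios}} object.
#' @param trans A \code{\link{translationParams}} object.
#' @return An \code{estimation_result} (iterations = 0).
#' @examples
#' seedEstimate(observedRatios(), translationParams())
#' @export
seedEstimate <- function(ratios, trans = translationParams()) {
  .check_ratios(ratios)
  .check_trans(trans)
  r_M <- ratios$r_M; r_C <- ratios$r_C; r_block <- ratios$r_block

  u <- r_M / r_C - 1                       # p_eq^4
  p_eq <- u^0.25
  beta <- (r_block * r_M - 1) / (r_M - 1)
  if (beta <= 0)
    stop("infeasible ratios: r_block * r_M <= 1 implies beta <= 0",
         call. = FALSE)
  if (beta > 1)
    stop("infeasible ratios: implied beta exceeds 1", call. = FALSE)

  fg_ratio <- (1 + u) * r_block            # f/g from activity equality
  denom <- u - (r_M - 1) * (fg_ratio + 1)
  g <- ((r_M - 1) - u) / denom
  if (!is.finite(g) || g <= 0)
    stop("infeasible ratios: implied g is not positive", call. = FALSE)
  f <- fg_ratio * g

  Z <- 1 + f + g + (1 + g) * u
  alpha_tilde <- (trans$x / trans$k_tilde) * p_eq * Z /
    (g * (1 + u) * r_block)

  params <- thermoParams(f, g, alpha_tilde, beta)
  res <- estimationResiduals(params, p_eq, ratios, trans)
  .estimation_result(params, p_eq, max(abs(res)), 0L)
}

#' Residuals of the five estimation constraints
#'
#' Components (left-hand side minus right-hand side) of: the M-promoter
#' repression ratio, the C-promoter activation ratio, the roadblock
#' read-through fraction, the steady-state equality of M and C activities
#' (as the promoter-weight ratio \eqn{f/g}), and the equilibrium protein
#' balance \eqn{(x/\tilde k)\,p_{eq} = \tilde\varphi_C(p_{eq})}. All five
#' vanish at an exact solution.
#'
#' @param params A \code{\link{thermoParams}} object.
#' @param p_c_eq Candidate equilibrium rescaled C-protein level, > 0.
#' @param ratios An \code{\link{observedRatios}} object.
#' @param trans A \code{\link{translationParams}} object.
#' @return Named numeric vector of five residuals.
#' @export
estimationResiduals <- function(params, p_c_eq, ratios,
                                trans = translationParams()) {
  .check_params(params)
  .check_ratios(ratios)
  .check_trans(trans)
  if (!is.finite(p_c_eq) || p_c_eq <= 0)
    stop("p_c_eq must be finite and positive", call. = FALSE)
  f <- params$f; g <- params$g; beta <- params$beta
  u <- p_c_eq^4
  c(
    repression_M = activityM(params, 0) / activityM(params, p_c_eq) -
      ratios$r_M,
    activation_C = initiationRateC(params, 0) /
      initiationRateC(params, p_c_eq) - ratios$r_C,
    read_through = elongationProbability(params, p_c_eq) - ratios$r_block,
    activity_equality = f / g -
      (1 + u) * (f / (1 + g) + 1 + beta * u) / (f / (1 + g) + 1 + u),
    protein_balance = (trans$x / trans$k_tilde) * p_c_eq -
      activityC(params, p_c_eq)
  )
}

#' Estimate the regulatory constants from ratio observables
#'
#' Root-solves the five-constraint system for \eqn{(f, g, \tilde\alpha,
#' \beta, p_{eq})}, initialized from the closed-form
#' \code{\link{seedEstimate}} and polished by Levenberg--Marquardt damped
#' least squares on transformed variables (log for the positive parameters,
#' logit for \eqn{\beta}), which enforces the domain constraints without
#' explicit inequality handling. When the observables imply \eqn{\beta = 1}
#' exactly (no roadblock observed, \code{r_block = 1}), \eqn{\beta} is held
#' at 1 and the remaining four unknowns are solved.
#'
#' @inheritParams seedEstimate
#' @param tol Convergence tolerance on the maximum residual; constraints
#'   whose right-hand side exceeds 1 in magnitude (the fold-repression and
#'   promoter-weight ratios reach into the hundreds) are judged relative to
#'   that magnitude. Default 1e-10.
#' @param max_iter Maximum solver iterations; default 200.
#' @return An \code{estimation_result} with fields \code{params},
#'   \code{p_c_eq}, \code{residual_norm} and \code{iterations}.
#' @examples
#' est <- estimateParameters(observedRatios(), translationParams())
#' est$params$f
#' @export
estimateParameters <- function(ratios, trans = translationParams(),
                               tol = 1e-10, max_iter = 200L) {
  seed <- seedEstimate(ratios, trans)
  fix_beta <- ratios$r_block >= 1          # beta = 1 exactly, stay on boundary

  beta0 <- min(max(seed$params$beta, 1e-12), 1 - 1e-12)
  theta0 <- c(log(seed$params$f), log(seed$params$g),
              log(seed$params$alpha_tilde), log(seed$p_c_eq))
  if (!fix_beta) theta0 <- c(theta0, stats::qlogis(beta0))

  unpack <- function(theta) {
    beta <- if (fix_beta) 1 else stats::plogis(theta[5])
    list(params = thermoParams(exp(theta[1]), exp(theta[2]),
                               exp(theta[3]), beta),
         p = exp(theta[4]))
  }
  fn <- function(theta) {
    s <- unpack(theta)
    r <- estimationResiduals(s$params, s$p, ratios, trans)
    if (fix_beta) r[-3] else r             # read-through residual is 0 by construction
  }

  fit <- minpack.lm::nls.lm(
    par = theta0, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-15, ptol = 1e-15))
  sol <- unpack(fit$par)
  res <- estimationResiduals(sol$params, sol$p, ratios, trans)
  # constraints with right-hand sides far above 1 (the fold-repression and
  # promoter-weight ratios can reach hundreds) are judged relatively
  scale <- pmax(1, abs(c(ratios$r_M, ratios$r_C, ratios$r_block,
                         sol$params$f / sol$params$g,
                         (trans$x / trans$k_tilde) * sol$p)))
  rnorm <- max(abs(res) / scale)
  if (rnorm > tol)
    stop(sprintf(paste0("parameter estimation did not converge: max ",
                        "|residual| = %.3g (tolerance %.3g); residuals: %s"),
                 rnorm, tol,
                 paste(sprintf("%s=%.3g", names(res), res), collapse = ", ")),
         call. = FALSE)
  .estimation_result(sol$params, sol$p, rnorm, as.integer(fit$niter))
}
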