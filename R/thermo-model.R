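# Statistical-weight (Shea-Ackers) model of the shared kpn2I.M / kpn2I.C
# regulatory region. All quantities are rescaled/dimensionless; p_c is the
# rescaled C-protein monomer level and enters tetramer binding as p_c^4 with
# the composite binding constant absorbed by the rescaling.

# Above this value of p_c^4 the activities are evaluated with numerator and
# denominator divided by p_c^4, so the p_c -> Inf limits are exact.
.LARGE_PC4 <- 1e12

#' Regulatory constants of the thermodynamic promoter model
#'
#' Bundles the four dimensionless constants governing transcription of the
#' divergent \emph{kpn2I.M} / \emph{kpn2I.C} promoters: the statistical
#' weights of RNAP bound at each promoter, the rescaled promoter-escape rate,
#' and the roadblock read-through probability.
#'
#' @param f Statistical weight of RNAP bound at the M promoter
#'   (free RNAP concentration over its dissociation constant there); > 0.
#' @param g Statistical weight of RNAP bound at the C promoter(s); > 0.
#' @param alpha_tilde Rescaled rate at which RNAP leaves a promoter once
#'   bound (per unit rescaled time); > 0.
#' @param beta Probability that an elongating RNAP reads through the bound
#'   C-protein roadblock; in [0, 1].
#'
#' @return An object of class \code{thermo_params}.
#' @examples
#' thermoParams(f = 2.9, g = 0.02, alpha_tilde = 28, beta = 0.44)
#' @export
thermoParams <- function(f, g, alpha_tilde, beta) {
  vals <- c(f = f, g = g, alpha_tilde = alpha_tilde, beta = beta)
  if (any(!is.finite(vals)))
    stop("thermo parameters must be finite", call. = FALSE)
  if (f < 0 || g < 0 || alpha_tilde < 0)
    stop("f, g and alpha_tilde must be non-negative", call. = FALSE)
  if (beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]", call. = FALSE)
  structure(list(f = f, g = g, alpha_tilde = alpha_tilde, beta = beta),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Thermodynamic promoter model parameters (rescaled)\n")
  cat(sprintf("  f (RNAP weight, M promoter)   : %.6g\n", x$f))
  cat(sprintf("  g (RNAP weight, C promoters)  : %.6g\n", x$g))
  cat(sprintf("  alpha_tilde (escape rate)     : %.6g\n", x$alpha_tilde))
  cat(sprintf("  beta (roadblock read-through) : %.6g\n", x$beta))
  invisible(x)
}

.check_pc <- function(p_c) {
  if (!is.numeric(p_c) || any(!is.finite(p_c)) || any(p_c < 0))
    stop("p_c must be finite and non-negative", call. = FALSE)
  invisible(p_c)
}

.check_params <- function(params) {
  if (!inherits(params, "thermo_params"))
    stop("'params' must be a thermo_params object", call. = FALSE)
  invisible(params)
}

#' Statistical weights of the five regulatory-region configurations
#'
#' The regulatory region separating the divergent M and C promoters admits
#' five configurations: (i) empty DNA, (ii) RNAP at the M promoter, (iii)
#' RNAP at the C promoter(s), (iv) a C-protein tetramer bound to the C-box
#' (excluding RNAP from the M promoter), (v) RNAP at the C promoter(s)
#' together with the bound tetramer. Their statistical weights are
#' \eqn{(1, f, g, p_c^4, g \cdot p_c^4)}; occupancy probabilities are
#' weights over the partition sum.
#'
#' @param params A \code{\link{thermoParams}} object.
#' @param p_c Rescaled C-protein monomer level, a single value >= 0.
#'
#' @return A list with components \code{w_empty}, \code{w_RNAP_M},
#'   \code{w_RNAP_C}, \code{w_tetramer}, \code{w_RNAP_C_plus_tetramer} and
#'   the partition sum \code{Z}.
#' @examples
#' configurationWeights(thermoParams(2.9, 0.02, 28, 0.44), p_c = 1)
#' @export
configurationWeights <- function(params, p_c) {
  .check_params(params)
  .check_pc(p_c)
  stopifnot(length(p_c) == 1L)
  u <- p_c^4
  w <- list(w_empty = 1, w_RNAP_M = params$f, w_RNAP_C = params$g,
            w_tetramer = u, w_RNAP_C_plus_tetramer = params$g * u)
  w$Z <- 1 + params$f + params$g + (1 + params$g) * u
  w
}

#' Occupancy probabilities of the five configurations
#'
#' @inheritParams configurationWeights
#' @return Named numeric vector of the five occupancy probabilities
#'   (summing to 1).
#' @export
occupancyProbabilities <- function(params, p_c) {
  .check_params(params)
  .check_pc(p_c)
  stopifnot(length(p_c) == 1L)
  u <- p_c^4
  if (is.finite(u) && u <= .LARGE_PC4) {
    w <- c(1, params$f, params$g, u, params$g * u)
    p <- w / sum(w)
  } else {
    # divide weights by p_c^4 so the saturated limit is exact
    w <- c(1 / u, params$f / u, params$g / u, 1, params$g)
    w[!is.finite(w)] <- 0
    p <- w / sum(w)
  }
  stats::setNames(p, c("empty", "RNAP_M", "RNAP_C", "tetramer",
                       "RNAP_C_plus_tetramer"))
}

#' Rescaled transcription activity of the M promoter
#'
#' Under the Shea-Ackers assumption the M-promoter activity is the
#' promoter-escape rate times RNAP occupancy of the M promoter:
#' \deqn{\tilde\varphi_M(p_c) = \frac{\tilde\alpha f}{1+f+g+(1+g)p_c^4}.}
#' It is strictly decreasing in \code{p_c} and tends to 0 as
#' \code{p_c} grows (full tetramer repression).
#'
#' @inheritParams configurationWeights
#' @param p_c Rescaled C-protein level(s); vectorized.
#' @return Numeric vector of activities (per unit rescaled time).
#' @export
activityM <- function(params, p_c) {
  .check_params(params)
  .check_pc(p_c)
  u <- p_c^4
  a <- 1 + params$f + params$g
  b <- 1 + params$g
  out <- params$alpha_tilde * params$f / (a + b * u)
  big <- !is.finite(u) | u > .LARGE_PC4
  if (any(big))  # divide through by u so the large-p_c limit is exact
    out[big] <- (params$alpha_tilde * params$f / u[big]) / (a / u[big] + b)
  out
}

#' Rescaled transcript-initiation rate of the C promoter(s)
#'
#' Initiation from the C promoter(s) occurs from configurations with RNAP
#' bound there, with or without the C-protein tetramer:
#' \deqn{\tilde\alpha g (1 + p_c^4) / (1+f+g+(1+g)p_c^4).}
#' Tetramer binding indirectly activates the C promoters by displacing RNAP
#' from the overlapping M promoter.
#'
#' @inheritParams activityM
#' @return Numeric vector of initiation rates.
#' @export
initiationRateC <- function(params, p_c) {
  .check_params(params)
  .check_pc(p_c)
  u <- p_c^4
  a <- 1 + params$f + params$g
  b <- 1 + params$g
  out <- params$alpha_tilde * params$g * (1 + u) / (a + b * u)
  big <- !is.finite(u) | u > .LARGE_PC4
  if (any(big))
    out[big] <- params$alpha_tilde * params$g * (1 / u[big] + 1) /
      (a / u[big] + b)
  out
}

#' Probability that an initiated C transcript is completely elongated
#'
#' A transcript initiated at the C promoter(s) is completed if no tetramer
#' blocks the elongating RNAP, or if the RNAP reads through the roadblock
#' (probability \code{beta}):
#' \deqn{\frac{1+f+g+\beta(1+g)p_c^4}{1+f+g+(1+g)p_c^4}.}
#' Bounded below by \code{beta}, above by 1, non-increasing in \code{p_c}.
#'
#' @inheritParams activityM
#' @return Numeric vector of probabilities in [beta, 1].
#' @export
elongationProbability <- function(params, p_c) {
  .check_params(params)
  .check_pc(p_c)
  u <- p_c^4
  a <- 1 + params$f + params$g
  b <- 1 + params$g
  out <- (a + params$beta * b * u) / (a + b * u)
  big <- !is.finite(u) | u > .LARGE_PC4
  if (any(big))
    out[big] <- (a / u[big] + params$beta * b) / (a / u[big] + b)
  out
}

#' Effective rescaled transcription activity of the C promoter(s)
#'
#' Product of the initiation rate and the elongation-completion probability:
#' the rate at which full-length C transcripts are produced. With
#' \code{beta = 1} (no roadblock) it equals \code{\link{initiationRateC}}
#' exactly.
#'
#' @inheritParams activityM
#' @return Numeric vector of effective activities.
#' @export
activityC <- function(params, p_c) {
  initiationRateC(params, p_c) * elongationProbability(params, p_c)
}

#' Constitutive rescaled transcription activity of the R gene
#'
#' Transcription of \emph{kpn2I.R} is constitutive and C-independent, so its
#' activity is a constant. By the steady-state assumption its default in the
#' dynamics equals the common equilibrium activity of the M and C promoters.
#'
#' @param value Constant activity, >= 0.
#' @return The value, validated.
#' @export
activityR <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 0)
    stop("activityR requires a single finite value >= 0", call. = FALSE)
  value
}

#' Convert rescaled quantities back to absolute units
#'
#' The model works in rescaled variables: time is multiplied by the
#' transcript degradation rate \code{lambda_t}, and amounts are divided by
#' the fourth root of the composite tetramer-binding constant
#' \code{h = K_D^2 K_L K_R}. Given user-supplied values of these two
#' constants (no defaults are shipped), this helper restores absolute time
#' and amounts for a trajectory.
#'
#' @param traj A \code{\link{simulateDynamics}} trajectory.
#' @param lambda_t Transcript degradation rate (per unit absolute time).
#' @param h Composite tetramer-binding constant (concentration^4).
#' @return A data frame with absolute \code{time} and unrescaled amounts.
#' @export
unrescaleTrajectory <- function(traj, lambda_t, h) {
  stopifnot(is.data.frame(traj), lambda_t > 0, h > 0)
  out <- traj
  out$tau <- traj$tau / lambda_t
  names(out)[names(out) == "tau"] <- "time"
  amount_cols <- setdiff(names(out), "time")
  out[amount_cols] <- out[amount_cols] * h^0.25
  out
}
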