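# Deterministic dynamics of the rescaled transcript and protein amounts for
# the R, M and C genes. Each gene follows the two-stage cascade
#   dm/dtau = phi(p_C) - m,    dp/dtau = k_tilde * m - x * p,
# with promoter activities from the thermodynamic model; the C protein feeds
# back on its own and the M gene's transcription.

.STATE_NAMES <- c("m_R", "m_M", "m_C", "p_R", "p_M", "p_C")

#' Rescaled system state
#'
#' Transcript (\code{m_*}) and protein (\code{p_*}) amounts of the R, M and
#' C genes, all dimensionless and non-negative. The default (all zero) is
#' the naive-host initial condition: a cell newly receiving the R-M genes
#' with no pre-existing products.
#'
#' @param m_R,m_M,m_C Rescaled transcript amounts, >= 0.
#' @param p_R,p_M,p_C Rescaled protein amounts, >= 0.
#' @return Named numeric vector of length six, class \code{system_state}.
#' @export
systemState <- function(m_R = 0, m_M = 0, m_C = 0,
                        p_R = 0, p_M = 0, p_C = 0) {
  s <- c(m_R = m_R, m_M = m_M, m_C = m_C, p_R = p_R, p_M = p_M, p_C = p_C)
  if (any(!is.finite(s)) || any(s < 0))
    stop("state components must be finite and non-negative", call. = FALSE)
  structure(s, class = c("system_state", "numeric"))
}

#' Time derivatives of the rescaled expression dynamics
#'
#' @param state A \code{\link{systemState}} (or named numeric with the same
#'   six components).
#' @param thermo A \code{\link{thermoParams}} object.
#' @param trans A \code{\link{translationParams}} object.
#' @param phi_R Constant rescaled activity of the constitutive R promoter.
#' @param clamp_p_C If \code{TRUE}, the C-protein level seen by the promoter
#'   activities is clamped to zero (knockout of C-protein feedback); the C
#'   transcript/protein are still propagated.
#' @return Named numeric vector of the six derivatives.
#' @export
stateDerivatives <- function(state, thermo, trans = translationParams(),
                             phi_R, clamp_p_C = FALSE) {
  .check_params(thermo)
  .check_trans(trans)
  phi_R <- activityR(phi_R)
  s <- state[.STATE_NAMES]
  if (any(is.na(s)))
    stop("state must contain components ",
         paste(.STATE_NAMES, collapse = ", "), call. = FALSE)
  p_eff <- if (clamp_p_C) 0 else s[["p_C"]]
  phi <- c(phi_R, activityM(thermo, p_eff), activityC(thermo, p_eff))
  m <- s[1:3]; p <- s[4:6]
  stats::setNames(c(phi - m, trans$k_tilde * m - trans$x * p), .STATE_NAMES)
}

#' Analytic steady state of the expression dynamics
#'
#' Solves the scalar fixed-point condition
#' \eqn{(x/\tilde k)\,p_C = \tilde\varphi_C(p_C)} for the equilibrium
#' C-protein level by bracketed root-finding, then sets each transcript to
#' its promoter activity and each protein to \eqn{(\tilde k/x)} times its
#' transcript.
#'
#' @inheritParams stateDerivatives
#' @param phi_R Constant R-promoter activity; if \code{NULL} (default) the
#'   common equilibrium activity of the M/C promoters is used (the
#'   steady-state equality assumption under which the parameters were
#'   estimated).
#' @param tol Root-finding tolerance on \code{p_C}; default 1e-12.
#' @return A \code{\link{systemState}} at the fixed point.
#' @examples
#' est <- estimateParameters(observedRatios())
#' steadyState(est$params)
#' @export
steadyState <- function(thermo, trans = translationParams(), phi_R = NULL,
                        tol = 1e-12) {
  .check_params(thermo)
  .check_trans(trans)
  ratio_kx <- trans$k_tilde / trans$x
  bal <- function(p) (trans$x / trans$k_tilde) * p - activityC(thermo, p)
  # activityC <= alpha_tilde, so the balance is positive past this point
  upper <- ratio_kx * thermo$alpha_tilde + 1
  if (bal(upper) <= 0)
    stop(sprintf("no steady-state bracket: balance still %.3g at p_C = %.3g",
                 bal(upper), upper), call. = FALSE)
  p_eq <- if (bal(0) >= 0) 0 else
    stats::uniroot(bal, c(0, upper), tol = tol)$root
  m <- c(if (is.null(phi_R)) activityC(thermo, p_eq) else activityR(phi_R),
         activityM(thermo, p_eq), activityC(thermo, p_eq))
  systemState(m[1], m[2], m[3],
              ratio_kx * m[1], ratio_kx * m[2], ratio_kx * m[3])
}

#' Integrate the rescaled expression dynamics
#'
#' Numerically integrates the six-dimensional system on \code{[0, tau_end]}
#' with an adaptive method (lsoda; relative tolerance 1e-8, absolute 1e-10),
#' sampled on a uniform grid. When \code{extend = TRUE} the horizon is
#' doubled until the maximum relative derivative at the final state falls
#' below \code{settle_tol}, so the returned trajectory always reaches
#' (numerical) steady state.
#'
#' @inheritParams stateDerivatives
#' @param initial Initial \code{\link{systemState}}; default all-zero
#'   (naive host).
#' @param phi_R Constant R activity; \code{NULL} uses the equilibrium M/C
#'   activity (see \code{\link{steadyState}}).
#' @param tau_end Rescaled integration horizon, > 0; default 60.
#' @param n_points Number of grid points (>= 2); default 1000.
#' @param extend Extend the horizon until settled; default \code{TRUE}.
#' @param settle_tol Relative-derivative threshold for settling; 1e-8.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class \code{trajectory} with columns \code{tau},
#'   \code{m_R}, \code{m_M}, \code{m_C}, \code{p_R}, \code{p_M}, \code{p_C}.
#' @examples
#' est <- estimateParameters(observedRatios())
#' traj <- simulateDynamics(est$params, tau_end = 30, extend = FALSE)
#' tail(traj, 1)
#' @export
simulateDynamics <- function(thermo, trans = translationParams(),
                             phi_R = NULL, initial = systemState(),
                             tau_end = 60, n_points = 1000L,
                             clamp_p_C = FALSE, extend = TRUE,
                             settle_tol = 1e-8, rtol = 1e-8, atol = 1e-10) {
  .check_params(thermo)
  .check_trans(trans)
  if (!is.finite(tau_end) || tau_end <= 0) stop("tau_end must be positive")
  if (n_points < 2L) stop("n_points must be at least 2")
  if (is.null(phi_R)) {
    eq <- steadyState(thermo, trans)
    phi_R <- eq[["m_C"]]                   # common equilibrium activity
  }
  init <- systemState(initial[["m_R"]], initial[["m_M"]], initial[["m_C"]],
                      initial[["p_R"]], initial[["p_M"]], initial[["p_C"]])

  rhs <- function(tau, y, parms) {
    list(stateDerivatives(y, thermo, trans, phi_R, clamp_p_C = clamp_p_C))
  }
  max_doublings <- 8L
  repeat {
    times <- seq(0, tau_end, length.out = n_points)
    sol <- deSolve::ode(y = unclass(init)[.STATE_NAMES], times = times,
                        func = rhs, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    attr_diag <- attributes(sol)$istate
    if (!is.null(attr_diag) && attr_diag[1] < 0)
      stop(sprintf("integrator failed (istate = %d) at tau_end = %.3g",
                   attr_diag[1], tau_end), call. = FALSE)
    final <- sol[nrow(sol), -1]
    d <- stateDerivatives(final, thermo, trans, phi_R, clamp_p_C = clamp_p_C)
    rel <- max(abs(d) / pmax(abs(final), 1))
    if (!extend || rel < settle_tol || max_doublings == 0L) break
    tau_end <- tau_end * 2
    max_doublings <- max_doublings - 1L
  }
  traj <- as.data.frame(sol)
  names(traj) <- c("tau", .STATE_NAMES)
  traj[.STATE_NAMES][traj[.STATE_NAMES] < 0] <- 0  # clip integrator noise
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Summary metrics of a species trajectory
#'
#' @param traj A \code{trajectory} from \code{\link{simulateDynamics}}.
#' @param species One of the six state columns; default \code{"p_M"}
#'   (the methyltransferase, whose transient overshoot is the hallmark of
#'   R-M system establishment).
#' @return A list with \code{peak}, \code{peak_time}, \code{final} and
#'   \code{overshoot_ratio} (peak over final; 1 when both are zero).
#' @export
trajectoryMetrics <- function(traj, species = "p_M") {
  if (!is.data.frame(traj) || nrow(traj) == 0L)
    stop("trajectory must be a non-empty data frame", call. = FALSE)
  species <- match.arg(species, .STATE_NAMES)
  y <- traj[[species]]
  i <- which.max(y)
  peak <- y[i]
  final <- y[length(y)]
  ratio <- if (final == 0) {
    if (peak == 0) 1 else Inf
  } else peak / final
  list(peak = peak, peak_time = traj$tau[i], final = final,
       overshoot_ratio = ratio)
}
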