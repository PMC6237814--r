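# In-silico perturbations of the regulatory circuit: abolishing C-protein
# feedback (knockout) and sweeping the roadblock read-through probability
# beta, with steady-state / trajectory summaries comparable to wild type.

#' Default grid of read-through probabilities for a sweep
#'
#' Eleven equally spaced values from 0 (complete roadblock) to 1
#' (no roadblock), plus the wild-type estimate 0.44.
#' @return Sorted numeric vector.
#' @export
defaultBetaGrid <- function() sort(unique(c(seq(0, 1, by = 0.1), 0.44)))

#' Simulate establishment with C-protein feedback abolished
#'
#' Integrates the dynamics with the C-protein level clamped to zero inside
#' the promoter activities (the C transcript and protein are still
#' propagated but exert no feedback). M transcription is then limited only
#' by RNAP competition from the overlapping C promoter, so its activity is
#' the constant \eqn{\tilde\alpha f/(1+f+g)} and the M protein rises
#' monotonically to \eqn{(\tilde k/x)\,\tilde\alpha f/(1+f+g)}.
#'
#' @inheritParams simulateDynamics
#' @param ... Further arguments passed to \code{\link{simulateDynamics}}.
#' @return A \code{trajectory} data frame.
#' @export
simulateKnockout <- function(thermo, trans = translationParams(),
                             phi_R = NULL, tau_end = 60, ...) {
  simulateDynamics(thermo, trans, phi_R = phi_R, tau_end = tau_end,
                   clamp_p_C = TRUE, ...)
}

.perturbation_report <- function(label, beta, steady_p_M, peak_p_M,
                                 ratio_vs_wildtype = NA_real_) {
  data.frame(label = label, beta = beta, steady_p_M = steady_p_M,
             peak_p_M = peak_p_M, ratio_vs_wildtype = ratio_vs_wildtype,
             stringsAsFactors = FALSE)
}

#' Perturbation report for one parameter set
#'
#' Computes the steady-state and trajectory-peak M-protein level for the
#' given parameters (optionally with C feedback clamped off).
#'
#' @inheritParams simulateDynamics
#' @param label Identifier for the report row.
#' @return One-row data frame: \code{label}, \code{beta},
#'   \code{steady_p_M}, \code{peak_p_M}, \code{ratio_vs_wildtype} (NA until
#'   filled by \code{\link{compareToWildtype}}).
#' @export
perturbationReport <- function(thermo, trans = translationParams(),
                               phi_R = NULL, label = "wild_type",
                               clamp_p_C = FALSE, tau_end = 60, ...) {
  traj <- simulateDynamics(thermo, trans, phi_R = phi_R, tau_end = tau_end,
                           clamp_p_C = clamp_p_C, ...)
  steady <- if (clamp_p_C) {
    (trans$k_tilde / trans$x) * activityM(thermo, 0)
  } else {
    steadyState(thermo, trans, phi_R = phi_R)[["p_M"]]
  }
  m <- trajectoryMetrics(traj, "p_M")
  .perturbation_report(label, if (clamp_p_C) NA_real_ else thermo$beta,
                       steady, m$peak)
}

#' Sweep the roadblock read-through probability
#'
#' For each value of \eqn{\beta} (all other parameters fixed) recomputes the
#' steady state and establishment trajectory. Higher read-through lets more
#' C protein accumulate, which represses M more strongly: the steady-state
#' M level decreases monotonically across an increasing \eqn{\beta} grid.
#'
#' @inheritParams simulateDynamics
#' @param beta_values Read-through probabilities, each in [0, 1].
#' @return Data frame with one \code{\link{perturbationReport}} row per
#'   \eqn{\beta}.
#' @examples
#' est <- estimateParameters(observedRatios())
#' betaSweep(est$params, beta_values = c(0, 0.5, 1), tau_end = 30)
#' @export
betaSweep <- function(thermo, trans = translationParams(), phi_R = NULL,
                      beta_values = defaultBetaGrid(), tau_end = 60, ...) {
  .check_params(thermo)
  if (any(!is.finite(beta_values)) || any(beta_values < 0) ||
      any(beta_values > 1))
    stop("all beta values must lie in [0, 1]", call. = FALSE)
  rows <- lapply(beta_values, function(b) {
    th <- thermoParams(thermo$f, thermo$g, thermo$alpha_tilde, b)
    perturbationReport(th, trans, phi_R = phi_R,
                       label = sprintf("beta=%g", b), tau_end = tau_end, ...)
  })
  do.call(rbind, rows)
}

#' Annotate perturbation reports with their ratio to wild type
#'
#' Fills \code{ratio_vs_wildtype} = steady-state M protein over the
#' wild-type steady-state M protein. For the knockout this ratio equals the
#' M-repression observable \eqn{r_M} identically: clamping the C level to
#' zero restores exactly the C-free activity whose quotient with the
#' equilibrium activity defined \eqn{r_M}.
#'
#' @param reports Data frame of perturbation rows.
#' @param wildtype_report One-row wild-type report with
#'   \code{steady_p_M > 0}.
#' @return \code{reports} with \code{ratio_vs_wildtype} filled.
#' @export
compareToWildtype <- function(reports, wildtype_report) {
  wt <- wildtype_report$steady_p_M[1]
  if (!is.finite(wt) || wt <= 0)
    stop("wild-type steady-state M protein must be positive", call. = FALSE)
  reports$ratio_vs_wildtype <- reports$steady_p_M / wt
  reports
}
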