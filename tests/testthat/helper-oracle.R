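# Independent oracle implementations, written directly from the model
# formulas with plain arithmetic. They deliberately do not call the package
# functions they are used to check.

# Promoter activities, direct formulas.
oracle_phi_M <- function(f, g, at, p) at * f / (1 + f + g + (1 + g) * p^4)
oracle_init_C <- function(f, g, at, p) {
  at * g * (1 + p^4) / (1 + f + g + (1 + g) * p^4)
}
oracle_elong <- function(f, g, beta, p) {
  (1 + f + g + beta * (1 + g) * p^4) / (1 + f + g + (1 + g) * p^4)
}
oracle_phi_C <- function(f, g, at, beta, p) {
  oracle_init_C(f, g, at, p) * oracle_elong(f, g, beta, p)
}

# Sequential algebraic elimination of the five-constraint system.
oracle_solve <- function(r_M, r_C, r_block, k_tilde = 3, x = 1 / 6) {
  u <- r_M / r_C - 1
  p <- u^0.25
  beta <- (r_block * r_M - 1) / (r_M - 1)
  fg <- (1 + u) * r_block
  g <- ((r_M - 1) - u) / (u - (r_M - 1) * (fg + 1))
  f <- fg * g
  Z <- 1 + f + g + (1 + g) * u
  at <- (x / k_tilde) * p * Z / (g * (1 + u) * r_block)
  list(f = f, g = g, alpha_tilde = at, beta = beta, p_eq = p)
}

# Equilibrium C level by plain bisection on the protein-balance condition.
oracle_steady_pC <- function(f, g, at, beta, k_tilde = 3, x = 1 / 6,
                             tol = 1e-12) {
  bal <- function(p) (x / k_tilde) * p - oracle_phi_C(f, g, at, beta, p)
  lo <- 0
  hi <- (k_tilde / x) * at + 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (bal(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# The measured Kpn2I observables and translation constants.
kpn_ratios <- function() observedRatios(86.229, 0.263, 0.44)
kpn_trans <- function() translationParams(3, 1 / 6)

# Reproducible draws of valid ground-truth parameter sets for
# property-style tests. Valid means lying on the manifold where the M and C
# steady-state activities are equal (the assumption under which the
# five-constraint system is posed), so draws go through observable space
# and the independent elimination oracle.
draw_params <- function(i) {
  set.seed(1000 + i)
  s <- oracle_solve(r_M = stats::runif(1, 20, 300),
                    r_C = stats::runif(1, 0.1, 0.8),
                    r_block = stats::runif(1, 0.2, 0.95))
  thermoParams(s$f, s$g, s$alpha_tilde, s$beta)
}
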