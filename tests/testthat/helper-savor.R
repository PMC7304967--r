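# shared fixtures: admissible random parameter draws and quadrature oracles

# one random admissible parameter set; C placed at a random fraction of the
# stability bound so solve_arpe is always well defined
rand_params <- function(C_frac = runif(1, 0, 0.9)) {
  Rm <- -runif(1, 0, 1.2)
  nu_p <- exp(runif(1, log(0.05), log(1)))
  nu_m <- exp(runif(1, log(0.05), log(1)))
  gam <- exp(runif(1, log(0.005), log(0.3)))
  eta0 <- runif(1, 0, 1.5)
  base <- savor_params(R_minus = Rm, eta0 = eta0, C = 0, nu_plus = nu_p,
                       nu_minus = nu_m, gamma = gam, sigma = 0.3)
  savor_params(R_minus = Rm, eta0 = eta0,
               C = C_frac * stability_bound(base), nu_plus = nu_p,
               nu_minus = nu_m, gamma = gam, sigma = runif(1, 0.05, 1))
}

rand_condition <- function() {
  list(q = runif(1), T = runif(1, 0.5, 60))
}

# independent quadrature of the anticipation value integral
# int_0^T e^{-gamma t'} R e^{-nu (T - t')} dt'
quad_anticipation <- function(R, nu, gamma, T) {
  if (T == 0) return(0)
  stats::integrate(function(tp) exp(-gamma * tp) * R * exp(-nu * (T - tp)),
                   0, T, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# boosting-on parameters with weak discounting and a strong, monotone
# delay preference (used for qualitative behavioral checks)
boost_params <- function(sigma = 0.15) {
  base <- savor_params(R_minus = -0.2, eta0 = 0.5, C = 0, nu_plus = 0.15,
                       nu_minus = 0.15, gamma = 0.002, sigma = sigma)
  savor_params(R_minus = -0.2, eta0 = 0.5,
               C = 0.5 * stability_bound(base), nu_plus = 0.15,
               nu_minus = 0.15, gamma = 0.002, sigma = sigma)
}

# small simulated cohort for fitting tests
small_cohort <- function(n_subjects = 4, n_runs = 2L, params = boost_params(),
                         seed = 99) {
  set.seed(seed)
  tr <- generate_trials(task_config(n_runs = n_runs), n_subjects)
  simulate_choices(params, tr)
}
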