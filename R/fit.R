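#' Control settings for the hierarchical fit
#'
#' @param em_tol convergence tolerance on the maximum absolute change of the
#'   group-prior mean between EM iterations (transformed space).
#' @param em_max_iter maximum EM iterations.
#' @param n_restarts optimizer restarts per subject, drawn from the current
#'   group prior (the previous MAP and the prior mean are always tried too).
#' @param optim_maxit BFGS iteration cap per start.
#' @param hess_step relative step of the central-difference Hessian used for
#'   the Laplace covariance.
#' @param ridge ridge added (and doubled) to the Hessian until it is positive
#'   definite.
#' @param loglik_floor per-trial likelihood floor guarding \code{-Inf} under
#'   extreme parameters.
#' @param var_floor lower bound applied to group-prior variances between EM
#'   iterations (keeps the E-step posterior proper).
#' @param em_patience stop when the Monte-Carlo-estimated marginal
#'   likelihood has not improved for this many iterations; the best-scoring
#'   iterate is returned. Because the E step is approximate, the EM
#'   objective is not exactly monotone, and along weakly identified
#'   directions the iteration can otherwise random-walk away from its
#'   optimum.
#' @param n_em_inits number of independent EM runs (the first from the
#'   nominal initialization, the rest from jittered ones); the run with the
#'   best approximate marginal likelihood wins. The likelihood surface over
#'   group priors has local basins, so a single run can depend on its start.
#' @param init_jitter standard deviation of the mean jitter (transformed
#'   space) applied to additional initializations.
#' @param init_var starting variance (transformed space) of the group prior
#'   around the pooled-MAP initialization.
#' @param mc_samples Monte-Carlo draws per subject used to score each EM
#'   iterate's marginal likelihood (common random numbers across iterates).
#' @return A list of class \code{savor_control}.
#' @export
savor_control <- function(em_tol = 1e-3, em_max_iter = 200L, n_restarts = 10L,
                          optim_maxit = 200L, hess_step = 1e-4, ridge = 1e-6,
                          loglik_floor = 1e-12, var_floor = 1e-8,
                          em_patience = 8L, n_em_inits = 1L,
                          init_jitter = 0.5, init_var = 0.1,
                          mc_samples = 500L) {
  structure(list(em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 n_restarts = as.integer(n_restarts),
                 optim_maxit = as.integer(optim_maxit),
                 hess_step = hess_step, ridge = ridge,
                 loglik_floor = loglik_floor, var_floor = var_floor,
                 em_patience = as.integer(em_patience),
                 n_em_inits = as.integer(n_em_inits),
                 init_jitter = init_jitter, init_var = init_var,
                 mc_samples = as.integer(mc_samples)),
            class = "savor_control")
}

# choice column -> 0/1 (1 = immediate information)
.choice01 <- function(choice) {
  if (is.character(choice) || is.factor(choice)) {
    ch <- as.character(choice)
    bad <- !ch %in% c("info", "noinfo")
    if (any(bad)) stop("choice must be 'info' or 'noinfo'")
    as.integer(ch == "info")
  } else {
    v <- as.integer(choice)
    if (any(!v %in% c(0L, 1L))) stop("numeric choices must be 0/1")
    v
  }
}

# collapse one subject's trials to condition-level counts
.condition_counts <- function(trials) {
  info <- .choice01(trials$choice)
  a <- aggregate(cbind(n_info = info, n_tot = rep(1L, length(info))),
                 by = list(q = trials$q, T_s = trials$T_s), FUN = sum)
  data.frame(q = a$q, T_s = a$T_s, n_info = a$n_info,
             n_noinfo = a$n_tot - a$n_info, row.names = NULL)
}

.split_counts <- function(trials) {
  need <- c("subject", "q", "T_s", "choice")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  lapply(split(trials[need], trials$subject), .condition_counts)
}

#' Log-likelihood of one subject's choices
#'
#' Bernoulli log-likelihood of the observed choices under the model's sigmoid
#' choice probabilities, with each trial's likelihood floored at
#' \code{floor} to guard against \code{-Inf} under extreme parameters.
#'
#' @param trials trial table for one subject (columns \code{q}, \code{T_s},
#'   \code{choice}).
#' @param params a \code{\link{savor_params}} object.
#' @param floor per-trial probability floor.
#' @return Scalar log-likelihood.
#' @export
subject_log_likelihood <- function(trials, params, floor = 1e-12) {
  p <- choice_prob(params, trials$q, trials$T_s)
  info <- .choice01(trials$choice)
  p_choice <- ifelse(info == 1L, p, 1 - p)
  sum(log(pmax(p_choice, floor)))
}

# prior restricted to the free coordinates of a model spec
.prior_free <- function(prior, spec) {
  if (!all(spec$free %in% names(prior$mean)))
    stop("prior does not cover the model's free parameters")
  savor_prior(prior$mean[spec$free], prior$var[spec$free])
}

# default broad initialization of the group prior (transformed space)
.default_prior <- function(spec) {
  p0 <- savor_params(R_minus = -0.5, eta0 = 0.5, C = 0, nu_plus = 0.2,
                     nu_minus = 0.2, gamma = 0.05, sigma = 0.5)
  h0 <- transform_params(p0)
  h0["C"] <- qlogis(0.2)  # C at 20% of the stability bound
  savor_prior(h0[spec$free], setNames(rep(1, length(spec$free)), spec$free))
}

# base natural-parameter vector with the spec's fixed values filled in
.base_par <- function(spec) {
  base <- setNames(numeric(7L), .param_names)
  base[names(spec$fixed)] <- spec$fixed
  base
}

.nlp_closure <- function(counts, prior, spec, control, gradient = FALSE) {
  free_idx <- match(spec$free, .param_names) - 1L
  base <- .base_par(spec)
  floor_log <- log(control$loglik_floor)
  pm <- unname(prior$mean[spec$free])
  pv <- unname(prior$var[spec$free])
  if (gradient)
    function(h) neg_log_post_grad_cpp(h, free_idx, base, counts$q,
                                      counts$T_s, counts$n_info,
                                      counts$n_noinfo, pm, pv, floor_log)
  else
    function(h) neg_log_post_cpp(h, free_idx, base, counts$q, counts$T_s,
                                 counts$n_info, counts$n_noinfo, pm, pv,
                                 floor_log)
}

# central-difference Hessian with relative steps
.num_hessian <- function(fn, x, rel_step = 1e-4) {
  d <- length(x)
  s <- rel_step * pmax(1, abs(x))
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- s[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / s[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- rep(0, d); ej[j] <- s[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * s[i] * s[j])
    }
  }
  H
}

# invert a Hessian into a PD covariance, escalating the ridge as needed
.laplace_cov <- function(H, ridge = 1e-6) {
  d <- nrow(H)
  H <- (H + t(H)) / 2
  r <- ridge
  for (k in 1:60) {
    ch <- tryCatch(chol(H + r * diag(d)), error = function(e) NULL)
    if (!is.null(ch)) {
      S <- chol2inv(ch)
      if (all(is.finite(S))) return((S + t(S)) / 2)
    }
    r <- r * 10
  }
  stop("could not regularize the Laplace Hessian to positive definiteness")
}

#' MAP estimate and Laplace approximation for one subject
#'
#' Maximizes the per-subject log posterior (choice likelihood times the
#' Gaussian group prior in transformed space) by multi-start BFGS, then
#' approximates the posterior by a Gaussian centred at the MAP with
#' covariance the inverse of a ridge-regularized numerical Hessian.
#' With zero trials the posterior equals the prior, so the MAP is the prior
#' mean and the covariance the prior covariance.
#'
#' @param trials one subject's trial table (or \code{NULL} for zero trials).
#' @param prior a \code{\link{savor_prior}} over the free coordinates.
#' @param spec a \code{\link{savor_model_spec}}.
#' @param control a \code{\link{savor_control}}.
#' @param start optional extra starting point (transformed space), e.g. the
#'   MAP from the previous EM iteration.
#' @return A list (class \code{savor_subject_fit}): \code{m} (MAP, transformed
#'   space), \code{Sigma} (Laplace covariance), \code{log_post},
#'   \code{params} (natural scale), \code{convergence}.
#' @export
fit_subject_map <- function(trials, prior, spec = savor_model_spec("full"),
                            control = savor_control(), start = NULL) {
  prior <- .prior_free(prior, spec)
  d <- length(spec$free)
  if (is.null(trials) || nrow(trials) == 0) {
    m <- prior$mean
    out <- list(m = m, Sigma = diag(prior$var, d), log_post = NA_real_,
                params = .assemble_params(m, spec), convergence = 0L)
    class(out) <- "savor_subject_fit"
    return(out)
  }
  counts <- if (all(c("n_info", "n_noinfo") %in% names(trials))) trials
            else .condition_counts(trials)
  fn <- .nlp_closure(counts, prior, spec, control)
  gr <- .nlp_closure(counts, prior, spec, control, gradient = TRUE)
  starts <- list(prior$mean)
  if (!is.null(start)) starts <- c(list(start), starts)
  if (control$n_restarts > 0) {
    draws <- replicate(control$n_restarts,
                       rnorm(d, prior$mean, sqrt(prior$var)),
                       simplify = FALSE)
    starts <- c(starts, draws)
  }
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      optim(s0, fn, gr, method = "BFGS",
            control = list(maxit = control$optim_maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed for this subject")
  m <- setNames(best$par, spec$free)
  H <- .num_hessian(fn, m, control$hess_step)
  Sigma <- .laplace_cov(H, control$ridge)
  out <- list(m = m, Sigma = Sigma, log_post = -best$value,
              params = .assemble_params(m, spec),
              convergence = best$convergence)
  class(out) <- "savor_subject_fit"
  out
}

#' M-step update of the group prior
#'
#' Given the subjects' Laplace approximations, updates the population mean to
#' the average MAP and each diagonal variance to
#' \eqn{\frac{1}{N}\sum_i (m_{ij}^2 + \Sigma_{i,jj}) - \mu_j^2}: the average
#' second moment (MAP squared plus posterior variance) minus the squared new
#' mean. Off-diagonal covariance is assumed zero.
#'
#' @param subject_fits list of \code{\link{fit_subject_map}} results.
#' @return A \code{\link{savor_prior}} over the same coordinates.
#' @export
em_update <- function(subject_fits) {
  M <- do.call(rbind, lapply(subject_fits, `[[`, "m"))
  V <- do.call(rbind, lapply(subject_fits, function(f) diag(f$Sigma)))
  mu <- colMeans(M)
  v <- colMeans(M^2 + V) - mu^2
  savor_prior(mu, pmax(v, .Machine$double.eps))
}

# vectorized stability bound over parameter draws
.branch_bound_vec <- function(Rabs, nu, gam) {
  n <- max(length(Rabs), length(nu), length(gam))
  Rabs <- rep_len(Rabs, n); nu <- rep_len(nu, n); gam <- rep_len(gam, n)
  ifelse(Rabs <= 0, Inf,
         ifelse(gam <= 0, nu / Rabs,
                ifelse(abs(nu - gam) < 1e-9, gam * exp(1) / Rabs,
                       gam / Rabs * (gam / nu)^(nu / (gam - nu)))))
}

# map a K x free matrix of transformed draws to natural-scale parameters
.batch_assemble <- function(H, spec) {
  K <- nrow(H)
  full <- matrix(-.H_CLAMP, K, 7L, dimnames = list(NULL, .param_names))
  full[, colnames(H)] <- H
  full <- pmin(pmax(full, -40), 40)
  P <- matrix(0, K, 7L, dimnames = list(NULL, .param_names))
  P[, "R_minus"] <- -exp(full[, "R_minus"])
  P[, "eta0"] <- log1p(exp(full[, "eta0"]))
  P[, "nu_plus"] <- exp(full[, "nu_plus"])
  P[, "nu_minus"] <- exp(full[, "nu_minus"])
  P[, "gamma"] <- exp(full[, "gamma"])
  P[, "sigma"] <- exp(full[, "sigma"])
  b <- pmin(.branch_bound_vec(1, P[, "nu_plus"], P[, "gamma"]),
            .branch_bound_vec(abs(P[, "R_minus"]), P[, "nu_minus"],
                              P[, "gamma"]))
  P[, "C"] <- b * plogis(full[, "C"])
  for (nm in names(spec$fixed)) P[, nm] <- spec$fixed[[nm]]
  P
}

# Monte-Carlo estimate of log p(D | theta) over the cohort, using fixed
# standard-normal draws (common random numbers across candidate priors)
.mc_logml <- function(counts, prior, spec, Z_list, floor_log) {
  mu <- prior$mean[spec$free]
  sdv <- sqrt(prior$var[spec$free])
  tot <- 0
  for (i in seq_along(counts)) {
    Z <- Z_list[[i]]
    H <- sweep(Z, 2, sdv, `*`)
    H <- sweep(H, 2, mu, `+`)
    colnames(H) <- spec$free
    P <- .batch_assemble(H, spec)
    cc <- counts[[i]]
    ll <- loglik_counts_batch_cpp(P, cc$q, cc$T_s, cc$n_info, cc$n_noinfo,
                                  floor_log)
    m <- max(ll)
    tot <- tot + m + log(mean(exp(ll - m)))
  }
  tot
}

# Laplace estimate of the summed log marginal likelihood log p(D | theta)
.approx_logml <- function(subject_fits) {
  sum(vapply(subject_fits, function(f) {
    d <- length(f$m)
    ld <- determinant(f$Sigma, logarithm = TRUE)$modulus
    f$log_post + d / 2 * log(2 * pi) + 0.5 * as.numeric(ld)
  }, numeric(1)))
}

#' Fit the savoring model hierarchically by approximate EM
#'
#' Random-effects fit of the boosted-anticipation choice model: each
#' subject's transformed parameters are a draw from a diagonal Gaussian
#' population distribution, whose maximum-likelihood mean and variances are
#' found by expectation-maximization. The E step computes each subject's MAP
#' and a Laplace (inverse-Hessian) covariance under the current prior
#' (\code{\link{fit_subject_map}}); the M step re-estimates the prior moments
#' (\code{\link{em_update}}). Iterations stop when the prior mean moves less
#' than \code{em_tol} (transformed space), when the approximate marginal
#' likelihood has not improved for \code{em_patience} iterations, or at
#' \code{em_max_iter}; the prior achieving the best approximate marginal
#' likelihood is returned (the approximate E step makes the EM objective
#' non-monotone, so the last iterate is not necessarily the best one).
#'
#' @param trials cohort trial table: columns \code{subject}, \code{q},
#'   \code{T_s}, \code{choice} (\code{"info"}/\code{"noinfo"} or 0/1).
#' @param model model variant name or a \code{\link{savor_model_spec}}.
#' @param control a \code{\link{savor_control}}.
#' @param seed integer seed making the fit fully reproducible (optimizer
#'   restart draws); \code{NULL} uses the current RNG state.
#' @param prior_init optional initial \code{\link{savor_prior}}; by default
#'   the starting prior is centred on the pooled-data MAP (all subjects'
#'   trials fitted as a single subject) with variance
#'   \code{control$init_var}.
#' @return An object of class \code{savor_fit}; see
#'   \code{\link{summary.savor_fit}}, \code{\link{coef.savor_fit}},
#'   \code{\link{predict.savor_fit}}, \code{\link{simulate.savor_fit}}.
#' @examples
#' cfg <- task_config()
#' set.seed(7)
#' trials <- generate_trials(cfg, n_subjects = 4)
#' truth <- savor_params(R_minus = -0.3, eta0 = 0.6, C = 0.15,
#'                       nu_plus = 0.25, nu_minus = 0.25, gamma = 0.03,
#'                       sigma = 0.3)
#' trials <- simulate_choices(truth, trials)
#' fit <- fit_savor(trials, model = "full", seed = 1,
#'                  control = savor_control(em_max_iter = 3, n_restarts = 2))
#' coef(fit)
#' @export
fit_savor <- function(trials, model = "full", control = savor_control(),
                      seed = NULL, prior_init = NULL) {
  spec <- if (inherits(model, "savor_model_spec")) model
          else savor_model_spec(model)
  counts <- .split_counts(trials)
  if (length(counts) < 2)
    stop("hierarchical fitting needs at least 2 subjects")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  prior0 <- if (is.null(prior_init)) .pooled_init(counts, spec, control)
            else .prior_free(prior_init, spec)
  d <- length(spec$free)
  Z_list <- lapply(counts, function(cc)
    matrix(rnorm(control$mc_samples * d), control$mc_samples, d))
  runs <- vector("list", max(1L, control$n_em_inits))
  for (k in seq_along(runs)) {
    pk <- prior0
    if (k > 1)
      pk$mean <- pk$mean + rnorm(length(pk$mean), 0, control$init_jitter)
    runs[[k]] <- .run_em(counts, pk, spec, control, Z_list)
  }
  logmls <- vapply(runs, function(r) r$best_logml, numeric(1))
  em <- runs[[which.max(logmls)]]
  prior <- em$prior
  fits <- em$fits
  names(fits) <- names(counts)
  out <- list(model = spec, prior = prior, subjects = fits,
              counts = counts, trace = em$trace, converged = em$converged,
              init_logml = logmls,
              n_trials = sum(vapply(counts, function(cc)
                sum(cc$n_info + cc$n_noinfo), numeric(1))),
              seed = seed, control = control, call = match.call())
  class(out) <- "savor_fit"
  out
}

# starting prior centred on the pooled-data MAP (all subjects as one):
# lands in the population likelihood's main basin far more reliably than a
# fixed guess
.pooled_init <- function(counts, spec, control) {
  all_cc <- do.call(rbind, counts)
  agg <- aggregate(cbind(n_info, n_noinfo) ~ q + T_s, all_cc, FUN = sum)
  pm <- fit_subject_map(agg, .default_prior(spec), spec, control)
  savor_prior(pm$m, setNames(rep(control$init_var, length(spec$free)),
                             spec$free))
}

# one EM run from a given initialization; the EM objective (the marginal
# likelihood of the group prior) is tracked by Monte-Carlo integration with
# common random numbers, and the best-scoring iterate is returned
.run_em <- function(counts, prior, spec, control, Z_list) {
  n_sub <- length(counts)
  floor_log <- log(control$loglik_floor)
  fits <- vector("list", n_sub)
  trace <- data.frame(iter = integer(0), mu_change = numeric(0),
                      approx_logml = numeric(0), mc_logml = numeric(0))
  converged <- FALSE
  best <- list(logml = -Inf, prior = prior, fits = NULL, iter = 0L)
  for (it in seq_len(control$em_max_iter)) {
    for (i in seq_len(n_sub)) {
      fits[[i]] <- fit_subject_map(counts[[i]], prior, spec, control,
                                   start = if (it > 1) fits[[i]]$m)
    }
    logml <- .mc_logml(counts, prior, spec, Z_list, floor_log)
    if (is.finite(logml) && logml > best$logml)
      best <- list(logml = logml, prior = prior, fits = fits, iter = it)
    new_prior <- em_update(fits)
    new_prior$var <- pmax(new_prior$var, control$var_floor)
    change <- max(abs(new_prior$mean - prior$mean))
    trace <- rbind(trace, data.frame(iter = it, mu_change = change,
                                     approx_logml = .approx_logml(fits),
                                     mc_logml = logml))
    prior <- new_prior
    if (!all(is.finite(prior$mean)) || !all(is.finite(prior$var)))
      stop("EM diverged to a non-finite group prior; trace:\n",
           paste(utils::capture.output(print(trace)), collapse = "\n"))
    if (change < control$em_tol) { converged <- TRUE; break }
    if (it - best$iter >= control$em_patience) break
  }
  if (!is.null(best$fits)) { prior <- best$prior; fits <- best$fits }
  list(prior = prior, fits = fits, trace = trace, converged = converged,
       best_logml = best$logml)
}
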