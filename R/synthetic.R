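#' Task configuration for the information-seeking paradigm
#'
#' Describes the factorial task: reward probability levels crossed with delay
#' levels, several scanning runs per subject, each run presenting every
#' condition exactly once in a randomized order. Timing constants give the
#' response window before the cue, the outcome display and the inter-trial
#' blank, all in seconds.
#'
#' @param q_levels reward probability levels.
#' @param T_levels waiting-period (delay) levels in seconds.
#' @param n_runs runs per subject.
#' @param response_s response window between trial start and cue onset (s).
#' @param outcome_s outcome display duration (s).
#' @param blank_s inter-trial blank duration (s).
#' @return An object of class \code{savor_task} (a list of the above).
#' @export
task_config <- function(q_levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                        T_levels = c(1, 5, 10, 20, 40),
                        n_runs = 3L, response_s = 3, outcome_s = 1,
                        blank_s = 1) {
  if (length(q_levels) < 1 || any(q_levels < 0) || any(q_levels > 1))
    stop("q_levels must be non-empty probabilities in [0, 1]")
  if (length(T_levels) < 1 || any(T_levels <= 0))
    stop("T_levels must be non-empty positive delays")
  out <- list(q_levels = sort(unique(q_levels)),
              T_levels = sort(unique(T_levels)),
              n_runs = as.integer(n_runs), response_s = response_s,
              outcome_s = outcome_s, blank_s = blank_s)
  out$trials_per_run <- length(out$q_levels) * length(out$T_levels)
  class(out) <- "savor_task"
  out
}

#' Full factorial condition grid
#'
#' @param cfg a \code{\link{task_config}}.
#' @return A data frame with one row per unique (q, T) condition, columns
#'   \code{q} and \code{T_s}.
#' @export
condition_grid <- function(cfg = task_config()) {
  g <- expand.grid(q = cfg$q_levels, T_s = cfg$T_levels,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$q, g$T_s), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Generate a cohort's trial and event tables
#'
#' For each subject and run, lays out one randomized pass through the full
#' condition grid, draws the binary outcome of every trial as
#' Bernoulli(\code{q}), and assigns event onsets within the run: trial start
#' (choice screen), cue onset after the response window, outcome onset after
#' the waiting period \code{T}, then the outcome display and blank before the
#' next trial.
#'
#' @param cfg a \code{\link{task_config}}.
#' @param n_subjects number of subjects (study default 39).
#' @return A data frame (one row per trial) with columns \code{subject},
#'   \code{run}, \code{trial}, \code{q}, \code{T_s}, \code{outcome} (1 =
#'   reward), \code{t_screen}, \code{t_cue}, \code{t_outcome}. Choices and cue
#'   identities are added by \code{\link{simulate_choices}}.
#' @seealso \code{\link{simulate_choices}}, \code{\link{build_design_matrix}}
#' @export
generate_trials <- function(cfg = task_config(), n_subjects = 39L) {
  grid <- condition_grid(cfg)
  n <- nrow(grid)
  rows <- vector("list", n_subjects * cfg$n_runs)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(cfg$n_runs)) {
      ord <- sample.int(n)
      g <- grid[ord, , drop = FALSE]
      dur <- cfg$response_s + g$T_s + cfg$outcome_s + cfg$blank_s
      t0 <- cumsum(c(0, dur[-n]))
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = s, run = r, trial = seq_len(n),
        q = g$q, T_s = g$T_s,
        outcome = rbinom(n, 1L, g$q),
        t_screen = t0,
        t_cue = t0 + cfg$response_s,
        t_outcome = t0 + cfg$response_s + g$T_s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "task") <- cfg
  out
}

#' Group-level prior over transformed parameters
#'
#' A diagonal Gaussian population distribution over the transformed parameter
#' vector \code{h} (see \code{\link{transform_params}}): one mean and one
#' variance per free coordinate.
#'
#' @param mean named numeric vector of means in transformed space.
#' @param var named numeric vector of variances (all \eqn{> 0}).
#' @return Object of class \code{savor_prior}.
#' @export
savor_prior <- function(mean, var) {
  if (length(mean) != length(var)) stop("mean and var lengths differ")
  if (any(var <= 0) || any(!is.finite(var)) || any(!is.finite(mean)))
    stop("prior variances must be positive and finite")
  if (is.null(names(mean))) names(mean) <- .param_names[seq_along(mean)]
  names(var) <- names(mean)
  structure(list(mean = mean, var = var), class = "savor_prior")
}

#' Reference population prior for simulation studies
#'
#' A group-level prior (transformed space) describing a realistic cohort for
#' this task: at its mean, subjects hold a moderate negative no-reward value
#' (\eqn{R^- \approx -0.3}), base anticipation \eqn{\eta_0 \approx 0.5},
#' boosting at 40\% of the stability bound, anticipation rates
#' \eqn{\nu^{\pm} \approx 0.2} /s, weak discounting
#' (\eqn{\gamma \approx 0.01} /s) and choice noise \eqn{\sigma \approx 0.2}.
#' These values produce information-choice rates that rise from near
#' indifference at 1-s delays to roughly 70--80\% at 10--20 s — the
#' qualitative preference profile this task elicits. Population variances
#' give moderate between-subject spread on every coordinate.
#'
#' @return A \code{\link{savor_prior}} over all seven coordinates.
#' @export
default_group_prior <- function() {
  savor_prior(
    mean = c(R_minus = log(0.3), eta0 = log(expm1(0.5)), C = qlogis(0.4),
             nu_plus = log(0.2), nu_minus = log(0.2), gamma = log(0.01),
             sigma = log(0.2)),
    var = c(R_minus = 0.2, eta0 = 0.2, C = 0.3, nu_plus = 0.1,
            nu_minus = 0.1, gamma = 0.1, sigma = 0.1))
}

#' @export
print.savor_prior <- function(x, ...) {
  cat("Group prior over transformed parameters:\n")
  print(round(rbind(mean = x$mean, sd = sqrt(x$var)), 4))
  invisible(x)
}

# draw one admissible savor_params from a prior (fixed values from spec)
.draw_params <- function(prior, spec = savor_model_spec("full")) {
  h <- rnorm(length(prior$mean), prior$mean, sqrt(prior$var))
  names(h) <- names(prior$mean)
  .assemble_params(h, spec)
}

# build savor_params from free-coordinate h vector + model spec
.assemble_params <- function(h_free, spec) {
  h <- setNames(rep(-.H_CLAMP, 7L), .param_names)
  h[spec$free] <- h_free[spec$free]
  p <- untransform_params(h)
  for (nm in names(spec$fixed)) p[[nm]] <- unname(spec$fixed[[nm]])
  p
}

#' Simulate choices from the model
#'
#' Fills in the \code{choice} column of a trial table by sampling each
#' trial's choice from the model's sigmoid choice probability, and sets the
#' cue identity implied by choice and outcome (\code{S+}/\code{S-} after an
#' information choice, \code{NI} otherwise). Given a single
#' \code{\link{savor_params}}, all subjects share those parameters; given a
#' \code{\link{savor_prior}}, each subject's parameters are drawn from it
#' (the stability-aware transform guarantees admissibility).
#'
#' @param params a \code{savor_params} or \code{savor_prior}.
#' @param trials a trial table from \code{\link{generate_trials}}.
#' @param spec model variant used when drawing from a prior.
#' @return The trial table with columns \code{choice} (\code{"info"} /
#'   \code{"noinfo"}) and \code{cue} (\code{"S+"}, \code{"S-"}, \code{"NI"})
#'   added; per-subject true parameters are attached as attribute
#'   \code{"true_params"}.
#' @export
simulate_choices <- function(params, trials,
                             spec = savor_model_spec("full")) {
  subjects <- unique(trials$subject)
  true <- vector("list", length(subjects))
  names(true) <- as.character(subjects)
  choice <- character(nrow(trials))
  for (i in seq_along(subjects)) {
    idx <- trials$subject == subjects[i]
    p_i <- if (inherits(params, "savor_prior")) .draw_params(params, spec)
           else as_savor_params(params)
    true[[i]] <- p_i
    pr <- choice_prob(p_i, trials$q[idx], trials$T_s[idx])
    choice[idx] <- ifelse(runif(sum(idx)) < pr, "info", "noinfo")
  }
  trials$choice <- choice
  trials$cue <- ifelse(trials$choice == "noinfo", "NI",
                       ifelse(trials$outcome == 1, "S+", "S-"))
  attr(trials, "true_params") <- true
  trials
}

#' Mean information-choice rate by condition level
#'
#' @param trials a trial table with a \code{choice} column.
#' @return A list of two data frames, \code{by_delay} and \code{by_prob},
#'   each with the level, trial count \code{n} and mean \code{info_rate}.
#' @export
summarize_preferences <- function(trials) {
  info <- as.numeric(trials$choice == "info")
  agg <- function(v) {
    a <- aggregate(list(info_rate = info), by = list(level = v), FUN = mean)
    a$n <- as.vector(table(v)[as.character(a$level)])
    a[, c("level", "n", "info_rate")]
  }
  list(by_delay = agg(trials$T_s), by_prob = agg(trials$q))
}

#' Synthetic BOLD from a design matrix
#'
#' Generates multi-channel scanner-like time series as design times weights
#' plus slow cosine drift plus AR(1) Gaussian noise — the null/alternative
#' generator for \code{\link{fit_glm}} and
#' \code{\link{randomization_fwe_test}}.
#'
#' @param design a \code{\link{build_design_matrix}} result (or plain matrix).
#' @param weights columns-by-channels matrix of true effect weights (a vector
#'   is treated as one channel).
#' @param ar1 lag-one autocorrelation of the noise.
#' @param noise_sd marginal standard deviation of the noise.
#' @param drift_sd amplitude (sd scale) of the low-frequency cosine drift;
#'   two low-order cosines per series.
#' @return A scans-by-channels matrix with attribute \code{"weights"}.
#' @export
simulate_bold <- function(design, weights, ar1 = 0.3, noise_sd = 1,
                          drift_sd = 0.5) {
  X <- if (inherits(design, "savor_design")) design$X else as.matrix(design)
  W <- if (is.null(dim(weights))) matrix(weights, ncol = 1) else weights
  if (nrow(W) != ncol(X)) stop("weights rows must match design columns")
  n <- nrow(X); m <- ncol(W)
  tgrid <- seq_len(n) / n
  Y <- X %*% W
  for (j in seq_len(m)) {
    drift <- drift_sd * (rnorm(1) * cos(pi * tgrid) +
                         rnorm(1) * cos(2 * pi * tgrid))
    e <- if (ar1 == 0) rnorm(n, sd = noise_sd)
         else as.numeric(stats::arima.sim(list(ar = ar1), n = n,
                                          sd = noise_sd * sqrt(1 - ar1^2)))
    Y[, j] <- Y[, j] + drift + e
  }
  attr(Y, "weights") <- W
  Y
}
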