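#' @export
print.savor_fit <- function(x, ...) {
  cat(sprintf("Hierarchical savoring-model fit ('%s' variant)\n",
              x$model$name))
  cat(sprintf("  %d subjects, %d choices, %d EM iterations (%s)\n",
              length(x$subjects), x$n_trials, nrow(x$trace),
              if (x$converged) "converged" else "not converged"))
  cat("  Group means (natural scale, at the prior mean):\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Group- and subject-level estimates
#'
#' \code{coef} returns the model parameters on the natural scale: at
#' \code{level = "group"}, the untransformed group-prior mean (with fixed
#' parameters at their fixed values); at \code{level = "subject"}, a matrix of
#' per-subject MAP parameters.
#'
#' @param object a \code{\link{fit_savor}} result.
#' @param level \code{"group"} or \code{"subject"}.
#' @param ... unused.
#' @return Named numeric vector, or subjects-by-parameters matrix.
#' @export
coef.savor_fit <- function(object, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  if (level == "group") {
    p <- .assemble_params(object$prior$mean, object$model)
    return(unlist(p[c("R_plus", .param_names)]))
  }
  t(vapply(object$subjects,
           function(f) unlist(f$params[c("R_plus", .param_names)]),
           numeric(8)))
}

#' @export
summary.savor_fit <- function(object, ...) {
  h <- rbind(mean = object$prior$mean, sd = sqrt(object$prior$var))
  out <- list(model = object$model, transformed = h,
              natural_group = coef(object),
              subject = coef(object, level = "subject"),
              trace = object$trace, converged = object$converged,
              n_subjects = length(object$subjects),
              n_trials = object$n_trials)
  class(out) <- "summary.savor_fit"
  out
}

#' @export
print.summary.savor_fit <- function(x, ...) {
  cat(sprintf("Hierarchical savoring-model fit ('%s' variant)\n",
              x$model$name))
  cat(sprintf("  %d subjects, %d choices; EM %s in %d iterations\n",
              x$n_subjects, x$n_trials,
              if (x$converged) "converged" else "stopped", nrow(x$trace)))
  cat("\nGroup prior (transformed space):\n")
  print(round(x$transformed, 4))
  cat("\nGroup-mean parameters (natural scale):\n")
  print(round(x$natural_group, 4))
  cat("\nPer-subject MAP parameters (natural scale):\n")
  print(round(x$subject, 4))
  invisible(x)
}

#' Predicted information-choice probabilities
#'
#' @param object a \code{\link{fit_savor}} result.
#' @param newdata data frame with columns \code{q} and \code{T_s} (default:
#'   the union of fitted conditions) and, for \code{level = "subject"},
#'   optionally \code{subject}.
#' @param level \code{"group"} predicts at the untransformed group-prior
#'   mean; \code{"subject"} at each subject's MAP.
#' @param ... unused.
#' @return For \code{"group"}, \code{newdata} with a \code{p_info} column;
#'   for \code{"subject"}, additionally a \code{subject} column (long
#'   format).
#' @export
predict.savor_fit <- function(object, newdata = NULL,
                              level = c("group", "subject"), ...) {
  level <- match.arg(level)
  if (is.null(newdata)) {
    all_cond <- unique(do.call(rbind, lapply(object$counts,
                                             function(cc) cc[c("q", "T_s")])))
    newdata <- all_cond[order(all_cond$q, all_cond$T_s), , drop = FALSE]
    rownames(newdata) <- NULL
  }
  if (level == "group") {
    p <- .assemble_params(object$prior$mean, object$model)
    newdata$p_info <- choice_prob(p, newdata$q, newdata$T_s)
    return(newdata)
  }
  out <- lapply(names(object$subjects), function(s) {
    d <- newdata
    d$subject <- s
    d$p_info <- choice_prob(object$subjects[[s]]$params, d$q, d$T_s)
    d
  })
  do.call(rbind, out)
}

#' Simulate choice data from a fitted model
#'
#' Draws new choices for the fitted subjects at their MAP parameters, on a
#' freshly generated task of the same factorial structure.
#'
#' @param object a \code{\link{fit_savor}} result.
#' @param nsim number of simulated cohorts.
#' @param seed optional seed.
#' @param cfg task configuration (defaults to the standard task).
#' @param ... unused.
#' @return A list of \code{nsim} trial tables with simulated choices.
#' @export
simulate.savor_fit <- function(object, nsim = 1, seed = NULL,
                               cfg = task_config(), ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  subjects <- names(object$subjects)
  lapply(seq_len(nsim), function(k) {
    trials <- generate_trials(cfg, n_subjects = length(subjects))
    pr <- numeric(nrow(trials))
    for (i in seq_along(subjects)) {
      idx <- trials$subject == i
      pr[idx] <- choice_prob(object$subjects[[i]]$params,
                             trials$q[idx], trials$T_s[idx])
    }
    trials$choice <- ifelse(runif(nrow(trials)) < pr, "info", "noinfo")
    trials$cue <- ifelse(trials$choice == "noinfo", "NI",
                         ifelse(trials$outcome == 1, "S+", "S-"))
    trials$subject <- subjects[trials$subject]
    trials
  })
}

#' @export
logLik.savor_fit <- function(object, ...) {
  ll <- sum(vapply(seq_along(object$subjects), function(i) {
    cc <- object$counts[[i]]
    loglik_counts_cpp(par_vector(object$subjects[[i]]$params), cc$q, cc$T_s,
                      cc$n_info, cc$n_noinfo,
                      log(object$control$loglik_floor))
  }, numeric(1)))
  structure(ll, df = object$model$n_prior, nobs = object$n_trials,
            class = "logLik")
}

#' Observed vs predicted preference curves
#'
#' Plots the cohort's mean information-choice rate against delay (left) and
#' reward probability (right), with the fitted group-level prediction
#' overlaid.
#'
#' @param x a \code{\link{fit_savor}} result.
#' @param trials the trial table the model was fitted to (for the observed
#'   rates); omitted, only predictions are drawn.
#' @param ... passed to \code{plot}.
#' @export
plot.savor_fit <- function(x, trials = NULL, ...) {
  grid <- predict(x)
  by_T <- aggregate(p_info ~ T_s, grid, mean)
  by_q <- aggregate(p_info ~ q, grid, mean)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(by_T$T_s, by_T$p_info, type = "b", ylim = c(0, 1), pch = 19,
       xlab = "delay T (s)", ylab = "p(choose information)", ...)
  if (!is.null(trials)) {
    obs <- summarize_preferences(trials)$by_delay
    points(obs$level, obs$info_rate, col = 2, pch = 4)
    legend("bottomright", c("model", "observed"), col = c(1, 2),
           pch = c(19, 4), bty = "n")
  }
  plot(by_q$q, by_q$p_info, type = "b", ylim = c(0, 1), pch = 19,
       xlab = "reward probability q", ylab = "p(choose information)", ...)
  if (!is.null(trials)) {
    obs <- summarize_preferences(trials)$by_prob
    points(obs$level, obs$info_rate, col = 2, pch = 4)
  }
  invisible(x)
}

#' Choice residuals
#'
#' @param object a \code{\link{fit_savor}} result.
#' @param trials the trial table (defaults to refusing politely — residuals
#'   need the per-trial data, which the fit stores only as counts).
#' @param ... unused.
#' @return Numeric vector of per-trial response residuals (choice minus the
#'   subject-level predicted probability).
#' @export
residuals.savor_fit <- function(object, trials, ...) {
  if (missing(trials)) stop("supply the trial table to compute residuals")
  pr <- numeric(nrow(trials))
  for (s in names(object$subjects)) {
    idx <- as.character(trials$subject) == s
    pr[idx] <- choice_prob(object$subjects[[s]]$params, trials$q[idx],
                           trials$T_s[idx])
  }
  .choice01(trials$choice) - pr
}
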