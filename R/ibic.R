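#' Integrated BIC of a hierarchical fit
#'
#' Estimates the log marginal likelihood of the whole data set under the
#' fitted group prior by Monte-Carlo integration: for each subject, \code{K}
#' parameter vectors are drawn from the prior, the subject's choice
#' likelihood is averaged over the draws (log-sum-exp stabilized), and the
#' per-subject logs are summed. The integrated Bayesian information criterion
#' then penalizes the number of fitted group-prior parameters:
#' \deqn{\mathrm{iBIC} = -2\,\log p(D\mid\theta^{ML}) + |M|\,\log|D|,}
#' where \eqn{|M|} counts the prior means and variances and \eqn{|D|} the
#' total number of choices across subjects.
#'
#' @param fit a \code{\link{fit_savor}} result.
#' @param K Monte-Carlo samples per subject (\eqn{\ge 100} recommended).
#' @param seed optional seed for the prior draws.
#' @return A list of class \code{savor_ibic}: \code{logp}, \code{n_prior}
#'   (\eqn{|M|}), \code{n_data} (\eqn{|D|}), \code{ibic}, \code{K},
#'   \code{se} (Monte-Carlo standard error of \code{logp}), \code{seed},
#'   \code{n_floored} (draws that hit the likelihood floor).
#' @export
ibic <- function(fit, K = 1000L, seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  spec <- fit$model
  prior <- fit$prior
  d <- length(prior$mean)
  floor_log <- log(fit$control$loglik_floor)
  logp <- 0
  se2 <- 0
  n_floored <- 0L
  for (cc in fit$counts) {
    H <- matrix(rnorm(K * d, rep(prior$mean, each = K),
                      rep(sqrt(prior$var), each = K)), nrow = K)
    colnames(H) <- names(prior$mean)
    P <- .batch_assemble(H, spec)
    ll <- loglik_counts_batch_cpp(P, cc$q, cc$T_s, cc$n_info, cc$n_noinfo,
                                  floor_log)
    ntot <- sum(cc$n_info + cc$n_noinfo)
    n_floored <- n_floored + sum(ll <= ntot * floor_log + 1e-9)
    m <- max(ll)
    w <- exp(ll - m)
    logp_i <- m + log(mean(w))
    # delta-method SE of log-mean over K draws
    se2 <- se2 + var(w) / (K * mean(w)^2)
    logp <- logp + logp_i
  }
  n_data <- sum(vapply(fit$counts,
                       function(cc) sum(cc$n_info + cc$n_noinfo),
                       numeric(1)))
  out <- list(model = spec$name, logp = logp, n_prior = spec$n_prior,
              n_data = n_data,
              ibic = -2 * logp + spec$n_prior * log(n_data),
              K = as.integer(K), se = sqrt(se2), seed = seed,
              n_floored = n_floored)
  class(out) <- "savor_ibic"
  out
}

#' @export
print.savor_ibic <- function(x, ...) {
  cat(sprintf(
    "iBIC ('%s'): %.2f  [logp = %.2f (MC se %.2f), |M| = %d, |D| = %d, K = %d]\n",
    x$model, x$ibic, x$logp, x$se, x$n_prior, x$n_data, x$K))
  invisible(x)
}

#' Fit and compare model variants by iBIC
#'
#' Fits each requested variant of the savoring model hierarchically to the
#' same cohort, computes each fit's integrated BIC, and ranks them (lowest
#' iBIC preferred). A fit failure in one variant is reported but does not
#' abort the others.
#'
#' @param trials cohort trial table (see \code{\link{fit_savor}}).
#' @param models character vector of variant names.
#' @param K Monte-Carlo samples per subject for \code{\link{ibic}}.
#' @param control a \code{\link{savor_control}}.
#' @param seed integer seed (used, with offsets, for every fit and iBIC).
#' @return A data frame of class \code{savor_comparison}: \code{model},
#'   \code{logp}, \code{n_prior}, \code{n_data}, \code{ibic}, \code{se},
#'   \code{rank}, \code{preferred}; the fits are attached as attribute
#'   \code{"fits"}.
#' @export
compare_savor_models <- function(trials,
                                 models = c("full", "noboost",
                                            "noanticipation"),
                                 K = 1000L, control = savor_control(),
                                 seed = NULL) {
  fits <- list(); scores <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    s_i <- if (is.null(seed)) NULL else seed + i
    res <- tryCatch({
      f <- fit_savor(trials, model = m, control = control, seed = s_i)
      list(fit = f, ib = ibic(f, K = K, seed = s_i))
    }, error = function(e) {
      warning(sprintf("model '%s' failed: %s", m, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    fits[[m]] <- res$fit
    scores[[m]] <- res$ib
  }
  if (!length(scores)) stop("all model fits failed")
  tab <- do.call(rbind, lapply(scores, function(x)
    data.frame(model = x$model, logp = x$logp, n_prior = x$n_prior,
               n_data = x$n_data, ibic = x$ibic, se = x$se)))
  tab$rank <- rank(tab$ibic, ties.method = "first")
  tab$preferred <- tab$rank == 1L
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("savor_comparison", "data.frame")
  tab
}

#' @export
print.savor_comparison <- function(x, ...) {
  cat("Model comparison by integrated BIC (lower is better):\n")
  print.data.frame(cbind(x[c("model", "logp", "n_prior", "n_data")],
                         ibic = round(x$ibic, 2), se = round(x$se, 3),
                         rank = x$rank, preferred = x$preferred),
                   row.names = FALSE)
  invisible(x)
}
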