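#' Mass-univariate ordinary least squares
#'
#' Fits \code{Y = X beta + e} independently per channel (column of \code{Y})
#' and returns coefficient estimates with t-statistics for the tested
#' columns. The design must have full column rank; a rank-deficient design is
#' an error naming the collinear columns.
#'
#' @param Y scans-by-channels response matrix (a vector is one channel).
#' @param X design matrix or \code{\link{build_design_matrix}} result.
#' @param tested names (or indices) of the columns whose t-statistics are
#'   wanted; default all task columns (for a \code{savor_design}) or all
#'   columns.
#' @return A list of class \code{savor_glm}: \code{beta} (columns-by-channels),
#'   \code{sigma2} residual variance per channel, \code{t} (tested
#'   columns-by-channels), \code{se}, \code{df}, \code{tested}.
#' @export
fit_glm <- function(Y, X, tested = NULL) {
  des <- NULL
  if (inherits(X, "savor_design")) { des <- X; X <- des$X }
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have matching rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(tested)) tested <- if (!is.null(des)) des$task_cols
                                 else colnames(X)
  if (is.numeric(tested)) tested <- colnames(X)[tested]
  if (!all(tested %in% colnames(X)))
    stop("tested columns not in design: ",
         paste(setdiff(tested, colnames(X)), collapse = ", "))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- nrow(X) - qx$rank
  if (df <= 0) stop("no residual degrees of freedom")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  Ri <- chol2inv(qr.R(qx))
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qx$pivot, qx$pivot] <- Ri
  vfac <- diag(XtXinv)[match(tested, colnames(X))]
  se <- sqrt(outer(vfac, sigma2))
  tstat <- beta[tested, , drop = FALSE] / se
  tstat[se == 0] <- 0
  out <- list(beta = beta, sigma2 = sigma2,
              t = tstat, se = se, df = df, tested = tested)
  class(out) <- "savor_glm"
  out
}

#' @export
print.savor_glm <- function(x, ...) {
  cat(sprintf("GLM fit: %d channel(s), df = %d\n", ncol(x$beta), x$df))
  cat("t-statistics of tested columns:\n")
  print(round(x$t, 3))
  invisible(x)
}

#' Fourier phase randomization of a time series
#'
#' Produces a surrogate series with exactly the amplitude spectrum of the
#' input but phases of the positive frequencies drawn uniformly from
#' \eqn{(-\pi, \pi]}. Negative frequencies carry the mirrored conjugates and
#' the DC (and, for even length, Nyquist) terms are kept unchanged, so the
#' output is real with the original mean and power spectrum.
#'
#' @param x finite numeric series.
#' @return Surrogate series of the same length.
#' @export
phase_scramble <- function(x) {
  n <- length(x)
  if (any(!is.finite(x))) stop("series must be finite")
  if (n < 3) return(x)
  f <- fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half >= 1) {
    ph <- runif(half, -pi, pi)
    k <- 2:(half + 1)
    f[k] <- Mod(f[k]) * exp(1i * ph)
    f[n + 2 - k] <- Conj(f[k])
  }
  Re(fft(f, inverse = TRUE)) / n
}

# one-sample t across subjects, per channel (rows = subjects)
.group_t <- function(B) {
  n <- nrow(B)
  m <- colMeans(B)
  s <- sqrt(colSums(sweep(B, 2, m)^2) / (n - 1))
  tt <- m / (s / sqrt(n))
  tt[s == 0] <- 0
  tt
}

#' Phase-randomization test with max-statistic FWE correction
#'
#' Tests, across a cohort, whether one model-derived regressor explains the
#' channel time series beyond what slowly varying signals of the same power
#' spectrum would. First level: per subject, the tested column of the design
#' is replaced by a phase-scrambled surrogate (all other columns kept) and
#' the GLM refit \code{n_scrambles} times. Second level: \code{n_resamples}
#' times, one scrambled result is drawn per subject and a one-sample t across
#' subjects is computed per channel; the maximum statistic over the channel
#' family (or the mean over a given cluster) is recorded, forming the null
#' distribution of the familywise maximum. The observed group statistic per
#' channel is compared against it with the add-one rule,
#' \eqn{p = (1 + \#\{null \ge t\})/(\mathrm{resamples} + 1)}, giving
#' FWE-corrected p-values.
#'
#' @param Y_list per-subject scans-by-channels matrices.
#' @param design_list per-subject design matrices (or
#'   \code{\link{build_design_matrix}} results), same order.
#' @param tested name of the single regressor under test.
#' @param n_scrambles phase-scrambled refits per subject.
#' @param n_resamples second-level resamples forming the null.
#' @param statistic \code{"max"} (default) or \code{"cluster_mean"}.
#' @param cluster channel indices defining the cluster for
#'   \code{"cluster_mean"}.
#' @return A list of class \code{savor_fwe}: \code{observed_t} per channel,
#'   \code{null_max} (length \code{n_resamples}), \code{p_fwe} per channel,
#'   plus the settings.
#' @export
randomization_fwe_test <- function(Y_list, design_list, tested,
                                   n_scrambles = 100L, n_resamples = 1000L,
                                   statistic = c("max", "cluster_mean"),
                                   cluster = NULL) {
  statistic <- match.arg(statistic)
  n_sub <- length(Y_list)
  if (n_sub < 2) stop("at least 2 subjects are required")
  if (n_scrambles < 1) stop("n_scrambles must be >= 1")
  if (length(design_list) != n_sub)
    stop("Y_list and design_list lengths differ")
  getX <- function(d) if (inherits(d, "savor_design")) d$X else as.matrix(d)
  n_chan <- ncol(as.matrix(Y_list[[1]]))
  obs_b <- matrix(NA_real_, n_sub, n_chan)
  null_b <- array(NA_real_, c(n_sub, n_scrambles, n_chan))
  for (s in seq_len(n_sub)) {
    X <- getX(design_list[[s]])
    if (!tested %in% colnames(X))
      stop("tested column '", tested, "' missing for subject ", s)
    Y <- as.matrix(Y_list[[s]])
    obs_b[s, ] <- fit_glm(Y, X, tested = tested)$beta[tested, ]
    xcol <- X[, tested]
    for (j in seq_len(n_scrambles)) {
      X[, tested] <- phase_scramble(xcol)
      null_b[s, j, ] <- fit_glm(Y, X, tested = tested)$beta[tested, ]
    }
  }
  fam_stat <- function(tt) {
    if (statistic == "max") max(tt)
    else mean(tt[cluster])
  }
  if (statistic == "cluster_mean" && is.null(cluster))
    stop("cluster indices are required for the cluster-mean statistic")
  observed_t <- .group_t(obs_b)
  null_max <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    pick <- sample.int(n_scrambles, n_sub, replace = TRUE)
    B <- matrix(0, n_sub, n_chan)
    for (s in seq_len(n_sub)) B[s, ] <- null_b[s, pick[s], ]
    null_max[r] <- fam_stat(.group_t(B))
  }
  p_fwe <- vapply(observed_t, function(tt)
    (1 + sum(null_max >= tt)) / (n_resamples + 1), numeric(1))
  out <- list(observed_t = observed_t, null_max = null_max, p_fwe = p_fwe,
              tested = tested, n_scrambles = as.integer(n_scrambles),
              n_resamples = as.integer(n_resamples), statistic = statistic)
  class(out) <- "savor_fwe"
  out
}

#' @export
print.savor_fwe <- function(x, ...) {
  cat(sprintf(
    "Phase-randomization FWE test of '%s' (%d scrambles/subject, %d resamples)\n",
    x$tested, x$n_scrambles, x$n_resamples))
  print(data.frame(channel = seq_along(x$observed_t),
                   t = round(x$observed_t, 3),
                   p_fwe = round(x$p_fwe, 4)))
  invisible(x)
}
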