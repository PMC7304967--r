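# gain (eta), probability scale, outcome value and rate for a cue/valence pair
.signal_gain <- function(p, q, T, cue, valence) {
  R <- if (valence == "+") p$R_plus else p$R_minus
  nu <- if (valence == "+") p$nu_plus else p$nu_minus
  if (cue == "NI") {
    scale <- if (valence == "+") q else 1 - q
    return(list(eta = p$eta0, scale = scale, R = R, nu = nu))
  }
  match_val <- (cue == "S+") == (valence == "+")
  if (!match_val) return(list(eta = 0, scale = 0, R = R, nu = nu))
  d <- solve_arpe(p, q, T)
  delta <- if (cue == "S+") d$delta_plus else d$delta_minus
  list(eta = p$eta0 + p$C * abs(delta), scale = 1, R = R, nu = nu)
}

#' Model-predicted signals during the waiting period
#'
#' Time courses of the model's latent signals over a waiting period of length
#' \code{T}, as functions of time \code{t} since cue onset (zero outside
#' \eqn{[0, T]}):
#' \itemize{
#' \item \code{anticipation_timecourse}: the anticipatory utility
#'   \eqn{V_{Ant,\pm}(t) = R^{\pm}\eta/(\nu^{\pm}-\gamma)\,
#'   (e^{-\gamma(T-t)}-e^{-\nu^{\pm}(T-t)})}, the discounted integral of the
#'   urgency signal over the remaining wait;
#' \item \code{urgency_timecourse}: the anticipation urgency
#'   \eqn{a(t) = R^{\pm}\eta\, e^{-\nu^{\pm}(T-t)}}, ramping up towards the
#'   outcome;
#' \item \code{discounted_reward_timecourse}: the conventionally discounted
#'   outcome value \eqn{R^{\pm} e^{-\gamma(T-t)}}.
#' }
#' After a predictive cue (\code{"S+"}/\code{"S-"}), the matching valence
#' carries the boosted weight \eqn{\eta = \eta_0 + C|\delta^{\pm}|} and the
#' opposite valence is zero; after a no-information cue (\code{"NI"}) both
#' valences are present, unboosted (\eqn{\eta = \eta_0}) and scaled by
#' \eqn{q} (positive) or \eqn{1-q} (negative) — no prediction error occurs.
#'
#' @param params a \code{\link{savor_params}} object.
#' @param q reward probability of the condition.
#' @param T delay of the condition (s).
#' @param cue \code{"S+"}, \code{"S-"} or \code{"NI"}.
#' @param t times since cue onset (s); vectorized.
#' @param valence \code{"+"} or \code{"-"} domain of the signal.
#' @return Numeric vector of signal values at \code{t}.
#' @export
anticipation_timecourse <- function(params, q, T, cue = c("S+", "S-", "NI"),
                                    t, valence = c("+", "-")) {
  cue <- match.arg(cue); valence <- match.arg(valence)
  p <- as_savor_params(params)
  g <- .signal_gain(p, q, T, cue, valence)
  tau <- T - t
  v <- g$scale * g$eta * .acoef(g$R, g$nu, p$gamma, pmax(tau, 0))
  v[t < 0 | t > T] <- 0
  v
}

#' @rdname anticipation_timecourse
#' @export
urgency_timecourse <- function(params, q, T, cue = c("S+", "S-", "NI"), t,
                               valence = c("+", "-")) {
  cue <- match.arg(cue); valence <- match.arg(valence)
  p <- as_savor_params(params)
  g <- .signal_gain(p, q, T, cue, valence)
  v <- g$scale * g$eta * g$R * exp(-g$nu * pmax(T - t, 0))
  v[t < 0 | t > T] <- 0
  v
}

#' @rdname anticipation_timecourse
#' @export
discounted_reward_timecourse <- function(params, q, T,
                                         cue = c("S+", "S-", "NI"), t,
                                         valence = c("+", "-")) {
  cue <- match.arg(cue); valence <- match.arg(valence)
  p <- as_savor_params(params)
  R <- if (valence == "+") p$R_plus else p$R_minus
  scale <- if (cue == "NI") { if (valence == "+") q else 1 - q }
           else if ((cue == "S+") == (valence == "+")) 1 else 0
  v <- scale * R * exp(-p$gamma * pmax(T - t, 0))
  v[t < 0 | t > T] <- 0
  v
}

#' Event-locked prediction-error amplitudes
#'
#' \code{arpe_event_amplitude} returns the self-consistent aRPE elicited at a
#' cue: \eqn{\delta^+} for \code{"S+"}, \eqn{\delta^-} for \code{"S-"}, and 0
#' for the no-information cue (which resolves nothing, hence no prediction
#' error). \code{state_prediction_error} is the unsigned outcome-identity
#' error \eqn{|1-q|} (\code{"S+"}) or \eqn{|0-q|} (\code{"S-"}) used as a
#' control regressor. \code{standard_rpe} is the prediction error of a
#' conventional discounted-reward model (the aRPE with
#' \eqn{C = \eta_0 = 0}): \eqn{(1-q)(B^+-B^-)} for \code{"S+"} and
#' \eqn{-q(B^+-B^-)} for \code{"S-"}.
#'
#' @inheritParams anticipation_timecourse
#' @param cue character vector of cue identities (recycled against \code{q},
#'   \code{T}).
#' @return Numeric vector of amplitudes.
#' @export
arpe_event_amplitude <- function(params, q, T, cue) {
  n <- max(length(q), length(T), length(cue))
  q <- rep_len(q, n); T <- rep_len(T, n); cue <- rep_len(cue, n)
  d <- solve_arpe(params, q, T)
  ifelse(cue == "S+", d$delta_plus,
         ifelse(cue == "S-", d$delta_minus, 0))
}

#' @rdname arpe_event_amplitude
#' @export
state_prediction_error <- function(q, cue) {
  n <- max(length(q), length(cue))
  q <- rep_len(q, n); cue <- rep_len(cue, n)
  ifelse(cue == "S+", abs(1 - q), ifelse(cue == "S-", abs(q), 0))
}

#' @rdname arpe_event_amplitude
#' @export
standard_rpe <- function(params, q, T, cue) {
  p <- as_savor_params(params)
  n <- max(length(q), length(T), length(cue))
  q <- rep_len(q, n); T <- rep_len(T, n); cue <- rep_len(cue, n)
  gap <- (p$R_plus - p$R_minus) * exp(-p$gamma * T)
  ifelse(cue == "S+", (1 - q) * gap, ifelse(cue == "S-", -q * gap, 0))
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma-density response minus a scaled
#' gamma-density undershoot, sampled at the microtime step and normalized to
#' unit integral (so the sampled values approximate a continuous density and
#' are independent of the sampling step).
#'
#' @param dt sampling step (s).
#' @param duration kernel length (s).
#' @param peak_delay,undershoot_delay gamma means (s) of response and
#'   undershoot.
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio response-to-undershoot amplitude ratio.
#' @return Numeric kernel vector with attribute \code{"time"}.
#' @export
canonical_hrf <- function(dt = 0.1, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 6) {
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  h <- h / (sum(h) * dt)
  attr(h, "time") <- t
  h
}

#' Configuration of GLM design-matrix construction
#'
#' @param TR repetition time (s).
#' @param dt microtime step (s) at which signals are built before HRF
#'   convolution.
#' @param highpass high-pass cutoff (s) of the discrete-cosine drift basis
#'   added as nuisance columns (\code{NULL} to omit).
#' @param short_delay delays \code{<= short_delay} get their cue onsets
#'   modeled in a separate column and are excluded from the time-varying and
#'   parametric cue columns.
#' @param center_modulators mean-center parametric modulator amplitudes
#'   across their events before convolution.
#' @param ev_boxcar add a waiting-period boxcar parametrically modulated by
#'   the constant expected outcome value \eqn{qR^+ + (1-q)R^-} (control
#'   column).
#' @param ramp add a linear 0-to-1 ramp over each anticipatory period
#'   (control column).
#' @param run_padding seconds of scanning appended after the last outcome of
#'   a run.
#' @param scans_per_run fixed number of scans per run (\code{NULL}: derived
#'   from run duration and \code{run_padding}).
#' @return List of class \code{savor_design_config}.
#' @export
design_config <- function(TR = 3.36, dt = 0.1, highpass = 128,
                          short_delay = 1, center_modulators = TRUE,
                          ev_boxcar = FALSE, ramp = FALSE, run_padding = 16,
                          scans_per_run = NULL) {
  structure(list(TR = TR, dt = dt, highpass = highpass,
                 short_delay = short_delay,
                 center_modulators = center_modulators,
                 ev_boxcar = ev_boxcar, ramp = ramp,
                 run_padding = run_padding, scans_per_run = scans_per_run),
            class = "savor_design_config")
}

# discrete cosine high-pass basis: cosines with period > cutoff
.dct_basis <- function(n_scans, TR, cutoff) {
  order <- floor(2 * n_scans * TR / cutoff)
  if (order < 1) return(NULL)
  t <- seq_len(n_scans) - 0.5
  B <- sapply(seq_len(order), function(k)
    sqrt(2 / n_scans) * cos(pi * k * t / n_scans))
  B <- matrix(B, nrow = n_scans)
  colnames(B) <- paste0("dct", seq_len(order))
  B
}

# place stick events on the microtime grid as unit-area impulses
# (height amplitude/dt), so convolution with the density-normalized HRF
# yields amplitude * kernel independent of the microtime step
.sticks <- function(onsets, amplitudes, L, dt) {
  x <- numeric(L)
  if (!length(onsets)) return(x)
  idx <- pmin(pmax(round(onsets / dt) + 1L, 1L), L)
  for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + amplitudes[i] / dt
  x
}

# boxcar / sampled-signal support on [t0, t1]
.interval_idx <- function(t0, t1, L, dt) {
  i0 <- pmin(pmax(floor(t0 / dt) + 1L, 1L), L)
  i1 <- pmin(pmax(floor(t1 / dt) + 1L, 1L), L)
  if (i1 < i0) integer(0) else i0:i1
}

# trapezoid-rule weights (half at both edges) making the discrete
# convolution a second-order approximation of the continuous integral
.trap <- function(v) {
  n <- length(v)
  if (n >= 2) { v[1] <- v[1] / 2; v[n] <- v[n] / 2 }
  v
}

#' Build a GLM design matrix from an event table
#'
#' Assembles the model-based GLM for one subject: onset sticks (trial
#' screen, cue, outcome, with short-delay cues in their own column),
#' parametric modulators (aRPE at information cues; outcome value at
#' outcomes), the model's time-varying waiting-period signals (anticipatory
#' utility, discounted outcome value and anticipation urgency, each split by
#' valence) and nuisance columns (waiting-period boxcar, per-run intercepts
#' and a discrete-cosine high-pass basis). Task columns are built at
#' microtime resolution, convolved with the canonical HRF and sampled at the
#' scan times; parametric modulators are mean-centered, never orthogonalized.
#' Trials at the shortest delay are excluded from the time-varying and
#' parametric cue columns (their cue onsets get a separate stick column so
#' outcome-related variance cannot leak into the prediction-error
#' regressors). All-zero task columns (e.g. an empty short-delay column) are
#' dropped.
#'
#' @param events one subject's trial/event table: columns \code{run},
#'   \code{q}, \code{T_s}, \code{cue}, \code{outcome}, \code{t_screen},
#'   \code{t_cue}, \code{t_outcome} (see \code{\link{generate_trials}} and
#'   \code{\link{simulate_choices}}).
#' @param params the subject's \code{\link{savor_params}} (typically MAP
#'   estimates from \code{\link{fit_savor}}).
#' @param config a \code{\link{design_config}}.
#' @return An object of class \code{savor_design}: list with the
#'   scans-by-columns matrix \code{X}, \code{TR}, \code{dt},
#'   \code{frame_times}, \code{run} (run index per scan), \code{task_cols},
#'   \code{nuisance_cols} and \code{config}.
#' @export
build_design_matrix <- function(events, params, config = design_config()) {
  p <- as_savor_params(params)
  if (nrow(events) > 0) {
    need <- c("run", "q", "T_s", "cue", "outcome", "t_screen", "t_cue",
              "t_outcome")
    miss <- setdiff(need, names(events))
    if (length(miss))
      stop("event table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(events$t_screen < 0)) stop("negative onsets in event table")
    if (any(!(events$t_screen <= events$t_cue &
              events$t_cue < events$t_outcome)))
      stop("onsets must increase within each trial")
    if (any(abs(events$t_outcome - events$t_cue - events$T_s) > 1e-6))
      stop("outcome onset minus cue onset must equal the delay T_s")
  }
  runs <- if (nrow(events)) sort(unique(events$run)) else 1L
  hrf <- canonical_hrf(dt = config$dt)
  task_names <- c("screen", "cue", "cue_short", "outcome", "arpe",
                  "outcome_value", "ant_pos", "ant_neg", "ev_pos", "ev_neg",
                  "urg_pos", "urg_neg", "wait_boxcar")
  if (config$ev_boxcar) task_names <- c(task_names, "ev_const")
  if (config$ramp) task_names <- c(task_names, "ramp")

  per_run <- lapply(runs, function(r) {
    ev <- if (nrow(events)) events[events$run == r, , drop = FALSE]
          else events
    dur <- if (nrow(ev)) max(ev$t_outcome) + config$run_padding
           else config$run_padding
    n_scans <- as.integer(if (!is.null(config$scans_per_run))
      config$scans_per_run else ceiling(dur / config$TR))
    L <- ceiling(n_scans * config$TR / config$dt) + 1L
    M <- matrix(0, L, length(task_names),
                dimnames = list(NULL, task_names))
    if (nrow(ev)) {
      short <- ev$T_s <= config$short_delay
      M[, "screen"] <- .sticks(ev$t_screen, rep(1, nrow(ev)), L, config$dt)
      M[, "cue"] <- .sticks(ev$t_cue[!short], rep(1, sum(!short)), L,
                            config$dt)
      M[, "cue_short"] <- .sticks(ev$t_cue[short], rep(1, sum(short)), L,
                                  config$dt)
      M[, "outcome"] <- .sticks(ev$t_outcome, rep(1, nrow(ev)), L,
                                config$dt)
      info <- ev$cue %in% c("S+", "S-") & !short
      if (any(info)) {
        amp <- arpe_event_amplitude(p, ev$q[info], ev$T_s[info],
                                    ev$cue[info])
        if (config$center_modulators) amp <- amp - mean(amp)
        M[, "arpe"] <- .sticks(ev$t_cue[info], amp, L, config$dt)
      }
      oval <- ifelse(ev$outcome == 1, p$R_plus, p$R_minus)
      if (config$center_modulators) oval <- oval - mean(oval)
      M[, "outcome_value"] <- .sticks(ev$t_outcome, oval, L, config$dt)
      for (i in which(!short)) {
        idx <- .interval_idx(ev$t_cue[i], ev$t_outcome[i], L, config$dt)
        tt <- (idx - 1) * config$dt - ev$t_cue[i]
        for (val in c("+", "-")) {
          sfx <- if (val == "+") "pos" else "neg"
          M[idx, paste0("ant_", sfx)] <- M[idx, paste0("ant_", sfx)] +
            .trap(anticipation_timecourse(p, ev$q[i], ev$T_s[i], ev$cue[i],
                                          tt, val))
          M[idx, paste0("ev_", sfx)] <- M[idx, paste0("ev_", sfx)] +
            .trap(discounted_reward_timecourse(p, ev$q[i], ev$T_s[i],
                                               ev$cue[i], tt, val))
          M[idx, paste0("urg_", sfx)] <- M[idx, paste0("urg_", sfx)] +
            .trap(urgency_timecourse(p, ev$q[i], ev$T_s[i], ev$cue[i], tt,
                                     val))
        }
      }
      ev_amp <- ev$q * p$R_plus + (1 - ev$q) * p$R_minus
      if (config$ev_boxcar && config$center_modulators)
        ev_amp <- ev_amp - mean(ev_amp)
      for (i in seq_len(nrow(ev))) {
        idx <- .interval_idx(ev$t_cue[i], ev$t_outcome[i], L, config$dt)
        M[idx, "wait_boxcar"] <- M[idx, "wait_boxcar"] +
          .trap(rep(1, length(idx)))
        if (config$ev_boxcar)
          M[idx, "ev_const"] <- M[idx, "ev_const"] +
            .trap(rep(ev_amp[i], length(idx)))
        if (config$ramp && length(idx) > 1)
          M[idx, "ramp"] <- M[idx, "ramp"] +
            .trap(seq(0, 1, length.out = length(idx)))
      }
    }
    Xr <- apply(M, 2, function(x)
      stats::convolve(x, rev(hrf), type = "open")[seq_len(L)] * config$dt)
    micro_t <- (seq_len(L) - 1) * config$dt
    scan_t <- (seq_len(n_scans) - 1) * config$TR
    Xs <- apply(Xr, 2, function(x)
      stats::approx(micro_t, x, xout = scan_t, rule = 2)$y)
    Xs <- matrix(Xs, nrow = n_scans, dimnames = list(NULL, colnames(M)))
    list(X = Xs, n_scans = n_scans)
  })

  X_task <- do.call(rbind, lapply(per_run, `[[`, "X"))
  n_per_run <- vapply(per_run, `[[`, integer(1), "n_scans")
  run_id <- rep(runs, n_per_run)

  nuis <- matrix(1, nrow(X_task), 0)
  for (j in seq_along(runs)) {
    block <- matrix(0, nrow(X_task), 1)
    block[run_id == runs[j], 1] <- 1
    colnames(block) <- paste0("run", runs[j])
    nuis <- cbind(nuis, block)
    if (!is.null(config$highpass)) {
      B <- .dct_basis(n_per_run[j], config$TR, config$highpass)
      if (!is.null(B)) {
        D <- matrix(0, nrow(X_task), ncol(B))
        D[run_id == runs[j], ] <- B
        colnames(D) <- paste0("run", runs[j], "_", colnames(B))
        nuis <- cbind(nuis, D)
      }
    }
  }
  keep <- colSums(abs(X_task)) > 0
  X_task <- X_task[, keep, drop = FALSE]
  X <- cbind(X_task, nuis)
  out <- list(X = X, TR = config$TR, dt = config$dt,
              frame_times = (seq_len(nrow(X)) - 1) * config$TR,
              run = run_id, task_cols = colnames(X_task),
              nuisance_cols = colnames(nuis), config = config)
  class(out) <- "savor_design"
  out
}

#' @export
print.savor_design <- function(x, ...) {
  cat(sprintf("GLM design: %d scans (TR %.2f s, %d run(s)), %d columns\n",
              nrow(x$X), x$TR, length(unique(x$run)), ncol(x$X)))
  cat("  task:", paste(x$task_cols, collapse = ", "), "\n")
  cat("  nuisance:", length(x$nuisance_cols), "columns\n")
  invisible(x)
}

#' Psychophysiological interaction regressor
#'
#' Elementwise product of a seed (physiological) time series and a
#' psychological time series, each mean-centered first; the psychological
#' series can be z-scored (as done for prediction-error modulators whose
#' units are arbitrary). The product is formed in signal space, without
#' hemodynamic deconvolution.
#'
#' @param seed_series numeric seed-region time series.
#' @param psych_series numeric psychological series of equal length.
#' @param zscore divide the centered psychological series by its standard
#'   deviation.
#' @return Numeric interaction series.
#' @export
ppi_regressor <- function(seed_series, psych_series, zscore = FALSE) {
  if (length(seed_series) != length(psych_series))
    stop("seed and psychological series must have equal length")
  s <- seed_series - mean(seed_series)
  p <- psych_series - mean(psych_series)
  if (zscore) {
    sp <- sd(p)
    if (sp > 0) p <- p / sp
  }
  s * p
}
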