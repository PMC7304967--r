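test_that("waiting-period signals obey their boundary values", {
  p <- boost_params()
  q <- 0.6; T <- 20
  d <- solve_arpe(p, q, T)
  # anticipation vanishes at outcome delivery
  expect_equal(anticipation_timecourse(p, q, T, "S+", T, "+"), 0)
  expect_equal(anticipation_timecourse(p, q, T, "S-", T, "-"), 0)
  # at cue onset with no boosting it equals eta0 * A
  p0 <- savor_params(R_minus = -0.2, eta0 = 0.5, C = 0, nu_plus = 0.15,
                     nu_minus = 0.15, gamma = 0.002, sigma = 0.15)
  expect_equal(anticipation_timecourse(p0, q, T, "S+", 0, "+"),
               0.5 * anticipation_coefficient(p0, T, "+"))
  # urgency peaks at outcome time at the boosted drive R (eta0 + C|delta|)
  expect_equal(urgency_timecourse(p, q, T, "S+", T, "+"),
               1 * (p$eta0 + p$C * abs(d$delta_plus)))
  # urgency ramps up monotonically over the wait
  tt <- seq(0, T, by = 0.5)
  expect_true(all(diff(urgency_timecourse(p, q, T, "S+", tt, "+")) > 0))
  # discounted outcome value reaches R at delivery, decays backwards
  expect_equal(discounted_reward_timecourse(p, q, T, "S+", T, "+"), 1)
  expect_equal(discounted_reward_timecourse(p, q, T, "S-", T - 10, "-"),
               p$R_minus * exp(-p$gamma * 10))
  pg0 <- savor_params(R_minus = -0.2, eta0 = 0.5, C = 0, gamma = 0)
  expect_equal(discounted_reward_timecourse(pg0, q, T, "S+", tt, "+"),
               rep(1, length(tt)))
  # signals vanish outside the waiting window
  expect_equal(anticipation_timecourse(p, q, T, "S+", c(-1, T + 1), "+"),
               c(0, 0))
})

test_that("anticipation is the discounted integral of urgency", {
  set.seed(55)
  for (i in 1:8) {
    p <- rand_params()
    q <- runif(1); T <- runif(1, 2, 50)
    for (cue in c("S+", "S-", "NI")) for (val in c("+", "-")) {
      for (t0 in c(0, 0.3 * T, 0.9 * T)) {
        quad <- stats::integrate(function(tp)
          exp(-p$gamma * (tp - t0)) *
            urgency_timecourse(p, q, T, cue, tp, val),
          t0, T, rel.tol = 1e-11, abs.tol = 1e-13)$value
        expect_equal(anticipation_timecourse(p, q, T, cue, t0, val), quad,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("no-information signals are probability-scaled and unboosted", {
  p <- boost_params()
  q <- 0.7; T <- 10
  p_unboost <- savor_params(R_minus = p$R_minus, eta0 = p$eta0, C = 0,
                            nu_plus = p$nu_plus, nu_minus = p$nu_minus,
                            gamma = p$gamma, sigma = p$sigma)
  tt <- seq(0, T, by = 1)
  expect_equal(anticipation_timecourse(p, q, T, "NI", tt, "+"),
               q * anticipation_timecourse(p_unboost, q, T, "S+", tt, "+"))
  expect_equal(anticipation_timecourse(p, q, T, "NI", tt, "-"),
               (1 - q) *
                 anticipation_timecourse(p_unboost, q, T, "S-", tt, "-"))
  expect_equal(discounted_reward_timecourse(p, q, T, "NI", tt, "+"),
               q * exp(-p$gamma * (T - tt)))
  # mismatched valence after a predictive cue carries no signal
  expect_equal(anticipation_timecourse(p, q, T, "S+", tt, "-"),
               rep(0, length(tt)))
  expect_equal(urgency_timecourse(p, q, T, "S-", tt, "+"),
               rep(0, length(tt)))
})

test_that("event amplitudes: aRPE, state and standard prediction errors", {
  p <- boost_params()
  d <- solve_arpe(p, 0.25, 20)
  expect_equal(
    arpe_event_amplitude(p, c(0.25, 0.25, 0.25), c(20, 20, 20),
                         c("S+", "S-", "NI")),
    c(d$delta_plus, d$delta_minus, 0))
  expect_equal(arpe_event_amplitude(p, 1, 10, "S+"), 0)
  # SPE is the unsigned identity error
  expect_equal(state_prediction_error(0.95, "S+"), 0.05)
  expect_equal(state_prediction_error(0.95, "S-"), 0.95)
  expect_equal(state_prediction_error(0.5, c("S+", "S-")), c(0.5, 0.5))
  # standard RPE equals the aRPE of the plain discounting model
  p00 <- savor_params(R_minus = p$R_minus, eta0 = 0, C = 0,
                      nu_plus = p$nu_plus, nu_minus = p$nu_minus,
                      gamma = p$gamma, sigma = p$sigma)
  for (q in c(0.25, 0.75)) {
    d0 <- solve_arpe(p00, q, 20)
    expect_equal(standard_rpe(p, q, 20, "S+"), d0$delta_plus)
    expect_equal(standard_rpe(p, q, 20, "S-"), d0$delta_minus)
  }
  expect_equal(standard_rpe(p, 1, 10, "S+"), 0)
  pg0 <- savor_params(R_minus = 0, gamma = 0)
  expect_equal(standard_rpe(pg0, 0.3, 10, "S+"), 0.7)
})

test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(dt = 0.1)
  tt <- attr(h, "time")
  expect_equal(h[tt == 0], 0, ignore_attr = TRUE)
  expect_gt(sum(h) * 0.1, 0)
  expect_equal(sum(h) * 0.1, 1, tolerance = 1e-6)
  peak <- tt[which.max(h)]
  expect_gte(peak, 4.5); expect_lte(peak, 6.5)
  # kernel values are independent of the sampling step
  h2 <- canonical_hrf(dt = 0.05)
  expect_lt(max(abs(h2[seq(1, length(h2), by = 2)] - h)), 1e-5)
})

test_that("an isolated cue event produces a shifted HRF kernel", {
  p <- boost_params()
  ev <- data.frame(run = 1L, trial = 1L, q = 0.5, T_s = 10, cue = "S+",
                   outcome = 1L, choice = "info", t_screen = 5, t_cue = 8,
                   t_outcome = 18)
  cfg <- design_config(TR = 2, dt = 0.1, highpass = NULL,
                       scans_per_run = 40)
  des <- build_design_matrix(ev, p, cfg)
  h <- canonical_hrf(dt = 0.1)
  kt <- attr(h, "time")
  expected <- stats::approx(8 + kt, h, xout = des$frame_times,
                            yleft = 0, yright = 0)$y
  expect_equal(unname(des$X[, "cue"]), expected, tolerance = 1e-10)
})

test_that("design construction is linear over disjoint event sets", {
  p <- boost_params()
  set.seed(8)
  tr <- simulate_choices(p, generate_trials(task_config(n_runs = 1L), 1))
  A <- tr[1:12, ]; B <- tr[13:25, ]
  cfg <- design_config(center_modulators = FALSE, highpass = NULL,
                       scans_per_run = ceiling(max(tr$t_outcome + 16) /
                                                 3.36))
  dAB <- build_design_matrix(tr, p, cfg)
  dA <- build_design_matrix(A, p, cfg)
  dB <- build_design_matrix(B, p, cfg)
  shared <- intersect(dAB$task_cols, union(dA$task_cols, dB$task_cols))
  for (cn in shared) {
    a <- if (cn %in% dA$task_cols) dA$X[, cn] else 0
    b <- if (cn %in% dB$task_cols) dB$X[, cn] else 0
    expect_equal(unname(dAB$X[, cn]), unname(a + b), tolerance = 1e-10)
  }
})

test_that("halving the microtime step barely changes the regressors", {
  p <- boost_params()
  set.seed(21)
  tr <- simulate_choices(p, generate_trials(task_config(n_runs = 1L), 1))
  d1 <- build_design_matrix(tr, p, design_config(dt = 0.1))
  d2 <- build_design_matrix(tr, p, design_config(dt = 0.05))
  for (cn in d1$task_cols) {
    rel <- sqrt(mean((d1$X[, cn] - d2$X[, cn])^2)) /
      sqrt(mean(d1$X[, cn]^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("design handles empty tables, short delays and bad onsets", {
  p <- boost_params()
  empty <- generate_trials(task_config(), 1)[0, ]
  empty$choice <- character(0); empty$cue <- character(0)
  d0 <- build_design_matrix(empty, p, design_config(highpass = NULL))
  expect_equal(colnames(d0$X), "run1")
  # a run holding only 1-s trials has no time-varying columns at all
  set.seed(3)
  tr <- simulate_choices(p, generate_trials(task_config(), 1))
  short <- tr[tr$T_s == 1 & tr$run == 1, ]
  ds <- build_design_matrix(short, p, design_config())
  expect_true("cue_short" %in% ds$task_cols)
  expect_false(any(c("cue", "ant_pos", "urg_pos", "ev_pos", "arpe") %in%
                     ds$task_cols))
  # long-delay trials populate them, and never leave an all-zero column
  dl <- build_design_matrix(tr, p, design_config())
  expect_true(all(c("cue", "ant_pos", "ant_neg", "urg_pos", "ev_pos",
                    "arpe") %in% dl$task_cols))
  expect_true(all(colSums(abs(dl$X[, dl$task_cols])) > 0))
  # validation
  bad <- tr; bad$t_screen[1] <- -2
  expect_error(build_design_matrix(bad, p), "negative")
  bad2 <- tr; bad2$t_outcome[1] <- bad2$t_cue[1] + bad2$T_s[1] + 5
  expect_error(build_design_matrix(bad2, p), "delay")
  # optional control columns appear on request
  dc <- build_design_matrix(tr, p, design_config(ev_boxcar = TRUE,
                                                 ramp = TRUE))
  expect_true(all(c("ev_const", "ramp") %in% dc$task_cols))
})

test_that("PPI regressor is the centered product of seed and psych series", {
  set.seed(10)
  seed_ts <- rnorm(100)
  expect_equal(ppi_regressor(seed_ts, rep(0, 100)), rep(0, 100))
  # constant seed contributes nothing after centering
  expect_equal(ppi_regressor(rep(3, 100), rnorm(100)), rep(0, 100))
  psych <- rnorm(100)
  expect_equal(ppi_regressor(seed_ts, psych),
               (seed_ts - mean(seed_ts)) * (psych - mean(psych)))
  z <- ppi_regressor(seed_ts, psych, zscore = TRUE)
  expect_equal(z, (seed_ts - mean(seed_ts)) * (psych - mean(psych)) /
                 sd(psych), tolerance = 1e-12)
  expect_error(ppi_regressor(rnorm(5), rnorm(6)), "length")
})
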