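test_that("anticipation coefficient matches its closed form and quadrature", {
  p0 <- savor_params(R_minus = -1, eta0 = 0.5, C = 0, nu_plus = 1,
                     nu_minus = 0.3, gamma = 0.05, sigma = 0.3)
  # zero delay leaves no anticipation window
  expect_equal(anticipation_coefficient(p0, 0, "+"), 0)
  expect_equal(anticipation_coefficient(p0, 0, "-"), 0)
  # undiscounted closed form: R (1 - e^{-nu T}) / nu at gamma = 0
  pg0 <- savor_params(R_minus = -1, eta0 = 0.5, C = 0, nu_plus = 1,
                      nu_minus = 0.3, gamma = 0, sigma = 0.3)
  expect_equal(anticipation_coefficient(pg0, log(2), "+"), 0.5)
  # adaptive-quadrature oracle on a specific setting
  p1 <- savor_params(R_minus = -0.4, eta0 = 0.5, C = 0, nu_plus = 0.2,
                     nu_minus = 0.2, gamma = 0.05, sigma = 0.3)
  expect_equal(anticipation_coefficient(p1, 10, "+"),
               quad_anticipation(1, 0.2, 0.05, 10), tolerance = 1e-8)
  # and on seeded random parameter draws, both valences
  set.seed(421)
  for (i in 1:40) {
    p <- rand_params()
    T <- runif(1, 0.1, 60)
    expect_equal(anticipation_coefficient(p, T, "+"),
                 quad_anticipation(1, p$nu_plus, p$gamma, T),
                 tolerance = 1e-8)
    expect_equal(anticipation_coefficient(p, T, "-"),
                 quad_anticipation(p$R_minus, p$nu_minus, p$gamma, T),
                 tolerance = 1e-8)
  }
  expect_error(anticipation_coefficient(p1, -1, "+"), "T must")
})

test_that("discounted outcome value is R exp(-gamma T)", {
  p <- savor_params(R_minus = -0.7, gamma = 0.1)
  expect_equal(discounted_outcome(p, 0, "+"), 1)
  expect_equal(discounted_outcome(p, 0, "-"), -0.7)
  expect_equal(discounted_outcome(p, 10, "+"), exp(-1))
  pg0 <- savor_params(R_minus = -0.7, gamma = 0)
  expect_equal(discounted_outcome(pg0, 500, "-"), -0.7)
})

test_that("values are continuous across the nu = gamma degeneracy", {
  for (T in c(1, 10, 40)) {
    mk <- function(nu) savor_params(R_minus = -0.5, eta0 = 0.5, C = 0,
                                    nu_plus = nu, nu_minus = nu,
                                    gamma = 0.1, sigma = 0.3)
    at_limit <- anticipation_coefficient(mk(0.1), T, "+")
    # probe just outside the analytic-limit switch: no numerical jump
    above <- anticipation_coefficient(mk(0.1 + 2e-9), T, "+")
    below <- anticipation_coefficient(mk(0.1 - 2e-9), T, "+")
    expect_equal(above, at_limit, tolerance = 1e-6)
    expect_equal(below, at_limit, tolerance = 1e-6)
    # and the closed form is smooth through the neighbourhood
    near <- anticipation_coefficient(mk(0.1 + 1e-6), T, "+")
    expect_equal(near, at_limit, tolerance = 1e-4)
  }
})

test_that("stability bound matches a dense grid search over delays", {
  # positive branch binding (|R-| tiny): gamma (gamma/nu)^(nu/(gamma-nu))
  p <- savor_params(R_minus = -1e-9, eta0 = 0.5, C = 0, nu_plus = 0.2,
                    nu_minus = 0.2, gamma = 0.1, sigma = 0.3)
  b <- stability_bound(p)
  expect_equal(b, 0.1 * (0.1 / 0.2)^(0.2 / (0.1 - 0.2)))
  Tgrid <- seq(0.01, 500, length.out = 20000)
  Amax <- max(anticipation_coefficient(p, Tgrid, "+"))
  expect_equal(b, 1 / Amax, tolerance = 1e-6)
  # the maximizing delay is ln(gamma/nu) / (gamma - nu)
  Tstar <- log(0.1 / 0.2) / (0.1 - 0.2)
  expect_equal(Tgrid[which.max(anticipation_coefficient(p, Tgrid, "+"))],
               Tstar, tolerance = 0.05)
  # grid search with both branches active, random draws
  set.seed(33)
  for (i in 1:20) {
    p <- rand_params()
    b <- stability_bound(p)
    worst <- max(anticipation_coefficient(p, Tgrid, "+"),
                 abs(anticipation_coefficient(p, Tgrid, "-")))
    expect_equal(b, 1 / worst, tolerance = 1e-5)
  }
})

test_that("gains below the bound keep all denominators positive, above break them", {
  set.seed(77)
  qg <- seq(0, 1, length.out = 50)
  Tg <- seq(0.1, 120, length.out = 50)
  grid <- expand.grid(q = qg, T = Tg)
  for (i in 1:10) {
    p0 <- rand_params(C_frac = 0)
    b <- stability_bound(p0)
    den <- function(C) {
      Ap <- anticipation_coefficient(p0, grid$T, "+")
      Am <- anticipation_coefficient(p0, grid$T, "-")
      1 - C * ((1 - grid$q) * Ap - grid$q * Am)
    }
    expect_true(all(den(0.95 * b) > 0))
    Tdense <- seq(0.01, 500, length.out = 5000)
    Apd <- anticipation_coefficient(p0, Tdense, "+")
    Amd <- anticipation_coefficient(p0, Tdense, "-")
    dend <- pmin(1 - 1.05 * b * Apd, 1 - 1.05 * b * (-Amd))
    expect_true(any(dend <= 0))
  }
})

test_that("closed-form aRPE agrees with the fixed-point oracle", {
  set.seed(5150)
  for (i in 1:60) {
    p <- rand_params()
    cond <- rand_condition()
    cf <- solve_arpe(p, cond$q, cond$T)
    fp <- arpe_fixed_point(p, cond$q, cond$T, tol = 1e-14)
    expect_equal(cf$delta_plus, fp$delta_plus, tolerance = 1e-10)
    expect_equal(cf$delta_minus, fp$delta_minus, tolerance = 1e-10)
    # signs and the zero-mean property of prediction errors
    expect_gte(cf$delta_plus, 0)
    expect_lte(cf$delta_minus, 0)
    expect_equal(cond$q * cf$delta_plus + (1 - cond$q) * cf$delta_minus, 0,
                 tolerance = 1e-12)
  }
})

test_that("aRPE degenerates correctly at certain outcomes and without coupling", {
  p <- rand_params()
  expect_equal(solve_arpe(p, 1, 10)$delta_plus, 0)
  expect_equal(solve_arpe(p, 0, 10)$delta_minus, 0)
  # C = 0: one fixed-point step reaches the closed form
  p0 <- savor_params(R_minus = -0.5, eta0 = 0.7, C = 0, nu_plus = 0.3,
                     nu_minus = 0.2, gamma = 0.04, sigma = 0.3)
  fp <- arpe_fixed_point(p0, 0.4, 12)
  expect_lte(fp$iterations, 2)
  Ap <- anticipation_coefficient(p0, 12, "+")
  Am <- anticipation_coefficient(p0, 12, "-")
  gap <- 0.7 * (Ap - Am) + discounted_outcome(p0, 12, "+") -
    discounted_outcome(p0, 12, "-")
  expect_equal(fp$delta_plus, 0.6 * gap, tolerance = 1e-10)
  # symmetric magnitudes at q = 1/2
  s <- solve_arpe(p, 0.5, 20)
  expect_equal(abs(s$delta_plus), abs(s$delta_minus), tolerance = 1e-12)
  # violating the bound raises a stability error
  pbad <- savor_params(R_minus = -0.5, eta0 = 0.5,
                       C = 1.05 * stability_bound(p0), nu_plus = 0.3,
                       nu_minus = 0.2, gamma = 0.04, sigma = 0.3,
                       check_stability = FALSE)
  Tstar <- log(0.04 / 0.3) / (0.04 - 0.3)
  expect_error(solve_arpe(pbad, 0, Tstar), "stability")
  expect_error(arpe_fixed_point(pbad, 0, Tstar), "stability|converge")
})

test_that("cue value combines boosted anticipation with the discounted outcome", {
  # immediate consumption: no anticipation window, full reward value
  p <- rand_params()
  expect_equal(cue_value(p, 0.5, 0, "S+"), 1)
  # pure discounting without anticipation
  p0 <- savor_params(R_minus = -0.4, eta0 = 0, C = 0, nu_plus = 0.2,
                     nu_minus = 0.2, gamma = 0.08, sigma = 0.3)
  expect_equal(cue_value(p0, 0.3, 15, "S+"), exp(-0.08 * 15))
  # quadrature oracle: Q = eta * integral + B with the self-consistent eta
  set.seed(91)
  for (i in 1:20) {
    p <- rand_params()
    cond <- rand_condition()
    d <- solve_arpe(p, cond$q, cond$T)
    eta_p <- p$eta0 + p$C * abs(d$delta_plus)
    expect_equal(cue_value(p, cond$q, cond$T, "S+"),
                 eta_p * quad_anticipation(1, p$nu_plus, p$gamma, cond$T) +
                   discounted_outcome(p, cond$T, "+"),
                 tolerance = 1e-8)
    eta_m <- p$eta0 + p$C * abs(d$delta_minus)
    expect_equal(cue_value(p, cond$q, cond$T, "S-"),
                 eta_m * quad_anticipation(p$R_minus, p$nu_minus, p$gamma,
                                           cond$T) +
                   discounted_outcome(p, cond$T, "-"),
                 tolerance = 1e-8)
  }
})

test_that("without boosting the two targets are exactly equivalued", {
  g <- condition_grid()
  # no anticipation at all
  p00 <- savor_params(R_minus = -0.6, eta0 = 0, C = 0, nu_plus = 0.2,
                      nu_minus = 0.3, gamma = 0.05, sigma = 0.3)
  v <- target_values(p00, g$q, g$T_s)
  expect_equal(v$V_II, v$V_NI, tolerance = 1e-14)
  # anticipation present but unboosted: probability weighting cancels
  p0 <- savor_params(R_minus = -0.6, eta0 = 0.9, C = 0, nu_plus = 0.2,
                     nu_minus = 0.3, gamma = 0.05, sigma = 0.3)
  v <- target_values(p0, g$q, g$T_s)
  expect_equal(v$V_II, v$V_NI, tolerance = 1e-14)
})

test_that("boosting makes advance information strictly valuable", {
  base <- savor_params(R_minus = 0, eta0 = 0.4, C = 0, nu_plus = 0.25,
                       nu_minus = 0.25, gamma = 0.03, sigma = 0.3)
  p <- savor_params(R_minus = 0, eta0 = 0.4,
                    C = 0.6 * stability_bound(base), nu_plus = 0.25,
                    nu_minus = 0.25, gamma = 0.03, sigma = 0.3)
  grid <- expand.grid(q = seq(0.05, 0.95, length.out = 15),
                      T = seq(0.5, 60, length.out = 15))
  v <- target_values(p, grid$q, grid$T)
  expect_true(all(v$V_II > v$V_NI))
})

test_that("choice probability is a sigmoid in the value difference", {
  g <- condition_grid()
  p00 <- savor_params(R_minus = -0.6, eta0 = 0, C = 0, nu_plus = 0.2,
                      nu_minus = 0.3, gamma = 0.05, sigma = 0.3)
  # conventional discounting predicts indifference on the whole grid
  expect_equal(choice_prob(p00, g$q, g$T_s), rep(0.5, 25))
  # boosting + weak discounting: preference grows with delay at q = 1/2
  pb <- boost_params()
  pr <- choice_prob(pb, 0.5, c(5, 10, 20, 40))
  expect_true(all(diff(pr) > 0))
  expect_error(
    savor_params(R_minus = -0.5, sigma = 0),
    "sigma")
})

test_that("the compiled likelihood path reproduces the R closed form", {
  set.seed(314)
  g <- condition_grid()
  for (i in 1:15) {
    p <- rand_params()
    pr_r <- choice_prob(p, g$q, g$T_s)
    pr_c <- savor:::choice_prob_cpp(savor:::par_vector(p), g$q, g$T_s)
    expect_equal(pr_r, pr_c, tolerance = 1e-12)
  }
})
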