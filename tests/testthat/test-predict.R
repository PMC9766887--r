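test_that("Breslow baseline reproduces the hand-computed toy cumulative hazard", {
  f <- fake_fit(toy3())
  b <- breslow_baseline(f)
  expect_equal(b$R$times, c(1, 2))
  expect_equal(b$R$cumhaz, c(1 / 3, 1 / 3 + 1 / 2))
  expect_equal(b$R$surv[2], exp(-5 / 6))
  expect_equal(b$R$t_h, 2)
  # no deaths: flat terminal baseline flagged by NA tail rate
  expect_length(b$D$times, 0)
  expect_true(is.na(b$D$tail_rate))
})

test_that("null-model Breslow equals Nelson-Aalen at machine precision", {
  skip_if_not_installed("survival")
  sim <- small_sim(M = 50, seed = 14)
  f <- fake_fit(sim$table)    # all linear predictors zero
  b <- breslow_baseline(f)
  na_fit <- survival::survfit(
    survival::Surv(gap_time, recurrent_event) ~ 1,
    data = as.data.frame(sim$table), ctype = 1)
  na_ch <- na_fit$cumhaz[na_fit$n.event > 0]
  expect_equal(b$R$cumhaz, na_ch, tolerance = 1e-12)
})

test_that("baseline survival is monotone and tail completion is continuous", {
  set.seed(6)
  for (i in 1:10) {
    sim <- small_sim(M = 15, seed = 600 + i)
    b <- breslow_baseline(fake_fit(sim$table,
                                   eta = rnorm(nrow(sim$table), 0, 0.5),
                                   zeta = rnorm(nrow(sim$table), 0, 0.5)))
    for (pr in c("R", "D")) {
      if (length(b[[pr]]$times) == 0) next
      grid <- seq(0, 2 * b[[pr]]$t_h, length.out = 101)
      sv <- tail_completion(b, grid, pr)
      expect_true(all(diff(sv) <= 1e-12))
      expect_true(all(sv >= 0 & sv <= 1))
      # continuity at t_h: step value equals tail value
      expect_equal(tail_completion(b, b[[pr]]$t_h, pr),
                   exp(-b[[pr]]$tail_rate * b[[pr]]$t_h))
    }
  }
  # closed-form tail example: S(t_h) = e^-2 at t_h = 10 gives rate 0.2
  fake <- structure(list(
    R = list(times = 10, cumhaz = 2, surv = exp(-2), t_h = 10,
             tail_rate = 0.2),
    D = list(times = numeric(0), cumhaz = numeric(0), surv = numeric(0),
             t_h = NA_real_, tail_rate = NA_real_)), class = "jf_baseline")
  expect_equal(tail_completion(fake, 20, "R"), exp(-4))
})

test_that("predict_survival multiplies powered baselines", {
  sim <- small_sim(M = 30, seed = 41)
  b <- breslow_baseline(fake_fit(sim$table))
  beta <- c(0.5, -0.2); gamma <- c(0.3, 0.1)
  t <- c(0, 40, 200)
  # X with zero linear predictors: product of the raw baselines
  s0 <- predict_survival(b, beta, gamma, c(0, 0), t)
  expect_equal(s0, tail_completion(b, t, "R") * tail_completion(b, t, "D"))
  expect_equal(s0[1], 1)
  # raising risk in both processes lowers survival
  s1 <- predict_survival(b, beta, gamma, c(1, 0), t[-1])
  expect_true(all(s1 < s0[-1]))
  expect_error(predict_survival(b, beta, gamma, c(1, 0, 0), 1),
               "dimension mismatch")
})

test_that("mean residual life: memoryless tail and quadrature agreement", {
  fake <- structure(list(
    R = list(times = c(5, 9), cumhaz = c(0.2, 0.55),
             surv = exp(-c(0.2, 0.55)), t_h = 9,
             tail_rate = 0.55 / 9),
    D = list(times = c(3, 7, 12), cumhaz = c(0.1, 0.35, 0.8),
             surv = exp(-c(0.1, 0.35, 0.8)), t_h = 12,
             tail_rate = 0.8 / 12)), class = "jf_baseline")
  beta <- 0.4; gamma <- -0.3; X <- 0.8
  # beyond both tails the combined hazard is constant: m(t) = 1/rate
  rate <- fake$R$tail_rate * exp(X * beta) + fake$D$tail_rate * exp(X * gamma)
  expect_equal(mean_residual_life(fake, beta, gamma, X, 15), 1 / rate)
  expect_equal(mean_residual_life(fake, beta, gamma, X, 30), 1 / rate)
  # interior t: exact piecewise integral matches adaptive quadrature
  for (t0 in c(0, 1.7, 6.2)) {
    num <- stats::integrate(function(s)
      predict_survival(fake, beta, gamma, X, s), t0, Inf,
      rel.tol = 1e-12, subdivisions = 500L)$value
    oracle <- num / predict_survival(fake, beta, gamma, X, t0)
    expect_equal(mean_residual_life(fake, beta, gamma, X, t0), oracle,
                 tolerance = 1e-6)
  }
})

test_that("predict.jf_fit produces tidy curves from a real fit", {
  sim <- small_sim(M = 40, seed = 19)
  f <- fit_joint(sim$table, fast_control())
  out <- predict(f, X = rbind(c(0, 0), c(1, 1)), times = c(0, 50, 150))
  expect_equal(names(out), c("profile", "time", "survival", "mrl"))
  expect_equal(nrow(out), 6)
  expect_true(all(out$survival >= 0 & out$survival <= 1))
  expect_true(all(out$mrl >= 0))
  expect_equal(out$survival[out$time == 0], c(1, 1))
})
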