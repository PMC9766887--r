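zero_state <- function(design) {
  make_state(rep(0, ncol(design$X1)), rep(0, ncol(design$X2)),
             rep(0, design$M), rep(0, design$M), design)
}

test_that("risk sets enumerate distinct event times and ties", {
  rs <- build_risk_sets(toy3())
  expect_equal(rs$R$event_times, c(1, 2))
  expect_equal(rs$R$m, c(1L, 1L))
  expect_equal(rs$D$n_events, 0L)
  rs2 <- build_risk_sets(toy_tied())
  expect_equal(rs2$R$event_times, 1)
  expect_equal(rs2$R$m, 2L)
  rs3 <- build_risk_sets(toy_censored())
  expect_equal(rs3$R$n_events, 0L)
  expect_equal(rs3$D$n_events, 0L)
})

test_that("l1 reproduces hand-enumerated toy values", {
  d <- build_design(toy3())
  expect_equal(log_partial_l1(zero_state(d), build_risk_sets(toy3())),
               -log(6))
  d2 <- build_design(toy_tied())
  expect_equal(log_partial_l1(zero_state(d2), build_risk_sets(toy_tied())),
               -2 * log(3))
})

test_that("l1 is invariant to a constant shift of one process's predictors", {
  sim <- small_sim(M = 25, seed = 8)
  d <- build_design(sim$table)
  rs <- build_risk_sets(sim$table, d)
  st <- make_state(c(0.3, -0.2), c(0.1, 0.4), rnorm(d$M, 0, 0.3),
                   rnorm(d$M, 0, 0.3), d)
  l0 <- log_partial_l1(st, rs)
  st_shift <- st
  st_shift$eta <- st$eta + 5
  expect_equal(log_partial_l1(st_shift, rs), l0, tolerance = 1e-10)
  st_shift2 <- st
  st_shift2$zeta <- st$zeta - 3
  expect_equal(log_partial_l1(st_shift2, rs), l0, tolerance = 1e-10)
})

test_that("l2 is the exact bivariate normal log-density via Kronecker", {
  phi <- variance_components(1, 1, 0)
  expect_equal(log_penalty_l2(0, 0, phi), -log(2 * pi))
  expect_equal(log_penalty_l2(1, 1, phi), -log(2 * pi) - 1)
  # anti-correlated q is increasingly penalized as rho grows
  u <- c(1, -0.5); v <- -u
  vals <- vapply(c(0.1, 0.5, 0.9, 0.99), function(r)
    log_penalty_l2(u, v, variance_components(1, 1, r)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("score matches the hand Cox score and finite differences", {
  d <- build_design(toy3())
  rs <- build_risk_sets(toy3())
  phi <- variance_components(1, 1, 0)
  g <- joint_score(zero_state(d), phi, rs, d)
  expect_equal(g[1], 2 / 3)   # d l1 / d beta for x = (1,0,0)
  lay <- jfrailty:::omega_layout(d)
  expect_equal(unname(g[lay$u]), rep(0, 3) + jfrailty:::cox_core(
    rs$R, rep(0, 3), "score")$score)  # penalty is zero at q = 0

  # central finite differences of l1 + l2 on random small instances
  set.seed(31)
  for (i in 1:20) {
    sim <- small_sim(M = sample(4:8, 1), seed = 200 + i,
                     rho = runif(1, -0.8, 0.8))
    d <- build_design(sim$table)
    rs <- build_risk_sets(sim$table, d)
    lay <- jfrailty:::omega_layout(d)
    phi <- variance_components(runif(1, 0.3, 1.5), runif(1, 0.3, 1.5),
                               runif(1, -0.8, 0.8))
    om <- rnorm(lay$total, 0, 0.4)
    st <- jfrailty:::state_from_omega(om, d)
    g <- joint_score(st, phi, rs, d)
    f <- function(o) {
      s <- jfrailty:::state_from_omega(o, d)
      log_partial_l1(s, rs) + log_penalty_l2(s$u, s$v, phi)
    }
    h <- 1e-6
    gfd <- vapply(seq_len(lay$total), function(k) {
      e <- replace(numeric(lay$total), k, h)
      (f(om + e) - f(om - e)) / (2 * h)
    }, numeric(1))
    expect_equal(g, gfd, tolerance = 1e-6)
  }
})

test_that("information matches the finite-difference Hessian", {
  set.seed(17)
  for (i in 1:6) {
    sim <- small_sim(M = 5, seed = 400 + i)
    d <- build_design(sim$table)
    rs <- build_risk_sets(sim$table, d)
    lay <- jfrailty:::omega_layout(d)
    phi <- variance_components(0.6, 0.9, 0.3)
    om <- rnorm(lay$total, 0, 0.3)
    st <- jfrailty:::state_from_omega(om, d)
    info <- joint_information(st, phi, rs, d, inverse = FALSE)
    h <- 1e-4
    Hfd <- matrix(0, lay$total, lay$total)
    for (k in seq_len(lay$total)) {
      e <- replace(numeric(lay$total), k, h)
      Hfd[, k] <- (joint_score(jfrailty:::state_from_omega(om + e, d),
                               phi, rs, d) -
                   joint_score(jfrailty:::state_from_omega(om - e, d),
                               phi, rs, d)) / (2 * h)
    }
    Hfd <- -(Hfd + t(Hfd)) / 2
    expect_equal(info$G, Hfd, tolerance = 1e-4)
    # penalized information is positive definite on the informative
    # parameters (fixed effects of an event-free process drop out)
    act <- which(diag(info$G) > 0)
    expect_gt(min(eigen(info$G[act, act], symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("with no events the information reduces to the penalty block", {
  tab <- toy_censored(5)
  d <- build_design(tab)
  rs <- build_risk_sets(tab, d)
  phi <- variance_components(0.5, 0.8, 0.4)
  st <- zero_state(d)
  info <- joint_information(st, phi, rs, d, inverse = FALSE)
  lay <- jfrailty:::omega_layout(d)
  Gi <- jfrailty:::gamma_inverse(phi)
  expected <- matrix(0, lay$total, lay$total)
  expected[lay$u, lay$u] <- diag(Gi[1, 1], 5)
  expected[lay$v, lay$v] <- diag(Gi[2, 2], 5)
  expected[lay$u, lay$v] <- diag(Gi[1, 2], 5)
  expected[lay$v, lay$u] <- diag(Gi[1, 2], 5)
  expect_equal(info$G, expected)
})

test_that("l1 with one process and no frailty equals coxph's partial loglik", {
  skip_if_not_installed("survival")
  sim <- small_sim(M = 30, seed = 12)
  tab <- sim$table
  d <- build_design(tab)
  rs <- build_risk_sets(tab, d)
  beta <- c(0.4, -0.3)
  st <- make_state(beta, c(0, 0), rep(0, d$M), rep(0, d$M), d)
  ours <- jfrailty:::cox_core(rs$R, st$eta, "loglik")$loglik
  cox <- survival::coxph(
    survival::Surv(gap_time, recurrent_event) ~ x1 + x2,
    data = as.data.frame(tab), init = beta, ties = "breslow",
    control = survival::coxph.control(iter.max = 0))
  expect_equal(ours, unname(cox$loglik[2]), tolerance = 1e-8)
})
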