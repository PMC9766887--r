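test_that("blup_step is exact on the penalty-only quadratic and stationary at the mode", {
  tab <- toy_censored(6)
  d <- build_design(tab)
  rs <- build_risk_sets(tab, d)
  phi <- variance_components(0.7, 0.5, 0.3)
  st0 <- make_state(numeric(1), numeric(1), rnorm(6), rnorm(6), d)
  stp <- blup_step(st0, phi, rs, d)
  expect_equal(stp$state$u, rep(0, 6), tolerance = 1e-12)
  expect_equal(stp$state$v, rep(0, 6), tolerance = 1e-12)
  # starting at the maximizer leaves the state unchanged
  stp2 <- blup_step(stp$state, phi, rs, d)
  expect_equal(stp2$state$u, rep(0, 6), tolerance = 1e-12)
})

test_that("accepted Newton steps never decrease the penalized objective", {
  set.seed(5)
  for (i in 1:20) {
    sim <- small_sim(M = sample(8:14, 1), seed = 500 + i,
                     rho = runif(1, -0.7, 0.7))
    if (length(unique(sim$table$x1)) < 2) next  # degenerate binary draw
    d <- build_design(sim$table)
    rs <- build_risk_sets(sim$table, d)
    lay <- jfrailty:::omega_layout(d)
    phi <- variance_components(runif(1, 0.2, 1), runif(1, 0.2, 1),
                               runif(1, -0.7, 0.7))
    st <- jfrailty:::state_from_omega(rnorm(lay$total, 0, 0.5), d)
    l_old <- log_partial_l1(st, rs) + log_penalty_l2(st$u, st$v, phi)
    stp <- blup_step(st, phi, rs, d)
    expect_gte(stp$l, l_old - 1e-10)
  }
})

test_that("solve_blup reaches a stationary point with a small score", {
  sim <- small_sim(M = 30, seed = 21)
  d <- build_design(sim$table)
  rs <- build_risk_sets(sim$table, d)
  phi <- variance_components(0.49, 0.49, 0.5)
  st0 <- make_state(c(0, 0), c(0, 0), rep(0, 30), rep(0, 30), d)
  sol <- solve_blup(st0, phi, rs, d, fit_control())
  expect_true(sol$converged)
  expect_lt(sol$score_max, 1e-4)
})

test_that("theta -> 0 recovers the unpenalized Cox fits of each process", {
  skip_if_not_installed("survival")
  sim <- small_sim(M = 60, seed = 33)
  tab <- sim$table
  d <- build_design(tab)
  rs <- build_risk_sets(tab, d)
  phi <- variance_components(1e-8, 1e-8, 0)
  st0 <- make_state(c(0, 0), c(0, 0), rep(0, 60), rep(0, 60), d)
  sol <- solve_blup(st0, phi, rs, d, fit_control())
  expect_lt(max(abs(c(sol$state$u, sol$state$v))), 1e-4)
  cox_r <- survival::coxph(
    survival::Surv(gap_time, recurrent_event) ~ x1 + x2,
    data = as.data.frame(tab), ties = "breslow")
  cox_d <- survival::coxph(
    survival::Surv(gap_time, death_event) ~ x1 + x2,
    data = as.data.frame(tab), ties = "breslow")
  expect_equal(unname(sol$state$beta), unname(coef(cox_r)),
               tolerance = 1e-3)
  expect_equal(unname(sol$state$gamma), unname(coef(cox_d)),
               tolerance = 1e-3)
})

test_that("reml_update implements the trace arithmetic with clipping", {
  st <- list(u = rep(1, 4), v = rep(1, 4))
  blocks0 <- list(tr_Buu = 0, tr_Buv = 0, tr_Bvv = 0)
  p <- reml_update(st, blocks0, 4)
  expect_equal(p$theta_u2, 1)
  expect_equal(p$theta_v2, 1)
  expect_equal(p$rho, 0.999)                    # clipped from 1
  expect_true(attr(p, "clipped"))
  # orthogonal modes give rho = 0
  st2 <- list(u = c(1, 1, -1, -1), v = c(1, -1, 1, -1))
  p2 <- reml_update(st2, blocks0, 4)
  expect_equal(p2$rho, 0)
  # identity B block: theta^2 = tr(I_M)/M = 1, cross trace 0
  stz <- list(u = rep(0, 4), v = rep(0, 4))
  p3 <- reml_update(stz, list(tr_Buu = 4, tr_Buv = 0, tr_Bvv = 4), 4)
  expect_equal(p3$theta_u2, 1)
  expect_equal(p3$rho, 0)
  expect_error(reml_update(stz, list(tr_Buu = 0, tr_Buv = 0, tr_Bvv = 0), 4),
               "information collapse")
})

test_that("fit_joint is deterministic and returns a coherent result", {
  sim <- small_sim(M = 40, seed = 55)
  f1 <- fit_joint(sim$table, fast_control())
  f2 <- fit_joint(sim$table, fast_control())
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$phi, f2$phi)
  expect_s3_class(f1, "jf_fit")
  expect_length(f1$se_beta, 2)
  expect_true(all(is.finite(f1$se_beta)))
  expect_true(all(c("l1", "l2", "theta_u2", "rho") %in% names(f1$trace)))
  expect_output(print(f1), "Joint frailty model fit")
})

test_that("empty-event data returns the penalty-only maximum", {
  tab <- toy_censored(5)
  f <- fit_joint(tab, fast_control())
  expect_equal(unname(f$u), rep(0, 5))
  expect_equal(unname(f$v), rep(0, 5))
  expect_true(f$converged)
  # variance components stay at their starting values (the update map is
  # the identity with no events)
  expect_equal(f$phi$theta_u2, 0.1, tolerance = 1e-4)
})

test_that("EB frailty intervals use the normal half-width and calibrate", {
  sim <- small_sim(M = 150, seed = 77, rho = 0.6)
  f <- fit_joint(sim$table, fast_control())
  eb <- eb_frailty_intervals(f, level = 0.95)
  su <- sqrt(f$blocks$diag_qq[seq_len(150)])
  expect_equal(eb$u_upper - eb$u, qnorm(0.975) * su)
  expect_equal(nrow(eb), 150)
  # truth retained by the simulator: intervals should cover ~95%
  cover_u <- mean(sim$truth$u >= eb$u_lower & sim$truth$u <= eb$u_upper)
  cover_v <- mean(sim$truth$v >= eb$v_lower & sim$truth$v <= eb$v_upper)
  expect_gt(cover_u, 0.85)
  expect_gt(cover_v, 0.85)
})

test_that("separate frailty fits run and agree with joint under rho = 0", {
  sim <- small_sim(M = 80, seed = 91, rho = 0)
  joint <- fit_joint(sim$table, fast_control())
  sep <- fit_separate_frailty(sim$table, fast_control())
  expect_s3_class(sep, "jf_separate_fit")
  # independence: coefficient estimates agree loosely (same data, nearly
  # equivalent models when the frailty correlation is absent)
  expect_equal(unname(sep$recurrent$coef), unname(joint$beta),
               tolerance = 0.15)
  expect_equal(unname(sep$terminal$coef), unname(joint$gamma),
               tolerance = 0.15)
  # no deaths at all: terminal fit returns the empty-model result
  tab_nd <- sim$table
  tab_nd$death_event <- 0
  tab_nd <- event_table(as.data.frame(tab_nd))
  sep2 <- fit_separate_frailty(tab_nd, fast_control())
  expect_true(sep2$terminal$empty)
  expect_true(all(is.na(sep2$terminal$se)))
})

test_that("variance_component_se returns positive SEs or a diagnostic", {
  sim <- small_sim(M = 60, seed = 13, rho = 0.5)
  f <- fit_joint(sim$table, fast_control())
  se <- variance_component_se(f)
  if (any(is.na(se))) {
    expect_true(!is.null(attr(se, "diagnostic")))
  } else {
    expect_true(all(se > 0))
    expect_named(se, c("theta_u2", "theta_v2", "rho"))
  }
  # clipped-correlation boundary reports not-available, no crash
  f2 <- f
  f2$phi <- variance_components(f$phi$theta_u2, f$phi$theta_v2, 0.999)
  se2 <- variance_component_se(f2)
  expect_true(all(is.na(se2)))
  expect_match(attr(se2, "diagnostic"), "boundary")
})
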