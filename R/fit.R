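#' Fitting control parameters
#'
#' @param init_phi starting variance components; the algorithm starts the
#'   variance components at relatively small values (default variances 0.1,
#'   correlation 0.05) and all of (beta, gamma, u, v) at zero.
#' @param inner_tol,outer_tol relative sup-norm convergence thresholds for
#'   the inner BLUP Newton-Raphson loop and the outer REML loop.
#' @param max_inner,max_outer iteration caps.
#' @param rho_bound clip the REML correlation update at +/- this bound to
#'   keep Gamma positive definite.
#' @param step_halving halve a Newton step (up to 20 times) when it would
#'   decrease the penalized objective.
#' @param covariates_recurrent,covariates_terminal optional covariate-name
#'   subsets entering each submodel (default: all covariate columns).
#' @param phi_se compute standard errors of the variance components at
#'   convergence (a profiled finite-difference Hessian; adds noticeable
#'   cost).
#' @return a list of class `jf_fit_control`.
#' @export
fit_control <- function(init_phi = variance_components(0.1, 0.1, 0.05),
                        inner_tol = 1e-6, outer_tol = 1e-5,
                        max_inner = 50L, max_outer = 100L,
                        rho_bound = 0.999, step_halving = TRUE,
                        covariates_recurrent = NULL,
                        covariates_terminal = NULL,
                        phi_se = FALSE) {
  stopifnot(inherits(init_phi, "jf_phi"), inner_tol > 0, outer_tol > 0,
            rho_bound > 0, rho_bound < 1)
  structure(list(init_phi = init_phi, inner_tol = inner_tol,
                 outer_tol = outer_tol, max_inner = as.integer(max_inner),
                 max_outer = as.integer(max_outer), rho_bound = rho_bound,
                 step_halving = step_halving,
                 covariates_recurrent = covariates_recurrent,
                 covariates_terminal = covariates_terminal,
                 phi_se = phi_se),
            class = "jf_fit_control")
}

# indices of Omega that carry information: fixed effects of a process with
# zero observed events are dropped from the Newton system (their Cox
# information is identically zero)
active_indices <- function(risksets, design) {
  lay <- omega_layout(design)
  idx <- c(if (risksets$R$n_events > 0) lay$beta,
           if (risksets$D$n_events > 0) lay$gamma,
           lay$u, lay$v)
  sort(idx)
}

#' One BLUP Newton-Raphson step
#'
#' Updates Omega = (beta, gamma, u, v) by one step
#' Omega + G^{-1} grad(l), implemented as a single symmetric
#' positive-definite solve of the observed information. If the penalized
#' objective l = l1 + l2 decreases, the step is halved up to 20 times.
#'
#' @param state a `jf_state`.
#' @param phi a `jf_phi`.
#' @param risksets a `jf_risksets`.
#' @param design a `jf_design`.
#' @param control a `jf_fit_control`.
#' @return a list with the updated `state`, the objective `l` (= l1 + l2)
#'   at the accepted point, `step_scale` (1 unless halved), and
#'   `delta` (the accepted parameter change).
#' @export
blup_step <- function(state, phi, risksets, design,
                      control = fit_control()) {
  act <- active_indices(risksets, design)
  g <- joint_score(state, phi, risksets, design)
  info <- joint_information(state, phi, risksets, design, inverse = FALSE)
  ch <- tryCatch(chol(info$G[act, act]), error = function(e) {
    stop("convergence error: singular information matrix: ",
         conditionMessage(e), call. = FALSE)
  })
  step <- backsolve(ch, forwardsolve(t(ch), g[act]))
  omega <- omega_from_state(state)
  l_old <- log_partial_l1(state, risksets) +
    log_penalty_l2(state$u, state$v, phi)
  scale <- 1
  repeat {
    omega_new <- omega
    omega_new[act] <- omega[act] + scale * step
    state_new <- state_from_omega(omega_new, design)
    l_new <- log_partial_l1(state_new, risksets) +
      log_penalty_l2(state_new$u, state_new$v, phi)
    if (is.finite(l_new) && (l_new >= l_old || !control$step_halving ||
                             scale < 2^-20)) break
    scale <- scale / 2
  }
  list(state = state_new, l = l_new, step_scale = scale,
       delta = omega_new - omega)
}

#' Maximize the penalized joint log-likelihood over Omega (BLUP)
#'
#' Iterates [blup_step()] with the variance components held fixed until the
#' relative sup-norm parameter change drops below `inner_tol` or `max_inner`
#' steps are taken.
#'
#' @inheritParams blup_step
#' @param state0 starting `jf_state`.
#' @return a list with `state`, `converged`, `n_iter`, `l` (final
#'   objective), `score_max` (sup-norm of the score at return).
#' @export
solve_blup <- function(state0, phi, risksets, design,
                       control = fit_control()) {
  state <- state0
  converged <- FALSE
  n_iter <- 0L
  l <- NA_real_
  for (it in seq_len(control$max_inner)) {
    stp <- blup_step(state, phi, risksets, design, control)
    n_iter <- it
    rel <- max(abs(stp$delta)) /
      max(1, max(abs(omega_from_state(stp$state))))
    state <- stp$state
    l <- stp$l
    if (rel < control$inner_tol) {
      converged <- TRUE
      break
    }
  }
  act <- active_indices(risksets, design)
  score_max <- max(abs(joint_score(state, phi, risksets, design)[act]))
  list(state = state, converged = converged, n_iter = n_iter, l = l,
       score_max = score_max)
}

#' Approximate REML update of the variance components
#'
#' Given the BLUP solution and the random-effect block B_qq of the inverse
#' information, updates theta_u^2 = I1 / M, theta_v^2 = I3 / M and
#' rho = I2 / sqrt(I1 I3), where I1 = tr(B_uu) + u'u,
#' I2 = tr(B_uv) + u'v and I3 = tr(B_vv) + v'v (the traces of the masked
#' products tr\{K_i (B_qq + q q')\}, computed without materializing q q').
#' The correlation is clipped at +/- `rho_bound`.
#'
#' @param state a `jf_state` at the BLUP solution.
#' @param blocks a `jf_information` with inverse summaries (or any list with
#'   `tr_Buu`, `tr_Buv`, `tr_Bvv`).
#' @param M number of subjects.
#' @param rho_bound clip bound for the correlation.
#' @return a `jf_phi`; attribute `"clipped"` is `TRUE` if rho was clipped.
#' @export
reml_update <- function(state, blocks, M, rho_bound = 0.999) {
  I1 <- blocks$tr_Buu + sum(state$u^2)
  I2 <- blocks$tr_Buv + sum(state$u * state$v)
  I3 <- blocks$tr_Bvv + sum(state$v^2)
  if (I1 <= 0 || I3 <= 0) {
    stop("numerical error: information collapse in REML update ",
         "(nonpositive trace)", call. = FALSE)
  }
  rho <- I2 / sqrt(I1 * I3)
  clipped <- abs(rho) > rho_bound
  rho <- max(min(rho, rho_bound), -rho_bound)
  out <- variance_components(I1 / M, I3 / M, rho)
  attr(out, "clipped") <- clipped
  out
}

#' Fit the joint frailty model
#'
#' Full estimation: alternate maximization of the penalized joint partial
#' log-likelihood over (beta, gamma, u, v) with the variance components
#' fixed (inner BLUP Newton-Raphson), and approximate REML updates of
#' (theta_u^2, theta_v^2, rho) (outer loop), until the relative change in
#' the variance components is below `outer_tol`. Standard errors of the
#' fixed effects come from the (beta, beta) and (gamma, gamma) blocks of
#' the inverse information at convergence.
#'
#' @param table a validated `jf_event_table`.
#' @param control a `jf_fit_control`.
#' @return an object of class `jf_fit` with components `beta`, `gamma`,
#'   `u`, `v`, `phi`, `se_beta`, `se_gamma`, `se_phi` (NA unless
#'   `control$phi_se`), `blocks` (inverse-information summaries), `trace`
#'   (per-outer-iteration data.frame), `converged`, `inner_converged`,
#'   `n_outer`, `n_inner_total`, `l1`, `l2`, plus the `table`, `design`,
#'   `risksets`, `state` and `control` needed by the prediction layer.
#' @seealso [fit_separate_frailty()] for the naive comparator,
#'   [breslow_baseline()], [predict_survival()], [mean_residual_life()].
#' @export
fit_joint <- function(table, control = fit_control()) {
  stopifnot(inherits(table, "jf_event_table"))
  design <- build_design(table, control$covariates_recurrent,
                         control$covariates_terminal)
  risksets <- build_risk_sets(table, design)
  lay <- omega_layout(design)
  state <- make_state(rep(0, lay$p1), rep(0, lay$p2),
                      rep(0, lay$M), rep(0, lay$M), design)
  phi <- control$init_phi
  trace <- vector("list", control$max_outer)
  n_inner_total <- 0L
  converged <- FALSE
  inner_ok <- TRUE
  n_outer <- 0L
  phi_vec <- function(p) unlist(p[c("theta_u2", "theta_v2", "rho")])
  rel_change <- function(new, old) max(abs(new - old) / pmax(abs(old), 1e-2))
  # unconstrained coordinates for the fixed-point extrapolation
  to_w <- function(p) c(log(p$theta_u2), log(p$theta_v2), atanh(p$rho))
  from_w <- function(w) {
    w <- pmin(pmax(w, c(-18, -18, -atanh(control$rho_bound))),
              c(18, 18, atanh(control$rho_bound)))
    variance_components(exp(w[1]), exp(w[2]), tanh(w[3]))
  }
  # one Step 2 + Step 3 cycle: BLUP solve, inverse-information traces,
  # trace-formula REML update
  last_clipped <- FALSE
  n_clipped_run <- 0L
  reml_map <- function(phi) {
    sb <- solve_blup(state, phi, risksets, design, control)
    state <<- sb$state
    n_inner_total <<- n_inner_total + sb$n_iter
    inner_ok <<- inner_ok && sb$converged
    info <- joint_information(sb$state, phi, risksets, design,
                              inverse = TRUE)
    phi_new <- reml_update(sb$state, info, design$M, control$rho_bound)
    last_clipped <<- isTRUE(attr(phi_new, "clipped"))
    n_clipped_run <<- if (last_clipped) n_clipped_run + 1L else 0L
    n_outer <<- n_outer + 1L
    trace[[n_outer]] <<- data.frame(
      outer = n_outer, l1 = log_partial_l1(sb$state, risksets),
      l2 = log_penalty_l2(sb$state$u, sb$state$v, phi),
      theta_u2 = phi_new$theta_u2, theta_v2 = phi_new$theta_v2,
      rho = phi_new$rho, inner_iters = sb$n_iter,
      rho_clipped = last_clipped)
    phi_new
  }
  # The raw Step 2-3 alternation is an EM-like fixed-point map whose
  # contraction factor approaches 1 when events are sparse (hundreds to
  # thousands of sweeps would be needed). The same fixed point is reached
  # by component-wise sign-adaptive over-relaxation on the unconstrained
  # scale w = (log theta_u^2, log theta_v^2, atanh rho): each step moves
  # along the raw update residual g(w) = F(w) - w with a per-component
  # factor that doubles while the residual keeps its sign and quarters
  # when it flips, capped per step. Following the map's own flow avoids
  # the spurious degenerate roots (theta^2 -> 0) that Newton-type solvers
  # on this near-identity residual can land on. Convergence is declared on
  # the raw update residual, so the REML fixed-point identity holds at
  # return.
  g_of <- function(w) to_w(reml_map(from_w(w))) - w
  # a correlation update sitting at the clip bound reproduces itself
  # artificially, so a clipped update never counts as converged
  small_resid <- function(w, g) {
    !last_clipped &&
      rel_change(phi_vec(from_w(w + g)), phi_vec(from_w(w))) <
        control$outer_tol
  }
  w <- to_w(phi)
  g <- g_of(w)
  s <- rep(1, 3)
  step_cap <- 0.5
  while (!small_resid(w, g) && n_outer < control$max_outer &&
         n_clipped_run < 8L) {
    w <- w + pmin(pmax(s * g, -step_cap), step_cap)
    g_new <- g_of(w)
    flip <- g_new * g < 0
    s[flip] <- pmax(s[flip] / 4, 0.25)
    s[!flip] <- pmin(s[!flip] * 2, 4096)
    g <- g_new
  }
  converged <- small_resid(w, g)
  phi <- from_w(w + g)  # last raw update from the solved point
  # final BLUP solution and inference at the converged variance components
  sb <- solve_blup(state, phi, risksets, design, control)
  state <- sb$state
  n_inner_total <- n_inner_total + sb$n_iter
  info <- joint_information(state, phi, risksets, design, inverse = TRUE)

  se_beta <- rep(NA_real_, lay$p1)
  se_gamma <- rep(NA_real_, lay$p2)
  if (risksets$R$n_events > 0) se_beta <- sqrt(diag(info$B_beta))
  if (risksets$D$n_events > 0) se_gamma <- sqrt(diag(info$B_gamma))
  names(se_beta) <- colnames(design$X1)
  names(se_gamma) <- colnames(design$X2)
  beta <- stats::setNames(state$beta, colnames(design$X1))
  gamma <- stats::setNames(state$gamma, colnames(design$X2))

  fit <- structure(list(
    beta = beta, gamma = gamma, u = state$u, v = state$v, phi = phi,
    se_beta = se_beta, se_gamma = se_gamma,
    se_phi = c(theta_u2 = NA_real_, theta_v2 = NA_real_, rho = NA_real_),
    blocks = list(B_beta = info$B_beta, B_gamma = info$B_gamma,
                  diag_qq = info$diag_qq, tr_Buu = info$tr_Buu,
                  tr_Buv = info$tr_Buv, tr_Bvv = info$tr_Bvv),
    trace = do.call(rbind, trace[seq_len(n_outer)]),
    converged = converged, inner_converged = inner_ok,
    n_outer = n_outer, n_inner_total = n_inner_total,
    l1 = log_partial_l1(state, risksets),
    l2 = log_penalty_l2(state$u, state$v, phi),
    table = table, design = design, risksets = risksets, state = state,
    control = control), class = "jf_fit")
  if (control$phi_se) fit$se_phi <- variance_component_se(fit)
  fit
}

#' @export
print.jf_fit <- function(x, ...) {
  cat("Joint frailty model fit (", x$design$M, " subjects, ",
      x$design$N, " gaps)\n", sep = "")
  cat(if (x$converged) "converged" else "NOT converged",
      "after", x$n_outer, "outer /", x$n_inner_total,
      "total inner iterations\n")
  est <- rbind(
    data.frame(process = "recurrent", term = names(x$beta),
               estimate = unname(x$beta), se = unname(x$se_beta)),
    data.frame(process = "terminal", term = names(x$gamma),
               estimate = unname(x$gamma), se = unname(x$se_gamma)))
  est$hr <- exp(est$estimate)
  print(est, row.names = FALSE, digits = 4)
  cat(sprintf("frailty variances: theta_u^2 = %.4f, theta_v^2 = %.4f, rho = %.4f\n",
              x$phi$theta_u2, x$phi$theta_v2, x$phi$rho))
  invisible(x)
}

# profiled Laplace-type REML objective in Phi:
#   l_R(Phi) = l1(Omega_hat) + l2(Omega_hat, Phi) - 1/2 log|G_qq(Phi)|
# with Omega profiled out by the inner BLUP solve (warm-started).
profiled_reml_objective <- function(phi, fit) {
  sb <- solve_blup(fit$state, phi, fit$risksets, fit$design, fit$control)
  st <- sb$state
  info <- joint_information(st, phi, fit$risksets, fit$design,
                            inverse = FALSE)
  lay <- info$layout
  qq <- c(lay$u, lay$v)
  ch <- chol(info$G[qq, qq])
  log_partial_l1(st, fit$risksets) + log_penalty_l2(st$u, st$v, phi) -
    sum(log(diag(ch)))
}

#' Standard errors of the variance components
#'
#' Approximates the REML information for Phi = (theta_u^2, theta_v^2, rho)
#' by a central finite-difference Hessian of the profiled Laplace-type REML
#' objective (see Details in the package vignette), with relative step
#' sizes 1e-4 and enforced symmetry. Returns `NA` with a diagnostic
#' attribute when the correlation sits at the clip boundary or the Hessian
#' is not negative definite.
#'
#' @param fit a converged `jf_fit`.
#' @return named 3-vector of standard errors for (theta_u2, theta_v2, rho);
#'   possibly NA with attribute `"diagnostic"`.
#' @export
variance_component_se <- function(fit) {
  stopifnot(inherits(fit, "jf_fit"))
  na <- c(theta_u2 = NA_real_, theta_v2 = NA_real_, rho = NA_real_)
  phi0 <- unlist(fit$phi[c("theta_u2", "theta_v2", "rho")])
  if (abs(fit$phi$rho) >= fit$control$rho_bound) {
    attr(na, "diagnostic") <- "rho at clip boundary"
    return(na)
  }
  f <- function(p) {
    profiled_reml_objective(
      variance_components(p[1], p[2], p[3]), fit)
  }
  h <- 1e-4 * pmax(abs(phi0), 0.01)
  H <- matrix(0, 3, 3)
  f0 <- f(phi0)
  for (i in 1:3) {
    ei <- replace(numeric(3), i, h[i])
    H[i, i] <- (f(phi0 + ei) - 2 * f0 + f(phi0 - ei)) / h[i]^2
    for (j in seq_len(i - 1)) {
      ej <- replace(numeric(3), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(phi0 + ei + ej) - f(phi0 + ei - ej) -
           f(phi0 - ei + ej) + f(phi0 - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0)) {
    attr(na, "diagnostic") <- "REML Hessian not negative definite"
    return(na)
  }
  stats::setNames(sqrt(diag(V)), names(na))
}

#' Empirical-Bayes prediction intervals for the frailties
#'
#' Normal-approximation intervals u_hat_j +/- z sqrt(var_j), with the
#' posterior variances taken from the diagonal of the random-effect block
#' of the inverse information.
#'
#' @param fit a `jf_fit`.
#' @param level coverage level (default 0.95).
#' @return a data.frame with one row per subject: `subject_id`, `u`,
#'   `u_lower`, `u_upper`, `v`, `v_lower`, `v_upper`.
#' @export
eb_frailty_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "jf_fit"), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  M <- fit$design$M
  su <- sqrt(fit$blocks$diag_qq[seq_len(M)])
  sv <- sqrt(fit$blocks$diag_qq[M + seq_len(M)])
  data.frame(subject_id = fit$design$subjects,
             u = fit$u, u_lower = fit$u - z * su, u_upper = fit$u + z * su,
             v = fit$v, v_lower = fit$v - z * sv, v_upper = fit$v + z * sv)
}
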