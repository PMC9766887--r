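#' Risk sets for the joint partial likelihood
#'
#' Arranges the recurrent and death gap/censoring times in increasing order
#' and groups tied uncensored times. Both hazards live on the gap-time
#' (renewal) scale, so all N gap rows enter both processes: an observation
#' is at risk at an event time t if its own gap time is >= t. A death can
#' only be flagged on a subject's final gap; earlier gaps contribute
#' death-free exposure.
#'
#' @param table a validated `jf_event_table`.
#' @param design the matching `jf_design` from [build_design()] (unused,
#'   kept for call symmetry).
#' @return a list of class `jf_risksets` with components `R` and `D`, each a
#'   list with `time` (observation times in canonical row order), `status`
#'   (event indicators), `event_times` (sorted distinct uncensored times,
#'   length K), `m` (tie multiplicities), `n_events`.
#' @export
build_risk_sets <- function(table, design = NULL) {
  stopifnot(inherits(table, "jf_event_table"))
  one <- function(time, status) {
    ev <- sort(unique(time[status == 1]))
    m <- if (length(ev)) {
      as.integer(tapply(rep(1L, sum(status == 1)),
                        factor(time[status == 1], levels = ev), sum))
    } else integer(0)
    list(time = time, status = as.integer(status), event_times = ev,
         m = m, n_events = sum(status == 1))
  }
  structure(list(
    R = one(table$gap_time, table$recurrent_event),
    D = one(table$gap_time, table$death_event)),
    class = "jf_risksets")
}

# Core Cox quantities for one process under Breslow tie handling.
# Returns the partial log-likelihood, the score in the linear predictor,
# and the pieces needed for the observed information:
#   info in lp = diag(d) - W diag(m) W^T,
# where w_{l,r} = e^{lp_l} 1{t_l >= t_r} / D_r and d_l = sum_r m_r w_{l,r}.
# Denominators use a global log-sum-exp shift for stability.
cox_core <- function(rs, lp, what = c("loglik", "score", "info")) {
  K <- length(rs$event_times)
  n <- length(lp)
  if (K == 0) {
    out <- list(loglik = 0)
    if ("score" %in% what) out$score <- rep(0, n)
    if ("info" %in% what) {
      out$d <- rep(0, n); out$W <- matrix(0, n, 0); out$m <- integer(0)
    }
    return(out)
  }
  c0 <- max(lp)
  elp <- exp(lp - c0)
  ord <- order(rs$time)
  # D_r (scaled): sum of elp over observations with time >= event_times[r]
  cs <- rev(cumsum(rev(elp[ord])))
  pos <- findInterval(rs$event_times, rs$time[ord], left.open = TRUE) + 1L
  D <- cs[pos]
  out <- list()
  if ("loglik" %in% what) {
    out$loglik <- sum(lp[rs$status == 1]) -
      sum(rs$m * (log(D) + c0))
  }
  # A(t_l) = sum_{r: event_times[r] <= t_l} m_r / D_r  (scaled cumhaz)
  if (any(c("score", "info") %in% what)) {
    cumA <- cumsum(rs$m / D)
    rk <- findInterval(rs$time, rs$event_times)
    A <- ifelse(rk == 0, 0, cumA[pmax(rk, 1L)])
    d <- elp * A
    if ("score" %in% what) out$score <- rs$status - d
    if ("info" %in% what) {
      # W[l, r] = elp_l / D_r if time_l >= event_times[r]
      W <- (elp %o% (1 / D)) * outer(rs$time, rs$event_times, ">=")
      out$d <- d; out$W <- W; out$m <- rs$m
    }
  }
  out
}

#' Joint Cox partial log-likelihood with fixed frailties (l1)
#'
#' Evaluates the Breslow-tie partial log-likelihood
#' `sum_r (eta_r - m_r^R log sum_{l in R(t_Rr)} e^{eta_l})` over recurrent
#' event times plus the analogous sum over death times, with the random
#' effects held fixed inside the linear predictors.
#'
#' @param state a `jf_state` (see [make_state()]).
#' @param risksets a `jf_risksets`.
#' @return scalar l1.
#' @export
log_partial_l1 <- function(state, risksets) {
  cox_core(risksets$R, state$eta, "loglik")$loglik +
    cox_core(risksets$D, state$zeta, "loglik")$loglik
}

#' Log-density penalty of the frailties (l2)
#'
#' The log joint density of q = (u', v')' under N(0, Sigma) with
#' Sigma = Gamma kron I_M, evaluated through the Kronecker structure
#' (log|Sigma| = M log|Gamma|, Sigma^{-1} = Gamma^{-1} kron I_M) without
#' forming any 2M x 2M matrix. The full 2M-dimensional normalizing constant
#' is used (2M log 2pi + log|Sigma|).
#'
#' @param u,v frailty M-vectors.
#' @param phi a `jf_phi`.
#' @return scalar l2.
#' @export
log_penalty_l2 <- function(u, v, phi) {
  stopifnot(inherits(phi, "jf_phi"), length(u) == length(v))
  M <- length(u)
  Gi <- gamma_inverse(phi)
  logdetG <- log(phi$theta_u2) + log(phi$theta_v2) + log1p(-phi$rho^2)
  quad <- Gi[1, 1] * sum(u * u) + 2 * Gi[1, 2] * sum(u * v) +
    Gi[2, 2] * sum(v * v)
  -0.5 * (2 * M * log(2 * pi) + M * logdetG + quad)
}

#' Model state: fixed effects, frailties and linear predictors
#'
#' @param beta,gamma fixed-effect vectors (lengths p1, p2).
#' @param u,v frailty M-vectors.
#' @param design a `jf_design`.
#' @return a list of class `jf_state` with `eta = X1 beta + Z1 u` and
#'   `zeta = X2 gamma + Z2 v` (both length N, computed by subject lookup).
#' @export
make_state <- function(beta, gamma, u, v, design) {
  stopifnot(length(beta) == ncol(design$X1),
            length(gamma) == ncol(design$X2),
            length(u) == design$M, length(v) == design$M)
  eta <- drop(design$X1 %*% beta) + u[design$subject_index]
  zeta <- drop(design$X2 %*% gamma) + v[design$subject_index]
  structure(list(beta = beta, gamma = gamma, u = u, v = v,
                 eta = eta, zeta = zeta), class = "jf_state")
}

# pack/unpack the parameter vector Omega = (beta, gamma, u, v)
omega_layout <- function(design) {
  p1 <- ncol(design$X1); p2 <- ncol(design$X2); M <- design$M
  list(beta = seq_len(p1), gamma = p1 + seq_len(p2),
       u = p1 + p2 + seq_len(M), v = p1 + p2 + M + seq_len(M),
       p1 = p1, p2 = p2, M = M, total = p1 + p2 + 2 * M)
}

state_from_omega <- function(omega, design) {
  lay <- omega_layout(design)
  make_state(omega[lay$beta], omega[lay$gamma], omega[lay$u], omega[lay$v],
             design)
}

omega_from_state <- function(state) {
  c(state$beta, state$gamma, state$u, state$v)
}

#' Score of the penalized joint log-likelihood
#'
#' Gradient of l = l1 + l2 over (beta, gamma, u, v). The Cox score in the
#' linear predictor is delta_l - e^(lp_l) sum over event times whose risk
#' set contains l of m_r / D_r; it is pushed through the design matrices,
#' and the frailty blocks receive the Gaussian penalty
#' -(Gamma^{-1} kron I_M) q.
#'
#' @param state a `jf_state`.
#' @param phi a `jf_phi`.
#' @param risksets a `jf_risksets`.
#' @param design a `jf_design`.
#' @return numeric vector of length p1 + p2 + 2M in (beta, gamma, u, v)
#'   order.
#' @export
joint_score <- function(state, phi, risksets, design) {
  gR <- cox_core(risksets$R, state$eta, "score")$score
  gD <- cox_core(risksets$D, state$zeta, "score")$score
  Gi <- gamma_inverse(phi)
  g_u <- rowsum(gR, design$subject_index, reorder = TRUE)[, 1] -
    (Gi[1, 1] * state$u + Gi[1, 2] * state$v)
  g_v <- rowsum(gD, design$subject_index, reorder = TRUE)[, 1] -
    (Gi[1, 2] * state$u + Gi[2, 2] * state$v)
  unname(c(drop(crossprod(design$X1, gR)), drop(crossprod(design$X2, gD)),
           g_u, g_v))
}

# Observed information of l = l1 + l2 over (beta, gamma, u, v).
# The Cox information in the linear predictor, diag(d) - W diag(m) W',
# is congruence-transformed by [X Z] using the subject-incidence structure
# of Z1 (rowsum aggregation), then the penalty Gamma^{-1} kron I_M is added
# to the (u, v) block.
#' Observed information matrix and its inverse blocks
#'
#' @inheritParams joint_score
#' @param inverse if `TRUE`, also return the (beta, beta), (gamma, gamma)
#'   blocks of G^{-1} and summaries of the random-effect block B_qq (its
#'   diagonal and the traces of its u-u, u-v, v-v sub-blocks, which are what
#'   the REML update consumes).
#' @return a list of class `jf_information` with `G` (the full observed
#'   information) and, if requested, `B_beta`, `B_gamma`, `diag_qq`,
#'   `tr_Buu`, `tr_Buv`, `tr_Bvv`.
#' @export
joint_information <- function(state, phi, risksets, design,
                              inverse = TRUE) {
  lay <- omega_layout(design)
  G <- matrix(0, lay$total, lay$total)
  si <- design$subject_index

  # one process: congruence of diag(d) - W diag(m) W' by [X Z], using the
  # subject-incidence structure of Z (rowsum aggregation)
  process_block <- function(rs, lp, X) {
    cc <- cox_core(rs, lp, "info")
    XdX <- crossprod(X, cc$d * X)
    XdZ <- t(rowsum(cc$d * X, si, reorder = TRUE))       # p x M
    Q <- diag(rowsum(cc$d, si, reorder = TRUE)[, 1], lay$M)
    if (length(cc$m) > 0) {
      UX <- crossprod(X, cc$W)                           # p x K
      UZ <- rowsum(cc$W, si, reorder = TRUE)             # M x K
      XdX <- XdX - UX %*% (cc$m * t(UX))
      XdZ <- XdZ - UX %*% (cc$m * t(UZ))
      Q <- Q - UZ %*% (cc$m * t(UZ))
    }
    list(XX = XdX, XZ = XdZ, ZZ = Q)
  }
  bR <- process_block(risksets$R, state$eta, design$X1)
  bD <- process_block(risksets$D, state$zeta, design$X2)
  G[lay$beta, lay$beta] <- bR$XX
  G[lay$beta, lay$u] <- bR$XZ
  G[lay$u, lay$beta] <- t(bR$XZ)
  G[lay$gamma, lay$gamma] <- bD$XX
  G[lay$gamma, lay$v] <- bD$XZ
  G[lay$v, lay$gamma] <- t(bD$XZ)

  # Gaussian penalty on (u, v): Gamma^{-1} kron I_M
  Gi <- gamma_inverse(phi)
  Quu <- bR$ZZ
  Qvv <- bD$ZZ
  diag(Quu) <- diag(Quu) + Gi[1, 1]
  diag(Qvv) <- diag(Qvv) + Gi[2, 2]
  G[lay$u, lay$u] <- Quu
  G[lay$v, lay$v] <- Qvv
  G[lay$u, lay$v] <- diag(Gi[1, 2], lay$M)
  G[lay$v, lay$u] <- diag(Gi[1, 2], lay$M)

  out <- list(G = G, layout = lay)
  if (inverse) {
    # fixed effects of a process with no events carry no information
    # (identically zero rows); invert the informative submatrix and
    # report NA blocks for the rest
    act <- c(if (risksets$R$n_events > 0) lay$beta,
             if (risksets$D$n_events > 0) lay$gamma,
             lay$u, lay$v)
    act <- sort(act)
    ch <- tryCatch(chol(G[act, act]), error = function(e) {
      stop("numerical error: information matrix not positive definite ",
           "(possible causes: rho near +/-1, separation): ",
           conditionMessage(e), call. = FALSE)
    })
    Ginv_act <- chol2inv(ch)
    Ginv <- matrix(NA_real_, lay$total, lay$total)
    Ginv[act, act] <- Ginv_act
    out$B_beta <- Ginv[lay$beta, lay$beta, drop = FALSE]
    out$B_gamma <- Ginv[lay$gamma, lay$gamma, drop = FALSE]
    out$diag_qq <- diag(Ginv)[c(lay$u, lay$v)]
    out$tr_Buu <- sum(diag(Ginv)[lay$u])
    out$tr_Bvv <- sum(diag(Ginv)[lay$v])
    out$tr_Buv <- sum(Ginv[cbind(lay$u, lay$v)])
    qq <- c(lay$u, lay$v)
    out$logdet_qq <- 2 * sum(log(diag(chol(G[qq, qq]))))
  }
  structure(out, class = "jf_information")
}
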