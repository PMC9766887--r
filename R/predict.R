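#' Breslow-type baseline survival estimator
#'
#' Estimates the baseline survival functions of the recurrent and terminal
#' processes from a fitted joint model: the cumulative hazard jumps by
#' m_r / sum_{l in R(t_r)} e^(lp_l) at each distinct uncensored gap time,
#' with the fitted linear predictors (including the predicted frailties) in
#' the denominators, and S_0(t) = exp(-H_0(t)). The exponential tail rate
#' lambda_hat = -log S_0(t_h) / t_h (t_h the largest uncensored time)
#' extends the estimate beyond the last event.
#'
#' @param fit a `jf_fit`.
#' @return an object of class `jf_baseline`: a list with components `R` and
#'   `D`, each holding `times` (jump times), `cumhaz`, `surv`, `t_h`,
#'   `tail_rate` (NA when the process has no events and the step estimate
#'   is identically 1).
#' @export
breslow_baseline <- function(fit) {
  stopifnot(inherits(fit, "jf_fit"))
  one <- function(rs, lp) {
    K <- length(rs$event_times)
    if (K == 0) {
      return(list(times = numeric(0), cumhaz = numeric(0),
                  surv = numeric(0), t_h = NA_real_, tail_rate = NA_real_))
    }
    c0 <- max(lp)
    elp <- exp(lp - c0)
    ord <- order(rs$time)
    cs <- rev(cumsum(rev(elp[ord])))
    pos <- findInterval(rs$event_times, rs$time[ord], left.open = TRUE) + 1L
    D <- cs[pos] * exp(c0)
    cumhaz <- cumsum(rs$m / D)
    t_h <- rs$event_times[K]
    list(times = rs$event_times, cumhaz = cumhaz, surv = exp(-cumhaz),
         t_h = t_h, tail_rate = cumhaz[K] / t_h)
  }
  structure(list(R = one(fit$risksets$R, fit$state$eta),
                 D = one(fit$risksets$D, fit$state$zeta)),
            class = "jf_baseline")
}

#' Evaluate a baseline survival function with exponential tail completion
#'
#' Returns the Breslow step estimate S_i0(t) for t <= t_h and the
#' exponential tail exp(-lambda_hat t) for t > t_h; the two agree at t_h by
#' construction of the tail rate.
#'
#' @param baseline a `jf_baseline`.
#' @param t evaluation time(s), >= 0.
#' @param process `"R"` (recurrent) or `"D"` (terminal).
#' @return survival value(s) in (0, 1].
#' @export
tail_completion <- function(baseline, t, process = c("R", "D")) {
  process <- match.arg(process)
  b <- baseline[[process]]
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (length(b$times) == 0) return(rep(1, length(t)))
  if (b$surv[length(b$surv)] <= 0) {
    stop("tail undefined: baseline survival reaches 0 at the last event",
         call. = FALSE)
  }
  idx <- findInterval(t, b$times)
  out <- ifelse(idx == 0, 1, b$surv[pmax(idx, 1L)])
  tail <- t > b$t_h
  out[tail] <- exp(-b$tail_rate * t[tail])
  out
}

lp_pair <- function(beta, gamma, X) {
  X <- unname(rbind(X))
  if (ncol(X) != length(beta) || ncol(X) != length(gamma)) {
    stop("covariate dimension mismatch", call. = FALSE)
  }
  list(eR = exp(drop(X %*% beta)), eD = exp(drop(X %*% gamma)))
}

#' Predicted event-free survival for a covariate profile
#'
#' S_hat(t; X) = S_R0(t)^exp(X'beta) * S_D0(t)^exp(X'gamma): the
#' probability of remaining free of both a recurrent event and death at
#' gap time t, for a subject with covariates X and zero frailty.
#'
#' @param baseline a `jf_baseline`.
#' @param beta,gamma fitted coefficient vectors.
#' @param X a covariate vector (or matrix with one row per profile).
#' @param t evaluation time(s).
#' @return a numeric vector (single profile) or matrix (profiles x times).
#' @export
predict_survival <- function(baseline, beta, gamma, X, t) {
  e <- lp_pair(beta, gamma, X)
  sR <- tail_completion(baseline, t, "R")
  sD <- tail_completion(baseline, t, "D")
  out <- outer(e$eR, log(sR)) + outer(e$eD, log(sD))
  out <- exp(out)
  if (nrow(out) == 1) drop(out) else out
}

#' Mean residual life for a covariate profile
#'
#' m(t; X) = E(T - t | T > t; X) = integral of S(s; X) over (t, Inf)
#' divided by S(t; X), with S from [predict_survival()]. The integral is
#' computed exactly: between consecutive knots (the union of the two
#' processes' jump times) the powered product survival is either constant
#' or a single exponential decay (once a process has passed its last event
#' time its baseline is an exponential tail), and beyond the later of the
#' two tail starts the remaining integral is
#' S(t*; X) / (lambda_R e^(X'beta) + lambda_D e^(X'gamma)) in closed form.
#'
#' @inheritParams predict_survival
#' @param t time(s) from which residual life is measured.
#' @return mean residual life value(s), same shape as
#'   [predict_survival()].
#' @export
mean_residual_life <- function(baseline, beta, gamma, X, t) {
  e <- lp_pair(beta, gamma, X)
  X <- rbind(X)
  thR <- if (length(baseline$R$times)) baseline$R$t_h else 0
  thD <- if (length(baseline$D$times)) baseline$D$t_h else 0
  lamR <- if (length(baseline$R$times)) baseline$R$tail_rate else 0
  lamD <- if (length(baseline$D$times)) baseline$D$tail_rate else 0
  t_star <- max(thR, thD)
  knots <- sort(unique(c(baseline$R$times, baseline$D$times, thR, thD)))

  one <- function(i, t0) {
    rate_star <- lamR * e$eR[i] + lamD * e$eD[i]
    if (rate_star <= 0) {
      stop("infinite mean residual life: combined tail rate is zero",
           call. = FALSE)
    }
    s_t0 <- predict_survival(baseline, beta, gamma, X[i, ], t0)
    if (s_t0 <= 0) {
      stop("mean residual life undefined: survival is 0 at t", call. = FALSE)
    }
    ks <- c(t0, knots[knots > t0 & knots <= t_star], t_star)
    ks <- unique(ks)
    total <- 0
    if (length(ks) > 1) {
      left <- ks[-length(ks)]
      width <- diff(ks)
      sv <- predict_survival(baseline, beta, gamma, X[i, ], left)
      # decay rate on [left, left + width): tails only once past t_h
      mu <- lamR * e$eR[i] * (left >= thR) + lamD * e$eD[i] * (left >= thD)
      seg <- ifelse(mu > 0, sv / mu * (1 - exp(-mu * width)), sv * width)
      total <- sum(seg)
    }
    s_star <- if (t0 >= t_star) s_t0 else
      predict_survival(baseline, beta, gamma, X[i, ], t_star)
    if (t0 >= t_star) {
      # entirely in the joint exponential tail: memoryless closed form
      total <- s_t0 / rate_star
    } else {
      total <- total + s_star / rate_star
    }
    total / s_t0
  }
  out <- vapply(seq_len(nrow(X)), function(i) {
    vapply(t, function(tt) one(i, tt), numeric(1))
  }, numeric(length(t)))
  out <- matrix(out, nrow = nrow(X), byrow = TRUE)
  if (nrow(out) == 1) drop(out) else out
}

#' Predicted survival and mean residual life curves from a fit
#'
#' Convenience wrapper: computes the Breslow baselines and evaluates
#' [predict_survival()] and [mean_residual_life()] on a time grid for one
#' or more covariate profiles (zero frailty).
#'
#' @param object a `jf_fit`.
#' @param X covariate vector or matrix (profiles in rows).
#' @param times evaluation grid; default is the union of baseline jump
#'   times with 200 equally spaced points up to 1.5 times the last event
#'   time.
#' @param ... unused.
#' @return a data.frame with columns `profile`, `time`, `survival`, `mrl`.
#' @export
predict.jf_fit <- function(object, X, times = NULL, ...) {
  b <- breslow_baseline(object)
  if (is.null(times)) {
    t_star <- max(b$R$t_h, b$D$t_h, na.rm = TRUE)
    times <- sort(unique(c(b$R$times, b$D$times,
                           seq(0, 1.5 * t_star, length.out = 200))))
  }
  X <- rbind(X)
  sv <- predict_survival(b, object$beta, object$gamma, X, times)
  ml <- mean_residual_life(b, object$beta, object$gamma, X, times)
  sv <- matrix(sv, nrow = nrow(X))
  ml <- matrix(ml, nrow = nrow(X))
  data.frame(profile = rep(seq_len(nrow(X)), each = length(times)),
             time = rep(times, nrow(X)),
             survival = as.vector(t(sv)), mrl = as.vector(t(ml)))
}
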