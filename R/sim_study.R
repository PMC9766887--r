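#' Coverage of normal-approximation confidence intervals
#'
#' Fraction of replicates whose interval `estimate +/- z * se` contains the
#' true value, at the given level. Replicates with missing estimate or
#' standard error are dropped.
#'
#' @param estimates,ses numeric vectors of equal length.
#' @param truth true parameter value.
#' @param level confidence level (default 0.95).
#' @return a fraction in \[0, 1\] (NA if no usable replicates remain).
#' @export
coverage <- function(estimates, ses, truth, level = 0.95) {
  if (length(estimates) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(estimates) == length(ses))
  ok <- is.finite(estimates) & is.finite(ses)
  if (!any(ok)) return(NA_real_)
  z <- stats::qnorm(1 - (1 - level) / 2)
  mean(abs(estimates[ok] - truth) <= z * ses[ok])
}

# per-replicate parameter extraction; theta reported on the SD scale with
# delta-method SEs: se(theta) = se(theta^2) / (2 theta)
extract_joint <- function(fit) {
  th_u <- sqrt(fit$phi$theta_u2)
  th_v <- sqrt(fit$phi$theta_v2)
  est <- c(stats::setNames(fit$beta, paste0("beta", seq_along(fit$beta))),
           stats::setNames(fit$gamma, paste0("gamma", seq_along(fit$gamma))),
           theta_u = th_u, theta_v = th_v, rho = fit$phi$rho)
  se <- c(stats::setNames(fit$se_beta, paste0("beta", seq_along(fit$beta))),
          stats::setNames(fit$se_gamma,
                          paste0("gamma", seq_along(fit$gamma))),
          theta_u = unname(fit$se_phi["theta_u2"]) / (2 * th_u),
          theta_v = unname(fit$se_phi["theta_v2"]) / (2 * th_v),
          rho = unname(fit$se_phi["rho"]))
  list(est = est, se = se, converged = fit$converged)
}

extract_separate <- function(fit) {
  rec <- fit$recurrent
  term <- fit$terminal
  est <- c(stats::setNames(rec$coef, paste0("beta", seq_along(rec$coef))),
           stats::setNames(term$coef, paste0("gamma", seq_along(term$coef))),
           theta_u = sqrt(rec$theta2), theta_v = sqrt(term$theta2),
           rho = NA_real_)
  se <- c(stats::setNames(rec$se, paste0("beta", seq_along(rec$coef))),
          stats::setNames(term$se, paste0("gamma", seq_along(term$coef))),
          theta_u = NA_real_, theta_v = NA_real_, rho = NA_real_)
  list(est = est, se = se,
       converged = rec$converged && term$converged)
}

truth_vector <- function(config) {
  c(stats::setNames(config$beta, paste0("beta", seq_along(config$beta))),
    stats::setNames(config$gamma, paste0("gamma", seq_along(config$gamma))),
    theta_u = config$theta_u, theta_v = config$theta_v, rho = config$rho)
}

#' Run a replicated simulation study
#'
#' Simulates `n_replicates` datasets from a scenario configuration (seeded
#' `base_seed + r` for replicate r, so replicates are independent,
#' reproducible jobs), fits the requested models to each, and aggregates
#' the evaluation metrics per parameter: bias (mean estimate minus truth),
#' SEE (mean of the model-reported standard errors), SE (standard
#' deviation of the estimates across replicates), and CP (coverage of the
#' 95% normal-approximation interval). Frailty standard deviations are
#' reported on the theta (SD) scale. Non-converged replicates are excluded
#' from aggregation and counted.
#'
#' @param config a `jf_sim_config` (e.g. from [preset_config()]).
#' @param n_replicates number of replicates (>= 1).
#' @param base_seed integer base seed.
#' @param models `"joint"`, `"separate"`, or `"both"`.
#' @param control a `jf_fit_control`; set `phi_se = TRUE` to obtain SEE and
#'   CP for the variance components (slower).
#' @param level confidence level for CP.
#' @return a list of class `jf_study` with one `jf_metrics` data.frame per
#'   fitted model (`joint`, `separate`), each with columns `parameter`,
#'   `truth`, `bias`, `see`, `se`, `cp`, `n_converged`; per-replicate
#'   estimates are kept in `attr(metrics, "replicates")` for audit.
#' @export
run_study <- function(config, n_replicates = 100, base_seed = 20210101,
                      models = c("both", "joint", "separate"),
                      control = fit_control(), level = 0.95) {
  stopifnot(inherits(config, "jf_sim_config"), n_replicates >= 1)
  models <- match.arg(models)
  do_joint <- models %in% c("both", "joint")
  do_sep <- models %in% c("both", "separate")
  truth <- truth_vector(config)

  res <- list(joint = list(), separate = list())
  for (r in seq_len(n_replicates)) {
    sim <- simulate_dataset(config, seed = base_seed + r)
    if (do_joint) {
      res$joint[[r]] <- tryCatch(
        extract_joint(fit_joint(sim$table, control)),
        error = function(e) NULL)
    }
    if (do_sep) {
      res$separate[[r]] <- tryCatch(
        extract_separate(fit_separate_frailty(sim$table, control)),
        error = function(e) NULL)
    }
  }

  aggregate_one <- function(lst) {
    lst <- Filter(function(x) !is.null(x) && x$converged, lst)
    if (length(lst) == 0) stop("all replicates failed or did not converge",
                               call. = FALSE)
    est <- do.call(rbind, lapply(lst, `[[`, "est"))
    ses <- do.call(rbind, lapply(lst, `[[`, "se"))
    params <- names(truth)
    metrics <- data.frame(
      parameter = params, truth = unname(truth),
      bias = colMeans(est[, params, drop = FALSE]) - unname(truth),
      see = colMeans(ses[, params, drop = FALSE]),
      se = if (nrow(est) > 1) {
        apply(est[, params, drop = FALSE], 2, stats::sd)
      } else NA_real_,
      cp = vapply(params, function(p) {
        if (all(!is.finite(ses[, p]))) NA_real_ else
          coverage(est[, p], ses[, p], truth[p], level)
      }, numeric(1)),
      n_converged = length(lst), row.names = NULL)
    # parameters the model cannot estimate (e.g. rho for the separate
    # model) carry NA estimates throughout
    bad <- !is.finite(colMeans(est[, params, drop = FALSE]))
    metrics$bias[bad] <- NA_real_
    metrics$se[bad] <- NA_real_
    structure(metrics, replicates = list(est = est, se = ses),
              class = c("jf_metrics", "data.frame"))
  }

  out <- list(config = config, n_replicates = n_replicates,
              base_seed = base_seed)
  if (do_joint) out$joint <- aggregate_one(res$joint)
  if (do_sep) out$separate <- aggregate_one(res$separate)
  structure(out, class = "jf_study")
}

#' Side-by-side comparison of joint and separate-model metrics
#'
#' Renders the two metrics tables in the familiar simulation-table layout
#' (Bias, SEE, SE, CP per model); cells the separate model cannot estimate
#' (the correlation, frailty-SD standard errors) are shown as `"n.a."`.
#'
#' @param joint,separate `jf_metrics` tables for the same parameters.
#' @return a data.frame of class `jf_comparison` (numeric columns
#'   suffixed `_joint` / `_separate`).
#' @export
summarize_comparison <- function(joint, separate) {
  if (!identical(joint$parameter, separate$parameter)) {
    stop("parameter mismatch between metrics tables", call. = FALSE)
  }
  out <- data.frame(parameter = joint$parameter, truth = joint$truth,
                    bias_joint = joint$bias, see_joint = joint$see,
                    se_joint = joint$se, cp_joint = joint$cp,
                    bias_separate = separate$bias,
                    see_separate = separate$see,
                    se_separate = separate$se, cp_separate = separate$cp)
  structure(out, class = c("jf_comparison", "data.frame"))
}

#' @export
print.jf_comparison <- function(x, digits = 3, ...) {
  fmt <- function(v) ifelse(is.finite(v), formatC(v, digits = digits,
                                                  format = "f"), "n.a.")
  disp <- data.frame(parameter = x$parameter,
                     truth = formatC(x$truth, digits = digits, format = "f"))
  for (col in setdiff(names(x), c("parameter", "truth"))) {
    disp[[col]] <- fmt(x[[col]])
  }
  print(disp, row.names = FALSE)
  invisible(x)
}
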