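# shared fixtures, built in code

# three independent subjects, one gap each: recurrent events at 1 and 2,
# censoring at 3; no deaths; covariate x = (1, 0, 0)
toy3 <- function() {
  event_table(data.frame(
    subject_id = c("a", "b", "c"), gap_index = 1,
    gap_time = c(1, 2, 3), recurrent_event = c(1, 1, 0),
    death_event = 0, x = c(1, 0, 0)))
}

# tied version: events at 1, 1 and censoring at 2
toy_tied <- function() {
  event_table(data.frame(
    subject_id = c("a", "b", "c"), gap_index = 1,
    gap_time = c(1, 1, 2), recurrent_event = c(1, 1, 0),
    death_event = 0, x = c(1, 0, 0)))
}

# a fully censored table (no events in either process)
toy_censored <- function(M = 4) {
  event_table(data.frame(
    subject_id = letters[seq_len(M)], gap_index = 1,
    gap_time = seq_len(M) * 10, recurrent_event = 0, death_event = 0,
    x = rnorm(M)))
}

# small simulated dataset with plenty of events (scaled-up hazards so the
# follow-up window sees many failures at modest M)
small_sim <- function(M = 40, seed = 1, rho = 0.5, ...) {
  cfg <- sim_config(M = M, lambda_R = 3e-4, lambda_D = 2e-4,
                    theta_u = 0.7, theta_v = 0.7, rho = rho, ...)
  simulate_dataset(cfg, seed = seed)
}

# quick controls for small fits
fast_control <- function(...) {
  fit_control(max_outer = 60L, ...)
}

# a hand-built fit-like object for the prediction layer: baselines come
# straight from risk sets and fixed linear predictors
fake_fit <- function(table, eta = NULL, zeta = NULL) {
  design <- build_design(table)
  rs <- build_risk_sets(table, design)
  n <- nrow(table)
  structure(list(risksets = rs,
                 state = list(eta = if (is.null(eta)) rep(0, n) else eta,
                              zeta = if (is.null(zeta)) rep(0, n) else zeta),
                 design = design),
            class = "jf_fit")
}
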