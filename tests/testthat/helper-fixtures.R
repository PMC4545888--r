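# shared small fixtures for the unit tests (heavier shared simulations for
# the acceptance checks are built inside test-acceptance.R)

cond_cong4 <- trial_condition(4, "R1", "E_right")
cond_incong4 <- trial_condition(4, "L1", "E_right")

zero_noise <- function(params) {
  update_params(params, c_lip = 0, c_it = 0, c_maip = 0)
}

# deterministic Heun (RK2) reference integrator built on the R drift
# implementation; independent of the compiled engine
r_integrate <- function(params, condition, t_end, dt = 0.5,
                        engine = list()) {
  x <- network_state()
  t <- 0
  steps <- round(t_end / dt)
  out <- matrix(NA_real_, nrow = steps + 1, ncol = 20)
  out[1, ] <- x
  cst <- attr(params, "constants")
  cap <- cst$motor_cap
  for (k in seq_len(steps)) {
    f0 <- lca_drift(x, params, condition, t, engine)$drift
    xt <- x + dt * f0
    f1 <- lca_drift(xt, params, condition, t + dt, engine)$drift
    x <- x + dt / 2 * (f0 + f1)
    x[19:20] <- pmin(x[19:20], cap)
    x[17:20] <- pmax(x[17:20], 0)
    t <- t + dt
    out[k + 1, ] <- x
  }
  colnames(out) <- names(network_state())
  out
}
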