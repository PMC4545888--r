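test_that("a fixed seed reproduces trials and batches bit-identically", {
  tr1 <- simulate_trial(params_m11(), cond_cong4, seed = 42)
  tr2 <- simulate_trial(params_m11(), cond_cong4, seed = 42)
  expect_identical(tr1, tr2)
  b1 <- simulate_batch(params_m11(), cond_cong4, 50, seed = 7)
  b2 <- simulate_batch(params_m11(), cond_cong4, 50, seed = 7)
  expect_identical(b1$trials, b2$trials)
  b3 <- simulate_batch(params_m11(), cond_cong4, 50, seed = 8)
  expect_false(identical(b1$trials$rt_ms, b3$trials$rt_ms))
})

test_that("a trial can be reproduced outside its batch from the same stream", {
  b <- simulate_batch(params_m11(), cond_cong4, 20, seed = 9)
  tr <- simulate_trial(params_m11(), cond_cong4,
    seed = 9,
    trial_index = 4, stream = 0
  )
  expect_equal(tr$rt_ms, b$trials$rt_ms[5])
  expect_equal(tr$response_side, b$trials$response_side[5])
})

test_that("zero-noise trials are deterministic and identical across seeds", {
  p0 <- zero_noise(params_m12())
  tr1 <- simulate_trial(p0, cond_cong4, seed = 1)
  tr2 <- simulate_trial(p0, cond_cong4, seed = 999)
  expect_equal(tr1$rt_ms, tr2$rt_ms)
  expect_equal(tr1$crossing_ms, tr2$crossing_ms)
})

test_that("zero-noise integration matches the R reference RK2 integrator", {
  p0 <- zero_noise(params_m11())
  tr <- simulate_trial(p0, cond_incong4,
    seed = 1, t_max = 200,
    keep_trajectory = TRUE, sample_every = 1
  )
  traj <- attr(tr, "trajectory")
  ref <- r_integrate(p0, cond_incong4, t_end = 200)
  # compare at the 1-ms marks (ref computed at 0.5-ms steps)
  ref_ms <- ref[seq(1, nrow(ref), by = 2), ]
  for (j in seq_len(20)) {
    expect_equal(
      traj[[names(network_state())[j]]],
      unname(ref_ms[seq_len(nrow(traj)), j]),
      tolerance = 1e-10
    )
  }
})

test_that("zero-noise deterministic response follows the target drive", {
  # right-facing target, congruent: the only orientation drive is rightward
  p0 <- zero_noise(params_m12())
  tr <- simulate_trial(p0, cond_cong4, seed = 1, engine = list())
  # M12 zero-noise dynamics stay below threshold (noise-driven crossings);
  # M11 crosses deterministically on the correct side
  tr11 <- simulate_trial(zero_noise(params_m11()), cond_cong4, seed = 1)
  expect_false(tr11$timed_out)
  expect_equal(tr11$response_side, "R")
  expect_true(tr11$correct)
  expect_equal(tr11$rt_ms, tr11$crossing_ms + params_m11()$t_0)
})

test_that("halving dt changes the zero-noise crossing time by < 1 ms", {
  p0 <- zero_noise(params_m11())
  t1 <- simulate_trial(p0, cond_cong4, seed = 1)$crossing_ms
  t2 <- simulate_trial(p0, cond_cong4, seed = 1, engine = list(dt = 0.25))$crossing_ms
  expect_lt(abs(t1 - t2), 1)
})

test_that("an unreachable threshold above the motor cap times out", {
  p <- update_params(params_m11(), theta = 0.2) # above the 0.150 kHz cap
  tr <- simulate_trial(p, cond_cong4, seed = 3, t_max = 500)
  expect_true(tr$timed_out)
  expect_true(is.na(tr$rt_ms))
})

test_that("motor activities never exceed the 150 Hz cap", {
  p <- update_params(params_m11(), c_maip = 3) # exaggerated motor noise
  tr <- simulate_trial(p, cond_cong4,
    seed = 5, t_max = 800,
    keep_trajectory = TRUE
  )
  traj <- attr(tr, "trajectory")
  expect_true(all(traj$x_m_L <= 0.150 + 1e-12))
  expect_true(all(traj$x_m_R <= 0.150 + 1e-12))
  expect_true(all(traj$x_m_L >= 0 & traj$x_m_R >= 0))
})

test_that("OU input processes reach the closed-form stationary moments", {
  # freeze every input so a LIP rho is a pure OU process around s_back:
  # tau dr = (s_back - r) dt + c dW => mean s_back, var c^2/(2 tau)
  p <- update_params(params_m11(),
    s_lip = 0, s_tar = 0, s_back = 0.3, c_lip = 1.2,
    c_it = 0, c_maip = 0
  )
  tr <- simulate_trial(p, cond_cong4,
    seed = 8, t_max = 1500, keep_trajectory = TRUE,
    engine = list(dt = 0.5)
  )
  traj <- attr(tr, "trajectory")
  # pool the six iid rho channels, discarding a 100-ms burn-in
  rho <- unlist(traj[traj$t_ms > 100, paste0("rho_lip_", c(
    "L1", "L2", "L3", "R1", "R2", "R3"
  ))])
  # autocorrelation (tau = 5 ms) leaves ~1e3 effective samples
  expect_equal(mean(rho), 0.3, tolerance = 0.15)
  expect_equal(var(rho), 1.2^2 / (2 * 5), tolerance = 0.15)
})

test_that("mirrored conditions produce mirrored response statistics", {
  b_r <- simulate_batch(params_m11(), cond_cong4, 400, seed = 21)
  cond_mirror <- trial_condition(4, "L1", "E_left") # mirror of (R1, E_right)
  b_l <- simulate_batch(params_m11(), cond_mirror, 400, seed = 21)
  # both are congruent conditions with all drives mirrored: accuracy and
  # RT distributions agree within sampling error
  expect_equal(
    mean(b_r$trials$correct), mean(b_l$trials$correct),
    tolerance = 0.05
  )
  expect_equal(
    mean(b_r$trials$rt_ms, na.rm = TRUE),
    mean(b_l$trials$rt_ms, na.rm = TRUE),
    tolerance = 0.05
  )
  expect_equal(
    mean(b_r$trials$response_side == "R", na.rm = TRUE),
    mean(b_l$trials$response_side == "L", na.rm = TRUE),
    tolerance = 0.05
  )
})

test_that("batch summaries conserve counts and define accuracy on responders", {
  b <- simulate_batch(params_m12(), rbind(cond_cong4, cond_incong4),
    150,
    seed = 31
  )
  g <- glance(b)
  expect_equal(sum(g$n), 300)
  tr <- b$trials[b$trials$congruent, ]
  expect_equal(
    g$accuracy[g$congruent],
    sum(tr$correct[!tr$timed_out]) / sum(!tr$timed_out)
  )
  s <- batch_summary(b)
  expect_equal(s$n, 300)
  expect_equal(s$n_timeout, sum(b$trials$timed_out))
})

test_that("mean trace accumulation matches single-trial trajectories", {
  p <- params_m11()
  b <- simulate_batch(p, cond_cong4, 3,
    seed = 13, keep_traces = TRUE,
    trace_t_max = 300
  )
  lip_l1 <- b$traces %>%
    dplyr::filter(unit == "L1") %>%
    dplyr::pull(rate_hz)
  manual <- sapply(0:2, function(i) {
    tr <- simulate_trial(p, cond_cong4,
      seed = 13, trial_index = i, stream = 0,
      keep_trajectory = TRUE, sample_every = 1, t_max = 1500
    )
    attr(tr, "trajectory")$x_lip_L1[1:301]
  })
  expect_equal(lip_l1, rowMeans(manual) * 1000, tolerance = 1e-10)
})
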