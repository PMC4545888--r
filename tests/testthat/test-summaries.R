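test_that("congruence follows the response-hemifield rule", {
  expect_true(trial_condition(4, "R1", "E_right")$congruent)
  expect_false(trial_condition(4, "L1", "E_right")$congruent)
  expect_true(trial_condition(2, "L1", "E_left")$congruent)
  expect_false(trial_condition(6, "R3", "E_left")$congruent)
  expect_equal(
    is_congruent(c("R2", "L3"), c("E_left", "E_left")),
    c(FALSE, TRUE)
  )
  # positions must be stimulated at the given set size
  expect_error(trial_condition(2, "L2", "E_left"), "not stimulated")
  expect_error(trial_condition(4, "R3", "E_left"), "not stimulated")
  expect_silent(trial_condition(6, "R3", "E_left"))
})

test_that("decision time subtracts the three latency components", {
  expect_equal(decision_time(500, params_m11()),
    500 - (24.08 + 55.72 + 169.8))
  # linear with slope 1
  rt <- seq(300, 700, by = 50)
  dt <- decision_time(rt, params_m12())
  expect_equal(diff(dt), diff(rt))
  expect_error(decision_time(100, params_m11()), "must exceed")
})

test_that("quantile bin edges follow type-7 order-statistic interpolation", {
  x <- c(300, 320, 350, 400, 420, 450, 500, 520, 580, 700)
  edges <- rt_quantile_bins(x)
  # independent arithmetic: h = (n-1)p + 1, linear interpolation
  oracle <- sapply(c(.1, .3, .5, .7, .9), function(p) {
    h <- (10 - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  })
  expect_equal(edges, oracle)
  # the extreme bins then hold exactly one of the ten samples each
  counts <- covertsearch:::bin_counts(x, edges)
  expect_equal(counts[1], 1L)
  expect_equal(counts[6], 1L)
  expect_equal(sum(counts), 10L)
})

test_that("degenerate and large-sample quantile bins behave as specified", {
  same <- rep(412, 20)
  edges <- rt_quantile_bins(same)
  expect_equal(edges, rep(412, 5))
  counts <- covertsearch:::bin_counts(same, edges)
  expect_equal(sum(counts), 20L)
  expect_equal(max(counts), 20L) # all mass in one bin
  expect_error(rt_quantile_bins(numeric(0)), "empty")

  set.seed(1)
  big <- rnorm(20000, 500, 60)
  props <- covertsearch:::bin_counts(big, rt_quantile_bins(big)) / 20000
  expect_equal(props, c(.1, .2, .2, .2, .2, .1), tolerance = 0.01)
})

test_that("kernel firing-rate estimates have unit-area Gaussian kernels", {
  # no spikes at all
  empty <- fr_from_spikes(
    tibble::tibble(trial_id = integer(), spike_time_ms = numeric()),
    trial_ids = 1:3
  )
  expect_true(all(empty$rate_hz == 0))

  # a single spike at t = 100: peak 1/(sqrt(2*pi)*0.015) ~ 26.6 Hz
  one <- fr_from_spikes(
    tibble::tibble(trial_id = 1, spike_time_ms = 100),
    trial_ids = 1
  )
  expect_equal(max(one$rate_hz), 1 / (sqrt(2 * pi) * 0.015), tolerance = 1e-6)
  expect_equal(one$t_ms[which.max(one$rate_hz)], 100)

  # time-integral of the mean trace ~ mean spike count per trial
  set.seed(2)
  spk <- tibble::tibble(
    trial_id = rep(1:20, each = 5),
    spike_time_ms = runif(100, 100, 600)
  )
  fr <- fr_from_spikes(spk, trial_ids = 1:20)
  expect_equal(sum(fr$rate_hz) / 1000, 5, tolerance = 0.01)
})

test_that("kernel estimate of a homogeneous Poisson train converges to its rate", {
  set.seed(3)
  r <- 30 # Hz
  trains <- purrr::map(1:1000, function(i) {
    n <- rpois(1, r * 1.0)
    tibble::tibble(trial_id = i, spike_time_ms = runif(n, -200, 800))
  })
  fr <- fr_from_spikes(dplyr::bind_rows(trains), trial_ids = 1:1000)
  mid <- fr$rate_hz[fr$t_ms > -100 & fr$t_ms < 700]
  expect_equal(mean(mid), r, tolerance = 0.05)
})

test_that("accuracy-vs-RT bins report occupied bins only", {
  trials <- tibble::tibble(
    set_size = 4, congruent = TRUE,
    rt_ms = c(250, 260, 340, 360, 510),
    correct = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    timed_out = FALSE
  )
  bins <- accuracy_vs_rt(trials)
  expect_equal(bins$rt_bin, c(200, 300, 500)) # the empty 400 bin is absent
  expect_equal(bins$accuracy, c(1, 0.5, 0))
  expect_equal(sum(bins$n), 5)

  # constructed accuracy decreasing in RT stays monotone after binning
  set.seed(4)
  rt <- runif(4000, 200, 800)
  tr2 <- tibble::tibble(
    set_size = 4, congruent = FALSE, rt_ms = rt,
    correct = runif(4000) < (1 - (rt - 200) / 800), timed_out = FALSE
  )
  b2 <- accuracy_vs_rt(tr2)
  expect_true(all(diff(b2$accuracy) < 0))
})

test_that("model trace labels follow the target/distractor mapping", {
  b <- simulate_batch(params_m11(), rbind(cond_cong4, cond_incong4), 5,
    seed = 2, keep_traces = TRUE, trace_t_max = 50
  )
  tr <- model_fr_traces(b)
  cong <- tr %>% dplyr::filter(congruent) %>% dplyr::distinct(unit, label)
  expect_equal(cong$label[cong$unit == "R1"], "target_in_rf")
  expect_equal(cong$label[cong$unit == "R2"], "distractor_same_hemifield")
  expect_setequal(cong$unit[cong$label == "distractor_opposite"], c("L1", "L2"))
  # lower units carry no stimulus at set size 4 and are excluded
  expect_false(any(cong$unit %in% c("L3", "R3")))
  # mirrored (incongruent) condition swaps hemifields
  inc <- tr %>% dplyr::filter(!congruent) %>% dplyr::distinct(unit, label)
  expect_equal(inc$label[inc$unit == "L1"], "target_in_rf")
  expect_equal(inc$label[inc$unit == "L2"], "distractor_same_hemifield")

  # set size 2: only the top units are labelled; no same-hemifield label
  b2 <- simulate_batch(params_m11(), trial_condition(2, "R1", "E_right"), 5,
    seed = 2, keep_traces = TRUE, trace_t_max = 50
  )
  t2 <- model_fr_traces(b2)
  expect_setequal(unique(t2$unit), c("L1", "R1"))
  expect_false("distractor_same_hemifield" %in% t2$label)
})

test_that("cell filters apply the 80 Hz and all-set-sizes rules", {
  ds <- generate_dataset(params_m11(),
    n_cells = 2, trials_per_block = 4,
    seed = 5
  )
  aug <- inject_artifacts(ds,
    hot_cells = 1, hot_rate_hz = 120,
    missing_set_size_cells = 1, dropped_set_size = 6, seed = 6
  )
  kept <- filter_cells(aug)
  excluded <- attr(kept, "excluded")
  expect_setequal(excluded, c("hot_01", "missing_01"))
  expect_setequal(kept$cells$cell_id, ds$cells$cell_id)
  expect_false(any(kept$trials$cell_id %in% excluded))
  expect_false(any(kept$spikes$cell_id %in% excluded))
  # empty artifact spec leaves the dataset unchanged
  expect_identical(inject_artifacts(ds), ds)
})
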