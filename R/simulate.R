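#' Simulate a single trial
#'
#' Integrates the 20-SDE network from cue onset (t = 0, all states zero)
#' with a second-order stochastic Runge-Kutta scheme (step `dt`, default
#' 0.5 ms) until the first motor unit reaches the threshold `theta` or
#' `t_max` is reached (a timeout). The reported reaction time is the
#' threshold-crossing time plus the nondecision time `t_0`; the response is
#' correct when its side matches the target orientation (right-facing
#' target: right release).
#'
#' @param params a [search_params()] object.
#' @param condition a one-row tibble from [trial_condition()].
#' @param seed integer master seed (every source of randomness).
#' @param t_max timeout (ms from cue onset).
#' @param keep_trajectory record the full state every `sample_every` ms.
#' @param sample_every trajectory sampling interval (ms).
#' @param engine engine options: `lip_leak` (logical, include the leak term
#'   in the LIP equations; default TRUE), `clamp_nonneg` (clamp AIP/motor
#'   activities at 0; default TRUE), `noise_scale` (`"tau"` or
#'   `"sqrt_tau"`), and overrides for `dt`, `tau_noise`, `motor_cap`.
#' @param trial_index,stream internal stream identifiers allowing a trial
#'   to be reproduced independently of the batch that contained it.
#' @return a one-row tibble: `response_side` (`"L"`, `"R"` or NA),
#'   `correct`, `rt_ms`, `crossing_ms`, `timed_out`, `seed`, plus a
#'   `trajectory` attribute (tibble: `t_ms`, one column per state) when
#'   requested.
#' @export
#' @examples
#' cond <- trial_condition(4, "R1", "E_right")
#' simulate_trial(params_m12(), cond, seed = 1)
simulate_trial <- function(params, condition, seed, t_max = 1500,
                           keep_trajectory = FALSE, sample_every = 1,
                           engine = list(), trial_index = 0, stream = 0) {
  stopifnot(inherits(params, "search_params"))
  opts <- engine_opts(params, engine)
  if (t_max <= params$p_delay + params$t_delay) {
    stop("t_max must exceed p_delay + t_delay", call. = FALSE)
  }
  cc <- condition_codes(condition)
  res <- cs_simulate_trial(
    param_vector(params), cc$set_size, cc$pos, cc$ori,
    as.numeric(seed), as.numeric(stream), as.numeric(trial_index),
    t_max, opts, keep_trajectory, sample_every, !keep_trajectory
  )
  side <- c("L", "R")[res$side + 1L]
  correct_side <- if (condition$orientation == "E_right") "R" else "L"
  out <- tibble(
    set_size = condition$set_size,
    position = condition$position,
    orientation = condition$orientation,
    congruent = condition$congruent,
    response_side = side,
    correct = side == correct_side,
    rt_ms = res$rt_ms,
    crossing_ms = res$crossing_ms,
    timed_out = is.na(res$side),
    seed = as.integer(seed)
  )
  if (keep_trajectory) {
    traj <- as_tibble(setNames(
      as.data.frame(t(res$trajectory)),
      STATE_NAMES
    ))
    traj <- bind_cols(tibble(t_ms = res$trajectory_t), traj)
    attr(out, "trajectory") <- traj
  }
  out
}

#' Simulate a batch of trials
#'
#' Runs `n_per_condition` independent trials for each row of
#' `conditions`. Per-trial noise streams are derived by hashing the master
#' seed, the condition index and the trial index, so a fixed seed gives a
#' bit-identical batch regardless of evaluation order. Mean LIP and motor
#' trajectories on a 1-ms grid can be accumulated for firing-rate
#' comparisons; when traces are kept, integration continues to
#' `trace_t_max` even after the response so post-decision suppression is
#' visible in the averages.
#'
#' @param params a [search_params()] object.
#' @param conditions a condition tibble (one or more rows from
#'   [trial_condition()]).
#' @param n_per_condition trials per condition row.
#' @param seed integer master seed.
#' @param t_max timeout (ms).
#' @param keep_traces accumulate mean unit trajectories (1-ms grid).
#' @param trace_t_max last grid time (ms) for the mean trajectories.
#' @param engine engine options (see [simulate_trial()]).
#' @return a `search_batch` object: a list with `trials` (tibble of per-
#'   trial outcomes), `traces` (tibble of mean unit activities, or NULL),
#'   `params`, `seed`. Use [tidy()][tidy.search_batch()] /
#'   [glance()][glance.search_batch()] / `autoplot()` on it.
#' @export
#' @examples
#' conds <- rbind(
#'   trial_condition(4, "R1", "E_right"),
#'   trial_condition(4, "L1", "E_right")
#' )
#' b <- simulate_batch(params_m11(), conds, n_per_condition = 200, seed = 42)
#' glance(b)
simulate_batch <- function(params, conditions, n_per_condition, seed,
                           t_max = 1500, keep_traces = FALSE,
                           trace_t_max = 800, engine = list()) {
  stopifnot(inherits(params, "search_params"), n_per_condition >= 1)
  opts <- engine_opts(params, engine)
  if (t_max <= params$p_delay + params$t_delay) {
    stop("t_max must exceed p_delay + t_delay", call. = FALSE)
  }
  pv <- param_vector(params)
  correct_side <- ifelse(conditions$orientation == "E_right", "R", "L")

  trial_rows <- vector("list", nrow(conditions))
  trace_rows <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    cc <- condition_codes(cond)
    res <- cs_simulate_batch(
      pv, cc$set_size, cc$pos, cc$ori, as.integer(n_per_condition),
      as.numeric(seed), as.numeric(ci - 1), t_max, opts,
      keep_traces, trace_t_max
    )
    side <- c("L", "R")[res$side + 1L]
    trial_rows[[ci]] <- tibble(
      condition_id = ci,
      set_size = cond$set_size,
      position = cond$position,
      orientation = cond$orientation,
      congruent = cond$congruent,
      trial = seq_len(n_per_condition),
      response_side = side,
      correct = side == correct_side[ci],
      rt_ms = res$rt_ms,
      crossing_ms = res$crossing_ms,
      timed_out = is.na(res$side)
    )
    if (keep_traces) {
      nt <- ncol(res$lip_trace_sum)
      lip <- res$lip_trace_sum / n_per_condition
      mot <- res$motor_trace_sum / n_per_condition
      trace_rows[[ci]] <- tibble(
        condition_id = ci,
        set_size = cond$set_size,
        position = cond$position,
        orientation = cond$orientation,
        congruent = cond$congruent,
        t_ms = rep(seq_len(nt) - 1, times = 8),
        unit = rep(c(LIP_LOCATIONS, "m_L", "m_R"), each = nt),
        area = rep(c(rep("lip", 6), rep("motor", 2)), each = nt),
        rate_hz = c(t(lip), t(mot)) * 1000
      )
    }
  }
  structure(
    list(
      trials = bind_rows(trial_rows),
      traces = if (keep_traces) bind_rows(trace_rows) else NULL,
      params = params,
      seed = as.integer(seed),
      n_per_condition = as.integer(n_per_condition)
    ),
    class = "search_batch"
  )
}

#' @export
print.search_batch <- function(x, ...) {
  cat(
    "<search_batch>", nrow(x$trials), "trials,",
    length(unique(x$trials$condition_id)), "condition(s), seed", x$seed, "\n"
  )
  print(glance(x))
  invisible(x)
}

#' Tidiers for simulation batches
#'
#' `tidy()` returns the per-trial outcome table; `glance()` returns one row
#' per condition with accuracy (timeouts excluded), mean RT and its
#' standard error.
#'
#' @param x a `search_batch`, `search_params` or `search_fit` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.search_batch <- function(x, ...) {
  x$trials
}

#' @rdname tidy.search_batch
#' @export
glance.search_batch <- function(x, ...) {
  x$trials %>%
    group_by(.data$set_size, .data$congruent) %>%
    summarise(
      n = dplyr::n(),
      n_timeout = sum(.data$timed_out),
      accuracy = mean(.data$correct[!.data$timed_out]),
      mean_rt_ms = mean(.data$rt_ms[!.data$timed_out]),
      sem_rt_ms = sd(.data$rt_ms[!.data$timed_out]) /
        sqrt(sum(!.data$timed_out)),
      .groups = "drop"
    )
}

#' Pooled accuracy and mean RT of a batch
#'
#' @param batch a `search_batch` object.
#' @return one-row tibble with pooled `accuracy`, `mean_rt_ms`, `sem_rt_ms`,
#'   `n`, `n_timeout` over all conditions (timeouts excluded from accuracy
#'   and RT).
#' @export
batch_summary <- function(batch) {
  tr <- batch$trials
  ok <- !tr$timed_out
  tibble(
    n = nrow(tr),
    n_timeout = sum(!ok),
    accuracy = mean(tr$correct[ok]),
    mean_rt_ms = mean(tr$rt_ms[ok]),
    sem_rt_ms = sd(tr$rt_ms[ok]) / sqrt(sum(ok))
  )
}

#' @export
#' @rdname tidy.search_batch
glance.search_params <- function(x, ...) {
  tibble(
    n_params = length(PARAM_NAMES),
    n_shared = length(SHARED_PARAMS),
    n_subject_specific = length(PARAM_NAMES) - length(SHARED_PARAMS)
  )
}
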