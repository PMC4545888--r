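#' Published behavioral summaries for the two subjects
#'
#' Accuracy and mean reaction time (±SEM) observed in the covert search
#' experiment for subjects M11 and M12, split by set size and
#' response-hemifield congruence. These observed values are the behavioral
#' reference that the model was fitted against, and are the inputs to
#' [decision_time()] reports.
#'
#' @return a tibble with columns `subject`, `set_size`, `congruent`,
#'   `accuracy_pct`, `mean_rt_ms`, `sem_rt_ms`.
#' @export
#' @examples
#' macaque_behavior() %>% dplyr::filter(set_size == 4)
macaque_behavior <- function() {
  tibble(
    subject = rep(c("M11", "M12"), each = 6),
    set_size = rep(rep(c(2L, 4L, 6L), each = 2), 2),
    congruent = rep(c(TRUE, FALSE), 6),
    accuracy_pct = c(
      97.4, 93.5, 95.8, 81.5, 92.4, 73.5,
      98.0, 98.2, 96.2, 95.9, 94.1, 93.1
    ),
    mean_rt_ms = c(
      437.6, 500.2, 444.3, 537.2, 457.6, 549.0,
      468.7, 455.1, 491.8, 488.0, 506.7, 499.7
    ),
    sem_rt_ms = c(
      4.2, 5.7, 4.0, 5.1, 3.4, 4.6,
      8.1, 7.4, 6.8, 6.0, 7.5, 6.4
    )
  )
}

#' Decision time implied by a mean reaction time
#'
#' The model decomposes a reaction time into the perceptual delay (retina
#' to LIP), the target-search delay, the nondecision (motor) time, and the
#' remaining deliberation. The decision time attributed to the accumulation
#' process is therefore `mean_rt - (p_delay + t_delay + t_0)`.
#'
#' @param mean_rt mean reaction time (ms), vectorised.
#' @param params a [search_params()] object.
#' @return decision time(s) in ms.
#' @export
#' @examples
#' delay_sum(params_m11())                 # ~250 ms of latencies
#' decision_time(444.3, params_m11())      # ~195 ms deliberation
decision_time <- function(mean_rt, params) {
  stopifnot(inherits(params, "search_params"), is.numeric(mean_rt))
  d <- delay_sum(params)
  if (any(mean_rt <= d)) {
    stop("mean_rt must exceed p_delay + t_delay + t_0 (", round(d, 2), " ms)",
      call. = FALSE
    )
  }
  mean_rt - d
}

#' @rdname decision_time
#' @export
delay_sum <- function(params) {
  stopifnot(inherits(params, "search_params"))
  params$p_delay + params$t_delay + params$t_0
}

#' Quantile bin edges for reaction-time distributions
#'
#' Returns the 0.1, 0.3, 0.5, 0.7 and 0.9 quantiles of an RT sample,
#' defining six bins of which the fastest and slowest hold 10% of the
#' trials each and the central four hold 20% each. Quantiles use linear
#' interpolation of order statistics (type 7).
#'
#' @param rt_samples numeric vector of reaction times (ms).
#' @return numeric vector of five bin edges.
#' @export
#' @examples
#' rt_quantile_bins(c(300, 320, 350, 400, 420, 450, 500, 520, 580, 700))
rt_quantile_bins <- function(rt_samples) {
  rt_samples <- rt_samples[!is.na(rt_samples)]
  if (length(rt_samples) == 0) stop("empty RT sample", call. = FALSE)
  unname(quantile(rt_samples, probs = c(0.1, 0.3, 0.5, 0.7, 0.9), type = 7))
}

# counts per quantile bin given edges (6 bins; edges belong to the lower
# bin). Duplicate edges (degenerate samples) give empty inner bins.
bin_counts <- function(rt, edges) {
  breaks <- c(-Inf, edges, Inf)
  vapply(
    seq_len(6),
    function(b) sum(rt > breaks[b] & rt <= breaks[b + 1]),
    integer(1)
  )
}

#' Accuracy as a function of reaction time
#'
#' Partitions reaction times into 100-ms bins and computes per-bin accuracy
#' separately for each set size and congruence condition. Bins with no
#' trials are omitted rather than reported as zero accuracy; timeouts are
#' excluded.
#'
#' @param trials a trial tibble (from [tidy()][tidy.search_batch()] of a
#'   batch, or the `trials` table of a dataset) with columns `rt_ms`,
#'   `correct`, `set_size`, `congruent` and optionally `timed_out`.
#' @param bin_width bin width in ms.
#' @return a tibble with `set_size`, `congruent`, `rt_bin` (left edge, ms),
#'   `n`, `accuracy`.
#' @export
accuracy_vs_rt <- function(trials, bin_width = 100) {
  stopifnot(nrow(trials) > 0)
  if ("timed_out" %in% names(trials)) {
    trials <- trials[!trials$timed_out, ]
  }
  trials %>%
    mutate(rt_bin = floor(.data$rt_ms / bin_width) * bin_width) %>%
    group_by(.data$set_size, .data$congruent, .data$rt_bin) %>%
    summarise(
      n = dplyr::n(), accuracy = mean(.data$correct),
      .groups = "drop"
    )
}

#' Firing-rate estimation from spike trains
#'
#' Convolves spike times with a unit-area Gaussian kernel (standard
#' deviation `sigma_ms`, default 15 ms) on a 1-ms grid aligned to cue
#' onset, averages over trials, and attaches the across-trial SEM. With a
#' unit-area kernel in seconds, rates are in Hz and the time-integral of a
#' trial's trace equals its spike count.
#'
#' @param spikes a tibble with columns `trial_id` and `spike_time_ms`
#'   (times relative to cue onset). Trials with no spikes must still
#'   appear in `trial_ids` to contribute zeros to the average.
#' @param trial_ids ids of all trials to average over (defaults to the
#'   trials present in `spikes`).
#' @param sigma_ms Gaussian kernel standard deviation (ms).
#' @param t_grid time grid (ms); default -200..800 in 1-ms steps.
#' @return a tibble with `t_ms`, `rate_hz`, `sem_hz`, `n_trials`.
#' @export
fr_from_spikes <- function(spikes, trial_ids = NULL, sigma_ms = 15,
                           t_grid = seq(-200, 800, by = 1)) {
  stopifnot(sigma_ms > 0)
  if (is.null(trial_ids)) trial_ids <- unique(spikes$trial_id)
  n_trials <- length(trial_ids)
  if (n_trials == 0) stop("no trials to average over", call. = FALSE)
  acc <- matrix(0, nrow = n_trials, ncol = length(t_grid))
  spk <- split(spikes$spike_time_ms, factor(spikes$trial_id, levels = trial_ids))
  for (i in seq_len(n_trials)) {
    st <- spk[[i]]
    if (length(st) == 0) next
    # unit-area Gaussian in seconds -> rate in Hz; dnorm over ms x 1000
    for (s in st) {
      acc[i, ] <- acc[i, ] + dnorm(t_grid, mean = s, sd = sigma_ms) * 1000
    }
  }
  tibble(
    t_ms = t_grid,
    rate_hz = colMeans(acc),
    sem_hz = apply(acc, 2, sd) / sqrt(n_trials),
    n_trials = n_trials
  )
}

#' Label model LIP traces by their relation to the target
#'
#' Maps each LIP unit's mean trajectory in a batch to the condition labels
#' used for data comparison: the unit with the target in its receptive
#' field is `target_in_rf`; stimulated units in the target's hemifield are
#' `distractor_same_hemifield`; stimulated units in the opposite hemifield
#' are `distractor_opposite`. Units without stimulus input at the given set
#' size are excluded (at set size 4 the lower two units; at set size 2 the
#' four non-top units, and no same-hemifield distractor exists).
#'
#' @param batch a `search_batch` simulated with `keep_traces = TRUE`.
#' @return a tibble `condition_id`, `set_size`, `congruent`, `unit`,
#'   `label`, `t_ms`, `rate_hz` (LIP units only, rates in Hz).
#' @export
model_fr_traces <- function(batch) {
  stopifnot(inherits(batch, "search_batch"))
  if (is.null(batch$traces)) {
    stop("batch was simulated without keep_traces = TRUE", call. = FALSE)
  }
  tr <- batch$traces %>% filter(.data$area == "lip")
  tr %>%
    mutate(
      stimulated = (.data$unit %in% c("L1", "R1")) |
        (.data$set_size >= 4 & .data$unit %in% c("L2", "R2")) |
        .data$set_size == 6,
      label = dplyr::case_when(
        .data$unit == .data$position ~ "target_in_rf",
        substr(.data$unit, 1, 1) == substr(.data$position, 1, 1) ~
          "distractor_same_hemifield",
        TRUE ~ "distractor_opposite"
      )
    ) %>%
    filter(.data$stimulated) %>%
    select(
      "condition_id", "set_size", "congruent", "unit", "label",
      "t_ms", "rate_hz"
    )
}

#' Cell exclusion filters for spike datasets
#'
#' Removes cells whose maximum smoothed firing rate (Gaussian kernel,
#' 15 ms) exceeds `max_fr_hz` (default 80 Hz), and cells that lack trials
#' at any of the three set sizes, mirroring the selection applied to the
#' recorded population before analysis and fitting.
#'
#' @param dataset a `spike_dataset` (see [generate_dataset()]) or a list
#'   with `cells`, `trials`, `spikes` tibbles.
#' @param max_fr_hz exclusion threshold on the peak of the cell's mean
#'   firing-rate trace (Hz).
#' @param required_set_sizes set sizes that every retained cell must have
#'   trials for.
#' @return the dataset with excluded cells (and their trials/spikes)
#'   removed; excluded cell ids are recorded in the `excluded` attribute.
#' @export
filter_cells <- function(dataset, max_fr_hz = 80,
                         required_set_sizes = c(2, 4, 6)) {
  stopifnot(all(c("cells", "trials", "spikes") %in% names(dataset)))
  drop <- character(0)
  for (cid in dataset$cells$cell_id) {
    ctr <- dataset$trials %>% filter(.data$cell_id == cid)
    if (!all(required_set_sizes %in% ctr$set_size)) {
      drop <- c(drop, cid)
      next
    }
    csp <- dataset$spikes %>% filter(.data$cell_id == cid)
    if (nrow(csp) > 0) {
      fr <- fr_from_spikes(csp, trial_ids = ctr$trial_id)
      if (max(fr$rate_hz) > max_fr_hz) drop <- c(drop, cid)
    }
  }
  out <- dataset
  out$cells <- dataset$cells %>% filter(!.data$cell_id %in% drop)
  out$trials <- dataset$trials %>% filter(!.data$cell_id %in% drop)
  out$spikes <- dataset$spikes %>% filter(!.data$cell_id %in% drop)
  attr(out, "excluded") <- drop
  out
}
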