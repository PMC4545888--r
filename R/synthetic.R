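#' Generate a surrogate spike/behavior dataset
#'
#' Emulates the structure of the recorded covert-search dataset: cells
#' with assigned receptive-field locations, trials organised in
#' fixed-set-size blocks with target location and orientation drawn
#' uniformly at random, behavioral outcomes, and per-trial spike times
#' aligned to cue onset. Each trial is simulated from the network model;
#' the spike train of a cell is an inhomogeneous Poisson process whose
#' intensity is the trajectory of the LIP unit matching the cell's
#' receptive field. Receptive-field assignments rotate across cells so all
#' six geometries occur. The recording window is [-500, rt + 200] ms; the
#' network is integrated from cue onset, so the pre-cue baseline carries
#' no spikes.
#'
#' @param params a [search_params()] object.
#' @param n_cells number of cells (one session per cell).
#' @param trials_per_block trials per (cell, set size) block.
#' @param set_sizes set sizes administered as blocks to every cell.
#' @param seed integer seed (all randomness).
#' @param subject subject label stored on the records.
#' @param t_max simulation timeout (ms).
#' @return a list of class `spike_dataset` with tibbles `cells`
#'   (`cell_id`, `session`, `rf_location`), `trials` (`trial_id`,
#'   `cell_id`, `session`, `block`, `set_size`, `position`, `orientation`,
#'   `congruent`, `response_side`, `correct`, `rt_ms`, `timed_out`) and
#'   `spikes` (`cell_id`, `trial_id`, `spike_time_ms`).
#' @export
#' @examples
#' ds <- generate_dataset(params_m12(), n_cells = 2, trials_per_block = 5, seed = 1)
#' ds$trials
generate_dataset <- function(params, n_cells = 6, trials_per_block = 40,
                             set_sizes = c(2, 4, 6), seed = 1,
                             subject = "M11", t_max = 1500) {
  stopifnot(
    inherits(params, "search_params"), n_cells >= 1,
    trials_per_block >= 1, all(set_sizes %in% c(2, 4, 6))
  )
  set.seed(seed)
  cells <- tibble(
    cell_id = sprintf("%s_c%02d", subject, seq_len(n_cells)),
    session = seq_len(n_cells),
    rf_location = LIP_LOCATIONS[(seq_len(n_cells) - 1) %% 6 + 1]
  )
  trial_rows <- list()
  spike_rows <- list()
  trial_no <- 0L
  block_no <- 0L
  for (ci in seq_len(n_cells)) {
    rf_idx <- match(cells$rf_location[ci], LIP_LOCATIONS)
    for (ss in sample(set_sizes)) { # blocks in random order within session
      block_no <- block_no + 1L
      positions <- positions_for_set_size(ss)
      for (k in seq_len(trials_per_block)) {
        trial_no <- trial_no + 1L
        cond <- trial_condition(
          ss, sample(positions, 1), sample(ORIENTATIONS, 1)
        )
        tr <- simulate_trial(params, cond,
          seed = seed, t_max = t_max,
          keep_trajectory = TRUE, sample_every = 1,
          trial_index = trial_no, stream = 1000 + ci
        )
        traj <- attr(tr, "trajectory")
        rec_end <- if (tr$timed_out) t_max else min(tr$rt_ms + 200, t_max)
        rate_hz <- traj[[paste0("x_lip_", cells$rf_location[ci])]] * 1000
        keep <- traj$t_ms <= rec_end
        st <- poisson_spikes(traj$t_ms[keep], rate_hz[keep])
        trial_rows[[trial_no]] <- tibble(
          trial_id = trial_no, cell_id = cells$cell_id[ci],
          session = ci, block = block_no,
          set_size = cond$set_size, position = cond$position,
          orientation = cond$orientation, congruent = cond$congruent,
          response_side = tr$response_side, correct = tr$correct,
          rt_ms = tr$rt_ms, timed_out = tr$timed_out
        )
        if (length(st) > 0) {
          spike_rows[[trial_no]] <- tibble(
            cell_id = cells$cell_id[ci], trial_id = trial_no,
            spike_time_ms = st
          )
        }
      }
    }
  }
  structure(
    list(
      cells = cells, trials = bind_rows(trial_rows),
      spikes = bind_rows(spike_rows), subject = subject, seed = seed
    ),
    class = "spike_dataset"
  )
}

# inhomogeneous Poisson sampler on a 1-ms grid: per-bin Poisson counts with
# mean rate*dt, spike times jittered uniformly within the bin
poisson_spikes <- function(t_ms, rate_hz) {
  rate_hz <- pmax(rate_hz, 0)
  counts <- rpois(length(t_ms), rate_hz / 1000)
  idx <- rep.int(seq_along(t_ms), counts)
  if (length(idx) == 0) return(numeric(0))
  sort(t_ms[idx] + runif(length(idx)))
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(
    "<spike_dataset>", nrow(x$cells), "cells,", nrow(x$trials), "trials,",
    nrow(x$spikes), "spikes\n"
  )
  invisible(x)
}

#' Inject pathological cells to exercise the exclusion filters
#'
#' Adds synthetic cells that violate the selection rules: "hot" cells
#' whose firing exceeds the 80 Hz ceiling, and cells missing one set size.
#' Hot cells get homogeneous-Poisson spike trains at `hot_rate_hz` over
#' [0, 500] ms; missing-set-size cells copy the behavioral structure of
#' the first cell with one set size dropped.
#'
#' @param dataset a `spike_dataset`.
#' @param hot_cells number of >80 Hz cells to add.
#' @param hot_rate_hz their firing rate (Hz).
#' @param missing_set_size_cells number of cells lacking one set size.
#' @param dropped_set_size which set size those cells lack.
#' @param seed integer seed.
#' @return the augmented `spike_dataset`.
#' @export
inject_artifacts <- function(dataset, hot_cells = 0, hot_rate_hz = 120,
                             missing_set_size_cells = 0,
                             dropped_set_size = 6, seed = 1) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (hot_cells == 0 && missing_set_size_cells == 0) return(dataset)
  set.seed(seed)
  out <- dataset
  next_trial <- max(out$trials$trial_id)
  next_session <- max(out$cells$session)
  template <- out$trials %>% filter(.data$cell_id == out$cells$cell_id[1])

  add_cell <- function(out, cid, keep_set_sizes, rate_hz) {
    out$cells <- bind_rows(out$cells, tibble(
      cell_id = cid, session = next_session + 1L, rf_location = "L1"
    ))
    tmpl <- template %>% filter(.data$set_size %in% keep_set_sizes)
    tmpl$cell_id <- cid
    tmpl$session <- next_session + 1L
    tmpl$trial_id <- next_trial + seq_len(nrow(tmpl))
    out$trials <- bind_rows(out$trials, tmpl)
    if (!is.null(rate_hz)) {
      sp <- purrr::map(tmpl$trial_id, function(tid) {
        st <- poisson_spikes(0:500, rep(rate_hz, 501))
        if (length(st) == 0) return(NULL)
        tibble(cell_id = cid, trial_id = tid, spike_time_ms = st)
      })
      out$spikes <- bind_rows(out$spikes, bind_rows(sp))
    }
    next_trial <<- next_trial + nrow(tmpl)
    next_session <<- next_session + 1L
    out
  }

  for (i in seq_len(hot_cells)) {
    out <- add_cell(
      out, sprintf("hot_%02d", i), c(2, 4, 6), hot_rate_hz
    )
  }
  for (i in seq_len(missing_set_size_cells)) {
    out <- add_cell(
      out, sprintf("missing_%02d", i),
      setdiff(c(2, 4, 6), dropped_set_size), 20
    )
  }
  out
}

#' Read and write spike datasets as plain-text CSV
#'
#' The on-disk format is three CSV files in one directory: `trials.csv`,
#' `spikes.csv` and `cells.csv`, with the columns documented in
#' [generate_dataset()]. External recordings arranged into this layout
#' (spike times in ms aligned to cue onset) are read the same way.
#'
#' @param dataset a `spike_dataset`.
#' @param dir directory path.
#' @return `read_dataset()` returns a `spike_dataset`; `write_dataset()`
#'   returns `dir` invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(dataset$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  for (f in c("cells.csv", "trials.csv", "spikes.csv")) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing ", f, " in ", dir, call. = FALSE)
    }
  }
  structure(
    list(
      cells = as_tibble(read.csv(file.path(dir, "cells.csv"))),
      trials = as_tibble(read.csv(file.path(dir, "trials.csv"))),
      spikes = as_tibble(read.csv(file.path(dir, "spikes.csv")))
    ),
    class = "spike_dataset"
  )
}
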