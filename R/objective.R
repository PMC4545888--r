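#' Configuration of the composite neural/behavioral objective
#'
#' The objective combines a relative firing-rate error over the first
#' 800 ms after cue onset with quantile chi-square errors for correct and
#' error reaction-time distributions, each averaged over the congruent and
#' incongruent response-hemifield conditions:
#' \deqn{\frac{\alpha_{FR}}{2 SS} \sum_{cong} \sum_{j=1}^{SS} \sum_{t=0}^{800}
#'   \left(\frac{FR^j_t - \bar{FR}^j_t}{FR^j_t}\right)^2
#'   + \frac{\alpha_{corr}}{2} \sum_{cong} \chi^2_{correct}
#'   + \frac{\alpha_{incorr}}{2} \sum_{cong} \chi^2_{incorrect}}
#' where \eqn{FR} is the simulated and \eqn{\bar{FR}} the reference rate.
#'
#' @param alpha_fr,alpha_corr,alpha_incorr weights of the three error
#'   terms (defaults 0.25, 1, 1).
#' @param n_sim simulated trials per congruence condition per evaluation.
#' @param set_size stimulus set size of the fitted condition.
#' @param fr_window time window (ms from cue onset) of the FR comparison.
#' @param fr_floor_hz floor applied to the model FR in the relative-error
#'   denominator (Hz), guarding the near-zero rates just after cue onset.
#' @param min_expected floor on expected model counts per chi-square bin.
#' @param sparse_n below this many reference trials in a correct/error
#'   class, the class collapses to a single count-only bin.
#' @param t_max simulation timeout (ms).
#' @param engine engine options, see [simulate_trial()].
#' @return a list of class `objective_config`.
#' @export
objective_config <- function(alpha_fr = 0.25, alpha_corr = 1,
                             alpha_incorr = 1, n_sim = 6000, set_size = 4,
                             fr_window = c(0, 800), fr_floor_hz = 1,
                             min_expected = 1, sparse_n = 12,
                             t_max = 1500, engine = list()) {
  stopifnot(
    alpha_fr >= 0, alpha_corr >= 0, alpha_incorr >= 0, n_sim >= 1,
    length(fr_window) == 2, fr_window[1] >= 0, fr_window[2] > fr_window[1]
  )
  structure(
    list(
      alpha_fr = alpha_fr, alpha_corr = alpha_corr,
      alpha_incorr = alpha_incorr, n_sim = as.integer(n_sim),
      set_size = as.integer(set_size), fr_window = fr_window,
      fr_floor_hz = fr_floor_hz, min_expected = min_expected,
      sparse_n = sparse_n, t_max = t_max, engine = engine
    ),
    class = "objective_config"
  )
}

#' Quantile chi-square error between two reaction-time samples
#'
#' Bins are defined by the 0.1/0.3/0.5/0.7/0.9 quantiles of the reference
#' sample ([rt_quantile_bins()]). Model RTs are binned into the same edges
#' and rescaled to expected counts `n_data * model proportion`; the
#' statistic is \eqn{\sum_b (data_b - expected_b)^2 / expected_b} with
#' expected counts floored at `min_expected`. An empty model sample leaves
#' every expected count at the floor, giving a large, well-defined penalty.
#'
#' @param data_rts reference RT sample (defines the bins and the counts).
#' @param model_rts simulated RT sample.
#' @param n_data reference count used for rescaling (defaults to
#'   `length(data_rts)`; pass the total across correct and error classes to
#'   penalise accuracy mismatches as in the joint fit).
#' @param model_total simulated count used for proportions (defaults to
#'   `length(model_rts)`).
#' @param min_expected floor on expected counts.
#' @return non-negative chi-square value.
#' @export
#' @examples
#' x <- c(310, 350, 380, 410, 440, 470, 500, 540, 590, 680)
#' chi_square_rt(x, x) # identical samples: 0
chi_square_rt <- function(data_rts, model_rts, n_data = length(data_rts),
                          model_total = length(model_rts),
                          min_expected = 1) {
  data_rts <- data_rts[!is.na(data_rts)]
  model_rts <- model_rts[!is.na(model_rts)]
  if (length(data_rts) == 0) stop("empty reference RT sample", call. = FALSE)
  edges <- rt_quantile_bins(data_rts)
  dcount <- bin_counts(data_rts, edges)
  if (length(model_rts) == 0 || model_total == 0) {
    expected <- rep(min_expected, 6)
  } else {
    expected <- pmax(n_data * bin_counts(model_rts, edges) / model_total,
      min_expected)
  }
  sum((dcount - expected)^2 / expected)
}

#' Relative firing-rate error term
#'
#' Computes the time-summed squared relative error between simulated and
#' reference LIP firing rates for the stimulated units, averaged over the
#' two congruence conditions:
#' \eqn{(1/(2 SS)) \sum_{cong} \sum_j \sum_t ((FR_{model} - FR_{ref}) /
#' FR_{model})^2}, with the model rate in the denominator floored at
#' `fr_floor_hz`. Model traces carry one row per unit; the reference carries
#' one trace per condition label, and each model unit is compared against
#' the reference trace of its label.
#'
#' @param model_traces tibble from [model_fr_traces()] (columns
#'   `congruent`, `unit`, `label`, `t_ms`, `rate_hz`).
#' @param data_traces reference tibble (columns `congruent`, `label`,
#'   `t_ms`, `rate_hz`).
#' @param set_size stimulus set size (number of compared units).
#' @param fr_window time window in ms.
#' @param fr_floor_hz denominator floor (Hz).
#' @return non-negative error value.
#' @export
fr_error_term <- function(model_traces, data_traces, set_size,
                          fr_window = c(0, 800), fr_floor_hz = 1) {
  m <- model_traces %>%
    filter(.data$t_ms >= fr_window[1], .data$t_ms <= fr_window[2])
  d <- data_traces %>%
    filter(.data$t_ms >= fr_window[1], .data$t_ms <= fr_window[2]) %>%
    select("congruent", "label", "t_ms", ref_hz = "rate_hz")
  j <- inner_join(m, d, by = c("congruent", "label", "t_ms"))
  if (nrow(j) < nrow(m)) {
    stop("reference traces do not cover the model grid/labels", call. = FALSE)
  }
  resid <- (j$rate_hz - j$ref_hz) / pmax(j$rate_hz, fr_floor_hz)
  sum(resid^2) / (2 * set_size)
}

#' Assemble a reference data bundle from a batch or dataset
#'
#' A data bundle holds the reaction-time samples (split by congruence and
#' correctness) and the labelled LIP firing-rate traces that the objective
#' compares simulations against. `objective_data()` builds one from a
#' traced `search_batch` (used in self-fit and parameter-recovery
#' studies); bundles from experimental recordings can be built by
#' supplying the two tibbles directly.
#'
#' @param batch a `search_batch` simulated with `keep_traces = TRUE` under
#'   the congruent and incongruent fitting conditions.
#' @param rts tibble (`congruent`, `correct`, `rt_ms`); overrides `batch`.
#' @param fr tibble (`congruent`, `label`, `t_ms`, `rate_hz`).
#' @return a list of class `objective_data` with elements `rts` and `fr`.
#' @export
objective_data <- function(batch = NULL, rts = NULL, fr = NULL) {
  if (!is.null(batch)) {
    stopifnot(inherits(batch, "search_batch"))
    rts <- batch$trials %>%
      filter(!.data$timed_out) %>%
      select("congruent", "correct", "rt_ms")
    fr <- model_fr_traces(batch) %>%
      group_by(.data$congruent, .data$label, .data$t_ms) %>%
      summarise(rate_hz = mean(.data$rate_hz), .groups = "drop")
  }
  stopifnot(
    all(c("congruent", "correct", "rt_ms") %in% names(rts)),
    all(c("congruent", "label", "t_ms", "rate_hz") %in% names(fr))
  )
  structure(list(rts = as_tibble(rts), fr = as_tibble(fr)),
    class = "objective_data"
  )
}

#' The two standard fitting conditions
#'
#' The joint fit simulates a right-facing target at the upper-right
#' location (congruent) and at the upper-left location (incongruent);
#' this suffices because the network is bilaterally symmetric and data
#' firing rates were averaged over receptive-field configurations.
#'
#' @param set_size stimulus set size.
#' @return a two-row condition tibble.
#' @export
fitting_conditions <- function(set_size = 4) {
  bind_rows(
    trial_condition(set_size, "R1", "E_right"),
    trial_condition(set_size, "L1", "E_right")
  )
}

#' Evaluate the composite objective for one subject
#'
#' Simulates `n_sim` trials per congruence condition (right-facing target
#' in the upper-right or upper-left location), computes labelled mean LIP
#' traces and RT distributions, and combines the firing-rate error with
#' correct- and error-trial quantile chi-squares under the configured
#' weights. The simulation seed is part of the call, so an optimizer using
#' a fixed seed sees a deterministic (common-random-numbers) objective.
#'
#' @param params a [search_params()] object.
#' @param data an [objective_data()] bundle.
#' @param config an [objective_config()].
#' @param seed integer seed for the simulated trials.
#' @return a list of class `objective_value`: `total`, `fr_term`,
#'   `chi2_correct`, `chi2_error`, and a per-congruence `breakdown` tibble.
#' @export
#' @examples
#' \donttest{
#' cfg <- objective_config(n_sim = 200)
#' b <- simulate_batch(params_m11(), fitting_conditions(4), 200,
#'   seed = 1, keep_traces = TRUE
#' )
#' obj <- objective(params_m11(), objective_data(b), cfg, seed = 1)
#' obj$total # near the sampling-noise floor for a self-fit
#' }
objective <- function(params, data, config = objective_config(), seed = 1) {
  stopifnot(
    inherits(params, "search_params"), inherits(data, "objective_data"),
    inherits(config, "objective_config")
  )
  batch <- simulate_batch(
    params, fitting_conditions(config$set_size),
    n_per_condition = config$n_sim, seed = seed, t_max = config$t_max,
    keep_traces = config$alpha_fr > 0,
    trace_t_max = config$fr_window[2], engine = config$engine
  )
  fr_term <- 0
  if (config$alpha_fr > 0) {
    fr_term <- fr_error_term(
      model_fr_traces(batch), data$fr, config$set_size,
      config$fr_window, config$fr_floor_hz
    )
  }

  rows <- vector("list", 2)
  for (i in 1:2) {
    cg <- c(TRUE, FALSE)[i]
    drt <- data$rts %>% filter(.data$congruent == cg)
    mrt <- batch$trials %>%
      filter(.data$congruent == cg, !.data$timed_out)
    n_data <- nrow(drt)
    model_total <- nrow(mrt)
    chi <- purrr::map_dbl(c(TRUE, FALSE), function(corr) {
      dr <- drt$rt_ms[drt$correct == corr]
      mr <- mrt$rt_ms[mrt$correct == corr]
      if (length(dr) < config$sparse_n) {
        expected <- max(
          n_data * length(mr) / max(model_total, 1),
          config$min_expected
        )
        (length(dr) - expected)^2 / expected
      } else {
        chi_square_rt(dr, mr,
          n_data = n_data, model_total = model_total,
          min_expected = config$min_expected
        )
      }
    })
    rows[[i]] <- tibble(
      congruent = cg, chi2_correct = chi[1], chi2_error = chi[2]
    )
  }
  breakdown <- bind_rows(rows)
  chi2_correct <- sum(breakdown$chi2_correct) / 2
  chi2_error <- sum(breakdown$chi2_error) / 2
  total <- config$alpha_fr * fr_term + config$alpha_corr * chi2_correct +
    config$alpha_incorr * chi2_error
  structure(
    list(
      total = total, fr_term = fr_term, chi2_correct = chi2_correct,
      chi2_error = chi2_error, breakdown = breakdown,
      config = config, seed = seed
    ),
    class = "objective_value"
  )
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf(
    "<objective_value> total %.3f (FR %.3f, chi2 correct %.3f, chi2 error %.3f)\n",
    x$total, x$fr_term, x$chi2_correct, x$chi2_error
  ))
  invisible(x)
}

#' Joint objective over both subjects
#'
#' Sums the single-subject objectives with equal weight, as in the joint
#' fit where eighteen parameters are shared between the subjects.
#'
#' @param params_pair named list of two [search_params()] objects.
#' @param data_pair named list of two [objective_data()] bundles (same
#'   names as `params_pair`).
#' @inheritParams objective
#' @return a list with `total` and the per-subject `objective_value`s.
#' @export
joint_objective <- function(params_pair, data_pair,
                            config = objective_config(), seed = 1) {
  stopifnot(
    length(params_pair) == 2, length(data_pair) == 2,
    setequal(names(params_pair), names(data_pair))
  )
  vals <- lapply(names(params_pair), function(nm) {
    objective(params_pair[[nm]], data_pair[[nm]], config, seed)
  })
  names(vals) <- names(params_pair)
  list(total = sum(purrr::map_dbl(vals, "total")), subjects = vals)
}
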