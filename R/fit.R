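#' Pack and unpack the joint free-parameter vector
#'
#' The joint fit over the two subjects uses a single free-parameter
#' vector: the 18 shared parameters appear once, and the 13
#' subject-specific parameters (delays, LIP inhibition, the
#' LIP/IT/AIP connection weights, input strengths `s_lip`/`s_tar`, noise
#' levels `c_it`/`c_lip`, nondecision time and threshold) appear once per
#' subject, for 18 + 2 x 13 = 44 free values. `pack_params()` flattens a
#' named pair of parameter sets into that vector (shared values taken from
#' the first subject); `unpack_params()` rebuilds the pair, with shared
#' values identical across subjects by construction.
#'
#' @param params_pair named list of two [search_params()] objects.
#' @param vec named numeric vector as produced by `pack_params()`.
#' @param subjects subject names for unpacking.
#' @param constants fixed simulation constants for the rebuilt objects.
#' @return `pack_params()`: a named numeric vector of length 44;
#'   `unpack_params()`: a named list of two `search_params` objects.
#' @export
#' @examples
#' v <- pack_params(list(M11 = params_m11(), M12 = params_m12()))
#' length(v) # 44
#' p2 <- unpack_params(v)
#' identical(param_vector(p2$M11), param_vector(params_m11()))
pack_params <- function(params_pair) {
  stopifnot(length(params_pair) == 2, !is.null(names(params_pair)))
  subjects <- names(params_pair)
  specific <- setdiff(PARAM_NAMES, SHARED_PARAMS)
  shared_vals <- unlist(unclass(params_pair[[1]])[SHARED_PARAMS])
  spec_vals <- unlist(lapply(subjects, function(s) {
    v <- unlist(unclass(params_pair[[s]])[specific])
    names(v) <- paste(specific, s, sep = ".")
    v
  }))
  c(shared_vals, spec_vals)
}

#' @rdname pack_params
#' @export
unpack_params <- function(vec, subjects = NULL,
                          constants = list(tau_noise = 5, dt = 0.5,
                                           motor_cap = 0.150)) {
  specific <- setdiff(PARAM_NAMES, SHARED_PARAMS)
  if (is.null(subjects)) {
    subjects <- unique(sub("^.*\\.", "", grep("\\.", names(vec), value = TRUE)))
  }
  stopifnot(length(subjects) == 2)
  expected <- length(SHARED_PARAMS) + 2 * length(specific)
  if (length(vec) != expected) {
    stop("free-parameter vector must have ", expected, " entries", call. = FALSE)
  }
  out <- lapply(subjects, function(s) {
    vals <- as.list(c(
      vec[SHARED_PARAMS],
      setNames(vec[paste(specific, s, sep = ".")], specific)
    ))
    search_params(vals,
      tau_noise = constants$tau_noise, dt = constants$dt,
      motor_cap = constants$motor_cap
    )
  })
  names(out) <- subjects
  out
}

#' Default box bounds for fitted parameters
#'
#' Wide bounds used by the optimizer when none are supplied: positive
#' quantities bounded away from zero, decay factors and gates in [0, 1]-ish
#' ranges, weights allowed up to several times the fitted values.
#'
#' @return a tibble with `name`, `lower`, `upper`.
#' @export
param_bounds <- function() {
  lo <- c(
    p_delay = 1, t_delay = 1, tau_m = 50, tau_it = 10, tau_aip = 10,
    tau_lip = 5, eta_maipit = 0, eta_lip = 0, eta_lip_decay1 = 0,
    eta_lip_decay2 = 0, alpha_lip = 0, w_aipm = 0.1, w_itaip = 0.5,
    w_lipaip = 0.1, w_aiplip = 0.1, beta_aiplip = 0.1, beta_maip = 0,
    beta_mitlip = 0, s_lip = 0.05, s_tar = 0.05, s_back = 0,
    s_ori = 0.05, c_maip = 0, c_it = 0, c_lip = 0, k_m = 0, g_m = 0,
    k_aip = 0, g_aip = 0, t_0 = 10, theta = 0.01
  )
  hi <- c(
    p_delay = 150, t_delay = 200, tau_m = 1000, tau_it = 300,
    tau_aip = 500, tau_lip = 200, eta_maipit = 20, eta_lip = 10,
    eta_lip_decay1 = 1, eta_lip_decay2 = 1, alpha_lip = 5, w_aipm = 20,
    w_itaip = 40, w_lipaip = 20, w_aiplip = 20, beta_aiplip = 20,
    beta_maip = 20, beta_mitlip = 40, s_lip = 2, s_tar = 2, s_back = 2,
    s_ori = 4, c_maip = 4, c_it = 4, c_lip = 4, k_m = 5, g_m = 1,
    k_aip = 40, g_aip = 0.5, t_0 = 400, theta = 0.2
  )
  tibble(
    name = PARAM_NAMES, lower = unname(lo[PARAM_NAMES]),
    upper = unname(hi[PARAM_NAMES])
  )
}

#' Fit model parameters to a data bundle
#'
#' Minimizes the composite [objective()] over a chosen subset of free
#' parameters, holding the rest at their values in `init`. A simulated
#' annealing stage explores globally, followed by Nelder-Mead refinement;
#' both operate on a logit-transformed scale that enforces the box
#' bounds. Every objective evaluation uses the same simulation seed
#' (common random numbers), so the noisy simulation objective is a fixed
#' deterministic function during optimization and two runs with the same
#' master seed produce identical traces.
#'
#' @param data an [objective_data()] bundle.
#' @param init a [search_params()] starting point (also supplies the
#'   clamped values of non-free parameters).
#' @param free character vector of parameter names to optimize.
#' @param bounds tibble (`name`, `lower`, `upper`); defaults to
#'   [param_bounds()].
#' @param config an [objective_config()] (use a reduced `n_sim` for
#'   desk-scale fits).
#' @param seed master seed: seeds both the annealer and the simulations.
#' @param sann_iter,nm_iter evaluation budgets of the two stages
#'   (`sann_iter = 0` skips the annealing stage).
#' @param nm_restarts number of Nelder-Mead runs, each restarted from the
#'   best point so far with a fresh simplex.
#' @return an object of class `search_fit`: `params` (fitted
#'   [search_params()]), `estimates` (tibble of free-parameter values),
#'   `objective` (final [objective()] value), `trace` (tibble of all
#'   evaluations), `converged`.
#' @export
fit_search_model <- function(data, init, free, bounds = param_bounds(),
                             config = objective_config(n_sim = 1000),
                             seed = 1, sann_iter = 80, nm_iter = 160,
                             nm_restarts = 1) {
  stopifnot(
    inherits(data, "objective_data"), inherits(init, "search_params"),
    all(free %in% PARAM_NAMES), length(free) >= 1
  )
  b <- bounds[match(free, bounds$name), ]
  lower <- b$lower
  upper <- b$upper
  theta0 <- unlist(unclass(init)[free])
  if (any(theta0 <= lower | theta0 >= upper)) {
    stop("init must lie strictly inside the bounds for all free parameters",
      call. = FALSE
    )
  }

  to_z <- function(th) stats::qlogis((th - lower) / (upper - lower))
  to_theta <- function(z) lower + (upper - lower) * stats::plogis(z)

  trace_env <- new.env()
  trace_env$rows <- list()
  n_eval <- 0L

  fn <- function(z) {
    th <- to_theta(z)
    p <- do.call(update_params, c(list(init), as.list(setNames(th, free))))
    val <- objective(p, data, config, seed = seed)$total
    n_eval <<- n_eval + 1L
    trace_env$rows[[n_eval]] <- tibble(
      eval = n_eval, total = val, !!!setNames(as.list(th), free)
    )
    val
  }

  set.seed(seed)
  z0 <- to_z(theta0)
  z_best <- z0
  converged <- FALSE
  if (sann_iter > 0) {
    # annealing proposals: local Gaussian steps on the transformed scale
    propose <- function(z, ...) z + rnorm(length(z), 0, 0.25)
    sann <- optim(z0, fn,
      gr = propose, method = "SANN",
      control = list(maxit = sann_iter, temp = 2, tmax = 5)
    )
    z_best <- sann$par
  }
  # restarted Nelder-Mead refinement, each restart from the best point so
  # far with a fresh simplex (the simulation objective has long curved
  # valleys where a single collapsed simplex stalls). For a single free
  # parameter R advises against NM; local refinement from a good start is
  # exactly what is wanted here, so the advisory warning is suppressed.
  for (r in seq_len(max(nm_restarts, 1))) {
    nm <- suppressWarnings(optim(z_best, fn,
      method = "Nelder-Mead",
      control = list(maxit = nm_iter, reltol = 1e-5)
    ))
    z_best <- nm$par
    converged <- nm$convergence == 0
  }
  # best-so-far over every logged evaluation (all stages)
  trace_tbl <- bind_rows(trace_env$rows)
  best_row <- trace_tbl[which.min(trace_tbl$total), ]
  best <- unlist(best_row[free])
  fitted <- do.call(update_params, c(list(init), as.list(setNames(best, free))))
  structure(
    list(
      params = fitted,
      estimates = tibble(
        name = free, estimate = unname(best),
        start = unname(theta0), lower = lower, upper = upper
      ),
      objective = objective(fitted, data, config, seed = seed),
      trace = trace_tbl,
      converged = converged,
      seed = seed
    ),
    class = "search_fit"
  )
}

#' @export
print.search_fit <- function(x, ...) {
  cat(
    "<search_fit>", nrow(x$estimates), "free parameter(s),",
    nrow(x$trace), "objective evaluations\n"
  )
  print(x$estimates)
  cat(sprintf("final objective: %.3f\n", x$objective$total))
  invisible(x)
}

#' @rdname tidy.search_batch
#' @export
tidy.search_fit <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.search_batch
#' @export
glance.search_fit <- function(x, ...) {
  tibble(
    objective = x$objective$total,
    fr_term = x$objective$fr_term,
    chi2_correct = x$objective$chi2_correct,
    chi2_error = x$objective$chi2_error,
    n_eval = nrow(x$trace),
    converged = x$converged
  )
}
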