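#' @useDynLib covertsearch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile sd rnorm runif rpois median optim dnorm setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

# canonical parameter order; must match the Par enum in src/engine.cpp
PARAM_NAMES <- c(
  "p_delay", "t_delay", "tau_m", "tau_it", "tau_aip", "tau_lip",
  "eta_maipit", "eta_lip", "eta_lip_decay1", "eta_lip_decay2", "alpha_lip",
  "w_aipm", "w_itaip", "w_lipaip", "w_aiplip", "beta_aiplip", "beta_maip",
  "beta_mitlip", "s_lip", "s_tar", "s_back", "s_ori", "c_maip", "c_it",
  "c_lip", "k_m", "g_m", "k_aip", "g_aip", "t_0", "theta"
)

# the 18 parameters constrained equal across subjects in the joint fit
SHARED_PARAMS <- c(
  "tau_m", "tau_it", "tau_aip", "tau_lip", "eta_maipit",
  "eta_lip_decay1", "eta_lip_decay2", "alpha_lip", "w_aipm",
  "beta_maip", "beta_mitlip", "s_back", "s_ori", "c_maip",
  "k_m", "g_m", "k_aip", "g_aip"
)

#' Model parameter set for the covert-search network
#'
#' Bundles the 31 fitted parameters of the multi-area accumulator network
#' (delays, time constants, connection weights, input strengths, noise levels,
#' gate/leak constants, nondecision time and motor threshold) together with
#' the fixed constants of the simulation (OU input time constant, integration
#' step, motor firing-rate cap). Time constants and delays are in ms; unit
#' activities are in kHz, so the motor threshold `theta` and the 0.150 kHz
#' motor cap correspond to 92.6 Hz (M11) and 150 Hz respectively.
#'
#' @param ... named parameter values; all 31 names must be supplied (most
#'   users start from [params_m11()] or [params_m12()] and override).
#' @param tau_noise time constant (ms) of the Ornstein-Uhlenbeck input
#'   processes filtering the step stimuli (fast AMPA/GABA-A synapses).
#' @param dt integration step (ms).
#' @param motor_cap hard cap on motor-unit activity (kHz).
#' @return an object of class `search_params`: a named list of parameter
#'   values plus a `constants` attribute.
#' @seealso [params_m11()], [params_m12()], [param_info()]
#' @export
#' @examples
#' p <- params_m11()
#' p$theta            # motor threshold, kHz
#' update_params(p, s_lip = 0.5)$s_lip
search_params <- function(..., tau_noise = 5, dt = 0.5, motor_cap = 0.150) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1]])) {
    vals <- vals[[1]]
  }
  missing <- setdiff(PARAM_NAMES, names(vals))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(vals), PARAM_NAMES)
  if (length(extra) > 0) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  p <- lapply(vals[PARAM_NAMES], function(v) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
    as.numeric(v)
  })
  validate_params(p, tau_noise = tau_noise, dt = dt, motor_cap = motor_cap)
  structure(p,
    constants = list(tau_noise = tau_noise, dt = dt, motor_cap = motor_cap),
    class = "search_params"
  )
}

validate_params <- function(p, tau_noise, dt, motor_cap) {
  taus <- c("tau_m", "tau_it", "tau_aip", "tau_lip")
  for (nm in taus) {
    if (p[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  }
  if (p$theta <= 0) stop("theta must be > 0", call. = FALSE)
  for (nm in c("c_maip", "c_it", "c_lip")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  for (nm in c("p_delay", "t_delay", "t_0")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (tau_noise <= 0 || dt <= 0 || motor_cap <= 0) {
    stop("tau_noise, dt and motor_cap must all be > 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.search_params <- function(x, ...) {
  cat("<search_params> 31 parameters\n")
  print(tidy(x), n = 31)
  invisible(x)
}

#' Update parameters in a `search_params` object
#'
#' @param params a [search_params()] object.
#' @param ... named replacement values.
#' @return a new `search_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "search_params"))
  cst <- attr(params, "constants")
  vals <- modifyList(unclass(params), list(...))
  search_params(vals,
    tau_noise = cst$tau_noise, dt = cst$dt,
    motor_cap = cst$motor_cap
  )
}

#' Fitted parameter values for the two subjects
#'
#' The parameter sets obtained by jointly fitting the network to the two
#' macaques' set-size-4 neural and behavioral data (subjects M11 and M12).
#' Eighteen parameters are shared between the subjects; thirteen
#' (delays, LIP inhibition, the LIP/IT/AIP connection weights, input and
#' noise strengths, nondecision time and threshold) differ.
#'
#' @return a [search_params()] object.
#' @export
#' @examples
#' params_m11()$eta_lip   # LIP mutual inhibition, much stronger in M11
#' params_m12()$w_itaip   # IT -> AIP drive, stronger in M12
params_m11 <- function() {
  search_params(
    p_delay = 24.08, t_delay = 55.72,
    tau_m = 438.2, tau_it = 68.66, tau_aip = 119.7, tau_lip = 34.80,
    eta_maipit = 5.371, eta_lip = 2.936,
    eta_lip_decay1 = 0.8470, eta_lip_decay2 = 0.1300,
    alpha_lip = 1.469, w_aipm = 4.827,
    w_itaip = 10.98, w_lipaip = 6.495, w_aiplip = 6.276,
    beta_aiplip = 8.422, beta_maip = 3.108, beta_mitlip = 11.02,
    s_lip = 0.6317, s_tar = 0.3997, s_back = 0.5038, s_ori = 1.227,
    c_maip = 0.7866, c_it = 1.465, c_lip = 1.950,
    k_m = 0.0000, g_m = 0.1079, k_aip = 12.51, g_aip = 0.0005,
    t_0 = 169.8, theta = 0.0926
  )
}

#' @rdname params_m11
#' @export
params_m12 <- function() {
  update_params(
    params_m11(),
    p_delay = 44.58, t_delay = 48.20,
    eta_lip = 0.1032,
    w_itaip = 18.75, w_lipaip = 2.520, w_aiplip = 1.166,
    beta_aiplip = 4.266,
    s_lip = 0.4088, s_tar = 0.4165,
    c_it = 0.6744, c_lip = 1.818,
    t_0 = 96.17, theta = 0.0961
  )
}

#' Parameter metadata table
#'
#' One row per fitted parameter: name, role in the network, physical units,
#' and whether the joint fit constrains it to be shared across subjects
#' (18 shared + 13 per-subject, i.e. 44 free values for two subjects).
#'
#' @return a tibble with columns `name`, `shared`, `units`, `description`.
#' @export
param_info <- function() {
  desc <- c(
    p_delay = "perceptual delay (retina to LIP)",
    t_delay = "target-search delay before target/orientation input",
    tau_m = "motor unit time constant",
    tau_it = "IT unit time constant",
    tau_aip = "AIP unit time constant",
    tau_lip = "LIP unit time constant",
    eta_maipit = "mutual inhibition within motor, AIP and IT pairs",
    eta_lip = "mutual inhibition strength in LIP",
    eta_lip_decay1 = "inhibition decay, LIP units one step removed",
    eta_lip_decay2 = "additional decay, LIP units two steps removed",
    alpha_lip = "recurrent self-excitation in LIP",
    w_aipm = "excitatory weight AIP -> motor",
    w_itaip = "excitatory weight IT -> AIP",
    w_lipaip = "excitatory weight LIP -> AIP",
    w_aiplip = "excitatory weight AIP -> same-side LIP",
    beta_aiplip = "inhibitory crossed weight AIP -> opposite LIP",
    beta_maip = "inhibitory weight motor -> AIP",
    beta_mitlip = "inhibitory weight motor -> IT and LIP",
    s_lip = "perceptual input strength to stimulated LIP units",
    s_tar = "target input strength to the target LIP unit",
    s_back = "background input to all LIP units",
    s_ori = "orientation input strength to the matching IT unit",
    c_maip = "noise SD for motor and AIP units",
    c_it = "noise SD for IT input OU processes",
    c_lip = "noise SD for LIP input OU processes",
    k_m = "motor leak",
    g_m = "motor gate level",
    k_aip = "AIP leak",
    g_aip = "AIP gate level",
    t_0 = "nondecision time (motor latency)",
    theta = "motor response threshold"
  )
  units <- c(
    p_delay = "ms", t_delay = "ms", tau_m = "ms", tau_it = "ms",
    tau_aip = "ms", tau_lip = "ms", eta_maipit = "-", eta_lip = "-",
    eta_lip_decay1 = "-", eta_lip_decay2 = "-", alpha_lip = "-",
    w_aipm = "-", w_itaip = "-", w_lipaip = "-", w_aiplip = "-",
    beta_aiplip = "-", beta_maip = "-", beta_mitlip = "-",
    s_lip = "a.u.", s_tar = "a.u.", s_back = "a.u.", s_ori = "a.u.",
    c_maip = "a.u.", c_it = "a.u.", c_lip = "a.u.",
    k_m = "-", g_m = "a.u.", k_aip = "-", g_aip = "a.u.",
    t_0 = "ms", theta = "kHz"
  )
  tibble(
    name = PARAM_NAMES,
    shared = PARAM_NAMES %in% SHARED_PARAMS,
    units = unname(units[PARAM_NAMES]),
    description = unname(desc[PARAM_NAMES])
  )
}

#' @export
#' @rdname tidy.search_batch
tidy.search_params <- function(x, ...) {
  tibble(name = PARAM_NAMES, value = unname(unlist(unclass(x)[PARAM_NAMES]))) %>%
    left_join(param_info(), by = "name")
}

# numeric vector in engine order
param_vector <- function(params) {
  stopifnot(inherits(params, "search_params"))
  unlist(unclass(params)[PARAM_NAMES])
}

engine_opts <- function(params, engine = list()) {
  cst <- attr(params, "constants")
  defaults <- list(
    tau_noise = cst$tau_noise, dt = cst$dt, motor_cap = cst$motor_cap,
    lip_leak = TRUE, clamp_nonneg = TRUE, noise_scale = 0L
  )
  opts <- modifyList(defaults, engine)
  opts$noise_scale <- switch(as.character(opts$noise_scale),
    "0" = 0L, "tau" = 0L, "1" = 1L, "sqrt_tau" = 1L,
    stop("noise_scale must be 'tau' or 'sqrt_tau'", call. = FALSE)
  )
  opts
}

#' Read or write a parameter set as a flat YAML file
#'
#' Parameter files are flat key-value maps using the canonical parameter
#' names (see [param_info()]); the fixed constants are stored under a
#' `constants` key.
#'
#' @param path file path.
#' @param params a [search_params()] object.
#' @return `read_params()` returns a `search_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  cst <- y$constants %||% list()
  y$constants <- NULL
  search_params(y,
    tau_noise = cst$tau_noise %||% 5,
    dt = cst$dt %||% 0.5,
    motor_cap = cst$motor_cap %||% 0.150
  )
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "search_params"))
  out <- unclass(params)
  out$constants <- attr(params, "constants")
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
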