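# state variable names in engine order
STATE_NAMES <- c(
  paste0("x_lip_", LIP_LOCATIONS), paste0("rho_lip_", LIP_LOCATIONS),
  "x_it_E_left", "x_it_E_right", "rho_it_E_left", "rho_it_E_right",
  "x_aip_L", "x_aip_R", "x_m_L", "x_m_R"
)

#' Zero network state
#'
#' All 20 state variables (six LIP activities, six LIP input OU processes,
#' two IT activities, two IT input OU processes, two AIP and two motor
#' accumulators) start at zero at cue onset.
#'
#' @return a named numeric vector of length 20.
#' @export
network_state <- function() {
  setNames(numeric(20), STATE_NAMES)
}

#' Deterministic drift and noise amplitudes of the 20-SDE system
#'
#' Reference (pure R) evaluation of the right-hand side of the network
#' SDEs at a given state and time. Each LIP unit passes its net input --
#' same-side AIP excitation, crossed AIP inhibition, self-excitation,
#' global motor inhibition, distance-weighted ring inhibition from the
#' other LIP units, and its OU-filtered stimulus input -- through the
#' firing-rate function [phi()], with a leak; IT units are an analogous
#' mutually-inhibiting pair; AIP and motor units are leaky gated
#' accumulators. The compiled integrator implements the same equations;
#' this function exists for inspection and testing.
#'
#' For an equation written \eqn{\tau dX = f dt + c\,\xi(t)}, the returned
#' drift is \eqn{f/\tau} and the noise amplitude is \eqn{c/\tau}
#' (`noise_scale = "tau"`, the literal reading) or \eqn{c/\sqrt{\tau}}
#' (`noise_scale = "sqrt_tau"`).
#'
#' @param state named numeric vector of length 20, see [network_state()].
#' @param params a [search_params()] object.
#' @param condition a one-row condition tibble from [trial_condition()].
#' @param t time (ms) since cue onset.
#' @param engine list of engine options (`lip_leak`, `noise_scale`).
#' @return a list with `drift` and `noise` (named length-20 vectors).
#' @export
#' @examples
#' d <- lca_drift(network_state(), params_m11(), trial_condition(4, "R1", "E_right"), 0)
#' d$drift[["x_lip_L1"]] # phi(0)/tau_lip > 0 at the origin
lca_drift <- function(state, params, condition, t, engine = list()) {
  stopifnot(length(state) == 20, all(is.finite(state)))
  p <- params
  opts <- engine_opts(params, engine)
  cc <- condition_codes(condition)

  x_lip <- state[1:6]
  rho_lip <- state[7:12]
  x_it <- state[13:14]
  rho_it <- state[15:16]
  x_aip <- state[17:18]
  x_m <- state[19:20]

  i_mi <- motor_inhibition(x_m, p$beta_mitlip)
  i_maip <- motor_inhibition(x_m, p$beta_maip)

  topo <- lip_topology()
  d_lip <- numeric(6)
  for (i in seq_len(6)) {
    loc <- LIP_LOCATIONS[i]
    nb <- topo[topo$from == loc, ]
    w <- p$eta_lip * c(1, p$eta_lip_decay1, p$eta_lip_decay1 * p$eta_lip_decay2)
    inhib <- sum(w[nb$distance] * x_lip[match(nb$to, LIP_LOCATIONS)])
    same <- if (substr(loc, 1, 1) == "L") 1 else 2
    I <- -p$beta_aiplip * x_aip[3 - same] + p$w_aiplip * x_aip[same] +
      p$alpha_lip * x_lip[i] - i_mi - inhib + rho_lip[i]
    leak <- if (isTRUE(opts$lip_leak)) x_lip[i] else 0
    d_lip[i] <- (phi(I) - leak) / p$tau_lip
  }

  d_rho_lip <- numeric(6)
  for (i in seq_len(6)) {
    loc <- LIP_LOCATIONS[i]
    inp <- perceptual_input(condition$set_size, loc, p$s_lip) *
      heaviside(t - p$p_delay) +
      target_input(condition$position, loc, p$s_tar) *
        heaviside(t - p$p_delay - p$t_delay) +
      p$s_back
    d_rho_lip[i] <- (-rho_lip[i] + inp) / opts$tau_noise
  }

  d_it <- numeric(2)
  for (k in 1:2) {
    I <- rho_it[k] - p$eta_maipit * x_it[3 - k] - i_mi
    d_it[k] <- (phi(I) - x_it[k]) / p$tau_it
  }
  d_rho_it <- numeric(2)
  for (k in 1:2) {
    inp <- orientation_input(condition$orientation, ORIENTATIONS[k], p$s_ori) *
      heaviside(t - p$p_delay - p$t_delay)
    d_rho_it[k] <- (-rho_it[k] + inp) / opts$tau_noise
  }

  d_aip <- numeric(2)
  for (k in 1:2) {
    lip_sum <- if (k == 1) sum(x_lip[1:3]) else sum(x_lip[4:6])
    gin <- p$w_itaip * x_it[k] + p$w_lipaip * lip_sum - i_maip
    d_aip[k] <- (-p$k_aip * x_aip[k] - p$eta_maipit * x_aip[3 - k] +
      gate_input(gin, p$g_aip)) / p$tau_aip
  }

  d_m <- numeric(2)
  for (k in 1:2) {
    d_m[k] <- (-p$k_m * x_m[k] - p$eta_maipit * x_m[3 - k] +
      gate_input(p$w_aipm * x_aip[k], p$g_m)) / p$tau_m
  }

  scale <- function(tau) if (opts$noise_scale == 0L) tau else sqrt(tau)
  noise <- setNames(numeric(20), STATE_NAMES)
  noise[7:12] <- p$c_lip / scale(opts$tau_noise)
  noise[15:16] <- p$c_it / scale(opts$tau_noise)
  noise[17:18] <- p$c_maip / scale(p$tau_aip)
  noise[19:20] <- p$c_maip / scale(p$tau_m)

  list(
    drift = setNames(
      c(d_lip, d_rho_lip, d_it, d_rho_it, d_aip, d_m),
      STATE_NAMES
    ),
    noise = noise
  )
}
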