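#' Deterministic nonlinearities of the network
#'
#' `phi()` is the firing-rate input-output function used by the LIP and IT
#' units (rates in kHz):
#' \deqn{\phi[I] = 0.001 + \frac{0.352 (I - 0.384)}{1 - e^{-352 (I - 0.384)}
#'   + 0.352 (I - 0.384)/0.1}.}
#' It is continuous and strictly increasing from 0.001 kHz (1 Hz) at large
#' negative input to 0.101 kHz (101 Hz) at large positive input; the
#' removable singularity at I = 0.384 is defined by its limit
#' 0.001 + 0.352/355.52. `gate_input()` is the piecewise-linear gate used by
#' the AIP and motor accumulators, max(I - g, 0). `heaviside()` is the unit
#' step with H(0) = 1, used by the input onset schedules.
#'
#' @param I input current (vectorised).
#' @param g gate level.
#' @param x real input (vectorised).
#' @return numeric vector.
#' @export
#' @examples
#' phi(0.384)            # limit value at the removable singularity
#' phi(c(-10, 0, 1, 10)) # strictly increasing, in (0.001, 0.101)
phi <- function(I) {
  stopifnot(is.numeric(I), all(is.finite(I)))
  u <- I - 0.384
  out <- numeric(length(u))
  small <- abs(u) < 1e-12
  out[small] <- 0.001 + 0.352 / 355.52
  ub <- u[!small]
  out[!small] <- 0.001 + 0.352 * ub / (-expm1(-352 * ub) + 3.52 * ub)
  out
}

#' @rdname phi
#' @export
gate_input <- function(I, g) {
  pmax(I - g, 0)
}

#' @rdname phi
#' @export
heaviside <- function(x) {
  if (!all(is.finite(x))) stop("heaviside() requires finite input", call. = FALSE)
  as.numeric(x >= 0)
}

#' Global motor inhibition current
#'
#' The summed motor-unit activity scaled by an inhibitory weight; with
#' weight `beta_mitlip` it is the feedback inhibition onto LIP and IT, with
#' `beta_maip` the feedback onto AIP. This reset signal grows as a motor
#' unit approaches threshold and drives down LIP/IT firing before the
#' response.
#'
#' @param x_m length-2 numeric, motor-unit activities (L, R) in kHz.
#' @param weight inhibitory weight.
#' @return inhibitory current (scalar).
#' @export
motor_inhibition <- function(x_m, weight) {
  stopifnot(length(x_m) == 2, is.numeric(x_m))
  weight * sum(x_m)
}
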