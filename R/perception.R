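#' Ganglion-cell density weight
#'
#' Front-back anisotropy of the retinal ganglion-cell density as a weight
#' on the signal from bin center `phi_mu`:
#' `D(phi_mu; chi) = (1 + chi * cos(phi_mu)) / (1 + chi)`.
#' `D = 1` straight ahead and `(1 - chi)/(1 + chi)` straight behind.
#'
#' @param phi_mu bin center angles (rad, egocentric)
#' @param chi anisotropy in `[0, 1]`
#' @return weights in `[(1-chi)/(1+chi), 1]`
#' @export
ganglion_density <- function(phi_mu, chi) {
  stopifnot(chi >= 0, chi <= 1)
  (1 + chi * cos(phi_mu)) / (1 + chi)
}

#' Unit signal kernel on the perception field
#'
#' `G(phi, phi_mu; kappa) = exp(kappa * (cos(phi - phi_mu) - 1))`:
#' a 2*pi-periodic bump with maximum 1 at `phi = phi_mu`, sharper for
#' larger `kappa`.
#'
#' @param phi evaluation angles (rad)
#' @param phi_mu signal center (rad)
#' @param kappa sharpness (> 0)
#' @return kernel values in `(0, 1]`
#' @export
signal_kernel <- function(phi, phi_mu, kappa) {
  stopifnot(kappa > 0)
  exp(kappa * (cos(phi - phi_mu) - 1))
}

#' Signal amplitude from apparent size
#'
#' The amplitude of a ganglion-cell signal decreases with the distance of
#' its source: `A(r) = amp * r0 / (r0 + r)`, where `r` is recovered from
#' the vertical angular diameter via [vision_distance()].  At contact
#' (`r = 0`) the amplitude is `amp`; at the limiting identification
#' distance `r0` it has dropped to half.
#'
#' @param r distances of the visible intersection (BL)
#' @param params a [model_params()] object (uses `amp`, `r0`)
#' @return amplitudes, strictly decreasing in `r`
#' @export
signal_amplitude <- function(r, params) params$amp * params$r0 / (params$r0 + r)

#' Speed gain of a signal
#'
#' `U(r, u) = (1 - exp(-r/ra)) + exp(-r/ra) * exp(beta * (u/v0 - 1))`:
#' within the pattern-detection distance `ra` the signal of a neighbor
#' moving at high relative speed `u` is amplified; far away the speed
#' cannot be read and `U ~ 1`.  Nondecreasing in `u`, equal to 1 when
#' `u = v0` or `beta = 0`.
#'
#' @param r distances (BL)
#' @param u relative speeds (BL/s), non-negative
#' @param params a [model_params()] object (uses `ra`, `beta`, `v0`)
#' @return gains (> 0)
#' @export
speed_gain <- function(r, u, params) {
  era <- exp(-r / params$ra)
  (1 - era) + era * exp(params$beta * (u / params$v0 - 1))
}

#' Synthesize the perception field from a visual field
#'
#' Superimposes the per-bin signals into the perception field
#' `Gamma(phi) = sum_mu D(phi_mu) * (-U * A * G(phi, phi_mu))`
#' over the occupied bins, together with its analytic derivative
#' `dGamma/dphi = sum_mu D * U * A * kappa * sin(phi - phi_mu) * G`.
#' `Gamma <= 0` everywhere and its local minima are the attractors of the
#' attention angle.
#'
#' @param vf a [visual_field()] object
#' @param params a [model_params()] object
#' @return a list of two vectorized functions, `gamma(phi)` and
#'   `dgamma(phi)`
#' @export
perception_field <- function(vf, params) {
  keep <- !is.na(vf$occupier)
  phi_mu <- vf$phi_mu[keep]
  if (!length(phi_mu)) {
    return(list(gamma = function(phi) rep(0, length(phi)),
                dgamma = function(phi) rep(0, length(phi))))
  }
  w <- ganglion_density(phi_mu, params$chi) *
    speed_gain(vf$r[keep], vf$u[keep], params) *
    signal_amplitude(vf$r[keep], params)
  kap <- params$kappa
  gamma <- function(phi) {
    vapply(phi, function(p)
      -sum(w * exp(kap * (cos(p - phi_mu) - 1))), numeric(1))
  }
  dgamma <- function(phi) {
    vapply(phi, function(p)
      sum(w * kap * sin(p - phi_mu) * exp(kap * (cos(p - phi_mu) - 1))),
      numeric(1))
  }
  list(gamma = gamma, dgamma = dgamma)
}

#' One explicit update of the attention angle
#'
#' Gradient descent on the perception field:
#' `phi' = wrap(phi - (dt / tau_phi) * dGamma/dphi(phi))`.
#' The step is capped at `dphi_max` (a numerical safeguard for steep
#' transient fields; inactive under ordinary conditions).
#'
#' @param phi current attention angle (rad)
#' @param dgamma derivative function, e.g. from [perception_field()]
#' @param params a [model_params()] object (uses `tau_phi`, `dphi_max`)
#' @param dt time step (s)
#' @return the updated attention angle in `[-pi, pi]`
#' @export
attention_step <- function(phi, dgamma, params, dt) {
  stopifnot(dt > 0)
  step <- -(dt / params$tau_phi) * dgamma(phi)
  step <- pmin(pmax(step, -params$dphi_max), params$dphi_max)
  wrap_angle(phi + step)
}
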