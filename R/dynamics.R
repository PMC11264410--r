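#' Radial speeding-force profile
#'
#' Piecewise-linear repulsion/attraction profile of the speeding force:
#' maximal repulsion `-fr` at contact, zero at the equilibrium front-back
#' distance `re`, maximal attraction `fa` at `ra`, decaying as
#' `fa * ra / r` beyond.  Continuous at both break points.
#'
#' @param r distances (BL), non-negative
#' @param params a [model_params()] object
#' @return force values
#' @export
speeding_profile <- function(r, params) {
  with(params, ifelse(r < re, -fr * (re - r) / re,
                      ifelse(r < ra, fa * (r - re) / (ra - re),
                             fa * ra / r)))
}

#' Radial turning-rate profile
#'
#' Analogue of [speeding_profile()] for the turning interaction, with the
#' equilibrium at the left-right distance `rho_e < re`.  The repulsive
#' branch is `-omega_r * (rho_e - r) / re` (note the `re` denominator, kept
#' exactly as in the source model), the attractive branch rises linearly to
#' `omega_a` at `ra`, then decays as `omega_a * ra / r`.
#'
#' @inheritParams speeding_profile
#' @return turning rates (rad/s)
#' @export
turning_profile <- function(r, params) {
  with(params, ifelse(r < rho_e, -omega_r * (rho_e - r) / re,
                      ifelse(r < ra, omega_a * (r - rho_e) / (ra - rho_e),
                             omega_a * ra / r)))
}

#' Speeding force of one visual reading
#'
#' `F = f(r) * cos(phi_mu)`: a neighbor ahead accelerates or decelerates
#' the focal agent depending on the sign of the radial profile; a neighbor
#' abeam (`phi_mu = +-pi/2`) exerts no speeding force.
#'
#' @param phi_mu bearing of the reading (rad, egocentric)
#' @param r distance of the reading (BL)
#' @param params a [model_params()] object
#' @return speeding-force values
#' @export
speeding_force <- function(phi_mu, r, params) {
  speeding_profile(r, params) * cos(phi_mu)
}

#' Angular velocity of one visual reading
#'
#' Sum of the repulsion-attraction term
#' `omega(r) * sin(phi_mu) * (1 - exp(-r/ra) * (1 + cos(psi)) / 2)`
#' and the alignment term
#' `omega_o * exp(-(r - ro)^2 / (2 lo^2)) * (1 + cos(phi_mu))/2 * sin(psi)`.
#' Near a neighbor the heading factor of the first term behaves as
#' `(1 - cos(psi))/2` and far away it reaches 1; alignment is strongest
#' for frontal neighbors at the intermediate distance `ro`.
#'
#' @param phi_mu bearing of the reading (rad, egocentric)
#' @param r distance of the reading (BL)
#' @param psi relative heading of the occupier (rad)
#' @param params a [model_params()] object
#' @return angular velocities (rad/s)
#' @export
turning_rate <- function(phi_mu, r, psi, params) {
  era <- exp(-r / params$ra)
  turning_profile(r, params) * sin(phi_mu) * (1 - era * (1 + cos(psi)) / 2) +
    params$omega_o * exp(-(r - params$ro)^2 / (2 * params$lo^2)) *
      (1 + cos(phi_mu)) / 2 * sin(psi)
}

#' Average a per-reading quantity over the resolution window
#'
#' Interactions are read only within the horizontal resolution window of
#' width `delta0 = 2*atan(lb/(2 r0))` centered on the attention angle:
#' the summed readings over the occupied bins whose centers fall in
#' `[phi - delta0/2, phi + delta0/2]` (wrap-aware) are divided either by
#' the occupied-bin count (default, `window_norm = "occupied"`: plain
#' mean over readings) or by the window size `|R_i|` (`"window"`: the
#' force is graded by how much of the window the attended image fills,
#' which weakens the reading of small distant images).
#' Either way the result is 0 when no occupied bin lies in the window
#' (no visual information at the attention angle, hence no interaction).
#'
#' @param vf a [visual_field()] object
#' @param phi attention angle (rad)
#' @param params a [model_params()] object
#' @param fn function of `(phi_mu, r, psi, u)` returning one value per
#'   reading (vectorized)
#' @return the window mean (scalar)
#' @export
resolution_average <- function(vf, phi, params, fn) {
  win <- window_bins(phi, params)
  sel <- win[!is.na(vf$occupier[win])]
  if (!length(sel)) return(0)
  denom <- if (params$window_norm == 1L) length(win) else length(sel)
  sum(fn(vf$phi_mu[sel], vf$r[sel], vf$psi[sel], vf$u[sel])) / denom
}

# one capped gradient sub-step of the attention angle (unwrapped; the
# caller wraps once after the sub-step loop, as the engine does)
attention_substep <- function(phi, dgamma, params, h, cap) {
  step <- -(h / params$tau_phi) * dgamma(phi)
  phi + min(max(step, -cap), cap)
}

# indices of bins whose centers lie in the window, matching the compiled
# engine's index arithmetic exactly (used by the reference step)
window_bins <- function(phi, params) {
  nb <- params$n_bins
  binw <- 2 * pi / nb
  lo <- wrap_angle(phi - params$delta0 / 2)
  g1 <- (lo + pi) / binw + 0.5
  mu <- seq(ceiling(g1 - 1e-9), floor(g1 + params$delta0 / binw + 1e-9))
  if (!length(mu)) return(integer(0))
  ((mu - 1) %% nb) + 1
}

#' One synchronous step of the full model (plain-R reference)
#'
#' Readable reference implementation of a single Euler--Maruyama step of
#' all agents: build each agent's visual field from the pre-step state,
#' move the attention angle down the perception-field gradient, average
#' the speeding force and angular velocity over the resolution window at
#' the pre-step attention angle, then update speed (clamped at 0), heading
#' and position.  All agents are updated from the pre-step state.  The
#' compiled engine used by [simulate_school()] performs the same update;
#' the two are cross-checked in the package tests.
#'
#' @param states agent state table ([agent_states()])
#' @param params a [model_params()] object
#' @param dt time step (s)
#' @param noise `n x 2` matrix of standard normals (speed, heading), or
#'   `NULL` for the noiseless update
#' @param virtual logical vector: scripted agents whose `(v, theta, phi)`
#'   are never updated by the model
#' @return the updated state table
#' @export
step_school <- function(states, params, dt, noise = NULL, virtual = NULL) {
  stopifnot(dt > 0)
  n <- nrow(states)
  if (is.null(noise)) noise <- matrix(0, n, 2)
  if (is.null(virtual)) virtual <- rep(FALSE, n)
  out <- states
  sv <- sqrt(2 * params$Dv * dt)
  sth <- sqrt(2 * params$Dtheta * dt)
  for (i in seq_len(n)) {
    out$x[i] <- states$x[i] + dt * states$v[i] * cos(states$theta[i])
    out$y[i] <- states$y[i] + dt * states$v[i] * sin(states$theta[i])
    if (virtual[i]) next
    vf <- visual_field(states, i, params)
    pf <- perception_field(vf, params)
    K <- params$phi_substeps
    phv <- states$phi[i]
    for (ss in seq_len(K))
      phv <- attention_substep(phv, pf$dgamma, params, dt / K,
                               params$dphi_max / K)
    out$phi[i] <- wrap_angle(phv)
    Fbar <- resolution_average(vf, states$phi[i], params,
                               function(pm, r, psi, u)
                                 speeding_force(pm, r, params))
    Obar <- resolution_average(vf, states$phi[i], params,
                               function(pm, r, psi, u)
                                 turning_rate(pm, r, psi, params))
    vn <- states$v[i] +
      dt * (params$drag * (params$v0^2 - states$v[i]^2) + Fbar) +
      sv * noise[i, 1]
    out$v[i] <- max(0, vn)
    out$theta[i] <- wrap_angle(states$theta[i] + dt * Obar +
                                 sth * noise[i, 2])
  }
  out
}
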