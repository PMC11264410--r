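#' Wrap an angle to [-pi, pi]
#'
#' The result is congruent to `x` modulo `2*pi`.  Endpoint convention:
#' `+pi` maps to `+pi` and `-pi` maps to `-pi` (the `atan2` form keeps both
#' endpoints fixed rather than collapsing one onto the other).
#'
#' @param x angles (rad), finite
#' @return wrapped angles in `[-pi, pi]`
#' @export
#' @examples
#' wrap_angle(3 * pi / 2)   # -pi/2
wrap_angle <- function(x) atan2(sin(x), cos(x))

#' Top-view body segment of an agent
#'
#' The rectangular body plate reduces, seen from above, to a line segment
#' of length `lb` along the heading.  The eye sits at offset `le` from the
#' body center toward the head, so the segment runs from
#' `r - (le + lb/2) e` to `r - (le - lb/2) e` with `e = (cos theta, sin
#' theta)`.
#'
#' @param state a one-row state (list or data.frame row with `x, y, theta`)
#' @param params a [model_params()] object (uses `lb`, `le`)
#' @return a 2x2 matrix; rows are the tail and head endpoints
#' @export
body_segment <- function(state, params) {
  e <- c(cos(state$theta), sin(state$theta))
  ctr <- c(state$x, state$y) - params$le * e
  rbind(tail = ctr - (params$lb / 2) * e,
        head = ctr + (params$lb / 2) * e)
}

#' Occlusion-resolved visual field of one agent
#'
#' Casts one ray per bin center from the focal eye; the occupier of a bin
#' is the neighbor whose body segment yields the nearest intersection, so
#' nearer bodies screen farther ones.  For occupied bins the vertical
#' angular diameter is `delta_perp = 2*atan(hb / (2*r))`, the relative
#' speed `u` is the magnitude of the relative velocity vector, and `psi`
#' is the relative heading.  Intersections closer than `eps_r` are clamped
#' to `eps_r` (transiently overlapping bodies).
#'
#' @param states agent state table ([agent_states()])
#' @param focal index of the focal agent
#' @param params a [model_params()] object
#' @return an object of class `visual_field`: a list with `n_bins`,
#'   `phi_mu` (bin centers, egocentric, rad), `occupier` (neighbor index,
#'   `NA` if empty), `r` (distance to the visible intersection, BL),
#'   `delta_perp`, `u`, `psi`
#' @export
visual_field <- function(states, focal, params) {
  pr <- cpp_project(states$x, states$y, states$v, states$theta, focal,
                    unclass(params))
  occ <- pr$occupier
  occ[occ == 0L] <- NA_integer_
  r <- pr$r
  j <- occ[!is.na(occ)]
  u <- psi <- rep(NA_real_, params$n_bins)
  if (length(j)) {
    i <- focal
    dux <- states$v[j] * cos(states$theta[j]) -
      states$v[i] * cos(states$theta[i])
    duy <- states$v[j] * sin(states$theta[j]) -
      states$v[i] * sin(states$theta[i])
    u[!is.na(occ)] <- sqrt(dux^2 + duy^2)
    psi[!is.na(occ)] <- wrap_angle(states$theta[j] - states$theta[i])
  }
  structure(list(n_bins = params$n_bins, phi_mu = pr$phi_mu,
                 occupier = occ, r = r,
                 delta_perp = ifelse(is.na(r), NA_real_,
                                     2 * atan(params$hb / (2 * r))),
                 u = u, psi = psi, focal = focal),
            class = "visual_field")
}

#' @export
print.visual_field <- function(x, ...) {
  nocc <- sum(!is.na(x$occupier))
  cat(sprintf("<visual_field> %d bins, %d occupied (pv = %.3f)\n",
              x$n_bins, nocc, nocc / x$n_bins))
  invisible(x)
}

#' Convert between distance and vertical angular diameter
#'
#' A body of height `hb` at distance `r` subtends the vertical angle
#' `delta_perp = 2*atan(hb/(2 r))`; the inverse `r = hb / (2
#' tan(delta_perp/2))` is how an agent estimates distance from apparent
#' height.
#'
#' @param delta_perp vertical angular diameters (rad), in `(0, pi)`
#' @param r distances (BL), positive
#' @param hb body height (BL)
#' @return distances, resp. angular diameters
#' @export
vision_distance <- function(delta_perp, hb) hb / (2 * tan(delta_perp / 2))

#' @rdname vision_distance
#' @export
angular_diameter <- function(r, hb) 2 * atan(hb / (2 * r))
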