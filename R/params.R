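#' Model parameters
#'
#' Builds the validated parameter record used by every stage of the model:
#' body geometry, visual-signal parameters, attention dynamics, and the
#' repulsion/attraction/alignment kinematics.  All lengths are in body
#' lengths (BL), times in seconds, angles in radians; the body length,
#' one second and the body mass set the unit system.
#'
#' @param lb body length (defines the length unit; default 1)
#' @param hb body height, the vertical extent of the body plate (BL)
#' @param le eye offset from the body center along the heading (BL);
#'   must lie in `[0, lb/2]` (eye toward the head)
#' @param n_bins number of visual-field bins (ganglion cells); the field of
#'   view is the full circle, bin width `2*pi/n_bins`
#' @param kappa sharpness of a single ganglion-cell signal on the
#'   perception field (> 0); larger values localize the signal better
#' @param chi front-back anisotropy of the ganglion-cell density, in
#'   `[0, 1]`; the front/back density ratio is `(1+chi)/(1-chi)`
#' @param beta speed-gain exponent (>= 0): how strongly a fast-moving
#'   neighbor is amplified when close enough for its speed to be read
#' @param amp amplitude scale of a single signal at contact
#' @param r0 limiting identification distance (BL): distance at which a
#'   body length subtends the horizontal resolution angle
#' @param ra pattern-detection distance (BL); also the distance of maximum
#'   attractive force
#' @param tau_phi time scale of the attention dynamics (s)
#' @param v0 steady swimming speed (BL/s)
#' @param drag drag/thrust coefficient `C` in `C (v0^2 - v^2)` (1/BL)
#' @param fr maximum repulsive speeding force (at contact)
#' @param fa maximum attractive speeding force (at distance `ra`)
#' @param re equilibrium front-back distance (BL)
#' @param rho_e equilibrium left-right distance (BL); `rho_e < re` for a
#'   slender body
#' @param omega_r,omega_a turning repulsion/attraction strengths (rad/s)
#' @param omega_o alignment strength (rad/s); with `chi` this is the main
#'   control parameter of the collective patterns
#' @param ro alignment-peak distance (BL), with `rho_e < ro < ra`
#' @param lo alignment width (BL)
#' @param Dv,Dtheta speed / heading noise intensities
#' @param eps_r minimum ray-intersection distance (BL): readings from
#'   transiently overlapping bodies are clamped to this distance
#' @param dphi_max cap on the attention step per time step (rad); a
#'   numerical safeguard for the explicit gradient update, inactive in
#'   ordinary conditions
#' @param phi_substeps gradient sub-steps of the attention equation per
#'   kinematic time step.  The default single capped step is the scheme
#'   the package is calibrated under; sub-stepping refines the descent in
#'   very dense packs at proportional cost
#' @param window_norm normalization of the resolution-window average:
#'   `"window"` divides the summed per-bin forces by the window size
#'   `|R_i|` (about five bins), so the force is graded by how much of the
#'   window the attended image fills; `"occupied"` divides by the number
#'   of occupied bins (plain mean over readings)
#'
#' @return an object of class `school_params` (a validated named list with
#'   the derived resolution window `delta0 = 2*atan(lb/(2*r0))` attached)
#' @export
#' @examples
#' p <- model_params(chi = 0.3, omega_o = 1.0)
#' p$delta0   # angular resolution window, rad
model_params <- function(lb = 1, hb = 0.25, le = 0.4, n_bins = 160,
                         kappa = 6, chi = 0.3, beta = 1, amp = 0.15,
                         r0 = 5, ra = 6, tau_phi = 0.1,
                         v0 = 1, drag = 1, fr = 1, fa = 1.5,
                         re = 2, rho_e = 1,
                         omega_r = 1, omega_a = 1.5, omega_o = 1.0,
                         ro = 2, lo = 1, Dv = 0.02, Dtheta = 0.02,
                         eps_r = 1e-3, dphi_max = 1.0,
                         phi_substeps = 1, window_norm = c("occupied", "window")) {
  p <- list(lb = lb, hb = hb, le = le, n_bins = as.integer(n_bins),
            kappa = kappa, chi = chi, beta = beta, amp = amp,
            r0 = r0, ra = ra, tau_phi = tau_phi,
            v0 = v0, drag = drag, fr = fr, fa = fa,
            re = re, rho_e = rho_e,
            omega_r = omega_r, omega_a = omega_a, omega_o = omega_o,
            ro = ro, lo = lo, Dv = Dv, Dtheta = Dtheta,
            eps_r = eps_r, dphi_max = dphi_max,
            phi_substeps = as.integer(phi_substeps),
            window_norm = normalize_window_norm(window_norm))
  validate_params(p)
  p$delta0 <- 2 * atan(p$lb / (2 * p$r0))
  class(p) <- "school_params"
  p
}

# accepts the documented strings or the stored integer code (0/1), so
# serialized parameter records round-trip through configs and sidecars
normalize_window_norm <- function(x) {
  if (is.numeric(x)) {
    stopifnot(x %in% c(0, 1))
    return(as.integer(x))
  }
  match(match.arg(x, c("occupied", "window")), c("occupied", "window")) - 1L
}

validate_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  num <- vapply(p, is.numeric, logical(1))
  chk(all(num), "all parameters must be numeric")
  chk(p$window_norm %in% c(0L, 1L), "window_norm must be 0 or 1")
  chk(all(vapply(p, function(z) all(is.finite(z)), logical(1))),
      "all parameters must be finite")
  chk(p$lb > 0, "lb > 0 required")
  chk(p$hb > 0, "hb > 0 required")
  chk(p$le >= 0 && p$le <= p$lb / 2, "le must lie in [0, lb/2]")
  chk(p$n_bins >= 8, "n_bins >= 8 required")
  chk(p$kappa > 0, "kappa > 0 required")
  chk(p$chi >= 0 && p$chi <= 1, "chi must lie in [0, 1]")
  chk(p$beta >= 0, "beta >= 0 required")
  chk(p$amp > 0, "amp > 0 required")
  chk(p$r0 > 0, "r0 > 0 required")
  chk(p$ra > 0, "ra > 0 required")
  chk(p$tau_phi > 0, "tau_phi > 0 required")
  chk(p$v0 > 0, "v0 > 0 required")
  chk(p$rho_e < p$re, "rho_e < re required (slender body)")
  chk(p$rho_e < p$ro && p$ro < p$ra, "rho_e < ro < ra required")
  chk(p$fr >= 0 && p$fa >= 0 && p$omega_r >= 0 && p$omega_a >= 0 &&
        p$omega_o >= 0, "force strengths must be >= 0")
  chk(p$Dv >= 0 && p$Dtheta >= 0, "noise intensities must be >= 0")
  chk(p$eps_r > 0, "eps_r > 0 required")
  chk(p$dphi_max > 0, "dphi_max > 0 required")
  chk(p$phi_substeps >= 1, "phi_substeps >= 1 required")
  invisible(p)
}

#' @export
print.school_params <- function(x, ...) {
  cat("<school_params>\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 9), " = ",
             signif(flat, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Construct a table of agent states
#'
#' An agent state holds the eye position `(x, y)`, speed `v >= 0`, heading
#' `theta` and attention angle `phi` (both wrapped to `[-pi, pi]`; `phi` is
#' measured relative to the heading, counterclockwise positive).
#'
#' @param x,y eye positions (BL)
#' @param v speeds (BL/s), non-negative
#' @param theta headings (rad)
#' @param phi attention angles (rad), default 0
#' @return a `data.frame` with columns `x, y, v, theta, phi`
#' @export
agent_states <- function(x, y, v, theta, phi = 0) {
  n <- length(x)
  stopifnot(length(y) == n, length(v) %in% c(1, n),
            length(theta) %in% c(1, n), length(phi) %in% c(1, n))
  if (any(v < 0)) stop("speeds must be non-negative")
  data.frame(x = x, y = y, v = rep_len(v, n),
             theta = wrap_angle(rep_len(theta, n)),
             phi = wrap_angle(rep_len(phi, n)))
}
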