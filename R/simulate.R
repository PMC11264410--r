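#' Run the compiled simulation engine
#'
#' Integrates the coupled attention/speed/heading/position system with an
#' explicit Euler--Maruyama scheme (single shared time step).  Scripted
#' ("virtual") agents keep their initial speed and heading and move
#' rigidly; they are visible to the model agents like any other body but
#' are never updated by the model.  Noise is generated from per-agent
#' counter-based streams keyed by `(seed, id, step)`, so trajectories are
#' bit-reproducible and invariant under permutation of agent storage
#' order.
#'
#' @param states initial agent state table ([agent_states()])
#' @param params a [model_params()] object
#' @param t_end duration (s)
#' @param dt time step (s, default 0.01)
#' @param seed integer seed for the noise streams
#' @param record_every record every this many steps (default 10)
#' @param virtual logical vector of scripted agents (default none)
#' @param baseline if `TRUE`, run the conventional averaged-force control:
#'   no visual field, no attention; forces are arithmetic means over all
#'   virtual agents
#' @param ids stable agent identities for the noise streams (default
#'   `1:n`)
#' @return a `school_traj`: a long `data.frame` with columns
#'   `t, id, x, y, v, theta, phi, virtual` and the run configuration in
#'   `attr(, "config")`
#' @export
simulate_school <- function(states, params, t_end, dt = 0.01, seed = 1,
                            record_every = 10L, virtual = NULL,
                            baseline = FALSE, ids = NULL) {
  stopifnot(t_end > 0, dt > 0, record_every >= 1)
  n <- nrow(states)
  if (is.null(virtual)) virtual <- rep(FALSE, n)
  if (is.null(ids)) ids <- seq_len(n)
  nsteps <- round(t_end / dt)
  init <- cbind(states$x, states$y, states$v, states$theta, states$phi)
  res <- cpp_simulate(init, as.integer(virtual), as.integer(ids),
                      unclass(params), as.integer(nsteps), dt,
                      as.double(seed), as.integer(record_every), baseline)
  nrec <- res$nrec
  if (res$failed_step > 0)
    warning(sprintf(paste0("numerical blow-up at step %d (agent %d); ",
                           "trajectory truncated at the last valid frame"),
                    res$failed_step, res$failed_agent))
  keep <- seq_len(nrec)
  traj <- data.frame(
    t = rep(res$t[keep], each = n),
    id = rep(ids, nrec),
    x = as.vector(t(res$x[keep, , drop = FALSE])),
    y = as.vector(t(res$y[keep, , drop = FALSE])),
    v = as.vector(t(res$v[keep, , drop = FALSE])),
    theta = as.vector(t(res$theta[keep, , drop = FALSE])),
    phi = as.vector(t(res$phi[keep, , drop = FALSE])),
    virtual = rep(virtual, nrec))
  attr(traj, "config") <- list(params = params, t_end = t_end, dt = dt,
                               seed = seed, record_every = record_every,
                               baseline = baseline, n = n)
  class(traj) <- c("school_traj", "data.frame")
  traj
}

#' Extract one recorded frame of a trajectory
#'
#' @param traj a `school_traj`
#' @param time a recorded time (the nearest recorded frame is used)
#' @return an [agent_states()] table with a `virtual` column
#' @export
traj_frame <- function(traj, time) {
  tt <- unique(traj$t)
  tsel <- tt[which.min(abs(tt - time))]
  fr <- traj[traj$t == tsel, c("x", "y", "v", "theta", "phi", "virtual")]
  rownames(fr) <- NULL
  attr(fr, "t") <- tsel
  fr
}

#' Recorded times of a trajectory
#' @param traj a `school_traj`
#' @return numeric vector of recorded times
#' @export
traj_times <- function(traj) unique(traj$t)

#' @export
print.school_traj <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<school_traj> %d agents, t in [0, %g], dt = %g, %d frames\n",
              cfg$n, max(x$t), cfg$dt, length(unique(x$t))))
  invisible(x)
}

#' Simulate a free group of agents
#'
#' Places `n` agents uniformly at random in a disk, all with speed `v0`,
#' headings and attention angles uniform in `[-pi, pi]`, and integrates
#' the full model.  This is the scenario behind the collective-pattern
#' phase diagram (default: 100 agents in a disk of radius 7 BL).
#'
#' @param params a [model_params()] object
#' @param n number of agents (default 100)
#' @param init_radius radius of the seeding disk (BL, default 7)
#' @param t_end duration (s)
#' @param dt time step (s)
#' @param seed integer seed (initial condition and noise)
#' @param record_every recording decimation
#' @return a `school_traj`
#' @export
run_collective <- function(params, n = 100, init_radius = 7, t_end = 300,
                           dt = 0.01, seed = 1, record_every = 50L) {
  st <- disk_states(n, init_radius, params$v0, seed)
  simulate_school(st, params, t_end, dt, seed = seed,
                  record_every = record_every)
}

# uniform random placement in a disk with uniform headings and attention
disk_states <- function(n, radius, v0, seed) {
  set.seed(seed %% .Machine$integer.max)
  rr <- radius * sqrt(runif(n))
  aa <- runif(n, -pi, pi)
  agent_states(x = rr * cos(aa), y = rr * sin(aa), v = v0,
               theta = runif(n, -pi, pi), phi = runif(n, -pi, pi))
}

#' Virtual-agent decision-making assay
#'
#' Reproduces the branching assay: scripted virtual agents start on the
#' line `y = 0` and move along the y-axis at `v0`; the focal agent starts
#' at `(0, -ra)` moving along y at `v0` with attention straight ahead, and
#' obeys the full model.  Two virtual agents sit at `x = -L/2, +L/2`;
#' three sit at `x = -L, 0, +L` with the center one shifted right by
#' `L_asym` in the asymmetric configuration.
#'
#' @param params a [model_params()] object
#' @param L lateral spacing (BL)
#' @param n_virtual 2 or 3
#' @param L_asym rightward shift of the center virtual agent (BL)
#' @param t_end duration (s)
#' @param dt time step (s)
#' @param seed integer seed
#' @param record_every recording decimation
#' @param baseline if `TRUE`, use the conventional averaged-force control
#'   (forces averaged over all virtual agents, no vision, no attention)
#' @return a `school_traj`; the focal agent has `id = 1`
#' @export
run_virtual_assay <- function(params, L, n_virtual = 2, L_asym = 0,
                              t_end = 300, dt = 0.01, seed = 1,
                              record_every = 10L, baseline = FALSE) {
  stopifnot(n_virtual %in% c(2, 3), L >= 0, L_asym >= 0)
  xv <- if (n_virtual == 2) c(-L / 2, L / 2) else c(-L, L, L_asym)
  st <- agent_states(x = c(0, xv), y = c(-params$ra, rep(0, n_virtual)),
                     v = params$v0, theta = pi / 2, phi = 0)
  virtual <- c(FALSE, rep(TRUE, n_virtual))
  simulate_school(st, params, t_end, dt, seed = seed,
                  record_every = record_every, virtual = virtual,
                  baseline = baseline)
}

#' Conventional averaged-force baseline assay
#'
#' Same assay as [run_virtual_assay()] but the focal agent's speeding
#' force and angular velocity are arithmetic means of the contributions
#' from all virtual agents, computed from their true relative positions:
#' no visual field, no occlusion, no attention.
#'
#' @inheritParams run_virtual_assay
#' @return a `school_traj`
#' @export
run_conventional_baseline <- function(params, L, n_virtual = 2, L_asym = 0,
                                      t_end = 300, dt = 0.01, seed = 1,
                                      record_every = 10L) {
  run_virtual_assay(params, L, n_virtual, L_asym, t_end, dt, seed,
                    record_every, baseline = TRUE)
}

#' Static random configurations for visual statistics
#'
#' Places `n` agents uniformly at random in a disk of the given radius
#' with headings either uniform in `[-pi, pi]` (`mode = "random"`) or all
#' identical (`mode = "aligned"`).  Used only as a static reference for
#' the visual-information statistics; never stepped.
#'
#' @param n number of agents
#' @param radius disk radius (BL, default 7)
#' @param mode `"random"` or `"aligned"`
#' @param seed integer seed
#' @param v0 common speed (BL/s)
#' @return an [agent_states()] table
#' @export
random_configuration <- function(n, radius = 7, mode = c("random", "aligned"),
                                 seed = 1, v0 = 1) {
  mode <- match.arg(mode)
  set.seed(seed %% .Machine$integer.max)
  rr <- radius * sqrt(runif(n))
  aa <- runif(n, -pi, pi)
  th <- if (mode == "random") runif(n, -pi, pi) else rep(runif(1, -pi, pi), n)
  agent_states(x = rr * cos(aa), y = rr * sin(aa), v = v0, theta = th,
               phi = runif(n, -pi, pi))
}

#' Focal trajectory in the frame co-moving with the virtual agents
#'
#' The virtual agents translate rigidly at `v0` along y, so the co-moving
#' frame subtracts `v0 * t` from y; x is unchanged.  Positions are
#' reported relative to the virtual agents' initial line `y = 0`.
#'
#' @param traj an assay `school_traj`
#' @param v0 speed of the co-moving frame (defaults to the run's `v0`)
#' @return a `data.frame` with the focal agent's `t, x, y` in the
#'   co-moving frame
#' @export
comoving_focal <- function(traj, v0 = attr(traj, "config")$params$v0) {
  foc <- traj[!traj$virtual & traj$id == traj$id[!traj$virtual][1], ]
  data.frame(t = foc$t, x = foc$x, y = foc$y - v0 * foc$t)
}
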