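# Independent brute-force oracles used to validate the compiled engine.
# Everything here is deliberately naive: plain all-pairs ray/segment
# intersection with no angular-interval shortcuts, no occlusion pruning,
# no shared code with the package internals.

# intersection distance of the ray (origin o, unit direction d) with the
# segment p1--p2; NA if no hit
ray_segment_dist <- function(o, d, p1, p2) {
  q1 <- p1 - o
  e <- p2 - p1
  den <- d[1] * e[2] - d[2] * e[1]
  if (abs(den) < 1e-12) {
    # parallel: endpoints lying on the ray
    tt <- Inf
    for (q in list(q1, p2 - o)) {
      if (abs(d[1] * q[2] - d[2] * q[1]) < 1e-7 * (sum(abs(q)) + 1e-30)) {
        tp <- sum(d * q)
        if (tp > 0 && tp < tt) tt <- tp
      }
    }
    return(if (is.finite(tt)) tt else NA_real_)
  }
  s <- (q1[1] * d[2] - q1[2] * d[1]) / den
  if (s < 0 || s > 1) return(NA_real_)
  tt <- (q1[1] * e[2] - q1[2] * e[1]) / den
  if (tt <= 0) return(NA_real_)
  tt
}

# brute-force occlusion-resolved projection: for every bin, test every
# neighbor and keep the nearest intersection
oracle_project <- function(states, focal, params) {
  nb <- params$n_bins
  binw <- 2 * pi / nb
  phi_mu <- -pi + (seq_len(nb) - 0.5) * binw
  o <- c(states$x[focal], states$y[focal])
  occ <- rep(NA_integer_, nb)
  r <- rep(NA_real_, nb)
  segs <- lapply(seq_len(nrow(states)), function(j) {
    e <- c(cos(states$theta[j]), sin(states$theta[j]))
    ctr <- c(states$x[j], states$y[j]) - params$le * e
    list(p1 = ctr - params$lb / 2 * e, p2 = ctr + params$lb / 2 * e)
  })
  for (k in seq_len(nb)) {
    a <- states$theta[focal] + phi_mu[k]
    d <- c(cos(a), sin(a))
    for (j in seq_len(nrow(states))) {
      if (j == focal) next
      tt <- ray_segment_dist(o, d, segs[[j]]$p1, segs[[j]]$p2)
      if (!is.na(tt)) {
        tt <- max(tt, params$eps_r)
        if (is.na(r[k]) || tt < r[k]) { r[k] <- tt; occ[k] <- j }
      }
    }
  }
  list(phi_mu = phi_mu, occupier = occ, r = r)
}

# random scene of n agents in a disk
random_scene <- function(n, radius = 5, seed = 1) {
  set.seed(seed)
  rr <- radius * sqrt(runif(n))
  aa <- runif(n, -pi, pi)
  agent_states(x = rr * cos(aa), y = rr * sin(aa), v = runif(n, 0.2, 2),
               theta = runif(n, -pi, pi), phi = runif(n, -pi, pi))
}

# quiet default parameters for deterministic unit tests
quiet_params <- function(...) model_params(Dv = 0, Dtheta = 0, ...)
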