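test_that("polar order matches closed forms and random-heading statistics", {
  aligned <- agent_states(x = 1:5, y = rep(0, 5), v = 1, theta = 0.8)
  expect_equal(polar_order(aligned), 1)
  anti <- agent_states(x = c(0, 1), y = c(0, 0), v = 1, theta = c(0, pi))
  expect_equal(polar_order(anti), 0, tolerance = 1e-12)
  # N uniform random headings: resultant ~ sqrt(pi)/(2 sqrt(N))
  set.seed(1)
  P <- replicate(20, polar_order(
    agent_states(x = rnorm(1000), y = rnorm(1000), v = 1,
                 theta = runif(1000, -pi, pi))))
  expect_lt(mean(P), 0.1)
  expect_equal(mean(P), sqrt(pi) / (2 * sqrt(1000)), tolerance = 0.3)
})

test_that("rotational order distinguishes vortex, radial and mixed states", {
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- agent_states(x = cos(ang), y = sin(ang), v = 1,
                       theta = wrap_angle(ang + pi / 2))   # tangential
  expect_equal(rotational_order(circ), 1, tolerance = 1e-12)
  radial <- agent_states(x = cos(ang), y = sin(ang), v = 1, theta = ang)
  expect_equal(rotational_order(radial), 0, tolerance = 1e-12)
  # two agents rotating in opposite senses cancel
  two <- agent_states(x = c(-1, 1), y = c(0, 0), v = 1,
                      theta = c(pi / 2, pi / 2))
  expect_equal(rotational_order(two), 0, tolerance = 1e-12)
})

test_that("order parameters are invariant under rigid motions", {
  st <- random_scene(40, seed = 5)
  a <- 1.1
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- cbind(st$x, st$y) %*% t(R)
  moved <- st
  moved$x <- xy[, 1] + 17; moved$y <- xy[, 2] - 4
  moved$theta <- wrap_angle(st$theta + a)
  expect_equal(polar_order(moved), polar_order(st), tolerance = 1e-12)
  expect_equal(rotational_order(moved), rotational_order(st),
               tolerance = 1e-12)
})

test_that("pattern classification maps order-parameter regimes to labels", {
  tt <- seq(0, 300, 0.5)
  mk <- function(P, M) data.frame(t = tt, P = P, M = M)
  expect_equal(classify_pattern(mk(0.95, 0.05)), "polarized_school")
  expect_equal(classify_pattern(mk(0.1, 0.9)), "vortex")
  expect_equal(classify_pattern(mk(0.2, 0.1)), "swarm")
  # oscillating series: unsteady aggregation
  osc <- mk(0.45 + 0.35 * sin(tt / 15), 0.45 + 0.35 * cos(tt / 15))
  expect_equal(classify_pattern(osc), "unsteady")
  # polarized with intermittent milling spikes: turning
  M <- rep(0.08, length(tt))
  M[tt %% 60 < 6] <- 0.75
  expect_equal(classify_pattern(mk(0.8, M)), "turning")
})

test_that("marginal distributions and mode finding recover known mixtures", {
  set.seed(7)
  uni <- rnorm(4000, 0, 0.5)
  duni <- marginal_distribution(uni, bw = 0.25)
  expect_equal(find_modes(duni), 0, tolerance = 0.2)
  # well-separated symmetric mixture: two modes at +-2
  bi <- c(rnorm(2000, -2, 0.4), rnorm(2000, 2, 0.4))
  dbi <- marginal_distribution(bi, bw = 0.25)
  m <- find_modes(dbi)
  expect_length(m, 2)
  expect_equal(sort(m), c(-2, 2), tolerance = 0.25)
  # normalization
  dx <- diff(dbi$x[1:2])
  expect_equal(sum(dbi$density) * dx, 1, tolerance = 0.01)
})

test_that("bifurcation threshold finds the first multimodal spacing", {
  set.seed(8)
  L <- seq(1, 5, 0.5)
  dists <- lapply(L, function(l) {
    x <- if (l >= 3) c(rnorm(1500, -l / 2, 0.3), rnorm(1500, l / 2, 0.3))
         else rnorm(3000, 0, 0.4)
    marginal_distribution(x, bw = 0.25)
  })
  expect_equal(bifurcation_threshold(dists, L), 3)
  # unimodal family: no threshold
  duni <- lapply(L, function(l) marginal_distribution(rnorm(2000, 0, 0.4)))
  expect_true(is.na(bifurcation_threshold(duni, L)))
})

test_that("visual statistics match the geometry oracle for simple scenes", {
  p <- quiet_params(le = 0)
  # one broadside neighbor at distance 3: pv equals the analytic angular
  # fraction, dv ~ 3, dmin = 3
  st <- agent_states(x = c(0, 3), y = c(0, 0), v = 1,
                     theta = c(0, pi / 2), phi = 0)
  vs <- visual_statistics(st, p)
  expect_lt(abs(vs$pv[1] - 2 * atan(1 / 6) / (2 * pi)), 1.5 / p$n_bins)
  expect_equal(vs$dv[1], 3, tolerance = 0.05)
  expect_equal(vs$dmin[1], 3, tolerance = 1e-9)
  expect_equal(vs$pn[1, 1], 1)
})

test_that("a fully occluded neighbor has zero relative occupancy", {
  p <- quiet_params(le = 0)
  st <- agent_states(x = c(0, 2, 5), y = c(0, 0, 0), v = 1,
                     theta = c(0, pi / 2, pi / 2), phi = 0)
  vs <- visual_statistics(st, p)
  expect_equal(vs$pn[1, 1], 1)   # nearest neighbor holds every occupied bin
  expect_equal(vs$pn[1, 2], 0)   # the one behind it is fully screened
})

test_that("pn profiles reconstruct pv and favor near neighbors", {
  p <- quiet_params()
  st <- random_configuration(30, radius = 6, mode = "random", seed = 9)
  vs <- visual_statistics(st, p)
  # per-agent pn sums to 1 over topological distance (fractions of the
  # occupied bins)
  expect_equal(rowSums(vs$pn), rep(1, 30), tolerance = 1e-12)
  prof <- colMeans(vs$pn)
  # the nearest neighbors hold more of the field than the farthest
  expect_gt(mean(prof[1:3]), mean(prof[27:29]))
})

test_that("force maps recover a known force field from its trajectories", {
  # synthetic data: a focal 'agent' with prescribed acceleration field
  # a(front) = A0 * sin(front), neighbor orbiting; integrate forward, then
  # invert with the central-difference estimator
  p <- quiet_params()
  dtr <- 0.05
  tt <- seq(0, 400, dtr)
  A0 <- 0.4
  # neighbor path chosen to sweep front-back positions; focal at rest frame
  # moving on x with slowly varying speed
  vx <- numeric(length(tt)); vx[1] <- 1
  xx <- numeric(length(tt))
  front <- 3 * sin(tt / 7)           # neighbor's relative front coordinate
  for (k in seq_len(length(tt) - 1)) {
    acc <- A0 * sin(front[k])
    vx[k + 1] <- vx[k] + dtr * acc
    xx[k + 1] <- xx[k] + dtr * vx[k]
  }
  traj <- rbind(
    data.frame(t = tt, id = 1, x = xx, y = 0, v = vx, theta = 0, phi = 0,
               virtual = FALSE),
    data.frame(t = tt, id = 2, x = xx + front, y = 0.4, v = 1, theta = 0,
               phi = 0, virtual = FALSE))
  class(traj) <- c("school_traj", "data.frame")
  p0 <- quiet_params(drag = 0)       # no self-propulsion in the fixture
  fm <- force_map(traj, p0, extent = 4, cell = 0.5, min_count = 30)
  # compare recovered speeding force against the prescribed field
  ok <- which(!is.na(fm$speeding), arr.ind = TRUE)
  expect_gt(nrow(ok), 5)
  pred <- A0 * sin(fm$front[ok[, 1]])
  expect_equal(fm$speeding[ok], pred, tolerance = 0.1)
})
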