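#' Polar order parameter
#'
#' Magnitude of the mean heading unit vector,
#' `P = |sum_i e_i| / N`: 1 for a perfectly aligned school, ~0 for random
#' headings.
#'
#' @param states an [agent_states()] table (or anything with `theta`)
#' @return `P` in `[0, 1]`
#' @export
polar_order <- function(states) {
  th <- states$theta
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Rotational (milling) order parameter
#'
#' Magnitude of the mean 2D cross product between the unit vector from
#' the group centroid and the heading, `M = |sum_i chat_i x e_i| / N`:
#' 1 for a perfect common-sense vortex, 0 for radial headings or opposite
#' rotation senses.  Agents lying exactly at the centroid carry no radial
#' direction and are skipped.
#'
#' @param states an [agent_states()] table (needs `x, y, theta`)
#' @return `M` in `[0, 1]`
#' @export
rotational_order <- function(states) {
  n <- nrow(states)
  stopifnot(n >= 2)
  cx <- states$x - mean(states$x)
  cy <- states$y - mean(states$y)
  rr <- sqrt(cx^2 + cy^2)
  keep <- rr > 1e-12
  if (!any(keep)) stop("all agents at the center of mass")
  cross <- (cx[keep] * sin(states$theta[keep]) -
              cy[keep] * cos(states$theta[keep])) / rr[keep]
  abs(sum(cross)) / n
}

#' Order-parameter time series of a trajectory
#'
#' @param traj a `school_traj`
#' @return a `data.frame` with columns `t, P, M`
#' @export
order_series <- function(traj) {
  tt <- unique(traj$t)
  P <- M <- numeric(length(tt))
  for (k in seq_along(tt)) {
    fr <- traj[traj$t == tt[k], ]
    P[k] <- polar_order(fr)
    M[k] <- rotational_order(fr)
  }
  data.frame(t = tt, P = P, M = M)
}

#' Classify a collective pattern from its order-parameter series
#'
#' Labels the steady pattern from the time-averaged polarization `P` and
#' milling order `M` past the burn-in: `vortex` (high `M`, low `P`),
#' `polarized_school` (high `P`, low `M`), `swarm` (both low), `turning`
#' (high mean `P` with intermittent spikes of `M`), `unsteady` (both
#' series oscillating with large amplitude), otherwise `unclassified`.
#' The thresholds are artifact choices exposed as arguments; the
#' underlying order-parameter map is continuous.
#'
#' @param series a `data.frame` from [order_series()]
#' @param burn_in time discarded before averaging (s)
#' @param hi,lo thresholds on the time-averaged order parameters
#' @param osc_sd standard deviation above which a series counts as
#'   oscillating
#' @param spike_height excursion of `M` above its median that counts as a
#'   spike
#' @return a label string
#' @export
classify_pattern <- function(series, burn_in = 100, hi = 0.6, lo = 0.4,
                             osc_sd = 0.2, spike_height = 0.3) {
  s <- series[series$t >= burn_in, ]
  if (nrow(s) < 3) stop("series too short past burn-in")
  Pm <- mean(s$P); Mm <- mean(s$M)
  Psd <- sd(s$P);  Msd <- sd(s$M)
  spikes <- any(s$M > median(s$M) + spike_height)
  if (Psd > osc_sd && Msd > osc_sd) return("unsteady")
  if (Mm > hi && Pm < lo) return("vortex")
  if (Pm > hi) {
    if (spikes && Msd > osc_sd / 2) return("turning")
    if (Mm < lo) return("polarized_school")
    return("unclassified")
  }
  if (Pm < lo && Mm < lo) return("swarm")
  "unclassified"
}

#' Marginal position distribution of the focal agent
#'
#' Kernel-smoothed marginal distribution `P(x; L)` of the focal agent's
#' lateral position in the co-moving frame of the virtual agents,
#' accumulated after the burn-in.  Samples may come from several
#' concatenated runs.
#'
#' @param x focal lateral positions after burn-in, or a `school_traj`
#'   (assay) from which they are extracted
#' @param burn_in time discarded at the start of each run (s)
#' @param bw kernel bandwidth (BL)
#' @param from,to evaluation range (defaults to the sample range padded
#'   by `3*bw`)
#' @return a `data.frame` with columns `x, density`; the sample size in
#'   `attr(, "n")`
#' @export
marginal_distribution <- function(x, burn_in = 50, bw = 0.25,
                                  from = NULL, to = NULL) {
  if (inherits(x, "school_traj")) {
    cf <- comoving_focal(x)
    x <- cf$x[cf$t >= burn_in]
  }
  stopifnot(length(x) > 10)
  if (is.null(from)) from <- min(x) - 3 * bw
  if (is.null(to)) to <- max(x) + 3 * bw
  d <- density(x, bw = bw, from = from, to = to, n = 512)
  structure(data.frame(x = d$x, density = d$y), n = length(x))
}

#' Locate the modes of a smoothed distribution
#'
#' A mode is a strict local maximum of the smoothed density whose height
#' exceeds `min_height` times the global maximum.
#'
#' @param dist a `data.frame` from [marginal_distribution()]
#' @param min_height relative height threshold (default 0.1)
#' @return the mode locations (numeric vector, possibly length 0)
#' @export
find_modes <- function(dist, min_height = 0.1) {
  y <- dist$density
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  # include boundary maxima so a mode pushed to the range edge still counts
  if (y[1] > y[2]) is_max[1] <- TRUE
  if (y[n] > y[n - 1]) is_max[n] <- TRUE
  keep <- is_max & y >= min_height * max(y)
  dist$x[keep]
}

#' Bifurcation threshold of a family of marginal distributions
#'
#' Scans the distributions in increasing order of `L` and returns the
#' smallest `L` whose smoothed marginal has at least `n_modes` modes
#' (ties broken toward smaller `L`); `NA` if no distribution in the
#' family is multimodal.
#'
#' @param dists list of [marginal_distribution()] results
#' @param L lateral spacings, same length as `dists`
#' @param n_modes required number of modes (default 2)
#' @param min_height passed to [find_modes()]
#' @return the threshold `L` (or `NA`)
#' @export
bifurcation_threshold <- function(dists, L, n_modes = 2, min_height = 0.1) {
  stopifnot(length(dists) == length(L))
  o <- order(L)
  for (k in o) {
    if (length(find_modes(dists[[k]], min_height)) >= n_modes)
      return(L[k])
  }
  NA_real_
}

#' Visual-information statistics of a configuration
#'
#' For each agent of a static configuration (or recorded frame), builds
#' the occlusion-resolved visual field and measures: the occupancy ratio
#' `pv` (fraction of occupied bins), the visually estimated mean neighbor
#' distance `dv` (mean of the per-bin distances recovered from the
#' vertical angular diameter), the minimum Euclidean distance `dmin` from
#' the focal eye to a neighbor body center, the relative occupancy `pn`
#' of the n-th nearest neighbor (fraction of the occupied bins held by
#' the image of the n-th nearest neighbor, neighbors ranked by Euclidean
#' distance), and `attn[n]`, the indicator that the attention angle lies
#' in a bin occupied by the n-th nearest neighbor.
#'
#' @param states an [agent_states()] table (a `virtual` column, if
#'   present, is ignored: all bodies are visible)
#' @param params a [model_params()] object
#' @return a list with per-agent vectors `pv, dv, dmin`, and `n x (n-1)`
#'   matrices `pn`, `attn`
#' @export
visual_statistics <- function(states, params) {
  n <- nrow(states)
  stopifnot(n >= 2)
  nb <- params$n_bins
  pv <- dv <- dmin <- numeric(n)
  pn <- attn <- matrix(0, n, n - 1)
  for (i in seq_len(n)) {
    vf <- visual_field(states, i, params)
    occ <- vf$occupier
    nocc <- sum(!is.na(occ))
    pv[i] <- nocc / nb
    dv[i] <- if (nocc) mean(vf$r[!is.na(occ)]) else NA_real_
    # Euclidean distance from the focal eye to neighbor body centers
    cx <- states$x - params$le * cos(states$theta)
    cy <- states$y - params$le * sin(states$theta)
    dd <- sqrt((cx - states$x[i])^2 + (cy - states$y[i])^2)
    dd[i] <- Inf
    dmin[i] <- min(dd)
    rank_of <- integer(n)
    rank_of[order(dd)] <- seq_len(n)       # rank n means Inf (self) last
    if (nocc) {
      occ_rank <- rank_of[occ[!is.na(occ)]]
      tab <- tabulate(occ_rank, nbins = n - 1)
      pn[i, ] <- tab / nocc
      # bin holding the attention angle
      binw <- 2 * pi / nb
      bidx <- floor((wrap_angle(states$phi[i]) + pi) / binw) + 1
      bidx <- min(max(bidx, 1L), nb)
      if (!is.na(occ[bidx])) attn[i, rank_of[occ[bidx]]] <- 1
    }
  }
  list(pv = pv, dv = dv, dmin = dmin, pn = pn, attn = attn)
}

#' Aggregate visual statistics over recorded frames
#'
#' @param traj a `school_traj`
#' @param params a [model_params()] object
#' @param times recorded times to analyze (default: the last 5 frames)
#' @return a list with the pooled means and standard deviations of
#'   `pv`, `dv`, `dmin`, and the mean `pn` profile over topological
#'   distance
#' @export
visual_statistics_traj <- function(traj, params, times = NULL) {
  tt <- traj_times(traj)
  if (is.null(times)) times <- utils::tail(tt, 5)
  acc <- lapply(times, function(tm)
    visual_statistics(traj_frame(traj, tm), params))
  pool <- function(f) unlist(lapply(acc, `[[`, f))
  pn <- Reduce(`+`, lapply(acc, function(a) colMeans(a$pn))) / length(acc)
  attn <- Reduce(`+`, lapply(acc, function(a) colMeans(a$attn))) / length(acc)
  list(pv_mean = mean(pool("pv")), pv_sd = sd(pool("pv")),
       dv_mean = mean(pool("dv"), na.rm = TRUE),
       dv_sd = sd(pool("dv"), na.rm = TRUE),
       dmin_mean = mean(pool("dmin")), dmin_sd = sd(pool("dmin")),
       pn = pn, attn = attn)
}

#' Pairwise force and density maps from a trajectory
#'
#' Measures the force on the focal agent as its acceleration (central
#' differences of the recorded velocity vector) and splits it into the
#' speeding component (along the heading) and the turning component
#' (perpendicular, left positive).  Forces and visit counts are binned
#' over the neighbor's position in the focal frame (front-back along the
#' heading, left-right perpendicular).  With `subtract_self = TRUE` the
#' self-propulsion `drag * (v0^2 - v^2)` is removed from the speeding
#' component before binning.
#'
#' @param traj a `school_traj` of exactly two interacting agents
#' @param params a [model_params()] object
#' @param extent half-extent of the map (BL, default 5)
#' @param cell cell size (BL, default 0.25)
#' @param min_count cells with fewer samples are masked to `NA`
#' @param subtract_self remove the self-propulsion term (default FALSE)
#' @return a list with `front`, `left` (cell center axes), and matrices
#'   `count, density, speeding, turning` (front along rows)
#' @export
force_map <- function(traj, params, extent = 5, cell = 0.25,
                      min_count = 20, subtract_self = FALSE) {
  smp <- force_samples(traj, params, subtract_self)
  edges <- seq(-extent, extent, by = cell)
  mids <- edges[-1] - cell / 2
  nbin <- length(mids)
  ifb <- findInterval(smp$front, edges, rightmost.closed = TRUE)
  ilr <- findInterval(smp$left, edges, rightmost.closed = TRUE)
  ok <- ifb >= 1 & ifb <= nbin & ilr >= 1 & ilr <= nbin
  cnt <- sp <- tu <- matrix(0, nbin, nbin)
  idx <- cbind(ifb[ok], ilr[ok])
  for (k in which(ok)) {
    i <- ifb[k]; j <- ilr[k]
    cnt[i, j] <- cnt[i, j] + 1
    sp[i, j] <- sp[i, j] + smp$f_speed[k]
    tu[i, j] <- tu[i, j] + smp$f_turn[k]
  }
  mask <- cnt >= min_count
  sp <- ifelse(mask, sp / pmax(cnt, 1), NA_real_)
  tu <- ifelse(mask, tu / pmax(cnt, 1), NA_real_)
  dens <- cnt / sum(cnt) / cell^2
  list(front = mids, left = mids, count = cnt, density = dens,
       speeding = sp, turning = tu)
}

# per-sample force decomposition and neighbor relative coordinates;
# neighbors = all agents other than the focal (id 1 by convention of the
# two/three-agent runs)
force_samples <- function(traj, params, subtract_self = FALSE) {
  tt <- traj_times(traj)
  stopifnot(length(tt) >= 3)
  dtr <- diff(tt[1:2])
  ids <- unique(traj$id)
  foc_id <- ids[1]
  foc <- traj[traj$id == foc_id, ]
  vx <- foc$v * cos(foc$theta)
  vy <- foc$v * sin(foc$theta)
  m <- nrow(foc)
  k <- 2:(m - 1)
  ax <- (vx[k + 1] - vx[k - 1]) / (2 * dtr)
  ay <- (vy[k + 1] - vy[k - 1]) / (2 * dtr)
  ex <- cos(foc$theta[k]); ey <- sin(foc$theta[k])
  f_speed <- ax * ex + ay * ey
  if (subtract_self)
    f_speed <- f_speed - params$drag * (params$v0^2 - foc$v[k]^2)
  f_turn <- -ax * ey + ay * ex
  out <- NULL
  for (nid in ids[-1]) {
    nb <- traj[traj$id == nid, ]
    rx <- nb$x[k] - foc$x[k]
    ry <- nb$y[k] - foc$y[k]
    out <- rbind(out, data.frame(
      t = foc$t[k], neighbor = nid,
      front = rx * ex + ry * ey, left = -rx * ey + ry * ex,
      f_speed = f_speed, f_turn = f_turn))
  }
  out
}

#' Three-body force map over the neighbors' front-back positions
#'
#' For a three-agent run, bins the total measured speeding force over the
#' two neighbors' front-back coordinates (both orderings accumulated,
#' making the map symmetric), together with the normalized number
#' density.  The difference force subtracts, sample by sample, the
#' position-matched mean pairwise speeding forces looked up in a pairwise
#' map from a dedicated two-agent run; samples falling in unmeasured
#' pairwise cells are dropped.
#'
#' @param traj a `school_traj` of exactly three interacting agents
#' @param pair_map a pairwise [force_map()] (same `params`), used for the
#'   position-matched subtraction
#' @param params a [model_params()] object
#' @param extent,cell,min_count as in [force_map()]
#' @return a list with `front` (axis), matrices `count, density,
#'   speeding, difference` over (front_1, front_2)
#' @export
three_body_map <- function(traj, pair_map, params, extent = 5, cell = 0.25,
                           min_count = 20) {
  smp <- force_samples(traj, params)
  ids <- unique(smp$neighbor)
  stopifnot(length(ids) == 2)
  a <- smp[smp$neighbor == ids[1], ]
  b <- smp[smp$neighbor == ids[2], ]
  stopifnot(nrow(a) == nrow(b))
  lookup <- function(fr, lf) {
    edges <- c(pair_map$front - (pair_map$front[2] - pair_map$front[1]) / 2,
               max(pair_map$front) + (pair_map$front[2] - pair_map$front[1]) / 2)
    i <- findInterval(fr, edges, rightmost.closed = TRUE)
    j <- findInterval(lf, edges, rightmost.closed = TRUE)
    ok <- i >= 1 & i <= length(pair_map$front) &
      j >= 1 & j <= length(pair_map$front)
    val <- rep(NA_real_, length(fr))
    val[ok] <- pair_map$speeding[cbind(i[ok], j[ok])]
    val
  }
  pred <- lookup(a$front, a$left) + lookup(b$front, b$left)
  edges <- seq(-extent, extent, by = cell)
  mids <- edges[-1] - cell / 2
  nbin <- length(mids)
  cnt <- tot <- dif <- difn <- matrix(0, nbin, nbin)
  bin2 <- function(f1, f2, w, M) {
    i <- findInterval(f1, edges, rightmost.closed = TRUE)
    j <- findInterval(f2, edges, rightmost.closed = TRUE)
    ok <- i >= 1 & i <= nbin & j >= 1 & j <= nbin & !is.na(w)
    for (k in which(ok)) M[i[k], j[k]] <- M[i[k], j[k]] + w[k]
    M
  }
  one <- rep(1, nrow(a))
  # both orderings: (front_1, front_2) and (front_2, front_1)
  cnt <- bin2(a$front, b$front, one, cnt)
  cnt <- bin2(b$front, a$front, one, cnt)
  tot <- bin2(a$front, b$front, a$f_speed, tot)
  tot <- bin2(b$front, a$front, a$f_speed, tot)
  dd <- a$f_speed - pred
  dif <- bin2(a$front, b$front, dd, dif)
  dif <- bin2(b$front, a$front, dd, dif)
  dok <- as.numeric(!is.na(dd))
  difn <- bin2(a$front, b$front, dok, difn)
  difn <- bin2(b$front, a$front, dok, difn)
  mask <- cnt >= min_count
  list(front = mids, count = cnt, density = cnt / sum(cnt) / cell^2,
       speeding = ifelse(mask, tot / pmax(cnt, 1), NA_real_),
       difference = ifelse(difn >= min_count, dif / pmax(difn, 1), NA_real_))
}
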