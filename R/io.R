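#' Load a structured configuration file
#'
#' Reads a YAML configuration with up to three sections: `params` (any
#' subset of the [model_params()] fields), `scenario` (agent count,
#' seeding radius, duration, time step, seed, recording decimation) and
#' `experiment` (grid specification, see [run_experiment()]).  Unknown
#' keys are rejected with an error naming the key (note the key
#' `n_agents`, not `n`, which YAML would read as a boolean); missing keys
#' take the
#' documented defaults; parameter invariants (e.g. `rho_e < re`) are
#' enforced by the [model_params()] validator.
#'
#' @param path path to a YAML file; an empty file yields all defaults
#' @return a list with elements `params` (`school_params`), `scenario`,
#'   and `experiment` (possibly `NULL`)
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) raw <- list()   # empty file: all defaults
  bad <- setdiff(names(raw), c("params", "scenario", "experiment"))
  if (length(bad))
    stop("unknown top-level key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pdef <- formals(model_params)
  bad <- setdiff(names(raw$params), names(pdef))
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_params, as.list(raw$params))
  sdef <- list(n_agents = 100L, init_radius = 7, t_end = 300, dt = 0.01,
               seed = 1L, record_every = 50L)
  bad <- setdiff(names(raw$scenario), names(sdef))
  if (length(bad))
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  scenario <- modifyList(sdef, as.list(raw$scenario))
  if (scenario$n_agents < 1 || scenario$t_end <= 0 || scenario$dt <= 0)
    stop("scenario requires n_agents >= 1, t_end > 0, dt > 0",
         call. = FALSE)
  experiment <- raw$experiment
  if (!is.null(experiment)) experiment <- normalize_experiment(experiment)
  list(params = params, scenario = scenario, experiment = experiment)
}

experiment_fields <- c("kind", "chi_grid", "omega_grid", "L_grid",
                       "n_virtual", "L_asym", "replicates", "base_seed",
                       "output_dir", "burn_in", "t_end", "baseline")

normalize_experiment <- function(e) {
  bad <- setdiff(names(e), experiment_fields)
  if (length(bad))
    stop("unknown experiment key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  kinds <- c("collective", "assay", "baseline", "phase_scan", "L_scan",
             "force_map_run")
  if (is.null(e$kind) || !e$kind %in% kinds)
    stop("experiment kind must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  def <- list(n_virtual = 2L, L_asym = 0, replicates = 1L, base_seed = 1L,
              burn_in = 50, t_end = 300, baseline = FALSE)
  e <- modifyList(def, e)
  for (g in c("chi_grid", "omega_grid", "L_grid"))
    if (!is.null(e[[g]]) && !length(e[[g]]))
      stop(g, " must be non-empty", call. = FALSE)
  e
}

#' Write a configuration back to YAML
#'
#' Round-trip companion of [load_config()]: `load_config(save_config(x))`
#' reproduces the normalized configuration.
#'
#' @param config a list as returned by [load_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  p <- unclass(config$params)
  p$delta0 <- NULL                      # derived, not a free key
  yaml::write_yaml(list(params = p, scenario = config$scenario,
                        experiment = config$experiment), path)
  invisible(path)
}

#' Trajectory text interchange format
#'
#' Trajectories travel as delimited tabular text with the fixed column
#' order `t, id, x, y, v, theta, phi, virtual` (angles in radians,
#' positions in BL), plus a YAML sidecar `<path>.yaml` holding the run
#' configuration so the run can be reproduced.
#'
#' @param traj a `school_traj`
#' @param path output path (tab-separated text)
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[, c("t", "id", "x", "y", "v", "theta", "phi",
                                "virtual")]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- attr(traj, "config")
  if (!is.null(cfg)) {
    p <- unclass(cfg$params)
    p$delta0 <- NULL
    yaml::write_yaml(list(params = p,
                          run = cfg[setdiff(names(cfg), "params")]),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    raw <- yaml::read_yaml(side)
    cfg <- raw$run
    cfg$params <- do.call(model_params, raw$params)
    attr(df, "config") <- cfg
  }
  class(df) <- c("school_traj", "data.frame")
  df
}

#' Deterministic replicate seeds
#'
#' Derives the seed of one grid cell/replicate from the base seed by a
#' fixed integer hash, so an experiment is reproducible cell by cell and
#' two cells never share a noise stream.
#'
#' @param base base seed (integer)
#' @param cell grid-cell index (integer)
#' @param replicate replicate index (integer)
#' @return a positive integer seed below 2^31
#' @export
derive_seed <- function(base, cell, replicate = 1) {
  (((base %% 1e6) * 131071 + cell * 8191 + replicate * 127) %%
     2147483629) + 1
}

#' Run a gridded experiment
#'
#' Executes an experiment specification (see [load_config()]): a
#' collective run, an assay, a phase-diagram grid over `(chi, omega_o)`,
#' an `L` scan of the virtual-agent assay, or a dedicated force-map run.
#' Per-cell seeds come from [derive_seed()]; summary tables are written
#' as tab-separated text in `output_dir` together with a manifest
#' recording the configuration and seeds.  Failures of individual cells
#' are caught, logged in the summary, and do not stop the grid.
#'
#' @param config a configuration list from [load_config()] with a
#'   non-`NULL` `experiment` section
#' @param output_dir output directory (overrides the experiment field)
#' @return the summary `data.frame`, invisibly; written files as a side
#'   effect
#' @export
run_experiment <- function(config, output_dir = NULL) {
  e <- config$experiment
  stopifnot(!is.null(e))
  if (is.null(output_dir)) output_dir <- e$output_dir
  stopifnot(!is.null(output_dir))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  sc <- config$scenario
  rows <- list()
  cell <- 0L
  run_one <- function(fun) {
    tryCatch(fun(), error = function(err)
      list(error = conditionMessage(err)))
  }
  if (e$kind %in% c("collective", "phase_scan")) {
    chi_grid <- if (is.null(e$chi_grid)) p$chi else e$chi_grid
    om_grid <- if (is.null(e$omega_grid)) p$omega_o else e$omega_grid
    for (chi in chi_grid) for (om in om_grid) {
      cell <- cell + 1L
      for (rep_i in seq_len(e$replicates)) {
        seed <- derive_seed(e$base_seed, cell, rep_i)
        pr <- modifyList(p, list(chi = chi, omega_o = om))
        class(pr) <- "school_params"
        res <- run_one(function() {
          tr <- run_collective(pr, n = sc$n_agents,
                               init_radius = sc$init_radius,
                               t_end = e$t_end, dt = sc$dt, seed = seed,
                               record_every = sc$record_every)
          os <- order_series(tr)
          lab <- classify_pattern(os, burn_in = e$burn_in)
          s <- os[os$t >= e$burn_in, ]
          list(P = mean(s$P), M = mean(s$M), label = lab)
        })
        rows[[length(rows) + 1]] <- data.frame(
          chi = chi, omega_o = om, replicate = rep_i, seed = seed,
          P = if (is.null(res$error)) res$P else NA,
          M = if (is.null(res$error)) res$M else NA,
          label = if (is.null(res$error)) res$label else "error",
          error = if (is.null(res$error)) "" else res$error)
      }
    }
    summary_file <- "phase_summary.tsv"
  } else if (e$kind %in% c("assay", "baseline", "L_scan")) {
    L_grid <- if (is.null(e$L_grid)) stop("L_grid required") else e$L_grid
    base <- e$baseline || e$kind == "baseline"
    for (L in L_grid) {
      cell <- cell + 1L
      xs <- c()
      for (rep_i in seq_len(e$replicates)) {
        seed <- derive_seed(e$base_seed, cell, rep_i)
        tr <- run_virtual_assay(p, L = L, n_virtual = e$n_virtual,
                                L_asym = e$L_asym, t_end = e$t_end,
                                dt = sc$dt, seed = seed, baseline = base)
        cf <- comoving_focal(tr)
        xs <- c(xs, cf$x[cf$t >= e$burn_in])
      }
      dist <- marginal_distribution(xs)
      modes <- find_modes(dist)
      write.table(dist, file.path(output_dir,
                                  sprintf("marginal_L%.2f.tsv", L)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        L = L, n_modes = length(modes),
        modes = paste(round(modes, 3), collapse = ","),
        n_samples = attr(dist, "n"), error = "")
    }
    summary_file <- "assay_summary.tsv"
  } else if (e$kind == "force_map_run") {
    seed <- derive_seed(e$base_seed, 1L, 1L)
    st <- agent_states(x = c(0, 1.5), y = c(0, 1.5), v = p$v0,
                       theta = c(pi / 2, pi / 2), phi = 0)
    tr <- simulate_school(st, p, t_end = e$t_end, dt = sc$dt, seed = seed,
                          record_every = 5L)
    fm <- force_map(tr, p)
    dens <- data.frame(front = rep(fm$front, times = length(fm$left)),
                       left = rep(fm$left, each = length(fm$front)),
                       count = as.vector(fm$count),
                       density = as.vector(fm$density),
                       speeding = as.vector(fm$speeding),
                       turning = as.vector(fm$turning))
    write.table(dens, file.path(output_dir, "force_map.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    rows[[1]] <- data.frame(kind = "force_map_run", seed = seed,
                            n_samples = sum(fm$count), error = "")
    summary_file <- "force_map_summary.tsv"
  }
  summary <- do.call(rbind, rows)
  write.table(summary, file.path(output_dir, summary_file), sep = "\t",
              row.names = FALSE, quote = FALSE)
  save_config(config, file.path(output_dir, "manifest.yaml"))
  invisible(summary)
}
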