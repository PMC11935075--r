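#' Default hierarchical run configuration
#'
#' One YAML document drives the whole pipeline; CLI flags override config
#' keys, and all randomness flows from the single root `seed` through
#' deterministic per-run substreams.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = "egressr_out",
    log_level = "info",
    system = list(n_subunits = 16, open = FALSE, ring_radius = 15,
                  n_tail_beads = 12, well_depth = 3),
    dynamics = list(temperature = 300, friction = 1, timestep = 0.001),
    ramd = list(accel = 0.4, threshold_d = 0.4, force_group = "tail",
                eval_window = 100, event_window = 10, md_relax_steps = 400,
                steps_per_ns = 1e6),
    campaign = list(accelerations = c(0.3, 0.35, 0.4, 0.45, 0.5),
                    thresholds_d = c(0.3, 0.4, 0.5), snapshots = 3,
                    modes = c("head", "tail")),
    umbrella = list(n_windows = 8, spring_k = 10, from = 2, to = 20,
                    production_time = 6),
    wham = list(bin_width = 0.2, tolerance = 1e-7, max_iter = 1e5,
                temperature = 300),
    permeability = list(bulk = "upper", temperature = 300),
    interactions = list(hbond_dist = 3.5, hbond_angle = 150,
                        pistack_dist = 5.5, pistack_angle = 30)
  )
}

#' Load and validate a run configuration
#'
#' Unknown keys (at the top level or inside a known section) are rejected
#' with the offending key named.
#'
#' @param path YAML file (NULL gives the defaults)
#' @return validated configuration list
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check_keys <- function(given, known, where) {
    bad <- setdiff(names(given), known)
    if (length(bad)) {
      stop("invalid config: unknown key '", bad[1], "' in ", where)
    }
  }
  check_keys(user, names(cfg), "top level")
  for (sec in names(user)) {
    if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
      check_keys(user[[sec]], names(cfg[[sec]]), paste0("section '", sec, "'"))
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

write_provenance <- function(cfg, outdir, extra = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  yaml::write_yaml(cfg, tmp)
  prov <- c(list(
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("egressr")),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), extra)
  unlink(tmp)
  yaml::write_yaml(prov, file.path(outdir, "provenance.yaml"))
  invisible(prov)
}

cli_usage <- function() {
  paste(
    "usage: egressr <command> [--config FILE] [--out DIR] [options]",
    "",
    "commands:",
    "  build         build and serialize the toy system",
    "  simulate      unbiased Langevin run, writes an XYZ trajectory",
    "  ramd          one S-RaMD-MD egress run, writes event + phase logs",
    "  campaign      expand (and optionally run) the parameter campaign",
    "                  [--mode head|tail|both] [--snapshots N] [--dry-run]",
    "  channels      channel table from an event-log CSV [--events FILE]",
    "  umbrella      umbrella sampling on the toy system, writes windows",
    "  wham          WHAM on window files [--windows GLOB], writes pmf.tsv",
    "  permeability  P from pmf.tsv + diffusion constant [--pmf FILE --D X]",
    "  interactions  occupancy report on an XYZ/PDB trajectory [--traj FILE]",
    "  validate      check a config file",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(flags = character(0))
  i <- 1
  known <- c("--config", "--out", "--mode", "--snapshots", "--events",
             "--windows", "--pmf", "--D", "--traj", "--seed", "--n-steps")
  while (i <= length(argv)) {
    a <- argv[i]
    if (a %in% c("--dry-run", "--help")) {
      opts$flags <- c(opts$flags, a)
      i <- i + 1
    } else if (startsWith(a, "--")) {
      if (!(a %in% known)) stop("unknown flag: ", a)
      if (i == length(argv)) stop("flag ", a, " needs a value")
      opts[[sub("^--", "", a)]] <- argv[i + 1]
      i <- i + 2
    } else {
      stop("unexpected argument: ", a)
    }
  }
  opts
}

build_from_config <- function(cfg) {
  sysc <- cfg$system
  chain <- build_quinol_chain(n_tail_beads = sysc$n_tail_beads,
                              seed = cfg$seed)
  ring <- build_ring_system(n_subunits = sysc$n_subunits, open = sysc$open,
                            seed = cfg$seed, ring_radius = sysc$ring_radius,
                            well_depth = sysc$well_depth)
  make_system(chain, ring)
}

#' Command-line dispatcher
#'
#' Executes one pipeline stage and returns an exit status: 0 on success,
#' 2 on configuration/usage errors, 3 on runtime or numerical failure.
#' `--dry-run` prints the resolved plan without executing.  A provenance
#' block (config hash, package version, seed) is written next to every
#' output set.
#'
#' @param argv character vector of command-line arguments (first element:
#'   the subcommand)
#' @return integer exit status
#' @export
cli_dispatch <- function(argv) {
  if (!length(argv) || argv[1] %in% c("--help", "help")) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  cmd <- argv[1]
  commands <- c("build", "simulate", "ramd", "campaign", "channels",
                "umbrella", "wham", "permeability", "interactions",
                "validate")
  if (!(cmd %in% commands)) {
    message("unknown command: ", cmd, "\n", cli_usage())
    return(2L)
  }
  opts <- tryCatch(parse_cli_args(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", cli_usage())
    return(2L)
  }
  cfg <- tryCatch(load_run_config(opts$config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(2L)
  }
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  outdir <- opts$out %||% cfg$output_dir
  dry <- "--dry-run" %in% opts$flags

  status <- tryCatch({
    switch(cmd,
      validate = {
        cat("config OK (seed ", cfg$seed, ")\n", sep = "")
        0L
      },
      build = {
        system <- build_from_config(cfg)
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        traj <- make_trajectory(list(system$positions), times = 0)
        write_xyz(traj, file.path(outdir, "system.xyz"))
        write_provenance(cfg, outdir)
        cat("wrote", file.path(outdir, "system.xyz"), "\n")
        0L
      },
      simulate = {
        system <- build_from_config(cfg)
        dyn <- cfg$dynamics
        params <- langevin_params(dyn$temperature, dyn$friction,
                                  dyn$timestep, seed = cfg$seed)
        n_steps <- as.numeric(opts$`n-steps` %||% 10000)
        traj <- run_md(system, params, n_steps,
                       stride = max(1, n_steps %/% 100))
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_xyz(traj, file.path(outdir, "trajectory.xyz"))
        write_provenance(cfg, outdir)
        cat("wrote", file.path(outdir, "trajectory.xyz"), "\n")
        0L
      },
      ramd = {
        system <- build_from_config(cfg)
        dyn <- cfg$dynamics
        params <- langevin_params(dyn$temperature, dyn$friction,
                                  dyn$timestep, seed = cfg$seed)
        rc <- cfg$ramd
        rcfg <- ramd_config(accel = rc$accel, threshold_d = rc$threshold_d,
                            force_group = rc$force_group,
                            eval_window = rc$eval_window,
                            event_window = rc$event_window,
                            md_relax_steps = rc$md_relax_steps,
                            steps_per_ns = rc$steps_per_ns,
                            seed = cfg$seed)
        res <- s_ramd_md_run(system, rcfg, params)
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_event_log(list(res$event), file.path(outdir, "events.csv"))
        write_phase_log(res$phase_log, file.path(outdir, "phases.csv"))
        write_provenance(cfg, outdir)
        cat("event:", if (res$event$occurred) {
          paste0(res$event$pore_id, " at ", signif(res$event$time, 4), " ns")
        } else "undissociated", "\n")
        0L
      },
      campaign = {
        cc <- cfg$campaign
        modes <- switch(opts$mode %||% "both",
                        both = c("head", "tail"), head = "head",
                        tail = "tail",
                        stop("invalid config: --mode must be head, tail ",
                             "or both"))
        snaps <- seq_len(as.integer(opts$snapshots %||% cc$snapshots))
        plan <- plan_campaign(accelerations = cc$accelerations,
                              thresholds_d = cc$thresholds_d,
                              snapshots = snaps, modes = modes,
                              event_window = cfg$ramd$event_window,
                              base_seed = cfg$seed,
                              steps_per_ns = cfg$ramd$steps_per_ns)
        cat(nrow(plan$runs), "planned runs (", plan$planned_ns,
            "engine-ns )\n")
        print(utils::head(plan$runs, 15))
        if (nrow(plan$runs) > 15) cat("... (", nrow(plan$runs) - 15,
                                      "more )\n")
        if (!dry) {
          system <- build_from_config(cfg)
          dyn <- cfg$dynamics
          params <- langevin_params(dyn$temperature, dyn$friction,
                                    dyn$timestep, seed = cfg$seed)
          res <- run_campaign(plan, system, params)
          dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
          write.table(res$table, file.path(outdir, "events.csv"), sep = ",",
                      row.names = FALSE, quote = FALSE)
          tab <- tryCatch(channel_probabilities(res$events),
                          error = function(e) NULL)
          if (!is.null(tab)) {
            write_channel_table(tab, file.path(outdir, "channels.tsv"))
          }
          write_provenance(cfg, outdir)
          cat("wrote", file.path(outdir, "events.csv"), "\n")
        }
        0L
      },
      channels = {
        if (is.null(opts$events)) {
          stop("invalid config: channels needs --events FILE")
        }
        d <- read.table(opts$events, sep = ",", header = TRUE,
                        stringsAsFactors = FALSE)
        d <- d[d$occurred %in% c(TRUE, "TRUE"), ]
        counts <- aggregate(run_id ~ mode + pore_id, d, length)
        names(counts) <- c("mode", "channel", "count")
        tab <- channel_table(counts)
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_channel_table(tab, file.path(outdir, "channels.tsv"))
        print(tab)
        0L
      },
      umbrella = {
        system <- build_from_config(cfg)
        dyn <- cfg$dynamics
        params <- langevin_params(dyn$temperature, dyn$friction,
                                  dyn$timestep, seed = cfg$seed)
        u <- cfg$umbrella
        windows <- umbrella_ladder(u$from, u$to, u$n_windows, u$spring_k,
                                   production_time = u$production_time)
        windows <- run_umbrella(system, windows, params,
                                steps_per_ns = cfg$ramd$steps_per_ns)
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (i in seq_along(windows)) {
          write_window(windows[[i]],
                       file.path(outdir, sprintf("window_%02d.txt", i)),
                       temperature = dyn$temperature)
        }
        write_provenance(cfg, outdir)
        cat("wrote", length(windows), "window files to", outdir, "\n")
        0L
      },
      wham = {
        pat <- opts$windows %||% file.path(outdir, "window_*.txt")
        files <- Sys.glob(pat)
        if (!length(files)) stop("invalid config: no window files match ",
                                 pat)
        windows <- lapply(files, read_window)
        ord <- order(vapply(windows, `[[`, 0, "center"))
        windows <- windows[ord]
        w <- cfg$wham
        prof <- wham_solve(windows,
                           wham_config(bin_width = w$bin_width,
                                       tolerance = w$tolerance,
                                       max_iter = w$max_iter,
                                       temperature = w$temperature))
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_pmf(prof, file.path(outdir, "pmf.tsv"))
        cat("wrote", file.path(outdir, "pmf.tsv"), "( barrier",
            signif(barrier_height(prof), 4), "kcal/mol )\n")
        0L
      },
      permeability = {
        if (is.null(opts$pmf)) {
          stop("invalid config: permeability needs --pmf FILE")
        }
        prof <- read_pmf(opts$pmf)
        d <- as.numeric(opts$D %||% 100)
        p <- permeability(prof, d, bulk = cfg$permeability$bulk,
                          temperature = cfg$permeability$temperature)
        cat(sprintf("permeability: %.6g cm/s (D = %g A^2/ns)\n", p, d))
        0L
      },
      interactions = {
        if (is.null(opts$traj)) {
          stop("invalid config: interactions needs --traj FILE")
        }
        traj <- if (grepl("\\.pdb$", opts$traj)) {
          read_pdb_traj(opts$traj)
        } else read_xyz(opts$traj)
        ic <- cfg$interactions
        labs <- unique(traj$labels)
        spec <- interaction_spec(hbond = list(
          donors = labs[1], acceptors = labs[min(2, length(labs))],
          dist_cutoff = ic$hbond_dist, angle_cutoff = ic$hbond_angle))
        series <- occupancy_series(traj, spec)
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_occupancy(series, file.path(outdir, "occupancy_flags.csv"),
                        file.path(outdir, "occupancy_summary.csv"))
        print(series)
        0L
      })
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("invalid config|invalid argument|unknown|parse error", msg)) {
      2L
    } else 3L
  })
  status
}

#' Write-then-read round trip for package objects
#'
#' Serialises an object to its canonical plain-text format and reads it
#' back: channel tables and PMF profiles as TSV, umbrella windows as
#' two-column text, trajectories as XYZ, configurations as YAML.
#'
#' @param path file path to use
#' @param object a supported object
#' @return the re-read object
#' @export
round_trip <- function(path, object) {
  if (inherits(object, "channel_table")) {
    write_channel_table(object, path)
    read_channel_table(path)
  } else if (inherits(object, "pmf_profile")) {
    write_pmf(object, path)
    read_pmf(path)
  } else if (inherits(object, "umbrella_window")) {
    write_window(object, path)
    read_window(path)
  } else if (inherits(object, "egress_trajectory")) {
    write_xyz(object, path)
    read_xyz(path)
  } else if (is.list(object)) {
    yaml::write_yaml(object, path)
    yaml::read_yaml(path)
  } else {
    stop("invalid argument: unsupported object class '",
         class(object)[1], "'")
  }
}
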