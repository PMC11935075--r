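#' S-RaMD-MD controller configuration
#'
#' Control parameters for self-referenced random-acceleration MD: a constant
#' force of magnitude `accel * m_group` is applied to the ligand's head ring
#' or tail tip along a random direction; progress of the force group is
#' evaluated every `eval_window` steps against the stall threshold
#' `threshold_d`, and the direction is redrawn on a stall.  The reference
#' site is the ligand's own centre of mass, and `com_threshold_D` must
#' exceed the ligand length: the force group can therefore never terminate
#' the force by distance, which keeps the bias permanently active and drives
#' the chosen end persistently away from the molecular centre.  Biased
#' phases alternate with `md_relax_steps` of unbiased relaxation;
#' `md_relax_steps = 0` gives the pure RaMD limit.
#'
#' Durations are expressed in engine nanoseconds and converted to steps
#' through the single `steps_per_ns` constant (default 1e6 steps at the
#' 0.001 ps timestep); toy-system kinetics are not atomistic kinetics, so
#' studies pick the mapping that suits their system.
#'
#' @param accel acceleration `a`, kcal A^-1 g^-1; default grid in campaigns
#'   is {0.3, 0.35, 0.4, 0.45, 0.5}.
#' @param threshold_d stall threshold `d`, Angstrom (grid {0.3, 0.4, 0.5}).
#' @param com_threshold_D self-COM distance bound `D`, Angstrom; must exceed
#'   the ligand length (validated when a chain is available; default
#'   1.25 x chain length).
#' @param force_group "head" (head ring) or "tail" (tail tip).
#' @param eval_window steps between stall evaluations.
#' @param event_window engine-ns after which an unfinished run is declared
#'   undissociated (default 10).
#' @param md_relax_steps unbiased relaxation steps between biased windows.
#' @param steps_per_ns engine steps per engine-ns.
#' @param displacement_metric "radial" (change of the force-group-COM to
#'   ligand-COM distance over the window) or "absolute" (full 3D group-COM
#'   displacement).
#' @param seed integer seed for directions, noise and initial velocities.
#' @return an object of class `ramd_config`
#' @export
ramd_config <- function(accel = 0.4, threshold_d = 0.4,
                        com_threshold_D = NULL,
                        force_group = c("tail", "head"),
                        eval_window = 100, event_window = 10,
                        md_relax_steps = 400, steps_per_ns = 1e6,
                        displacement_metric = c("radial", "absolute"),
                        seed = 1) {
  force_group <- match.arg(force_group)
  displacement_metric <- match.arg(displacement_metric)
  if (accel <= 0) stop("invalid argument: accel must be > 0")
  if (threshold_d <= 0) stop("invalid argument: threshold_d must be > 0")
  if (eval_window < 1) stop("invalid argument: eval_window must be >= 1")
  if (md_relax_steps < 0) stop("invalid argument: md_relax_steps >= 0")
  structure(list(accel = accel, threshold_d = threshold_d,
                 com_threshold_D = com_threshold_D,
                 force_group = force_group, eval_window = eval_window,
                 event_window = event_window,
                 md_relax_steps = md_relax_steps,
                 steps_per_ns = steps_per_ns,
                 displacement_metric = displacement_metric,
                 seed = as.integer(seed)),
            class = "ramd_config")
}

resolve_force_group <- function(chain, force_group) {
  switch(force_group, head = chain$head_ring, tail = chain$tail_tip)
}

validate_ramd_against_chain <- function(ramd, chain) {
  D <- ramd$com_threshold_D %||% (1.25 * chain$chain_length)
  if (D <= chain$chain_length) {
    stop("invalid argument: com_threshold_D (", D,
         ") must exceed the ligand length (",
         round(chain$chain_length, 2), " A)")
  }
  D
}

#' Random-acceleration force on a bead group
#'
#' The total force is `a * m_group` along `direction`, distributed over the
#' group beads proportionally to bead mass (i.e. a uniform acceleration of
#' the group).
#'
#' @param group_mass bead masses of the group (amu); a scalar is treated as
#'   the total group mass carried by one bead
#' @param a acceleration, kcal A^-1 g^-1
#' @param direction unit 3-vector
#' @return a matrix of per-bead forces (kcal/mol/A) with attribute `total`
#'   (the summed force vector, magnitude `a * sum(group_mass)`)
#' @export
ramd_force <- function(group_mass, a, direction) {
  if (a <= 0) stop("invalid argument: a must be > 0")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    stop("invalid argument: direction must be a unit vector (|v| = ",
         format(nrm), ")")
  }
  per_bead <- outer(a * group_mass, direction)
  attr(per_bead, "total") <- a * sum(group_mass) * direction
  per_bead
}

#' Draw a direction uniformly on the unit sphere
#'
#' Normalised 3D Gaussian draw; uses the current R RNG stream.
#'
#' @return unit 3-vector
#' @export
random_unit_direction <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Stall test and direction update
#'
#' When the force group's progress over the last evaluation window fell
#' below the threshold `d`, a fresh direction is drawn uniformly on the unit
#' sphere; otherwise the current direction is kept.  The decision is
#' appended to the phase log.
#'
#' @param log a `ramd_phase_log` data.frame (or NULL to start one)
#' @param displacement progress measured over the elapsed window, Angstrom
#'   (may be negative under the radial metric when the group moved inward)
#' @param d stall threshold, Angstrom
#' @param direction current unit direction
#' @param phase "ramd" or "md"
#' @return list(direction, redrawn, log)
#' @export
update_direction <- function(log, displacement, d, direction,
                             phase = "ramd") {
  redrawn <- displacement < d
  new_dir <- if (redrawn) random_unit_direction() else direction
  row <- data.frame(window = if (is.null(log)) 0L else nrow(log),
                    phase = phase, displacement = displacement,
                    redrawn = redrawn, dir_x = direction[1],
                    dir_y = direction[2], dir_z = direction[3])
  log <- if (is.null(log)) row else rbind(log, row)
  class(log) <- c("ramd_phase_log", "data.frame")
  list(direction = new_dir, redrawn = redrawn, log = log)
}

#' Run one S-RaMD-MD egress simulation
#'
#' Alternates random-acceleration phases (constant force `a * m_group` on
#' the head ring or tail tip along a managed random direction) with unbiased
#' relaxation phases, under membrane-boundary walls.  Progress is evaluated
#' at every phase boundary and the direction redrawn on stalls.  The run
#' terminates at the first dissociation event (the mid-tail centre of mass
#' crossing the subunit ring radius while inside the slab) or when the event
#' window expires.
#'
#' @param system a `toy_system` built with a ring
#' @param ramd a `ramd_config`
#' @param md_params a `langevin_params` (its seed is superseded by the
#'   config seed so one integer controls the whole run)
#' @param stride steps between saved trajectory frames
#' @return list with elements `trajectory` (an `egress_trajectory`),
#'   `phase_log` (a `ramd_phase_log` data.frame) and `event`
#'   (a `dissociation_event`)
#' @export
s_ramd_md_run <- function(system, ramd, md_params, stride = 1000) {
  stopifnot(inherits(system, "toy_system"), inherits(ramd, "ramd_config"),
            inherits(md_params, "langevin_params"))
  if (is.null(system$ring)) {
    stop("invalid argument: s_ramd_md_run needs a system with a ring")
  }
  chain <- system$chain
  validate_ramd_against_chain(ramd, chain)
  group <- resolve_force_group(chain, ramd$force_group)

  set.seed(ramd$seed)
  vel <- maxwell_velocities(system$core$masses, md_params$temperature)
  max_steps <- round(ramd$event_window * ramd$steps_per_ns)

  res <- cpp_sramd_run(system$positions, vel, system$core,
                       md_params$timestep, md_params$friction,
                       kT_kcal(md_params$temperature),
                       as.integer(group), as.integer(chain$mid_tail),
                       ramd$accel, ramd$threshold_d,
                       as.numeric(ramd$eval_window),
                       as.numeric(ramd$md_relax_steps),
                       as.numeric(max_steps), as.numeric(stride),
                       system$ring$ring_radius,
                       if (ramd$displacement_metric == "radial") 0L else 1L)

  steps <- round(res$times / md_params$timestep)
  traj <- new_trajectory(res$frames, res$times, steps,
                         metadata = list(ramd = ramd, params = md_params,
                                         steps_per_ns = ramd$steps_per_ns))
  lg <- as.data.frame(res$log)
  names(lg) <- c("window", "phase", "displacement", "redrawn",
                 "dir_x", "dir_y", "dir_z")
  lg$phase <- c("ramd", "md")[lg$phase + 1]
  lg$redrawn <- lg$redrawn > 0
  class(lg) <- c("ramd_phase_log", "data.frame")

  event <- if (res$occurred) {
    exit <- as.numeric(res$exit)
    dissociation_event(TRUE, time = res$event_step / ramd$steps_per_ns,
                       exit_point = exit,
                       pore_id = assign_channel(exit, system$ring),
                       mode = ramd$force_group, config = ramd)
  } else {
    dissociation_event(FALSE, mode = ramd$force_group, config = ramd)
  }
  list(trajectory = traj, phase_log = lg, event = event)
}

#' Dissociation event record
#'
#' @param occurred did the ligand leave through the ring within the window?
#' @param time event time, engine-ns (NA when not occurred)
#' @param exit_point 3-vector, mid-tail COM at the crossing
#' @param pore_id channel label from [assign_channel()]
#' @param mode "head" or "tail"
#' @param config the `ramd_config` that produced the event
#' @return an object of class `dissociation_event`
#' @export
dissociation_event <- function(occurred, time = NA_real_, exit_point = NULL,
                               pore_id = NULL, mode = NA_character_,
                               config = NULL) {
  if (!occurred && (!is.null(exit_point) || !is.null(pore_id))) {
    stop("invalid argument: a non-event cannot carry an exit point or pore")
  }
  structure(list(occurred = occurred, time = time, exit_point = exit_point,
                 pore_id = pore_id, mode = mode, config = config),
            class = "dissociation_event")
}

#' @export
print.dissociation_event <- function(x, ...) {
  if (x$occurred) {
    cat("dissociation_event:", x$mode, "-first via", x$pore_id, "at t =",
        signif(x$time, 4), "ns\n")
  } else {
    cat("dissociation_event: undissociated (", x$mode, "-first )\n")
  }
  invisible(x)
}

#' Detect a ring-passage dissociation event in a trajectory
#'
#' The event is the first frame at which the mid-tail group's centre of mass
#' lies radially outside the subunit ring while its z stays inside the
#' membrane slab.  Leaving through the slab top or bottom is not a ring
#' passage and does not count.
#'
#' @param traj an `egress_trajectory`
#' @param system a `ring_system`
#' @param chain the `quinol_chain` defining `mid_tail`
#' @param window event window, engine-ns
#' @param steps_per_ns steps per engine-ns (default: trajectory metadata,
#'   else 1e6)
#' @return a `dissociation_event`
#' @export
detect_dissociation <- function(traj, system, chain, window = 10,
                                steps_per_ns = NULL) {
  stopifnot(inherits(system, "ring_system"), inherits(chain, "quinol_chain"))
  steps_per_ns <- steps_per_ns %||% traj$metadata$steps_per_ns %||% 1e6
  times_ns <- traj$steps / steps_per_ns
  mode <- traj$metadata$ramd$force_group %||% NA_character_
  for (f in seq_along(traj$frames)) {
    if (times_ns[f] > window) break
    com <- com_of(traj$frames[[f]], chain$masses, chain$mid_tail)
    rho <- sqrt(com[1]^2 + com[2]^2)
    inside_slab <- com[3] >= system$slab_z[1] && com[3] <= system$slab_z[2]
    if (rho > system$ring_radius && inside_slab) {
      return(dissociation_event(TRUE, time = times_ns[f], exit_point = com,
                                pore_id = assign_channel(com, system),
                                mode = mode))
    }
  }
  if (max(times_ns) < window) {
    warning("trajectory covers only ", signif(max(times_ns), 4),
            " of the ", window, " engine-ns event window")
  }
  dissociation_event(FALSE, mode = mode)
}

#' Write an event table as CSV
#'
#' Columns: run_id, mode, a, d, seed, snapshot_id, occurred, time_ns,
#' pore_id, exit_x, exit_y, exit_z.
#'
#' @param events list of `dissociation_event` objects
#' @param path output CSV
#' @param run_info optional data.frame with per-run columns (run_id,
#'   snapshot_id, ...) aligned with `events`
#' @return the event table invisibly
#' @export
write_event_log <- function(events, path, run_info = NULL) {
  tab <- events_to_table(events, run_info)
  write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(tab)
}

events_to_table <- function(events, run_info = NULL) {
  rows <- lapply(seq_along(events), function(i) {
    e <- events[[i]]
    cfg <- e$config
    data.frame(
      run_id = i, mode = e$mode,
      a = cfg$accel %||% NA_real_, d = cfg$threshold_d %||% NA_real_,
      seed = cfg$seed %||% NA_integer_,
      snapshot_id = NA_integer_,
      occurred = e$occurred, time_ns = e$time,
      pore_id = e$pore_id %||% NA_character_,
      exit_x = if (e$occurred) e$exit_point[1] else NA_real_,
      exit_y = if (e$occurred) e$exit_point[2] else NA_real_,
      exit_z = if (e$occurred) e$exit_point[3] else NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(run_info)) {
    for (cl in intersect(names(run_info), names(tab))) {
      tab[[cl]] <- run_info[[cl]]
    }
  }
  tab
}

#' Write a phase log as CSV
#'
#' @param log a `ramd_phase_log`
#' @param path output CSV
#' @export
write_phase_log <- function(log, path) {
  write.table(log, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(log)
}
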