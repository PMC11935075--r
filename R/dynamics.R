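#' Langevin dynamics parameters
#'
#' @param temperature bath temperature, K.
#' @param friction Langevin friction, ps^-1 (0 gives the NVE limit).
#' @param timestep integration timestep, ps.
#' @param seed integer seed for thermostat noise and velocity draws.
#' @return an object of class `langevin_params`
#' @export
langevin_params <- function(temperature = 300, friction = 1,
                            timestep = 0.001, seed = 1) {
  if (temperature <= 0) stop("invalid argument: temperature must be > 0")
  if (timestep <= 0) stop("invalid argument: timestep must be > 0")
  if (friction < 0) stop("invalid argument: friction must be >= 0")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, seed = as.integer(seed)),
            class = "langevin_params")
}

#' Assemble a simulatable toy system
#'
#' Combines a ligand chain and a ring system into one simulation object,
#' placing the chain so that its overall centre of mass sits at `at`
#' (default: the binding-well centre).
#'
#' @param chain a `quinol_chain`
#' @param ring a `ring_system` (optional; omit for a free chain)
#' @param at 3-vector, target position for the ligand centre of mass
#' @return an object of class `toy_system`
#' @export
make_system <- function(chain, ring = NULL, at = NULL) {
  stopifnot(inherits(chain, "quinol_chain"))
  if (!is.null(ring)) stopifnot(inherits(ring, "ring_system"))
  if (is.null(at)) at <- if (is.null(ring)) c(0, 0, 0) else ring$well_center
  pos <- chain$positions
  shift <- at - com_of(pos, chain$masses)
  pos <- sweep(pos, 2, -shift)

  sites <- if (is.null(ring)) matrix(0, 0, 2) else
    as.matrix(ring$subunits[, c("x", "y")])
  structure(list(
    chain = chain, ring = ring, positions = pos,
    core = list(
      masses = chain$masses,
      bonds = chain$bonds,
      angles = chain$angles %||% matrix(0, 0, 5),
      sites = unname(sites),
      site_eps = if (is.null(ring)) 0 else ring$site_eps,
      site_sigma = if (is.null(ring)) 1 else ring$site_sigma,
      well_center = if (is.null(ring)) c(0, 0, 0) else ring$well_center,
      well_depth = if (is.null(ring)) 0 else ring$well_depth,
      well_width = if (is.null(ring)) 1 else ring$well_width,
      z_lo = if (is.null(ring)) -Inf else ring$slab_z[1],
      z_hi = if (is.null(ring)) Inf else ring$slab_z[2],
      wall_k = if (is.null(ring)) 0 else ring$wall_k
    )
  ), class = "toy_system")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param masses bead masses, amu
#' @param temperature temperature, K
#' @return n x 3 matrix of velocities, A/ps
#' @export
maxwell_velocities <- function(masses, temperature) {
  sds <- sqrt(kT_kcal(temperature) * KCAL_INTERNAL / masses)
  matrix(rnorm(3 * length(masses)), ncol = 3) * sds
}

#' Flat-bottom membrane wall force
#'
#' Zero inside the slab; a linear restoring force `-wall_k * (z - boundary)`
#' outside (harmonic energy `1/2 k (z - boundary)^2`), continuous at both
#' boundaries.
#'
#' @param z z-coordinate(s), Angstrom
#' @param slab_z numeric(2), (z_lo, z_hi)
#' @param wall_k wall stiffness, kcal/mol/A^2
#' @return force in kcal/mol/A (vectorised over `z`)
#' @export
wall_force <- function(z, slab_z, wall_k) {
  if (slab_z[1] >= slab_z[2]) stop("invalid argument: slab_z must increase")
  f <- numeric(length(z))
  above <- z > slab_z[2]
  below <- z < slab_z[1]
  f[above] <- -wall_k * (z[above] - slab_z[2])
  f[below] <- -wall_k * (z[below] - slab_z[1])
  f
}

new_trajectory <- function(frames, times, steps, velocities = NULL,
                           labels = NULL, metadata = list()) {
  structure(list(frames = frames, times = times, steps = steps,
                 velocities = velocities, labels = labels,
                 metadata = metadata),
            class = "egress_trajectory")
}

#' Construct a trajectory object from frames
#'
#' @param frames list of n x 3 coordinate matrices
#' @param times frame times (ps); must be strictly increasing
#' @param steps integer step index of each frame (defaults to times / dt = 1)
#' @param labels optional bead labels (recycled as rownames for analysis)
#' @param metadata free-form provenance list
#' @return an `egress_trajectory`
#' @export
make_trajectory <- function(frames, times, steps = NULL, labels = NULL,
                            metadata = list()) {
  if (any(diff(times) <= 0)) {
    stop("invalid argument: frame times must be strictly increasing")
  }
  if (is.null(steps)) steps <- seq_along(times) - 1
  new_trajectory(frames, times, steps, labels = labels, metadata = metadata)
}

#' @export
print.egress_trajectory <- function(x, ...) {
  cat("egress_trajectory:", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "beads, t =", min(x$times), "..",
      max(x$times), "ps\n")
  invisible(x)
}

#' @export
length.egress_trajectory <- function(x) length(x$frames)

#' Run unbiased (or externally forced) Langevin dynamics
#'
#' Propagates a toy system with a BAOAB-splitting Langevin integrator.
#' Identical `(seed, configuration)` pairs give identical trajectories.
#'
#' @param system a `toy_system`
#' @param params a `langevin_params`
#' @param n_steps number of steps (>= 1)
#' @param stride steps between saved frames (>= 1)
#' @param state optional list(positions, velocities) overriding the default
#'   initial state (system positions + fresh Maxwell-Boltzmann velocities)
#' @param external_force optional constant per-bead force matrix (n x 3,
#'   kcal/mol/A), e.g. from [ramd_force()]
#' @param umbrella optional umbrella bias:
#'   list(group, anchor_x, anchor_y, k, center)
#' @return an `egress_trajectory`; `$metadata$xi` holds the biased reaction
#'   coordinate series when an umbrella is active, `$metadata$potential` the
#'   per-frame potential energy (kcal/mol)
#' @export
run_md <- function(system, params, n_steps, stride = 100, state = NULL,
                   external_force = NULL, umbrella = NULL) {
  stopifnot(inherits(system, "toy_system"), inherits(params, "langevin_params"))
  if (n_steps < 1) stop("invalid argument: n_steps must be >= 1")
  if (stride < 1) stop("invalid argument: stride must be >= 1")
  set.seed(params$seed)
  if (is.null(state)) {
    state <- list(positions = system$positions,
                  velocities = maxwell_velocities(system$core$masses,
                                                  params$temperature))
  }
  res <- cpp_run_md(state$positions, state$velocities, system$core,
                    params$timestep, params$friction,
                    kT_kcal(params$temperature),
                    as.numeric(n_steps), as.numeric(stride),
                    external_force, umbrella)
  steps <- round(res$times / params$timestep)
  new_trajectory(res$frames, res$times, steps, velocities = res$velocities,
                 metadata = list(params = params, xi = res$xi,
                                 potential = res$potential,
                                 final_pos = res$final_pos,
                                 final_vel = res$final_vel))
}

#' Advance a simulation state by one step
#'
#' Single-step interface around the same integrator as [run_md()], with a
#' per-step force callback: `external_force(state)` must return an n x 3
#' matrix of forces in kcal/mol/A (or NULL).
#'
#' @param state list(positions, velocities, time)
#' @param system a `toy_system`
#' @param params a `langevin_params`
#' @param external_force optional callback
#' @return the advanced state (time grows by one timestep)
#' @export
step_state <- function(state, system, params, external_force = NULL) {
  fext <- if (is.null(external_force)) NULL else external_force(state)
  if (!is.null(fext) && !all(is.finite(fext))) {
    stop("numerical failure: non-finite external force")
  }
  res <- cpp_run_md(state$positions, state$velocities, system$core,
                    params$timestep, params$friction,
                    kT_kcal(params$temperature), 1, 1, fext, NULL)
  list(positions = res$final_pos, velocities = res$final_vel,
       time = (state$time %||% 0) + params$timestep)
}

#' Potential energy of a configuration
#'
#' @param system a `toy_system`
#' @param positions n x 3 coordinates (default: the system's own)
#' @return potential energy, kcal/mol
#' @export
potential_energy <- function(system, positions = system$positions) {
  cpp_system_energy(positions, system$core)
}

#' Kinetic energy of a velocity set
#'
#' @param velocities n x 3, A/ps
#' @param masses amu
#' @return kinetic energy, kcal/mol
#' @export
kinetic_energy <- function(velocities, masses) {
  sum(0.5 * masses * rowSums(velocities^2)) / KCAL_INTERNAL
}

# ---- trajectory file formats ----------------------------------------------

#' Write a trajectory as multi-frame XYZ
#'
#' One block per frame; the element column carries the bead label.
#'
#' @param traj an `egress_trajectory`
#' @param path output file
#' @param labels bead labels (default "C1".."Cn")
#' @export
write_xyz <- function(traj, path, labels = NULL) {
  n <- nrow(traj$frames[[1]])
  labels <- labels %||% traj$labels %||% paste0("C", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d time_ps %.6f", f - 1, traj$times[f]), con)
    m <- traj$frames[[f]]
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, m[, 1], m[, 2], m[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz()] (or compatible)
#' @return an `egress_trajectory` with bead labels
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  labels <- NULL
  i <- 1
  f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("parse error: bad atom count at line ", i)
    f <- f + 1
    if (i + 1 + n > length(lines)) {
      stop("parse error: truncated XYZ file in frame ", f)
    }
    comment <- lines[i + 1]
    t <- suppressWarnings(
      as.numeric(sub(".*time_ps\\s+([-0-9.eE+]+).*", "\\1", comment)))
    if (is.na(t)) t <- f - 1
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    bad <- which(vapply(rows, length, 0L) < 4)
    if (length(bad)) {
      stop("parse error: malformed atom record in frame ", f,
           " at line ", i + 1 + bad[1])
    }
    lab <- vapply(rows, `[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("parse error: non-numeric coordinate in frame ", f)
    }
    if (is.null(labels)) labels <- lab
    frames[[f]] <- unname(xyz)
    times <- c(times, t)
    i <- i + 2 + n
  }
  if (!length(frames)) stop("parse error: no frames in ", path)
  new_trajectory(frames, times, steps = seq_along(frames) - 1,
                 labels = labels)
}

#' Write a trajectory as a minimal multi-MODEL PDB
#'
#' HETATM records; the occupancy column carries a numeric group id
#' (0 = untagged, 1 = head ring, 2 = mid tail, 3 = tail tip when a chain is
#' supplied).
#'
#' @param traj an `egress_trajectory`
#' @param path output file
#' @param chain optional `quinol_chain` used to tag the group id column
#' @export
write_pdb_traj <- function(traj, path, chain = NULL) {
  n <- nrow(traj$frames[[1]])
  group <- numeric(n)
  if (!is.null(chain)) {
    group[chain$head_ring] <- 1
    group[chain$mid_tail] <- 2
    group[chain$tail_tip] <- 3
  }
  labels <- traj$labels %||% paste0("C", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- traj$frames[[f]]
    writeLines(sprintf(
      "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n), substr(labels, 1, 4), m[, 1], m[, 2], m[, 3], group,
      0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a minimal multi-MODEL PDB trajectory
#'
#' @param path PDB file with HETATM/ATOM records in MODEL blocks
#' @return an `egress_trajectory`
#' @export
read_pdb_traj <- function(path) {
  lines <- readLines(path)
  frames <- list()
  labels <- NULL
  cur <- NULL
  cur_lab <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1, 6)
    if (tag %in% c("HETATM", "ATOM  ")) {
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (any(is.na(c(x, y, z)))) {
        stop("parse error: bad coordinates at line ", i)
      }
      cur <- rbind(cur, c(x, y, z))
      cur_lab <- c(cur_lab, trimws(substr(ln, 13, 16)))
    } else if (trimws(ln) == "ENDMDL") {
      frames[[length(frames) + 1]] <- unname(cur)
      if (is.null(labels)) labels <- cur_lab
      cur <- NULL
      cur_lab <- character(0)
    }
  }
  if (!is.null(cur) && nrow(cur) > 0) {
    frames[[length(frames) + 1]] <- unname(cur)
    if (is.null(labels)) labels <- cur_lab
  }
  if (!length(frames)) stop("parse error: no MODEL frames in ", path)
  new_trajectory(frames, times = seq_along(frames) - 1,
                 steps = seq_along(frames) - 1, labels = labels)
}
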