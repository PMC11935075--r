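#' Build a coarse-grained quinol-like bead chain
#'
#' Constructs the toy ligand: a six-bead hexagonal "aromatic" head ring with
#' a linear isoprenoid-like tail.  Three bead groups are labelled the way
#' egress analysis needs them: `head_ring` (the six ring beads), `tail_tip`
#' (the last six tail beads) and `mid_tail` (a five-bead window at the middle
#' of the tail, the group whose centre of mass defines a dissociation event).
#'
#' One bead stands for a small cluster of heavy atoms; the bonded model is
#' harmonic bonds plus harmonic angles only.  The maximum pairwise bead
#' distance of the as-built (straight) conformation is reported as
#' `chain_length`; the S-RaMD-MD distance bound `com_threshold_D` must
#' exceed it.
#'
#' The centred five-bead `mid_tail` window is shifted head-wards when it
#' would overlap `tail_tip`; disjointness is only achievable for
#' `n_tail_beads >= 11`, so 7..10 raise an error (the group-definition
#' contract cannot be honoured there).
#'
#' @param n_tail_beads number of tail beads (>= 7; see Details).
#' @param seed integer seed for the small coordinate jitter that breaks
#'   exact collinearity of the tail.
#' @param bond_length equilibrium bond length, Angstrom.
#' @param bead_mass bead mass, amu (default 12, carbon-like).
#' @param bond_k bond stiffness, kcal/mol/A^2 (energy = 1/2 k dx^2).
#' @param angle_k angle stiffness, kcal/mol/rad^2.
#' @return an object of class `quinol_chain`: positions (M x 3, Angstrom),
#'   masses (amu), bond and angle tables, the three index groups, and
#'   `chain_length`.
#' @export
build_quinol_chain <- function(n_tail_beads = 24, seed = 1,
                               bond_length = 1.5, bead_mass = 12,
                               bond_k = 50, angle_k = 5) {
  if (!is.numeric(n_tail_beads) || length(n_tail_beads) != 1 ||
      n_tail_beads < 7 || n_tail_beads != round(n_tail_beads)) {
    stop("invalid argument: n_tail_beads must be an integer >= 7")
  }
  n_tail <- as.integer(n_tail_beads)
  n <- 6L + n_tail

  # hexagonal head ring of side bond_length in the xy-plane
  ring_r <- bond_length
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)

  # linear tail along +x from ring bead 1, with a deterministic jitter so
  # tail angles are not exactly collinear at start
  set.seed(seed)
  jit <- matrix(runif(3 * n_tail, -0.05, 0.05), ncol = 3)
  tail_x <- ring_r + bond_length * seq_len(n_tail)
  tail <- cbind(tail_x, 0, 0) + jit
  pos <- rbind(ring, tail)

  # bonds: ring edges, three rigidifying ring diagonals, ring->tail, tail
  ring_edges <- cbind(1:6, c(2:6, 1), bond_length, bond_k)
  diag_len <- 2 * ring_r
  ring_diag <- cbind(1:3, 4:6, diag_len, bond_k)
  attach_b <- cbind(1, 7, bond_length, bond_k)
  tail_idx <- 7:(6 + n_tail)
  tail_b <- if (n_tail > 1) {
    cbind(tail_idx[-n_tail], tail_idx[-1], bond_length, bond_k)
  } else NULL
  bonds <- rbind(ring_edges, ring_diag, attach_b, tail_b)
  colnames(bonds) <- c("i", "j", "r0", "k")

  # straight-chain angles along the tail (and through the attachment)
  chain_path <- c(1L, tail_idx)
  angles <- if (length(chain_path) >= 3) {
    m <- length(chain_path)
    cbind(chain_path[1:(m - 2)], chain_path[2:(m - 1)], chain_path[3:m],
          pi, angle_k)
  } else NULL
  if (!is.null(angles)) colnames(angles) <- c("i", "j", "k", "theta0", "kang")

  head_ring <- 1:6
  tail_tip <- tail_idx[(n_tail - 5):n_tail]
  centre <- tail_idx[ceiling(n_tail / 2)]
  win <- (centre - 2):(centre + 2)
  max_allowed <- tail_idx[n_tail - 6]  # last tail bead before tail_tip
  if (max(win) > max_allowed) win <- win - (max(win) - max_allowed)
  if (min(win) < 7 || length(intersect(win, tail_tip)) > 0) {
    stop("invalid argument: mid_tail window cannot be made disjoint from ",
         "tail_tip for n_tail_beads = ", n_tail,
         " (need n_tail_beads >= 11)")
  }

  structure(list(
    positions = unname(pos),
    masses = rep(bead_mass, n),
    bonds = bonds,
    angles = angles,
    head_ring = head_ring,
    mid_tail = win,
    tail_tip = tail_tip,
    n_beads = n,
    n_tail_beads = n_tail,
    chain_length = max(stats::dist(pos)),
    seed = seed
  ), class = "quinol_chain")
}

#' @export
print.quinol_chain <- function(x, ...) {
  cat("quinol_chain:", x$n_beads, "beads (6 head-ring +", x$n_tail_beads,
      "tail)\n")
  cat("  chain length:", round(x$chain_length, 2), "A\n")
  cat("  head_ring:", paste(x$head_ring, collapse = " "), "\n")
  cat("  mid_tail: ", paste(x$mid_tail, collapse = " "), "\n")
  cat("  tail_tip: ", paste(x$tail_tip, collapse = " "), "\n")
  invisible(x)
}

#' Build a ring-in-slab toy binding system
#'
#' Places `n_subunits` repulsive subunit sites on a circle of radius
#' `ring_radius` inside a membrane slab, with an attractive Gaussian binding
#' well at the centre.  The gaps between adjacent subunits are the egress
#' pores, labelled `"i-j"` after the flanking subunits.  The open variant
#' removes two adjacent subunits (a protein-W-like substitution) and the
#' whole freed arc becomes a single pore labelled `"Gap"`.
#'
#' Subunit angular sectors (half-width `occupancy * pi / n`) and pore
#' sectors alternate and tile the circle exactly.  For channel assignment
#' every azimuth is owned by exactly one pore: a subunit sector belongs to
#' the pore counterclockwise of it, which also fixes the documented boundary
#' tie-break.
#'
#' @param n_subunits number of subunits in the closed ring (>= 3, default 16).
#' @param open if TRUE remove two adjacent subunits and merge the freed arc
#'   into the "Gap" pore.
#' @param seed integer seed, stored for provenance (the geometry itself is
#'   deterministic).
#' @param ring_radius radius of the subunit circle, Angstrom.
#' @param occupancy fraction of the circle covered by subunit sectors.
#' @param site_eps repulsive strength of a subunit site, kcal/mol.
#' @param site_sigma Gaussian range of a subunit site, Angstrom.
#' @param slab_z numeric(2), membrane slab bounds (z_lo, z_hi), Angstrom.
#' @param wall_k flat-bottom wall stiffness, kcal/mol/A^2.
#' @param well_depth,well_width,well_center binding-well parameters
#'   (kcal/mol, Angstrom, 3-vector inside ring and slab).
#' @param removed ids of the two adjacent subunits removed when `open`;
#'   default the last pair `c(n-1, n)`.
#' @return an object of class `ring_system`.
#' @export
build_ring_system <- function(n_subunits = 16, open = FALSE, seed = 1,
                              ring_radius = 15, occupancy = 0.55,
                              site_eps = 6, site_sigma = 2,
                              slab_z = c(-12, 12), wall_k = 10,
                              well_depth = 3, well_width = 3,
                              well_center = c(0, 0, 0), removed = NULL) {
  if (!is.numeric(n_subunits) || length(n_subunits) != 1 || n_subunits < 3 ||
      n_subunits != round(n_subunits)) {
    stop("invalid argument: n_subunits must be an integer >= 3")
  }
  n <- as.integer(n_subunits)
  if (slab_z[1] >= slab_z[2]) stop("invalid argument: slab_z must increase")
  if (well_center[3] < slab_z[1] || well_center[3] > slab_z[2]) {
    stop("invalid argument: binding well must lie inside the slab")
  }
  if (sqrt(sum(well_center[1:2]^2)) >= ring_radius) {
    stop("invalid argument: binding well must lie inside the ring")
  }
  half_width <- occupancy * pi / n
  phi <- 2 * pi * (0:(n - 1)) / n

  if (open) {
    if (is.null(removed)) removed <- c(n - 1L, n)
    removed <- sort(as.integer(removed))
    adjacent <- (diff(removed) == 1) ||
      identical(removed, c(1L, n))
    if (length(removed) != 2 || !adjacent) {
      stop("invalid argument: 'removed' must be two adjacent subunit ids")
    }
  } else {
    removed <- integer(0)
  }
  retained <- setdiff(seq_len(n), removed)

  subunits <- data.frame(
    id = retained,
    angle = phi[retained],
    x = ring_radius * cos(phi[retained]),
    y = ring_radius * sin(phi[retained])
  )

  # pores between cyclically consecutive retained subunits; a non-adjacent
  # pair (the removed arc) becomes the Gap
  k <- length(retained)
  nxt <- c(retained[-1], retained[1])
  labels <- character(k)
  start <- end <- own_start <- own_end <- numeric(k)
  for (q in seq_len(k)) {
    i <- retained[q]; j <- nxt[q]
    adjacent <- (j == i %% n + 1)
    labels[q] <- if (adjacent) paste0(i, "-", j) else "Gap"
    start[q] <- (phi[i] + half_width) %% (2 * pi)
    end[q] <- (phi[j] - half_width) %% (2 * pi)
    own_start[q] <- (phi[i] - half_width) %% (2 * pi)
    own_end[q] <- (phi[j] - half_width) %% (2 * pi)
  }
  pores <- data.frame(label = labels, subunit_cw = retained, subunit_ccw = nxt,
                      start = start, end = end,
                      own_start = own_start, own_end = own_end,
                      stringsAsFactors = FALSE)

  structure(list(
    n_subunits = n, ring_radius = ring_radius, half_width = half_width,
    occupancy = occupancy, open = open, removed = removed,
    subunits = subunits, pores = pores,
    site_eps = site_eps, site_sigma = site_sigma,
    slab_z = slab_z, wall_k = wall_k,
    well_center = well_center, well_depth = well_depth,
    well_width = well_width, seed = seed
  ), class = "ring_system")
}

#' @export
print.ring_system <- function(x, ...) {
  cat("ring_system:", nrow(x$subunits), "subunits on radius",
      x$ring_radius, "A", if (x$open) "(open)" else "(closed)", "\n")
  cat("  pores:", paste(x$pores$label, collapse = ", "), "\n")
  cat("  slab z:", x$slab_z[1], "to", x$slab_z[2], "A; wall_k =", x$wall_k,
      "\n")
  cat("  binding well: depth", x$well_depth, "kcal/mol, width", x$well_width,
      "A\n")
  invisible(x)
}

#' Angular width of each pore sector
#'
#' Physical pore sector widths (the open angle between the flanking subunit
#' sectors).  Together with the subunit sectors these tile the full circle.
#'
#' @param system a `ring_system`
#' @return named numeric vector of widths in radians
#' @export
pore_sector_widths <- function(system) {
  w <- (system$pores$end - system$pores$start) %% (2 * pi)
  names(w) <- system$pores$label
  w
}

# ---- analytic reference potentials -----------------------------------------

#' Analytic reference free-energy profiles
#'
#' Closed-form one-dimensional potentials used as validation oracles for the
#' umbrella-sampling/WHAM stack and the permeability integral: a flat
#' profile, a harmonic well, a (possibly tilted) quartic double well, and a
#' square barrier.
#'
#' The double well is
#' `F(x) = B ((x/a)^2 - 1)^2 + tilt * x / (2 a)`,
#' with barrier height `B` (kcal/mol) between wells near `x = -a, +a`, and
#' `tilt` the approximate free-energy difference between the two wells.
#'
#' @param kind one of "flat", "harmonic", "double_well", "square_barrier".
#' @param domain numeric(2), evaluable range of the reaction coordinate (A).
#' @param constant flat value, kcal/mol.
#' @param k,center harmonic spring constant (kcal/mol/A^2) and minimum.
#' @param barrier,half_sep,tilt double-well parameters (kcal/mol, A,
#'   kcal/mol).
#' @param height,width square-barrier height (kcal/mol) and width (A),
#'   centred at `center`.
#' @return an object of class `analytic_pmf`
#' @export
analytic_pmf <- function(kind = c("flat", "harmonic", "double_well",
                                  "square_barrier"),
                         domain = c(-10, 10), constant = 0,
                         k = 1, center = 0,
                         barrier = 3, half_sep = 2, tilt = 0,
                         height = 4.51, width = 5) {
  kind <- match.arg(kind)
  if (domain[1] >= domain[2]) stop("invalid argument: domain must increase")
  params <- switch(kind,
    flat = list(constant = constant),
    harmonic = list(k = k, center = center),
    double_well = list(barrier = barrier, half_sep = half_sep, tilt = tilt),
    square_barrier = list(height = height, width = width, center = center)
  )
  structure(list(kind = kind, params = params, domain = domain),
            class = "analytic_pmf")
}

#' Evaluate an analytic reference profile
#'
#' @param pmf an `analytic_pmf`
#' @param xi reaction-coordinate values, Angstrom (vectorised)
#' @return free energy values, kcal/mol
#' @export
evaluate_analytic_pmf <- function(pmf, xi) {
  stopifnot(inherits(pmf, "analytic_pmf"))
  if (any(xi < pmf$domain[1] - 1e-12 | xi > pmf$domain[2] + 1e-12)) {
    stop("out of range: xi outside the profile domain [",
         pmf$domain[1], ", ", pmf$domain[2], "]")
  }
  p <- pmf$params
  switch(pmf$kind,
    flat = rep(p$constant, length(xi)),
    harmonic = 0.5 * p$k * (xi - p$center)^2,
    double_well = {
      u <- xi / p$half_sep
      p$barrier * (u^2 - 1)^2 + 0.5 * p$tilt * u
    },
    square_barrier = ifelse(abs(xi - p$center) <= p$width / 2, p$height, 0)
  )
}

# integer code + parameter vector for the compiled 1D sampler
pmf_engine_code <- function(pmf) {
  p <- pmf$params
  switch(pmf$kind,
    flat = list(code = 0L, params = c(p$constant)),
    harmonic = list(code = 1L, params = c(p$k, p$center)),
    double_well = list(code = 2L, params = c(p$barrier, p$half_sep, p$tilt)),
    stop("cannot integrate this potential kind (no continuous force): ",
         pmf$kind)
  )
}
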