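# Shared fixture builders: everything is generated in code, at sizes chosen
# for fast, well-converged toy statistics.

small_chain <- function(n_tail = 12, seed = 1) {
  build_quinol_chain(n_tail_beads = n_tail, seed = seed)
}

closed_ring <- function(...) build_ring_system(16, open = FALSE, ...)

open_ring <- function(...) build_ring_system(16, open = TRUE, ...)

quick_params <- function(seed = 1, friction = 1) {
  langevin_params(temperature = 300, friction = friction,
                  timestep = 0.001, seed = seed)
}

# a small bound system used by the egress tests
bound_system <- function(well_depth = 3, n_tail = 12, n_subunits = 16,
                         ring_radius = 15) {
  make_system(small_chain(n_tail),
              build_ring_system(n_subunits, well_depth = well_depth,
                                ring_radius = ring_radius))
}

# analytic double well shared by engine and WHAM checks
dw_pmf <- function(barrier = 3, tilt = 0) {
  analytic_pmf("double_well", barrier = barrier, half_sep = 2, tilt = tilt,
               domain = c(-8, 8))
}

# standard error of a correlated series from block means
block_se <- function(x, n_blocks = 20) {
  n <- length(x)
  bl <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(x[((b - 1) * bl + 1):(b * bl)])
  }, 0)
  sd(means) / sqrt(n_blocks)
}

expect_rigid_invariant <- function(detect, frame, spec, tol = 1e-9,
                                   n_rot = 5, seed = 42) {
  set.seed(seed)
  base <- detect(frame, spec)
  for (r in seq_len(n_rot)) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- rnorm(3, sd = 20)
    moved <- sweep(frame %*% q, 2, -shift)
    rownames(moved) <- rownames(frame)
    got <- detect(moved, spec)
    expect_equal(got$flag, base$flag)
    num <- vapply(base, is.numeric, TRUE)
    expect_equal(as.matrix(got[, num]), as.matrix(base[, num]),
                 tolerance = tol)
  }
}
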