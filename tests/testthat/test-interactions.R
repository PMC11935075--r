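hex_ring <- function(center = c(0, 0, 0), radius = 1.4, normal_z = TRUE) {
  a <- 2 * pi * (0:5) / 6
  ring <- cbind(radius * cos(a), radius * sin(a), 0)
  sweep(ring, 2, -center)
}

stack_frame <- function(offset = c(0, 0, 3.8), rot = diag(3)) {
  r1 <- hex_ring()
  r2 <- sweep(hex_ring() %*% rot, 2, -offset)
  fr <- rbind(r1, r2)
  rownames(fr) <- c(paste0("A", 1:6), paste0("B", 1:6))
  fr
}

pistack_spec <- function(...) {
  interaction_spec(pistack = list(ring1 = paste0("A", 1:6),
                                  ring2 = paste0("B", 1:6), ...))
}

test_that("hydrogen bond detection follows the distance/angle criterion", {
  spec <- interaction_spec(hbond = list(donors = "D", acceptors = "A",
                                        hydrogens = list(D = "H")))
  mk <- function(dist, angle_deg) {
    # donor at origin, H at 1 A along x, acceptor placed to give the
    # requested D-H-A angle and D-A distance
    th <- (180 - angle_deg) * pi / 180
    apos <- c(1, 0, 0) + (dist - 1) * c(cos(th), sin(th), 0)
    fr <- rbind(D = c(0, 0, 0), H = c(1, 0, 0), A = apos)
    fr
  }
  good <- detect_hbond(mk(2.8, 170), spec)
  expect_true(good$flag)
  expect_equal(good$distance, 2.8, tolerance = 0.15)
  expect_false(detect_hbond(mk(4.0, 170), spec)$flag)
  expect_false(detect_hbond(mk(2.8, 120), spec)$flag)

  # with no explicit hydrogen the criterion reduces to the distance
  spec2 <- interaction_spec(hbond = list(donors = "D", acceptors = "A"))
  fr <- rbind(D = c(0, 0, 0), A = c(0, 3.2, 0))
  expect_true(detect_hbond(fr, spec2)$flag)
  expect_error(detect_hbond(fr[1, , drop = FALSE], spec2), "acceptor")
})

test_that("pi-stacking needs close, parallel, laterally aligned rings", {
  expect_true(detect_pistack(stack_frame(c(0, 0, 3.8)), pistack_spec())$flag)
  expect_false(detect_pistack(stack_frame(c(0, 0, 8)), pistack_spec())$flag)
  # coplanar side-by-side rings: angle 0, centroids 5.0 A, lateral offset 5
  side <- stack_frame(c(5, 0, 0))
  res <- detect_pistack(side, pistack_spec())
  expect_equal(res$plane_angle, 0, tolerance = 1e-6)
  expect_gt(res$offset, 2)
  expect_false(res$flag)
  # perpendicular rings in range are T-shaped, not parallel-stacked
  rotx <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  tsh <- detect_pistack(stack_frame(c(0, 0, 4.5), rot = rotx),
                        pistack_spec())
  expect_false(tsh$flag)
  expect_true(tsh$t_shaped)

  # symmetric in ring order
  spec_rev <- interaction_spec(pistack = list(ring1 = paste0("B", 1:6),
                                              ring2 = paste0("A", 1:6)))
  fr <- stack_frame(c(1.2, 0.5, 3.6))
  a <- detect_pistack(fr, pistack_spec())
  b <- detect_pistack(fr, spec_rev)
  expect_equal(a$flag, b$flag)
  expect_equal(a$plane_angle, b$plane_angle, tolerance = 1e-9)
  expect_equal(a$offset, b$offset, tolerance = 1e-9)

  # collinear "ring" atoms are a geometry error
  bad <- rbind(A1 = c(0, 0, 0), A2 = c(1, 0, 0), A3 = c(2, 0, 0),
               A4 = c(3, 0, 0), A5 = c(4, 0, 0), A6 = c(5, 0, 0),
               stack_frame()[7:12, ])
  expect_error(detect_pistack(bad, pistack_spec()), "geometry error")
})

test_that("water bridges require one water within both legs", {
  spec <- interaction_spec(waterbridge = list(solvent = "W1",
                                              partners1 = "P1",
                                              partners2 = "P2"))
  fr <- rbind(P1 = c(0, 0, 0), W1 = c(2.9, 0, 0), P2 = c(5.8, 0, 0))
  expect_true(detect_waterbridge(fr, spec)$flag)
  fr2 <- rbind(P1 = c(0, 0, 0), W1 = c(2.9, 0, 0), P2 = c(7.9, 0, 0))
  expect_false(detect_waterbridge(fr2, spec)$flag)

  # a two-water chain is outside the single-water definition
  fr3 <- rbind(P1 = c(0, 0, 0), W1 = c(2.9, 0, 0), W2 = c(5.8, 0, 0),
               P2 = c(8.7, 0, 0))
  spec3 <- interaction_spec(waterbridge = list(solvent = c("W1", "W2"),
                                               partners1 = "P1",
                                               partners2 = "P2"))
  expect_false(any(detect_waterbridge(fr3, spec3)$flag))
})

test_that("occupancies are exact fractions of flagged frames", {
  spec <- interaction_spec(hbond = list(donors = "D", acceptors = "A"))
  near <- rbind(D = c(0, 0, 0), A = c(0, 3.0, 0))
  far <- rbind(D = c(0, 0, 0), A = c(0, 9.0, 0))
  frames <- c(replicate(60, near, simplify = FALSE),
              replicate(40, far, simplify = FALSE))
  traj <- make_trajectory(frames, times = seq_len(100),
                          labels = c("D", "A"))
  ser <- occupancy_series(traj, spec)
  expect_equal(ser$occupancy$occupancy, 0.60)
  expect_equal(ser$counts$count[1], 1)
  expect_equal(ser$counts$count[100], 0)

  all_far <- make_trajectory(replicate(10, far, simplify = FALSE),
                             times = 1:10, labels = c("D", "A"))
  expect_equal(occupancy_series(all_far, spec)$occupancy$occupancy, 0)

  # constructed decaying-contact schedule: smoothed count non-increasing
  sched <- c(rep(1, 30), rep(0, 40))
  frames2 <- lapply(sched, function(s) if (s) near else far)
  traj2 <- make_trajectory(frames2, times = seq_along(sched),
                           labels = c("D", "A"))
  ser2 <- occupancy_series(traj2, spec)
  sm <- smooth_counts(ser2$counts, width = 11)
  expect_true(all(diff(sm$smoothed) < 1e-9))
})

test_that("distance series track the group COM", {
  g <- hex_ring(center = c(-9, 0, 0))
  rownames(g) <- paste0("A", 1:6)
  frames <- replicate(5, g, simplify = FALSE)
  traj <- make_trajectory(frames, times = 1:5, labels = rownames(g))
  ds <- distance_series(traj, paste0("A", 1:6), c(0, 0, 0))
  expect_equal(ds, rep(9, 5), tolerance = 1e-9)
  expect_equal(distance_series(traj, paste0("A", 1:6), c(-9, 0, 0)),
               rep(0, 5), tolerance = 1e-9)

  # linear 10 -> 17 A drift reproduces its endpoints
  n <- 21
  drift <- lapply(seq(10, 17, length.out = n), function(r) {
    m <- hex_ring(center = c(r, 0, 0))
    rownames(m) <- paste0("A", 1:6)
    m
  })
  trajd <- make_trajectory(drift, times = seq_len(n),
                           labels = paste0("A", 1:6))
  dd <- distance_series(trajd, paste0("A", 1:6), c(0, 0, 0))
  expect_equal(dd[1], 10, tolerance = 1e-9)
  expect_equal(dd[n], 17, tolerance = 1e-9)
  expect_equal(diff(dd), rep(dd[2] - dd[1], n - 1), tolerance = 1e-9)

  expect_error(distance_series(traj, "ZZ", c(0, 0, 0)), "ZZ")
})

test_that("all detectors are invariant under rigid motions", {
  spec_h <- interaction_spec(hbond = list(donors = "D", acceptors = "A",
                                          hydrogens = list(D = "H")))
  frh <- rbind(D = c(0, 0, 0), H = c(1, 0, 0), A = c(2.9, 0.4, 0.2))
  expect_rigid_invariant(detect_hbond, frh, spec_h)

  expect_rigid_invariant(detect_pistack, stack_frame(c(0.8, 0.2, 3.7)),
                         pistack_spec())

  spec_w <- interaction_spec(waterbridge = list(solvent = "W1",
                                                partners1 = "P1",
                                                partners2 = "P2"))
  frw <- rbind(P1 = c(0, 0, 0), W1 = c(2.7, 0.7, 0), P2 = c(5.1, 0, 0.9))
  expect_rigid_invariant(detect_waterbridge, frw, spec_w)
})

test_that("occupancy results serialize to CSV", {
  spec <- interaction_spec(hbond = list(donors = "D", acceptors = "A"))
  near <- rbind(D = c(0, 0, 0), A = c(0, 3.0, 0))
  traj <- make_trajectory(replicate(4, near, simplify = FALSE),
                          times = 1:4, labels = c("D", "A"))
  ser <- occupancy_series(traj, spec)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_occupancy(ser, f1, f2)
  expect_equal(nrow(read.csv(f1)), 4)
  expect_equal(read.csv(f2)$occupancy, 1)
})
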