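test_that("ramd_force distributes a * m over the group by mass", {
  # six carbon-like beads, a = 0.5, +z: total force (0, 0, 36)
  f <- ramd_force(rep(12, 6), 0.5, c(0, 0, 1))
  expect_equal(attr(f, "total"), c(0, 0, 36))
  expect_equal(colSums(f), c(0, 0, 36))
  expect_equal(unname(f[, 3]), rep(0.5 * 12, 6))

  # |F| = a * m for any direction, against an independent scalar product
  set.seed(20)
  for (i in 1:25) {
    m <- runif(4, 5, 30)
    a <- runif(1, 0.1, 1)
    d <- random_unit_direction()
    f <- ramd_force(m, a, d)
    total <- attr(f, "total")
    expect_equal(sqrt(sum(total^2)), a * sum(m), tolerance = 1e-10)
    expect_equal(sum(total * d), a * sum(m), tolerance = 1e-10)
  }
  expect_error(ramd_force(12, 0.3, c(0, 0, 2)), "unit vector")
  expect_error(ramd_force(12, -1, c(0, 0, 1)), "invalid argument")
})

test_that("the stall test redraws below d and keeps direction above it", {
  set.seed(30)
  dir <- c(1, 0, 0)
  r1 <- update_direction(NULL, displacement = 0.2, d = 0.3, direction = dir)
  expect_true(r1$redrawn)
  expect_false(identical(r1$direction, dir))
  expect_equal(sqrt(sum(r1$direction^2)), 1, tolerance = 1e-9)

  r2 <- update_direction(r1$log, displacement = 0.5, d = 0.3,
                         direction = r1$direction)
  expect_false(r2$redrawn)
  expect_identical(r2$direction, r1$direction)
  expect_equal(nrow(r2$log), 2)
  expect_equal(r2$log$redrawn, c(TRUE, FALSE))
})

test_that("redrawn directions are uniform on the unit sphere", {
  set.seed(31)
  n <- 1e4
  dirs <- t(replicate(n, random_unit_direction()))
  expect_equal(sqrt(rowSums(dirs^2)), rep(1, n), tolerance = 1e-9)
  # first moments: mean 0, var 1/3 per component
  se1 <- sqrt(1 / (3 * n))
  expect_true(all(abs(colMeans(dirs)) < 4 * se1))
  # second moments: E[x_i^2] = 1/3, var(x_i^2) = 4/45
  se2 <- sqrt(4 / 45 / n)
  expect_true(all(abs(colMeans(dirs^2) - 1 / 3) < 4 * se2))
  # cross moments vanish
  cross <- c(mean(dirs[, 1] * dirs[, 2]), mean(dirs[, 1] * dirs[, 3]),
             mean(dirs[, 2] * dirs[, 3]))
  expect_true(all(abs(cross) < 4 * sqrt(2 / 15 / n)))
})

test_that("the controller validates D against the ligand length", {
  sys <- bound_system()
  p <- quick_params()
  bad <- ramd_config(com_threshold_D = 5, steps_per_ns = 1e3,
                     event_window = 1)
  expect_error(s_ramd_md_run(sys, bad, p), "exceed the ligand length")
  expect_error(ramd_config(accel = 0), "invalid argument")
  expect_error(ramd_config(threshold_d = -1), "invalid argument")
})

test_that("the controller runs, logs every window, and audits redraws", {
  sys <- bound_system()
  p <- quick_params()
  cfg <- ramd_config(accel = 0.45, threshold_d = 0.4, force_group = "tail",
                     steps_per_ns = 1e4, event_window = 3,
                     md_relax_steps = 400, seed = 44)
  res <- s_ramd_md_run(sys, cfg, p)
  lg <- res$phase_log
  expect_gt(nrow(lg), 2)
  expect_setequal(unique(lg$phase), c("ramd", "md"))
  # audit: redrawn <=> displacement < d, on every logged window
  expect_identical(lg$redrawn, lg$displacement < cfg$threshold_d)
  # logged directions are unit vectors
  norms <- sqrt(lg$dir_x^2 + lg$dir_y^2 + lg$dir_z^2)
  expect_equal(norms, rep(1, nrow(lg)), tolerance = 1e-9)

  # determinism: identical seed, identical outcome
  res2 <- s_ramd_md_run(sys, cfg, p)
  expect_identical(res$phase_log, res2$phase_log)
  expect_identical(res$event$occurred, res2$event$occurred)
  last <- length(res$trajectory$frames)
  expect_identical(res$trajectory$frames[[last]],
                   res2$trajectory$frames[[last]])
})

test_that("md_relax_steps = 0 is the pure RaMD limit", {
  sys <- bound_system()
  p <- quick_params()
  cfg <- ramd_config(accel = 0.5, threshold_d = 0.4, steps_per_ns = 5e3,
                     event_window = 2, md_relax_steps = 0, seed = 9)
  res <- s_ramd_md_run(sys, cfg, p)
  expect_true(all(res$phase_log$phase == "ramd"))
})

test_that("a free ligand is driven out within the window", {
  sys <- make_system(build_quinol_chain(11, seed = 1),
                     build_ring_system(12, well_depth = 0, ring_radius = 10))
  p <- quick_params()
  esc <- 0
  for (s in 1:20) {
    cfg <- ramd_config(accel = 0.3, threshold_d = 0.3, force_group = "tail",
                       steps_per_ns = 1e4, event_window = 10, seed = 7 * s)
    r <- s_ramd_md_run(sys, cfg, p)
    esc <- esc + r$event$occurred
    if (r$event$occurred) {
      expect_lte(r$event$time, 10)
      expect_true(nzchar(r$event$pore_id))
    }
  }
  expect_gte(esc / 20, 0.95)
})

test_that("dissociation detection tracks the mid-tail COM ring passage", {
  ch <- small_chain()
  rs <- closed_ring()
  inside <- matrix(0, ch$n_beads, 3)
  outside <- inside
  outside[ch$mid_tail, 1] <- rs$ring_radius + 2  # radial exit inside slab
  top <- inside
  top[ch$mid_tail, 1] <- rs$ring_radius + 2
  top[ch$mid_tail, 3] <- rs$slab_z[2] + 5        # exit above the slab

  mk <- function(frames, ns_times) {
    make_trajectory(frames, times = ns_times, steps = ns_times,
                    metadata = list(steps_per_ns = 1))
  }

  ev <- detect_dissociation(mk(list(inside, inside, outside, outside),
                               c(0, 2, 4, 6)), rs, ch, window = 10)
  expect_true(ev$occurred)
  expect_equal(ev$time, 4)
  expect_true(nzchar(ev$pore_id))
  expect_equal(ev$exit_point[1], rs$ring_radius + 2, tolerance = 1e-9)

  ev2 <- detect_dissociation(mk(list(inside, inside, outside),
                                c(0, 6, 12)), rs, ch, window = 10)
  expect_false(ev2$occurred)
  expect_null(ev2$pore_id)

  expect_warning(
    ev3 <- detect_dissociation(mk(list(inside, top), c(0, 4)), rs, ch,
                               window = 10),
    "event window")
  expect_false(ev3$occurred)
})

test_that("event and phase logs serialize to CSV", {
  ev <- dissociation_event(TRUE, time = 2.5, exit_point = c(16, 1, 0),
                           pore_id = "1-2", mode = "tail",
                           config = ramd_config(seed = 3))
  path <- tempfile(fileext = ".csv")
  tab <- write_event_log(list(ev), path)
  back <- read.csv(path)
  expect_equal(back$pore_id, "1-2")
  expect_equal(back$time_ns, 2.5)
  expect_error(dissociation_event(FALSE, pore_id = "1-2"),
               "invalid argument")
})
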