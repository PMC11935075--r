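test_that("the reaction coordinate is a pure xy projection", {
  expect_equal(project_xy(c(3, 4, 100), c(0, 0, 0)), 5.0)
  expect_equal(project_xy(c(2, -1, 7), c(2, -1, -50)), 0.0)
  expect_equal(project_xy(c(1, 0, 0), c(0, 0, 0)), 1.0)
  m <- rbind(c(3, 4, 1), c(0, 1, 2))
  expect_equal(project_xy(m, c(0, 0, 0)), c(5, 1))
})

test_that("window overlap matches the Gaussian closed form", {
  # flat landscape: window histograms are Gaussians of sd sqrt(kT/k);
  # neighbouring-window overlap = 2 * Phi(-spacing / (2 sd))
  k <- 4
  fl <- analytic_pmf("flat", domain = c(-30, 30))
  set.seed(21)
  wins <- sample_umbrella_analytic(fl, umbrella_ladder(-2, 2, 5, k),
                                   n_steps = 2e5, stride = 10)
  ov <- egressr:::adjacent_overlap(wins, bin_width = 0.05)
  sdv <- sqrt(kT_kcal(300) / k)
  expected <- 2 * pnorm(-1 / (2 * sdv))
  expect_true(all(abs(ov$overlap - expected) < 0.03))
  expect_true(all(ov$overlap > 0.05))
})

test_that("stiff narrow windows trigger the insufficient-overlap warning", {
  sys <- bound_system(well_depth = 0)
  p <- quick_params(seed = 3)
  wins <- umbrella_ladder(4, 9, 2, spring_k = 1e4, production_time = 0.02)
  expect_warning(
    run_umbrella(sys, wins, p, steps_per_ns = 1e5, stride = 50),
    "insufficient overlap.*1-2")
})

test_that("umbrella windows on the toy system sample around their centres", {
  sys <- bound_system(well_depth = 0)
  p <- quick_params(seed = 14)
  wins <- umbrella_ladder(5, 8, 4, spring_k = 4, production_time = 0.2)
  wins <- run_umbrella(sys, wins, p, steps_per_ns = 1e5, stride = 50)
  for (w in wins) {
    expect_gt(length(w$samples), 100)
    expect_lt(abs(mean(w$samples) - w$center), 1.5)
  }
  expect_true(all(attr(wins, "overlap")$overlap > 0.05))
  bad <- umbrella_ladder(8, 5, 3, spring_k = 10)
  expect_error(run_umbrella(sys, bad, p), "ordered")
})

test_that("WHAM degenerates to the Boltzmann histogram for one free window", {
  set.seed(22)
  fl <- analytic_pmf("harmonic", k = 1.5, domain = c(-10, 10))
  s <- sample_unbiased_analytic(fl, n_steps = 5e5, stride = 10)
  w <- umbrella_window(center = 0, spring_k = 1e-12, samples = s)
  prof <- suppressWarnings(
    wham_solve(list(w), wham_config(bin_width = 0.2, n_boot = 0)))
  ref <- boltzmann_pmf(s, bin_width = 0.2)
  common <- intersect(round(prof$xi, 6), round(ref$xi, 6))
  i1 <- match(common, round(prof$xi, 6)); i2 <- match(common, round(ref$xi, 6))
  expect_equal(prof$f[i1], ref$f[i2], tolerance = 1e-6)
})

test_that("WHAM output is invariant to window order", {
  pmf <- dw_pmf()
  set.seed(23)
  wins <- sample_umbrella_analytic(pmf, umbrella_ladder(-4, 4, 9, 4),
                                   n_steps = 5e4, stride = 10)
  cfg <- wham_config(bin_width = 0.2, n_boot = 0)
  a <- suppressWarnings(wham_solve(wins, cfg))
  b <- suppressWarnings(wham_solve(rev(wins), cfg))
  expect_equal(a$xi, b$xi)
  expect_lt(max(abs(a$f - b$f)), 1e-10)
})

test_that("convergence slicing flags drifting series and accepts clean ones", {
  # identical halves: zero deviation between the two cumulative slices
  set.seed(24)
  half <- rnorm(2000, 0, 0.5)
  w <- umbrella_window(0, spring_k = 2, samples = c(half, half))
  rep0 <- check_convergence(list(w), wham_config(bin_width = 0.2, n_boot = 0),
                            segments = 2, threshold = 0.5)
  expect_equal(rep0$deviations, 0, tolerance = 1e-12)
  expect_true(rep0$converged)

  # well-sampled harmonic landscape converges
  ha <- analytic_pmf("harmonic", k = 2, domain = c(-10, 10))
  set.seed(25)
  wins <- sample_umbrella_analytic(ha, umbrella_ladder(-2, 2, 5, 3),
                                   n_steps = 1e5, stride = 10)
  rep1 <- check_convergence(wins, wham_config(bin_width = 0.2, n_boot = 0),
                            segments = 4)
  expect_true(rep1$converged)
  expect_lt(rep1$deviations[3], 0.5)

  # a strongly drifting (non-equilibrated) series is not converged
  drift <- seq(0, 12, length.out = 4000) + rnorm(4000, 0, 0.2)
  wd <- umbrella_window(0, spring_k = 1e-12, samples = drift)
  rep2 <- suppressWarnings(
    check_convergence(list(wd), wham_config(bin_width = 0.2, n_boot = 0),
                      segments = 2))
  expect_false(rep2$converged)
})

test_that("endpoint re-anchoring tilts to the requested end-to-end offset", {
  prof <- pmf_profile(seq(0, 10, 0.5), 0.3 * seq(0, 10, 0.5)^1.3 / 10)
  p0 <- apply_endpoint_offset(prof, 0)
  expect_equal(p0$f[length(p0$f)] - p0$f[1], 0, tolerance = 1e-12)
  expect_equal(p0$offset_applied, 0)

  p1 <- apply_endpoint_offset(prof, -13.70)
  expect_equal(p1$f[length(p1$f)] - p1$f[1], -13.70, tolerance = 1e-12)
  # interior shape preserved up to the linear tilt
  expect_equal(diff(p1$f, differences = 2), diff(prof$f, differences = 2),
               tolerance = 1e-10)

  p2 <- apply_endpoint_offset(apply_endpoint_offset(prof, 0), -5)
  expect_equal(p2$f[length(p2$f)] - p2$f[1], -5, tolerance = 1e-12)
  expect_equal(p2$offset_applied, -5)
})

test_that("barrier heights are forward climbs over the range", {
  xi <- seq(-10, 10, 0.05)
  sq <- analytic_pmf("square_barrier", height = 4.51, width = 5,
                     domain = c(-10, 10))
  prof <- pmf_profile(xi, evaluate_analytic_pmf(sq, xi))
  expect_equal(barrier_height(prof), 4.51)

  down <- pmf_profile(xi, seq(8, 0, length.out = length(xi)),
                      normalize = FALSE)
  expect_equal(barrier_height(down), 0)

  dw <- dw_pmf(barrier = 3)
  xid <- seq(-8, 8, 0.05)
  profdw <- pmf_profile(xid, evaluate_analytic_pmf(dw, xid))
  # independent grid max-scan from the left well
  f <- profdw$f
  left <- which.min(abs(xid + 2))
  oracle <- max(vapply(seq(left, length(xid)), function(j) {
    f[j] - min(f[left:j])
  }, 0))
  expect_equal(barrier_height(profdw, range = c(-2, 8)), oracle)
  expect_equal(barrier_height(profdw, range = c(-2, 0.5)), 3.0,
               tolerance = 1e-3)
  expect_error(barrier_height(profdw, range = c(50, 60)), "empty")
})

test_that("the diffusion estimator recovers the Einstein relation", {
  # strongly overdamped harmonic coordinate: D = kT/(m gamma)
  m <- 12; gam <- 100; k <- 2
  d_true <- kT_kcal(300) * 418.4 / (m * gam) * 1000  # A^2/ns
  set.seed(26)
  r <- egressr:::cpp_langevin_xi(0, 0, m, 0.005, gam, kT_kcal(300),
                                 2e6, 10, 1L, c(k, 0), 0, 0)
  w <- umbrella_window(0, spring_k = k, samples = r$x,
                       dt_sample = 0.05 * 1e-3)
  d_hat <- estimate_diffusion(w)
  expect_lt(abs(d_hat - d_true) / d_true, 0.2)
  expect_gt(attr(d_hat, "tau_int"), 0)

  # white noise: D = var^2 / (discrete-sum integral of the autocovariance)
  set.seed(27)
  x <- rnorm(5e4, sd = 2)
  dt <- 0.01
  acov <- vapply(0:10, function(l) {
    mean((x[1:(length(x) - l)] - mean(x)) * (x[(1 + l):length(x)] - mean(x)))
  }, 0)
  zero <- which(acov <= 0)[1]
  oracle <- var(x)^2 / ((sum(acov[1:(zero - 1)]) - 0.5 * acov[1]) * dt)
  d_wn <- estimate_diffusion(x, dt_sample = dt)
  expect_equal(as.numeric(d_wn), oracle, tolerance = 0.02)

  expect_warning(estimate_diffusion(rep(1, 1000), dt_sample = dt),
                 "unreliable")
})

test_that("permeability reproduces its closed forms and gauge invariance", {
  # flat PMF: P = D / L (D = 1e-5 cm^2/s = 100 A^2/ns, L = 10 A = 1e-7 cm)
  xi <- seq(0, 10, 0.01)
  flat <- pmf_profile(xi, rep(0, length(xi)))
  d <- cm2s_to_A2ns(1e-5)
  expect_equal(permeability(flat, d), 100, tolerance = 1e-3)

  # square barrier: P = D / ((L - w) + w exp(beta B))
  B <- 3; w <- 5; L <- 20
  xi2 <- seq(0, L, 0.005)
  sq <- analytic_pmf("square_barrier", height = B, width = w, center = L / 2,
                     domain = c(0, L))
  prof <- pmf_profile(xi2, evaluate_analytic_pmf(sq, xi2))
  beta <- 1 / kT_kcal(300)
  p_analytic <- 10 * d / ((L - w) + w * exp(beta * B))  # A/ns -> cm/s
  expect_equal(permeability(prof, d), p_analytic, tolerance = 5e-3)

  # invariant to additive constants after bulk referencing
  set.seed(28)
  for (const in rnorm(5, sd = 10)) {
    shifted <- pmf_profile(xi2, prof$f + const, normalize = FALSE)
    expect_equal(permeability(shifted, d), permeability(prof, d),
                 tolerance = 1e-12)
  }

  # P strictly decreases with barrier height
  ps <- vapply(c(1, 2, 3, 4), function(b) {
    sqb <- analytic_pmf("square_barrier", height = b, width = w,
                        center = L / 2, domain = c(0, L))
    permeability(pmf_profile(xi2, evaluate_analytic_pmf(sqb, xi2)), d)
  }, 0)
  expect_true(all(diff(ps) < 0))

  expect_error(permeability(prof, -1), "must be > 0")
})

test_that("the printed permeability pair implies a ~40% rate increase", {
  expect_equal(percent_increase(0.043, 0.060), 39.53488, tolerance = 1e-5)
  expect_equal(round(percent_increase(0.043, 0.060)), 40)
})

test_that("windows and PMFs round-trip through their text formats", {
  w <- umbrella_window(3.5, 10, samples = round(rnorm(50, 3.5, 0.3), 6),
                       dt_sample = 0.001)
  path <- tempfile(fileext = ".txt")
  write_window(w, path)
  back <- read_window(path)
  expect_equal(back$center, 3.5)
  expect_equal(back$spring_k, 10)
  expect_equal(back$samples, w$samples, tolerance = 1e-7)

  prof <- pmf_profile(seq(0, 5, 0.5), runif(11), stderr = runif(11, 0, 0.1))
  p2 <- tempfile(fileext = ".tsv")
  write_pmf(prof, p2)
  back2 <- read_pmf(p2)
  expect_equal(back2$f, prof$f, tolerance = 1e-9)
  expect_equal(back2$stderr, prof$stderr, tolerance = 1e-9)
})
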