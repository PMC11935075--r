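#' xy-projected reaction coordinate
#'
#' Distance between a group centre of mass and an anchor projected onto the
#' membrane (xy) plane; the z separation is ignored entirely.  This is the
#' reaction coordinate used throughout the umbrella-sampling stack, because
#' lateral motion along the membrane plane, not depth, carries the egress.
#'
#' @param head_com 3-vector (or n x 3 matrix) of group COM coordinates
#' @param anchor 3-vector (or 2-vector) reference point
#' @return projected distance(s), Angstrom
#' @export
project_xy <- function(head_com, anchor) {
  if (is.matrix(head_com)) {
    sqrt((head_com[, 1] - anchor[1])^2 + (head_com[, 2] - anchor[2])^2)
  } else {
    sqrt((head_com[1] - anchor[1])^2 + (head_com[2] - anchor[2])^2)
  }
}

#' Umbrella window
#'
#' @param center bias centre on the reaction coordinate, Angstrom
#' @param spring_k harmonic bias constant, kcal/mol/A^2 (> 0; energy =
#'   1/2 k (xi - center)^2)
#' @param samples optional reaction-coordinate time series
#' @param production_time production length, engine-ns (default 6)
#' @param dt_sample sample spacing, engine-ns (set by the runners)
#' @return an object of class `umbrella_window`
#' @export
umbrella_window <- function(center, spring_k, samples = NULL,
                            production_time = 6, dt_sample = NA_real_) {
  if (spring_k <= 0) stop("invalid argument: spring_k must be > 0")
  if (!is.null(samples) && any(!is.finite(samples))) {
    stop("invalid argument: window samples must be finite")
  }
  structure(list(center = center, spring_k = spring_k, samples = samples,
                 production_time = production_time, dt_sample = dt_sample),
            class = "umbrella_window")
}

#' Evenly spaced umbrella windows
#'
#' @param from,to range of window centres, Angstrom
#' @param n number of windows
#' @param spring_k shared bias constant, kcal/mol/A^2
#' @param ... passed to [umbrella_window()]
#' @return list of `umbrella_window`
#' @export
umbrella_ladder <- function(from, to, n, spring_k, ...) {
  lapply(seq(from, to, length.out = n), umbrella_window,
         spring_k = spring_k, ...)
}

#' Histogram overlap of adjacent windows
#'
#' Fraction `sum(pmin(p_i, p_j))` of shared probability mass between
#' neighbouring window histograms on a common grid.
#'
#' @param windows populated `umbrella_window` list (ordered by centre)
#' @param bin_width histogram bin width, Angstrom
#' @return data.frame (pair, overlap)
#' @keywords internal
adjacent_overlap <- function(windows, bin_width = 0.2) {
  if (length(windows) < 2) {
    return(data.frame(pair = character(0), overlap = numeric(0)))
  }
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  breaks <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  probs <- lapply(windows, function(w) {
    h <- hist(w$samples, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  })
  ov <- vapply(seq_len(length(windows) - 1), function(i) {
    sum(pmin(probs[[i]], probs[[i + 1]]))
  }, 0)
  data.frame(pair = paste(seq_along(ov), seq_along(ov) + 1, sep = "-"),
             overlap = ov)
}

#' Run umbrella sampling on a toy system
#'
#' For each window the ligand is placed with its head-ring COM at the window
#' centre (measured from `anchor` in the xy plane), equilibrated and sampled
#' under the harmonic bias on the xy-projected head-ring-COM-to-anchor
#' distance.  The leading `equil_fraction` of each series is discarded.
#' Adjacent-window histogram overlaps below `overlap_warn` trigger an
#' insufficient-overlap warning naming the pair.
#'
#' @param system a `toy_system`
#' @param windows list of `umbrella_window` (centres ordered)
#' @param md_params a `langevin_params`
#' @param anchor 2- or 3-vector anchor point (default: ring centre)
#' @param steps_per_ns engine steps per engine-ns
#' @param stride steps between recorded samples
#' @param equil_fraction leading fraction of each series to discard
#' @param overlap_warn adjacent-overlap warning threshold (fraction)
#' @return the windows with `$samples` populated; attribute `overlap` holds
#'   the overlap report
#' @export
run_umbrella <- function(system, windows, md_params, anchor = c(0, 0),
                         steps_per_ns = 1e6, stride = 100,
                         equil_fraction = 1 / 6, overlap_warn = 0.05) {
  stopifnot(inherits(system, "toy_system"))
  centers <- vapply(windows, `[[`, 0, "center")
  if (is.unsorted(centers)) {
    stop("invalid argument: window centres must be ordered")
  }
  chain <- system$chain
  group <- chain$head_ring
  set.seed(md_params$seed)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    n_steps <- round(w$production_time * steps_per_ns)
    # place the head-ring COM at the window centre along +x from the anchor
    pos <- system$positions
    head_com <- com_of(pos, chain$masses, group)
    target <- c(anchor[1] + w$center, anchor[2], head_com[3])
    pos <- sweep(pos, 2, -(target - head_com))
    vel <- maxwell_velocities(system$core$masses, md_params$temperature)
    res <- cpp_run_md(pos, vel, system$core, md_params$timestep,
                      md_params$friction, kT_kcal(md_params$temperature),
                      as.numeric(n_steps), as.numeric(stride), NULL,
                      list(group = as.integer(group), anchor_x = anchor[1],
                           anchor_y = anchor[2], k = w$spring_k,
                           center = w$center))
    xi <- res$xi[-1]  # drop the initial frame
    keep <- xi[seq.int(floor(length(xi) * equil_fraction) + 1, length(xi))]
    windows[[i]]$samples <- keep
    windows[[i]]$dt_sample <- stride / steps_per_ns
  }
  ov <- adjacent_overlap(windows)
  low <- which(ov$overlap < overlap_warn)
  if (length(low)) {
    warning("insufficient overlap between adjacent windows: ",
            paste(ov$pair[low], collapse = ", "))
  }
  attr(windows, "overlap") <- ov
  windows
}

#' Sample umbrella windows on an analytic reference profile
#'
#' One-dimensional Langevin sampling of each biased window directly on an
#' [analytic_pmf()] landscape — the validation route for the WHAM solver.
#'
#' @param pmf an `analytic_pmf` (flat, harmonic or double_well)
#' @param windows list of `umbrella_window`
#' @param temperature temperature, K
#' @param n_steps integration steps per window
#' @param stride steps between samples
#' @param equil_fraction leading fraction discarded
#' @param mass,friction,dt particle mass (amu), friction (ps^-1), timestep
#'   (ps)
#' @return the windows with samples populated
#' @export
sample_umbrella_analytic <- function(pmf, windows, temperature = 300,
                                     n_steps = 2e5, stride = 10,
                                     equil_fraction = 1 / 6, mass = 12,
                                     friction = 5, dt = 0.01) {
  code <- pmf_engine_code(pmf)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    res <- cpp_langevin_xi(w$center, 0, mass, dt, friction,
                           kT_kcal(temperature), as.numeric(n_steps),
                           as.numeric(stride), code$code, code$params,
                           w$spring_k, w$center)
    xi <- res$x
    keep <- xi[seq.int(floor(length(xi) * equil_fraction) + 1, length(xi))]
    windows[[i]]$samples <- keep
    windows[[i]]$dt_sample <- stride * dt * 1e-3
  }
  windows
}

#' Long unbiased Boltzmann sampling on an analytic profile
#'
#' Reference-oracle generator: a long unbiased Langevin run whose histogram
#' gives `F = -kT ln p` independently of the WHAM machinery.
#'
#' @inheritParams sample_umbrella_analytic
#' @param x0 starting coordinate
#' @return numeric vector of samples
#' @export
sample_unbiased_analytic <- function(pmf, temperature = 300, n_steps = 2e6,
                                     stride = 10, x0 = 0, mass = 12,
                                     friction = 5, dt = 0.01) {
  code <- pmf_engine_code(pmf)
  res <- cpp_langevin_xi(x0, 0, mass, dt, friction, kT_kcal(temperature),
                         as.numeric(n_steps), as.numeric(stride), code$code,
                         code$params, 0, 0)
  res$x
}

#' Boltzmann-histogram free energy estimate
#'
#' `F = -kT ln p` from a plain histogram, min-normalised — the independent
#' reference against which WHAM output is validated.
#'
#' @param samples unbiased reaction-coordinate samples
#' @param bin_width bin width, Angstrom
#' @param temperature temperature, K
#' @return a `pmf_profile`
#' @export
boltzmann_pmf <- function(samples, bin_width = 0.2, temperature = 300) {
  rng <- range(samples)
  breaks <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  h <- hist(samples, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  f <- -kT_kcal(temperature) * log(h$counts[keep] / sum(h$counts))
  pmf_profile(h$mids[keep], f - min(f))
}

#' WHAM solver configuration
#'
#' @param bin_width histogram bin width, Angstrom
#' @param tolerance convergence threshold on the per-iteration change of the
#'   window free-energy constants, kcal/mol
#' @param max_iter iteration cap
#' @param temperature temperature, K (fixes beta = 1/kT)
#' @param n_boot block-bootstrap replicates for the PMF standard error
#'   (0 disables)
#' @param n_blocks blocks per window used by the bootstrap
#' @return an object of class `wham_config`
#' @export
wham_config <- function(bin_width = 0.2, tolerance = 1e-7, max_iter = 1e5,
                        temperature = 300, n_boot = 10, n_blocks = 10) {
  if (bin_width <= 0) stop("invalid argument: bin_width must be > 0")
  if (tolerance <= 0) stop("invalid argument: tolerance must be > 0")
  structure(list(bin_width = bin_width, tolerance = tolerance,
                 max_iter = max_iter, temperature = temperature,
                 n_boot = n_boot, n_blocks = n_blocks),
            class = "wham_config")
}

#' Free-energy profile container
#'
#' @param xi strictly increasing reaction-coordinate grid, Angstrom
#' @param f free energy, kcal/mol (min-normalised on construction unless
#'   `normalize = FALSE`)
#' @param stderr pointwise standard error, kcal/mol
#' @param offset_applied endpoint re-anchoring constant already applied
#' @param normalize subtract `min(f)`?
#' @return an object of class `pmf_profile`
#' @export
pmf_profile <- function(xi, f, stderr = rep(NA_real_, length(xi)),
                        offset_applied = 0, normalize = TRUE) {
  if (any(diff(xi) <= 0)) {
    stop("invalid argument: xi grid must be strictly increasing")
  }
  if (normalize) f <- f - min(f)
  structure(list(xi = xi, f = f, stderr = stderr,
                 offset_applied = offset_applied),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("pmf_profile:", length(x$xi), "bins, xi in [",
      signif(min(x$xi), 4), ",", signif(max(x$xi), 4), "] A, F range",
      signif(min(x$f), 4), "..", signif(max(x$f), 4), "kcal/mol\n")
  if (x$offset_applied != 0) {
    cat("  endpoint offset applied:", x$offset_applied, "kcal/mol\n")
  }
  invisible(x)
}

# core self-consistent iteration; windows -> list(xi, p, f, iterations,
# converged, residual)
wham_core <- function(windows, cfg) {
  beta <- 1 / kT_kcal(cfg$temperature)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  rng <- range(all_s)
  breaks <- seq(rng[1] - cfg$bin_width, rng[2] + cfg$bin_width,
                by = cfg$bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(mids)
  nw <- length(windows)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    counts[i, ] <- hist(windows[[i]]$samples, breaks = breaks,
                        plot = FALSE)$counts
  }
  N <- rowSums(counts)
  tot <- colSums(counts)
  # bias Boltzmann factors at bin centres
  cmat <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    w <- windows[[i]]
    cmat[i, ] <- exp(-beta * 0.5 * w$spring_k * (mids - w$center)^2)
  }
  fcon <- rep(0, nw)  # window free-energy constants, kcal/mol
  converged <- FALSE
  resid <- Inf
  iter <- 0
  while (iter < cfg$max_iter) {
    iter <- iter + 1
    denom <- colSums(N * exp(beta * fcon) * cmat)
    p <- ifelse(denom > 0, tot / denom, 0)
    fnew <- -log(as.vector(cmat %*% p)) / beta
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - fcon))
    fcon <- fnew
    if (resid < cfg$tolerance) { converged <- TRUE; break }
  }
  keep <- tot > 0
  if (any(!keep)) {
    interior <- which(!keep)
    interior <- interior[interior > min(which(keep)) &
                         interior < max(which(keep))]
    if (length(interior)) {
      warning("empty bins interior to the sampled range at xi = ",
              paste(signif(mids[interior], 4), collapse = ", "))
    }
  }
  list(xi = mids[keep], p = p[keep], fcon = fcon, iterations = iter,
       converged = converged, residual = resid)
}

#' Weighted histogram analysis of umbrella windows
#'
#' Self-consistently combines the biased window histograms into one unbiased
#' probability distribution and `F = -kT ln p`, min-normalised.  With a
#' single unbiased window this degenerates to the plain Boltzmann histogram.
#' The pointwise standard error comes from a block bootstrap over
#' contiguous sample blocks of every window.
#'
#' @param windows populated `umbrella_window` list
#' @param cfg a `wham_config`
#' @return a `pmf_profile`; attributes `iterations` and `fcon` expose the
#'   solver state
#' @export
wham_solve <- function(windows, cfg = wham_config()) {
  if (!length(windows)) stop("invalid argument: need at least one window")
  if (any(vapply(windows, function(w) is.null(w$samples), TRUE))) {
    stop("invalid argument: all windows must carry samples")
  }
  # zero-spring degenerate windows are handled with an explicit tiny k = 0
  windows <- lapply(windows, function(w) {
    if (w$spring_k <= 0) w$spring_k <- 0
    w
  })
  sol <- wham_core(windows, cfg)
  if (!sol$converged) {
    stop("convergence failure: WHAM residual ", signif(sol$residual, 3),
         " kcal/mol after ", sol$iterations, " iterations")
  }
  f <- -kT_kcal(cfg$temperature) * log(sol$p)
  prof <- pmf_profile(sol$xi, f)

  if (cfg$n_boot > 0) {
    boots <- matrix(NA_real_, cfg$n_boot, length(prof$xi))
    for (b in seq_len(cfg$n_boot)) {
      bw <- lapply(windows, function(w) {
        n <- length(w$samples)
        bl <- max(1, floor(n / cfg$n_blocks))
        starts <- sample.int(max(1, n - bl + 1), cfg$n_blocks,
                             replace = TRUE)
        w$samples <- unlist(lapply(starts, function(s) {
          w$samples[s:(s + bl - 1)]
        }))
        w
      })
      sb <- tryCatch(suppressWarnings(wham_core(bw, cfg)),
                     error = function(e) NULL)
      if (is.null(sb)) next
      fb <- -kT_kcal(cfg$temperature) * log(sb$p)
      fb <- fb - min(fb)
      boots[b, ] <- approx(sb$xi, fb, xout = prof$xi, rule = 2)$y
    }
    prof$stderr <- apply(boots, 2, sd, na.rm = TRUE)
  }
  attr(prof, "iterations") <- sol$iterations
  attr(prof, "fcon") <- sol$fcon
  prof
}

#' Umbrella-sampling convergence report
#'
#' Recomputes the PMF on cumulative time slices (1/segments, 2/segments,
#' ... of every window) and reports the maximum deviation between
#' successive slices; the estimate is declared converged when the final
#' deviation falls below `threshold`.
#'
#' @param windows populated `umbrella_window` list
#' @param cfg a `wham_config`
#' @param segments number of cumulative slices (>= 2)
#' @param threshold convergence threshold, kcal/mol
#' @return list(deviations, converged, profiles)
#' @export
check_convergence <- function(windows, cfg = wham_config(), segments = 4,
                              threshold = 0.5) {
  if (segments < 2) stop("invalid argument: segments must be >= 2")
  cfg$n_boot <- 0
  profs <- lapply(seq_len(segments), function(s) {
    sliced <- lapply(windows, function(w) {
      n <- length(w$samples)
      w$samples <- w$samples[seq_len(max(2, floor(n * s / segments)))]
      w
    })
    suppressWarnings(wham_solve(sliced, cfg))
  })
  devs <- vapply(seq_len(segments - 1), function(s) {
    a <- profs[[s]]; b <- profs[[s + 1]]
    fb <- approx(b$xi, b$f, xout = a$xi, rule = 2)$y
    max(abs(fb - a$f))
  }, 0)
  list(deviations = devs, converged = devs[length(devs)] < threshold,
       profiles = profs)
}

#' Re-anchor a PMF to a known end-to-end free-energy difference
#'
#' Applies a rigid end-to-end adjustment (a linear tilt) so that
#' `F(end) - F(start)` equals the supplied two-end-state offset, preserving
#' interior shape.  This is endpoint re-anchoring against an externally
#' computed initial-to-final free-energy difference, not a re-weighting of
#' the sampled distribution.  Re-applying with a new offset re-anchors from
#' scratch.
#'
#' @param pmf a `pmf_profile`
#' @param offset target `F(end) - F(start)`, kcal/mol (e.g. -13.70 from a
#'   two-end-state calculation)
#' @return the tilted `pmf_profile` with `offset_applied` recorded
#' @export
apply_endpoint_offset <- function(pmf, offset) {
  stopifnot(inherits(pmf, "pmf_profile"))
  xi <- pmf$xi
  span <- xi[length(xi)] - xi[1]
  current <- pmf$f[length(pmf$f)] - pmf$f[1]
  slope <- (offset - current) / span
  f <- pmf$f + slope * (xi - xi[1])
  out <- pmf
  out$f <- f
  out$offset_applied <- offset
  out
}

#' Forward barrier height of a PMF
#'
#' Maximum of `F(xi) - min(F)` over all preceding points within the range —
#' the largest forward climb a walker moving left-to-right must make.
#'
#' @param pmf a `pmf_profile`
#' @param range numeric(2) reaction-coordinate range (default: full grid)
#' @return barrier height, kcal/mol
#' @export
barrier_height <- function(pmf, range = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  idx <- if (is.null(range)) seq_along(pmf$xi) else
    which(pmf$xi >= range[1] & pmf$xi <= range[2])
  if (!length(idx)) stop("invalid argument: empty reaction-coordinate range")
  f <- pmf$f[idx]
  max(f - cummin(f))
}

#' Position-dependent diffusion coefficient from a biased window
#'
#' Positional-autocovariance estimator
#' `D = var(xi)^2 / integral of <d_xi(0) d_xi(t)> dt`, the integral
#' truncated at the first zero crossing of the autocovariance, which equals
#' `var(xi) / tau_int`.  Requires stationary samples whose autocorrelation
#' decays within the series.
#'
#' @param window a populated `umbrella_window` (or a numeric sample vector)
#' @param dt_sample sample spacing, engine-ns (default: window metadata)
#' @param max_lag autocovariance lags evaluated (default
#'   `min(n - 1, 5000)`)
#' @return D at the window centre, A^2/ns; attribute `tau_int` holds the
#'   integrated autocorrelation time (ns)
#' @export
estimate_diffusion <- function(window, dt_sample = NULL, max_lag = NULL) {
  x <- if (inherits(window, "umbrella_window")) window$samples else window
  if (inherits(window, "umbrella_window")) {
    dt_sample <- dt_sample %||% window$dt_sample
  }
  if (is.null(dt_sample) || is.na(dt_sample)) {
    stop("invalid argument: dt_sample (ns) is required")
  }
  v <- var(x)
  if (!is.finite(v) || v < 1e-14) {
    warning("unreliable estimate: series has (near-)zero variance")
    return(structure(NA_real_, tau_int = NA_real_))
  }
  n <- length(x)
  max_lag <- max_lag %||% min(n - 1, 5000)
  ac <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE,
            type = "covariance")$acf[, 1, 1]
  zero <- which(ac <= 0)[1]
  if (is.na(zero)) {
    warning("unreliable estimate: autocovariance does not decay to zero ",
            "within ", max_lag, " lags")
    zero <- max_lag + 1
  }
  # trapezoidal integral of C(t) up to the first zero crossing
  cc <- ac[seq_len(zero - 1)]
  integral <- (sum(cc) - 0.5 * cc[1]) * dt_sample
  d <- v^2 / integral
  structure(d, tau_int = integral / v)
}

#' Diffusion profile container
#'
#' @param xi grid, Angstrom
#' @param d diffusion coefficients, A^2/ns (all > 0)
#' @param method estimator tag
#' @return an object of class `diffusion_profile`
#' @export
diffusion_profile <- function(xi, d, method = "positional-autocovariance") {
  if (any(d <= 0)) stop("invalid argument: D must be > 0 everywhere")
  structure(list(xi = xi, d = d, method = method),
            class = "diffusion_profile")
}

#' Convert cm^2/s to A^2/ns
#' @param d_cm2s diffusion coefficient(s), cm^2/s
#' @return A^2/ns
#' @export
cm2s_to_A2ns <- function(d_cm2s) d_cm2s * 1e7

#' Permeability from the inhomogeneous solubility-diffusion model
#'
#' `P = 1 / integral over the range of exp(beta F(xi)) / D(xi) dxi`, with
#' the PMF first referenced to zero at the bulk end of the range so the
#' result is invariant to any additive constant in F.  Grids in Angstrom
#' and D in A^2/ns; the result is converted to cm/s.
#'
#' @param pmf a `pmf_profile`
#' @param diff a `diffusion_profile` (interpolated onto the PMF grid) or a
#'   single constant D, A^2/ns
#' @param range numeric(2) integration range (default full grid)
#' @param bulk which end of the range is bulk ("upper" or "lower")
#' @param temperature temperature, K
#' @return permeability coefficient, cm/s
#' @export
permeability <- function(pmf, diff, range = NULL, bulk = c("upper", "lower"),
                         temperature = 300) {
  stopifnot(inherits(pmf, "pmf_profile"))
  bulk <- match.arg(bulk)
  idx <- if (is.null(range)) seq_along(pmf$xi) else
    which(pmf$xi >= range[1] - 1e-9 & pmf$xi <= range[2] + 1e-9)
  if (length(idx) < 2) stop("invalid argument: integration range too small")
  xi <- pmf$xi[idx]
  f <- pmf$f[idx]
  d <- if (inherits(diff, "diffusion_profile")) {
    approx(diff$xi, diff$d, xout = xi, rule = 2)$y
  } else {
    rep(diff, length(xi))
  }
  if (any(d <= 0)) {
    stop("invalid argument: D must be > 0 over the integration range")
  }
  f <- f - if (bulk == "upper") f[length(f)] else f[1]
  beta <- 1 / kT_kcal(temperature)
  integrand <- exp(beta * f) / d
  resistance <- sum(diff(xi) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  # A/ns -> cm/s: 1 A/ns = 1e-8 cm / 1e-9 s = 10 cm/s
  10 / resistance
}

#' Relative permeability increase
#'
#' `100 * (p_new - p_ref) / p_ref`, the percent rate increase of one
#' crossing route over another.
#'
#' @param p_ref reference permeability
#' @param p_new comparison permeability
#' @return percent increase
#' @export
percent_increase <- function(p_ref, p_new) 100 * (p_new - p_ref) / p_ref

# ---- plain-text round trips ------------------------------------------------

#' Write / read an umbrella-window sample file
#'
#' Two-column plain text (time_ns, xi_angstrom) with a `#` metadata header
#' carrying center, spring_k and (optionally) temperature — the common WHAM
#' input dialect.
#'
#' @param window a populated `umbrella_window`
#' @param path file path
#' @param temperature recorded in the header
#' @return the path invisibly
#' @export
write_window <- function(window, path, temperature = 300) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# center= %.6f spring_k= %.6f temperature= %.2f",
                     window$center, window$spring_k, temperature), con)
  t <- (seq_along(window$samples) - 1) *
    (if (is.na(window$dt_sample)) 1 else window$dt_sample)
  writeLines(sprintf("%.8f %.8f", t, window$samples), con)
  invisible(path)
}

#' @rdname write_window
#' @export
read_window <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) {
    stop("parse error: missing metadata header at line 1")
  }
  num <- function(key) {
    m <- regmatches(first, regexec(paste0(key, "=\\s*([-0-9.eE+]+)"), first))
    as.numeric(m[[1]][2])
  }
  d <- read.table(path, comment.char = "#")
  if (ncol(d) < 2) stop("parse error: expected two columns in ", path)
  dt <- if (nrow(d) > 1) d[2, 1] - d[1, 1] else NA_real_
  umbrella_window(center = num("center"), spring_k = num("spring_k"),
                  samples = d[, 2], dt_sample = dt)
}

#' Write / read a PMF profile as TSV
#'
#' Columns: xi, F_kcal_mol, stderr.
#'
#' @param pmf a `pmf_profile`
#' @param path file path
#' @return the path invisibly
#' @export
write_pmf <- function(pmf, path) {
  d <- data.frame(xi = pmf$xi, F_kcal_mol = pmf$f, stderr = pmf$stderr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# offset_applied= %.6f", pmf$offset_applied), con)
  write.table(format(d, digits = 12, trim = TRUE), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  first <- readLines(path, n = 1)
  off <- 0
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("offset_applied=\\s*([-0-9.eE+]+)", first))
    off <- as.numeric(m[[1]][2])
  }
  d <- read.table(path, header = TRUE, comment.char = "#")
  pmf_profile(d$xi, d$F_kcal_mol,
              stderr = suppressWarnings(as.numeric(d$stderr)),
              offset_applied = off, normalize = FALSE)
}
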