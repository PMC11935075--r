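#' Plan an S-RaMD-MD parameter campaign
#'
#' Expands the acceleration x stall-threshold x snapshot x mode grid into a
#' stable, deterministic run list (ordered by acceleration, then threshold,
#' then snapshot, then mode), with per-run seeds derived from one base seed.
#' The default grids are the 5-value acceleration grid
#' {0.3, 0.35, 0.4, 0.45, 0.5} kcal A^-1 g^-1, the 3-value threshold grid
#' {0.3, 0.4, 0.5} A, and three starting snapshots: 45 runs per mode, 90 for
#' both modes.
#'
#' @param accelerations acceleration grid, kcal A^-1 g^-1
#' @param thresholds_d stall-threshold grid, Angstrom
#' @param snapshots starting-state identifiers
#' @param modes subset of c("head", "tail")
#' @param event_window engine-ns event window per run (default 10)
#' @param base_seed root seed from which per-run seeds are derived
#' @param ... further arguments passed to every [ramd_config()]
#' @return an object of class `campaign_plan`: a run table (`$runs`), the
#'   matching `ramd_config` list (`$configs`) and the total planned biased
#'   time `$planned_ns`
#' @export
plan_campaign <- function(accelerations = c(0.3, 0.35, 0.4, 0.45, 0.5),
                          thresholds_d = c(0.3, 0.4, 0.5),
                          snapshots = 1:3, modes = c("head", "tail"),
                          event_window = 10, base_seed = 1, ...) {
  if (!length(accelerations) || !length(thresholds_d) ||
      !length(snapshots) || !length(modes)) {
    stop("invalid argument: all campaign grid dimensions must be non-empty")
  }
  modes <- match.arg(modes, c("head", "tail"), several.ok = TRUE)
  runs <- expand.grid(mode = modes, snapshot = snapshots, d = thresholds_d,
                      a = accelerations, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  runs <- runs[, c("a", "d", "snapshot", "mode")]  # a-major ordering
  runs$run_id <- seq_len(nrow(runs))
  runs$seed <- (as.integer(base_seed) + 7919L * runs$run_id) %% .Machine$integer.max
  configs <- lapply(seq_len(nrow(runs)), function(i) {
    ramd_config(accel = runs$a[i], threshold_d = runs$d[i],
                force_group = runs$mode[i], event_window = event_window,
                seed = runs$seed[i], ...)
  })
  structure(list(runs = runs[, c("run_id", "a", "d", "snapshot", "mode",
                                 "seed")],
                 configs = configs,
                 planned_ns = nrow(runs) * event_window,
                 base_seed = base_seed),
            class = "campaign_plan")
}

#' @export
print.campaign_plan <- function(x, ...) {
  cat("campaign_plan:", nrow(x$runs), "runs (",
    length(unique(x$runs$a)), "a x", length(unique(x$runs$d)), "d x",
    length(unique(x$runs$snapshot)), "snapshots x",
    length(unique(x$runs$mode)), "modes ),",
    x$planned_ns, "engine-ns planned\n")
  invisible(x)
}

#' Execute a planned campaign on a toy system
#'
#' Runs [s_ramd_md_run()] for every planned configuration.  Snapshot ids
#' select among `states` (per-snapshot starting placements); with the
#' default NULL every run starts from the system's built-in placement.
#'
#' @param plan a `campaign_plan`
#' @param system a `toy_system` with a ring
#' @param md_params a `langevin_params`
#' @param states optional named list of list(positions) per snapshot id
#' @param stride trajectory save stride
#' @param keep_trajectories keep per-run trajectories (memory!)
#' @return list(events, table, plan, trajectories)
#' @export
run_campaign <- function(plan, system, md_params, states = NULL,
                         stride = 1000, keep_trajectories = FALSE) {
  stopifnot(inherits(plan, "campaign_plan"))
  events <- vector("list", nrow(plan$runs))
  trajs <- if (keep_trajectories) vector("list", nrow(plan$runs)) else NULL
  for (i in seq_len(nrow(plan$runs))) {
    sys_i <- system
    snap <- as.character(plan$runs$snapshot[i])
    if (!is.null(states) && !is.null(states[[snap]])) {
      sys_i$positions <- states[[snap]]$positions
    }
    res <- s_ramd_md_run(sys_i, plan$configs[[i]], md_params,
                         stride = stride)
    events[[i]] <- res$event
    if (keep_trajectories) trajs[[i]] <- res$trajectory
  }
  tab <- events_to_table(events)
  tab$snapshot_id <- plan$runs$snapshot
  list(events = events, table = tab, plan = plan, trajectories = trajs)
}

#' Assign an exit point to an inter-subunit channel
#'
#' Returns the label of the pore whose ownership sector contains the exit
#' azimuth.  Pore `"i-j"` owns the arc from the clockwise edge of subunit
#' i's sector up to (but excluding) the clockwise edge of subunit j's
#' sector, so subunit sectors are attributed to the pore counterclockwise of
#' the subunit and every azimuth belongs to exactly one pore; an azimuth
#' exactly on a subunit/pore boundary therefore lands in the pore
#' counterclockwise of that subunit.  In an open system the merged sector
#' returns `"Gap"`.
#'
#' @param exit_point 3-vector (or 2-vector) exit coordinate; its radial
#'   distance from the ring axis must be at least the ring radius
#' @param system a `ring_system`
#' @return a pore label
#' @export
assign_channel <- function(exit_point, system) {
  stopifnot(inherits(system, "ring_system"))
  rho <- sqrt(exit_point[1]^2 + exit_point[2]^2)
  if (rho < system$ring_radius - 1e-9) {
    stop("invalid argument: exit point lies inside the ring (rho = ",
         signif(rho, 4), " < ", system$ring_radius, ")")
  }
  az <- atan2(exit_point[2], exit_point[1]) %% (2 * pi)
  p <- system$pores
  for (q in seq_len(nrow(p))) {
    s <- p$own_start[q]
    e <- p$own_end[q]
    inside <- if (s <= e) (az >= s && az < e) else (az >= s || az < e)
    if (inside) return(p$label[q])
  }
  # numerically possible only at the 2*pi seam
  p$label[1]
}

#' Per-channel dissociation counts and probabilities
#'
#' Builds the channel table from raw counts: percentage =
#' `100 * count / total`, rounded to one decimal, rows sorted by descending
#' count within each mode.  When a printed/external `total` is supplied it
#' is used as the denominator even if the counts do not sum to it (the
#' mismatch is reported as a validation warning, never silently corrected).
#'
#' @param counts named integer vector (channel label -> count), or a
#'   data.frame with columns `mode`, `channel`, `count`
#' @param total denominator (dissociation events); default `sum(counts)`
#' @param mode dissociation mode label for the vector form
#' @param undissociated optional count of undissociated runs, reported in a
#'   separate summary attribute and excluded from the denominator
#' @return an object of class `channel_table`
#' @export
channel_table <- function(counts, total = NULL, mode = "tail",
                          undissociated = NULL) {
  if (is.data.frame(counts)) {
    parts <- lapply(split(counts, counts$mode), function(d) {
      channel_table(setNames(d$count, d$channel),
                    total = if (is.null(total)) NULL else
                      total[[unique(d$mode)]],
                    mode = unique(d$mode))
    })
    out <- do.call(rbind, lapply(parts, as.data.frame))
    rownames(out) <- NULL
    class(out) <- c("channel_table", "data.frame")
    return(out)
  }
  if (any(counts < 0)) stop("invalid argument: counts must be >= 0")
  if (!length(counts) || sum(counts) == 0) {
    stop("empty table: no dissociation events for mode '", mode, "'")
  }
  if (is.null(total)) total <- sum(counts)
  if (sum(counts) != total) {
    warning("channel counts for mode '", mode, "' sum to ", sum(counts),
            " but the stated total is ", total,
            "; using the stated total as denominator")
  }
  ord <- order(-counts)
  out <- data.frame(mode = mode, channel = names(counts)[ord],
                    count = as.integer(counts[ord]),
                    percentage = round(100 * counts[ord] / total, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- total
  attr(out, "undissociated") <- undissociated
  class(out) <- c("channel_table", "data.frame")
  out
}

#' Channel probabilities from dissociation events
#'
#' Counts events per (mode, channel); undissociated runs are tallied
#' separately and excluded from the percentage denominators.
#'
#' @param events list of `dissociation_event` objects
#' @return a `channel_table`; attribute `undissociated` holds the per-mode
#'   count of runs without an event
#' @export
channel_probabilities <- function(events) {
  modes <- unique(vapply(events, function(e) e$mode, ""))
  parts <- list()
  undiss <- integer(0)
  for (m in modes) {
    ev <- Filter(function(e) identical(e$mode, m), events)
    occ <- Filter(function(e) e$occurred, ev)
    undiss[m] <- length(ev) - length(occ)
    if (!length(occ)) {
      stop("empty table: no dissociation events for mode '", m, "'")
    }
    cnt <- table(vapply(occ, function(e) e$pore_id, ""))
    parts[[m]] <- channel_table(setNames(as.integer(cnt), names(cnt)),
                                mode = m)
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "undissociated") <- undiss
  class(out) <- c("channel_table", "data.frame")
  out
}

#' @export
print.channel_table <- function(x, ...) {
  cat("channel_table (percentages per mode):\n")
  print.data.frame(x)
  u <- attr(x, "undissociated")
  if (!is.null(u) && length(u)) {
    cat("undissociated runs:",
        paste(names(u), u, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a channel table
#'
#' TSV mirrors the printed layout (mode, channel, number, possibility); CSV
#' is the machine form.
#'
#' @param tab a `channel_table`
#' @param path output file
#' @param format "tsv" or "csv"
#' @return the path invisibly
#' @export
write_channel_table <- function(tab, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(mode = tab$mode, channel = tab$channel,
                      number = tab$count,
                      possibility = sprintf("%.1f%%", tab$percentage))
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write.table(as.data.frame(tab), path, sep = ",", row.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_channel_table
#' @export
read_channel_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    out <- data.frame(mode = d$mode, channel = as.character(d$channel),
                      count = as.integer(d$number),
                      percentage = as.numeric(sub("%", "", d$possibility)),
                      stringsAsFactors = FALSE)
  } else {
    out <- read.table(path, sep = ",", header = TRUE,
                      stringsAsFactors = FALSE)
    out$channel <- as.character(out$channel)
  }
  class(out) <- c("channel_table", "data.frame")
  out
}
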