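#' Geometric interaction criteria
#'
#' Cutoff definitions for the three detectors.  The defaults follow common
#' structural-analysis practice: hydrogen bond donor-acceptor distance
#' <= 3.5 A with donor-H-acceptor angle >= 150 degrees; pi-stacking with
#' ring-centroid distance <= 5.5 A, inter-plane angle <= 30 degrees and
#' lateral centroid offset <= 2.0 A (60-90 degrees is flagged separately as
#' T-shaped); water bridges with both legs satisfying the per-leg distance
#' cutoff (3.5 A).
#'
#' @param hbond list(donors, acceptors, hydrogens = NULL,
#'   dist_cutoff = 3.5, angle_cutoff = 150); `hydrogens` is a named map
#'   donor label -> explicit H label (H inferred along donor->acceptor when
#'   absent)
#' @param pistack list(ring1, ring2, dist_cutoff = 5.5, angle_cutoff = 30,
#'   offset_cutoff = 2.0) with >= 3 labels per ring
#' @param waterbridge list(solvent, partners1, partners2, leg_cutoff = 3.5)
#' @return an object of class `interaction_spec`
#' @export
interaction_spec <- function(hbond = NULL, pistack = NULL,
                             waterbridge = NULL) {
  fill <- function(x, defaults) {
    for (k in names(defaults)) x[[k]] <- x[[k]] %||% defaults[[k]]
    x
  }
  if (!is.null(hbond)) {
    hbond <- fill(hbond, list(dist_cutoff = 3.5, angle_cutoff = 150))
    if (hbond$dist_cutoff <= 0) stop("invalid argument: cutoffs must be > 0")
  }
  if (!is.null(pistack)) {
    pistack <- fill(pistack, list(dist_cutoff = 5.5, angle_cutoff = 30,
                                  offset_cutoff = 2.0))
    if (length(pistack$ring1) < 3 || length(pistack$ring2) < 3) {
      stop("invalid argument: ring label sets need >= 3 atoms")
    }
  }
  if (!is.null(waterbridge)) {
    waterbridge <- fill(waterbridge, list(leg_cutoff = 3.5))
  }
  structure(list(hbond = hbond, pistack = pistack,
                 waterbridge = waterbridge),
            class = "interaction_spec")
}

frame_coords <- function(frame, labels, what = "label") {
  if (is.null(rownames(frame))) {
    stop("invalid argument: frame must carry row labels")
  }
  missing <- setdiff(labels, rownames(frame))
  if (length(missing)) {
    stop("invalid argument: missing ", what, " '", missing[1], "' in frame")
  }
  frame[labels, , drop = FALSE]
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in one labelled frame
#'
#' A donor-acceptor pair is bonded when the D-A distance is at most the
#' distance cutoff and the D-H-A angle at least the angle cutoff.  With no
#' explicit hydrogen the H is taken to lie along the donor-to-acceptor
#' direction (angle 180 degrees), reducing the test to the distance.
#'
#' @param frame n x 3 coordinate matrix with row labels
#' @param spec an `interaction_spec` with an `hbond` block
#' @return data.frame (donor, acceptor, distance, angle, flag)
#' @export
detect_hbond <- function(frame, spec) {
  h <- spec$hbond
  if (is.null(h)) stop("invalid argument: spec has no hbond block")
  pairs <- expand.grid(donor = h$donors, acceptor = h$acceptors,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    dpos <- frame_coords(frame, pairs$donor[i], "donor")[1, ]
    apos <- frame_coords(frame, pairs$acceptor[i], "acceptor")[1, ]
    dist <- sqrt(sum((dpos - apos)^2))
    hl <- h$hydrogens[[pairs$donor[i]]]
    ang <- if (!is.null(hl)) {
      hpos <- frame_coords(frame, hl, "hydrogen")[1, ]
      vec_angle(dpos - hpos, apos - hpos)
    } else 180
    data.frame(donor = pairs$donor[i], acceptor = pairs$acceptor[i],
               distance = dist, angle = ang,
               flag = dist <= h$dist_cutoff && ang >= h$angle_cutoff)
  })
  do.call(rbind, res)
}

ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12)) {
    stop("geometry error: ring atoms are (near-)collinear")
  }
  planarity <- sqrt(mean((centered %*% sv$v[, 3])^2))
  list(centroid = centroid, normal = sv$v[, 3], planarity = planarity)
}

#' Detect pi-stacking between two labelled rings
#'
#' Parallel stacking: centroid distance at most the cutoff, inter-plane
#' angle at most the angle cutoff, and lateral centroid offset (the
#' centroid-to-centroid component perpendicular to the mean ring normal) at
#' most the offset cutoff.  Pairs in the 60-90 degree band within the
#' distance cutoff are flagged separately as T-shaped.  Symmetric in ring
#' order.
#'
#' @param frame n x 3 coordinate matrix with row labels
#' @param spec an `interaction_spec` with a `pistack` block
#' @return data.frame (distance, plane_angle, offset, flag, t_shaped)
#' @export
detect_pistack <- function(frame, spec) {
  p <- spec$pistack
  if (is.null(p)) stop("invalid argument: spec has no pistack block")
  g1 <- ring_geometry(frame_coords(frame, p$ring1, "ring atom"))
  g2 <- ring_geometry(frame_coords(frame, p$ring2, "ring atom"))
  dvec <- g2$centroid - g1$centroid
  dist <- sqrt(sum(dvec^2))
  ang <- vec_angle(g1$normal, g2$normal)
  if (ang > 90) ang <- 180 - ang  # normals are sign-ambiguous
  # symmetrised lateral offset: average the offsets w.r.t. both normals
  off1 <- sqrt(max(0, dist^2 - sum(dvec * g1$normal)^2))
  off2 <- sqrt(max(0, dist^2 - sum(dvec * g2$normal)^2))
  offset <- (off1 + off2) / 2
  data.frame(distance = dist, plane_angle = ang, offset = offset,
             flag = dist <= p$dist_cutoff && ang <= p$angle_cutoff &&
               offset <= p$offset_cutoff,
             t_shaped = dist <= p$dist_cutoff && ang >= 60 && ang <= 90)
}

#' Detect single-water bridges
#'
#' A (partner1, water, partner2) triple forms a bridge when the one water
#' site is simultaneously within the per-leg cutoff of both partners.
#' Two-water chains are outside this definition.
#'
#' @param frame n x 3 coordinate matrix with row labels
#' @param spec an `interaction_spec` with a `waterbridge` block
#' @return data.frame (partner1, solvent, partner2, d1, d2, flag)
#' @export
detect_waterbridge <- function(frame, spec) {
  w <- spec$waterbridge
  if (is.null(w)) stop("invalid argument: spec has no waterbridge block")
  triples <- expand.grid(partner1 = w$partners1, solvent = w$solvent,
                         partner2 = w$partners2, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(triples)), function(i) {
    p1 <- frame_coords(frame, triples$partner1[i])[1, ]
    sv <- frame_coords(frame, triples$solvent[i])[1, ]
    p2 <- frame_coords(frame, triples$partner2[i])[1, ]
    d1 <- sqrt(sum((p1 - sv)^2))
    d2 <- sqrt(sum((p2 - sv)^2))
    data.frame(partner1 = triples$partner1[i], solvent = triples$solvent[i],
               partner2 = triples$partner2[i], d1 = d1, d2 = d2,
               flag = d1 <= w$leg_cutoff && d2 <= w$leg_cutoff)
  })
  do.call(rbind, res)
}

labelled_frames <- function(traj) {
  if (is.null(traj$labels)) {
    stop("invalid argument: trajectory has no bead labels")
  }
  lapply(traj$frames, function(m) {
    rownames(m) <- traj$labels
    m
  })
}

#' Per-frame interaction occupancy over a trajectory
#'
#' Runs every detector block of the spec on each frame and aggregates
#' per-partner occupancy fractions and the per-frame interaction count.
#'
#' @param traj an `egress_trajectory` with bead labels
#' @param spec an `interaction_spec`
#' @return an object of class `occupancy_series`: `$flags` (frame, type,
#'   partner, flag), `$occupancy` (type, partner, occupancy), `$counts`
#'   (per-frame totals)
#' @export
occupancy_series <- function(traj, spec) {
  frames <- labelled_frames(traj)
  rows <- list()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    got <- tryCatch({
      out <- list()
      if (!is.null(spec$hbond)) {
        hb <- detect_hbond(fr, spec)
        out$hbond <- data.frame(frame = f, type = "hbond",
                                partner = paste(hb$donor, hb$acceptor,
                                                sep = ":"),
                                flag = hb$flag)
      }
      if (!is.null(spec$pistack)) {
        ps <- detect_pistack(fr, spec)
        out$pistack <- data.frame(frame = f, type = "pistack",
                                  partner = "ring1:ring2", flag = ps$flag)
      }
      if (!is.null(spec$waterbridge)) {
        wb <- detect_waterbridge(fr, spec)
        out$waterbridge <- data.frame(
          frame = f, type = "waterbridge",
          partner = paste(wb$partner1, wb$solvent, wb$partner2, sep = ":"),
          flag = wb$flag)
      }
      do.call(rbind, out)
    }, error = function(e) {
      stop("detector failure at frame ", f, ": ", conditionMessage(e))
    })
    rows[[f]] <- got
  }
  flags <- do.call(rbind, rows)
  rownames(flags) <- NULL
  occ <- aggregate(flag ~ type + partner, flags, mean)
  names(occ)[names(occ) == "flag"] <- "occupancy"
  counts <- aggregate(flag ~ frame, flags, sum)
  names(counts)[names(counts) == "flag"] <- "count"
  structure(list(flags = flags, occupancy = occ, counts = counts),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat("occupancy_series over", max(x$flags$frame), "frames:\n")
  print.data.frame(x$occupancy)
  invisible(x)
}

#' Windowed running mean of a per-frame count series
#'
#' @param counts data.frame (frame, count) as in an `occupancy_series`
#' @param width smoothing window (frames, odd)
#' @return the data.frame with an added `smoothed` column
#' @export
smooth_counts <- function(counts, width = 5) {
  k <- rep(1 / width, width)
  n <- nrow(counts)
  pad <- c(rep(counts$count[1], width %/% 2), counts$count,
           rep(counts$count[n], width %/% 2))
  counts$smoothed <- stats::filter(pad, k, sides = 2)[
    (width %/% 2 + 1):(width %/% 2 + n)]
  counts
}

#' Group-COM to reference distance series
#'
#' Per-frame Euclidean distance between the centre of mass of a labelled
#' group and a reference point (a label or a fixed coordinate).
#'
#' @param traj an `egress_trajectory` with bead labels
#' @param group character vector of bead labels
#' @param reference a single label or a numeric 3-vector
#' @param masses optional per-bead masses for the COM (default: equal)
#' @return numeric vector of distances, Angstrom
#' @export
distance_series <- function(traj, group, reference, masses = NULL) {
  frames <- labelled_frames(traj)
  vapply(frames, function(fr) {
    g <- frame_coords(fr, group, "group label")
    m <- masses %||% rep(1, nrow(g))
    com <- colSums(g * m) / sum(m)
    ref <- if (is.character(reference)) {
      frame_coords(fr, reference, "reference label")[1, ]
    } else reference
    sqrt(sum((com - ref)^2))
  }, 0)
}

#' Write occupancy results as CSV
#'
#' @param series an `occupancy_series`
#' @param flags_path per-frame flag CSV (frame, type, partner, flag)
#' @param summary_path summary CSV (type, partner, occupancy)
#' @export
write_occupancy <- function(series, flags_path, summary_path) {
  write.table(series$flags, flags_path, sep = ",", row.names = FALSE,
              quote = FALSE)
  write.table(series$occupancy, summary_path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(series)
}
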