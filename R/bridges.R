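#' Identify water bridges
#'
#' A water molecule bridges the two solutes in a frame when it holds at
#' least one qualifying hydrogen bond (in either donor or acceptor role) to
#' `solute_A` and at least one to `solute_B` in that frame. For mapping and
#' duration purposes each bridge contributes the (A atom, B atom) heavy-atom
#' pairs it joins.
#'
#' @param hbonds Per-frame bond table from [hbond_trajectory()] computed
#'   without a group filter (water bonds must be present).
#' @param topology The matching [topology()] object.
#' @return A list with `bridges` (one row per water per frame: `frame`,
#'   `time_ps`, `water`, `n_bonds_A`, `n_bonds_B`, `n_donor_role`,
#'   `n_acceptor_role`) and `pairs` (one row per joined A/B atom pair per
#'   bridge: `frame`, `time_ps`, `water`, `atom_A`, `atom_B`).
#' @export
find_water_bridges <- function(hbonds, topology) {
  g <- topology$groups
  wk <- .residue_key(topology$atoms)
  is_w <- seq_len(nrow(topology$atoms)) %in% g$water

  # side of each bond: which solute heavy atom and which water residue
  don_w <- is_w[hbonds$donor_heavy]
  acc_w <- is_w[hbonds$acceptor]
  partner <- ifelse(don_w, hbonds$acceptor, hbonds$donor_heavy)
  water_atom <- ifelse(don_w, hbonds$donor_heavy, hbonds$acceptor)
  touches_water <- xor(don_w, acc_w)  # water-water bonds are not bridges
  to_A <- touches_water & partner %in% g$solute_A
  to_B <- touches_water & partner %in% g$solute_B
  keep <- to_A | to_B
  empty_b <- data.frame(frame = integer(0), time_ps = numeric(0),
                        water = character(0), n_bonds_A = integer(0),
                        n_bonds_B = integer(0), n_donor_role = integer(0),
                        n_acceptor_role = integer(0))
  empty_p <- data.frame(frame = integer(0), time_ps = numeric(0),
                        water = character(0), atom_A = integer(0),
                        atom_B = integer(0))
  if (!any(keep)) return(list(bridges = empty_b, pairs = empty_p))

  wb <- data.frame(
    frame = hbonds$frame[keep], time_ps = hbonds$time_ps[keep],
    water = wk[water_atom[keep]], partner = partner[keep],
    side = ifelse(to_A[keep], "A", "B"),
    water_donates = don_w[keep]
  )
  bridges <- list(); pairs <- list()
  for (grp in split(wb, list(wb$frame, wb$water), drop = TRUE)) {
    a_rows <- grp[grp$side == "A", ]; b_rows <- grp[grp$side == "B", ]
    if (nrow(a_rows) == 0L || nrow(b_rows) == 0L) next
    bridges[[length(bridges) + 1L]] <- data.frame(
      frame = grp$frame[1], time_ps = grp$time_ps[1], water = grp$water[1],
      n_bonds_A = nrow(a_rows), n_bonds_B = nrow(b_rows),
      n_donor_role = sum(grp$water_donates),
      n_acceptor_role = sum(!grp$water_donates))
    pairs[[length(pairs) + 1L]] <- cbind(
      expand.grid(atom_A = unique(a_rows$partner), atom_B = unique(b_rows$partner)),
      frame = grp$frame[1], time_ps = grp$time_ps[1], water = grp$water[1])
  }
  if (length(bridges) == 0L) return(list(bridges = empty_b, pairs = empty_p))
  bridges <- do.call(rbind, bridges)
  bridges <- bridges[order(bridges$frame, bridges$water), , drop = FALSE]
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$frame, pairs$water, pairs$atom_A, pairs$atom_B),
                 c("frame", "time_ps", "water", "atom_A", "atom_B")]
  rownames(bridges) <- rownames(pairs) <- NULL
  list(bridges = bridges, pairs = pairs)
}

#' Per-frame hydrogen-bond and bridge counts
#'
#' One row per frame with the raw number of (deduplicated donor/acceptor)
#' direct bonds and of water bridges; frames with no detections report zero.
#' An optional centered moving average is added as separate columns and
#' never alters the raw counts.
#'
#' @param direct Bond table restricted to the solute A/B filter.
#' @param bridges `bridges` element of [find_water_bridges()] (or `NULL`).
#' @param n_frames,times Frame count and times (ps) of the trajectory.
#' @param window Odd integer width for moving-average smoothing, or `NULL`.
#' @return data.frame with `frame`, `time_ns`, `n_hbonds`, `n_bridges`
#'   (and `n_hbonds_smooth`, `n_bridges_smooth` when `window` is set).
#' @export
hbond_timeseries <- function(direct, bridges = NULL, n_frames,
                             times = seq_len(n_frames) - 1, window = NULL) {
  stopifnot(n_frames >= 0, length(times) == n_frames)
  out <- data.frame(frame = seq_len(n_frames), time_ns = times / 1000)
  out$n_hbonds <- tabulate(direct$frame, nbins = n_frames)
  out$n_bridges <- if (is.null(bridges) || nrow(bridges) == 0L) {
    rep(0L, n_frames)
  } else {
    tabulate(bridges$frame, nbins = n_frames)
  }
  if (!is.null(window)) {
    stopifnot(window >= 1, window %% 2 == 1)
    out$n_hbonds_smooth <- .moving_average(out$n_hbonds, window)
    out$n_bridges_smooth <- .moving_average(out$n_bridges, window)
  }
  out
}

.moving_average <- function(x, w) {
  half <- (w - 1) / 2
  vapply(seq_along(x), function(i) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Reduce a bond table to per-frame unique heavy-atom pairs oriented as
# (A-side atom, B-side atom).
.hbond_pairs <- function(hbonds, topology) {
  if (nrow(hbonds) == 0L) {
    return(data.frame(frame = integer(0), atom_A = integer(0), atom_B = integer(0)))
  }
  in_A <- hbonds$donor_heavy %in% topology$groups$solute_A
  d <- data.frame(
    frame = hbonds$frame,
    atom_A = ifelse(in_A, hbonds$donor_heavy, hbonds$acceptor),
    atom_B = ifelse(in_A, hbonds$acceptor, hbonds$donor_heavy))
  unique(d)
}

#' Build a unique-pair contact map
#'
#' Counts, over the whole trajectory, the frames in which each unique
#' (A atom, B atom) pair is present; a pair appearing several times within
#' one frame is treated as a single bond. Percentages are relative to the
#' total number of pair-frame incidences, mirroring the percentage legends
#' of per-pair interaction maps.
#'
#' @param pairs data.frame with columns `frame`, `atom_A`, `atom_B` —
#'   either from [hbond_pairs_of()] for direct bonds or the `pairs` element
#'   of [find_water_bridges()].
#' @param topology The matching [topology()] object.
#' @return data.frame of class `"contact_map"`: `label_A`, `label_B`,
#'   `count`, `percent`, ordered by decreasing count then labels; attribute
#'   `total` carries the denominator.
#' @export
build_contact_map <- function(pairs, topology) {
  pairs <- unique(pairs[, c("frame", "atom_A", "atom_B")])
  if (nrow(pairs) == 0L) {
    out <- data.frame(label_A = character(0), label_B = character(0),
                      count = integer(0), percent = numeric(0))
    attr(out, "total") <- 0L
    class(out) <- c("contact_map", class(out))
    return(out)
  }
  key <- paste(pairs$atom_A, pairs$atom_B)
  tab <- table(key)
  idx <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(
    label_A = atom_label(topology, as.integer(idx[, 1])),
    label_B = atom_label(topology, as.integer(idx[, 2])),
    count = as.integer(tab))
  total <- sum(out$count)
  out$percent <- 100 * out$count / total
  out <- out[order(-out$count, out$label_A, out$label_B), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  class(out) <- c("contact_map", class(out))
  out
}

#' Per-frame unique A/B pairs of a direct-bond table
#'
#' @inheritParams build_contact_map
#' @param hbonds Bond table restricted to the solute A/B filter.
#' @return data.frame with `frame`, `atom_A`, `atom_B`.
#' @export
hbond_pairs_of <- function(hbonds, topology) .hbond_pairs(hbonds, topology)

#' Occupancy-based duration statistics
#'
#' The duration of a pair is estimated by counting the frames in which it is
#' present: `occupancy_ns = occupancy_frames * snapshot interval`. The
#' longest contiguous run is reported alongside as a labeled extra, never
#' substituted for the occupancy estimator.
#'
#' @param pairs data.frame with `frame`, `atom_A`, `atom_B` (direct-bond
#'   pairs or bridge pairs).
#' @param topology The matching [topology()] object.
#' @param interval_ns Snapshot spacing in ns (required; no default).
#' @param n_frames Trajectory length in frames.
#' @param times Optional frame times (ps); if given, they must be uniformly
#'   spaced or an error instructs resampling.
#' @return data.frame: `label_A`, `label_B`, `occupancy_frames`,
#'   `occupancy_ns`, `longest_run_ns`, `first_frame`, `last_frame`, ordered
#'   by decreasing occupancy.
#' @export
duration_stats <- function(pairs, topology, interval_ns, n_frames, times = NULL) {
  stopifnot(is.numeric(interval_ns), interval_ns > 0, n_frames >= 1)
  if (!is.null(times) && length(times) > 2L) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-9 * max(abs(times), 1)) {
      stop("frame times are not uniformly spaced; resample the trajectory ",
           "to a fixed snapshot interval before computing durations",
           call. = FALSE)
    }
  }
  pairs <- unique(pairs[, c("frame", "atom_A", "atom_B")])
  if (nrow(pairs) == 0L) {
    return(data.frame(label_A = character(0), label_B = character(0),
                      occupancy_frames = integer(0), occupancy_ns = numeric(0),
                      longest_run_ns = numeric(0), first_frame = integer(0),
                      last_frame = integer(0)))
  }
  key <- paste(pairs$atom_A, pairs$atom_B)
  res <- lapply(split(pairs$frame, key), function(fr) {
    present <- seq_len(n_frames) %in% fr
    runs <- rle(present)
    data.frame(occupancy_frames = length(fr),
               occupancy_ns = length(fr) * interval_ns,
               longest_run_ns = max(runs$lengths[runs$values]) * interval_ns,
               first_frame = min(fr), last_frame = max(fr))
  })
  idx <- do.call(rbind, strsplit(names(res), " "))
  out <- cbind(
    data.frame(label_A = atom_label(topology, as.integer(idx[, 1])),
               label_B = atom_label(topology, as.integer(idx[, 2]))),
    do.call(rbind, res))
  out <- out[order(-out$occupancy_frames, out$label_A, out$label_B), , drop = FALSE]
  rownames(out) <- NULL
  out
}
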