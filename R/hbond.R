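#' Hydrogen-bond scoring parameters
#'
#' The energy of a donor-hydrogen...acceptor contact is
#' \deqn{E = E_{opt} \cdot \frac{d_0 - \max(d_{HA}, d_c)}{d_0 - d_c}
#'        \cdot S_{DHA} \cdot S_{HAX}}
#' with the hydrogen-acceptor distance clamped below `d_clamp` and vanishing
#' at `d_zero`, multiplied by two piecewise-linear angular scaling factors:
#' `S_DHA` ramps over the donor-hydrogen-acceptor angle between
#' `dha_ramp[1]` and `dha_ramp[2]` degrees, and `S_HAX` ramps over the
#' hydrogen-acceptor-X angle (X the atom covalently bound to the acceptor)
#' between `hax_heavy_ramp` degrees for a heavy X, or `hax_hydrogen_ramp`
#' for a hydrogen X, where slightly smaller angles are allowed. A bond is
#' reported when its energy strictly exceeds `threshold_energy`, one quarter
#' of the optimum by default.
#'
#' @param optimum_energy Maximum bond energy, kJ/mol (default 25).
#' @param threshold_energy Detection threshold, kJ/mol (default 6.25).
#' @param d_clamp,d_zero Distance clamp and zero-energy distance, Angstrom
#'   (defaults 2.1 and 2.6).
#' @param dha_ramp,hax_heavy_ramp,hax_hydrogen_ramp Lower/upper ramp
#'   breakpoints in degrees (defaults 100-165, 85-95, 75-85).
#' @return A list of class `"hbond_params"`.
#' @export
hbond_params <- function(optimum_energy = 25, threshold_energy = 6.25,
                         d_clamp = 2.1, d_zero = 2.6,
                         dha_ramp = c(100, 165),
                         hax_heavy_ramp = c(85, 95),
                         hax_hydrogen_ramp = c(75, 85)) {
  stopifnot(
    optimum_energy > 0, threshold_energy > 0,
    threshold_energy < optimum_energy,
    d_clamp > 0, d_clamp < d_zero,
    length(dha_ramp) == 2, dha_ramp[1] < dha_ramp[2],
    length(hax_heavy_ramp) == 2, hax_heavy_ramp[1] < hax_heavy_ramp[2],
    length(hax_hydrogen_ramp) == 2, hax_hydrogen_ramp[1] < hax_hydrogen_ramp[2]
  )
  structure(list(
    optimum_energy = optimum_energy, threshold_energy = threshold_energy,
    d_clamp = d_clamp, d_zero = d_zero, dha_ramp = dha_ramp,
    hax_heavy_ramp = hax_heavy_ramp, hax_hydrogen_ramp = hax_hydrogen_ramp
  ), class = "hbond_params")
}

.check_angle <- function(angle, what) {
  if (any(!is.finite(angle)) || any(angle < 0 | angle > 180)) {
    stop(what, " angle outside [0, 180] degrees", call. = FALSE)
  }
}

.ramp <- function(angle, lo, hi) pmin(1, pmax(0, (angle - lo) / (hi - lo)))

#' Donor-hydrogen-acceptor scaling factor
#'
#' 0 at or below the lower breakpoint, 1 at or above the upper, linear in
#' between (default ramp 100 to 165 degrees). Vectorized over `angle`.
#'
#' @param angle Angle in degrees, in \[0, 180\].
#' @param params An [hbond_params()] object.
#' @return Value(s) in \[0, 1\].
#' @export
scale_dha <- function(angle, params = hbond_params()) {
  .check_angle(angle, "donor-hydrogen-acceptor")
  .ramp(angle, params$dha_ramp[1], params$dha_ramp[2])
}

#' Hydrogen-acceptor-X scaling factor
#'
#' X is an atom covalently bound to the acceptor. The ramp runs 85 to 95
#' degrees for a heavy X and 75 to 85 degrees for a hydrogen X. Vectorized
#' over `angle` and `x_is_hydrogen`.
#'
#' @param angle Angle in degrees, in \[0, 180\].
#' @param x_is_hydrogen Logical: is X a hydrogen atom?
#' @param params An [hbond_params()] object.
#' @return Value(s) in \[0, 1\].
#' @export
scale_hax <- function(angle, x_is_hydrogen = FALSE, params = hbond_params()) {
  .check_angle(angle, "hydrogen-acceptor-X")
  n <- max(length(angle), length(x_is_hydrogen))
  angle <- rep_len(angle, n)
  x_is_hydrogen <- rep_len(x_is_hydrogen, n)
  ifelse(x_is_hydrogen,
         .ramp(angle, params$hax_hydrogen_ramp[1], params$hax_hydrogen_ramp[2]),
         .ramp(angle, params$hax_heavy_ramp[1], params$hax_heavy_ramp[2]))
}

#' Hydrogen-bond energy of a probe geometry
#'
#' Evaluates the scoring function for given hydrogen-acceptor distance and
#' the two angles; vectorized over all geometry arguments. The distance term
#' is clamped at `d_clamp` (any closer approach scores as optimal) and
#' becomes non-positive at or beyond `d_zero`.
#'
#' @param dist_ha Hydrogen-acceptor distance, Angstrom (> 0).
#' @param angle_dha Donor-hydrogen-acceptor angle, degrees.
#' @param angle_hax Hydrogen-acceptor-X angle, degrees.
#' @param x_is_hydrogen Logical: is X a hydrogen atom?
#' @param params An [hbond_params()] object.
#' @return Energy in kJ/mol (can be <= 0 for distances at/beyond `d_zero`).
#' @examples
#' hbond_energy(2.0, 180, 180)   # optimum: 25 kJ/mol
#' hbond_energy(2.35, 180, 180)  # half of optimum
#' @export
hbond_energy <- function(dist_ha, angle_dha, angle_hax,
                         x_is_hydrogen = FALSE, params = hbond_params()) {
  stopifnot(all(dist_ha > 0))
  dist_term <- (params$d_zero - pmax(dist_ha, params$d_clamp)) /
    (params$d_zero - params$d_clamp)
  params$optimum_energy * dist_term *
    scale_dha(angle_dha, params) *
    scale_hax(angle_hax, x_is_hydrogen, params)
}

# atan2 form: full precision at 0 and 180 degrees, where acos degrades
.vec_angle <- function(u, v) {
  cross <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cross * cross)), sum(u * v)) * 180 / pi
}

# angle at vertex b formed by points a-b-c (degrees)
.point_angle <- function(a, b, c) .vec_angle(a - b, c - b)

#' Detect hydrogen bonds in one frame
#'
#' Enumerates (donor hydrogen, acceptor) candidates within the `d_zero`
#' spatial prefilter, scores each with [hbond_energy()], and keeps contacts
#' whose energy strictly exceeds the detection threshold. For each candidate
#' the X atom is the acceptor's covalent partner that minimizes the
#' hydrogen-acceptor-X scaling factor; an acceptor with no covalent partner
#' scores that factor as 1. Pairs where the donor heavy atom is the acceptor
#' itself are excluded.
#'
#' @param topology A [topology()] object with covalent adjacency.
#' @param xyz n-by-3 coordinate matrix, Angstrom.
#' @param roles A [classify_polar_roles()] result (computed if `NULL`).
#' @param params An [hbond_params()] object.
#' @param between `NULL` for all bonds, or a character pair of group names
#'   (e.g. `c("solute_A", "solute_B")`) restricting donor/acceptor group
#'   membership.
#' @param direction `"either"` (default) accepts both orientations of
#'   `between`; `"forward"` requires donor in `between[1]` and acceptor in
#'   `between[2]`.
#' @param one_per_acceptor If `TRUE`, keep for each acceptor only the single
#'   contact with the smallest hydrogen-acceptor-X scaling factor (a strict
#'   reading of one-bond-per-acceptor); the default keeps every
#'   above-threshold contact.
#' @return data.frame with one row per bond: indices (`donor_heavy`,
#'   `hydrogen`, `acceptor`, `chosen_X`), `x_is_hydrogen`, geometry
#'   (`dist_HA`, `angle_DHA`, `angle_HAX`), scaling factors and `energy`.
#' @export
detect_hbonds <- function(topology, xyz, roles = NULL, params = hbond_params(),
                          between = NULL, direction = c("either", "forward"),
                          one_per_acceptor = FALSE) {
  direction <- match.arg(direction)
  if (is.null(roles)) roles <- classify_polar_roles(topology)
  out <- .score_all_hbonds(topology, xyz, roles, params, prefilter = TRUE)
  out <- out[out$energy > params$threshold_energy, , drop = FALSE]
  if (!is.null(between)) {
    stopifnot(length(between) == 2, all(between %in% names(topology$groups)))
    g1 <- topology$groups[[between[1]]]
    g2 <- topology$groups[[between[2]]]
    fwd <- out$donor_heavy %in% g1 & out$acceptor %in% g2
    keep <- if (direction == "forward") fwd
      else fwd | (out$donor_heavy %in% g2 & out$acceptor %in% g1)
    out <- out[keep, , drop = FALSE]
  }
  if (one_per_acceptor && nrow(out) > 0L) {
    ord <- order(out$acceptor, out$scale_HAX, -out$energy)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$acceptor), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$donor_heavy, out$hydrogen, out$acceptor), , drop = FALSE]
}

# Scores every (donor hydrogen, acceptor) candidate. With prefilter = FALSE
# every pair is evaluated regardless of distance (used by the brute-force
# cross-check in the test-suite through detect_hbonds' internals).
.score_all_hbonds <- function(topology, xyz, roles, params, prefilter = TRUE) {
  donors <- roles$donors
  acceptors <- roles$acceptors
  el <- topology$atoms$element
  empty <- data.frame(
    donor_heavy = integer(0), hydrogen = integer(0), acceptor = integer(0),
    chosen_X = integer(0), x_is_hydrogen = logical(0),
    dist_HA = numeric(0), angle_DHA = numeric(0), angle_HAX = numeric(0),
    scale_DHA = numeric(0), scale_HAX = numeric(0), energy = numeric(0)
  )
  if (nrow(donors) == 0L || length(acceptors) == 0L) return(empty)

  rows <- vector("list", nrow(donors))
  for (k in seq_len(nrow(donors))) {
    dh <- donors[k, 1]; hy <- donors[k, 2]
    acc <- acceptors[acceptors != dh & acceptors != hy]
    if (length(acc) == 0L) next
    dv <- xyz[acc, , drop = FALSE] -
      matrix(xyz[hy, ], nrow = length(acc), ncol = 3, byrow = TRUE)
    d_ha <- sqrt(rowSums(dv * dv))
    if (prefilter) {
      sel <- d_ha < params$d_zero
      acc <- acc[sel]; d_ha <- d_ha[sel]
      if (length(acc) == 0L) next
    }
    res <- lapply(seq_along(acc), function(m) {
      a <- acc[m]
      ang_dha <- .point_angle(xyz[dh, ], xyz[hy, ], xyz[a, ])
      xs <- .bonded_partners(topology, a)
      xs <- xs[xs != hy]
      if (length(xs) == 0L) {
        cx <- NA_integer_; xh <- FALSE; ang_hax <- 180; s_hax <- 1
      } else {
        angs <- vapply(xs, function(x) .point_angle(xyz[hy, ], xyz[a, ], xyz[x, ]),
                       numeric(1))
        xhs <- el[xs] == "H"
        scl <- scale_hax(angs, xhs, params)
        j <- which.min(scl)
        cx <- xs[j]; xh <- xhs[j]; ang_hax <- angs[j]; s_hax <- scl[j]
      }
      s_dha <- scale_dha(ang_dha, params)
      data.frame(
        donor_heavy = dh, hydrogen = hy, acceptor = a, chosen_X = cx,
        x_is_hydrogen = xh, dist_HA = d_ha[m], angle_DHA = ang_dha,
        angle_HAX = ang_hax, scale_DHA = s_dha, scale_HAX = s_hax,
        energy = params$optimum_energy *
          (params$d_zero - pmax(d_ha[m], params$d_clamp)) /
          (params$d_zero - params$d_clamp) * s_dha * s_hax
      )
    })
    rows[[k]] <- do.call(rbind, res)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Detect hydrogen bonds across a trajectory
#'
#' Applies [detect_hbonds()] to every frame and binds the results with
#' `frame` and `time_ps` columns prepended.
#'
#' @param traj A [trajectory()] object.
#' @param ... Passed on to [detect_hbonds()].
#' @inheritParams detect_hbonds
#' @return data.frame of per-frame bond records.
#' @export
hbond_trajectory <- function(traj, roles = NULL, params = hbond_params(), ...) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(roles)) roles <- classify_polar_roles(traj$topology)
  res <- lapply(seq_along(traj$frames), function(i) {
    b <- detect_hbonds(traj$topology, traj$frames[[i]], roles, params, ...)
    if (nrow(b) == 0L) return(NULL)
    cbind(frame = i, time_ps = traj$times[i], b)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    empty <- .score_all_hbonds(traj$topology, traj$frames[[1]],
                               structure(list(donors = matrix(integer(0), ncol = 2),
                                              acceptors = integer(0)),
                                         class = "polar_roles"),
                               params)
    return(cbind(frame = integer(0), time_ps = numeric(0), empty))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a per-frame bond table as CSV
#'
#' Adds human-readable serial/name/residue columns for donor, hydrogen,
#' acceptor and X, and writes a comma-separated file with "." decimals,
#' header row and LF line endings.
#'
#' @param hbonds Output of [hbond_trajectory()].
#' @param topology The matching [topology()] object.
#' @param path Output CSV path.
#' @return The annotated data.frame, invisibly.
#' @export
write_hbond_csv <- function(hbonds, topology, path) {
  a <- topology$atoms
  lab <- function(idx, prefix) {
    d <- data.frame(
      serial = ifelse(is.na(idx), NA_integer_, a$serial[idx]),
      label = ifelse(is.na(idx), NA_character_, atom_label(topology, idx)))
    names(d) <- paste0(prefix, "_", names(d))
    d
  }
  out <- cbind(
    hbonds[, c("frame", "time_ps")],
    lab(hbonds$donor_heavy, "donor"), lab(hbonds$hydrogen, "hydrogen"),
    lab(hbonds$acceptor, "acceptor"), lab(hbonds$chosen_X, "X"),
    hbonds[, c("dist_HA", "angle_DHA", "angle_HAX",
               "scale_DHA", "scale_HAX", "energy")]
  )
  .write_csv_atomic(out, path)
  invisible(out)
}
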