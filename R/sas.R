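#' Solvent-accessible-surface parameters
#'
#' The solvent-accessible surface is the set of points the center of a
#' spherical water probe (the water oxygen nucleus) can reach while rolling
#' over the van der Waals surface of the solute. It is estimated by the
#' Shrake-Rupley method: each atom's expanded sphere (vdW radius + probe) is
#' sampled on a deterministic golden-angle spiral, and a sample point is
#' accessible when it lies outside every other selected atom's expanded
#' sphere.
#'
#' @param probe_radius Probe radius in Angstrom (default 1.4, water oxygen).
#' @param n_sphere_points Sample points per atom (default 960, >= 32).
#' @param radii Named numeric vector mapping element symbols to van der
#'   Waals radii (Angstrom); defaults to the Bondi set shipped with the
#'   package (`inst/extdata/bondi_radii.txt`).
#' @return A list of class `"sas_params"`.
#' @export
sas_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                       radii = default_vdw_radii()) {
  stopifnot(probe_radius > 0, n_sphere_points >= 32, all(radii > 0),
            !is.null(names(radii)))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii = radii), class = "sas_params")
}

#' Default van der Waals radii (Bondi)
#'
#' Read from the plain-text table shipped with the package.
#'
#' @return Named numeric vector, Angstrom.
#' @export
default_vdw_radii <- function() {
  path <- system.file("extdata", "bondi_radii.txt", package = "wbridge")
  if (path == "") path <- file.path("inst", "extdata", "bondi_radii.txt")
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stats::setNames(tab$radius, toupper(tab$element))
}

# Deterministic golden-angle spiral on the unit sphere: no RNG involved.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of an atom selection
#'
#' @param topology A [topology()] object.
#' @param xyz n-by-3 coordinate matrix, Angstrom.
#' @param selection Integer vector of atom indices (the solute; waters and
#'   ions are typically excluded).
#' @param params A [sas_params()] object.
#' @return Total area in Angstrom squared; attribute `per_atom` carries the
#'   per-atom accessible fractions for inspection.
#' @export
sas_of_selection <- function(topology, xyz, selection, params = sas_params()) {
  stopifnot(inherits(topology, "topology"), length(selection) >= 1L)
  el <- topology$atoms$element[selection]
  r <- params$radii[el]
  if (any(is.na(r))) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r_exp <- unname(r) + params$probe_radius
  pos <- xyz[selection, , drop = FALSE]
  pts <- .sphere_points(params$n_sphere_points)
  n_sel <- length(selection)
  frac <- numeric(n_sel)
  for (i in seq_len(n_sel)) {
    # neighbors whose expanded sphere can reach atom i's expanded sphere
    dvec <- sweep(pos, 2, pos[i, ])
    d2 <- rowSums(dvec * dvec)
    nb <- which(d2 < (r_exp + r_exp[i])^2)
    nb <- nb[nb != i]
    p <- sweep(pts * r_exp[i], 2, pos[i, ], "+")
    accessible <- rep(TRUE, nrow(p))
    for (j in nb) {
      dj <- sweep(p, 2, pos[j, ])
      accessible <- accessible & rowSums(dj * dj) > r_exp[j]^2
      if (!any(accessible)) break
    }
    frac[i] <- mean(accessible)
  }
  area <- sum(frac * 4 * pi * r_exp^2)
  attr(area, "per_atom") <- frac
  area
}

#' Solvent-accessible surface time series
#'
#' @param traj A [trajectory()] object.
#' @param selection Atom indices of the tracked solute group.
#' @param params A [sas_params()] object.
#' @return data.frame with `frame`, `time_ns`, `area_A2`.
#' @export
sas_timeseries <- function(traj, selection, params = sas_params()) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$frames)
  data.frame(
    frame = seq_len(n),
    time_ns = traj$times / 1000,
    area_A2 = vapply(traj$frames, function(f)
      as.numeric(sas_of_selection(traj$topology, f, selection, params)),
      numeric(1)))
}
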