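# Synthetic fixture systems with planted, manifest-recorded ground truth.
# Frames differ by seeded rigid-body motion of the whole system, which the
# scoring function is invariant to, so planted energies hold across frames.

.unit <- function(v) v / sqrt(sum(v * v))

.perp_unit <- function(u) {
  e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(e - sum(e * u) * u)
}

# Place an acceptor A and its covalent partner X realizing the requested
# hydrogen-acceptor distance and D-H-A / H-A-X angles for a donor at D with
# hydrogen at H. All construction stays in the plane spanned by the D-H
# axis and one perpendicular.
.plant_acceptor <- function(D, H, dist_ha, angle_dha, angle_hax, r_ax) {
  u <- .unit(H - D)
  p <- .perp_unit(u)
  a_dha <- angle_dha * pi / 180
  v <- cos(a_dha) * (-u) + sin(a_dha) * p
  A <- H + dist_ha * v
  a_hax <- angle_hax * pi / 180
  q_raw <- u - sum(u * v) * v
  q <- if (sqrt(sum(q_raw * q_raw)) < 1e-8) .perp_unit(v) else .unit(q_raw)
  w <- cos(a_hax) * (-v) + sin(a_hax) * q
  X <- A + r_ax * w
  list(A = A, X = X)
}

#' Build a four-atom donor-hydrogen-acceptor-X probe system
#'
#' Constructs coordinates realizing exactly the requested hydrogen-acceptor
#' distance, donor-hydrogen-acceptor angle and hydrogen-acceptor-X angle,
#' with the donor/hydrogen pair as `solute_A` and the acceptor/X pair as
#' `solute_B`. The realized geometry is recomputed from the coordinates and
#' must match the request to 1e-6 (an unrealizable request, e.g. one that
#' collapses two atoms, errors instead).
#'
#' @param dist_ha Hydrogen-acceptor distance, Angstrom.
#' @param angle_dha Donor-hydrogen-acceptor angle, degrees.
#' @param angle_hax Hydrogen-acceptor-X angle, degrees.
#' @param x_is_hydrogen Build X as a hydrogen (bond length 0.96) instead of
#'   a carbon (1.43).
#' @return List with `topology`, `xyz` and the realized `probe` geometry.
#' @export
make_geometry_probe_system <- function(dist_ha, angle_dha, angle_hax,
                                       x_is_hydrogen = FALSE) {
  stopifnot(dist_ha > 0)
  .check_angle(angle_dha, "donor-hydrogen-acceptor")
  .check_angle(angle_hax, "hydrogen-acceptor-X")
  D <- c(0, 0, 1); H <- c(0, 0, 0)
  r_ax <- if (x_is_hydrogen) 0.96 else 1.43
  ax <- .plant_acceptor(D, H, dist_ha, angle_dha, angle_hax, r_ax)
  xyz <- rbind(D, H, ax$A, ax$X)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))

  # reject geometrically degenerate requests (coincident non-bonded atoms)
  pairs <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  dmin <- min(apply(pairs, 1, function(ij)
    sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2))))
  # the H...A contact itself may be short, but nothing may collapse
  if (dmin < 0.4 && dmin < dist_ha - 1e-9) {
    stop("unrealizable probe geometry: atoms collapse (min distance ",
         round(dmin, 3), " A)", call. = FALSE)
  }
  atoms <- data.frame(
    serial = 1:4,
    name = c("OD", "HD", "OA", if (x_is_hydrogen) "HX" else "CX"),
    resname = c("DNR", "DNR", "ACC", "ACC"),
    chain = c("A", "A", "B", "B"),
    resid = c(1L, 1L, 2L, 2L),
    element = c("O", "H", "O", if (x_is_hydrogen) "H" else "C"),
    stringsAsFactors = FALSE
  )
  top <- topology(atoms, bonds = rbind(c(1L, 2L), c(3L, 4L)))
  top$groups$solute_A <- 1:2
  top$groups$solute_B <- 3:4
  top$groups$other <- integer(0)

  got <- list(
    dist_ha = sqrt(sum((xyz[3, ] - xyz[2, ])^2)),
    angle_dha = .point_angle(xyz[1, ], xyz[2, ], xyz[3, ]),
    angle_hax = .point_angle(xyz[2, ], xyz[3, ], xyz[4, ])
  )
  if (abs(got$dist_ha - dist_ha) > 1e-6 ||
      abs(got$angle_dha - angle_dha) > 1e-6 ||
      abs(got$angle_hax - angle_hax) > 1e-6) {
    stop("unrealizable probe geometry: requested angles conflict", call. = FALSE)
  }
  list(topology = top, xyz = xyz,
       probe = c(got, list(x_is_hydrogen = x_is_hydrogen)))
}

## ---- fixture building blocks ------------------------------------------

# each block returns list(atoms = data.frame, xyz, bonds = local 1-based pairs)
.blk <- function(names, resname, chain, resid, elements, xyz, bonds) {
  list(atoms = data.frame(serial = NA_integer_, name = names, resname = resname,
                          chain = chain, resid = as.integer(resid),
                          element = elements, stringsAsFactors = FALSE),
       xyz = xyz, bonds = bonds)
}

# carbonyl mimic: single-partner acceptor oxygen (O with one C)
.blk_carbonyl <- function(resname, chain, resid, O_pos, C_pos) {
  .blk(c("C", "O"), resname, chain, resid, c("C", "O"),
       rbind(C_pos, O_pos), rbind(c(1, 2)))
}

# phosphoryl mimic: acceptor oxygen bonded to one phosphorus
.blk_phosphoryl <- function(resname, chain, resid, O_pos, P_pos) {
  .blk(c("P", "O1P"), resname, chain, resid, c("P", "O"),
       rbind(P_pos, O_pos), rbind(c(1, 2)))
}

# hydroxyl donor: C-O-H with the O-H axis along `direction`
.blk_hydroxyl <- function(resname, chain, resid, O_pos, direction) {
  u <- .unit(direction)
  H_pos <- O_pos + 0.96 * u
  p <- .perp_unit(u)
  c_dir <- cos(109.5 * pi / 180) * u + sin(109.5 * pi / 180) * p
  C_pos <- O_pos + 1.43 * c_dir
  .blk(c("C", "OH", "HO"), resname, chain, resid, c("C", "O", "H"),
       rbind(C_pos, O_pos, H_pos), rbind(c(1, 2), c(2, 3)))
}

# ethanolamine-like headgroup: N with two polar hydrogens and one carbon
.blk_amine <- function(resname, chain, resid, N_pos, dir1, dir2) {
  u1 <- .unit(dir1); u2 <- .unit(dir2)
  c_dir <- -.unit(u1 + u2)
  .blk(c("N", "HN1", "HN2", "C"), resname, chain, resid, c("N", "H", "H", "C"),
       rbind(N_pos, N_pos + 1.01 * u1, N_pos + 1.01 * u2, N_pos + 1.47 * c_dir),
       rbind(c(1, 2), c(1, 3), c(1, 4)))
}

# choline-like headgroup: N with three methyl carbons, no polar hydrogen;
# methyls avoid the +x axis where planted acceptors sit
.blk_choline <- function(resname, chain, resid, N_pos) {
  dirs <- rbind(c(0.5, sqrt(3) / 2, 0), c(0.5, -sqrt(3) / 2, 0), c(-1, 0, 0))
  xyz <- rbind(N_pos, t(apply(dirs, 1, function(d) N_pos + 1.51 * d)))
  .blk(c("N", "C1", "C2", "C3"), resname, chain, resid, c("N", "C", "C", "C"),
       xyz, rbind(c(1, 2), c(1, 3), c(1, 4)))
}

# water with the two O-H axes along u1/u2 (must be ~104.5 deg apart)
.blk_water <- function(resid, O_pos, u1 = c(1, 0, 0),
                       u2 = c(cos(104.52 * pi / 180), sin(104.52 * pi / 180), 0)) {
  u1 <- .unit(u1); u2 <- .unit(u2)
  .blk(c("O", "H1", "H2"), "HOH", "W", resid, c("O", "H", "H"),
       rbind(O_pos, O_pos + 0.9572 * u1, O_pos + 0.9572 * u2),
       rbind(c(1, 2), c(1, 3)))
}

# lone carbon decoy
.blk_decoy <- function(chain, resid, pos) {
  .blk("C", "DCY", chain, resid, "C", rbind(pos), matrix(integer(0), ncol = 2))
}

.blk_ion <- function(element, resid, pos) {
  .blk(element, element, "I", resid, element, rbind(pos),
       matrix(integer(0), ncol = 2))
}

.assemble_blocks <- function(blocks) {
  atoms <- do.call(rbind, lapply(blocks, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  offsets <- cumsum(c(0, vapply(blocks, function(b) nrow(b$atoms), integer(1))))
  bonds <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]$bonds
    if (nrow(b) == 0L) return(NULL)
    b + offsets[i]
  }))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(xyz) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  top <- topology(atoms, bonds = bonds)
  list(topology = top, xyz = xyz)
}

# One seeded whole-system translation per frame, snapped to the 0.001-A
# grid of the PDB coordinate field. Translations leave every internal
# distance and angle untouched, so planted energies hold bit-for-bit
# through file round trips; rotation invariance of the scoring is a
# property of the detector and is exercised on in-memory geometry instead.
.frame_shifts <- function(n_frames, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_frames), function(f) round(stats::runif(3, -5, 5), 3))
}

.shift_frame <- function(xyz, shift) {
  out <- sweep(xyz, 2, shift, "+")
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

# Energy of one planted contact recomputed from the coordinates actually
# emitted (after grid snapping); X is the acceptor's single covalent partner.
.realized_bond <- function(top, xyz, donor_label, hydrogen_label,
                           acceptor_label, params = hbond_params()) {
  labs <- atom_label(top, seq_len(nrow(top$atoms)))
  dh <- match(donor_label, labs); hy <- match(hydrogen_label, labs)
  ac <- match(acceptor_label, labs)
  stopifnot(!is.na(dh), !is.na(hy), !is.na(ac))
  xs <- setdiff(.bonded_partners(top, ac), hy)
  stopifnot(length(xs) == 1L)
  d <- sqrt(sum((xyz[hy, ] - xyz[ac, ])^2))
  adha <- .point_angle(xyz[dh, ], xyz[hy, ], xyz[ac, ])
  ahax <- .point_angle(xyz[hy, ], xyz[ac, ], xyz[xs, ])
  xh <- top$atoms$element[xs] == "H"
  c(energy = hbond_energy(d, adha, ahax, xh, params))
}

## ---- scenarios ---------------------------------------------------------

.fixture_scenarios <- c("bridge_basic", "no_donors_on_B",
                        "pl_ethanolamine", "pl_choline")

#' Shipped fixture scenario names
#' @return Character vector of scenario names accepted by [generate_fixture()].
#' @export
fixture_scenarios <- function() .fixture_scenarios

# Plant a hydroxyl -> single-partner-acceptor contact and return the two
# blocks plus the planted-geometry record.
.plant_direct <- function(origin, direction, dist_ha, angle_dha, angle_hax,
                          donor_resid, acc_resid, acc_kind = c("phosphoryl", "carbonyl"),
                          donor_chain = "A", acc_chain = "B") {
  acc_kind <- match.arg(acc_kind)
  don <- .blk_hydroxyl("GOH", donor_chain, donor_resid, origin, direction)
  O_pos <- don$xyz[2, ]; H_pos <- don$xyz[3, ]
  r_ax <- if (acc_kind == "phosphoryl") 1.61 else 1.22
  ax <- .plant_acceptor(O_pos, H_pos, dist_ha, angle_dha, angle_hax, r_ax)
  acc <- if (acc_kind == "phosphoryl") {
    .blk_phosphoryl("LPO", acc_chain, acc_resid, ax$A, ax$X)
  } else {
    .blk_carbonyl("GCO", acc_chain, acc_resid, ax$A, ax$X)
  }
  list(blocks = list(don, acc),
       planted = data.frame(
         donor_label = paste("GOH", donor_resid, "OH"),
         hydrogen_label = paste("GOH", donor_resid, "HO"),
         acceptor_label = paste(if (acc_kind == "phosphoryl") "LPO" else "GCO",
                                acc_resid, if (acc_kind == "phosphoryl") "O1P" else "O"),
         kind = "direct_AB", dist_ha = dist_ha, angle_dha = angle_dha,
         angle_hax = angle_hax, x_is_hydrogen = FALSE,
         energy = hbond_energy(dist_ha, angle_dha, angle_hax, FALSE),
         stringsAsFactors = FALSE))
}

# Plant a water donating H1 to an A-side carbonyl and H2 to a B-side
# phosphoryl: one bridge.
.plant_bridge <- function(origin, water_resid, a_resid, b_resid,
                          d1 = 1.8, d2 = 1.85) {
  wat <- .blk_water(water_resid, origin)
  Ow <- wat$xyz[1, ]; H1 <- wat$xyz[2, ]; H2 <- wat$xyz[3, ]
  ax1 <- .plant_acceptor(Ow, H1, d1, 180, 110, 1.22)
  ax2 <- .plant_acceptor(Ow, H2, d2, 180, 115, 1.61)
  a_blk <- .blk_carbonyl("GCO", "A", a_resid, ax1$A, ax1$X)
  b_blk <- .blk_phosphoryl("LPO", "B", b_resid, ax2$A, ax2$X)
  planted <- data.frame(
    donor_label = c(paste("HOH", water_resid, "O"), paste("HOH", water_resid, "O")),
    hydrogen_label = c(paste("HOH", water_resid, "H1"), paste("HOH", water_resid, "H2")),
    acceptor_label = c(paste("GCO", a_resid, "O"), paste("LPO", b_resid, "O1P")),
    kind = c("water_A", "water_B"),
    dist_ha = c(d1, d2), angle_dha = 180, angle_hax = c(110, 115),
    x_is_hydrogen = FALSE,
    energy = hbond_energy(c(d1, d2), 180, c(110, 115), FALSE),
    stringsAsFactors = FALSE)
  list(blocks = list(wat, a_blk, b_blk), planted = planted,
       bridge = data.frame(water = paste("W", "HOH", water_resid, sep = "|"),
                           a_label = paste("GCO", a_resid, "O"),
                           b_label = paste("LPO", b_resid, "O1P"),
                           stringsAsFactors = FALSE))
}

#' Generate a planted fixture system
#'
#' Builds a small multi-frame system for a named scenario, with ground truth
#' recorded in a manifest: planted hydrogen bonds with their exact geometry
#' and energy, planted water bridges, per-frame expected counts, and the
#' expected contact-map percentages and occupancy durations. Frames are
#' related by seeded rigid-body motion, which leaves all bond energies
#' unchanged; decoy atoms (nonpolar carbons, isolated waters, an ion pair)
#' are always present and must not register in any statistic.
#'
#' Scenarios:
#' \describe{
#'   \item{`bridge_basic`}{two direct solute A-B bonds (one optimal, one
#'     near threshold), one water bridge, one water bound to A only.}
#'   \item{`no_donors_on_B`}{a choline-like B headgroup with no polar
#'     hydrogen: B never donates.}
#'   \item{`pl_ethanolamine` / `pl_choline`}{identical two-site placement of
#'     a B headgroup near A-side acceptors; the ethanolamine-like mimic
#'     (N-H donors) binds both sites, the choline-like mimic none.}
#' }
#'
#' @param scenario One of [fixture_scenarios()].
#' @param n_frames Number of frames (default 5).
#' @param interval_ns Snapshot interval in ns (default 0.1).
#' @param seed Integer seed for the rigid-body motion and decoy placement.
#' @param path Optional output basename: writes `<path>.pdb` and
#'   `<path>.manifest.json`.
#' @return List with `trajectory`, `manifest`, and (if written) `pdb_path`,
#'   `manifest_path`.
#' @export
generate_fixture <- function(scenario, n_frames = 5, interval_ns = 0.1,
                             seed = 1, path = NULL) {
  scenario <- match.arg(scenario, .fixture_scenarios)
  stopifnot(n_frames >= 1, interval_ns > 0)
  blocks <- list(); planted <- list(); bridges <- list()

  if (scenario == "bridge_basic") {
    d1 <- .plant_direct(c(0, 0, 0), c(1, 0, 0), 1.9, 180, 120, 2, 10)
    d2 <- .plant_direct(c(0, 14, 0), c(0, 0, 1), 2.3, 150, 91, 3, 11)
    br <- .plant_bridge(c(20, 0, 0), 100, 1, 12)
    # water bound to A only: donates to a lone carbonyl site
    wA <- .blk_water(102, c(14, 14, 0))
    axA <- .plant_acceptor(wA$xyz[1, ], wA$xyz[2, ], 1.9, 180, 110, 1.22)
    gco4 <- .blk_carbonyl("GCO", "A", 4, axA$A, axA$X)
    blocks <- c(d1$blocks, d2$blocks, br$blocks,
                list(wA, gco4, .blk_water(101, c(0, 0, 20)),
                     .blk_decoy("A", 90, c(-10, -10, 0)),
                     .blk_decoy("B", 91, c(-10, -14, 0)),
                     .blk_ion("NA", 95, c(30, 30, 30)),
                     .blk_ion("CL", 96, c(33, 30, 30))))
    planted <- rbind(d1$planted, d2$planted, br$planted,
                     data.frame(donor_label = "HOH 102 O",
                                hydrogen_label = "HOH 102 H1",
                                acceptor_label = "GCO 4 O", kind = "water_A",
                                dist_ha = 1.9, angle_dha = 180, angle_hax = 110,
                                x_is_hydrogen = FALSE,
                                energy = hbond_energy(1.9, 180, 110, FALSE),
                                stringsAsFactors = FALSE))
    bridges <- br$bridge
  } else if (scenario == "no_donors_on_B") {
    d1 <- .plant_direct(c(0, 0, 0), c(1, 0, 0), 1.9, 180, 120, 2, 10)
    cho <- .blk_choline("LNC", "B", 20, c(0, 14, 0))
    gco5 <- .blk_carbonyl("GCO", "A", 5, c(14, 0, 0), c(14, 0, 1.22))
    blocks <- c(d1$blocks, list(cho, gco5, .blk_water(101, c(0, 0, 20)),
                                .blk_decoy("A", 90, c(-10, -10, 0)),
                                .blk_decoy("B", 91, c(-10, -14, 0))))
    planted <- d1$planted
  } else {  # pl_ethanolamine / pl_choline: identical two-site placement
    sites <- list(c(0, 0, 0), c(0, 14, 0))
    resids <- c(1L, 2L)
    for (k in 1:2) {
      N_pos <- sites[[k]]
      if (scenario == "pl_ethanolamine") {
        u1 <- c(1, 0, 0)
        u2 <- c(cos(106 * pi / 180), sin(106 * pi / 180), 0)
        amine <- .blk_amine("LNH", "B", 20L + k, N_pos, u1, u2)
        H1 <- amine$xyz[2, ]
        ax <- .plant_acceptor(N_pos, H1, 1.95, 180, 109, 1.22)
        acc <- .blk_carbonyl("GCO", "A", resids[k], ax$A, ax$X)
        blocks <- c(blocks, list(amine, acc))
        planted[[k]] <- data.frame(
          donor_label = paste("LNH", 20L + k, "N"),
          hydrogen_label = paste("LNH", 20L + k, "HN1"),
          acceptor_label = paste("GCO", resids[k], "O"),
          kind = "direct_AB", dist_ha = 1.95, angle_dha = 180,
          angle_hax = 109, x_is_hydrogen = FALSE,
          energy = hbond_energy(1.95, 180, 109, FALSE),
          stringsAsFactors = FALSE)
      } else {
        cho <- .blk_choline("LNC", "B", 20L + k, N_pos)
        # same A-side acceptor position as in the ethanolamine twin
        u1 <- c(1, 0, 0)
        H1 <- N_pos + 1.01 * u1
        ax <- .plant_acceptor(N_pos, H1, 1.95, 180, 109, 1.22)
        acc <- .blk_carbonyl("GCO", "A", resids[k], ax$A, ax$X)
        blocks <- c(blocks, list(cho, acc))
      }
    }
    planted <- if (scenario == "pl_ethanolamine") do.call(rbind, planted)
      else .empty_planted()
    blocks <- c(blocks, list(.blk_water(101, c(0, 0, 20)),
                             .blk_decoy("A", 90, c(-10, -10, 0)),
                             .blk_decoy("B", 91, c(14, 7, 0))))
  }

  sys <- .assemble_blocks(blocks)
  sys$topology <- assign_groups(sys$topology, "chain A", "chain B")
  sys$xyz <- round(sys$xyz, 3)   # snap to the PDB coordinate grid
  frames <- lapply(.frame_shifts(n_frames, seed), function(s)
    .shift_frame(sys$xyz, s))
  traj <- trajectory(sys$topology, frames,
                     times = (seq_len(n_frames) - 1) * interval_ns * 1000)

  if (length(planted) == 0L || nrow(planted) == 0L) planted <- .empty_planted()
  if (nrow(planted) > 0L) {
    planted$energy_requested <- planted$energy
    realized <- vapply(seq_len(nrow(planted)), function(i)
      .realized_bond(sys$topology, sys$xyz, planted$donor_label[i],
                     planted$hydrogen_label[i], planted$acceptor_label[i]),
      numeric(1))
    # grid snapping moves each energy by at most a few hundredths of kJ/mol
    stopifnot(max(abs(realized - planted$energy_requested)) < 0.1)
    planted$energy <- realized
  }
  if (length(bridges) == 0L) {
    bridges <- data.frame(water = character(0), a_label = character(0),
                          b_label = character(0), stringsAsFactors = FALSE)
  }
  direct <- planted[planted$kind == "direct_AB", , drop = FALSE]
  n_direct <- nrow(unique(direct[, c("donor_label", "acceptor_label")]))
  cm_direct <- .expected_map(direct$donor_label, direct$acceptor_label,
                             swap = grepl("^LNH", direct$donor_label))
  cm_bridge <- if (nrow(bridges) > 0L) {
    data.frame(label_A = bridges$a_label, label_B = bridges$b_label,
               percent = 100 / nrow(bridges), stringsAsFactors = FALSE)
  } else data.frame(label_A = character(0), label_B = character(0),
                    percent = numeric(0))

  manifest <- list(
    scenario = scenario, seed = seed, n_frames = n_frames,
    interval_ns = interval_ns,
    planted_hbonds = planted,
    planted_bridges = bridges,
    per_frame = list(n_direct = n_direct, n_bridges = nrow(bridges)),
    contact_map_direct = cm_direct,
    contact_map_bridges = cm_bridge,
    expected_occupancy_ns = n_frames * interval_ns)

  out <- list(trajectory = traj, manifest = manifest)
  if (!is.null(path)) {
    pdb <- paste0(path, ".pdb"); mf <- paste0(path, ".manifest.json")
    write_pdb_trajectory(sys$topology, frames, pdb)
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    out$pdb_path <- pdb; out$manifest_path <- mf
  }
  out
}

.empty_planted <- function() {
  data.frame(donor_label = character(0), hydrogen_label = character(0),
             acceptor_label = character(0), kind = character(0),
             dist_ha = numeric(0), angle_dha = numeric(0),
             angle_hax = numeric(0), x_is_hydrogen = logical(0),
             energy = numeric(0), stringsAsFactors = FALSE)
}

# expected contact map (donor heavy label, acceptor label) -> A/B orientation
.expected_map <- function(donor_label, acceptor_label, swap) {
  if (length(donor_label) == 0L) {
    return(data.frame(label_A = character(0), label_B = character(0),
                      percent = numeric(0)))
  }
  label_A <- ifelse(swap, acceptor_label, donor_label)
  label_B <- ifelse(swap, donor_label, acceptor_label)
  data.frame(label_A = label_A, label_B = label_B,
             percent = 100 / length(label_A), stringsAsFactors = FALSE)
}

#' Generate a kinetic on/off trajectory
#'
#' One planted donor-acceptor pair per pattern; on "off" frames the acceptor
#' unit is displaced well beyond the detection cutoff, so occupancy-based
#' duration statistics must recover each pattern exactly.
#'
#' @param patterns List of equal-length 0/1 vectors (or a single vector),
#'   one per planted pair; element f gives the state of that pair in frame f.
#' @param interval_ns Snapshot interval, ns.
#' @param seed Integer seed for the per-frame rigid-body motion.
#' @param path Optional output basename (as in [generate_fixture()]).
#' @return List with `trajectory` and `manifest` (expected per-pair
#'   `occupancy_ns`, `longest_run_ns` and per-frame direct counts).
#' @export
generate_kinetic_trajectory <- function(patterns, interval_ns = 0.1, seed = 1,
                                        path = NULL) {
  if (!is.list(patterns)) patterns <- list(patterns)
  lens <- vapply(patterns, length, integer(1))
  stopifnot(length(unique(lens)) == 1L, all(unlist(patterns) %in% c(0, 1)))
  n_frames <- lens[1]
  n_pairs <- length(patterns)

  plants <- lapply(seq_len(n_pairs), function(k) {
    .plant_direct(c(0, 14 * (k - 1), 0), c(1, 0, 0), 1.9, 180, 120,
                  donor_resid = k, acc_resid = 100L + k)
  })
  blocks <- c(unlist(lapply(plants, `[[`, "blocks"), recursive = FALSE),
              list(.blk_water(201, c(0, -8, 14)),
                   .blk_decoy("A", 90, c(-10, 0, 0))))
  sys <- .assemble_blocks(blocks)
  sys$topology <- assign_groups(sys$topology, "chain A", "chain B")

  # acceptor-unit atom indices per pair (P and O of the LPO residue)
  a <- sys$topology$atoms
  acc_idx <- lapply(seq_len(n_pairs), function(k)
    which(a$resname == "LPO" & a$resid == 100L + k))

  # displace "off" acceptors before the per-frame translation: the off
  # geometry is then identical in every frame and for every seed
  sys$xyz <- round(sys$xyz, 3)
  shifts <- .frame_shifts(n_frames, seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    m <- sys$xyz
    for (k in seq_len(n_pairs)) {
      if (patterns[[k]][f] == 0) {
        m[acc_idx[[k]], ] <- sweep(m[acc_idx[[k]], , drop = FALSE], 2,
                                   c(10, 0, 0), "+")
      }
    }
    .shift_frame(m, shifts[[f]])
  })
  traj <- trajectory(sys$topology, frames,
                     times = (seq_len(n_frames) - 1) * interval_ns * 1000)

  expected <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    pat <- patterns[[k]]
    runs <- rle(pat == 1)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    data.frame(label_A = paste("GOH", k, "OH"),
               label_B = paste("LPO", 100L + k, "O1P"),
               occupancy_frames = sum(pat),
               occupancy_ns = sum(pat) * interval_ns,
               longest_run_ns = longest * interval_ns,
               stringsAsFactors = FALSE)
  }))
  expected <- expected[expected$occupancy_frames > 0L, , drop = FALSE]
  manifest <- list(
    patterns = patterns, seed = seed, n_frames = n_frames,
    interval_ns = interval_ns, expected_durations = expected,
    per_frame_direct = Reduce(`+`, lapply(patterns, as.integer)))

  out <- list(trajectory = traj, manifest = manifest)
  if (!is.null(path)) {
    pdb <- paste0(path, ".pdb"); mf <- paste0(path, ".manifest.json")
    write_pdb_trajectory(sys$topology, frames, pdb)
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    out$pdb_path <- pdb; out$manifest_path <- mf
  }
  out
}
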