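# Independent oracles and random-system generators used across the suite.
# The brute-force scorer re-derives everything from the topology with plain
# loops and inline piecewise arithmetic; it shares no code path with
# detect_hbonds().

oracle_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

oracle_scale_dha <- function(a) {
  if (a <= 100) 0 else if (a >= 165) 1 else (a - 100) / 65
}

oracle_scale_hax <- function(a, x_is_h) {
  lo <- if (x_is_h) 75 else 85
  hi <- lo + 10
  if (a <= lo) 0 else if (a >= hi) 1 else (a - lo) / 10
}

# Exhaustive scorer: every (donor hydrogen, acceptor) pair, no prefilter.
oracle_hbonds <- function(topology, xyz, threshold = 6.25) {
  el <- topology$atoms$element
  eligible <- setdiff(seq_len(nrow(topology$atoms)), topology$groups$other)
  polar <- intersect(which(el %in% c("N", "O", "S")), eligible)
  b <- topology$bonds
  adj <- lapply(seq_len(nrow(topology$atoms)), function(i)
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
  found <- list()
  for (heavy in polar) {
    for (hy in adj[[heavy]]) {
      if (el[hy] != "H" || !(hy %in% eligible)) next
      for (acc in polar) {
        if (acc == heavy || acc == hy) next
        d <- sqrt(sum((xyz[hy, ] - xyz[acc, ])^2))
        ang_dha <- oracle_angle(xyz[heavy, ], xyz[hy, ], xyz[acc, ])
        partners <- setdiff(adj[[acc]], hy)
        if (length(partners) == 0) {
          s_hax <- 1
        } else {
          s_hax <- min(vapply(partners, function(x)
            oracle_scale_hax(oracle_angle(xyz[hy, ], xyz[acc, ], xyz[x, ]),
                             el[x] == "H"), numeric(1)))
        }
        e <- 25 * (2.6 - max(d, 2.1)) / 0.5 * oracle_scale_dha(ang_dha) * s_hax
        if (e > threshold) {
          found[[length(found) + 1]] <- data.frame(
            donor_heavy = heavy, hydrogen = hy, acceptor = acc, energy = e)
        }
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(donor_heavy = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), energy = numeric(0)))
  }
  out <- do.call(rbind, found)
  out[order(out$donor_heavy, out$hydrogen, out$acceptor), ]
}

rot3 <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2)); c_ <- cos(angle); s <- sin(angle)
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(
    c_ + x^2 * (1 - c_),     x * y * (1 - c_) - z * s, x * z * (1 - c_) + y * s,
    y * x * (1 - c_) + z * s, c_ + y^2 * (1 - c_),     y * z * (1 - c_) - x * s,
    z * x * (1 - c_) - y * s, z * y * (1 - c_) + x * s, c_ + z^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
}

random_rot <- function() rot3(stats::runif(3, -1, 1) + 1e-3, stats::runif(1, 0, 2 * pi))

# Random clustered system: waters plus amine (chain A) and carbonyl
# (chain B) fragments in a small box, dense enough to form real contacts.
random_polar_system <- function(n_water = 6, n_amine = 1, n_carbonyl = 1,
                                box = 8) {
  frag_water <- rbind(c(0, 0, 0), c(0.9572, 0, 0),
                      c(0.9572 * cos(104.52 * pi / 180),
                        0.9572 * sin(104.52 * pi / 180), 0))
  frag_amine <- rbind(c(0, 0, 0), c(1.01, 0, 0),
                      c(1.01 * cos(106 * pi / 180), 1.01 * sin(106 * pi / 180), 0),
                      c(-0.7, -1.2, 0))  # N, H, H, C
  frag_carbonyl <- rbind(c(0, 0, 0), c(1.22, 0, 0))  # C, O
  specs <- c(
    rep(list(list(f = frag_water, el = c("O", "H", "H"),
                  nm = c("O", "H1", "H2"), rn = "HOH", ch = "W")), n_water),
    rep(list(list(f = frag_amine, el = c("N", "H", "H", "C"),
                  nm = c("N", "HN1", "HN2", "C"), rn = "AMN", ch = "A")), n_amine),
    rep(list(list(f = frag_carbonyl, el = c("C", "O"),
                  nm = c("C", "O"), rn = "CBN", ch = "B")), n_carbonyl))
  # chain growth: each fragment lands near an earlier one (3.0-3.6 A), so
  # hydrogen-bond-range contacts are common; bounded retries keep it fast
  centers <- matrix(NA_real_, length(specs), 3)
  centers[1, ] <- stats::runif(3, 0, box)
  for (i in seq_along(specs)[-1]) {
    placed <- centers[seq_len(i - 1), , drop = FALSE]
    for (try in 1:200) {
      anchor <- placed[sample(nrow(placed), 1), ]
      dir <- stats::runif(3, -1, 1)
      while (sum(dir^2) < 1e-6) dir <- stats::runif(3, -1, 1)
      cand <- anchor + stats::runif(1, 3.0, 3.6) * dir / sqrt(sum(dir^2))
      if (min(sqrt(rowSums(sweep(placed, 2, cand)^2))) > 2.9) break
      if (try == 200) cand <- anchor + c(0, 0, 4 + i)
    }
    centers[i, ] <- cand
  }
  atoms <- list(); xyz <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    xyz[[i]] <- sweep(s$f %*% t(random_rot()), 2, centers[i, ], "+")
    atoms[[i]] <- data.frame(serial = NA_integer_, name = s$nm, resname = s$rn,
                             chain = s$ch, resid = i, element = s$el,
                             stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, xyz)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  top <- wbridge::topology(atoms)
  top$bonds <- wbridge::infer_covalent_bonds(top, xyz)
  top <- wbridge::assign_groups(top, "chain A", "chain B")
  list(topology = top, xyz = xyz)
}

# minimal two-water system with a planted linear O-H...O contact
water_dimer <- function(d_ha = 1.9) {
  a <- data.frame(
    serial = 1:6,
    name = c("O", "H1", "H2", "O", "H1", "H2"),
    resname = "HOH", chain = "W", resid = c(1, 1, 1, 2, 2, 2),
    element = c("O", "H", "H", "O", "H", "H"), stringsAsFactors = FALSE)
  ang <- 104.52 * pi / 180
  xyz <- rbind(
    c(0, 0, 0), c(0.9572, 0, 0), c(0.9572 * cos(ang), 0.9572 * sin(ang), 0),
    # acceptor water: O along the first O-H axis at H + d, its hydrogens
    # pointing away from the donor (H-A-X about 128 degrees)
    c(0.9572 + d_ha, 0, 0),
    c(0.9572 + d_ha + 0.9572 * cos(0.9122), 0.9572 * sin(0.9122), 0),
    c(0.9572 + d_ha + 0.9572 * cos(0.9122), -0.9572 * sin(0.9122), 0))
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  top <- wbridge::topology(a)
  top$bonds <- wbridge::infer_covalent_bonds(top, xyz)
  list(topology = top, xyz = xyz)
}

# label helpers mirroring the package's map labeling
atom_label_pub <- function(topology, idx) {
  paste(topology$atoms$resname[idx], topology$atoms$resid[idx],
        topology$atoms$name[idx])
}

atom_labels_of <- function(topology, pairs) {
  data.frame(label_A = paste(topology$atoms$resname[pairs$atom_A],
                             topology$atoms$resid[pairs$atom_A],
                             topology$atoms$name[pairs$atom_A]),
             label_B = paste(topology$atoms$resname[pairs$atom_B],
                             topology$atoms$resid[pairs$atom_B],
                             topology$atoms$name[pairs$atom_B]))
}
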