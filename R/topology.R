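#' Build a molecular topology
#'
#' A topology is the frame-invariant part of a trajectory: the atom table,
#' the covalent adjacency, and a named partition of the atoms into the
#' analysis groups `solute_A`, `solute_B`, `water` and `other`.
#'
#' Waters are recognized by residue name (configurable aliases) and must be
#' three-atom residues of one oxygen and two hydrogens; a matching residue
#' name with any other composition is left in `other` with a warning.
#' Monatomic ions are assigned to `other` and take no part in hydrogen-bond
#' analysis.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resid`, `element`.
#' @param bonds Two-column integer matrix of 1-based atom indices
#'   (covalent pairs), or `NULL` to fill in later via
#'   [infer_covalent_bonds()].
#' @param water_names Residue names recognized as water.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, bonds = NULL,
                     water_names = c("HOH", "WAT", "SOL", "TIP3", "TIP")) {
  req <- c("serial", "name", "resname", "chain", "resid", "element")
  stopifnot(all(req %in% names(atoms)))
  atoms$element <- toupper(atoms$element)
  if (!is.null(bonds)) {
    bonds <- .canonical_bonds(bonds, nrow(atoms))
  }
  top <- structure(list(
    atoms = atoms,
    bonds = bonds,
    groups = list(solute_A = integer(0), solute_B = integer(0),
                  water = integer(0), other = seq_len(nrow(atoms))),
    water_names = toupper(water_names)
  ), class = "topology")
  top$groups$water <- .find_waters(top)
  top$groups$other <- setdiff(seq_len(nrow(atoms)), top$groups$water)
  top
}

#' @export
print.topology <- function(x, ...) {
  g <- vapply(x$groups, length, integer(1))
  cat(sprintf("topology: %d atoms, %s covalent bonds\n", nrow(x$atoms),
              if (is.null(x$bonds)) "no" else nrow(x$bonds)))
  cat(sprintf("  groups: solute_A=%d solute_B=%d water=%d other=%d\n",
              g[["solute_A"]], g[["solute_B"]], g[["water"]], g[["other"]]))
  invisible(x)
}

#' Container for a trajectory
#'
#' @param topology A [topology()] object.
#' @param frames List of n-by-3 coordinate matrices, Angstrom.
#' @param times Numeric vector of frame times, ps.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "topology"))
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    m <- frames[[i]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3) {
      stop(sprintf("frame %d: expected a %d-by-3 coordinate matrix", i, n),
           call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop(sprintf("frame %d: non-finite coordinates", i), call. = FALSE)
    }
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  print(x$topology)
  invisible(x)
}

# Covalent radii (Cordero et al. consensus values), Angstrom.
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, NA. = 1.66,
                     MG = 1.41, K = 2.03, SE = 1.20)

.covalent_radius <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  r <- .covalent_radii[key]
  if (any(is.na(r))) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}

#' Infer covalent bonds from geometry
#'
#' A pair (i, j) is bonded when its distance does not exceed the sum of the
#' two covalent radii scaled by `1 + tolerance`. Each hydrogen keeps at most
#' one partner (the nearest heavy atom); a hydrogen with no partner within
#' the cutoff triggers a warning and is later excluded from the donor list.
#'
#' @param topology A [topology()] object.
#' @param xyz n-by-3 coordinate matrix, Angstrom.
#' @param tolerance Fractional slack on the covalent-radius sum (default 0.15).
#' @return Two-column integer matrix of bonded index pairs (i < j).
#' @export
infer_covalent_bonds <- function(topology, xyz, tolerance = 0.15) {
  stopifnot(inherits(topology, "topology"), all(is.finite(xyz)))
  el <- topology$atoms$element
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  r <- .covalent_radius(el)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") * (1 + tolerance)
  adj <- d <= cut
  diag(adj) <- FALSE

  is_h <- el == "H"
  # hydrogens bond to exactly one (nearest) heavy atom; no H-H bonds
  adj[is_h, is_h] <- FALSE
  for (i in which(is_h)) {
    partners <- which(adj[i, ])
    if (length(partners) == 0L) {
      warning(sprintf("hydrogen atom %d (%s %s %d) has no covalent partner within cutoff",
                      i, topology$atoms$name[i], topology$atoms$resname[i],
                      topology$atoms$resid[i]), call. = FALSE)
      next
    }
    keep <- partners[which.min(d[i, partners])]
    adj[i, ] <- adj[, i] <- FALSE
    adj[i, keep] <- adj[keep, i] <- TRUE
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  .canonical_bonds(idx, n)
}

.canonical_bonds <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) == 0L) return(bonds)
  if (any(bonds < 1L | bonds > n_atoms)) stop("bond index out of range", call. = FALSE)
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond in covalent adjacency", call. = FALSE)
  bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

# indices covalently bound to atom i
.bonded_partners <- function(topology, i) {
  b <- topology$bonds
  if (is.null(b) || nrow(b) == 0L) return(integer(0))
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

.residue_key <- function(atoms, idx = seq_len(nrow(atoms))) {
  paste(atoms$chain[idx], atoms$resname[idx], atoms$resid[idx], sep = "|")
}

.find_waters <- function(top) {
  a <- top$atoms
  cand <- which(toupper(a$resname) %in% top$water_names)
  if (length(cand) == 0L) return(integer(0))
  keys <- .residue_key(a, cand)
  keep <- integer(0)
  for (k in unique(keys)) {
    idx <- cand[keys == k]
    comp <- sort(a$element[idx])
    if (identical(comp, c("H", "H", "O"))) {
      keep <- c(keep, idx)
    } else {
      warning("residue ", k, " has water-like name but composition ",
              paste(comp, collapse = ""), "; left in 'other'", call. = FALSE)
    }
  }
  sort(keep)
}

#' Assign the solute groups of a topology
#'
#' Resolves two selection expressions (see [select_atoms()]) against the atom
#' table and stores the resulting partition. Waters keep their name-based
#' assignment; atoms matched by neither selection stay in `other`.
#'
#' @param topology A [topology()] object.
#' @param select_A,select_B Selection expressions for the two solute species.
#' @return The updated topology.
#' @export
assign_groups <- function(topology, select_A, select_B) {
  a_idx <- select_atoms(topology, select_A)
  b_idx <- select_atoms(topology, select_B)
  if (length(a_idx) == 0L) stop("selection for solute_A matches no atoms: ",
                                select_A, call. = FALSE)
  if (length(b_idx) == 0L) stop("selection for solute_B matches no atoms: ",
                                select_B, call. = FALSE)
  if (length(intersect(a_idx, b_idx)) > 0L) {
    stop("solute_A and solute_B selections overlap", call. = FALSE)
  }
  w <- topology$groups$water
  a_idx <- setdiff(a_idx, w)
  b_idx <- setdiff(b_idx, w)
  topology$groups$solute_A <- sort(a_idx)
  topology$groups$solute_B <- sort(b_idx)
  topology$groups$other <- setdiff(seq_len(nrow(topology$atoms)),
                                   c(a_idx, b_idx, w))
  topology
}

#' Select atoms by a minimal expression grammar
#'
#' Supported clauses: `chain <id>`, `resname <NAME> [NAME ...]`,
#' `resid <n> [n ...]` (ranges like `2:5` allowed), `name <ATOM> [ATOM ...]`,
#' `all`. Clauses combine left-associatively with `and` (intersection) and
#' `or` (union).
#'
#' @param topology A [topology()] object.
#' @param expr Selection string, e.g. `"resname GAG and chain A"`.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(topology, expr) {
  a <- topology$atoms
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0L) stop("empty selection expression", call. = FALSE)
  result <- NULL
  op <- NULL
  i <- 1L
  while (i <= length(toks)) {
    kw <- tolower(toks[i])
    if (kw %in% c("and", "or")) {
      if (is.null(result)) stop("selection cannot start with '", kw, "'", call. = FALSE)
      op <- kw; i <- i + 1L; next
    }
    if (kw == "all") {
      idx <- seq_len(nrow(a)); i <- i + 1L
    } else if (kw %in% c("chain", "resname", "resid", "name")) {
      j <- i + 1L
      vals <- character(0)
      while (j <= length(toks) && !tolower(toks[j]) %in%
             c("and", "or", "chain", "resname", "resid", "name", "all")) {
        vals <- c(vals, toks[j]); j <- j + 1L
      }
      if (length(vals) == 0L) stop("selection keyword '", kw, "' needs a value",
                                   call. = FALSE)
      idx <- switch(kw,
        chain = which(a$chain %in% vals),
        resname = which(toupper(a$resname) %in% toupper(vals)),
        name = which(toupper(a$name) %in% toupper(vals)),
        resid = which(a$resid %in% .expand_ranges(vals)))
      i <- j
    } else {
      stop("unknown selection keyword: '", toks[i], "'", call. = FALSE)
    }
    result <- if (is.null(result)) idx
      else if (identical(op, "or")) union(result, idx)
      else intersect(result, idx)
    op <- "and"
  }
  sort(unique(result))
}

.expand_ranges <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl(":", v, fixed = TRUE)) {
      ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
      if (length(ab) != 2L || any(is.na(ab))) stop("bad resid range: ", v, call. = FALSE)
      out <- c(out, ab[1]:ab[2])
    } else {
      n <- suppressWarnings(as.integer(v))
      if (is.na(n)) stop("bad resid value: ", v, call. = FALSE)
      out <- c(out, n)
    }
  }
  out
}

#' Classify hydrogen-bond donors and acceptors
#'
#' A donor is a (polar heavy atom, hydrogen) covalent pair; an acceptor is
#' any polar heavy atom. Water oxygens therefore appear both as donor heavy
#' atoms and as acceptors. Atoms in the `other` group (ions, decoys) are
#' excluded.
#'
#' @param topology A [topology()] object with its covalent adjacency filled in.
#' @param polar_elements Elements eligible as donor heavy atoms and
#'   acceptors (default N, O, S).
#' @return A list of class `"polar_roles"` with `donors` (two-column matrix:
#'   heavy index, hydrogen index) and `acceptors` (integer vector).
#' @export
classify_polar_roles <- function(topology, polar_elements = c("N", "O", "S")) {
  stopifnot(inherits(topology, "topology"))
  if (is.null(topology$bonds)) {
    stop("covalent adjacency not populated; run infer_covalent_bonds() first",
         call. = FALSE)
  }
  el <- topology$atoms$element
  eligible <- setdiff(seq_len(nrow(topology$atoms)), topology$groups$other)
  polar <- intersect(which(el %in% toupper(polar_elements)), eligible)
  b <- topology$bonds
  donors <- matrix(integer(0), ncol = 2,
                   dimnames = list(NULL, c("heavy", "hydrogen")))
  if (nrow(b) > 0L) {
    both <- rbind(b, b[, 2:1, drop = FALSE])
    hit <- both[, 1] %in% polar & el[both[, 2]] == "H" & both[, 2] %in% eligible
    if (any(hit)) {
      donors <- both[hit, , drop = FALSE]
      dimnames(donors) <- list(NULL, c("heavy", "hydrogen"))
      donors <- donors[order(donors[, 1], donors[, 2]), , drop = FALSE]
    }
  }
  structure(list(donors = donors, acceptors = polar), class = "polar_roles")
}

# human-readable atom label used in maps and duration tables
atom_label <- function(topology, idx) {
  a <- topology$atoms
  paste(a$resname[idx], a$resid[idx], a$name[idx])
}
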