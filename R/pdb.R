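#' Read a multi-model PDB trajectory
#'
#' Parses a PDB file in which each `MODEL`/`ENDMDL` block is one time-ordered
#' snapshot of the same atom table (a file without `MODEL` records is a
#' single-frame trajectory). Coordinates are in Angstrom. `CONECT` records,
#' if present, override distance-based covalent inference.
#'
#' @param path Path to a PDB file.
#' @param time_step_ps Time spacing between consecutive models, in ps.
#'   Frame `i` is assigned time `(i - 1) * time_step_ps`.
#' @param water_names Residue names recognized as water.
#' @param infer_bonds Infer the covalent adjacency from frame-1 geometry
#'   when no `CONECT` records are present (default `TRUE`).
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `topology` (see [topology()]), `frames` (list of n-by-3 coordinate
#'   matrices) and `times` (ps).
#'
#' @examples
#' probe <- make_geometry_probe_system(2.0, 180, 180)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb_trajectory(probe$topology, list(probe$xyz), f)
#' traj <- read_pdb_trajectory(f)
#' nrow(traj$topology$atoms)
#' @export
read_pdb_trajectory <- function(path, time_step_ps = 100,
                                water_names = c("HOH", "WAT", "SOL", "TIP3", "TIP"),
                                infer_bonds = TRUE) {
  if (!file.exists(path)) {
    stop("trajectory file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  .check_model_blocks(lines)

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  n_atom <- nrow(atoms)
  if (n_atom == 0L) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  element <- .resolve_elements(atoms)
  atom_tab <- data.frame(
    serial  = atoms$eleno,
    name    = atoms$elety,
    resname = atoms$resid,
    chain   = ifelse(is.na(atoms$chain), "", atoms$chain),
    resid   = atoms$resno,
    element = element,
    stringsAsFactors = FALSE
  )

  n_frame <- nrow(pdb$xyz)
  frames <- lapply(seq_len(n_frame), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })

  conect <- .parse_conect(lines, atom_tab$serial)
  top <- topology(atom_tab, bonds = conect, water_names = water_names)
  if (is.null(conect) && infer_bonds) {
    top$bonds <- infer_covalent_bonds(top, frames[[1]])
  }
  trajectory(top, frames, times = (seq_len(n_frame) - 1) * time_step_ps)
}

#' Write a multi-model PDB trajectory
#'
#' Inverse of [read_pdb_trajectory()]: one `MODEL` block per frame, identical
#' atom table throughout, coordinates printed to 3 decimals.
#'
#' @param topology A [topology()] object.
#' @param frames List of n-by-3 coordinate matrices (Angstrom).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(topology, frames, path) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1L)
  a <- topology$atoms
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(a)),
    eleno = a$serial, elety = a$name, resid = a$resname,
    chain = ifelse(a$chain == "", " ", a$chain), resno = a$resid,
    elesy = a$element, end = TRUE
  )
  invisible(path)
}

# Validate that every MODEL block carries the same number of coordinate
# records; bio3d would otherwise fail with an opaque recycling error.
.check_model_blocks <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) <= 1L) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
  }
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "atom count mismatch across models: model %d has %d atoms, model 1 has %d",
      bad, counts[bad], counts[1]), call. = FALSE)
  }
  invisible(TRUE)
}

.two_letter_elements <- c("CL", "NA", "BR", "MG", "ZN", "FE", "MN", "CU", "SE")

.resolve_elements <- function(atoms) {
  el <- toupper(trimws(ifelse(is.na(atoms$elesy), "", atoms$elesy)))
  missing <- el == ""
  if (any(missing)) {
    nm <- toupper(trimws(atoms$elety[missing]))
    inferred <- vapply(nm, .element_from_name, character(1))
    bad <- inferred == ""
    if (any(bad)) {
      stop("cannot determine element for atom(s): ",
           paste(nm[bad], collapse = ", "), call. = FALSE)
    }
    el[missing] <- inferred
  }
  el
}

.element_from_name <- function(name) {
  if (name %in% .two_letter_elements) return(name)
  stripped <- gsub("[^A-Z]", "", name)
  if (nchar(stripped) == 0L) return("")
  # names like 1H5, HO2 start with (or reduce to) the element letter
  substr(stripped, 1, 1)
}

.parse_conect <- function(lines, serials) {
  con <- grep("^CONECT", lines, value = TRUE)
  if (length(con) == 0L) return(NULL)
  pairs <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2L) next
    i <- match(flds[1], serials)
    js <- match(flds[-1], serials)
    js <- js[!is.na(js)]
    if (is.na(i) || length(js) == 0L) next
    pairs[[length(pairs) + 1L]] <- cbind(pmin(i, js), pmax(i, js))
  }
  if (length(pairs) == 0L) return(NULL)
  unique(do.call(rbind, pairs))
}
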