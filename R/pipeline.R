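#' Configuration for a full trajectory analysis
#'
#' @param trajectory Path to a multi-model PDB trajectory.
#' @param select_A,select_B Selection expressions (see [select_atoms()]) for
#'   the two solute species.
#' @param interval_ns Snapshot interval in ns. Required: the trajectory
#'   dialect carries no time stamps, and durations scale with it.
#' @param out_dir Output directory (created if missing).
#' @param water_names Residue-name aliases recognized as water.
#' @param hbond HBond scoring parameters ([hbond_params()]).
#' @param sas SAS parameters ([sas_params()]).
#' @param between_direction `"either"` or `"forward"` for the solute A/B
#'   bond filter.
#' @param smooth_window Optional odd moving-average window for the time
#'   series.
#' @param log_level `"info"` (per-frame progress) or `"quiet"`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(trajectory, select_A, select_B, interval_ns, out_dir,
                       water_names = c("HOH", "WAT", "SOL", "TIP3", "TIP"),
                       hbond = hbond_params(), sas = sas_params(),
                       between_direction = c("either", "forward"),
                       smooth_window = NULL,
                       log_level = c("info", "quiet")) {
  stopifnot(is.character(trajectory), length(trajectory) == 1,
            is.numeric(interval_ns), interval_ns > 0)
  structure(list(
    trajectory = trajectory, select_A = select_A, select_B = select_B,
    interval_ns = interval_ns, out_dir = out_dir, water_names = water_names,
    hbond = hbond, sas = sas,
    between_direction = match.arg(between_direction),
    smooth_window = smooth_window, log_level = match.arg(log_level)
  ), class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (`#` comments allowed). Recognized keys:
#' `trajectory`, `select_a`, `select_b`, `interval_ns`, `out_dir`,
#' `water_names` (comma-separated), `between_direction`, `smooth_window`,
#' `log_level`, and the scoring parameters `optimum_energy`,
#' `threshold_energy`, `d_clamp`, `d_zero`, `probe_radius`,
#' `n_sphere_points`.
#'
#' @param path Path to the config file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          tolower(vapply(kv, `[`, character(1), 1)))
  need <- c("trajectory", "select_a", "select_b", "interval_ns", "out_dir")
  miss <- setdiff(need, names(vals))
  if (length(miss) > 0) stop("config missing required key(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  hb <- hbond_params(
    optimum_energy = num("optimum_energy", 25),
    threshold_energy = num("threshold_energy", 6.25),
    d_clamp = num("d_clamp", 2.1), d_zero = num("d_zero", 2.6))
  sp <- sas_params(probe_radius = num("probe_radius", 1.4),
                   n_sphere_points = num("n_sphere_points", 960))
  run_config(
    trajectory = vals[["trajectory"]],
    select_A = vals[["select_a"]], select_B = vals[["select_b"]],
    interval_ns = as.numeric(vals[["interval_ns"]]),
    out_dir = vals[["out_dir"]],
    water_names = if ("water_names" %in% names(vals)) {
      trimws(strsplit(vals[["water_names"]], ",")[[1]])
    } else c("HOH", "WAT", "SOL", "TIP3", "TIP"),
    hbond = hb, sas = sp,
    between_direction = if ("between_direction" %in% names(vals)) {
      vals[["between_direction"]]
    } else "either",
    smooth_window = if ("smooth_window" %in% names(vals)) {
      as.integer(vals[["smooth_window"]])
    } else NULL,
    log_level = if ("log_level" %in% names(vals)) vals[["log_level"]] else "info")
}

.write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wb")  # binary: LF endings on every platform
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full hydrogen-bond / water-bridge / SAS analysis
#'
#' Reads the trajectory, resolves the solute groups, detects hydrogen bonds
#' in every frame, identifies water bridges, and writes the results bundle:
#' `timeseries.csv`, `hbonds.csv`, `contact_map_hbonds.csv`,
#' `contact_map_bridges.csv`, `durations_hbonds.csv`,
#' `durations_bridges.csv`, `sas_timeseries.csv`, `contact_map.json` and
#' `run_metadata.json`. All CSVs are written atomically and are
#' byte-identical across reruns of the same config and input.
#'
#' When the water aliases match no residue, bridge analysis is skipped with
#' a warning and the direct-bond outputs are produced unchanged.
#'
#' @param config A [run_config()] object.
#' @return A list of class `"results_bundle"` with all tables, the topology
#'   and the metadata record, invisibly.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_info <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  traj <- read_pdb_trajectory(config$trajectory,
                              time_step_ps = config$interval_ns * 1000,
                              water_names = config$water_names)
  top <- assign_groups(traj$topology, config$select_A, config$select_B)
  traj$topology <- top
  n_frames <- length(traj$frames)
  log_info("read %d frames x %d atoms from %s", n_frames,
           nrow(top$atoms), config$trajectory)

  has_water <- length(top$groups$water) > 0L
  if (!has_water) {
    warning("water aliases match no residue; bridge analysis disabled",
            call. = FALSE)
  }
  roles <- classify_polar_roles(top)
  all_bonds <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    b <- detect_hbonds(top, traj$frames[[i]], roles, config$hbond)
    if (nrow(b) > 0L) {
      all_bonds[[i]] <- cbind(frame = i, time_ps = traj$times[i], b)
    }
    log_info("frame %d/%d: %d bonds", i, n_frames,
             if (is.null(all_bonds[[i]])) 0L else nrow(all_bonds[[i]]))
  }
  all_bonds <- all_bonds[!vapply(all_bonds, is.null, logical(1))]
  all_bonds <- if (length(all_bonds) > 0L) do.call(rbind, all_bonds) else {
    cbind(frame = integer(0), time_ps = numeric(0),
          detect_hbonds(top, traj$frames[[1]], roles, config$hbond)[0, ])
  }

  in_A <- all_bonds$donor_heavy %in% top$groups$solute_A |
    all_bonds$acceptor %in% top$groups$solute_A
  in_B <- all_bonds$donor_heavy %in% top$groups$solute_B |
    all_bonds$acceptor %in% top$groups$solute_B
  fwd <- all_bonds$donor_heavy %in% top$groups$solute_A &
    all_bonds$acceptor %in% top$groups$solute_B
  direct <- if (config$between_direction == "forward") {
    all_bonds[fwd, , drop = FALSE]
  } else {
    all_bonds[in_A & in_B, , drop = FALSE]
  }

  wb <- if (has_water) find_water_bridges(all_bonds, top) else {
    find_water_bridges(all_bonds[0, , drop = FALSE], top)
  }
  ts <- hbond_timeseries(direct, wb$bridges, n_frames, traj$times,
                         window = config$smooth_window)
  direct_pairs <- hbond_pairs_of(direct, top)
  cm_h <- build_contact_map(direct_pairs, top)
  cm_b <- build_contact_map(wb$pairs, top)
  du_h <- duration_stats(direct_pairs, top, config$interval_ns, n_frames,
                         traj$times)
  du_b <- duration_stats(wb$pairs, top, config$interval_ns, n_frames,
                         traj$times)
  sas_tabs <- list()
  for (g in c("solute_A", "solute_B")) {
    st <- sas_timeseries(traj, top$groups[[g]], config$sas)
    st$group <- g
    sas_tabs[[g]] <- st[, c("frame", "time_ns", "group", "area_A2")]
  }
  sas_tab <- do.call(rbind, sas_tabs)
  rownames(sas_tab) <- NULL

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  .write_csv_atomic(ts, p("timeseries.csv"))
  write_hbond_csv(all_bonds, top, p("hbonds.csv"))
  .write_csv_atomic(as.data.frame(cm_h), p("contact_map_hbonds.csv"))
  .write_csv_atomic(as.data.frame(cm_b), p("contact_map_bridges.csv"))
  .write_csv_atomic(du_h, p("durations_hbonds.csv"))
  .write_csv_atomic(du_b, p("durations_bridges.csv"))
  .write_csv_atomic(sas_tab, p("sas_timeseries.csv"))
  jsonlite::write_json(
    list(hbonds = as.data.frame(cm_h), bridges = as.data.frame(cm_b),
         totals = list(hbonds = attr(cm_h, "total"),
                       bridges = attr(cm_b, "total"))),
    p("contact_map.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)

  meta <- list(
    config = list(
      trajectory = config$trajectory, select_A = config$select_A,
      select_B = config$select_B, interval_ns = config$interval_ns,
      out_dir = config$out_dir, water_names = config$water_names,
      hbond = unclass(config$hbond),
      sas = list(probe_radius = config$sas$probe_radius,
                 n_sphere_points = config$sas$n_sphere_points),
      between_direction = config$between_direction,
      smooth_window = config$smooth_window, log_level = config$log_level),
    package_version = as.character(utils::packageVersion("wbridge")),
    r_version = R.version.string,
    n_frames = n_frames, n_atoms = nrow(top$atoms),
    bridge_analysis = has_water,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_info("totals: %d bond records, %d bridge records, %d frames",
           nrow(all_bonds), nrow(wb$bridges), n_frames)

  invisible(structure(list(
    timeseries = ts, hbonds = all_bonds, bridges = wb$bridges,
    bridge_pairs = wb$pairs, contact_map_hbonds = cm_h,
    contact_map_bridges = cm_b, durations_hbonds = du_h,
    durations_bridges = du_b, sas = sas_tab, topology = top,
    metadata = meta), class = "results_bundle"))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("results_bundle: %d frames, %d bond records, %d bridges\n",
              x$metadata$n_frames, nrow(x$hbonds), nrow(x$bridges)))
  cat(sprintf("  unique A-B pairs: %d (bonds), %d (bridges)\n",
              nrow(x$contact_map_hbonds), nrow(x$contact_map_bridges)))
  invisible(x)
}
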