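fixture_bonds <- function(scenario = "bridge_basic", n_frames = 4, seed = 2) {
  fx <- generate_fixture(scenario, n_frames = n_frames, seed = seed)
  list(fx = fx, traj = fx$trajectory,
       bonds = hbond_trajectory(fx$trajectory))
}

test_that("a water bonded to both solutes is a bridge; one-sided waters are not", {
  fb <- fixture_bonds()
  wb <- find_water_bridges(fb$bonds, fb$traj$topology)
  # exactly one bridging water per frame (HOH 100); HOH 102 binds A only
  expect_equal(nrow(wb$bridges), 4L)
  expect_true(all(grepl("HOH\\|100", wb$bridges$water)))
  expect_equal(wb$bridges$n_bonds_A, rep(1L, 4))
  expect_equal(wb$bridges$n_bonds_B, rep(1L, 4))
  expect_true(all(wb$bridges$n_donor_role == 2L))
  lab <- atom_labels_of(fb$traj$topology, wb$pairs)
  expect_true(all(lab$label_A == "GCO 1 O" & lab$label_B == "LPO 12 O1P"))
})

test_that("two waters spanning the same atom pair give 2 bridges, 1 mapped pair", {
  # two waters, each donating to the same A-side O and B-side O
  blks <- list()
  a <- data.frame(serial = NA, name = c("C", "O"), resname = "GCO", chain = "A",
                  resid = 1, element = c("C", "O"))
  b <- data.frame(serial = NA, name = c("P", "O1P"), resname = "LPO", chain = "B",
                  resid = 2, element = c("P", "O"))
  # A-O at origin, B-O at (0, 5.4, 0); waters on either side donating to both
  w <- function(resid, x) data.frame(serial = NA, name = c("O", "H1", "H2"),
                                     resname = "HOH", chain = "W", resid = resid,
                                     element = c("O", "H", "H"))
  atoms <- rbind(a, b, w(10), w(11))
  atoms$serial <- seq_len(nrow(atoms))
  oa <- c(0, 0, 0); ca <- c(0, 0, -1.22)
  ob <- c(0, 5.4, 0); pb <- c(0, 5.4 + 1.61, 0)
  mk_water <- function(x_side) {
    # O equidistant from both acceptors; H1 aims at A-O, H2 at B-O, H...O 2.0
    ow <- c(x_side, 2.7, 0)
    h1 <- ow + 0.9572 * (oa - ow) / sqrt(sum((oa - ow)^2))
    h2 <- ow + 0.9572 * (ob - ow) / sqrt(sum((ob - ow)^2))
    rbind(ow, h1, h2)
  }
  xyz <- rbind(ca, oa, pb, ob, mk_water(1.206), mk_water(-1.206))
  # reorder: atoms rows are C,O,P,O1P then waters
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  top <- topology(atoms)
  top$bonds <- infer_covalent_bonds(top, xyz)
  top <- assign_groups(top, "chain A", "chain B")
  traj <- trajectory(top, list(xyz), times = 0)
  bonds <- hbond_trajectory(traj)
  wb <- find_water_bridges(bonds, top)
  expect_equal(nrow(wb$bridges), 2L)
  expect_equal(nrow(unique(wb$pairs[, c("atom_A", "atom_B")])), 1L)
  cm <- build_contact_map(wb$pairs, top)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$percent, 100)
  expect_equal(cm$count, 1L)  # per-frame dedup: one pair-frame incidence
})

test_that("waters bonded only to one solute never bridge", {
  fb <- fixture_bonds("no_donors_on_B")
  wb <- find_water_bridges(fb$bonds, fb$traj$topology)
  expect_equal(nrow(wb$bridges), 0L)
  expect_equal(nrow(wb$pairs), 0L)
})

test_that("removing waters kills bridges but not direct-bond statistics", {
  fb <- fixture_bonds()
  top <- fb$traj$topology
  keep <- setdiff(seq_len(nrow(top$atoms)), top$groups$water)
  atoms2 <- top$atoms[keep, ]
  atoms2$serial <- seq_along(keep)
  remap <- match(seq_len(nrow(top$atoms)), keep)
  bonds2 <- top$bonds[top$bonds[, 1] %in% keep & top$bonds[, 2] %in% keep, ]
  bonds2 <- cbind(remap[bonds2[, 1]], remap[bonds2[, 2]])
  top2 <- topology(atoms2, bonds = bonds2)
  top2 <- assign_groups(top2, "chain A", "chain B")
  frames2 <- lapply(fb$traj$frames, function(m) m[keep, , drop = FALSE])
  traj2 <- trajectory(top2, frames2, times = fb$traj$times)
  bonds_nw <- hbond_trajectory(traj2)
  wb2 <- find_water_bridges(bonds_nw, top2)
  expect_equal(nrow(wb2$bridges), 0L)
  direct_old <- fb$bonds[fb$bonds$donor_heavy %in% top$groups$solute_A &
                           fb$bonds$acceptor %in% top$groups$solute_B, ]
  direct_new <- bonds_nw[bonds_nw$donor_heavy %in% top2$groups$solute_A &
                           bonds_nw$acceptor %in% top2$groups$solute_B, ]
  expect_equal(nrow(direct_new), nrow(direct_old))
  expect_equal(sort(direct_new$energy), sort(direct_old$energy), tolerance = 1e-12)
})

test_that("the timeseries has one row per frame, zeros included, raw counts intact", {
  fb <- fixture_bonds()
  top <- fb$traj$topology
  direct <- fb$bonds[fb$bonds$donor_heavy %in% top$groups$solute_A &
                       fb$bonds$acceptor %in% top$groups$solute_B, ]
  wb <- find_water_bridges(fb$bonds, top)
  ts <- hbond_timeseries(direct, wb$bridges, length(fb$traj$frames),
                         fb$traj$times)
  expect_equal(nrow(ts), 4L)
  expect_equal(ts$n_hbonds, rep(2L, 4))
  expect_equal(ts$n_bridges, rep(1L, 4))
  expect_equal(ts$time_ns, (0:3) * 0.1)

  ts_s <- hbond_timeseries(direct, wb$bridges, 4, fb$traj$times, window = 3)
  expect_equal(ts_s$n_hbonds, ts$n_hbonds)  # smoothing never alters raw column
  expect_true(all(c("n_hbonds_smooth", "n_bridges_smooth") %in% names(ts_s)))

  empty <- hbond_timeseries(direct[0, ], NULL, 0, numeric(0))
  expect_equal(nrow(empty), 0L)
})

test_that("contact maps normalize per-frame-deduplicated pair counts", {
  top <- water_dimer()$topology  # any topology with labeled atoms
  # planted pair-frame incidences: pair (1,4) in frames 1-3, pair (2,5) in 4
  pairs <- data.frame(frame = c(1, 2, 3, 4, 1),
                      atom_A = c(1, 1, 1, 2, 1),
                      atom_B = c(4, 4, 4, 5, 4))  # duplicate row in frame 1
  cm <- build_contact_map(pairs, top)
  expect_equal(cm$count, c(3L, 1L))
  expect_equal(cm$percent, c(75, 25))
  expect_equal(attr(cm, "total"), 4L)
  expect_equal(sum(cm$percent), 100)

  single <- build_contact_map(data.frame(frame = 1, atom_A = 1, atom_B = 4), top)
  expect_equal(single$percent, 100)

  none <- build_contact_map(pairs[0, ], top)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "total"), 0L)
})

test_that("occupancy durations follow the presence-count estimator", {
  top <- water_dimer()$topology
  all_frames <- data.frame(frame = 1:10, atom_A = 1, atom_B = 4)
  d <- duration_stats(all_frames, top, interval_ns = 0.1, n_frames = 10)
  expect_equal(d$occupancy_ns, 1.0)
  expect_equal(d$longest_run_ns, 1.0)

  sparse <- data.frame(frame = c(1, 2, 5), atom_A = 1, atom_B = 4)
  d2 <- duration_stats(sparse, top, interval_ns = 0.1, n_frames = 10)
  expect_equal(d2$occupancy_frames, 3L)
  expect_equal(d2$occupancy_ns, 0.3)
  expect_equal(d2$longest_run_ns, 0.2)
  expect_equal(d2$first_frame, 1L)
  expect_equal(d2$last_frame, 5L)

  expect_equal(nrow(duration_stats(sparse[0, ], top, 0.1, 10)), 0L)
  expect_error(duration_stats(sparse, top, 0.1, 10,
                              times = c(0, 100, 150, 400)), "resample")
})

test_that("occupancy is additive over a concatenation with a shared clock", {
  set.seed(31)
  pat <- as.integer(stats::runif(12) > 0.4)
  first <- data.frame(frame = which(pat[1:6] == 1), atom_A = 1, atom_B = 4)
  second <- data.frame(frame = which(pat[7:12] == 1) + 6, atom_A = 1, atom_B = 4)
  top <- water_dimer()$topology
  whole <- duration_stats(rbind(first, second), top, 0.1, 12)
  d1 <- duration_stats(first, top, 0.1, 6)
  d2 <- duration_stats(second, top, 0.1, 12)
  expect_equal(whole$occupancy_ns, sum(d1$occupancy_ns, d2$occupancy_ns))
})

test_that("bridge count per frame never exceeds the number of waters", {
  for (seed in c(3, 17)) {
    fb <- fixture_bonds(seed = seed)
    top <- fb$traj$topology
    n_waters <- length(unique(top$atoms$resid[top$groups$water]))
    wb <- find_water_bridges(fb$bonds, top)
    per_frame <- table(wb$bridges$frame)
    expect_true(all(per_frame <= n_waters))
  }
})
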