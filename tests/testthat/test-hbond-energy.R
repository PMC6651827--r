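test_that("the angular scaling factors hit their breakpoints and midpoints", {
  expect_equal(scale_dha(180), 1)
  expect_equal(scale_dha(100), 0)
  expect_equal(scale_dha(132.5), 0.5)   # (132.5 - 100) / 65
  expect_equal(scale_dha(50), 0)
  expect_equal(scale_hax(95, x_is_hydrogen = FALSE), 1)
  expect_equal(scale_hax(75, x_is_hydrogen = TRUE), 0)
  expect_equal(scale_hax(90, x_is_hydrogen = FALSE), 0.5)  # (90 - 85) / 10
  expect_equal(scale_hax(80, x_is_hydrogen = TRUE), 0.5)
  expect_error(scale_dha(-1), "\\[0, 180\\]")
  expect_error(scale_dha(181), "\\[0, 180\\]")
  expect_error(scale_hax(200, FALSE), "\\[0, 180\\]")
})

test_that("bond energy reproduces the clamp, the zero and the linear middle", {
  expect_equal(hbond_energy(2.0, 180, 180), 25)
  expect_equal(hbond_energy(1.2, 180, 180), 25)    # clamp: closer is not better
  expect_equal(hbond_energy(2.1, 180, 180), 25)
  expect_equal(hbond_energy(2.6, 180, 180), 0)
  expect_equal(hbond_energy(2.35, 180, 180), 12.5) # 25 * (2.6 - 2.35) / 0.5
  expect_true(hbond_energy(3.0, 180, 180) < 0)
  expect_error(hbond_energy(-1, 180, 180))
})

test_that("scaling factors are continuous, bounded and monotone on a fine grid", {
  grid <- seq(0, 180, by = 0.01)
  p <- hbond_params()
  for (fn in list(function(a) scale_dha(a, p),
                  function(a) scale_hax(a, FALSE, p),
                  function(a) scale_hax(a, TRUE, p))) {
    v <- fn(grid)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))            # non-decreasing
    expect_lt(max(abs(diff(v))), 0.002)       # no jumps: continuous at 0.01 deg
  }
})

test_that("energy is monotone in distance and in each angle over its ramp", {
  d <- seq(1.5, 3.0, by = 0.01)
  e <- hbond_energy(d, 180, 180)
  expect_true(all(diff(e) <= 0))
  expect_true(all(e <= 25))
  a <- seq(0, 180, by = 0.5)
  expect_true(all(diff(hbond_energy(2.0, a, 180)) >= 0))
  expect_true(all(diff(hbond_energy(2.0, 180, a)) >= 0))
})

test_that("parameter validation rejects inverted ramps and thresholds", {
  expect_error(hbond_params(d_clamp = 2.6, d_zero = 2.1))
  expect_error(hbond_params(threshold_energy = 30))
  expect_error(hbond_params(dha_ramp = c(165, 100)))
})

test_that("an ideal water dimer yields exactly one bond", {
  dimer <- water_dimer(1.9)
  bonds <- detect_hbonds(dimer$topology, dimer$xyz)
  expect_equal(nrow(bonds), 1L)
  expect_equal(bonds$energy, 25)
  expect_equal(bonds$donor_heavy, 1L)
  expect_equal(bonds$acceptor, 4L)
  expect_equal(oracle_hbonds(dimer$topology, dimer$xyz)$energy, 25)
})

test_that("all pairs beyond the zero distance give an empty result", {
  dimer <- water_dimer(3.5)
  expect_equal(nrow(detect_hbonds(dimer$topology, dimer$xyz)), 0L)
})

test_that("a geometry scoring exactly the threshold is not reported", {
  # scales at plateau: E = 25 * (2.6 - d) / 0.5 = 6.25 at d = 2.475
  ps <- make_geometry_probe_system(2.475, 180, 180)
  expect_equal(hbond_energy(2.475, 180, 180), 6.25)
  expect_equal(nrow(detect_hbonds(ps$topology, ps$xyz)), 0L)
  ps2 <- make_geometry_probe_system(2.474, 180, 180)
  expect_equal(nrow(detect_hbonds(ps2$topology, ps2$xyz)), 1L)
})

test_that("the X minimizing the H-A-X scale is chosen per acceptor", {
  # acceptor with two partners at very different H-A-X angles
  a <- data.frame(serial = 1:5, name = c("OD", "HD", "OA", "C1", "C2"),
                  resname = c("DNR", "DNR", "ACC", "ACC", "ACC"),
                  chain = c("A", "A", "B", "B", "B"), resid = c(1, 1, 2, 2, 2),
                  element = c("O", "H", "O", "C", "C"))
  # D-H along +x; acceptor O at 1.9 beyond H; C1 at H-A-X 170 deg, C2 at 90 deg
  O_A <- c(0.96 + 1.9, 0, 0)
  ang <- function(th) O_A + 1.43 * c(-cos(th * pi / 180), sin(th * pi / 180), 0)
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), O_A, ang(170), ang(90))
  top <- topology(a, bonds = rbind(c(1L, 2L), c(3L, 4L), c(3L, 5L)))
  top <- assign_groups(top, "chain A", "chain B")
  b <- detect_hbonds(top, xyz)
  expect_equal(nrow(b), 1L)
  expect_equal(b$chosen_X, 5L)        # the 90-degree partner scales lower
  expect_equal(b$scale_HAX, 0.5)      # mid-ramp of the heavy-X factor
  expect_equal(b$energy, 12.5)
})

test_that("detection equals the exhaustive brute-force scorer on random systems", {
  set.seed(42)
  n_sys <- 200
  n_checked <- 0L
  n_with_bonds <- 0L
  for (k in seq_len(n_sys)) {
    sys <- random_polar_system(n_water = sample(3:9, 1),
                               n_amine = sample(1:2, 1),
                               n_carbonyl = sample(1:2, 1))
    got <- detect_hbonds(sys$topology, sys$xyz)
    want <- oracle_hbonds(sys$topology, sys$xyz)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got[, c("donor_heavy", "hydrogen", "acceptor")],
                   want[, c("donor_heavy", "hydrogen", "acceptor")],
                   ignore_attr = TRUE)
      expect_equal(got$energy, want$energy, tolerance = 1e-12)
      n_with_bonds <- n_with_bonds + 1L
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, n_sys)
  expect_gt(n_with_bonds, n_sys / 4)  # the comparison is not vacuous
})

test_that("rigid rotation and translation leave every energy unchanged", {
  set.seed(7)
  sys <- random_polar_system(n_water = 8, n_amine = 2, n_carbonyl = 2)
  ref <- detect_hbonds(sys$topology, sys$xyz)
  for (rep in 1:5) {
    R <- random_rot()
    shift <- stats::runif(3, -20, 20)
    moved <- sweep(sys$xyz %*% t(R), 2, shift, "+")
    got <- detect_hbonds(sys$topology, moved)
    expect_equal(got$energy, ref$energy, tolerance = 1e-9)
    expect_equal(got[, 1:3], ref[, 1:3], ignore_attr = TRUE)
  }
})

test_that("the group filter restricts donor/acceptor membership", {
  fx <- generate_fixture("bridge_basic", n_frames = 1, seed = 5)
  top <- fx$trajectory$topology
  xyz <- fx$trajectory$frames[[1]]
  all_b <- detect_hbonds(top, xyz)
  ab <- detect_hbonds(top, xyz, between = c("solute_A", "solute_B"))
  expect_equal(nrow(ab), 2L)   # the two planted direct bonds
  expect_true(nrow(all_b) > nrow(ab))  # water bonds exist too
  wa <- detect_hbonds(top, xyz, between = c("water", "solute_A"))
  expect_true(all(top$atoms$resname[wa$donor_heavy] == "HOH"))
  fwd <- detect_hbonds(top, xyz, between = c("solute_B", "solute_A"),
                       direction = "forward")
  expect_equal(nrow(fwd), 0L)  # B never donates in this fixture
})

test_that("the strictest-only toggle keeps the lowest-scale bond per acceptor", {
  # two hydroxide-like donors aimed at one carbonyl oxygen: donor 1 comes in
  # at H-A-X 90 deg (scale 0.5), donor 2 at 120 deg (scale 1)
  a <- data.frame(serial = 1:6,
                  name = c("O", "H", "O", "H", "C", "O"),
                  resname = c("DOH", "DOH", "DOH", "DOH", "ACC", "ACC"),
                  chain = c("A", "A", "A", "A", "B", "B"),
                  resid = c(1, 1, 2, 2, 3, 3),
                  element = c("O", "H", "O", "H", "C", "O"))
  v2 <- c(0, sin(2 * pi / 3), -cos(2 * pi / 3))  # 120 deg from the C direction
  xyz <- rbind(c(2.86, 0, 0), c(1.9, 0, 0),
               2.86 * v2, 1.9 * v2,
               c(0, 0, -1.22), c(0, 0, 0))
  top <- topology(a, bonds = rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
  top <- assign_groups(top, "chain A", "chain B")
  all_b <- detect_hbonds(top, xyz)
  expect_equal(nrow(all_b), 2L)
  expect_equal(sort(all_b$scale_HAX), c(0.5, 1))
  one <- detect_hbonds(top, xyz, one_per_acceptor = TRUE)
  expect_equal(nrow(one), 1L)
  expect_equal(one$scale_HAX, 0.5)
  expect_equal(one$donor_heavy, 1L)
  expect_equal(one$energy, 12.5)

  # on random systems the toggle never leaves a duplicated acceptor
  set.seed(99)
  for (k in 1:20) {
    sys <- random_polar_system(n_water = 8, n_amine = 2, n_carbonyl = 1)
    one_r <- detect_hbonds(sys$topology, sys$xyz, one_per_acceptor = TRUE)
    expect_equal(anyDuplicated(one_r$acceptor), 0L)
    expect_true(all(one_r$energy %in%
                      detect_hbonds(sys$topology, sys$xyz)$energy))
  }
})
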