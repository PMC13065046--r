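# hand-built single-water system: one channel-like protein atom column at
# the origin, one water whose z follows a scripted path
scripted_water_traj <- function(z_path, lateral = c(0, 0), box = c(40, 40, 80)) {
  prot_z <- seq(-15, 15, by = 2.5)
  prot <- cbind(3, 0, prot_z)
  atoms <- dplyr::bind_rows(
    tibble::tibble(atom_name = "C", element = "C", residue_name = "DUM",
                   residue_id = seq_along(prot_z), chain_id = "P"),
    tibble::tibble(atom_name = "O", element = "O", residue_name = "HOH",
                   residue_id = 1L, chain_id = "W"))
  frames <- lapply(z_path, function(z) rbind(prot, c(lateral[1], lateral[2], z)))
  toy_traj(frames, atoms = atoms, box = box)
}

slab <- membrane_slab(-15, 15)

run_events <- function(tr, cutoff = 6) {
  vol <- protein_volume(select_atoms(tr, water = FALSE), slab, cutoff)
  extract_events(occupancy_series(tr, vol), tr, slab)
}

test_that("slab estimation from leaflet markers", {
  mk <- c(rep(-17, 50), rep(17, 50))
  atoms <- tibble::tibble(atom_name = "P", element = "P", residue_name = "POPC",
                          residue_id = seq_along(mk), chain_id = "L")
  tr <- toy_traj(list(cbind(0, 0, mk)), atoms = atoms)
  sl <- estimate_slab(tr, seq_along(mk))
  expect_equal(sl$z_lower, -17)
  expect_equal(sl$z_upper, 17)

  # one +30 outlier, trimmed mean keeps the upper bound near +17
  mk2 <- c(rep(-17, 50), rep(17, 49), 30)
  tr2 <- toy_traj(list(cbind(0, 0, mk2)), atoms = atoms)
  sl2 <- estimate_slab(tr2, seq_along(mk2), quantile_trim = 0.05)
  expect_equal(sl2$z_upper, 17, tolerance = 1e-6)
  untrimmed <- estimate_slab(tr2, seq_along(mk2))
  expect_gt(untrimmed$z_upper, 17.2)

  mk3 <- rep(5, 10)
  tr3 <- toy_traj(list(cbind(0, 0, mk3)), atoms = atoms[1:10, ])
  expect_error(estimate_slab(tr3, 1:10), "one side")
})

test_that("in-volume membership needs both slab z-range and proximity", {
  # water at z=0, 3 A from protein -> inside
  tr <- scripted_water_traj(0, lateral = c(0, 0))  # protein column at x=3
  vol <- protein_volume(select_atoms(tr, water = FALSE), slab, 6)
  expect_equal(occupancy_series(tr, vol)[[1]], select_atoms(tr, water = TRUE))
  # 8 A from protein -> outside
  tr2 <- scripted_water_traj(0, lateral = c(11, 0))
  expect_length(occupancy_series(tr2, vol)[[1]], 0L)
  # above the slab -> outside even when near the protein
  tr3 <- scripted_water_traj(20, lateral = c(0, 0))
  expect_length(occupancy_series(tr3, vol)[[1]], 0L)
})

test_that("scripted crossings, returns and open events classify correctly", {
  crossed <- scripted_water_traj(c(-20, -10, 0, 10, 20))
  ev <- run_events(crossed)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$outcome, "crossed")
  expect_equal(ev$entry_side, "lower")
  expect_equal(ev$exit_side, "upper")
  expect_equal(ev$entry_frame, 2L)
  expect_equal(ev$exit_frame, 5L)

  returned <- scripted_water_traj(c(-20, -10, -5, -10, -20))
  ev2 <- run_events(returned)
  expect_equal(ev2$outcome, "returned")

  open_ev <- scripted_water_traj(c(-20, -10, 0, 5, 10))
  ev3 <- run_events(open_ev)
  expect_equal(ev3$outcome, "unresolved")
  expect_true(is.na(ev3$exit_frame))
  expect_equal(translocation_rate(ev3)$n_entries, 1L)
  expect_true(is.na(translocation_rate(ev3)$rate))
})

test_that("one water can produce several events; min_dwell debounces", {
  z <- c(-20, 0, -20, 0, 5, 20)
  tr <- scripted_water_traj(z)
  ev <- run_events(tr)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$outcome, c("returned", "crossed"))
  vol <- protein_volume(select_atoms(tr, water = FALSE), slab, 6)
  ev2 <- extract_events(occupancy_series(tr, vol), tr, slab, min_dwell = 2L)
  expect_equal(nrow(ev2), 1L)  # the single-frame excursion is debounced
  expect_equal(ev2$outcome, "crossed")
})

test_that("translocation rate arithmetic and sentinels", {
  ev <- tibble::tibble(outcome = c("crossed", rep("returned", 3)))
  r <- translocation_rate(ev)
  expect_equal(r$rate, 0.25)
  expect_equal(100 * r$rate, 25.0)
  expect_equal(translocation_rate(tibble::tibble(outcome = rep("returned", 5)))$rate, 0)
  r0 <- translocation_rate(tibble::tibble(outcome = character()))
  expect_true(is.na(r0$rate))
  # replica-tagged events give per-replica rates and their mean
  ev2 <- tibble::tibble(outcome = rep(c("crossed", "returned"), c(4, 6)),
                        replica = rep(1:2, each = 5))
  r2 <- translocation_rate(ev2)
  expect_equal(sort(r2$per_replica$rate), c(0, 4 / 5))
  expect_equal(r2$mean_replica_rate, 0.4)
})

test_that("planted events are recovered exactly with conservation", {
  sys <- generate_permeation_system(seed = 77, n_crossed = 12, n_returned = 28,
                                    n_unresolved = 6)
  res <- run_permeation(sys$traj, membrane_slab(-15, 15))
  r <- res$rate
  expect_equal(r$rate, sys$true_rate)
  expect_equal(r$n_crossed, 12L)
  expect_equal(r$n_returned, 28L)
  expect_equal(r$n_unresolved, 6L)
  expect_equal(r$n_entries, r$n_crossed + r$n_returned + r$n_unresolved)
  # event-level agreement with the planted script
  m <- merge(as.data.frame(res$events), as.data.frame(sys$truth), by = "water")
  expect_equal(nrow(m), 46L)
  expect_equal(m$outcome.x, m$outcome.y)
  expect_equal(m$entry_side.x, m$entry_side.y)
  expect_equal(m$entry_frame.x, m$entry_frame.y)
})

test_that("time reversal preserves the crossed count and swaps sides", {
  sys <- generate_permeation_system(seed = 19, n_crossed = 8, n_returned = 10,
                                    n_unresolved = 0)
  fwd <- run_permeation(sys$traj, membrane_slab(-15, 15))$rate
  rev_traj <- sys$traj
  rev_traj$coords <- rev_traj$coords[rev(seq_len(n_frames(sys$traj))), , , drop = FALSE]
  rev_traj$box <- rev_traj$box
  bwd <- run_permeation(rev_traj, membrane_slab(-15, 15))$rate
  expect_equal(bwd$n_crossed, fwd$n_crossed)
  expect_equal(bwd$n_returned, fwd$n_returned)
})

test_that("rate is invariant under refinement of a piecewise-constant path", {
  z <- c(-20, -10, 0, 10, 20)
  coarse <- scripted_water_traj(z)
  fine <- scripted_water_traj(rep(z, each = 3))
  rc <- translocation_rate(run_events(coarse))
  rf <- translocation_rate(run_events(fine))
  expect_equal(rc$rate, rf$rate)
  expect_equal(rc$n_entries, rf$n_entries)
})

test_that("laterally entering waters get the nearest-boundary side", {
  # water stays in the slab z-range but approaches from far away laterally,
  # near the upper boundary, then leaves again
  tr <- scripted_water_traj(c(10, 10, 10), lateral = c(0, 0))
  tr$coords[1, n_atoms(tr), 1] <- 30  # far in x at frame 1 (outside)
  tr$coords[3, n_atoms(tr), 1] <- 30  # and at frame 3
  ev <- run_events(tr)
  expect_equal(ev$entry_side, "upper")
  expect_equal(ev$outcome, "returned")
})
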