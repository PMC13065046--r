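test_that("contact graph edges follow the minimum heavy-atom distance", {
  # 7 copies far apart -> edgeless
  far <- cbind(seq(0, 180, by = 30), 0, 0)
  tr <- copies_traj(list(far), box = c(400, 400, 400))
  ed <- copy_contact_graph(frame_coords(tr, 1), tr$atoms$copy_id,
                           contact_graph_spec(4.5, use_pbc = TRUE),
                           box = c(400, 400, 400), heavy = tr$atoms$is_heavy)
  expect_equal(nrow(ed), 0L)

  # chain A-B-C: adjacent centres 6 apart (atom gap 4), C far from A
  abc <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  tr2 <- copies_traj(list(abc), box = c(200, 200, 200))
  ed2 <- copy_contact_graph(frame_coords(tr2, 1), tr2$atoms$copy_id,
                            contact_graph_spec(4.5, TRUE), box = c(200, 200, 200),
                            heavy = tr2$atoms$is_heavy)
  expect_equal(unname(ed2), rbind(c(1L, 2L), c(2L, 3L)), ignore_attr = TRUE)
  expect_error(copy_contact_graph(frame_coords(tr2, 1), tr2$atoms$copy_id,
                                  contact_graph_spec(4.5, TRUE), box = NULL),
               "periodic box")
})

test_that("a boundary-only contact needs the minimum image (27-image oracle)", {
  box <- c(50, 60, 70)
  cent <- rbind(c(2, 10, 10), c(47, 10, 10))  # 3 A apart only across x
  tr <- copies_traj(list(cent), box = box)
  xyz <- frame_coords(tr, 1)
  a <- xyz[1:2, , drop = FALSE]; b <- xyz[3:4, , drop = FALSE]
  oracle <- brute_pbc_min_dist(a, b, box)
  expect_equal(oracle, 3.0)  # centres 5 apart across x, dumbbell tips close by 2
  with_pbc <- copy_contact_graph(xyz, tr$atoms$copy_id, contact_graph_spec(4.5, TRUE),
                                 box = box, heavy = tr$atoms$is_heavy)
  no_pbc <- copy_contact_graph(xyz, tr$atoms$copy_id, contact_graph_spec(4.5, FALSE),
                               box = box, heavy = tr$atoms$is_heavy)
  expect_equal(nrow(with_pbc), 1L)
  expect_equal(nrow(no_pbc), 0L)
})

test_that("components agree with brute-force transitive closure", {
  set.seed(55)
  for (i in 1:40) {
    ids <- 1:7
    ed <- random_graph_edges(7, runif(1, 0.1, 0.5))
    edges <- cbind(i = as.integer(ed$from), j = as.integer(ed$to))
    attr(edges, "copies") <- ids
    got <- memflux:::graph_entities(edges)
    want <- brute_components(edges, ids)
    expect_equal(unname(got[order(vapply(got, min, numeric(1)))]),
                 unname(want[order(vapply(want, min, numeric(1)))]))
  }
})

test_that("scripted merge schedule 7 -> 4 -> 2 -> 1 is recovered exactly", {
  sched <- list(list(frame = 4, copies = c(1, 2)),
                list(frame = 4, copies = c(3, 4)),
                list(frame = 4, copies = c(5, 6)),
                list(frame = 8, copies = c(1, 3, 5)),
                list(frame = 12, copies = c(1, 7)))
  sys <- generate_aggregation_trajectory(seed = 66, merge_schedule = sched,
                                         n_frames = 16)
  tl <- entity_timeline(sys$traj)
  expect_equal(tl$n_entities, sys$truth$n_entities)
  expect_equal(tl$n_entities[c(1, 4, 8, 12)], c(7L, 4L, 2L, 1L))
  expect_equal(tl$entities, sys$truth$entities)
  expect_equal(attr(tl, "time_to_single_entity"), sys$traj$frame_times[12])
  expect_equal(glance(tl)$final_entities, 1L)
})

test_that("a merge placed only across the boundary needs use_pbc", {
  sys <- generate_aggregation_trajectory(
    seed = 67, n_frames = 6,
    pbc_contact = list(frame = 3, copies = c(2, 5)))
  tl_pbc <- entity_timeline(sys$traj, contact_graph_spec(4.5, TRUE))
  tl_raw <- entity_timeline(sys$traj, contact_graph_spec(4.5, FALSE))
  expect_equal(tl_pbc$n_entities, c(7L, 7L, 6L, 6L, 6L, 6L))
  expect_equal(tl_raw$n_entities, rep(7L, 6))
  expect_equal(tl_pbc$n_entities, sys$truth$n_entities)
})

test_that("counts never reach one -> time_to_single_entity is missing", {
  sys <- generate_aggregation_trajectory(seed = 68, n_frames = 5,
                                         merge_schedule = list(list(frame = 3, copies = c(1, 2))))
  tl <- entity_timeline(sys$traj)
  expect_equal(tl$n_entities, c(7L, 7L, 6L, 6L, 6L))
  expect_true(is.na(attr(tl, "time_to_single_entity")))
})

test_that("entity count is monotone non-increasing in the cutoff", {
  sys <- generate_aggregation_trajectory(seed = 69, n_frames = 8,
                                         merge_schedule = list(list(frame = 2, copies = c(1, 2)),
                                                               list(frame = 5, copies = c(3, 4))))
  sens <- entity_sensitivity(sys$traj, cutoffs = c(4.0, 4.5, 5.0))
  wide <- tidyr::pivot_wider(sens, names_from = "cutoff", values_from = "n_entities")
  expect_true(all(wide$`4.5` <= wide$`4`))
  expect_true(all(wide$`5` <= wide$`4.5`))
})

test_that("lattice-vector shifts leave the PBC contact graph unchanged", {
  box <- c(50, 50, 50)
  cent <- rbind(c(2, 10, 10), c(47, 10, 10), c(25, 25, 25))
  tr <- copies_traj(list(cent), box = box)
  xyz <- frame_coords(tr, 1)
  g0 <- copy_contact_graph(xyz, tr$atoms$copy_id, contact_graph_spec(4.5, TRUE),
                           box = box, heavy = tr$atoms$is_heavy)
  shifted <- sweep(xyz, 2, c(50, -100, 50), "+")
  g1 <- copy_contact_graph(shifted, tr$atoms$copy_id, contact_graph_spec(4.5, TRUE),
                           box = box, heavy = tr$atoms$is_heavy)
  expect_equal(unname(g0), unname(g1), ignore_attr = TRUE)
})

test_that("entity labels persist by maximal overlap with the stated tie rules", {
  # hand scripted partitions over 5 copies:
  # f1: {1}{2}{3}{4}{5} ; f2: {1}{2,3}{4}{5} ; f3: {1,2,3}{4,5} ; f4: {1,2,3,4,5}
  parts <- list(list(1, 2, 3, 4, 5),
                list(1, c(2, 3), 4, 5),
                list(c(1, 2, 3), c(4, 5)),
                list(c(1, 2, 3, 4, 5)))
  tl <- tibble::tibble(frame = 1:4,
                       time = NA_real_,
                       n_entities = vapply(parts, length, integer(1)),
                       entities = lapply(parts, function(p) lapply(p, as.integer)))
  lab <- entity_track_labels(tl)
  l <- split(lab$label, lab$frame)
  # frame 2: {2,3} inherits the label of {2} or {3}; overlap tie -> lowest copy id ({2})
  expect_equal(l[[2]][2], l[[1]][2])
  # frame 3: {1,2,3} inherits the larger predecessor {2,3}'s label, not {1}'s
  expect_equal(l[[3]][1], l[[2]][2])
  # frame 4: full merge keeps the largest predecessor's label
  expect_equal(l[[4]], l[[3]][1])
  # no topology change -> constant labels
  tl2 <- tibble::tibble(frame = 1:3, time = NA_real_, n_entities = 2L,
                        entities = rep(list(list(c(1L, 2L), c(3L, 4L))), 3))
  lab2 <- entity_track_labels(tl2)
  expect_equal(unique(split(lab2$label, lab2$frame)), unique(list(lab2$label[1:2])))
})
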