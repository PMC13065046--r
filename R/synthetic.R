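# Seeded generators for synthetic trajectories with machine-readable ground
# truth. These are not physical simulations: they plant the exact geometric
# structure each analysis assumes (crossing waters, hydrogen-bonded chains,
# merging copies, conformational clusters) so recovery can be scored exactly.

# run code under a temporary RNG state; leaves the caller's stream untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# dummy channel: rings of carbon atoms of given radius spanning the slab
channel_atoms <- function(slab, radius = 5, ring_spacing = 2.5, per_ring = 8) {
  zs <- seq(slab$z_lower, slab$z_upper, by = ring_spacing)
  ang <- seq(0, 2 * pi, length.out = per_ring + 1)[-(per_ring + 1)]
  xyz <- do.call(rbind, lapply(zs, function(z) cbind(radius * cos(ang), radius * sin(ang), z)))
  atoms <- tibble(atom_name = "C", element = "C", residue_name = "DUM",
                  residue_id = rep(seq_along(zs), each = per_ring), chain_id = "P")
  list(atoms = atoms, xyz = xyz)
}

# ideal water geometry: O at `o`, H1 along `dir1` (unit), H2 at the water
# angle from H1 in the plane spanned with `dir2`
water_coords <- function(o, dir1, dir2 = c(0, 0, 1)) {
  d1 <- dir1 / sqrt(sum(dir1^2))
  p <- dir2 - sum(dir2 * d1) * d1
  if (sum(p^2) < 1e-8) p <- c(1, 0, 0) - sum(c(1, 0, 0) * d1) * d1
  p <- p / sqrt(sum(p^2))
  ang <- 104.52 * pi / 180
  d2 <- cos(ang) * d1 + sin(ang) * p
  rbind(o, o + 0.9572 * d1, o + 0.9572 * d2)
}

water_atoms_meta <- function(n, start_resid = 1L, chain = "W") {
  tibble(atom_name = rep(c("O", "H1", "H2"), n), element = rep(c("O", "H", "H"), n),
         residue_name = "HOH",
         residue_id = rep(start_resid + seq_len(n) - 1L, each = 3L),
         chain_id = chain)
}

#' Generate a permeation system with planted crossing/returning events
#'
#' A static cylindrical dummy channel spans the slab; each planted water
#' follows a piecewise-linear path through the channel realising its
#' scripted outcome (`crossed`, `returned` or `unresolved`), and background
#' waters random-walk far outside the protein volume. Deterministic given
#' the seed.
#'
#' @param seed Integer seed.
#' @param n_crossed,n_returned,n_unresolved Numbers of planted events of
#'   each outcome.
#' @param n_background Background (never-entering) waters.
#' @param n_frames Trajectory length in frames (>= 8).
#' @param box Box lengths (angstrom).
#' @param slab A [membrane_slab()].
#' @return List with `traj` (`mdtrj`), `truth` (tibble of planted events:
#'   `water`, `entry_side`, `outcome`, `entry_frame`, `exit_frame`) and
#'   `true_rate`.
#' @export
generate_permeation_system <- function(seed, n_crossed = 10, n_returned = 30,
                                       n_unresolved = 0, n_background = 10,
                                       n_frames = 40, box = c(60, 60, 80),
                                       slab = membrane_slab(-15, 15)) {
  if (n_frames < 8L) abort("n_frames must be >= 8")
  if (slab$z_upper - slab$z_lower >= box[3] - 10) abort("slab must fit inside the box with margin")
  n_plant <- n_crossed + n_returned + n_unresolved
  with_local_seed(seed, {
    ch <- channel_atoms(slab)
    outcomes <- c(rep("crossed", n_crossed), rep("returned", n_returned),
                  rep("unresolved", n_unresolved))
    outcomes <- sample(outcomes)
    sides <- sample(c("lower", "upper"), n_plant, replace = TRUE)
    z_out <- function(side) if (side == "lower") slab$z_lower - 6 else slab$z_upper + 6
    zin_near <- function(side) if (side == "lower") slab$z_lower + 1 else slab$z_upper - 1
    wat_z <- matrix(NA_real_, n_frames, n_plant)
    truth <- vector("list", n_plant)
    for (i in seq_len(n_plant)) {
      if (outcomes[i] == "unresolved") {
        entry <- sample(2:(n_frames - 2L), 1)
        exitf <- NA_integer_
        dwell_end <- n_frames
      } else {
        entry <- sample(2:(n_frames - 4L), 1)
        exitf <- sample((entry + 2L):(n_frames - 1L), 1)
        dwell_end <- exitf - 1L
      }
      side <- sides[i]
      other <- if (side == "lower") "upper" else "lower"
      z <- rep(z_out(side), n_frames)
      zi <- zin_near(side)
      zf <- switch(outcomes[i],
                   crossed = zin_near(other),
                   returned = zi + if (side == "lower") 4 else -4,
                   unresolved = 0)
      z[entry:dwell_end] <- seq(zi, zf, length.out = dwell_end - entry + 1L)
      if (!is.na(exitf)) z[exitf:n_frames] <- z_out(if (outcomes[i] == "crossed") other else side)
      wat_z[, i] <- z
      truth[[i]] <- tibble(entry_side = side, outcome = outcomes[i],
                           entry_frame = entry, exit_frame = exitf)
    }
    lat <- cbind(runif(n_plant, -1.5, 1.5), runif(n_plant, -1.5, 1.5))
    # background waters: far from the channel laterally, inside the box
    bg0 <- cbind(runif(n_background, 18, 25) * sample(c(-1, 1), n_background, TRUE),
                 runif(n_background, 18, 25) * sample(c(-1, 1), n_background, TRUE),
                 runif(n_background, slab$z_lower, slab$z_upper))
    n_ch <- nrow(ch$xyz)
    nat <- n_ch + 3L * (n_plant + n_background)
    coords <- array(NA_real_, dim = c(n_frames, nat, 3L))
    for (f in seq_len(n_frames)) {
      w <- do.call(rbind, lapply(seq_len(n_plant), function(i) {
        water_coords(c(lat[i, 1], lat[i, 2], wat_z[f, i]), c(1, 0, 0))
      }))
      bgf <- bg0 + matrix(rnorm(3 * n_background, sd = 0.25), ncol = 3)
      bgw <- do.call(rbind, lapply(seq_len(n_background), function(i) {
        water_coords(bgf[i, ], c(0, 1, 0))
      }))
      coords[f, , ] <- rbind(ch$xyz, w, bgw)
    }
    atoms <- bind_rows(ch$atoms,
                       water_atoms_meta(n_plant, 1L, "W"),
                       water_atoms_meta(n_background, n_plant + 1L, "X"))
    traj <- trajectory(atoms, coords, box = box,
                       frame_times = 0.1 * seq_len(n_frames))
    o_idx <- n_ch + 3L * (seq_len(n_plant) - 1L) + 1L
    truth <- bind_rows(truth)
    truth$water <- o_idx
    truth <- truth[, c("water", "entry_side", "outcome", "entry_frame", "exit_frame")]
    resolved <- sum(truth$outcome %in% c("crossed", "returned"))
    list(traj = traj, truth = truth,
         true_rate = if (resolved > 0) sum(truth$outcome == "crossed") / resolved else NA_real_)
  })
}

#' Generate frames with planted hydrogen-bonded water chains
#'
#' Each frame contains the dummy channel, planted in-volume water chains at
#' 2.8 angstrom O-O spacing with the donor hydrogen on the O-O axis (ideal
#' D-H...A angle of 180 degrees), and isolated in-volume decoy waters.
#'
#' @param seed Integer seed.
#' @param planted_lengths List (one element per frame) of integer chain
#'   lengths; an empty vector means a decoys-only frame. Lengths 2-9 fit the
#'   default slab.
#' @param n_decoys Isolated waters per frame.
#' @param box,slab As in [generate_permeation_system()].
#' @return List with `traj`, `truth` (tibble `frame`, `lengths` list-column,
#'   `max_length`, `mean_length`).
#' @export
generate_wire_frames <- function(seed, planted_lengths = list(c(3, 5), 9, integer(0)),
                                 n_decoys = 4, box = c(60, 60, 80),
                                 slab = membrane_slab(-15, 15)) {
  planted_lengths <- lapply(planted_lengths, as.integer)
  nf <- length(planted_lengths)
  if (any(vapply(planted_lengths, function(v) length(v) > 0 && any(v < 2), logical(1)))) {
    abort("planted chain lengths must be >= 2")
  }
  span <- slab$z_upper - slab$z_lower - 4
  if (any(unlist(planted_lengths) * 2.8 > span)) abort("a planted chain does not fit the slab")
  with_local_seed(seed, {
    ch <- channel_atoms(slab)
    n_ch <- nrow(ch$xyz)
    # lateral slots for chains (distinct, > 3.6 A apart) and decoys
    chain_slots <- cbind(c(0, 0, 2.6, -2.6), c(0, 3.9, -2.9, -2.9))
    max_chains <- nrow(chain_slots)
    if (any(vapply(planted_lengths, length, integer(1)) > max_chains)) {
      abort(sprintf("at most %d chains per frame supported", max_chains))
    }
    n_water <- max(vapply(planted_lengths, sum, integer(1))) + n_decoys
    coords <- array(NA_real_, dim = c(nf, n_ch + 3L * n_water, 3L))
    truth <- vector("list", nf)
    decoy_z <- seq(slab$z_lower + 2, slab$z_upper - 2, length.out = max(n_decoys, 2))[seq_len(n_decoys)]
    for (f in seq_len(nf)) {
      lens <- planted_lengths[[f]]
      wxyz <- NULL
      for (ci in seq_along(lens)) {
        L <- lens[ci]
        z0 <- -(L - 1) * 2.8 / 2
        slot <- chain_slots[ci, ]
        for (k in seq_len(L)) {
          o <- c(slot[1], slot[2], z0 + (k - 1) * 2.8)
          # donor H on the O-O axis toward the next molecule (D-H...A = 180)
          dir1 <- if (k < L) c(0, 0, 1) else c(1, 0, 0)
          wxyz <- rbind(wxyz, water_coords(o, dir1, c(0, 1, 0)))
        }
      }
      # decoys on a distant lateral slot, spread in z, isolated (> 3.5 A)
      for (dk in seq_len(n_decoys)) {
        wxyz <- rbind(wxyz, water_coords(c(-4.2, 0.8, decoy_z[dk]), c(0, 1, 0)))
      }
      # park unused waters far outside the volume (bulk corner)
      n_used <- nrow(wxyz) / 3L
      n_park <- n_water - n_used
      if (n_park > 0) {
        for (pk in seq_len(n_park)) {
          wxyz <- rbind(wxyz, water_coords(c(22, 22, slab$z_lower - 12 - 4 * pk), c(1, 0, 0)))
        }
      }
      coords[f, , ] <- rbind(ch$xyz, wxyz)
      truth[[f]] <- tibble(frame = f, lengths = list(sort(lens)),
                           max_length = if (length(lens) > 0) max(lens) else NA_integer_,
                           mean_length = if (length(lens) > 0) mean(lens) else NA_real_)
    }
    atoms <- bind_rows(ch$atoms, water_atoms_meta(n_water, 1L, "W"))
    traj <- trajectory(atoms, coords, box = box, frame_times = 0.1 * seq_len(nf))
    list(traj = traj, truth = bind_rows(truth))
  })
}

#' Generate a multi-copy aggregation trajectory with scripted merges
#'
#' Rigid dummy copies (five heavy atoms each) sit on well-separated slots of
#' a periodic box; at each scheduled merge frame the named copies join into
#' one entity, placed as a contact chain (adjacent-copy minimum distance
#' about 3.5 angstrom), and stay bound. Optionally one merge is realised
#' only across the periodic boundary, so it is detectable only with
#' minimum-image distances.
#'
#' @param seed Integer seed.
#' @param n_copies Number of copies (default 7).
#' @param merge_schedule List of `list(frame =, copies =)` entries; at
#'   `frame`, all entities containing the named copies merge.
#' @param n_frames Total frames.
#' @param box Box lengths (angstrom).
#' @param pbc_contact Optional `list(frame =, copies = c(i, j))`: from
#'   `frame` on, copies `i` and `j` touch only across the x boundary.
#' @param jitter Per-frame uniform entity-centre jitter amplitude (angstrom).
#' @return List with `traj` (`mdtrj` with copy ids), `truth` (tibble
#'   `frame`, `n_entities`, `entities` list-column).
#' @export
generate_aggregation_trajectory <- function(seed, n_copies = 7,
                                            merge_schedule = list(),
                                            n_frames = 20, box = c(90, 90, 90),
                                            pbc_contact = NULL, jitter = 0.3) {
  with_local_seed(seed, {
    # copy geometry: centre + tetrahedron, radius 1 A
    tet <- rbind(c(0, 0, 0),
                 c(1, 1, 1) / sqrt(3), c(1, -1, -1) / sqrt(3),
                 c(-1, 1, -1) / sqrt(3), c(-1, -1, 1) / sqrt(3))
    slots <- as.matrix(expand.grid(x = c(15, 45, 75), y = c(15, 45, 75), z = c(15, 45, 75)))
    slots <- slots[seq(1, 27, length.out = max(n_copies, 2)), , drop = FALSE][seq_len(n_copies), , drop = FALSE]
    partition <- as.list(seq_len(n_copies))
    sched_at <- function(f) Filter(function(m) m$frame == f, merge_schedule)
    coords <- array(NA_real_, dim = c(n_frames, 5L * n_copies, 3L))
    truth <- vector("list", n_frames)
    pbc_on <- FALSE
    for (f in seq_len(n_frames)) {
      for (m in sched_at(f)) {
        hit <- vapply(partition, function(p) any(m$copies %in% p), logical(1))
        merged <- sort(unlist(partition[hit]))
        partition <- c(partition[!hit], list(merged))
      }
      if (!is.null(pbc_contact) && f >= pbc_contact$frame) pbc_on <- TRUE
      # deterministic order by lowest member
      partition <- partition[order(vapply(partition, min, numeric(1)))]
      centres <- matrix(NA_real_, n_copies, 3)
      for (p in partition) {
        anchor <- slots[min(p), ] + runif(3, -jitter, jitter)
        # contact chain centred on the anchor so long chains stay clear of
        # neighbouring slots even under the minimum image
        for (k in seq_along(p)) {
          centres[p[k], ] <- anchor + c((k - 1 - (length(p) - 1) / 2) * 5.5, 0, 0)
        }
      }
      if (pbc_on) {
        i <- pbc_contact$copies[1]; j <- pbc_contact$copies[2]
        yz <- c(4, 4)  # reserved lane far from every slot
        centres[i, ] <- c(1.0, yz) + runif(3, -jitter, jitter)
        centres[j, ] <- c(box[1] - 2.5, yz) + runif(3, -jitter, jitter)
      }
      for (cp in seq_len(n_copies)) {
        coords[f, 5L * (cp - 1L) + 1:5, ] <- sweep(tet, 2, centres[cp, ], "+")
      }
      eff_part <- partition
      if (pbc_on) {
        hit <- vapply(eff_part, function(p) any(pbc_contact$copies %in% p), logical(1))
        merged <- sort(unlist(eff_part[hit]))
        eff_part <- c(eff_part[!hit], list(merged))
        eff_part <- eff_part[order(vapply(eff_part, min, numeric(1)))]
      }
      truth[[f]] <- tibble(frame = f, n_entities = length(eff_part),
                           entities = list(eff_part))
    }
    atoms <- tibble(atom_name = rep(c("C1", "C2", "C3", "C4", "C5"), n_copies),
                    element = "C", residue_name = "DUM",
                    residue_id = rep(seq_len(n_copies), each = 5L),
                    chain_id = rep(LETTERS[seq_len(n_copies)], each = 5L))
    traj <- trajectory(atoms, coords, box = box, frame_times = 0.1 * seq_len(n_frames))
    traj <- assign_copies(traj, by = "chain")
    list(traj = traj, truth = bind_rows(truth))
  })
}

#' Generate frames drawn from planted conformational clusters
#'
#' Frames are sampled from a small set of planted conformations plus
#' isotropic Gaussian coordinate noise, then given a random rigid motion so
#' that recovery requires alignment. Conformation 2 is constructed at a
#' target aligned RMSD from conformation 1.
#'
#' @param seed Integer seed.
#' @param sizes Frames per planted conformation (first entry = most
#'   populated unless stated otherwise).
#' @param n_atoms Atoms per frame.
#' @param rmsd_sep Target pairwise aligned RMSD between consecutive planted
#'   conformations (angstrom).
#' @param noise_sigma Isotropic per-coordinate noise (angstrom).
#' @return List with `traj`, `truth` (tibble `frame`, `cluster`), and
#'   `conformations` (list of reference coordinate matrices).
#' @export
generate_cluster_frames <- function(seed, sizes = c(12, 8), n_atoms = 20,
                                    rmsd_sep = 8, noise_sigma = 0.2) {
  with_local_seed(seed, {
    base <- matrix(rnorm(n_atoms * 3, sd = 4), ncol = 3)
    confs <- list(base)
    for (k in seq_len(length(sizes) - 1L)) {
      D <- matrix(rnorm(n_atoms * 3), ncol = 3)
      fsep <- function(c0) kabsch_superpose(confs[[k]] + c0 * D, confs[[k]])$rmsd_after - rmsd_sep
      cc <- stats::uniroot(fsep, c(0, 100 * rmsd_sep))$root
      confs[[k + 1L]] <- confs[[k]] + cc * D
    }
    labels <- sample(rep(seq_along(sizes), sizes))
    nf <- length(labels)
    coords <- array(NA_real_, dim = c(nf, n_atoms, 3L))
    for (f in seq_len(nf)) {
      x <- confs[[labels[f]]] + matrix(rnorm(n_atoms * 3, sd = noise_sigma), ncol = 3)
      # random rigid motion: rotation from QR of a random matrix, det +1
      qr_ <- qr(matrix(rnorm(9), 3, 3))
      R <- qr.Q(qr_)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      coords[f, , ] <- sweep(x %*% t(R), 2, runif(3, -10, 10), "+")
    }
    atoms <- tibble(atom_name = "CA", element = "C", residue_name = "ALA",
                    residue_id = seq_len(n_atoms), chain_id = "A")
    traj <- trajectory(atoms, coords)
    list(traj = traj, truth = tibble(frame = seq_len(nf), cluster = labels),
         conformations = confs)
  })
}

#' Generate a two-chain trajectory with a scripted contact
#'
#' Chain A carries one acidic residue (glutamate, or phosphoserine when
#' `phosphorylated`), chain B an arginine. In frames where the schedule is
#' `TRUE` the charged groups sit at about 3.7 angstrom (a formed salt
#' bridge under the 4.0 angstrom convention); otherwise at about
#' 9 angstrom. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param present Logical vector, one entry per frame: contact formed?
#' @param phosphorylated Use a phosphoserine (SEP) anionic group instead of
#'   glutamate.
#' @param box Box lengths (angstrom).
#' @return List with `traj`, `truth` (tibble `frame`, `present`) and
#'   `true_occupancy`.
#' @export
generate_contact_trajectory <- function(seed, present, phosphorylated = FALSE,
                                        box = c(50, 50, 50)) {
  present <- as.logical(present)
  nf <- length(present)
  if (nf < 1L) abort("present must have at least one frame")
  with_local_seed(seed, {
    if (phosphorylated) {
      a_atoms <- tibble(atom_name = c("CB", "OG", "P", "O1P", "O2P", "O3P"),
                        element = c("C", "O", "P", "O", "O", "O"),
                        residue_name = "SEP", residue_id = 29L, chain_id = "A")
      a_local <- rbind(c(-2.5, 0, 0), c(-1.4, 0, 0), c(0, 0, 0),
                       c(0.6, 1.2, 0), c(0.6, -1.2, 0), c(0.6, 0, 1.2))
      a_anchor <- 4L  # O1P leads the approach
    } else {
      a_atoms <- tibble(atom_name = c("CG", "CD", "OE1", "OE2"),
                        element = c("C", "C", "O", "O"),
                        residue_name = "GLU", residue_id = 28L, chain_id = "A")
      a_local <- rbind(c(-2.4, 0, 0), c(-1.2, 0, 0), c(0, 0.9, 0), c(0, -0.9, 0))
      a_anchor <- 3L
    }
    b_atoms <- tibble(atom_name = c("CZ", "NE", "NH1", "NH2"),
                      element = c("C", "N", "N", "N"),
                      residue_name = "ARG", residue_id = 324L, chain_id = "B")
    b_local <- rbind(c(1.2, 0, 0), c(2.2, 1.0, 0), c(0, 0.9, 0), c(1.8, -1.1, 0))
    atoms <- bind_rows(a_atoms, b_atoms)
    na <- nrow(a_local)
    coords <- array(NA_real_, dim = c(nf, na + nrow(b_local), 3L))
    for (f in seq_len(nf)) {
      gap <- if (present[f]) 3.7 else 9.0
      # place chain A so the anchor oxygen sits `gap` from B's NH1 along -x
      shift <- c(-(gap + a_local[a_anchor, 1]), 0.9 - a_local[a_anchor, 2], 0)
      af <- sweep(a_local, 2, shift, "+") + matrix(rnorm(3 * na, sd = 0.03), ncol = 3)
      bf <- b_local + matrix(rnorm(3 * nrow(b_local), sd = 0.03), ncol = 3)
      coords[f, , ] <- rbind(af, bf) + 25
    }
    traj <- trajectory(atoms, coords, box = box, frame_times = 0.1 * seq_len(nf))
    list(traj = traj, truth = tibble(frame = seq_len(nf), present = present),
         true_occupancy = mean(present))
  })
}
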