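# Inter-chain contact detection: salt bridges between side-chain charged
# groups and hydrogen bonds between polar heavy atoms. Phosphoserine (SEP)
# is a first-class anionic group so phosphorylated systems are expressible.

# charged-group atom names by residue
ANIONIC_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  SEP = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3", "OG")
)
CATIONIC_ATOMS <- list(
  ARG = c("NH1", "NH2", "NE"), LYS = c("NZ"), HIS = c("ND1", "NE2")
)

#' Contact specification
#'
#' @param kind `"salt_bridge"` or `"hbond"`.
#' @param group_a,group_b Disjoint, non-empty atom index vectors (e.g. the
#'   carboxylate oxygens of one residue and the guanidinium nitrogens of
#'   another).
#' @param distance_cutoff Heavy-atom distance cutoff in angstrom. Default
#'   4.0 for salt bridges (any charged-group heavy-atom pair); for hbonds
#'   the water-wire O-O default 3.5 applies.
#' @param criteria [hbond_criteria()] used when `kind = "hbond"` and donor
#'   hydrogens are available.
#' @return A `contact_spec` list.
#' @export
contact_spec <- function(kind = c("salt_bridge", "hbond"), group_a, group_b,
                         distance_cutoff = NULL, criteria = hbond_criteria()) {
  kind <- match.arg(kind)
  if (length(group_a) == 0L || length(group_b) == 0L) abort("contact groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L) abort("contact groups must be disjoint")
  cutoff <- distance_cutoff %||% if (kind == "salt_bridge") 4.0 else criteria$max_oo_distance
  structure(list(kind = kind, group_a = group_a, group_b = group_b,
                 distance_cutoff = cutoff, criteria = criteria),
            class = "contact_spec")
}

#' Per-frame contact presence and occupancy
#'
#' The contact is present at a frame iff the minimum inter-group distance is
#' at most the cutoff (minimum-image when the trajectory has a box).
#' Occupancy is the fraction of analysed frames in which it is present.
#'
#' @param traj An `mdtrj` object.
#' @param spec A [contact_spec()].
#' @param replica Optional per-frame replica tags; when given, per-replica
#'   occupancies are also computed.
#' @return An `occupancy_result`: `present` (per-frame logical), `occupancy`
#'   (fraction), `n_frames`, optional `per_replica` tibble.
#' @export
contact_series <- function(traj, spec, replica = NULL) {
  nf <- n_frames(traj)
  present <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    present[f] <- min_cross_dist(xyz[spec$group_a, , drop = FALSE],
                                 xyz[spec$group_b, , drop = FALSE], box) <=
      spec$distance_cutoff
  }
  out <- list(present = present, occupancy = mean(present), n_frames = nf,
              kind = spec$kind, distance_cutoff = spec$distance_cutoff)
  if (!is.null(replica)) {
    stopifnot(length(replica) == nf)
    pr <- tibble(replica = replica, present = present) |>
      group_by(.data$replica) |>
      summarise(occupancy = mean(.data$present), n_frames = n(), .groups = "drop")
    out$per_replica <- pr
  }
  structure(out, class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> %s present in %.1f%% of %d frames\n",
              x$kind, 100 * x$occupancy, x$n_frames))
  invisible(x)
}

#' @rdname contact_series
#' @param x An `occupancy_result`.
#' @param ... Unused.
#' @exportS3Method
glance.occupancy_result <- function(x, ...) {
  tibble(kind = x$kind, occupancy = x$occupancy, pct = 100 * x$occupancy,
         n_frames = x$n_frames, distance_cutoff = x$distance_cutoff)
}

# candidate contact groups per residue of a chain selection
residue_groups <- function(traj, selection, kind) {
  a <- traj$atoms[selection, ]
  tabs <- if (kind == "anionic") ANIONIC_ATOMS else if (kind == "cationic") CATIONIC_ATOMS else NULL
  out <- list()
  for (key in unique(paste(a$chain_id, a$residue_id))) {
    rows <- a[paste(a$chain_id, a$residue_id) == key, ]
    rn <- rows$residue_name[1]
    idx <- if (!is.null(tabs)) {
      if (!rn %in% names(tabs)) next
      rows$atom_index[rows$atom_name %in% tabs[[rn]]]
    } else {
      # hbond donors/acceptors: polar heavy atoms (N, O) excluding backbone carbonyl C
      rows$atom_index[rows$element %in% c("N", "O")]
    }
    if (length(idx) > 0L) {
      out[[length(out) + 1L]] <- list(chain = rows$chain_id[1],
                                      resid = rows$residue_id[1],
                                      resname = rn, atoms = idx)
    }
  }
  out
}

#' Inventory of persistent cross-chain interactions
#'
#' Scans all cross-chain salt-bridge candidates (Asp/Glu/phosphoserine
#' anionic groups vs Arg/Lys/His cationic groups) and hydrogen-bond
#' candidates (polar N/O heavy-atom pairs), computes each pair's occupancy,
#' and reports pairs at or above `min_occupancy`, sorted by descending
#' occupancy.
#'
#' @param traj An `mdtrj` object.
#' @param chain_a,chain_b Disjoint atom index vectors for the two chains.
#' @param min_occupancy Reporting threshold (default 0.2).
#' @param saltbridge_cutoff Salt-bridge distance cutoff (angstrom).
#' @param hbond_cutoff Hydrogen-bond heavy-atom cutoff (angstrom).
#' @return `result_table` tibble with columns `kind`, `residue_a`,
#'   `residue_b`, `occupancy`.
#' @export
interaction_inventory <- function(traj, chain_a, chain_b, min_occupancy = 0.2,
                                  saltbridge_cutoff = 4.0, hbond_cutoff = 3.5) {
  if (length(intersect(chain_a, chain_b)) > 0L) abort("chain selections must be disjoint")
  rows <- list()
  scan <- function(ga, gb, kind, cutoff) {
    for (A in ga) for (B in gb) {
      sp <- contact_spec(if (kind == "salt_bridge") "salt_bridge" else "hbond",
                         A$atoms, B$atoms, distance_cutoff = cutoff)
      occ <- contact_series(traj, sp)$occupancy
      if (occ > 0) {
        rows[[length(rows) + 1L]] <<- tibble(
          kind = kind,
          residue_a = sprintf("%s%d:%s", A$resname, A$resid, A$chain),
          residue_b = sprintf("%s%d:%s", B$resname, B$resid, B$chain),
          occupancy = occ)
      }
    }
  }
  scan(residue_groups(traj, chain_a, "anionic"),
       residue_groups(traj, chain_b, "cationic"), "salt_bridge", saltbridge_cutoff)
  scan(residue_groups(traj, chain_a, "cationic"),
       residue_groups(traj, chain_b, "anionic"), "salt_bridge", saltbridge_cutoff)
  scan(residue_groups(traj, chain_a, "polar"),
       residue_groups(traj, chain_b, "polar"), "hbond", hbond_cutoff)
  tbl <- if (length(rows) == 0L) {
    tibble(kind = character(), residue_a = character(), residue_b = character(),
           occupancy = numeric())
  } else {
    bind_rows(rows) |>
      filter(.data$occupancy >= min_occupancy) |>
      arrange(desc(.data$occupancy), .data$residue_a, .data$residue_b)
  }
  result_table(tbl, params = list(analysis = "interaction_inventory",
                                  min_occupancy = min_occupancy,
                                  saltbridge_cutoff = saltbridge_cutoff,
                                  hbond_cutoff = hbond_cutoff))
}
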