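#' Membrane slab and protein volume definitions
#'
#' The slab is the z-interval of the bilayer hydrophobic core; it defines the
#' two aqueous "sides" (lower: z < z_lower, upper: z > z_upper) and, together
#' with a proximity shell around the protein, the "protein volume" a water
#' must visit for a permeation event. A water oxygen is inside the volume at
#' a frame iff its z lies in `[z_lower, z_upper]` (closed) and its minimum
#' distance to any protein heavy atom is at most `proximity_cutoff`
#' (minimum-image when the trajectory has a box).
#'
#' @param z_lower,z_upper Slab bounds in angstrom, `z_lower < z_upper`.
#' @return A `membrane_slab` list.
#' @export
membrane_slab <- function(z_lower, z_upper) {
  if (!(z_lower < z_upper)) abort("z_lower must be < z_upper")
  structure(list(z_lower = z_lower, z_upper = z_upper, axis = "z"),
            class = "membrane_slab")
}

#' @rdname membrane_slab
#' @param protein_selection Atom indices of the protein (heavy atoms are
#'   filtered internally).
#' @param proximity_cutoff Shell width in angstrom (default 6.0).
#' @param slab A [membrane_slab()].
#' @export
protein_volume <- function(protein_selection, slab, proximity_cutoff = 6.0) {
  if (length(protein_selection) == 0L) abort("empty protein selection")
  if (proximity_cutoff <= 0) abort("proximity_cutoff must be positive")
  structure(list(protein_selection = protein_selection,
                 proximity_cutoff = proximity_cutoff, slab = slab),
            class = "protein_volume")
}

#' Estimate the membrane slab from marker atoms
#'
#' Marker atoms (typically lipid phosphorus) are split into leaflets by their
#' position relative to the joint mean z, then each bound is the (optionally
#' trimmed) mean z of its leaflet, averaged over frames.
#'
#' @param traj An `mdtrj` object.
#' @param marker_selection Atom indices of the leaflet markers.
#' @param quantile_trim Fraction trimmed from each tail of each leaflet's z
#'   distribution before averaging (default 0).
#' @return A [membrane_slab()].
#' @export
estimate_slab <- function(traj, marker_selection, quantile_trim = 0) {
  if (length(marker_selection) == 0L) abort("empty marker selection")
  lows <- ups <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    z <- frame_coords(traj, f)[marker_selection, 3]
    mid <- mean(z)
    lo <- z[z < mid]; hi <- z[z >= mid]
    if (length(lo) == 0L || length(hi) == 0L) {
      abort("all slab markers lie on one side of their joint mean z")
    }
    lows[f] <- mean(lo, trim = quantile_trim)
    ups[f] <- mean(hi, trim = quantile_trim)
  }
  membrane_slab(mean(lows), mean(ups))
}

#' Per-frame in-volume water membership
#'
#' @param traj An `mdtrj` object.
#' @param volume A [protein_volume()].
#' @return List (one element per frame) of water-oxygen atom indices inside
#'   the protein volume, with attribute `waters` (all water oxygen indices).
#' @export
occupancy_series <- function(traj, volume) {
  waters <- which(traj$atoms$is_water_oxygen)
  if (length(waters) == 0L) {
    warn("trajectory contains no water oxygens")
    out <- replicate(n_frames(traj), integer(0), simplify = FALSE)
    attr(out, "waters") <- integer(0)
    return(out)
  }
  prot <- volume$protein_selection
  prot <- prot[traj$atoms$is_heavy[prot]]
  slab <- volume$slab
  out <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    wz <- xyz[waters, 3]
    cand <- waters[wz >= slab$z_lower & wz <= slab$z_upper]
    if (length(cand) > 0L) {
      d <- cross_dist(xyz[cand, , drop = FALSE], xyz[prot, , drop = FALSE], box)
      cand <- cand[apply(d, 1, min) <= volume$proximity_cutoff]
    }
    out[[f]] <- cand
  }
  attr(out, "waters") <- waters
  out
}

# side of a water at a frame when outside the volume: "lower"/"upper" by z,
# or nearest slab boundary when laterally outside within the slab z-range
outside_side <- function(z, slab) {
  if (z < slab$z_lower) "lower"
  else if (z > slab$z_upper) "upper"
  else if (z - slab$z_lower <= slab$z_upper - z) "lower" else "upper"
}

#' Extract permeation events from an occupancy series
#'
#' An event opens at the first frame a water is inside the volume after
#' being outside, with `entry_side` taken from its position at the last
#' outside frame; it closes at the first subsequent outside frame with
#' `exit_side` assigned the same way. Waters still inside at the final frame
#' yield `outcome = "unresolved"`. One water can generate several events.
#' Outcomes: `crossed` (exit side differs from entry side), `returned`
#' (same side), `unresolved`.
#'
#' @param occupancy Output of [occupancy_series()].
#' @param traj The same `mdtrj` the occupancy was computed on.
#' @param slab The [membrane_slab()] used.
#' @param min_dwell Minimum number of consecutive inside frames for an entry
#'   to count (default 1: single-frame excursions count).
#' @return `result_table` tibble with columns `water`, `entry_frame`,
#'   `entry_side`, `exit_frame` (`NA` if open), `exit_side` (`"none"` if
#'   open), `outcome`.
#' @export
extract_events <- function(occupancy, traj, slab, min_dwell = 1L) {
  waters <- attr(occupancy, "waters")
  nf <- length(occupancy)
  inside <- matrix(FALSE, nf, length(waters))
  for (f in seq_len(nf)) inside[f, match(occupancy[[f]], waters)] <- TRUE
  ev <- list()
  for (wi in seq_along(waters)) {
    w <- waters[wi]
    ins <- inside[, wi]
    f <- 1L
    # skip any initial inside stretch: entries require a preceding outside frame
    while (f <= nf && ins[f]) f <- f + 1L
    while (f <= nf) {
      if (!ins[f]) { f <- f + 1L; next }
      entry <- f
      while (f <= nf && ins[f]) f <- f + 1L
      dwell <- f - entry
      if (dwell < min_dwell) next
      eside <- outside_side(traj$coords[entry - 1L, w, 3], slab)
      if (f > nf) {
        ev[[length(ev) + 1L]] <- list(water = w, entry_frame = entry,
                                      entry_side = eside, exit_frame = NA_integer_,
                                      exit_side = "none", outcome = "unresolved")
      } else {
        xside <- outside_side(traj$coords[f, w, 3], slab)
        ev[[length(ev) + 1L]] <- list(water = w, entry_frame = entry,
                                      entry_side = eside, exit_frame = f,
                                      exit_side = xside,
                                      outcome = if (xside != eside) "crossed" else "returned")
      }
    }
  }
  tbl <- if (length(ev) == 0L) {
    tibble(water = integer(), entry_frame = integer(), entry_side = character(),
           exit_frame = integer(), exit_side = character(), outcome = character())
  } else {
    bind_rows(lapply(ev, as_tibble))
  }
  result_table(tbl, params = list(analysis = "permeation_events",
                                  z_lower = slab$z_lower, z_upper = slab$z_upper,
                                  min_dwell = min_dwell))
}

#' Translocation success rate
#'
#' The fraction of resolved permeation events that crossed:
#' `rate = n_crossed / (n_crossed + n_returned)`. Unresolved events (water
#' still inside at the last frame) are excluded from the denominator and
#' reported separately. When the event table carries a `replica` column,
#' per-replica rates and their unweighted mean are also returned.
#'
#' @param events Event table from [extract_events()] (optionally with a
#'   `replica` column).
#' @return A `translocation_result` list: `rate` (fraction in `[0, 1]`, `NA`
#'   when no events resolve), `n_crossed`, `n_returned`, `n_unresolved`,
#'   `n_entries`, and (with replicas) `per_replica` tibble and
#'   `mean_replica_rate`.
#' @export
translocation_rate <- function(events) {
  n_crossed <- sum(events$outcome == "crossed")
  n_returned <- sum(events$outcome == "returned")
  n_unresolved <- sum(events$outcome == "unresolved")
  resolved <- n_crossed + n_returned
  rate <- if (resolved > 0L) n_crossed / resolved else NA_real_
  out <- list(rate = rate, n_crossed = n_crossed, n_returned = n_returned,
              n_unresolved = n_unresolved,
              n_entries = n_crossed + n_returned + n_unresolved)
  if ("replica" %in% names(events)) {
    pr <- events |>
      group_by(.data$replica) |>
      summarise(n_crossed = sum(.data$outcome == "crossed"),
                n_returned = sum(.data$outcome == "returned"),
                n_unresolved = sum(.data$outcome == "unresolved"),
                .groups = "drop") |>
      mutate(rate = ifelse(.data$n_crossed + .data$n_returned > 0,
                           .data$n_crossed / (.data$n_crossed + .data$n_returned),
                           NA_real_))
    out$per_replica <- pr
    out$mean_replica_rate <- mean(pr$rate, na.rm = TRUE)
  }
  structure(out, class = "translocation_result")
}

#' @export
print.translocation_result <- function(x, ...) {
  cat(sprintf("<translocation_result> rate %s (%d crossed / %d resolved; %d unresolved)\n",
              if (is.na(x$rate)) "undefined" else sprintf("%.1f%%", 100 * x$rate),
              x$n_crossed, x$n_crossed + x$n_returned, x$n_unresolved))
  invisible(x)
}

#' @rdname translocation_rate
#' @param x,object A `translocation_result`.
#' @param ... Unused.
#' @exportS3Method
glance.translocation_result <- function(x, ...) {
  tibble(rate = x$rate, pct = 100 * x$rate, n_crossed = x$n_crossed,
         n_returned = x$n_returned, n_unresolved = x$n_unresolved,
         n_entries = x$n_entries)
}

#' @rdname translocation_rate
#' @exportS3Method ggplot2::autoplot
autoplot.translocation_result <- function(object, ...) {
  d <- tibble(outcome = c("crossed", "returned", "unresolved"),
              n = c(object$n_crossed, object$n_returned, object$n_unresolved))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$n, fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(y = "events",
                  title = sprintf("Translocation success rate: %s",
                                  if (is.na(object$rate)) "undefined"
                                  else sprintf("%.1f%%", 100 * object$rate)))
}
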