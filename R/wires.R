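#' Hydrogen-bond geometric criteria
#'
#' A pair of water oxygens is hydrogen bonded when the O-O distance
#' (minimum-image when a box is present) is at most `max_oo_distance` and,
#' when hydrogens are available and required, some donor-H-acceptor angle
#' (at the hydrogen) in either direction is at least `min_dha_angle`.
#' With `require_hydrogens = FALSE` only the distance criterion applies;
#' this is flagged in provenance because it is a superset of the angular
#' definition.
#'
#' @param max_oo_distance O-O cutoff in angstrom (default 3.5).
#' @param min_dha_angle D-H...A angle threshold in degrees (default 150).
#' @param require_hydrogens Apply the angle test (default TRUE).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_oo_distance = 3.5, min_dha_angle = 150,
                           require_hydrogens = TRUE) {
  if (max_oo_distance <= 0) abort("max_oo_distance must be positive")
  if (min_dha_angle <= 0 || min_dha_angle > 180) abort("min_dha_angle must be in (0, 180]")
  structure(list(max_oo_distance = max_oo_distance, min_dha_angle = min_dha_angle,
                 require_hydrogens = require_hydrogens),
            class = "hbond_criteria")
}

# map each water oxygen index to the indices of its hydrogens (same residue
# id + chain, element H)
water_hydrogens <- function(traj, oxygens) {
  a <- traj$atoms
  key <- paste(a$chain_id, a$residue_id)
  hs <- which(a$element == "H" & a$residue_name %in% traj$water_residues)
  split_h <- split(hs, key[hs])
  out <- lapply(oxygens, function(o) split_h[[paste(a$chain_id[o], a$residue_id[o])]] %||% integer(0))
  names(out) <- as.character(oxygens)
  out
}

# angle at H between H->D and H->A, degrees (min-image displacements)
dha_angle <- function(d, h, a, box = NULL) {
  v1 <- min_image(matrix(d - h, ncol = 3), box)
  v2 <- min_image(matrix(a - h, ncol = 3), box)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Hydrogen-bond edges among water oxygens in one frame
#'
#' @param coords Full-frame `n x 3` coordinate matrix.
#' @param water_oxygens Oxygen atom indices to consider as nodes.
#' @param hydrogens Named list mapping each oxygen index (as character) to
#'   its hydrogen atom indices; `NULL` to look at distances only.
#' @param criteria An [hbond_criteria()].
#' @param box Optional length-3 box for minimum-image distances.
#' @return Two-column integer matrix of bonded oxygen index pairs.
#' @export
hbond_edges <- function(coords, water_oxygens, hydrogens = NULL,
                        criteria = hbond_criteria(), box = NULL) {
  if (length(water_oxygens) == 0L) abort("empty oxygen set")
  use_angles <- criteria$require_hydrogens
  if (use_angles) {
    have_h <- !is.null(hydrogens) &&
      any(vapply(hydrogens, length, integer(1)) > 0L)
    if (!have_h) {
      abort(paste0("hydrogen positions unavailable; rerun with require_hydrogens",
                   " = FALSE for distance-only hydrogen bonds"))
    }
  }
  n <- length(water_oxygens)
  if (n < 2L) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  ox <- coords[water_oxygens, , drop = FALSE]
  dmat <- cross_dist(ox, ox, box)
  pairs <- which(upper.tri(dmat) & dmat <= criteria$max_oo_distance, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(pairs))
  if (use_angles && nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      oi <- water_oxygens[pairs[r, 1]]
      oj <- water_oxygens[pairs[r, 2]]
      ang <- -Inf
      for (dd in list(c(oi, oj), c(oj, oi))) {
        for (h in hydrogens[[as.character(dd[1])]]) {
          ang <- max(ang, dha_angle(coords[dd[1], ], coords[h, ], coords[dd[2], ], box))
        }
      }
      keep[r] <- is.finite(ang) && ang >= criteria$min_dha_angle
    }
  }
  out <- cbind(i = water_oxygens[pairs[keep, 1]], j = water_oxygens[pairs[keep, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# exact longest simple path (in nodes) by exhaustive DFS over an adjacency list
longest_path_exact <- function(adj) {
  n <- length(adj)
  best <- 1L
  visited <- logical(n)
  dfs <- function(v, depth) {
    visited[v] <<- TRUE
    if (depth > best) best <<- depth
    for (u in adj[[v]]) if (!visited[u]) dfs(u, depth + 1L)
    visited[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, 1L)
  best
}

# double-sweep BFS lower bound on the longest path (nodes): eccentricity path
longest_path_lower_bound <- function(g) {
  v0 <- igraph::V(g)[1]
  d1 <- igraph::distances(g, v = v0)
  a <- which.max(d1)
  d2 <- igraph::distances(g, v = a)
  as.integer(max(d2)) + 1L
}

#' Wire lengths of a hydrogen-bond graph
#'
#' A wire is a connected component with at least two molecules; its length
#' is the number of molecules on the longest simple path within the
#' component. Components of at most `exact_max` nodes are solved exactly by
#' exhaustive depth-first search; larger ones get a double-sweep BFS lower
#' bound and are flagged approximate.
#'
#' @param edges Two-column matrix of oxygen index pairs (from [hbond_edges()]).
#' @param nodes All oxygen node indices (isolated ones included).
#' @param exact_max Largest component size solved exactly (default 15).
#' @return Tibble with one row per wire: `component`, `n_molecules`
#'   (component size), `length` (longest-path molecules), `approx`.
#' @export
wire_lengths <- function(edges, nodes, exact_max = 15L) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes))
  )
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    if (length(vs) <= exact_max) {
      adj <- igraph::as_adj_list(sub)
      adj <- lapply(adj, as.integer)
      len <- longest_path_exact(adj)
      approx <- FALSE
    } else {
      len <- longest_path_lower_bound(sub)
      approx <- TRUE
    }
    out[[length(out) + 1L]] <- tibble(component = ci, n_molecules = length(vs),
                                      length = len, approx = approx)
  }
  if (length(out) == 0L) {
    return(tibble(component = integer(), n_molecules = integer(),
                  length = integer(), approx = logical()))
  }
  bind_rows(out)
}

#' Per-frame water-wire statistics
#'
#' For every frame: restrict to waters inside the protein volume, build the
#' hydrogen-bond graph, and report the number of wires, the maximum wire
#' length and the mean wire length (molecules). Frames with no wires carry
#' `NA` (missing, not zero) for max and mean.
#'
#' @param traj An `mdtrj` object.
#' @param volume A [protein_volume()].
#' @param criteria An [hbond_criteria()].
#' @return A `wire_stats` object: `result_table` tibble with columns `frame`,
#'   `n_in_volume`, `wire_count`, `max_length`, `mean_length`, plus attribute
#'   `wires` (list of per-frame wire tables).
#' @export
wire_stats_series <- function(traj, volume, criteria = hbond_criteria()) {
  occ <- occupancy_series(traj, volume)
  hyd <- if (criteria$require_hydrogens) {
    water_hydrogens(traj, attr(occ, "waters"))
  } else NULL
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  wires <- vector("list", nf)
  for (f in seq_len(nf)) {
    ow <- occ[[f]]
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    if (length(ow) >= 2L) {
      ed <- hbond_edges(frame_coords(traj, f), ow,
                        hydrogens = if (is.null(hyd)) NULL else hyd[as.character(ow)],
                        criteria = criteria, box = box)
      wl <- wire_lengths(ed, ow)
    } else {
      wl <- wire_lengths(matrix(integer(0), ncol = 2), ow)
    }
    wires[[f]] <- wl
    rows[[f]] <- tibble(frame = f, n_in_volume = length(ow),
                        wire_count = nrow(wl),
                        max_length = if (nrow(wl) > 0) max(wl$length) else NA_integer_,
                        mean_length = if (nrow(wl) > 0) mean(wl$length) else NA_real_)
  }
  tbl <- result_table(bind_rows(rows),
                      params = list(analysis = "wire_stats",
                                    max_oo_distance = criteria$max_oo_distance,
                                    min_dha_angle = criteria$min_dha_angle,
                                    require_hydrogens = criteria$require_hydrogens,
                                    distance_only = !criteria$require_hydrogens,
                                    proximity_cutoff = volume$proximity_cutoff))
  attr(tbl, "wires") <- wires
  class(tbl) <- c("wire_stats", class(tbl))
  tbl
}

#' Histograms of wire-length distributions
#' @param stats A `wire_stats` table from [wire_stats_series()].
#' @return Named list of two tibbles (`max_length`, `mean_length`) with
#'   `value` and `n` columns, missing frames dropped.
#' @export
wire_histograms <- function(stats) {
  hx <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(tibble(value = numeric(), n = integer()))
    tb <- table(v)
    tibble(value = as.numeric(names(tb)), n = as.integer(tb))
  }
  list(max_length = hx(stats$max_length), mean_length = hx(stats$mean_length))
}

#' @rdname wire_stats_series
#' @param object A `wire_stats` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.wire_stats <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[, c("frame", "max_length", "mean_length")],
                           c("max_length", "mean_length"),
                           names_to = "statistic", values_to = "molecules")
  ggplot2::ggplot(d[!is.na(d$molecules), ],
                  ggplot2::aes(x = .data$molecules, fill = .data$statistic)) +
    ggplot2::geom_histogram(binwidth = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~statistic, scales = "free_x") +
    ggplot2::labs(x = "wire length (molecules)", y = "frames",
                  title = "Water-wire length distributions")
}
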