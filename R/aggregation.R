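#' Contact-graph specification for entity counting
#'
#' Two protein copies "interact" when their minimum heavy-atom distance
#' (minimum-image when `use_pbc`) is at most `contact_cutoff`. An "entity"
#' is a single copy or a contact-connected group of copies.
#'
#' @param contact_cutoff Heavy-atom cutoff in angstrom (default 4.5).
#' @param use_pbc Apply periodic minimum-image distances (needs a per-frame
#'   box on the trajectory).
#' @return A `contact_graph_spec` list.
#' @export
contact_graph_spec <- function(contact_cutoff = 4.5, use_pbc = TRUE) {
  if (contact_cutoff <= 0) abort("contact_cutoff must be positive")
  structure(list(contact_cutoff = contact_cutoff, use_pbc = use_pbc),
            class = "contact_graph_spec")
}

# make each copy whole: shift every atom by the minimum image relative to
# the copy's first atom, so copies split across the boundary do not corrupt
# minimum distances
unwrap_copy <- function(xyz, box) {
  if (is.null(box) || nrow(xyz) < 2L) return(xyz)
  anchor <- xyz[1, ]
  d <- min_image(sweep(xyz, 2, anchor), box)
  sweep(d, 2, anchor, "+")
}

#' Per-frame contact graph over protein copies
#'
#' @param coords Full-frame `n x 3` coordinate matrix.
#' @param copy_ids Per-atom copy id (`NA` for non-copy atoms such as water);
#'   heavy-atom filtering must already have been applied via `heavy`.
#' @param spec A [contact_graph_spec()].
#' @param box Length-3 box vector; required when `spec$use_pbc`.
#' @param heavy Logical per-atom mask of heavy atoms.
#' @return Two-column matrix of copy-id pairs in contact, with attribute
#'   `copies` (all copy ids).
#' @export
copy_contact_graph <- function(coords, copy_ids, spec = contact_graph_spec(),
                               box = NULL, heavy = rep(TRUE, nrow(coords))) {
  if (spec$use_pbc && is.null(box)) {
    abort("use_pbc = TRUE requires a periodic box; none present")
  }
  ids <- sort(unique(copy_ids[!is.na(copy_ids)]))
  if (length(ids) < 2L) abort("need at least 2 copies")
  ubox <- if (spec$use_pbc) box else NULL
  sets <- lapply(ids, function(cid) {
    unwrap_copy(coords[which(copy_ids == cid & heavy), , drop = FALSE], ubox)
  })
  edges <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1L, length(ids))) {
      if (min_cross_dist(sets[[i]], sets[[j]], ubox) <= spec$contact_cutoff) {
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
  }
  out <- if (length(edges) > 0L) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  attr(out, "copies") <- ids
  out
}

# connected components of a copy contact graph -> list of integer vectors
graph_entities <- function(edges) {
  ids <- attr(edges, "copies")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  parts <- unname(split(ids, comp$membership))
  parts <- lapply(parts, sort)
  # deterministic order: by lowest member copy id
  parts[order(vapply(parts, min, numeric(1)))]
}

#' Entity timeline for a multi-copy trajectory
#'
#' Per frame, copies are partitioned into entities (connected components of
#' the copy contact graph) and counted. `time_to_single_entity` is the first
#' time (ns, when frame times exist, else the frame index) at which a single
#' entity remains, or `NA` if that never happens.
#'
#' @param traj An `mdtrj` with `copy_id` assigned (see [assign_copies()]).
#' @param spec A [contact_graph_spec()].
#' @return An `entity_timeline`: tibble with columns `frame`, `time`,
#'   `n_entities`, `entities` (list-column of integer vectors), plus
#'   attributes `time_to_single_entity` and `spec`.
#' @export
entity_timeline <- function(traj, spec = contact_graph_spec()) {
  if (all(is.na(traj$atoms$copy_id))) {
    abort("no copy ids assigned; call assign_copies() first")
  }
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    ed <- copy_contact_graph(frame_coords(traj, f), traj$atoms$copy_id, spec,
                             box = box, heavy = traj$atoms$is_heavy)
    parts <- graph_entities(ed)
    rows[[f]] <- tibble(frame = f,
                        time = if (!is.null(traj$frame_times)) traj$frame_times[f] else NA_real_,
                        n_entities = length(parts),
                        entities = list(parts))
  }
  tbl <- bind_rows(rows)
  hit <- which(tbl$n_entities == 1L)
  tts <- if (length(hit) == 0L) NA_real_ else {
    if (!is.null(traj$frame_times)) traj$frame_times[hit[1]] else as.numeric(hit[1])
  }
  tbl <- result_table(tbl, params = list(analysis = "entity_timeline",
                                         contact_cutoff = spec$contact_cutoff,
                                         use_pbc = spec$use_pbc))
  attr(tbl, "time_to_single_entity") <- tts
  class(tbl) <- c("entity_timeline", class(tbl))
  tbl
}

#' @rdname entity_timeline
#' @param x An `entity_timeline`.
#' @param ... Unused.
#' @exportS3Method
glance.entity_timeline <- function(x, ...) {
  tibble(n_frames = nrow(x),
         n_copies = length(unlist(x$entities[[1]])),
         final_entities = x$n_entities[nrow(x)],
         time_to_single_entity = attr(x, "time_to_single_entity"))
}

#' Stable entity labels across frames
#'
#' Labels persist through time by maximal-overlap matching: each entity
#' inherits the label of the previous-frame entity with which it shares most
#' copies (merges therefore keep the larger predecessor's label); overlap
#' ties go to the predecessor containing the lowest copy id; entities with
#' no predecessor get fresh labels. If two entities claim the same label
#' (a split), the larger one keeps it.
#'
#' @param timeline An [entity_timeline()].
#' @return Tibble with columns `frame`, `label`, `copies` (list-column).
#' @export
entity_track_labels <- function(timeline) {
  nf <- nrow(timeline)
  next_label <- 1L
  prev <- NULL  # list of (label, copies)
  out <- list()
  for (f in seq_len(nf)) {
    parts <- timeline$entities[[f]]
    claims <- lapply(parts, function(p) {
      if (is.null(prev)) return(NULL)
      ov <- vapply(prev, function(q) length(intersect(p, q$copies)), integer(1))
      if (max(ov) == 0L) return(NULL)
      cand <- which(ov == max(ov))
      # tie -> predecessor containing the lowest copy id
      cand <- cand[which.min(vapply(cand, function(ci) min(prev[[ci]]$copies), numeric(1)))]
      prev[[cand]]$label
    })
    labels <- integer(length(parts))
    # larger entity wins a contested label; order by size desc then lowest copy
    ord <- order(-vapply(parts, length, integer(1)),
                 vapply(parts, min, numeric(1)))
    taken <- integer(0)
    for (i in ord) {
      lb <- claims[[i]]
      if (!is.null(lb) && !(lb %in% taken)) {
        labels[i] <- lb
      } else {
        labels[i] <- next_label
        next_label <- next_label + 1L
      }
      taken <- c(taken, labels[i])
    }
    prev <- lapply(seq_along(parts), function(i) list(label = labels[i], copies = parts[[i]]))
    out[[f]] <- tibble(frame = timeline$frame[f], label = labels, copies = parts)
  }
  bind_rows(out)
}

#' Entity-count sensitivity over contact cutoffs
#'
#' @param traj An `mdtrj` with copy ids.
#' @param cutoffs Cutoffs to compare (angstrom).
#' @param use_pbc Passed to [contact_graph_spec()].
#' @return Tibble with columns `cutoff`, `frame`, `n_entities`.
#' @export
entity_sensitivity <- function(traj, cutoffs = c(4.0, 4.5, 5.0), use_pbc = TRUE) {
  bind_rows(lapply(cutoffs, function(co) {
    tl <- entity_timeline(traj, contact_graph_spec(co, use_pbc))
    tibble(cutoff = co, frame = tl$frame, n_entities = tl$n_entities)
  }))
}

#' @rdname entity_timeline
#' @param object An `entity_timeline`.
#' @exportS3Method ggplot2::autoplot
autoplot.entity_timeline <- function(object, ...) {
  lab <- entity_track_labels(object)
  d <- lab |>
    mutate(n = vapply(.data$copies, length, integer(1))) |>
    tidyr::unnest_longer("copies")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$copies,
                                  fill = factor(.data$label))) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::labs(x = "frame", y = "copy", fill = "entity",
                  title = "Aggregation entities over time")
}
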