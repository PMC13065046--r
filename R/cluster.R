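#' Pairwise aligned RMSD matrix between frames
#'
#' Every frame pair is superposed (Kabsch on `selection`) before the RMSD is
#' measured on the same selection.
#'
#' @param traj An `mdtrj` object.
#' @param selection Atom indices.
#' @return Symmetric `n_frames x n_frames` matrix (angstrom).
#' @export
rmsd_matrix <- function(traj, selection = seq_len(n_atoms(traj))) {
  if (length(selection) == 0L) abort("empty atom selection")
  nf <- n_frames(traj)
  sets <- lapply(seq_len(nf), function(f) frame_coords(traj, f)[selection, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in seq(i + 1L, nf)) {
      m[i, j] <- m[j, i] <- kabsch_superpose(sets[[i]], sets[[j]])$rmsd_after
    }
  }
  m
}

#' Cluster trajectory frames on the aligned RMSD matrix
#'
#' Average-linkage hierarchical clustering on pairwise Kabsch-aligned RMSD,
#' cut either to `k` clusters or at RMSD height `h`. The representative
#' structure is the medoid of the most populated cluster: the member frame
#' minimising the summed RMSD to its co-members. All ties (most populated
#' cluster, medoid) break to the lowest frame index, so the result is
#' deterministic.
#'
#' @param traj An `mdtrj` object.
#' @param selection Atom indices used for alignment and RMSD.
#' @param k Number of clusters (ignored when `h` given).
#' @param h RMSD cut height in angstrom.
#' @return A `cluster_result`: `labels` (per-frame integer), `medoid_frame`,
#'   `cluster_sizes` (named integer), `rmsd` (the matrix), `k`.
#' @export
cluster_frames <- function(traj, selection = seq_len(n_atoms(traj)),
                           k = NULL, h = NULL) {
  nf <- n_frames(traj)
  if (nf < 2L) abort("need at least 2 frames to cluster")
  if (!is.null(k) && k > nf) abort(sprintf("k = %d exceeds n_frames = %d", k, nf))
  if (is.null(k) && is.null(h)) abort("supply k or h")
  m <- rmsd_matrix(traj, selection)
  hc <- hclust(as.dist(m), method = "average")
  labels <- if (!is.null(h)) cutree(hc, h = h) else cutree(hc, k = k)
  # relabel cluster ids by first appearance so labels are frame-order stable
  first <- vapply(unique(labels), function(l) min(which(labels == l)), integer(1))
  remap <- setNames(rank(first, ties.method = "first"), unique(labels))
  labels <- unname(remap[as.character(labels)])
  sizes <- table(labels)
  top <- as.integer(names(sizes)[which(sizes == max(sizes))])
  # tie on size -> cluster containing the lowest frame index
  top_cluster <- top[which.min(vapply(top, function(cl) min(which(labels == cl)), integer(1)))]
  members <- which(labels == top_cluster)
  sums <- rowSums(m[members, members, drop = FALSE])
  medoid <- members[which.min(sums)]  # which.min ties to first = lowest frame
  structure(list(labels = labels, medoid_frame = medoid,
                 cluster_sizes = setNames(as.integer(sizes), names(sizes)),
                 most_populated = top_cluster, rmsd = m, k = length(sizes)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) over %d frames; medoid of most populated cluster (%d): frame %d\n",
              x$k, length(x$labels), x$most_populated, x$medoid_frame))
  invisible(x)
}

#' @rdname cluster_frames
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @exportS3Method
tidy.cluster_result <- function(x, ...) {
  tibble(frame = seq_along(x$labels), cluster = x$labels,
         is_medoid = seq_along(x$labels) == x$medoid_frame)
}

#' @rdname cluster_frames
#' @exportS3Method
glance.cluster_result <- function(x, ...) {
  tibble(n_frames = length(x$labels), n_clusters = x$k,
         most_populated = x$most_populated,
         most_populated_size = max(x$cluster_sizes),
         medoid_frame = x$medoid_frame)
}

#' @rdname cluster_frames
#' @param object A `cluster_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = factor(.data$cluster),
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_point(data = d[d$is_medoid, ], shape = 8, size = 3, colour = "black") +
    ggplot2::labs(x = "frame", y = "cluster",
                  title = "RMSD clustering of trajectory frames (star = medoid)")
}
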