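# Independent oracles used across the suite. Each is deliberately naive and
# shares no code with the implementation it checks.

# --- rotation oracle: quaternion grid search -------------------------------
# best RMSD over a grid of unit quaternions, refined around the best cell
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

grid_rmsd_oracle <- function(mobile, reference, n_coarse = 12, n_refine = 4) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  score <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  gr <- seq(-1, 1, length.out = n_coarse)
  best <- list(val = Inf, q = c(1, 0, 0, 0))
  for (w in gr) for (x in gr) for (y in gr) for (z in gr) {
    q <- c(w, x, y, z)
    if (sum(q^2) < 1e-6) next
    v <- score(q)
    if (v < best$val) best <- list(val = v, q = q / sqrt(sum(q^2)))
  }
  step <- 2 / (n_coarse - 1)
  for (it in seq_len(n_refine * 6)) {
    improved <- FALSE
    for (k in 1:4) for (s in c(-step, step)) {
      q <- best$q; q[k] <- q[k] + s
      v <- score(q)
      if (v < best$val) { best <- list(val = v, q = q / sqrt(sum(q^2))); improved <- TRUE }
    }
    if (!improved) step <- step / 2
    if (step < 1e-9) break
  }
  best$val
}

# --- longest simple path oracle: enumerate every simple path ---------------
brute_longest_path <- function(edge_df, n_nodes) {
  if (nrow(edge_df) == 0L) return(1L)
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = data.frame(name = as.character(seq_len(n_nodes))))
  best <- 1L
  for (v in seq_len(n_nodes)) {
    ps <- igraph::all_simple_paths(g, from = v)
    if (length(ps) > 0L) best <- max(best, max(vapply(ps, length, integer(1))))
  }
  best
}

# --- connected components oracle: boolean transitive closure ---------------
brute_components <- function(edges, ids) {
  n <- length(ids)
  M <- diag(TRUE, n)
  if (nrow(edges) > 0L) for (r in seq_len(nrow(edges))) {
    i <- match(edges[r, 1], ids); j <- match(edges[r, 2], ids)
    M[i, j] <- M[j, i] <- TRUE
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[which(M[i, ])] <- cid
  }
  lapply(split(ids, comp), sort)
}

# --- periodic distance oracle: explicit 27-image search --------------------
brute_pbc_min_dist <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    shift <- c(ix * box[1], iy * box[2], iz * box[3])
    bb <- sweep(b, 2, shift, "+")
    for (r in seq_len(nrow(a))) {
      d <- sqrt(rowSums(sweep(bb, 2, a[r, ])^2))
      best <- min(best, min(d))
    }
  }
  best
}

# --- random G(n, p) graph as an edge data frame ----------------------------
random_graph_edges <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(from = as.character(pairs[keep, 1]), to = as.character(pairs[keep, 2]))
}

# --- minimal CHARMM-format DCD writer (test fixture only) ------------------
write_dcd_fixture <- function(path, coords_list) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  nf <- length(coords_list)
  nat <- nrow(coords_list[[1]])
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- formatC("memflux test fixture", width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(nat), con, size = 4, endian = "little"), 4)
  for (xyz in coords_list) {
    for (k in 1:3) {
      rec(function() writeBin(as.numeric(xyz[, k]), con, size = 4, endian = "little"),
          4 * nat)
    }
  }
  invisible(path)
}

# --- small hand-built trajectories -----------------------------------------
toy_traj <- function(coords_list, atoms = NULL, box = NULL) {
  nat <- nrow(coords_list[[1]])
  if (is.null(atoms)) {
    atoms <- tibble::tibble(atom_name = "CA", element = "C", residue_name = "ALA",
                            residue_id = seq_len(nat), chain_id = "A")
  }
  arr <- array(NA_real_, dim = c(length(coords_list), nat, 3L))
  for (f in seq_along(coords_list)) arr[f, , ] <- coords_list[[f]]
  trajectory(atoms, arr, box = box)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q)
}
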