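#' Default van der Waals radii (angstrom)
#'
#' Bondi-style values for the elements common in proteins; unknown elements
#' fall back to 1.70.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii.
#' @export
vdw_radii <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# deterministic quasi-uniform sphere points (golden spiral / Fibonacci lattice)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom is expanded by the probe radius and sampled with a deterministic
#' golden-spiral point set; a sample point is accessible when it lies outside
#' every neighbouring expanded sphere. Per-atom SASA is the accessible
#' fraction times the expanded-sphere area.
#'
#' @param coords `n x 3` coordinate matrix (angstrom).
#' @param radii Per-atom van der Waals radii (angstrom), all positive.
#' @param probe Probe radius (angstrom); 1.4 approximates water.
#' @param n_points Sphere sample points per atom (>= 92).
#' @return List with `per_atom` (numeric vector, square angstrom) and
#'   `total` (their sum).
#' @export
sasa_shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L) coords <- matrix(coords, ncol = 3L)
  n <- nrow(coords)
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n || any(radii <= 0)) abort("radii must be positive, one per atom")
  if (n_points < 92L) abort("n_points must be >= 92")
  pts <- golden_spiral_points(as.integer(n_points))
  rext <- radii + probe
  # neighbour prefilter: only atoms whose expanded spheres can overlap
  dmat <- if (n > 1L) cross_dist(coords, coords) else matrix(0, 1, 1)
  per_atom <- vapply(seq_len(n), function(i) {
    nb <- which(dmat[i, ] < rext[i] + rext & seq_len(n) != i)
    area_i <- 4 * pi * rext[i]^2
    if (length(nb) == 0L) return(area_i)
    sp <- sweep(pts * rext[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, nrow(sp))
    for (j in nb) {
      d2 <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
        (sp[, 3] - coords[j, 3])^2
      acc <- acc & d2 > rext[j]^2
      if (!any(acc)) break
    }
    area_i * sum(acc) / nrow(sp)
  }, numeric(1))
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Per-frame SASA series for a trajectory selection
#'
#' @param traj An `mdtrj` object.
#' @param selection Atom indices (default: all heavy atoms).
#' @param probe,n_points See [sasa_shrake_rupley()].
#' @return `result_table` with columns `frame`, `time`, `sasa` (square angstrom).
#' @export
sasa_series <- function(traj, selection = select_atoms(traj, heavy = TRUE),
                        probe = 1.4, n_points = 960L) {
  if (length(selection) == 0L) abort("empty atom selection")
  radii <- vdw_radii(traj$atoms$element[selection])
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    sasa_shrake_rupley(frame_coords(traj, f)[selection, , drop = FALSE],
                       radii, probe = probe, n_points = n_points)$total
  }, numeric(1))
  result_table(
    tibble(frame = seq_len(n_frames(traj)),
           time = traj$frame_times %||% rep(NA_real_, n_frames(traj)),
           sasa = vals),
    params = list(analysis = "sasa_series", probe = probe, n_points = n_points,
                  n_select = length(selection))
  )
}
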