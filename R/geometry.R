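# Core geometric primitives. All distances in angstrom; periodic boundaries
# are orthorhombic only, applied per displacement component (minimum image).

#' Minimum-image displacement(s)
#'
#' @param d Numeric matrix (or vector) of Cartesian displacements.
#' @param box Length-3 box vector (Lx, Ly, Lz), or `NULL` for no wrapping.
#' @return Displacements wrapped into `[-L/2, L/2)` per component.
#' @export
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# all pairwise distances between two coordinate sets (na x 3, nb x 3),
# minimum image when box given; returns na x nb matrix
cross_dist <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  na <- nrow(a); nb <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

# minimum distance between two coordinate sets
min_cross_dist <- function(a, b, box = NULL) min(cross_dist(a, b, box))

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the (mass-)weighted
#' RMSD between `mobile` and `reference`. Reflections are excluded by sign
#' correction of the smallest singular value, so `det(rotation) = +1` always.
#'
#' @param mobile,reference `n x 3` coordinate matrices, matched row-wise.
#' @param weights Optional per-atom positive weights (e.g. masses).
#' @return A `superposition` list: `rotation` (3x3), `translation` (length 3),
#'   `rmsd_before`, `rmsd_after` (angstrom) and `degenerate` (TRUE when the
#'   point set is collinear or smaller than 3, making the rotation non-unique).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 1L || nrow(reference) != n) abort("mobile and reference must be matched n x 3 matrices with n >= 1")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) abort("weights must be positive, one per atom")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  rmsd_before <- sqrt(sum(w * rowSums((mobile - reference)^2)))
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  # degenerate if fewer than 3 points or collinear (rank of centred set < 2)
  degenerate <- n < 3L || {
    s <- svd(A, nu = 0, nv = 0)$d
    sum(s > max(s) * 1e-8) < 2L
  }
  aligned <- A %*% t(R)
  rmsd_after <- sqrt(sum(w * rowSums((aligned - B)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - cm %*% t(R)),
                 rmsd_before = rmsd_before, rmsd_after = rmsd_after,
                 degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f -> %.4f A%s\n", x$rmsd_before,
              x$rmsd_after, if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup A `superposition` from [kabsch_superpose()].
#' @param coords `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, -sup$translation)
}

# weighted RMSD of matched coordinate sets (no fitting)
coord_rmsd <- function(a, b, weights = NULL) {
  n <- nrow(a)
  w <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Per-frame RMSD series
#'
#' Each frame is superposed onto the reference frame using `align_selection`
#' (Kabsch, mass-unweighted) and the RMSD is then measured over `selection`.
#' Aligning on one selection while measuring another supports e.g. the RMSD
#' of a soluble domain after alignment on transmembrane helices.
#'
#' @param traj An `mdtrj` object.
#' @param selection Atom indices over which RMSD is measured.
#' @param reference_frame 1-based reference frame index.
#' @param align_selection Atom indices used for superposition; defaults to
#'   `selection`.
#' @return A `result_table` tibble with columns `frame`, `time` (ns or `NA`)
#'   and `rmsd` (angstrom).
#' @export
rmsd_series <- function(traj, selection, reference_frame = 1L,
                        align_selection = selection) {
  if (length(selection) == 0L || length(align_selection) == 0L) {
    abort("empty atom selection")
  }
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    sup <- kabsch_superpose(xyz[align_selection, , drop = FALSE],
                            ref[align_selection, , drop = FALSE])
    fit <- apply_superposition(sup, xyz[selection, , drop = FALSE])
    coord_rmsd(fit, ref[selection, , drop = FALSE])
  }, numeric(1))
  result_table(
    tibble(frame = seq_len(n_frames(traj)),
           time = traj$frame_times %||% rep(NA_real_, n_frames(traj)),
           rmsd = vals),
    params = list(analysis = "rmsd_series", reference_frame = reference_frame,
                  n_select = length(selection), n_align = length(align_selection))
  )
}

#' Radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - rbar|^2 / sum_i m_i )` with `rbar` the centre
#' of mass.
#'
#' @param coords `n x 3` coordinate matrix (angstrom).
#' @param masses Per-atom masses; unit masses by default.
#' @return Rg in angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  n <- nrow(coords)
  if (n < 1L) abort("need at least one atom")
  m <- if (is.null(masses)) rep(1, n) else as.numeric(masses)
  if (any(m <= 0)) abort("masses must be positive")
  com <- colSums(coords * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
}
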