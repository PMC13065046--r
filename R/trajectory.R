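#' Trajectory container
#'
#' An `mdtrj` object holds a molecular-dynamics trajectory in memory:
#' an atom table, per-frame Cartesian coordinates in angstrom, optional
#' per-frame orthorhombic box lengths, and optional frame times in
#' nanoseconds. All atom and frame indices are 1-based.
#'
#' @param atoms Data frame with one row per atom. Required columns:
#'   `atom_name`, `element`, `residue_name`, `residue_id`, `chain_id`.
#'   Optional: `copy_id` (integer protein-copy tag used by the aggregation
#'   module). Columns `atom_index`, `is_water_oxygen` and `is_heavy` are
#'   (re)derived by the constructor.
#' @param coords Numeric array of dimension `n_frames x n_atoms x 3` (angstrom).
#'   A single `n_atoms x 3` matrix is promoted to one frame.
#' @param box Optional numeric matrix `n_frames x 3` of orthorhombic box
#'   lengths (Lx, Ly, Lz) in angstrom, or a length-3 vector recycled over
#'   frames. `NULL` means no periodic box: operations that need the minimum
#'   image refuse to run.
#' @param frame_times Optional strictly increasing numeric vector of frame
#'   times in nanoseconds.
#' @param water_residues Residue names recognised as water.
#'
#' @return An object of class `mdtrj`.
#' @export
trajectory <- function(atoms, coords, box = NULL, frame_times = NULL,
                       water_residues = c("HOH", "WAT", "SOL", "TIP3")) {
  atoms <- as_tibble(atoms)
  need <- c("atom_name", "element", "residue_name", "residue_id", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    abort(paste0("atoms table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (nrow(atoms) != n_atoms) {
    abort(sprintf("atoms table has %d rows but coords has %d atoms", nrow(atoms), n_atoms))
  }
  if (!is.null(box)) {
    if (is.numeric(box) && is.null(dim(box)) && length(box) == 3L) {
      box <- matrix(box, nrow = n_frames, ncol = 3L, byrow = TRUE)
    }
    box <- as.matrix(box)
    if (nrow(box) != n_frames || ncol(box) != 3L) {
      abort("box must be an n_frames x 3 matrix of (Lx, Ly, Lz)")
    }
    if (any(!is.finite(box)) || any(box <= 0)) abort("box lengths must be positive and finite")
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != n_frames) abort("frame_times length must equal n_frames")
    if (n_frames > 1L && any(diff(frame_times) <= 0)) {
      abort("frame_times must be strictly increasing")
    }
  }
  atoms$atom_index <- seq_len(n_atoms)
  atoms$element <- toupper(atoms$element)
  atoms$is_water_oxygen <- atoms$element == "O" & atoms$residue_name %in% water_residues
  atoms$is_heavy <- atoms$element != "H"
  if (!"copy_id" %in% names(atoms)) atoms$copy_id <- NA_integer_
  structure(
    list(atoms = atoms, coords = coords, box = box, frame_times = frame_times,
         water_residues = water_residues),
    class = "mdtrj"
  )
}

#' Number of frames / atoms in a trajectory
#' @param traj An `mdtrj` object.
#' @return Integer scalar.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' @export
print.mdtrj <- function(x, ...) {
  cat(sprintf("<mdtrj> %d frame(s), %d atoms", n_frames(x), n_atoms(x)))
  if (!is.null(x$box)) cat(sprintf(", box %.1f x %.1f x %.1f A", x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  cat("\n")
  nw <- sum(x$atoms$is_water_oxygen)
  cat(sprintf("  chains: %s; water oxygens: %d\n",
              paste(unique(x$atoms$chain_id), collapse = " "), nw))
  invisible(x)
}

#' Extract the coordinates of one frame
#' @param traj An `mdtrj` object.
#' @param frame 1-based frame index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= n_frames(traj))
  matrix(traj$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atoms by chain, residue range, atom name or role
#'
#' Predicates are combined with AND; vector-valued predicates are ORed
#' internally (e.g. `chain = c("A", "B")`).
#'
#' @param traj An `mdtrj` object.
#' @param chain Chain identifiers to keep.
#' @param resid Residue ids to keep (any integer vector, e.g. `10:40`).
#' @param resname Residue names to keep.
#' @param name Atom names to keep.
#' @param element Elements to keep.
#' @param water `TRUE` to keep only water-oxygen atoms, `FALSE` to drop all
#'   water atoms.
#' @param heavy `TRUE` to keep only non-hydrogen atoms.
#' @return Integer vector of 1-based atom indices.
#' @export
select_atoms <- function(traj, chain = NULL, resid = NULL, resname = NULL,
                         name = NULL, element = NULL, water = NULL, heavy = NULL) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(resid)) keep <- keep & a$residue_id %in% resid
  if (!is.null(resname)) keep <- keep & a$residue_name %in% resname
  if (!is.null(name)) keep <- keep & a$atom_name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  if (!is.null(water)) {
    keep <- keep & if (water) a$is_water_oxygen else !(a$residue_name %in% traj$water_residues)
  }
  if (!is.null(heavy) && heavy) keep <- keep & a$is_heavy
  which(keep)
}

#' Parse a selection expression
#'
#' Mini-language used at the command line: clauses joined by `and`, each
#' being `chain <id...>`, `resid <a>-<b>` or `resid <a> <b> ...`,
#' `resname <name...>`, `name <name...>`, `element <sym...>`, `water`,
#' `protein` (non-water) or `heavy`. Example:
#' `"chain A and resid 1-35 and name CA"`.
#'
#' @param traj An `mdtrj` object.
#' @param expr Selection string.
#' @return Integer vector of 1-based atom indices.
#' @export
parse_selection <- function(traj, expr) {
  if (is.null(expr) || !nzchar(trimws(expr)) || identical(trimws(expr), "all")) {
    return(seq_len(n_atoms(traj)))
  }
  clauses <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  args <- list(traj = traj)
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- tolower(tok[1])
    vals <- tok[-1]
    if (key == "water") { args$water <- TRUE; next }
    if (key == "protein") { args$water <- FALSE; next }
    if (key == "heavy") { args$heavy <- TRUE; next }
    if (length(vals) == 0L) abort(sprintf("selection clause '%s' has no arguments", cl))
    if (key == "resid") {
      ids <- unlist(lapply(vals, function(v) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
          ab <- as.integer(strsplit(sub("(?<=[0-9])-", ";", v, perl = TRUE), ";")[[1]])
          seq(ab[1], ab[2])
        } else as.integer(v)
      }))
      args$resid <- ids
    } else if (key %in% c("chain", "resname", "name", "element")) {
      args[[key]] <- vals
    } else {
      abort(sprintf("unknown selection keyword '%s'", key))
    }
  }
  do.call(select_atoms, args)
}

#' Assign protein-copy identifiers
#'
#' Tags every non-water atom with an integer `copy_id` used by the
#' aggregation module. Copies are identified by chain id (default) or taken
#' from an explicit mapping.
#'
#' @param traj An `mdtrj` object.
#' @param by `"chain"` or a named integer vector mapping chain id to copy id.
#' @return The trajectory with `copy_id` filled in.
#' @export
assign_copies <- function(traj, by = "chain") {
  a <- traj$atoms
  is_prot <- !(a$residue_name %in% traj$water_residues)
  if (identical(by, "chain")) {
    chains <- sort(unique(a$chain_id[is_prot]))
    map <- setNames(seq_along(chains), chains)
  } else {
    map <- by
  }
  a$copy_id <- ifelse(is_prot, unname(map[a$chain_id]), NA_integer_)
  traj$atoms <- a
  traj
}

#' Standard atomic masses for common elements
#' @param elements Character vector of element symbols.
#' @return Numeric vector of masses (amu); unknown elements get 12.0 with a warning.
#' @export
atomic_masses <- function(elements) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
           CA = 40.078, FE = 55.845, ZN = 65.38)
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  m <- tab[key]
  if (anyNA(m)) {
    warn(paste0("unknown element(s) ", paste(unique(elements[is.na(m)]), collapse = ", "),
                "; assuming mass 12.0"))
    m[is.na(m)] <- 12.0
  }
  unname(m)
}

#' Take every k-th frame of a trajectory
#' @param traj An `mdtrj` object.
#' @param stride Positive integer stride; 1 keeps every frame.
#' @return A strided `mdtrj`.
#' @export
stride_frames <- function(traj, stride = 1L) {
  stride <- as.integer(stride)
  if (stride < 1L) abort("stride must be >= 1")
  if (stride == 1L) return(traj)
  idx <- seq(1L, n_frames(traj), by = stride)
  traj$coords <- traj$coords[idx, , , drop = FALSE]
  if (!is.null(traj$box)) traj$box <- traj$box[idx, , drop = FALSE]
  if (!is.null(traj$frame_times)) traj$frame_times <- traj$frame_times[idx]
  traj
}
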