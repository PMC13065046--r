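# Multi-model PDB reader/writer. Fixed-column parsing per the PDB v3 format:
# ATOM/HETATM records, MODEL/ENDMDL framing, CRYST1 for the box. Only
# orthorhombic cells are supported; triclinic input is refused explicitly.

guess_element <- function(atom_name) {
  nm <- gsub("[0-9'\"]", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  el <- toupper(substr(nm, 1, 1))
  el[two %in% c("CL", "NA", "MG", "FE", "ZN", "BR")] <-
    two[two %in% c("CL", "NA", "MG", "FE", "ZN", "BR")]
  # H named like 1H or HW1 etc.
  el[grepl("^[0-9]*H", toupper(trimws(atom_name)))] <- "H"
  el
}

#' Read a (multi-model) PDB file into a trajectory
#'
#' One frame per `MODEL` block (a single frame when the file has none).
#' `CRYST1` is parsed into per-frame orthorhombic box lengths; cells with
#' angles differing from 90 degrees are refused. Waters are detected by a
#' configurable residue-name whitelist.
#'
#' @param path Path to a PDB file.
#' @param water_residues Residue names treated as water.
#' @return An [trajectory()] object (`mdtrj`).
#' @export
read_traj_pdb <- function(path, water_residues = c("HOH", "WAT", "SOL", "TIP3")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cryst <- which(startsWith(rec, "CRYST1"))
  if (length(cryst) > 0L) {
    ln <- lines[cryst[1]]
    num <- function(a, b) suppressWarnings(as.numeric(substr(ln, a, b)))
    abc <- c(num(7, 15), num(16, 24), num(25, 33))
    ang <- c(num(34, 40), num(41, 47), num(48, 54))
    if (anyNA(abc)) abort(sprintf("malformed CRYST1 record at line %d", cryst[1]))
    if (any(abs(ang - 90) > 1e-3)) {
      abort("triclinic boxes are not supported (CRYST1 angles differ from 90 degrees)")
    }
    box <- abc
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_start <- startsWith(rec, "MODEL")
  model_end <- startsWith(rec, "ENDMDL")
  # assign a model id to every atom line
  model_id <- cumsum(model_start)
  if (!any(model_start)) model_id <- rep(1L, length(lines))
  model_id[model_end] <- 0L
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0L) abort(sprintf("no ATOM/HETATM records in %s", path))
  mid <- model_id[atom_lines]
  if (any(mid == 0L)) abort("ATOM record outside a MODEL block in a multi-model file")
  mids <- sort(unique(mid))
  counts <- tabulate(match(mid, mids))
  if (length(unique(counts)) != 1L) {
    abort(sprintf("inconsistent atom counts between models: %s",
                  paste(unique(counts), collapse = " vs ")))
  }
  nat <- counts[1]
  nfr <- length(mids)

  parse_block <- function(lns, line_nos) {
    fx <- suppressWarnings(as.numeric(substr(lns, 31, 38)))
    fy <- suppressWarnings(as.numeric(substr(lns, 39, 46)))
    fz <- suppressWarnings(as.numeric(substr(lns, 47, 54)))
    bad <- which(is.na(fx) | is.na(fy) | is.na(fz))
    if (length(bad) > 0L) {
      abort(sprintf("malformed ATOM record at line %d: unparseable coordinates",
                    line_nos[bad[1]]))
    }
    cbind(fx, fy, fz)
  }

  first <- atom_lines[mid == mids[1]]
  ln1 <- lines[first]
  atom_name <- trimws(substr(ln1, 13, 16))
  resname <- trimws(substr(ln1, 18, 21))
  chain <- trimws(substr(ln1, 22, 22))
  chain[chain == ""] <- " "
  resid <- suppressWarnings(as.integer(substr(ln1, 23, 26)))
  if (anyNA(resid)) {
    abort(sprintf("malformed ATOM record at line %d: unparseable residue number",
                  first[which(is.na(resid))[1]]))
  }
  el <- trimws(substr(ln1, 77, 78))
  el[el == ""] <- guess_element(atom_name[el == ""])

  coords <- array(NA_real_, dim = c(nfr, nat, 3L))
  for (i in seq_len(nfr)) {
    sel <- atom_lines[mid == mids[i]]
    coords[i, , ] <- parse_block(lines[sel], sel)
  }
  atoms <- tibble(atom_name = atom_name, element = toupper(el),
                  residue_name = resname, residue_id = resid, chain_id = chain)
  trajectory(atoms, coords,
             box = if (!is.null(box)) matrix(box, nfr, 3, byrow = TRUE) else NULL,
             water_residues = water_residues)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An `mdtrj` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traj_pdb <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[1, 1], traj$box[1, 2], traj$box[1, 3],
                       90, 90, 90), con)
  }
  # PDB name column: 1-char elements start in column 14
  fmt_name <- ifelse(nchar(a$atom_name) < 4 & nchar(a$element) == 1,
                     sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
  serial <- ((a$atom_index - 1L) %% 99999L) + 1L
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       serial, fmt_name, a$residue_name, a$chain_id,
                       a$residue_id, xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a topology plus binary trajectory (DCD)
#'
#' Coordinates come from the DCD (read with the bio3d reader); atom metadata
#' come from the PDB topology. Atom counts must agree. DCD carries no box
#' information here, so PBC-dependent analyses will refuse unless a box is
#' supplied afterwards.
#'
#' @param topology Path to a PDB file providing atom metadata.
#' @param traj_file Path to a DCD trajectory.
#' @param water_residues Residue names treated as water.
#' @return An `mdtrj` object.
#' @export
read_traj_dcd <- function(topology, traj_file,
                          water_residues = c("HOH", "WAT", "SOL", "TIP3")) {
  top <- read_traj_pdb(topology, water_residues = water_residues)
  xyz <- bio3d::read.dcd(traj_file, verbose = FALSE)
  nat <- ncol(xyz) / 3L
  if (nat != n_atoms(top)) {
    abort(sprintf("atom-count mismatch: topology has %d atoms, trajectory has %d",
                  n_atoms(top), nat))
  }
  nfr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nfr, nat, 3L))
  for (f in seq_len(nfr)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  trajectory(top$atoms[, c("atom_name", "element", "residue_name",
                           "residue_id", "chain_id", "copy_id")],
             coords, box = NULL, water_residues = water_residues)
}
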