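# High-level runs: each wrapper executes one analysis end to end, stamps
# provenance (inputs, parameters, seed, version) into every artifact, and
# writes figure-ready TSV plus a JSON summary. The command-line tool in
# exec/memflux is a thin shell over these functions.

stamp <- function(tbl, config) {
  attr(tbl, "provenance")$params <- c(attr(tbl, "provenance")$params, config[setdiff(names(config), "out")])
  attr(tbl, "provenance")$inputs <- as.character(config$inputs %||% character())
  attr(tbl, "provenance")$seed <- config$seed %||% NA_integer_
  tbl
}

write_summary_json <- function(x, path, config = list()) {
  obj <- list(provenance = list(tool = "memflux",
                                version = as.character(packageVersion("memflux")),
                                inputs = as.character(config$inputs %||% character()),
                                params = config[setdiff(names(config), c("out", "inputs"))],
                                seed = config$seed %||% NA_integer_),
              summary = x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Run the permeation analysis end to end
#'
#' @param traj An `mdtrj`, or a PDB path.
#' @param slab A [membrane_slab()], or `"auto"` with `marker_selection`.
#' @param protein_selection Atom indices of the protein (default: all
#'   non-water atoms).
#' @param marker_selection Marker atoms for `slab = "auto"`.
#' @param cutoff Proximity cutoff (angstrom).
#' @param stride Frame stride (default 1).
#' @param min_dwell Minimum inside dwell in frames.
#' @param out Optional output prefix; writes `<out>_events.tsv` and
#'   `<out>_summary.json`.
#' @return List with `events` (result table) and `rate`
#'   (`translocation_result`).
#' @export
run_permeation <- function(traj, slab, protein_selection = NULL,
                           marker_selection = NULL, cutoff = 6.0, stride = 1L,
                           min_dwell = 1L, out = NULL) {
  if (cutoff <= 0) abort("cutoff must be positive")
  inputs <- character()
  if (is.character(traj)) { inputs <- traj; traj <- read_traj_pdb(traj) }
  traj <- stride_frames(traj, stride)
  if (identical(slab, "auto")) {
    if (is.null(marker_selection)) abort("slab = 'auto' needs marker_selection")
    slab <- estimate_slab(traj, marker_selection)
  }
  protein_selection <- protein_selection %||% select_atoms(traj, water = FALSE)
  vol <- protein_volume(protein_selection, slab, cutoff)
  occ <- occupancy_series(traj, vol)
  events <- extract_events(occ, traj, slab, min_dwell = min_dwell)
  rate <- translocation_rate(events)
  cfg <- list(inputs = inputs, z_lower = slab$z_lower, z_upper = slab$z_upper,
              cutoff = cutoff, stride = stride, min_dwell = min_dwell)
  events <- stamp(events, cfg)
  if (!is.null(out)) {
    write_result(events, paste0(out, "_events.tsv"), "tsv", empty_ok = TRUE)
    write_summary_json(glance(rate), paste0(out, "_summary.json"), cfg)
  }
  list(events = events, rate = rate)
}

#' Run the water-wire analysis end to end
#'
#' @inheritParams run_permeation
#' @param oo_cutoff,angle,use_angles Hydrogen-bond criteria (see
#'   [hbond_criteria()]).
#' @return List with `stats` (per-frame table) and `histograms`.
#' @export
run_wires <- function(traj, slab, protein_selection = NULL, cutoff = 6.0,
                      oo_cutoff = 3.5, angle = 150, use_angles = TRUE,
                      stride = 1L, out = NULL) {
  inputs <- character()
  if (is.character(traj)) { inputs <- traj; traj <- read_traj_pdb(traj) }
  traj <- stride_frames(traj, stride)
  protein_selection <- protein_selection %||% select_atoms(traj, water = FALSE)
  vol <- protein_volume(protein_selection, slab, cutoff)
  crit <- hbond_criteria(oo_cutoff, angle, require_hydrogens = use_angles)
  stats <- wire_stats_series(traj, vol, crit)
  hists <- wire_histograms(stats)
  cfg <- list(inputs = inputs, oo_cutoff = oo_cutoff, angle = angle,
              use_angles = use_angles, cutoff = cutoff, stride = stride)
  stats <- stamp(stats, cfg)
  if (!is.null(out)) {
    write_result(stats, paste0(out, "_wires.tsv"), "tsv", empty_ok = TRUE)
    write_summary_json(list(max_length = hists$max_length,
                            mean_length = hists$mean_length),
                       paste0(out, "_wire_histograms.json"), cfg)
  }
  list(stats = stats, histograms = hists)
}

#' Run the cross-chain interaction inventory end to end
#'
#' @inheritParams run_permeation
#' @param chain_a,chain_b Chain identifiers.
#' @param min_occupancy Reporting threshold.
#' @param saltbridge_cutoff Salt-bridge cutoff (angstrom).
#' @return The inventory `result_table`.
#' @export
run_contacts <- function(traj, chain_a, chain_b, min_occupancy = 0.2,
                         saltbridge_cutoff = 4.0, stride = 1L, out = NULL) {
  inputs <- character()
  if (is.character(traj)) { inputs <- traj; traj <- read_traj_pdb(traj) }
  traj <- stride_frames(traj, stride)
  inv <- interaction_inventory(traj, select_atoms(traj, chain = chain_a),
                               select_atoms(traj, chain = chain_b),
                               min_occupancy = min_occupancy,
                               saltbridge_cutoff = saltbridge_cutoff)
  cfg <- list(inputs = inputs, chain_a = chain_a, chain_b = chain_b,
              min_occupancy = min_occupancy,
              saltbridge_cutoff = saltbridge_cutoff, stride = stride)
  inv <- stamp(inv, cfg)
  if (!is.null(out)) write_result(inv, paste0(out, "_contacts.tsv"), "tsv", empty_ok = TRUE)
  inv
}

#' Run the aggregation entity analysis end to end
#'
#' @inheritParams run_permeation
#' @param copies `"by-chain"` or a named chain-to-copy mapping.
#' @param contact_cutoff Heavy-atom contact cutoff (angstrom).
#' @param use_pbc Use minimum-image distances (needs a box).
#' @param sensitivity Also emit entity counts over cutoffs 4.0/4.5/5.0.
#' @return List with `timeline`, `labels`, optional `sensitivity`.
#' @export
run_aggregate <- function(traj, copies = "by-chain", contact_cutoff = 4.5,
                          use_pbc = TRUE, stride = 1L, sensitivity = TRUE,
                          out = NULL) {
  if (contact_cutoff <= 0) abort("contact_cutoff must be positive")
  inputs <- character()
  if (is.character(traj)) { inputs <- traj; traj <- read_traj_pdb(traj) }
  traj <- stride_frames(traj, stride)
  traj <- assign_copies(traj, by = if (identical(copies, "by-chain")) "chain" else copies)
  tl <- entity_timeline(traj, contact_graph_spec(contact_cutoff, use_pbc))
  labels <- entity_track_labels(tl)
  sens <- if (sensitivity) entity_sensitivity(traj, use_pbc = use_pbc) else NULL
  cfg <- list(inputs = inputs, contact_cutoff = contact_cutoff,
              use_pbc = use_pbc, stride = stride)
  if (!is.null(out)) {
    flat <- as_tibble(tl)[, c("frame", "time", "n_entities")]
    flat$partition <- vapply(tl$entities, function(ps) {
      paste(vapply(ps, function(p) paste(p, collapse = "+"), character(1)), collapse = " ")
    }, character(1))
    write_result(stamp(result_table(flat), cfg), paste0(out, "_entities.tsv"), "tsv")
    write_summary_json(as.list(glance(tl)), paste0(out, "_kinetics.json"), cfg)
  }
  list(timeline = tl, labels = labels, sensitivity = sens)
}

#' Merge replica result tables
#'
#' For rate/occupancy-style tables with `n_success` and `n_total` columns:
#' `pooled` sums counts across replicas before dividing, `per_replica_mean`
#' averages the per-replica rates with equal weights. Both agree exactly
#' when replicas contribute equal totals.
#'
#' @param tables List of data frames, each with `n_success` and `n_total`
#'   (one row per replica, or multiple rows summed per table).
#' @param mode `"pooled"`, `"per_replica_mean"` or `"both"`.
#' @return A `result_table` with columns `mode`, `rate`, `n_success`,
#'   `n_total`, `n_replicas`.
#' @export
replica_merge <- function(tables, mode = c("both", "pooled", "per_replica_mean")) {
  mode <- match.arg(mode)
  ok <- vapply(tables, function(t) all(c("n_success", "n_total") %in% names(t)), logical(1))
  if (!all(ok)) abort("every replica table needs n_success and n_total columns")
  succ <- vapply(tables, function(t) sum(t$n_success), numeric(1))
  tot <- vapply(tables, function(t) sum(t$n_total), numeric(1))
  if (any(tot == 0)) abort("a replica has zero total events")
  rows <- list()
  if (mode %in% c("both", "pooled")) {
    rows[[length(rows) + 1L]] <- tibble(mode = "pooled", rate = sum(succ) / sum(tot),
                                        n_success = sum(succ), n_total = sum(tot),
                                        n_replicas = length(tables))
  }
  if (mode %in% c("both", "per_replica_mean")) {
    rows[[length(rows) + 1L]] <- tibble(mode = "per_replica_mean",
                                        rate = mean(succ / tot),
                                        n_success = sum(succ), n_total = sum(tot),
                                        n_replicas = length(tables))
  }
  result_table(bind_rows(rows), params = list(analysis = "replica_merge", mode = mode))
}

#' Run a synthetic-system generator and write it to disk
#'
#' Writes `<out>.pdb` (multi-model, with box) and `<out>_truth.json`.
#'
#' @param what One of `"permeation"`, `"wires"`, `"aggregate"`, `"cluster"`.
#' @param seed Integer seed.
#' @param out Output prefix.
#' @param ... Passed to the generator.
#' @return The generator's list, invisibly.
#' @export
run_synth <- function(what = c("permeation", "wires", "aggregate", "cluster"),
                      seed, out, ...) {
  what <- match.arg(what)
  gen <- switch(what,
                permeation = generate_permeation_system,
                wires = generate_wire_frames,
                aggregate = generate_aggregation_trajectory,
                cluster = generate_cluster_frames)
  sys <- gen(seed = seed, ...)
  write_traj_pdb(sys$traj, paste0(out, ".pdb"))
  truth <- sys$truth
  for (cn in names(truth)) if (is.list(truth[[cn]])) {
    truth[[cn]] <- vapply(truth[[cn]], function(v) {
      if (is.list(v)) {
        paste(vapply(v, function(p) paste(p, collapse = "+"), character(1)), collapse = " ")
      } else paste(v, collapse = ",")
    }, character(1))
  }
  write_summary_json(truth, paste0(out, "_truth.json"),
                     list(seed = seed, generator = what))
  invisible(sys)
}
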