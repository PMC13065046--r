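# hand-built multi-copy frame: each copy is a 2-atom dumbbell at a centre
copies_frame <- function(centres) {
  do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    rbind(centres[i, ] + c(-1, 0, 0), centres[i, ] + c(1, 0, 0))
  }))
}
copies_traj <- function(centre_list, box = NULL) {
  n <- nrow(centre_list[[1]])
  atoms <- tibble::tibble(atom_name = "C", element = "C", residue_name = "DUM",
                          residue_id = rep(seq_len(n), each = 2L),
                          chain_id = rep(LETTERS[seq_len(n)], each = 2L))
  tr <- toy_traj(lapply(centre_list, copies_frame), atoms = atoms, box = box)
  assign_copies(tr, by = "chain")
}

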