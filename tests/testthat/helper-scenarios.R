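# Shared fixture builders.  Everything is generated in code at test time.

# A small, fast scenario for unit tests (well inside the default study
# conditions used by the acceptance suite).
small_scenario <- function(...) {
  conformer_scenario(n_residues = 16,
                     transition_midpoint = c(WT = 10, VARIANT = 16),
                     transition_gap = 12,
                     midpoint_jitter = 0,
                     noise_sd = 0.2,
                     buried_loop = 7:8,
                     exposed_motif = 11:12,
                     n_frames = 40L,
                     n_repeats = 1L,
                     n_points = 240L,
                     ...)
}

# A tiny rigid trajectory: one structure under random rigid-body motion.
rigid_body_trajectory <- function(n_atoms = 8, n_frames = 5, seed = 1) {
  set.seed(seed)
  base <- matrix(runif(n_atoms * 3, -5, 5), ncol = 3)
  top <- data.frame(atom_index = seq_len(n_atoms), atom_name = "CA",
                    element = "C", residue_index = seq_len(n_atoms),
                    residue_name = "GLY", chain_id = "A", vdw_radius = 1.7)
  coords <- array(0, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    coords[, , f] <- base %*% t(Rz %*% Rx) +
      matrix(runif(3, -10, 10), n_atoms, 3, byrow = TRUE)
  }
  trajectory(top, coords)
}

write_temp_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resno, x, y, z, resid = "GLY") {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, name, resid, resno, x, y, z)
}
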