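# Programmatic fixtures shared across tests.

# A PDB file with a 10-residue protein chain A (CA + CB per residue), a DNA
# chain B and waters, in n_models identical-layout models. Model m shifts
# protein x by (m - 1).
make_mixed_pdb <- function(path, n_models = 1L) {
  aa <- c("MET", "LYS", "ARG", "PRO", "ALA", "VAL", "TRP", "GLY", "LEU",
          "TYR")
  lines <- character()
  for (m in seq_len(n_models)) {
    if (n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    fmt <- "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s"
    for (i in seq_along(aa)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CA ", aa[i], "A", i,
                                i * 3.8 + (m - 1), 0, 0, "C"))
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CB ", aa[i], "A", i,
                                i * 3.8 + (m - 1), 1.5, 0, "C"))
    }
    for (i in 1:4) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " P  ", " DA", "B", i,
                                50, i * 6, 0, "P"))
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, " CA ", " DA", "B", i,
                                50, i * 6, 2, "C"))  # DNA pseudo-CA
    }
    for (i in 1:5) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
        serial, 100 + i, 20, 20, i * 1.0))
    }
    if (n_models > 1L) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Manual two-partner trajectory: receptor helix + peptide helix, with a
# list of per-frame functions editing the coordinate matrix.
make_complex_traj <- function(frame_edits, n_rec = 10L, n_pep = 4L) {
  rec <- synth_helix(n_rec, id = "rec")
  pep <- synth_helix(n_pep, id = "pep", resno_start = n_rec + 1L)
  ref <- rbind(rec$xyz, sweep(pep$xyz, 2L, c(30, 0, 0), `+`))
  arr <- array(0, dim = c(n_rec + n_pep, 3L, length(frame_edits) + 1L))
  arr[, , 1] <- ref
  for (k in seq_along(frame_edits))
    arr[, , k + 1L] <- frame_edits[[k]](ref)
  traj <- ca_trajectory(arr, c(rec$resno, pep$resno),
                        c(rec$resid, pep$resid), 25)
  complex_trajectory(traj, rec$resno, pep$resno, "DOCKED")
}
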