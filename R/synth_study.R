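#' Build a complete synthetic HMG-box study on disk
#'
#' Writes every input the pipeline consumes — variant catalog, family and
#' subfamily alignments, an MD-style trajectory and three docking-regime
#' complex trajectories — with known ground truth, plus a ready `run.yaml`.
#' The study emulates the real analysis' conditions: a 79-residue box; 69
#' family and 20 subfamily sequences; 44 variant records at 33 distinct
#' positions spread over 5 protein labels; 8 positions fully conserved in
#' the family with class-consistent symbols (hydrophobic/aromatic at 9, 12,
#' 40, 51; hydrophobic at 6, 32, 43; basic at 48), 19 further positions
#' conserved only in the subfamily (including the DNA-contact positions 4
#' and 29), and 6 positions (including 16 and 45) conserved in neither; a
#' 1000 ps trajectory stored every 25 ps whose per-residue sigma is 0.3 Å
#' at family-conserved positions and 1.0 Å elsewhere; and 1500 ps docking
#' runs with a 0.5 Å tether (DOCKED), 1.5 Å tether (DOCKED_ALA) and a
#' 0.5 Å/frame random walk (FREE).
#'
#' Engineered conserved columns use target frequency 1.0 and uniform
#' background elsewhere, so the tier ground truth (8/19/6) holds exactly
#' for every seed.
#'
#' @param dir Output directory for the generated files.
#' @param seed Integer master seed; per-generator seeds derive from it by a
#'   fixed counter scheme.
#' @return A config list (as taken by [run_pipeline()]) with attribute
#'   `"truth"` holding the engineered position sets and sigmas.
#' @export
synth_study <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  box_len <- 79L
  hmg_pos <- c(6L, 9L, 12L, 32L, 40L, 43L, 48L, 51L)
  hmg_sym <- c("L", "F", "W", "V", "F", "I", "R", "Y")
  sox_pos <- c(4L, 29L, 2L, 7L, 10L, 13L, 18L, 20L, 22L, 25L, 27L, 31L,
               34L, 36L, 38L, 53L, 56L, 58L, 60L)
  sox_sym <- c("N", "Y", "K", "S", "G", "E", "R", "W", "M", "K", "P", "F",
               "Q", "H", "D", "L", "T", "K", "E")
  not_pos <- c(16L, 45L, 63L, 66L, 70L, 74L)
  nv_pos <- sort(c(hmg_pos, sox_pos, not_pos))

  hmg_cols <- data.frame(column = hmg_pos, symbol = hmg_sym,
                         target_freq = 1.0)
  sox_cols <- data.frame(column = c(hmg_pos, sox_pos),
                         symbol = c(hmg_sym, sox_sym), target_freq = 1.0)
  hmg <- synth_msa(69L, box_len, hmg_cols, seed = child_seed(seed, 1L),
                   gap_freq = 0.03, name = "HMG")
  sox <- synth_msa(20L, box_len, sox_cols, seed = child_seed(seed, 2L),
                   gap_freq = 0.03, name = "SOX")
  f_hmg <- write_aligned_fasta(hmg, file.path(dir, "hmg_human.fasta"))
  f_sox <- write_aligned_fasta(sox, file.path(dir, "sox_human.fasta"))

  # 44 variant records at the 33 positions over 5 protein labels: the 11
  # lowest positions receive a second, different substitution.
  base <- synth_variant_table(hmg, nv_pos, seed = child_seed(seed, 3L))
  proteins <- rep(c("SRY", "SOX9", "SOX10", "SOX2"),
                  length.out = length(nv_pos))
  proteins[nv_pos %in% c(45L, 74L)] <- "HMGB1"
  base$protein <- proteins
  base$accession <- sprintf("SYN%05d", match(base$protein,
                                             unique(base$protein)))
  dup <- base[seq_len(11L), , drop = FALSE]
  set.seed(child_seed(seed, 4L))
  dup$var <- vapply(seq_len(nrow(dup)), function(i)
    sample(setdiff(AA1, c(dup$wt[i], dup$var[i])), 1L), "")
  catalog <- new_variant_catalog(rbind(base, dup))
  f_cat <- write_variants(catalog, file.path(dir, "variants.tsv"))

  # 1000 ps trajectory, 25 ps spacing: quiet family-conserved residues.
  ref <- synth_helix(box_len, id = "box")
  sigma <- ifelse(seq_len(box_len) %in% hmg_pos, 0.3, 1.0)
  traj <- synth_trajectory(ref, sigma, n_frames = 40L,
                           frame_interval_ps = 25,
                           jitter = list(max_rot_deg = 10, max_trans = 3),
                           seed = child_seed(seed, 5L))
  f_traj <- write_trajectory_pdb(traj, file.path(dir, "trajectory.pdb"))

  # 1500 ps docking regimes, 25 ps spacing (61 frames).
  receptor <- synth_helix(60L, id = "receptor")
  peptide <- synth_helix(12L, id = "peptide")
  regimes <- list(
    DOCKED = list(tether_sigma = 0.5),
    DOCKED_ALA = list(tether_sigma = 1.5),
    FREE = list(step = 0.5))
  complexes <- lapply(seq_along(regimes), function(i) {
    cond <- names(regimes)[i]
    cplx <- synth_complex_trajectory(receptor, peptide, cond,
                                     params = regimes[[i]], n_frames = 60L,
                                     frame_interval_ps = 25,
                                     seed = child_seed(seed, 10L + i))
    path <- write_trajectory_pdb(cplx$trajectory,
                                 file.path(dir,
                                           sprintf("complex_%s.pdb", cond)))
    list(path = path, condition = cond, receptor = "1-60",
         peptide = "61-72", interval_ps = 25)
  })

  cfg <- list(out_dir = file.path(dir, "out"),
              catalog = f_cat,
              hmg_alignment = f_hmg, sox_alignment = f_sox,
              trajectory = f_traj, trajectory_interval_ps = 25,
              complexes = complexes,
              threshold = 0.90, mode = "class", interval_ps = 25,
              fit = "ca", seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "run.yaml"))
  attr(cfg, "truth") <- list(hmg_positions = sort(hmg_pos),
                             sox_positions = sort(sox_pos),
                             not_positions = sort(not_pos),
                             sigma = sigma, box_len = box_len)
  cfg
}
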