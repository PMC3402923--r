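#' Generate a synthetic multiple sequence alignment
#'
#' Emulates the statistical structure of a protein family alignment with
#' controllable per-column conservation. At each specified column the
#' conserved symbol is drawn with the target probability (the remainder
#' spread uniformly over the other letters); unspecified columns are drawn
#' uniformly over the alphabet. The reference (first) sequence always
#' carries the conserved symbol at specified columns, so variant wild-types
#' read from it are consistent with the engineered conservation.
#'
#' @param n_sequences Number of sequences.
#' @param length Alignment length (columns).
#' @param columns Data.frame with columns `column`, `symbol`,
#'   `target_freq` (each in \[1/alphabet size, 1\]) naming the engineered
#'   columns.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param alphabet Symbol alphabet (default the 20 amino acids).
#' @param gap_freq Probability of a gap at unspecified columns of
#'   non-reference sequences (default 0).
#' @param name,reference_id Passed to [aligned_set()]; the reference is the
#'   first sequence, ids are `<name>_seq1 ...`.
#' @return An `aligned_set`.
#' @export
synth_msa <- function(n_sequences, length, columns = NULL, seed = 1L,
                      alphabet = AA1, gap_freq = 0, name = "synthetic") {
  stopifnot(n_sequences >= 1L, length >= 1L)
  if (!is.null(columns)) {
    stopifnot(all(c("column", "symbol", "target_freq") %in% names(columns)))
    if (any(columns$column < 1L | columns$column > length))
      stop_fmt("engineered column outside alignment length %d", length)
    if (any(!columns$symbol %in% alphabet))
      stop_fmt("engineered symbol not in alphabet")
    if (any(columns$target_freq < 1 / length(alphabet) |
            columns$target_freq > 1))
      stop_fmt("target frequency must lie in [1/|alphabet|, 1]")
  }
  set.seed(seed)
  m <- matrix(sample(alphabet, n_sequences * length, replace = TRUE),
              nrow = n_sequences)
  if (gap_freq > 0 && n_sequences > 1L) {
    gaps <- matrix(stats::runif(n_sequences * length) < gap_freq,
                   nrow = n_sequences)
    gaps[1, ] <- FALSE                       # reference stays ungapped
    m[gaps] <- "-"
  }
  if (!is.null(columns)) {
    for (j in seq_len(nrow(columns))) {
      cc <- columns$column[j]; sym <- columns$symbol[j]
      p <- columns$target_freq[j]
      others <- setdiff(alphabet, sym)
      hit <- stats::runif(n_sequences) < p
      m[, cc] <- ifelse(hit, sym,
                        sample(others, n_sequences, replace = TRUE))
      m[1, cc] <- sym
    }
  }
  ids <- sprintf("%s_seq%d", name, seq_len(n_sequences))
  aligned_set(ids, apply(m, 1L, paste, collapse = ""), name = name,
              reference_id = ids[1])
}

#' Generate an ideal alpha-helical Cα trace
#'
#' Standard helix geometry: 1.5 Å rise and 100 degrees of twist per
#' residue on a 2.3 Å radius. Deterministic (no seed); a toy stand-in for
#' HMG-box helices.
#'
#' @param n_residues Number of residues (>= 4).
#' @param id Model identifier.
#' @param resno_start First residue number.
#' @return A `structure_model` of all-alanine residues.
#' @export
synth_helix <- function(n_residues, id = "helix", resno_start = 1L) {
  if (n_residues < 4L)
    stop_fmt("a helix needs at least 4 residues, got %d", n_residues)
  i <- seq_len(n_residues) - 1L
  theta <- i * 100 * pi / 180
  xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  structure_model(id, resno_start + i, rep("ALA", n_residues), xyz)
}

#' Generate a synthetic Gaussian-fluctuation trajectory
#'
#' Frame 0 is the reference; every later frame displaces each residue's Cα
#' by an independent isotropic Gaussian of per-residue standard deviation
#' `sigma` (Å per coordinate), then optionally applies a random rigid-body
#' jitter (rotation about the centroid up to `max_rot_deg`, translation
#' with each component uniform in ±`max_trans`) to the whole frame.
#' Displacements are independent across frames — the analyzed statistic
#' (RMSD vs frame 0) is distribution-level and needs no kinetics. The
#' per-residue RMSD of such a trajectory concentrates at sigma_i * sqrt(3).
#'
#' @param reference A `structure_model`.
#' @param sigma Per-residue sigma vector (Å), length = residue count; a
#'   scalar is recycled.
#' @param n_frames Number of post-initial frames.
#' @param frame_interval_ps Frame spacing (ps, default 25).
#' @param jitter `NULL` or `list(max_rot_deg =, max_trans =)`.
#' @param seed Integer seed.
#' @param label Trajectory label.
#' @return A `ca_trajectory` with `n_frames + 1` frames.
#' @export
synth_trajectory <- function(reference, sigma, n_frames,
                             frame_interval_ps = 25, jitter = NULL,
                             seed = 1L, label = reference$id) {
  nr <- length(reference$resno)
  if (length(sigma) == 1L) sigma <- rep(sigma, nr)
  if (length(sigma) != nr)
    stop_fmt("sigma has length %d but the reference has %d residues",
             length(sigma), nr)
  if (any(sigma < 0)) stop_fmt("sigma must be non-negative")
  set.seed(seed)
  arr <- array(0, dim = c(nr, 3L, n_frames + 1L))
  arr[, , 1] <- reference$xyz
  for (k in seq_len(n_frames)) {
    fr <- reference$xyz + matrix(stats::rnorm(nr * 3L, sd = sigma),
                                 nrow = nr)
    if (!is.null(jitter)) fr <- rigid_jitter(fr, jitter$max_rot_deg,
                                             jitter$max_trans)
    arr[, , k + 1L] <- fr
  }
  ca_trajectory(arr, reference$resno, reference$resid, frame_interval_ps,
                label = label)
}

# Random rigid-body perturbation: rotation by a uniform angle up to
# max_rot_deg about a uniform random axis through the centroid, then a
# translation with components uniform in +/- max_trans.
rigid_jitter <- function(xyz, max_rot_deg, max_trans) {
  axis <- stats::rnorm(3L)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1L, 0, max_rot_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * K %*% K   # Rodrigues
  ctr <- colMeans(xyz)
  tr <- stats::runif(3L, -max_trans, max_trans)
  sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr + tr, `+`)
}

#' Generate a synthetic receptor-peptide complex trajectory
#'
#' Emulates the three peptide-docking regimes. The receptor fluctuates with
#' a small per-residue Gaussian everywhere; the peptide additionally moves
#' as a rigid body according to the condition:
#' * `DOCKED` — harmonic tether: at every frame the whole peptide is offset
#'   by an independent isotropic Gaussian of sd `tether_sigma` per axis
#'   (the stationary distribution of a harmonic restraint).
#' * `DOCKED_ALA` — the same process with a weaker tether (larger sigma),
#'   modeling the loss of sequence-specific contacts.
#' * `FREE` — unbiased random walk: the rigid offset accumulates a Gaussian
#'   step of sd `step` per axis per frame.
#'
#' @param receptor,peptide `structure_model`s; peptide residue numbers are
#'   shifted to follow the receptor's and its coordinates are placed beside
#'   the receptor, so the two selections are disjoint.
#' @param condition `"DOCKED"`, `"DOCKED_ALA"` or `"FREE"`.
#' @param params List: `tether_sigma` (Å, DOCKED/DOCKED_ALA), `step` (Å,
#'   FREE), optional `receptor_sigma` (Å, default 0.2) and
#'   `peptide_sigma` (Å internal peptide noise, default 0).
#' @param n_frames Post-initial frames.
#' @param frame_interval_ps Frame spacing (ps, default 25).
#' @param seed Integer seed.
#' @return A `complex_trajectory`.
#' @export
synth_complex_trajectory <- function(receptor, peptide,
                                     condition = c("DOCKED", "DOCKED_ALA",
                                                   "FREE"),
                                     params = list(), n_frames = 60L,
                                     frame_interval_ps = 25, seed = 1L) {
  condition <- match.arg(condition)
  rec_sigma <- params$receptor_sigma %||% 0.2
  pep_sigma <- params$peptide_sigma %||% 0
  if (condition %in% c("DOCKED", "DOCKED_ALA")) {
    tether <- params$tether_sigma
    if (is.null(tether))
      stop_fmt("condition %s requires params$tether_sigma", condition)
  } else {
    step <- params$step
    if (is.null(step)) stop_fmt("condition FREE requires params$step")
  }
  nr <- length(receptor$resno); np <- length(peptide$resno)
  pep_resno <- max(receptor$resno) + seq_len(np)
  pep_xyz <- sweep(peptide$xyz, 2L,
                   c(max(receptor$xyz[, 1]) + 8, 0, 0) - peptide$xyz[1, ],
                   `+`)
  ref <- rbind(receptor$xyz, pep_xyz)
  resno <- c(receptor$resno, pep_resno)
  resid <- c(receptor$resid,
             if (condition == "DOCKED_ALA") rep("ALA", np) else
               peptide$resid)
  set.seed(seed)
  arr <- array(0, dim = c(nr + np, 3L, n_frames + 1L))
  arr[, , 1] <- ref
  offset <- c(0, 0, 0)
  for (k in seq_len(n_frames)) {
    fr <- ref + matrix(stats::rnorm((nr + np) * 3L,
                                    sd = c(rep(rec_sigma, nr),
                                           rep(pep_sigma, np))),
                       nrow = nr + np)
    offset <- switch(condition,
                     DOCKED = stats::rnorm(3L, sd = tether),
                     DOCKED_ALA = stats::rnorm(3L, sd = tether),
                     FREE = offset + stats::rnorm(3L, sd = step))
    fr[nr + seq_len(np), ] <- sweep(fr[nr + seq_len(np), , drop = FALSE],
                                    2L, offset, `+`)
    arr[, , k + 1L] <- fr
  }
  traj <- ca_trajectory(arr, resno, resid, frame_interval_ps,
                        label = sprintf("complex_%s", condition))
  complex_trajectory(traj, receptor$resno, pep_resno, condition)
}

#' Generate a synthetic variant table from an alignment
#'
#' One record per requested position: the wild-type residue is read from
#' the alignment's reference sequence and the variant is a random different
#' amino acid.
#'
#' @param msa An `aligned_set`.
#' @param positions Ungapped reference positions.
#' @param seed Integer seed.
#' @param protein,accession Labels for the generated records.
#' @return A `variant_catalog`.
#' @export
synth_variant_table <- function(msa, positions, seed = 1L,
                                protein = msa$reference_id,
                                accession = "SYN00001") {
  set.seed(seed)
  ref <- reference_row(msa)
  ref_seq <- ref[ref != "-"]
  rows <- lapply(positions, function(p) {
    col <- map_position_to_column(msa, p)   # bounds-checked
    wt <- ref_seq[p]
    var <- sample(setdiff(AA1, wt), 1L)
    data.frame(protein = protein, accession = accession, position = p,
               wt = wt, var = var, phenotype = "synthetic")
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), accession = character(),
               position = integer(), wt = character(), var = character(),
               phenotype = character())
  new_variant_catalog(df)
}
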