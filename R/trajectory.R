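#' Construct a Cα trajectory
#'
#' Time-ordered Cα frames of one structure. Frame 1 (time 0) is the initial
#' structure; frame times are `(frame index - 1) * frame_interval_ps`.
#'
#' @param xyz Numeric array of dimension n_residues x 3 x n_frames (Å).
#' @param resno Integer residue numbers shared by all frames.
#' @param resid 3-letter residue names, parallel to `resno`.
#' @param frame_interval_ps Elapsed simulated time between stored frames
#'   (picoseconds, positive).
#' @param label Trajectory label.
#' @return A `ca_trajectory`.
#' @export
ca_trajectory <- function(xyz, resno, resid, frame_interval_ps,
                          label = "trajectory") {
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L,
            dim(xyz)[1] == length(resno), length(resid) == length(resno),
            frame_interval_ps > 0)
  structure(list(xyz = unname(xyz), resno = as.integer(resno),
                 resid = as.character(resid),
                 frame_interval_ps = as.numeric(frame_interval_ps),
                 label = label),
            class = "ca_trajectory")
}

n_frames <- function(traj) dim(traj$xyz)[3]

frame_model <- function(traj, i, id = NULL) {
  structure_model(id %||% sprintf("%s_frame%d", traj$label, i - 1L),
                  traj$resno, traj$resid, traj$xyz[, , i])
}

frame_times <- function(traj) (seq_len(n_frames(traj)) - 1L) *
  traj$frame_interval_ps

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf(
    "ca_trajectory '%s': %d residues x %d frames, %g ps interval (0-%g ps)\n",
    x$label, dim(x$xyz)[1], n_frames(x), x$frame_interval_ps,
    max(frame_times(x))))
  invisible(x)
}

#' Read a multi-model PDB file as a Cα trajectory
#'
#' Trajectory dialect: MODEL/ENDMDL-delimited multi-model PDB, frame time =
#' (model index - 1) x `frame_interval_ps`. Only protein Cα atoms of the
#' chosen chain are used; all frames must share one residue list.
#'
#' @param path Multi-model PDB file.
#' @param frame_interval_ps Time between stored models (ps).
#' @param chain Chain to read (default `"A"`).
#' @param label Trajectory label (defaults to file basename).
#' @return A `ca_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_interval_ps, chain = "A",
                                label = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", chain = chain, verbose = FALSE)
  if (length(sel$atom) == 0L)
    stop_fmt("no protein C-alpha atoms on chain '%s' in %s", chain, path)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  xyz_mat <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  nf <- nrow(xyz_mat)
  if (ncol(xyz_mat) < max(sel$xyz))
    stop_fmt("frames in %s do not share one residue list", path)
  arr <- array(NA_real_, dim = c(nrow(at), 3L, nf))
  for (k in seq_len(nf))
    arr[, , k] <- matrix(xyz_mat[k, sel$xyz], ncol = 3L, byrow = TRUE)
  if (anyNA(arr)) stop_fmt("frames in %s do not share one residue list", path)
  ca_trajectory(arr, at$resno, at$resid, frame_interval_ps,
                label = label %||% sub("\\.pdb$", "", basename(path)))
}

format_ca_atom_lines <- function(model) {
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          seq_along(model$resno), model$resid,
          substr(model$chain, 1, 1), model$resno,
          model$xyz[, 1], model$xyz[, 2], model$xyz[, 3])
}

#' Write a structure model as a Cα-only PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  writeLines(c(format_ca_atom_lines(model), "END"), path)
  invisible(path)
}

#' Write a Cα trajectory as a multi-model PDB file
#'
#' Coordinates are written at the PDB's fixed 3-decimal precision; a file
#' written, re-read and re-written is byte-stable.
#'
#' @param traj A `ca_trajectory`.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, chain = "A") {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    m <- frame_model(traj, k)
    m$chain <- chain
    writeLines(c(sprintf("MODEL     %4d", k), format_ca_atom_lines(m),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Subsample trajectory frames at a coarser time interval
#'
#' Retains frames at t = 0, `interval_ps`, 2 x `interval_ps`, ... A 1000 ps
#' trajectory subsampled every 25 ps keeps 41 frames (t = 0 ... 1000).
#'
#' @param traj A `ca_trajectory`.
#' @param interval_ps Target interval; must be a positive multiple of the
#'   stored `frame_interval_ps`.
#' @return A `ca_trajectory` at the new interval.
#' @export
subsample_frames <- function(traj, interval_ps = 25) {
  if (interval_ps <= 0)
    stop_fmt("interval must be positive, got %g", interval_ps)
  step <- interval_ps / traj$frame_interval_ps
  if (abs(step - round(step)) > 1e-9)
    stop_fmt("interval %g ps is not a multiple of the stored %g ps",
             interval_ps, traj$frame_interval_ps)
  step <- as.integer(round(step))
  keep <- seq(1L, n_frames(traj), by = step)
  ca_trajectory(traj$xyz[, , keep, drop = FALSE], traj$resno, traj$resid,
                interval_ps, label = traj$label)
}
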