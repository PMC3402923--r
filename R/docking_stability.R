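#' Construct a receptor-peptide complex trajectory
#'
#' Wraps a [ca_trajectory()] of a receptor-peptide complex with the residue
#' selections of the two partners and the simulation condition: `DOCKED`
#' (peptide bound at its site), `DOCKED_ALA` (all peptide residues swapped
#' to alanine, probing sequence specificity) or `FREE` (peptide pulled away
#' from the interaction and unrestrained).
#'
#' @param traj A `ca_trajectory` covering both partners.
#' @param receptor_residues,peptide_residues Disjoint residue-number sets
#'   that jointly cover the trajectory's residue list.
#' @param condition One of `"DOCKED"`, `"DOCKED_ALA"`, `"FREE"`.
#' @return A `complex_trajectory`.
#' @export
complex_trajectory <- function(traj, receptor_residues, peptide_residues,
                               condition = c("DOCKED", "DOCKED_ALA",
                                             "FREE")) {
  condition <- match.arg(condition)
  receptor_residues <- as.integer(receptor_residues)
  peptide_residues <- as.integer(peptide_residues)
  if (length(receptor_residues) == 0L || length(peptide_residues) == 0L)
    stop_fmt("receptor and peptide selections must be non-empty")
  if (length(intersect(receptor_residues, peptide_residues)) > 0L)
    stop_fmt("receptor and peptide selections overlap")
  if (!setequal(c(receptor_residues, peptide_residues), traj$resno))
    stop_fmt("selections must jointly cover the trajectory residue list")
  structure(list(trajectory = traj,
                 receptor_residues = receptor_residues,
                 peptide_residues = peptide_residues,
                 condition = condition),
            class = "complex_trajectory")
}

#' Peptide displacement time series in the receptor frame
#'
#' Each frame is superposed onto frame 0 using receptor Cα only; the
#' peptide's movement is then measured against its initial pose, free of
#' global tumbling. The default metric is the peptide Cα RMSD vs frame 0;
#' `metric = "com"` instead reports the center-of-mass displacement of the
#' peptide Cα set.
#'
#' @param cplx A `complex_trajectory` with at least 2 frames.
#' @param metric `"rmsd"` (default) or `"com"`.
#' @return A `docking_stability_series` data.frame with columns `time_ps`
#'   and `displacement` (Å, one row per frame including t = 0), attributes
#'   `condition`, `metric`, and `summary` (mean and max over post-initial
#'   frames).
#' @export
peptide_displacement <- function(cplx, metric = c("rmsd", "com")) {
  metric <- match.arg(metric)
  traj <- cplx$trajectory
  nf <- n_frames(traj)
  if (nf < 2L) stop_fmt("need at least 2 frames, got %d", nf)
  rec <- traj$resno %in% cplx$receptor_residues
  pep <- traj$resno %in% cplx$peptide_residues
  if (sum(rec) < 3L)
    stop_fmt("receptor selection has %d residues; need >= 3 to fit",
             sum(rec))
  ref <- traj$xyz[, , 1]
  disp <- numeric(nf)
  for (k in 2:nf) {
    fr <- traj$xyz[, , k]
    fit <- kabsch_fit(fr[rec, , drop = FALSE], ref[rec, , drop = FALSE])
    fr_pep <- apply_transform(fr[pep, , drop = FALSE], fit)
    d2 <- rowSums((fr_pep - ref[pep, , drop = FALSE])^2)
    disp[k] <- if (metric == "rmsd") sqrt(mean(d2)) else
      sqrt(sum((colMeans(fr_pep) - colMeans(ref[pep, , drop = FALSE]))^2))
  }
  out <- data.frame(time_ps = frame_times(traj), displacement = disp)
  attr(out, "condition") <- cplx$condition
  attr(out, "metric") <- metric
  attr(out, "summary") <- c(mean = mean(disp[-1]), max = max(disp[-1]))
  class(out) <- c("docking_stability_series", "data.frame")
  out
}

#' Rank docking conditions by peptide stability
#'
#' Orders conditions by mean post-initial displacement (most stable first)
#' and reports all pairwise mean differences. In the stable-binding picture,
#' `DOCKED` ranks below `DOCKED_ALA` which ranks below `FREE`.
#'
#' @param series List of `docking_stability_series`, one per condition;
#'   condition labels must be unique.
#' @return Data.frame with columns `condition`, `mean_displacement`,
#'   `max_displacement`, `rank`; pairwise differences in attribute
#'   `"pairwise"`.
#' @export
compare_conditions <- function(series) {
  stopifnot(length(series) >= 2L)
  conds <- vapply(series, attr, "", "condition")
  if (anyDuplicated(conds))
    stop_fmt("duplicate condition labels: %s",
             paste(conds[duplicated(conds)], collapse = ", "))
  smry <- t(vapply(series, attr, c(mean = 0, max = 0), "summary"))
  out <- data.frame(condition = conds,
                    mean_displacement = smry[, "mean"],
                    max_displacement = smry[, "max"])
  out <- out[order(out$mean_displacement), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  pairs <- utils::combn(seq_along(conds), 2L)
  pw <- data.frame(a = conds[pairs[1, ]], b = conds[pairs[2, ]],
                   mean_diff = smry[pairs[2, ], "mean"] -
                     smry[pairs[1, ], "mean"])
  attr(out, "pairwise") <- pw
  out
}
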