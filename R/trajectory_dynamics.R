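#' Per-residue Cα RMSD profile of a trajectory
#'
#' For every residue i, computes the root-mean-square displacement of its Cα
#' from the initial structure over the post-initial frames:
#' RMSD_i = sqrt( (1/T) * sum_t ||x_i(t) - x_i(0)||^2 ), t = 1..T. With
#' `fit = "ca"` (default) each frame is first rigidly superposed onto frame
#' 0 over all Cα via [kabsch_fit()], removing global tumbling and drift;
#' `fit = "none"` uses raw coordinates (useful against closed-form
#' expectations). Frame 0 is excluded from the average — it contributes
#' identically zero and would deflate all values. The reference is the
#' initial structure, not the time average, so this is an
#' initial-structure RMSD profile, not an RMSF.
#'
#' @param traj A `ca_trajectory` with at least 2 frames.
#' @param fit `"ca"` or `"none"`.
#' @return A `dynamics_profile` data.frame with columns `resno` and
#'   `mean_rmsd` (Å), and attributes `n_frames_used` (T) and `fit_scope`.
#' @export
per_residue_rmsd <- function(traj, fit = c("ca", "none")) {
  fit <- match.arg(fit)
  nf <- n_frames(traj)
  if (nf < 2L) stop_fmt("need at least 2 frames, got %d", nf)
  ref <- traj$xyz[, , 1]
  ssq <- numeric(length(traj$resno))
  for (k in 2:nf) {
    fr <- traj$xyz[, , k]
    if (fit == "ca") fr <- kabsch_fit(fr, ref)$coords
    ssq <- ssq + rowSums((fr - ref)^2)
  }
  out <- data.frame(resno = traj$resno, mean_rmsd = sqrt(ssq / (nf - 1L)))
  attr(out, "n_frames_used") <- nf - 1L
  attr(out, "fit_scope") <- fit
  class(out) <- c("dynamics_profile", "data.frame")
  out
}

#' Compare two per-residue dynamics profiles
#'
#' Typically wild-type (`a`) vs variant (`b`); a positive `delta` means the
#' residue moves more in `b`.
#'
#' @param a,b `dynamics_profile`s over identical residue numbering.
#' @param report_threshold |delta| (Å) above which a residue is flagged in
#'   the `"flagged"` attribute.
#' @return Data.frame with columns `resno`, `rmsd_a`, `rmsd_b`, `delta`.
#' @export
compare_dynamics <- function(a, b, report_threshold = 0.5) {
  if (nrow(a) != nrow(b) || !identical(a$resno, b$resno))
    stop_fmt("profiles do not share residue numbering")
  out <- data.frame(resno = a$resno, rmsd_a = a$mean_rmsd,
                    rmsd_b = b$mean_rmsd,
                    delta = b$mean_rmsd - a$mean_rmsd)
  attr(out, "flagged") <- out$resno[abs(out$delta) > report_threshold]
  out
}

#' Annotate a dynamics profile with conservation tiers
#'
#' Merges per-residue mean RMSD with the tier assignments of a
#' [conservation_report()], treating the residue number as the box-relative
#' position. Residues absent from the report are tiered `NO_VARIANT`.
#'
#' @param profile A `dynamics_profile`.
#' @param tiers A `conservation_report` (or any data.frame with `position`
#'   and `tier` columns); may be empty.
#' @return Data.frame with columns `resno`, `mean_rmsd`, `tier`, plus a
#'   `"tier_summary"` attribute giving the mean RMSD per tier.
#' @export
annotate_dynamics <- function(profile, tiers = NULL) {
  tier <- rep("NO_VARIANT", nrow(profile))
  if (!is.null(tiers) && nrow(tiers) > 0L) {
    m <- match(profile$resno, tiers$position)
    tier[!is.na(m)] <- tiers$tier[m[!is.na(m)]]
  }
  out <- data.frame(resno = profile$resno, mean_rmsd = profile$mean_rmsd,
                    tier = tier)
  smry <- stats::aggregate(mean_rmsd ~ tier, data = out, FUN = mean)
  attr(out, "tier_summary") <- smry[order(smry$mean_rmsd), ]
  out
}
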