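#' Construct a structure model
#'
#' An ordered Cα-only representation of one cleaned HMG domain: residue
#' numbers (strictly increasing), 3-letter residue names and Cα coordinates
#' in ångströms.
#'
#' @param id Model identifier.
#' @param resno Integer residue numbers, strictly increasing.
#' @param resid 3-letter residue names, parallel to `resno`.
#' @param xyz Numeric n x 3 matrix of Cα coordinates (Å).
#' @param chain Chain identifier (informational).
#' @return A `structure_model`.
#' @export
structure_model <- function(id, resno, resid, xyz, chain = "A") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(resno),
            length(resid) == length(resno))
  if (any(diff(resno) <= 0L))
    stop_fmt("residue numbers of '%s' are not strictly increasing", id)
  structure(list(id = id, chain = chain, resno = as.integer(resno),
                 resid = as.character(resid), xyz = unname(xyz)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d residues, chain %s (%d-%d)\n",
              x$id, length(x$resno), x$chain, min(x$resno), max(x$resno)))
  invisible(x)
}

#' Clean a PDB structure down to one bare HMG domain
#'
#' Retains only the Cα atoms of standard amino-acid residues of one chain of
#' one model: waters, ions, nucleic-acid chains and other heteroatoms are
#' dropped. For multi-model (NMR) files the first reported ensemble member
#' is used unless `model_index` overrides it.
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object read with
#'   `multi = TRUE`.
#' @param chain Chain identifier to keep.
#' @param model_index 1-based model number (default 1).
#' @param id Identifier for the resulting model (defaults to file basename).
#' @return A `structure_model`.
#' @export
clean_structure <- function(pdb, chain = "A", model_index = 1L, id = NULL) {
  if (is.character(pdb)) {
    id <- id %||% sub("\\.pdb$", "", basename(pdb))
    pdb <- bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE)
  }
  id <- id %||% "structure"
  if (!chain %in% unique(pdb$atom$chain))
    stop_fmt("chain '%s' not present (chains: %s)", chain,
             paste(unique(pdb$atom$chain), collapse = ", "))
  sel <- bio3d::atom.select(pdb, "calpha", chain = chain, verbose = FALSE)
  if (length(sel$atom) == 0L)
    stop_fmt("no protein C-alpha atoms on chain '%s'", chain)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  # drop alternate locations beyond the first
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (anyDuplicated(at$resno))
    stop_fmt("residue %d has multiple C-alpha records",
             at$resno[duplicated(at$resno)][1])
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models)
    stop_fmt("model %d requested but file has %d model(s)",
             model_index, n_models)
  xyz_row <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else
    as.numeric(pdb$xyz)
  idx <- sel$xyz[rep(keep, each = 3L)]
  xyz <- matrix(xyz_row[idx], ncol = 3L, byrow = TRUE)
  if (anyNA(xyz))
    stop_fmt("missing C-alpha coordinates in model %d", model_index)
  structure_model(id, at$resno, at$resid, xyz, chain = chain)
}

#' Least-squares rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired 3D points; reflections are rejected, so mirror-image sets retain a
#' positive residual. Requires at least three non-collinear pairs.
#'
#' @param mobile,target Numeric n x 3 matrices of paired coordinates (Å).
#' @return A `superposition` list: `rotation` (3 x 3, det +1), `translation`
#'   (length-3), `rmsd` (Å), `n_pairs`, `per_residue_deviation` (Å, one per
#'   pair), and `coords`, the transformed mobile set. The fitted coordinates
#'   are `mobile %*% rotation + translation` (rows as points).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop_fmt("mobile and target must be equal-sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop_fmt("need at least 3 point pairs, got %d", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm); Q <- sweep(target, 2L, ct)
  # degenerate (collinear or coincident) geometry leaves the rotation
  # under-determined
  for (M in list(P, Q)) {
    sv <- svd(M, nu = 0L, nv = 0L)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12))
      stop_fmt("degenerate geometry: point set is collinear or coincident")
  }
  H <- crossprod(P, Q)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # proper rotation only
  fitted <- P %*% R
  dev <- sqrt(rowSums((fitted - Q)^2))
  translation <- as.numeric(ct - cm %*% R)
  structure(list(rotation = R, translation = translation,
                 rmsd = sqrt(mean(dev^2)), n_pairs = n,
                 per_residue_deviation = dev,
                 coords = sweep(fitted, 2L, ct, `+`)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd %.3f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

# Apply a fitted rigid transform to arbitrary coordinates.
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2L, fit$translation, `+`)
}

#' Superpose a structure ensemble onto a reference
#'
#' Cα pairing is alignment-guided: for each structure, its row and the
#' reference's row in `correspondence` are compared and Cα pairs are taken
#' at columns where both are non-gapped; [kabsch_fit()] then yields the
#' optimal rigid transform. Residue pairing never uses raw PDB residue
#' numbers, which are inconsistent across entries.
#'
#' @param structures List of `structure_model`s; each `id` must name a row
#'   of the alignment and its sequence must match that row after gap
#'   removal.
#' @param reference A `structure_model` for the reference (e.g. the SRY box
#'   bound to DNA); its `id` must also be in the alignment.
#' @param correspondence An `aligned_set` providing the residue
#'   correspondence.
#' @return Named list of `superposition` results (one per structure), each
#'   with transformed coordinates in `$coords` and the paired reference
#'   residue numbers in `$ref_resno`.
#' @export
superpose_ensemble <- function(structures, reference, correspondence) {
  ref_row <- aligned_row(correspondence, reference$id, reference)
  out <- lapply(structures, function(st) {
    row <- aligned_row(correspondence, st$id, st)
    both <- which(row != "-" & ref_row != "-")
    if (length(both) < 3L)
      stop_fmt("fewer than 3 shared columns between '%s' and reference",
               st$id)
    mob_idx <- match(both, which(row != "-"))
    ref_idx <- match(both, which(ref_row != "-"))
    fit <- kabsch_fit(st$xyz[mob_idx, , drop = FALSE],
                      reference$xyz[ref_idx, , drop = FALSE])
    fit$id <- st$id
    fit$ref_resno <- reference$resno[ref_idx]
    fit$resno <- st$resno[mob_idx]
    fit
  })
  names(out) <- vapply(structures, `[[`, "", "id")
  out
}

# Fetch a structure's alignment row and verify it matches the structure's
# own sequence once gaps are removed.
aligned_row <- function(correspondence, id, model) {
  if (!id %in% correspondence$ids)
    stop_fmt("structure '%s' has no row in the correspondence alignment", id)
  row <- correspondence$seqs[id, ]
  seq_aln <- row[row != "-"]
  seq_str <- strsplit(model_seq1(model), "")[[1]]
  if (length(seq_aln) != length(seq_str) || any(seq_aln != seq_str))
    stop_fmt("sequence of structure '%s' does not match its alignment row",
             id)
  row
}

#' Trim an NMR ensemble to its region of high agreement
#'
#' Given all members of a multi-model structure, drops residues whose Cα
#' spread across members exceeds a threshold, returning the trimmed first
#' member. Spread is the RMS deviation of each residue's Cα from its
#' across-member mean after superposing every member onto the first.
#'
#' @param models List of `structure_model`s sharing one residue list (the
#'   members of one NMR ensemble).
#' @param spread_threshold Maximum allowed Cα spread (Å, default 2.0).
#' @return The first model restricted to residues within the threshold.
#' @export
trim_ensemble <- function(models, spread_threshold = 2.0) {
  stopifnot(length(models) >= 1L)
  ref <- models[[1]]
  if (length(models) == 1L) return(ref)
  coords <- lapply(models, function(m) {
    if (!identical(m$resno, ref$resno))
      stop_fmt("ensemble members disagree on residue numbering")
    kabsch_fit(m$xyz, ref$xyz)$coords
  })
  arr <- simplify2array(coords)                      # n x 3 x n_models
  mu <- apply(arr, c(1, 2), mean)
  spread <- sqrt(apply((arr - c(mu))^2, 1L, mean) * 3)  # RMS over 3D dev
  keep <- spread <= spread_threshold
  if (!any(keep)) stop_fmt("no residue satisfies the spread threshold")
  structure_model(ref$id, ref$resno[keep], ref$resid[keep],
                  ref$xyz[keep, , drop = FALSE], chain = ref$chain)
}
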