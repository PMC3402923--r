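#' Construct an aligned sequence set
#'
#' A light container for a gapped multiple sequence alignment with a named
#' reference sequence, used for position-to-column mapping and conservation
#' scoring. All gapped sequences must have equal length and the reference id
#' must be present.
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of gapped sequences (gap character `-`),
#'   parallel to `ids`.
#' @param name Set label, e.g. `"HMG-human"` or `"SOX-human"`.
#' @param reference_id Id of the reference sequence (defaults to the first).
#' @return An `aligned_set` list with fields `name`, `ids`, `seqs` (a
#'   character matrix, one row per sequence) and `reference_id`.
#' @export
aligned_set <- function(ids, seqs, name = "alignment",
                        reference_id = ids[1]) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  if (anyDuplicated(ids)) stop_fmt("duplicate sequence ids in '%s'", name)
  chars <- strsplit(toupper(seqs), "")
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop_fmt("gapped lengths differ in '%s' (%s)", name,
             paste(range(lens), collapse = "-"))
  if (!reference_id %in% ids)
    stop_fmt("reference id '%s' not among sequence ids", reference_id)
  m <- do.call(rbind, chars)
  rownames(m) <- ids
  structure(list(name = name, ids = ids, seqs = m,
                 reference_id = reference_id),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set '%s': %d sequences x %d columns (reference: %s)\n",
              x$name, nrow(x$seqs), ncol(x$seqs), x$reference_id))
  invisible(x)
}

#' Read an aligned FASTA file into an aligned_set
#'
#' @param path Aligned FASTA file (gaps `-`).
#' @inheritParams aligned_set
#' @param max_length Sanity bound on the ungapped reference length. HMG
#'   boxes are ~79 residues; proteins carrying several boxes must be
#'   pre-split into one sequence per domain, and a reference much longer
#'   than one box is the usual symptom that they were not.
#' @return An `aligned_set`.
#' @export
read_aligned_fasta <- function(path, name = basename(path),
                               reference_id = NULL, max_length = 90L) {
  fa <- bio3d::read.fasta(path)
  ids <- fa$id
  seqs <- apply(fa$ali, 1L, paste, collapse = "")
  set <- aligned_set(ids, seqs, name = name,
                     reference_id = reference_id %||% ids[1])
  n_ref <- sum(set$seqs[set$reference_id, ] != "-")
  if (n_ref > max_length)
    stop_fmt(paste0("reference '%s' has %d residues (> %d): multi-domain ",
                    "proteins must be split into one sequence per HMG box"),
             set$reference_id, n_ref, max_length)
  set
}

#' Write an aligned_set as FASTA
#'
#' @param aligned An `aligned_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aligned, path) {
  bio3d::write.fasta(ids = aligned$ids, seqs = aligned$seqs, file = path)
  invisible(path)
}

reference_row <- function(aligned) aligned$seqs[aligned$reference_id, ]

#' Map an ungapped reference position to an alignment column
#'
#' Returns the gapped column index holding the `position`-th non-gap
#' character of the reference sequence. Strictly increasing in `position`.
#'
#' @param aligned An `aligned_set`.
#' @param position 1-based position on the ungapped reference.
#' @return Integer column index.
#' @export
map_position_to_column <- function(aligned, position) {
  ref <- reference_row(aligned)
  nongap <- which(ref != "-")
  if (position < 1L || position > length(nongap))
    stop_fmt("position %d out of range: reference '%s' has %d residues",
             position, aligned$reference_id, length(nongap))
  nongap[position]
}

#' Default physicochemical residue classes
#'
#' Overlapping classes used for class-mode conservation: hydrophobic,
#' aromatic, polar-basic and polar-acidic. Overlaps are allowed (His is both
#' aromatic and basic); the best-scoring class is reported.
#'
#' @return Named list of character vectors of one-letter codes.
#' @export
residue_classes <- function() {
  list(hydrophobic    = c("A", "V", "L", "I", "M", "F", "W", "Y", "C"),
       aromatic       = c("F", "W", "Y", "H"),
       `polar-basic`  = c("K", "R", "H"),
       `polar-acidic` = c("D", "E"))
}

#' Profile one alignment column
#'
#' Tallies residues and gaps in a column and computes the identity frequency
#' (modal residue count over the non-gap count; 0 when the column is all
#' gaps) and the frequency of each physicochemical class over the non-gap
#' count.
#'
#' @param aligned An `aligned_set`.
#' @param column Gapped column index.
#' @param class_map Named list of residue classes (default
#'   [residue_classes()]).
#' @return An `alignment_column_profile` list: `column`, `residue_counts`,
#'   `gap_count`, `identity_freq`, `modal_residue` (ties broken by
#'   alphabetical order), `class_freqs`.
#' @export
column_profile <- function(aligned, column, class_map = residue_classes()) {
  if (column < 1L || column > ncol(aligned$seqs))
    stop_fmt("column %d outside gapped length %d", column, ncol(aligned$seqs))
  col <- aligned$seqs[, column]
  gap_count <- sum(col == "-")
  res <- col[col != "-"]
  counts <- table(factor(res, levels = sort(unique(res))))
  n_nongap <- length(res)
  if (n_nongap == 0L) {
    identity_freq <- 0
    modal <- NA_character_
  } else {
    identity_freq <- max(counts) / n_nongap
    modal <- names(counts)[which.max(counts)]  # alphabetical tie-break
  }
  class_freqs <- vapply(class_map, function(cl) {
    if (n_nongap == 0L) 0 else sum(res %in% cl) / n_nongap
  }, numeric(1))
  structure(list(column = column,
                 residue_counts = stats::setNames(as.integer(counts),
                                                 names(counts)),
                 gap_count = gap_count,
                 identity_freq = identity_freq,
                 modal_residue = modal,
                 class_freqs = class_freqs),
            class = "alignment_column_profile")
}

# Conservation score of a column under a mode. Class mode scores
# max(identity, best class frequency): a column perfectly conserved as a
# residue outside every named class (e.g. Gly) is still conserved.
conservation_score <- function(profile, mode = c("class", "identity")) {
  mode <- match.arg(mode)
  if (mode == "identity") profile$identity_freq
  else max(profile$identity_freq, profile$class_freqs)
}

# A column dominated by gaps carries no evidence of family conservation.
GAP_MAJORITY <- 0.5

column_conserved <- function(aligned, column, threshold, mode,
                             class_map = residue_classes()) {
  prof <- column_profile(aligned, column, class_map)
  n <- nrow(aligned$seqs)
  if (prof$gap_count > GAP_MAJORITY * n) return(FALSE)
  conservation_score(prof, mode) >= threshold
}

#' Classify the conservation tier of one HMG-box position
#'
#' Maps a box-relative position into the family (HMG) and subfamily (Sox)
#' alignments through each set's reference sequence and assigns a tier:
#' `HMG_CONSERVED` if the column's conservation is at or above `threshold`
#' in the HMG set; otherwise `SOX_CONSERVED` if at or above `threshold` in
#' the Sox set; otherwise `NOT_CONSERVED`. Columns with a gap majority are
#' never called conserved. Positions with no variant record are tiered
#' `NO_VARIANT` by [conservation_report()], not here.
#'
#' @param position 1-based box position on the reference sequences.
#' @param hmg,sox `aligned_set`s for the HMG family and Sox subfamily.
#' @param threshold Conservation threshold (default 0.90, i.e. "90% or
#'   greater").
#' @param mode `"class"` (default): a column counts as conserved when its
#'   identity frequency or its best physicochemical-class frequency reaches
#'   the threshold. `"identity"`: identity frequency only.
#' @param class_map Residue classes for class mode.
#' @return One of `"HMG_CONSERVED"`, `"SOX_CONSERVED"`, `"NOT_CONSERVED"`.
#' @export
classify_position <- function(position, hmg, sox, threshold = 0.90,
                              mode = c("class", "identity"),
                              class_map = residue_classes()) {
  mode <- match.arg(mode)
  col_h <- map_position_to_column(hmg, position)
  col_s <- map_position_to_column(sox, position)
  if (column_conserved(hmg, col_h, threshold, mode, class_map))
    "HMG_CONSERVED"
  else if (column_conserved(sox, col_s, threshold, mode, class_map))
    "SOX_CONSERVED"
  else "NOT_CONSERVED"
}

#' Conservation report over the variant catalog
#'
#' One row per distinct variant position, with its tier and the identity and
#' best-class frequencies in both alignments. The tier partition counts
#' (which always satisfy n_HMG + n_SOX + n_NOT = number of distinct
#' positions) are attached as attribute `"partition"` and printed as a
#' footer.
#'
#' @param catalog A `variant_catalog`.
#' @inheritParams classify_position
#' @return A `conservation_report` data.frame with columns `position`,
#'   `tier`, `identity_freq_hmg`, `identity_freq_sox`, `best_class_freq_hmg`,
#'   `best_class_freq_sox`.
#' @export
conservation_report <- function(catalog, hmg, sox, threshold = 0.90,
                                mode = c("class", "identity"),
                                class_map = residue_classes()) {
  mode <- match.arg(mode)
  positions <- sort(unique(catalog$position))
  rows <- lapply(positions, function(p) {
    ph <- column_profile(hmg, map_position_to_column(hmg, p), class_map)
    ps <- column_profile(sox, map_position_to_column(sox, p), class_map)
    data.frame(position = p,
               tier = classify_position(p, hmg, sox, threshold, mode,
                                        class_map),
               identity_freq_hmg = ph$identity_freq,
               identity_freq_sox = ps$identity_freq,
               best_class_freq_hmg = if (length(ph$class_freqs))
                 max(ph$class_freqs) else 0,
               best_class_freq_sox = if (length(ps$class_freqs))
                 max(ps$class_freqs) else 0)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), tier = character(),
               identity_freq_hmg = numeric(), identity_freq_sox = numeric(),
               best_class_freq_hmg = numeric(),
               best_class_freq_sox = numeric())
  part <- c(n_hmg = sum(out$tier == "HMG_CONSERVED"),
            n_sox = sum(out$tier == "SOX_CONSERVED"),
            n_not = sum(out$tier == "NOT_CONSERVED"),
            n_positions = nrow(out))
  attr(out, "partition") <- part
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  class(out) <- c("conservation_report", "data.frame")
  out
}

#' @export
print.conservation_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  p <- attr(x, "partition")
  cat(sprintf(
    "# tiers: %d HMG-conserved / %d Sox-conserved / %d not conserved (of %d positions; threshold %.2f, %s mode)\n",
    p["n_hmg"], p["n_sox"], p["n_not"], p["n_positions"],
    attr(x, "threshold"), attr(x, "mode")))
  invisible(x)
}
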