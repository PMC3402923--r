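#' Load a disease-variant catalog
#'
#' Reads a delimited table of disease-associated amino-acid substitutions in
#' HMG-box proteins. Each row is one single-position event at an HMG-box
#' position numbered 1-based from the first residue of the protein's own box;
#' cross-protein comparison happens only after alignment-column mapping (see
#' [classify_position()]). The delimiter (comma or tab) is auto-detected from
#' the header line.
#'
#' @param path Path to a TSV/CSV file whose header names the six fields
#'   `protein, accession, position, wt, var, phenotype`.
#' @param reference Optional one-letter reference sequence (a single string,
#'   e.g. the ungapped HMG box of SRY). When supplied, each record's
#'   wild-type residue is checked against `reference` at its position.
#' @return A `variant_catalog`: a data.frame with columns `protein`,
#'   `accession`, `position` (integer), `wt`, `var`, `phenotype`.
#'   Deletion events carry `var == "-"`.
#' @details Malformed rows (bad position, unknown residue code, wild-type
#'   equal to variant) raise an error naming the offending data row; a
#'   wild-type residue that contradicts `reference` raises an error naming
#'   the position.
#' @seealso [summarize_catalog()], [write_variants()]
#' @export
load_variants <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_fmt("variant catalog not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           quote = "\"", comment.char = "")
  need <- c("protein", "accession", "position", "wt", "var", "phenotype")
  if (!all(need %in% names(tab)))
    stop_fmt("catalog header must name fields: %s (got: %s)",
             paste(need, collapse = ", "), paste(names(tab), collapse = ", "))
  tab <- tab[, need, drop = FALSE]
  if (nrow(tab) == 0L) return(new_variant_catalog(tab))

  pos <- suppressWarnings(as.integer(tab$position))
  for (i in seq_len(nrow(tab))) {
    if (is.na(pos[i]) || pos[i] < 1L)
      stop_fmt("row %d: position '%s' is not a positive integer",
               i, tab$position[i])
    if (!is_aa1(tab$wt[i]))
      stop_fmt("row %d: wild-type residue '%s' is not a one-letter amino acid",
               i, tab$wt[i])
    if (!(is_aa1(tab$var[i]) || tab$var[i] == "-"))
      stop_fmt("row %d: variant residue '%s' is not a one-letter amino acid or '-'",
               i, tab$var[i])
    if (tab$wt[i] == tab$var[i])
      stop_fmt("row %d: wild-type and variant residue are both '%s'",
               i, tab$wt[i])
  }
  tab$position <- pos

  if (!is.null(reference)) {
    ref <- strsplit(gsub("-", "", reference, fixed = TRUE), "")[[1]]
    for (i in seq_len(nrow(tab))) {
      p <- tab$position[i]
      if (p > length(ref))
        stop_fmt("position %d exceeds reference length %d", p, length(ref))
      if (ref[p] != tab$wt[i])
        stop_fmt(paste0("wild-type mismatch at position %d: catalog says '%s'",
                        " but reference has '%s'"), p, tab$wt[i], ref[p])
    }
  }
  new_variant_catalog(tab)
}

new_variant_catalog <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("variant_catalog", "data.frame")
  df
}

#' Write a variant catalog as canonical TSV
#'
#' @param records A `variant_catalog` (see [load_variants()]).
#' @param path Output path.
#' @return `path`, invisibly. `load_variants(write_variants(x))` round-trips
#'   the records exactly.
#' @export
write_variants <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize a variant catalog
#'
#' Counts variants, distinct variant positions and distinct proteins. By
#' default distinct positions are pooled across proteins on the shared
#' box-relative numbering (so a variant at position 16 of SOX9 and one at
#' position 16 of SRY count one position); `per_protein = TRUE` instead
#' counts distinct (protein, position) pairs.
#'
#' @param records A `variant_catalog`.
#' @param per_protein Count positions per protein rather than pooled.
#' @return A `catalog_summary` list with `n_variants`, `n_positions`,
#'   `n_proteins`.
#' @export
summarize_catalog <- function(records, per_protein = FALSE) {
  pos_key <- if (per_protein && nrow(records) > 0L)
    paste(records$protein, records$position) else records$position
  out <- list(n_variants  = nrow(records),
              n_positions = length(unique(pos_key)),
              n_proteins  = length(unique(records$protein)))
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("%d variants at %d distinct positions in %d proteins\n",
              x$n_variants, x$n_positions, x$n_proteins))
  invisible(x)
}
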