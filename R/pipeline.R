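#' Run the integrative residue-function pipeline
#'
#' Orchestrates catalog loading, conservation classification, ensemble
#' superposition, per-residue dynamics and docking-stability comparison
#' into one reproducible run. Stages whose inputs are absent from the
#' config are skipped with a logged notice; a failing stage aborts the run
#' naming the stage, with outputs written so far retained next to a
#' `FAILED` marker file. All outputs are flat TSV plus a plain-text
#' manifest; a rerun with identical config and seed reproduces every file
#' byte for byte.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   `out_dir` (required); `catalog` (variant TSV/CSV);
#'   `hmg_alignment`, `sox_alignment` (aligned FASTA) with optional
#'   `hmg_reference`, `sox_reference` ids; `structures` (vector of PDB
#'   paths), `correspondence` (aligned FASTA), `structure_reference`
#'   (id of the reference structure among `structures`); `trajectory`
#'   (multi-model PDB) with `trajectory_interval_ps` (stored spacing);
#'   `complexes` (list of entries `path`, `condition`, `receptor`,
#'   `peptide`, the last two as residue ranges like `"1-60"`, plus
#'   `interval_ps`); analysis settings `threshold` (default 0.90), `mode`
#'   (`"class"`/`"identity"`), `interval_ps` (subsampling, default 25),
#'   `fit` (`"ca"`/`"none"`), `seed`.
#' @return Invisibly, a list with the stage results (`summary`, `report`,
#'   `superposition`, `profile`, `annotated`, `docking`) and the output
#'   paths (`files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir)) stop_fmt("config must name out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  threshold <- cfg$threshold %||% 0.90
  mode <- cfg$mode %||% "class"
  interval <- cfg$interval_ps %||% 25
  fit <- cfg$fit %||% "ca"
  for (p in c(cfg$catalog, cfg$hmg_alignment, cfg$sox_alignment,
              cfg[["trajectory"]], cfg$correspondence, unlist(cfg$structures),
              vapply(cfg$complexes, `[[`, "", "path")))
    if (!file.exists(p)) stop_fmt("config path does not exist: %s", p)

  res <- list(files = character())
  stage <- "setup"
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$files <<- c(res$files, path)
    path
  }
  run_stage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    v
  }
  on_fail <- function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }

  tryCatch({
    catalog <- NULL
    if (!is.null(cfg$catalog)) {
      catalog <- run_stage("variants", {
        cat <- load_variants(cfg$catalog)
        emit(cat, "variants.tsv")
        emit(as.data.frame(unclass(summarize_catalog(cat))),
             "catalog_summary.tsv")
        cat
      })
      res$summary <- summarize_catalog(catalog)
    } else message("[variants] skipped: no catalog in config")

    report <- NULL
    if (!is.null(catalog) && !is.null(cfg$hmg_alignment) &&
        !is.null(cfg$sox_alignment)) {
      report <- run_stage("conservation", {
        hmg <- read_aligned_fasta(cfg$hmg_alignment, name = "HMG",
                                  reference_id = cfg$hmg_reference)
        sox <- read_aligned_fasta(cfg$sox_alignment, name = "SOX",
                                  reference_id = cfg$sox_reference)
        rep <- conservation_report(catalog, hmg, sox, threshold, mode)
        emit(rep, "conservation.tsv")
        rep
      })
      res$report <- report
    } else message("[conservation] skipped: needs catalog + both alignments")

    if (!is.null(cfg$structures) && !is.null(cfg$correspondence)) {
      res$superposition <- run_stage("superposition", {
        corr <- read_aligned_fasta(cfg$correspondence,
                                   name = "correspondence")
        models <- lapply(cfg$structures, clean_structure,
                         chain = cfg$chain %||% "A")
        ids <- vapply(models, `[[`, "", "id")
        ref_id <- cfg$structure_reference %||% ids[1]
        ref <- models[[match(ref_id, ids)]]
        fits <- superpose_ensemble(models[ids != ref_id], ref, corr)
        smry <- data.frame(id = names(fits),
                           rmsd = vapply(fits, `[[`, 0, "rmsd"),
                           n_pairs = vapply(fits, `[[`, 0L, "n_pairs"))
        emit(smry, "superposition.tsv")
        dev <- do.call(rbind, lapply(fits, function(f)
          data.frame(id = f$id, ref_resno = f$ref_resno,
                     deviation = f$per_residue_deviation)))
        emit(dev, "superposition_residues.tsv")
        fits
      })
    } else message("[superposition] skipped: needs structures + correspondence")

    annotated <- NULL
    if (!is.null(cfg[["trajectory"]])) {
      annotated <- run_stage("dynamics", {
        traj <- read_trajectory_pdb(cfg[["trajectory"]],
                                    cfg[["trajectory_interval_ps"]] %||% interval,
                                    chain = cfg$chain %||% "A")
        traj <- subsample_frames(traj, interval)
        prof <- per_residue_rmsd(traj, fit = fit)
        res$profile <- prof
        ann <- annotate_dynamics(prof, report)
        emit(ann, "dynamics.tsv")
        emit(attr(ann, "tier_summary"), "dynamics_tier_summary.tsv")
        ann
      })
      res$annotated <- annotated
    } else message("[dynamics] skipped: no trajectory in config")

    if (!is.null(cfg$complexes)) {
      res$docking <- run_stage("docking", {
        series <- lapply(cfg$complexes, function(cx) {
          traj <- read_trajectory_pdb(cx$path,
                                      cx$interval_ps %||% interval,
                                      chain = cfg$chain %||% "A")
          cplx <- complex_trajectory(traj, parse_range(cx$receptor),
                                     parse_range(cx$peptide), cx$condition)
          s <- peptide_displacement(cplx)
          emit(s, sprintf("docking_%s.tsv", cx$condition))
          s
        })
        cmp <- compare_conditions(series)
        emit(cmp, "docking_comparison.tsv")
        cmp
      })
    } else message("[docking] skipped: no complexes in config")

    stage <- "report"
    if (!is.null(report)) {
      merged <- merge_annotation(catalog, report, annotated)
      emit(merged, "residue_annotation.tsv")
      res$merged <- merged
    }
    writeLines(run_summary_lines(res, threshold, mode),
               file.path(cfg$out_dir, "summary.txt"))
    writeLines(manifest_lines(cfg, res),
               file.path(cfg$out_dir, "manifest.txt"))
    res$files <- c(res$files, file.path(cfg$out_dir,
                                        c("summary.txt", "manifest.txt")))
  }, error = on_fail)
  invisible(res)
}

parse_range <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- as.integer(strsplit(as.character(x), "-", fixed = TRUE)[[1]])
  if (length(parts) != 2L || anyNA(parts))
    stop_fmt("cannot parse residue range '%s' (expected 'a-b')", x)
  seq.int(parts[1], parts[2])
}

# Merged per-position record: variant status, tier, frequencies, dynamics.
merge_annotation <- function(catalog, report, annotated) {
  n_pos <- max(c(report$position,
                 if (!is.null(annotated)) annotated$resno else 0L))
  out <- data.frame(position = seq_len(n_pos))
  out$has_NV <- out$position %in% catalog$position
  m <- match(out$position, report$position)
  out$tier <- ifelse(is.na(m), "NO_VARIANT", report$tier[m])
  out$identity_freq_hmg <- report$identity_freq_hmg[m]
  out$identity_freq_sox <- report$identity_freq_sox[m]
  if (!is.null(annotated)) {
    d <- match(out$position, annotated$resno)
    out$mean_rmsd <- annotated$mean_rmsd[d]
  }
  wt <- catalog$wt[match(out$position, catalog$position)]
  out$wt_residue <- ifelse(is.na(wt), "", wt)
  out
}

run_summary_lines <- function(res, threshold, mode) {
  lines <- "HMG residue-function pipeline summary"
  if (!is.null(res$summary))
    lines <- c(lines, sprintf(
      "variants: %d at %d distinct positions in %d proteins",
      res$summary$n_variants, res$summary$n_positions,
      res$summary$n_proteins))
  if (!is.null(res$report)) {
    p <- attr(res$report, "partition")
    lines <- c(lines, sprintf(
      "conservation (threshold %.2f, %s mode): %d HMG / %d Sox / %d not conserved of %d positions",
      threshold, mode, p["n_hmg"], p["n_sox"], p["n_not"],
      p["n_positions"]))
  }
  if (!is.null(res$annotated)) {
    s <- attr(res$annotated, "tier_summary")
    lines <- c(lines, "mean C-alpha RMSD by tier:",
               sprintf("  %-14s %.3f A", s$tier, s$mean_rmsd))
  }
  if (!is.null(res$docking))
    lines <- c(lines, "docking conditions by mean displacement:",
               sprintf("  %-10s %.3f A", res$docking$condition,
                       res$docking$mean_displacement))
  lines
}

manifest_lines <- function(cfg, res) {
  c("hmgfunc run manifest",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("hmgfunc"))),
    sprintf("seed: %s", cfg$seed %||% "none"),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(cfg), "\n")[[1]]),
    "outputs:",
    paste0("  ", basename(res$files)))
}
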