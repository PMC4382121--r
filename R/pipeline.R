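#' Pipeline configuration
#'
#' Bundles the tunable knobs of the processing chain. Round-trips through
#' YAML unchanged via [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param bandwidth Smoothing bandwidth in minutes, or `"auto"`.
#' @param min_prominence Peak prominence threshold as a fraction of the
#'   maximum smoothed intensity (default 0.0005).
#' @param position_tolerance Cross-sample grouping tolerance in minutes
#'   (default 0.1).
#' @param min_fraction Presence filter threshold (default 0.5).
#' @param subset `"all"` or `"neutral"` for the statistics stage.
#' @param gu_start Integer GU of the first ladder peak (default 4).
#' @param seed Seed for any stochastic step (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bandwidth = "auto", min_prominence = 0.0005,
                            position_tolerance = 0.1, min_fraction = 0.5,
                            subset = "all", gu_start = 4L, seed = 1L) {
  stopifnot(min_prominence >= 0, min_prominence < 1,
            position_tolerance > 0, min_fraction > 0, min_fraction <= 1,
            subset %in% c("all", "neutral"))
  structure(
    list(bandwidth = bandwidth, min_prominence = min_prominence,
         position_tolerance = position_tolerance,
         min_fraction = min_fraction, subset = subset,
         gu_start = as.integer(gu_start), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Process chromatograms: normalize, align, smooth, detect, integrate
#'
#' Runs the per-sample half of the pipeline and collects a QC report
#' (peak counts, applied shifts, clipped areas, negative-intensity
#' counts).
#'
#' @param chroms Named list of raw [chromatogram()]s.
#' @param config A [pipeline_config()].
#' @return List of class `processed_samples`: `chromatograms` (normalized
#'   and aligned, input order), `peaks` (named list of peak data.frames),
#'   `alignment`, `qc`.
#' @export
process_samples <- function(chroms, config = pipeline_config()) {
  if (length(chroms) == 0L) stop("no chromatograms supplied")
  if (is.null(names(chroms))) {
    names(chroms) <- vapply(chroms, `[[`, character(1L), "sample_id")
  }
  normed <- lapply(chroms, normalize_intensity)
  al <- align_to_reference(normed)
  peaks <- vector("list", length(al$chromatograms))
  names(peaks) <- names(al$chromatograms)
  qc <- do.call(rbind, lapply(al$chromatograms, qc_chromatogram))
  qc$n_peaks <- NA_integer_
  qc$n_clipped <- NA_integer_
  for (i in seq_along(al$chromatograms)) {
    ch <- al$chromatograms[[i]]
    sig <- smooth_derivatives(ch, config$bandwidth)
    pk <- detect_peaks(sig, config$min_prominence)
    pk <- integrate_perpendicular_drop(ch, pk)
    peaks[[i]] <- pk
    qc$n_peaks[i] <- nrow(pk)
    qc$n_clipped[i] <- length(attr(pk, "clipped"))
  }
  qc$shift_min <- al$shifts$shift_min
  rownames(qc) <- NULL
  structure(list(chromatograms = al$chromatograms, peaks = peaks,
                 alignment = al$shifts, reference_time = al$reference_time,
                 qc = qc),
            class = "processed_samples")
}

#' Match peaks across processed samples into a peak matrix
#'
#' Grouping, presence filtering, position imputation and matrix build.
#'
#' @param processed A [process_samples()] result.
#' @param config A [pipeline_config()].
#' @param cal Optional [fit_gu_map()] calibration for GU annotation.
#' @return A [peak_matrix()].
#' @export
match_peaks <- function(processed, config = pipeline_config(), cal = NULL) {
  stopifnot(inherits(processed, "processed_samples"))
  groups <- group_peaks(processed$peaks, config$position_tolerance)
  groups <- filter_presence(groups, config$min_fraction)
  build_peak_matrix(processed$chromatograms, groups, cal)
}

#' Run the full pipeline from raw chromatograms to statistics
#'
#' @param chroms Named list of raw [chromatogram()]s.
#' @param sheet Optional sample sheet (needed for the blocked ANOVA).
#' @param ladder Optional ladder [chromatogram()] for GU calibration.
#' @param config A [pipeline_config()].
#' @return List: `processed`, `calibration`, `matrix`, `summary`
#'   (per-peak summary table), `concordance` (r, d, hclust, pcoa).
#' @export
run_pipeline <- function(chroms, sheet = NULL, ladder = NULL,
                         config = pipeline_config()) {
  processed <- process_samples(chroms, config)
  cal <- if (!is.null(ladder)) {
    fit_gu_map_from_ladder(normalize_intensity(ladder), config$gu_start,
                           config$bandwidth)
  } else {
    NULL
  }
  pm <- match_peaks(processed, config, cal)
  summary <- summary_table(pm, sheet, config$subset)
  conc <- glycan_concordance(pm, config$subset)
  list(processed = processed, calibration = cal, matrix = pm,
       summary = summary, concordance = conc)
}

#' Write all pipeline outputs to a directory
#'
#' Peak matrix CSV + JSON sidecar, per-sample peak lists, QC and
#' alignment tables, summary table, correlation and distance matrices,
#' Newick dendrogram and PCoA coordinates.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_matrix(result$matrix, file.path(dir, "peak_matrix.csv"))
  for (s in names(result$processed$peaks)) {
    write_peak_list(result$processed$peaks[[s]],
                    file.path(dir, paste0("peaks_", s, ".csv")))
  }
  utils::write.csv(result$processed$qc, file.path(dir, "qc.csv"),
                   row.names = FALSE)
  utils::write.csv(result$processed$alignment,
                   file.path(dir, "alignment.csv"), row.names = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  write_square_matrix(result$concordance$r, file.path(dir, "pearson.csv"))
  write_square_matrix(result$concordance$d, file.path(dir, "distance.csv"))
  write_dendrogram(result$concordance$hclust,
                   file.path(dir, "dendrogram.nwk"))
  pc <- result$concordance$pcoa
  utils::write.csv(
    data.frame(sample_id = rownames(pc$points), pc$points,
               check.names = FALSE),
    file.path(dir, "pcoa.csv"), row.names = FALSE
  )
  writeLines(jsonlite::toJSON(list(eigenvalues = pc$eig), digits = NA),
             file.path(dir, "pcoa_eigenvalues.json"))
  invisible(dir)
}
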