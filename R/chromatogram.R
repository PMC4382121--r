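#' Chromatogram object
#'
#' A chromatogram is one sample's fluorescence trace: a strictly increasing
#' time grid in minutes and an intensity vector of the same length in
#' arbitrary fluorescence units. Optional metadata carry the patient letter,
#' tube type (1, 2 or 3) and diagnosis group used by the downstream
#' concordance statistics. Negative intensities are legal (detector/baseline
#' noise) but are counted so QC can flag them.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param time Numeric vector of retention times in minutes, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of fluorescence intensities, same length
#'   as `time`, all finite.
#' @param meta Optional named list; recognised entries are `patient`
#'   (letter), `tube` (integer 1-3) and `group`.
#' @return An object of class `chromatogram`.
#' @examples
#' ch <- chromatogram("A1", time = c(0, 0.5, 1), intensity = c(1, 2, 1))
#' ch
#' @export
chromatogram <- function(sample_id, time, intensity, meta = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) < 2L) {
    stop("chromatogram '", sample_id, "': needs at least 2 points")
  }
  if (length(time) != length(intensity)) {
    stop("chromatogram '", sample_id, "': time and intensity lengths differ (",
         length(time), " vs ", length(intensity), ")")
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("chromatogram '", sample_id, "': non-finite time values")
  }
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop("chromatogram '", sample_id, "': time not strictly increasing at row ",
         bad, " (", time[bad - 1L], " -> ", time[bad], ")")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("chromatogram '", sample_id, "': non-finite intensity values")
  }
  structure(
    list(sample_id = sample_id, time = time, intensity = intensity,
         meta = meta),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram> ", x$sample_id, ": ", length(x$time), " points, ",
      sprintf("%.3f-%.3f min", x$time[1L], x$time[length(x$time)]), sep = "")
  neg <- sum(x$intensity < 0)
  if (neg > 0) cat(", ", neg, " negative intensities", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$time)

#' QC summary for a chromatogram
#'
#' @param chrom A [chromatogram()].
#' @return A one-row data.frame: sample_id, number of points, time span,
#'   median sampling interval, count of negative intensities, total
#'   trapezoidal integral.
#' @export
qc_chromatogram <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  data.frame(
    sample_id = chrom$sample_id,
    n_points = length(chrom$time),
    t_min = chrom$time[1L],
    t_max = chrom$time[length(chrom$time)],
    dt_median = stats::median(diff(chrom$time)),
    n_negative = sum(chrom$intensity < 0),
    total_area = pracma::trapz(chrom$time, chrom$intensity),
    stringsAsFactors = FALSE
  )
}

# Detect the column delimiter of the first data line: comma or tab
# (Chromeleon exports vary by locale).
.detect_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a chromatogram from a delimited text export
#'
#' Expects two numeric columns, time in minutes then intensity. Comma or tab
#' delimiters are auto-detected from the first data line; lines starting
#' with `#` and non-numeric header lines are skipped.
#'
#' @param path Path to the text file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("cannot read chromatogram file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no data lines in ", path)
  delim <- .detect_delim(lines[1L])
  parts <- strsplit(lines, delim, fixed = TRUE)
  nums <- lapply(parts, function(p) suppressWarnings(as.numeric(trimws(p))))
  is_data <- vapply(nums, function(v) length(v) >= 2L && !anyNA(v[1:2]),
                    logical(1L))
  # tolerate leading header line(s) only
  first_data <- which(is_data)[1L]
  if (is.na(first_data)) stop("no numeric data rows in ", path)
  if (!all(is_data[first_data:length(is_data)])) {
    bad <- first_data - 1L + which(!is_data[first_data:length(is_data)])[1L]
    stop("malformed line ", bad, " of ", path,
         ": fewer than 2 numeric columns")
  }
  nums <- nums[is_data]
  time <- vapply(nums, `[`, numeric(1L), 1L)
  intensity <- vapply(nums, `[`, numeric(1L), 2L)
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1L] + 1L
    stop("time column not strictly increasing at data row ", bad,
         " of ", path)
  }
  chromatogram(sample_id, time, intensity)
}

#' Write a chromatogram as 2-column delimited text
#'
#' Full double precision is preserved so write/read round-trips are exact.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  header <- c(
    paste0("# sample_id: ", chrom$sample_id),
    "# columns: time_min,intensity"
  )
  body <- paste(sprintf("%.17g", chrom$time),
                sprintf("%.17g", chrom$intensity), sep = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' A CSV with header `sample_id,patient,tube,group`. If the `patient` or
#' `tube` columns are missing they are parsed from the sample naming
#' convention letter+digit (e.g. `"G3"` is patient G, tube 3); explicit
#' columns override the parsed values.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns sample_id, patient, tube, group.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("cannot read sample sheet: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) {
    warning("empty sample sheet: ", path)
    return(data.frame(sample_id = character(), patient = character(),
                      tube = integer(), group = character(),
                      stringsAsFactors = FALSE))
  }
  if (!"sample_id" %in% names(df)) stop("sample sheet lacks a sample_id column")
  parsed <- parse_sample_name(df$sample_id)
  if (!"patient" %in% names(df) || all(!nzchar(df$patient))) {
    df$patient <- parsed$patient
  }
  if (!"tube" %in% names(df) || all(!nzchar(df$tube))) {
    df$tube <- parsed$tube
  }
  if (!"group" %in% names(df)) df$group <- NA_character_
  df$tube <- as.integer(df$tube)
  validate_sample_sheet(df)
}

#' Parse letter+digit sample names into patient and tube
#'
#' @param ids Character vector of sample names such as `"G3"`.
#' @return A data.frame with columns patient and tube (NA where the name
#'   does not follow the convention).
#' @export
parse_sample_name <- function(ids) {
  m <- regmatches(ids, regexec("^([A-Za-z]+)([0-9]+)$", ids))
  patient <- vapply(m, function(g) if (length(g) == 3L) g[2L] else NA_character_,
                    character(1L))
  tube <- vapply(m, function(g) if (length(g) == 3L) g[3L] else NA_character_,
                 character(1L))
  data.frame(patient = patient, tube = as.integer(tube),
             stringsAsFactors = FALSE)
}

validate_sample_sheet <- function(df) {
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- !is.na(df$tube) & !(df$tube %in% 1:3)
  if (any(bad)) {
    stop("tube type outside {1,2,3} for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  df[, c("sample_id", "patient", "tube", "group")]
}

#' Write a sample sheet
#'
#' @param sheet A data.frame with columns sample_id, patient, tube, group.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet[, c("sample_id", "patient", "tube", "group")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a square labelled matrix (correlation or distance) as CSV
#'
#' @param m Square numeric matrix with row/column names.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_square_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a square labelled matrix written by [write_square_matrix()]
#'
#' @param path CSV path.
#' @return A numeric matrix with dimnames.
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths reflect the merge heights of the agglomeration.
#'
#' @param hc An [stats::hclust] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a per-sample peak list as CSV
#'
#' @param peaks Peak data.frame with columns apex, left, right, height, area.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_peak_list <- function(peaks, path) {
  cols <- c("apex", "left", "right", "height", "area")
  missing_cols <- setdiff(cols, names(peaks))
  if (length(missing_cols)) {
    stop("peak list lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- peaks[, cols]
  names(out) <- c("apex_min", "left_min", "right_min", "height", "area")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
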