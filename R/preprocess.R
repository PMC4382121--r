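#' Normalize a chromatogram to unit total area
#'
#' Divides the intensity vector by its total trapezoidal integral so the
#' trace integrates to 1. Downstream percent peak areas are scale-free, so
#' any positive scalar normalization is equivalent; unit total area is used
#' as the fixed contract.
#'
#' @param chrom A [chromatogram()].
#' @return The chromatogram with rescaled intensities.
#' @export
normalize_intensity <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  total <- pracma::trapz(chrom$time, chrom$intensity)
  if (!is.finite(total) || total <= 0) {
    stop("cannot normalize '", chrom$sample_id,
         "': total integral is ", total)
  }
  chrom$intensity <- chrom$intensity / total
  chrom
}

# Apex of the raw trace: time of the global intensity maximum,
# earliest time on ties.
.raw_apex_time <- function(chrom) chrom$time[which.max(chrom$intensity)]

#' Align chromatograms on their highest peak
#'
#' Each trace is rigidly shifted in time so that its global-maximum apex
#' coincides with the reference time, taken as the median apex time across
#' the collection. Intensities are untouched; the recorded shift is the
#' amount added to the trace's time axis.
#'
#' @param chroms List of [chromatogram()] objects (length >= 1).
#' @return A list with elements `chromatograms` (shifted, same order),
#'   `shifts` (data.frame sample_id, shift_min) and `reference_time`.
#' @export
align_to_reference <- function(chroms) {
  if (length(chroms) == 0L) stop("no chromatograms to align")
  stopifnot(all(vapply(chroms, inherits, logical(1L), "chromatogram")))
  apexes <- vapply(chroms, .raw_apex_time, numeric(1L))
  ref <- stats::median(apexes)
  shifts <- ref - apexes
  shifted <- Map(function(ch, s) {
    ch$time <- ch$time + s
    ch
  }, chroms, shifts)
  names(shifted) <- names(chroms)
  list(
    chromatograms = shifted,
    shifts = data.frame(
      sample_id = vapply(chroms, `[[`, character(1L), "sample_id"),
      shift_min = as.numeric(shifts),
      stringsAsFactors = FALSE
    ),
    reference_time = ref
  )
}
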