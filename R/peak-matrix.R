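#' Matched peak-area matrix
#'
#' Samples x matched-peak-groups container produced by the cross-sample
#' matching stage. Percent areas are computed per sample so each row sums
#' to 100; a neutral/charged split supports the subset analyses.
#'
#' @param areas Numeric matrix (samples x groups) of perpendicular-drop
#'   areas, with sample IDs as rownames; all entries non-negative and
#'   non-missing.
#' @param gu Numeric vector of glucose units per group (NA allowed when no
#'   calibration was supplied).
#' @param neutral Logical vector per group: TRUE for the neutral
#'   (early-eluting, largely IgG-type) region.
#' @param imputed Logical matrix, same shape as `areas`: TRUE where the
#'   peak position was imputed rather than detected.
#' @param presence Numeric vector per group: fraction of samples in which
#'   the peak was detected.
#' @param consensus_time Numeric vector of consensus apex times (minutes).
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(areas, gu = rep(NA_real_, ncol(areas)),
                        neutral = rep(NA, ncol(areas)),
                        imputed = NULL, presence = rep(NA_real_, ncol(areas)),
                        consensus_time = rep(NA_real_, ncol(areas))) {
  stopifnot(is.matrix(areas), !is.null(rownames(areas)))
  if (anyNA(areas)) {
    idx <- which(is.na(areas), arr.ind = TRUE)[1L, ]
    stop("peak matrix has a missing cell: sample '",
         rownames(areas)[idx[1L]], "', group ", idx[2L])
  }
  if (any(areas < 0)) stop("peak matrix has negative areas")
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(areas), ncol(areas),
                      dimnames = dimnames(areas))
  }
  stopifnot(length(gu) == ncol(areas), length(neutral) == ncol(areas),
            all(dim(imputed) == dim(areas)))
  if (is.null(colnames(areas))) {
    colnames(areas) <- paste0("P", seq_len(ncol(areas)))
  }
  rs <- rowSums(areas)
  if (any(rs <= 0)) {
    stop("sample(s) with zero total area: ",
         paste(rownames(areas)[rs <= 0], collapse = ", "))
  }
  percent <- sweep(areas, 1L, rs, "/") * 100
  structure(
    list(samples = rownames(areas), areas = areas, percent = percent,
         gu = gu, neutral = neutral, imputed = imputed,
         presence = presence, consensus_time = consensus_time),
    class = "peak_matrix"
  )
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat("<peak_matrix> ", length(x$samples), " samples x ",
      ncol(x$areas), " peak groups", sep = "")
  if (!all(is.na(x$neutral))) {
    cat(" (", sum(x$neutral, na.rm = TRUE), " neutral)", sep = "")
  }
  cat("; ", sum(x$imputed), " imputed cells\n", sep = "")
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$areas)

#' Percent areas renormalized within a subset of peak groups
#'
#' @param pm A [peak_matrix()].
#' @param subset `"all"` (total serum N-glycans) or `"neutral"` (the
#'   early-eluting subset, renormalized to sum to 100 within itself).
#' @return Numeric matrix of percent areas whose rows sum to 100.
#' @export
percent_areas <- function(pm, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  stopifnot(inherits(pm, "peak_matrix"))
  if (subset == "all") return(pm$percent)
  if (all(is.na(pm$neutral))) stop("no neutral/charged annotation available")
  keep <- which(pm$neutral %in% TRUE)
  if (length(keep) < 1L) stop("no neutral peak groups")
  sub <- pm$areas[, keep, drop = FALSE]
  rs <- rowSums(sub)
  if (any(rs <= 0)) stop("zero neutral-subset area for some sample")
  sweep(sub, 1L, rs, "/") * 100
}

#' Write a peak matrix as CSV plus a JSON sidecar
#'
#' The CSV holds one row per sample and one column per matched peak group,
#' in pipeline order. Group metadata (GU values, presence fractions,
#' neutral flags, consensus times and the imputed-cell mask) go to
#' `<path>.json`.
#'
#' @param pm A [peak_matrix()] with no missing cells.
#' @param path Output CSV path; the sidecar is written next to it.
#' @return Invisibly, `path`.
#' @export
write_peak_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "peak_matrix"))
  df <- data.frame(sample_id = pm$samples,
                   pm$areas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(
    groups = colnames(pm$areas),
    gu = pm$gu,
    presence = pm$presence,
    neutral = pm$neutral,
    consensus_time = pm$consensus_time,
    imputed = lapply(seq_along(pm$samples),
                     function(i) which(pm$imputed[i, ]))
  )
  names(side$imputed) <- pm$samples
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a peak matrix written by [write_peak_matrix()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  areas <- as.matrix(df[, -1L, drop = FALSE])
  rownames(areas) <- df$sample_id
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    return(peak_matrix(areas))
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  imputed <- matrix(FALSE, nrow(areas), ncol(areas),
                    dimnames = dimnames(areas))
  for (s in names(side$imputed)) {
    imputed[s, unlist(side$imputed[[s]])] <- TRUE
  }
  peak_matrix(areas, gu = as.numeric(side$gu),
              neutral = as.logical(side$neutral), imputed = imputed,
              presence = as.numeric(side$presence),
              consensus_time = as.numeric(side$consensus_time))
}
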