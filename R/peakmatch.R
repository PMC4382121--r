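#' Group detected peaks across samples
#'
#' Pools the apex times of all samples' detected peaks and clusters them
#' by average-linkage (UPGMA) agglomerative clustering on absolute time
#' difference, cutting the tree at `position_tolerance`. Average linkage
#' is used because the cut height then compares against the mean
#' within-cluster spacing (about `1.13 * jitter_sd` for Gaussian apex
#' jitter) rather than the full cluster diameter, which for dozens of
#' samples routinely exceeds any tolerance that still separates
#' neighbouring peaks; a complete-linkage cut at the same tolerance
#' splinters true peak groups. Clusters holding
#' two peaks from the same sample are split: the peak farther from the
#' cluster median is reassigned to its nearest other cluster within
#' tolerance that does not already contain that sample, or becomes a
#' singleton. Groups are ordered by consensus (median) apex time.
#'
#' @param peak_lists Named list: sample_id -> peak data.frame from
#'   [integrate_perpendicular_drop()] (or [detect_peaks()]).
#' @param position_tolerance Cut height in minutes (default 0.1).
#' @return An object of class `peak_groups`: list with `assign` (one row
#'   per detected peak: sample_id, apex, left, right, height, area,
#'   group), `summary` (per group: group, consensus_time, presence,
#'   left_off, right_off, n_members) and `samples`.
#' @export
group_peaks <- function(peak_lists, position_tolerance = 0.1) {
  if (position_tolerance <= 0) stop("position_tolerance must be positive")
  if (length(peak_lists) < 2L) stop("need at least 2 samples to group peaks")
  if (is.null(names(peak_lists)) || any(!nzchar(names(peak_lists)))) {
    stop("peak_lists must be a named list (sample_id -> peaks)")
  }
  assign <- do.call(rbind, lapply(names(peak_lists), function(s) {
    pk <- peak_lists[[s]]
    if (nrow(pk) == 0L) return(NULL)
    data.frame(sample_id = s, apex = pk$apex, left = pk$left,
               right = pk$right, height = pk$height,
               area = if ("area" %in% names(pk)) pk$area else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(assign) || nrow(assign) == 0L) stop("no peaks to group")
  if (nrow(assign) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(assign$apex), method = "average")
    cl <- stats::cutree(hc, h = position_tolerance)
  }
  assign$group <- cl
  assign <- .split_same_sample_clusters(assign, position_tolerance)
  .finalize_groups(assign, names(peak_lists))
}

# Enforce the one-peak-per-sample-per-group constraint.
.split_same_sample_clusters <- function(assign, tol) {
  for (iter in 1:20) {
    meds <- tapply(assign$apex, assign$group, stats::median)
    dup <- FALSE
    for (g in names(meds)) {
      idx <- which(assign$group == as.integer(g))
      tab <- table(assign$sample_id[idx])
      for (s in names(tab[tab > 1L])) {
        dup <- TRUE
        rows <- idx[assign$sample_id[idx] == s]
        d <- abs(assign$apex[rows] - meds[[g]])
        move <- rows[order(d)][-1L]  # keep the closest, move the rest
        for (r in move) {
          occupied <- unique(assign$group[assign$sample_id == s])
          cand <- setdiff(as.integer(names(meds)), occupied)
          if (length(cand)) {
            dc <- abs(assign$apex[r] - unlist(meds[as.character(cand)]))
            best <- cand[which.min(dc)]
            if (min(dc) <= tol) {
              assign$group[r] <- best
              next
            }
          }
          assign$group[r] <- max(assign$group) + 1L
        }
      }
    }
    if (!dup) break
  }
  assign
}

.finalize_groups <- function(assign, samples) {
  sp <- split(assign, assign$group)
  summary <- do.call(rbind, lapply(sp, function(df) {
    data.frame(
      group = df$group[1L],
      consensus_time = stats::median(df$apex),
      presence = length(unique(df$sample_id)) / length(samples),
      left_off = stats::median(df$left - df$apex),
      right_off = stats::median(df$right - df$apex),
      n_members = nrow(df)
    )
  }))
  ord <- order(summary$consensus_time)
  summary <- summary[ord, , drop = FALSE]
  relabel <- stats::setNames(seq_len(nrow(summary)), summary$group)
  summary$group <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  assign$group <- as.integer(relabel[as.character(assign$group)])
  assign <- assign[order(assign$group, assign$sample_id), , drop = FALSE]
  rownames(assign) <- NULL
  structure(list(assign = assign, summary = summary, samples = samples),
            class = "peak_groups")
}

#' @export
print.peak_groups <- function(x, ...) {
  cat("<peak_groups> ", nrow(x$summary), " groups from ",
      length(x$samples), " samples (", nrow(x$assign), " peaks)\n", sep = "")
  invisible(x)
}

#' Filter peak groups by cross-sample presence
#'
#' Keeps groups detected in at least `min_fraction` of all samples in the
#' run (inclusive at the boundary, so exactly 50% presence survives the
#' default). Group indices are reassigned 1..K in consensus-time order.
#'
#' @param groups A [group_peaks()] result.
#' @param min_fraction Minimum presence fraction in (0, 1]; default 0.5.
#' @return A filtered `peak_groups` object.
#' @export
filter_presence <- function(groups, min_fraction = 0.5) {
  stopifnot(inherits(groups, "peak_groups"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  keep <- groups$summary$presence >= min_fraction
  summary <- groups$summary[keep, , drop = FALSE]
  old <- summary$group
  relabel <- stats::setNames(seq_along(old), old)
  summary$group <- seq_along(old)
  rownames(summary) <- NULL
  assign <- groups$assign[groups$assign$group %in% old, , drop = FALSE]
  assign$group <- as.integer(relabel[as.character(assign$group)])
  rownames(assign) <- NULL
  structure(list(assign = assign, summary = summary,
                 samples = groups$samples),
            class = "peak_groups")
}

#' Impute positions of a sample's missing peaks
#'
#' For each retained group without a detected member from `sample_id`,
#' places the apex at the group consensus time plus this sample's local
#' time offset, linearly interpolated between the nearest matched groups
#' on each side (constant extrapolation at the edges). Boundaries are the
#' group's consensus trough offsets applied at the imputed apex.
#'
#' @param groups A filtered [peak_groups()] object.
#' @param sample_id Sample to impute.
#' @return data.frame: group, apex, left, right, imputed (TRUE for rows
#'   that were imputed), covering every retained group for this sample.
#' @export
impute_missing_positions <- function(groups, sample_id) {
  stopifnot(inherits(groups, "peak_groups"))
  own <- groups$assign[groups$assign$sample_id == sample_id, , drop = FALSE]
  if (nrow(own) == 0L) {
    stop("sample '", sample_id, "' matched zero retained peak groups")
  }
  sm <- groups$summary
  matched <- sm$group %in% own$group
  cons_m <- sm$consensus_time[matched]
  off_m <- own$apex[match(sm$group[matched], own$group)] - cons_m
  out <- data.frame(group = sm$group, apex = NA_real_, left = NA_real_,
                    right = NA_real_, imputed = !matched)
  out$apex[matched] <- own$apex[match(sm$group[matched], own$group)]
  out$left[matched] <- own$left[match(sm$group[matched], own$group)]
  out$right[matched] <- own$right[match(sm$group[matched], own$group)]
  miss <- which(!matched)
  if (length(miss)) {
    if (length(cons_m) == 1L) {
      off <- rep(off_m, length(miss))
    } else {
      off <- stats::approx(cons_m, off_m, xout = sm$consensus_time[miss],
                           rule = 2L)$y
    }
    out$apex[miss] <- sm$consensus_time[miss] + off
    out$left[miss] <- out$apex[miss] + sm$left_off[miss]
    out$right[miss] <- out$apex[miss] + sm$right_off[miss]
  }
  out[order(out$group), , drop = FALSE]
}

# Resolve overlapping boundaries between consecutive peaks of one sample:
# midpoint split, clamped between the two apexes.
.resolve_boundary_overlaps <- function(df) {
  df <- df[order(df$apex), , drop = FALSE]
  n <- nrow(df)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (df$right[i] > df$left[i + 1L]) {
        m <- (df$right[i] + df$left[i + 1L]) / 2
        m <- min(max(m, df$apex[i]), df$apex[i + 1L])
        df$right[i] <- m
        df$left[i + 1L] <- m
      }
    }
  }
  df[order(df$group), , drop = FALSE]
}

#' Build the matched peak-area matrix
#'
#' Completes every sample x retained-group cell: detected boundaries where
#' the sample has a member, imputed positions elsewhere, overlapping
#' boundaries resolved by midpoint split, and all areas (re-)integrated by
#' perpendicular drop over the raw normalized trace. Percent areas per
#' sample sum to 100; GU values come from the calibration evaluated at the
#' consensus apex times and drive the neutral/charged split.
#'
#' @param chroms Named list of normalized, aligned [chromatogram()]s.
#' @param groups A filtered [peak_groups()] object.
#' @param cal Optional [fit_gu_map()] calibration.
#' @return A [peak_matrix()].
#' @export
build_peak_matrix <- function(chroms, groups, cal = NULL) {
  stopifnot(inherits(groups, "peak_groups"))
  samples <- groups$samples
  if (is.null(names(chroms))) {
    names(chroms) <- vapply(chroms, `[[`, character(1L), "sample_id")
  }
  missing_tr <- setdiff(samples, names(chroms))
  if (length(missing_tr)) {
    stop("no chromatogram for sample(s): ",
         paste(missing_tr, collapse = ", "))
  }
  K <- nrow(groups$summary)
  areas <- matrix(NA_real_, length(samples), K,
                  dimnames = list(samples, paste0("P", seq_len(K))))
  imputed <- matrix(FALSE, length(samples), K,
                    dimnames = dimnames(areas))
  for (s in samples) {
    pos <- impute_missing_positions(groups, s)
    pos <- .resolve_boundary_overlaps(pos)
    ch <- chroms[[s]]
    a <- vapply(seq_len(nrow(pos)), function(i) {
      trapz_interval(ch$time, ch$intensity, pos$left[i], pos$right[i])
    }, numeric(1L))
    a[a < 0] <- 0
    areas[s, pos$group] <- a
    imputed[s, pos$group] <- pos$imputed
  }
  if (anyNA(areas)) {
    idx <- which(is.na(areas), arr.ind = TRUE)[1L, ]
    stop("unfilled peak matrix cell: sample '", samples[idx[1L]],
         "', group ", idx[2L])
  }
  gu <- if (!is.null(cal)) {
    predict(cal, groups$summary$consensus_time)
  } else {
    rep(NA_real_, K)
  }
  peak_matrix(areas, gu = gu, neutral = neutral_split(gu, K),
              imputed = imputed, presence = groups$summary$presence,
              consensus_time = groups$summary$consensus_time)
}
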