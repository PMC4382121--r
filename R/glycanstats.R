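# Replace zeros by half the smallest positive value in each column before
# taking logs; returns the matrix plus a count of substitutions.
.half_min_substitute <- function(m) {
  n_sub <- 0L
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (all(x <= 0)) {
      stop("peak group ", colnames(m)[j] %||% j,
           " has no positive areas in any sample")
    }
    z <- x <= 0
    if (any(z)) {
      m[z, j] <- min(x[!z]) / 2
      n_sub <- n_sub + sum(z)
    }
  }
  attr(m, "n_substituted") <- n_sub
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric means and log-scale coefficients of variation per peak group
#'
#' The geometric mean is `exp(mean(ln x))` and the coefficient of
#' variation is the log-normal form `100 * sqrt(exp(s^2) - 1)` with `s`
#' the sample standard deviation (n-1 denominator) of the natural-log
#' percent areas. Zeros are replaced by half the column's smallest
#' positive value before the log transform (reported via message).
#'
#' @param pm A [peak_matrix()].
#' @param subset `"all"` or `"neutral"` (percent areas renormalized within
#'   the subset).
#' @return data.frame: group, gu, geo_mean_pct, cv_pct.
#' @export
geometric_mean_cv <- function(pm, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  p <- percent_areas(pm, subset)
  p <- .half_min_substitute(p)
  if (attr(p, "n_substituted") > 0L) {
    message("substituted half-minimum for ", attr(p, "n_substituted"),
            " zero percent-area cell(s) before log transform")
  }
  lp <- log(p)
  gm <- exp(colMeans(lp))
  s <- apply(lp, 2L, stats::sd)
  idx <- if (subset == "all") seq_len(ncol(pm$areas)) else which(pm$neutral %in% TRUE)
  data.frame(group = idx, gu = pm$gu[idx], geo_mean_pct = as.numeric(gm),
             cv_pct = 100 * sqrt(exp(s^2) - 1))
}

#' Mean intra-individual coefficient of variation per peak group
#'
#' The tube-to-tube reproducibility measure: for each peak group and each
#' patient with at least two samples, the log-normal CV is computed from
#' that patient's samples alone, and the per-patient CVs are averaged.
#' Unlike the pooled [geometric_mean_cv()], this is unaffected by
#' inter-individual spread and isolates processing/tube variation.
#'
#' @param pm A [peak_matrix()].
#' @param sheet Sample sheet data.frame (sample_id, patient, tube, group).
#' @param subset `"all"` or `"neutral"`.
#' @return data.frame: group, gu, mean_cv_pct; attribute `n_patients`
#'   gives the number of patients contributing.
#' @export
intra_individual_cv <- function(pm, sheet, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  p <- percent_areas(pm, subset)
  p <- .half_min_substitute(p)
  patient <- sheet$patient[match(rownames(p), sheet$sample_id)]
  if (anyNA(patient)) {
    stop("sample sheet lacks entries for: ",
         paste(rownames(p)[is.na(patient)], collapse = ", "))
  }
  keep <- patient %in% names(which(table(patient) >= 2L))
  if (!any(keep)) stop("no patient has two or more samples")
  p <- p[keep, , drop = FALSE]
  patient <- patient[keep]
  lp <- log(p)
  cv <- apply(lp, 2L, function(col) {
    s <- tapply(col, patient, stats::sd)
    mean(100 * sqrt(exp(s^2) - 1))
  })
  idx <- if (subset == "all") seq_len(ncol(pm$areas)) else which(pm$neutral %in% TRUE)
  out <- data.frame(group = idx, gu = pm$gu[idx],
                    mean_cv_pct = as.numeric(cv))
  attr(out, "n_patients") <- length(unique(patient))
  out
}

#' Pairwise Pearson correlation of sample profiles
#'
#' Correlates the percent-area vectors of every pair of samples,
#' optionally restricted to the neutral subset (renormalized to 100
#' within the subset first).
#'
#' @param pm A [peak_matrix()].
#' @param subset `"all"` or `"neutral"`.
#' @return Symmetric correlation matrix with unit diagonal. Samples with
#'   zero-variance profiles get NA correlations and a warning.
#' @export
pairwise_pearson <- function(pm, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  p <- percent_areas(pm, subset)
  if (nrow(p) < 2L) stop("need at least 2 samples")
  if (ncol(p) < 3L) stop("need at least 3 peak groups in the subset")
  v <- apply(p, 1L, stats::var)
  r <- suppressWarnings(stats::cor(t(p)))
  diag(r) <- 1
  if (any(v == 0)) {
    warning("zero-variance profile(s): ",
            paste(rownames(p)[v == 0], collapse = ", "),
            "; their correlations are NA")
    r[v == 0, ] <- NA_real_
    r[, v == 0] <- NA_real_
    diag(r) <- ifelse(v == 0, NA_real_, 1)
  }
  r
}

#' Correlation distance 1 - |r|
#'
#' Symmetric with zero diagonal and entries in [0, 1]. Not a metric (the
#' triangle inequality can fail); it is used only for complete-linkage
#' clustering and principal coordinate analysis, neither of which
#' requires metricity.
#'
#' @param r Pearson correlation matrix.
#' @return Distance matrix of the same shape.
#' @export
cor_distance <- function(r) {
  d <- 1 - abs(r)
  diag(d) <- 0
  d
}

#' Complete-linkage clustering of samples on 1 - |r|
#'
#' @param r Pearson correlation matrix from [pairwise_pearson()].
#' @return An [stats::hclust] tree. Leaf order is deterministic given the
#'   sample order of `r` (ties resolve to the lower sample index).
#' @export
cluster_samples <- function(r) {
  if (anyNA(r)) stop("correlation matrix contains NA (undefined) entries")
  d <- cor_distance(r)
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers -d^2/2, eigendecomposes, and returns coordinates scaled
#' by the square roots of the top positive eigenvalues. Negative
#' eigenvalues (possible for the non-Euclidean 1 - |r| distance) are
#' reported but never used; if fewer than `k` positive eigenvalues exist,
#' fewer axes are returned with a warning.
#'
#' @param d Square distance matrix.
#' @param k Number of axes requested (default 2).
#' @return List: `points` (samples x axes), `eig` (all eigenvalues,
#'   decreasing), `k` (axes returned).
#' @export
pcoa <- function(d, k = 2L) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (npos < k) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos,
            " axes instead of ", k)
  }
  kk <- min(k, max(npos, 1L))
  pts <- as.matrix(fit$points)[, seq_len(min(kk, ncol(as.matrix(fit$points)))),
                               drop = FALSE]
  rownames(pts) <- rownames(d)
  list(points = pts, eig = eig, k = ncol(pts))
}

#' Per-peak blocked ANOVA of tube type
#'
#' For each peak group, fits a two-way fixed-effects analysis of variance
#' of the natural-log percent area on tube type (3 levels) with patient as
#' a blocking factor, using only patients that contributed all three tube
#' types. The design is then a balanced complete block (verified at run
#' time), so the tube sum of squares is unambiguous. Bonferroni
#' correction multiplies the tube p-value by the number of retained
#' groups, capped at 1.
#'
#' @param pm A [peak_matrix()].
#' @param sheet Sample sheet data.frame (sample_id, patient, tube, group).
#' @param subset `"all"` or `"neutral"`.
#' @return data.frame: group, gu, f_tube, p, p_bonferroni; attribute
#'   `n_patients` gives the number of complete patients used.
#' @export
blocked_anova <- function(pm, sheet, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  p <- percent_areas(pm, subset)
  info <- sheet[match(rownames(p), sheet$sample_id), , drop = FALSE]
  if (anyNA(info$sample_id)) {
    stop("sample sheet lacks entries for: ",
         paste(setdiff(rownames(p), sheet$sample_id), collapse = ", "))
  }
  tube_count <- tapply(info$tube, info$patient,
                       function(t) length(unique(t)))
  complete <- names(tube_count)[tube_count == 3L]
  if (length(complete) < 2L) {
    stop("need >= 2 patients with all three tube types (found ",
         length(complete), ")")
  }
  keep <- info$patient %in% complete
  p <- p[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  tab <- table(info$patient, info$tube)
  if (!all(tab == 1L)) {
    stop("design not a balanced complete block (patient x tube counts != 1)")
  }
  p <- .half_min_substitute(p)
  patient <- factor(info$patient)
  tube <- factor(info$tube)
  K <- ncol(p)
  res <- vapply(seq_len(K), function(j) {
    fit <- stats::lm(log(p[, j]) ~ patient + tube)
    an <- stats::anova(fit)
    c(an["tube", "F value"], an["tube", "Pr(>F)"])
  }, numeric(2L))
  idx <- if (subset == "all") seq_len(ncol(pm$areas)) else which(pm$neutral %in% TRUE)
  out <- data.frame(group = idx, gu = pm$gu[idx],
                    f_tube = res[1L, ], p = res[2L, ],
                    p_bonferroni = pmin(1, res[2L, ] * K))
  attr(out, "n_patients") <- length(complete)
  out
}

#' Summary table of peak-level statistics
#'
#' Combines GU values, geometric mean percent areas, log-scale CVs and
#' Bonferroni-corrected blocked-ANOVA p-values into one table per peak
#' group (the layout used to report whole-serum glycan panels).
#'
#' @param pm A [peak_matrix()].
#' @param sheet Optional sample sheet; the intra-individual CV and ANOVA
#'   columns are NA without it.
#' @param subset `"all"` or `"neutral"`.
#' @return data.frame: group, gu, geo_mean_pct, cv_pct (pooled across all
#'   samples), mean_cv_pct (mean of within-patient CVs), p, p_bonferroni.
#' @export
summary_table <- function(pm, sheet = NULL, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  tab <- geometric_mean_cv(pm, subset)
  tab$mean_cv_pct <- NA_real_
  if (!is.null(sheet)) {
    pat <- sheet$patient[match(pm$samples, sheet$sample_id)]
    if (any(table(pat) >= 2L)) {
      tab$mean_cv_pct <- intra_individual_cv(pm, sheet, subset)$mean_cv_pct
    }
  }
  has_design <- FALSE
  if (!is.null(sheet)) {
    info <- sheet[match(pm$samples, sheet$sample_id), , drop = FALSE]
    tube_count <- tapply(info$tube, info$patient,
                         function(t) length(unique(t)))
    has_design <- sum(tube_count == 3L, na.rm = TRUE) >= 2L
    if (!has_design) {
      message("fewer than 2 patients with all three tube types; ",
              "skipping the blocked ANOVA")
    }
  }
  if (has_design) {
    an <- blocked_anova(pm, sheet, subset)
    tab$p <- an$p
    tab$p_bonferroni <- an$p_bonferroni
  } else {
    tab$p <- NA_real_
    tab$p_bonferroni <- NA_real_
  }
  tab
}

#' Full concordance analysis of a peak matrix
#'
#' Pairwise Pearson correlation, 1 - |r| complete-linkage dendrogram and
#' a 2-axis principal coordinate embedding, as used to ask whether
#' repeat samples from one individual agree more than samples from
#' different individuals.
#'
#' @param pm A [peak_matrix()].
#' @param subset `"all"` or `"neutral"`.
#' @return List: `r`, `d`, `hclust`, `pcoa`.
#' @export
glycan_concordance <- function(pm, subset = c("all", "neutral")) {
  subset <- match.arg(subset)
  r <- pairwise_pearson(pm, subset)
  d <- cor_distance(r)
  hc <- cluster_samples(r)
  list(r = r, d = d, hclust = hc, pcoa = pcoa(d, 2L))
}
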