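# Build a peak matrix whose percent areas in column 1 equal `x` by
# padding with a complement column (rows sum to 100).
pm_from_column <- function(x, ids = paste0("S", seq_along(x))) {
  areas <- cbind(x, 100 - x)
  rownames(areas) <- ids
  peak_matrix(areas)
}

pm_from_percent <- function(p, ids = paste0("S", seq_len(nrow(p)))) {
  rownames(p) <- ids
  peak_matrix(p)
}

test_that("geometric mean and log-normal CV match closed forms", {
  pm <- pm_from_column(c(5, 5, 5))
  tab <- geometric_mean_cv(pm)
  expect_equal(tab$geo_mean_pct[1], 5)
  expect_equal(tab$cv_pct[1], 0)

  pm2 <- pm_from_column(c(1, exp(2)))
  tab2 <- geometric_mean_cv(pm2)
  expect_equal(tab2$geo_mean_pct[1], exp(1), tolerance = 1e-12)
  # s = sd(c(0, 2)) = sqrt(2); CV% = 100 * sqrt(exp(2) - 1)
  expect_equal(tab2$cv_pct[1], 100 * sqrt(exp(2) - 1), tolerance = 1e-12)
})

test_that("estimated CV recovers the generating log-normal CV at n = 66", {
  target_cv <- 0.0229  # the profile's largest peak in the emulated panel
  s <- sqrt(log(1 + target_cv^2))
  set.seed(66)
  x <- 36.29 * exp(rnorm(66, 0, s))
  tab <- geometric_mean_cv(pm_from_column(x))
  expect_lt(abs(tab$cv_pct[1] - 2.29), 0.6)
})

test_that("CV estimates converge to the generator CV as n grows", {
  s <- 0.1  # CV about 10.05%
  true_cv <- 100 * sqrt(exp(s^2) - 1)
  set.seed(99)
  err <- vapply(c(24, 48, 96), function(n) {
    reps <- vapply(1:10, function(r) {
      x <- 10 * exp(rnorm(n, 0, s))
      geometric_mean_cv(pm_from_column(x))$cv_pct[1]
    }, numeric(1))
    mean(abs(reps - true_cv))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1.5)
})

test_that("intra-individual CV averages within-patient log-normal CVs", {
  sheet <- data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                      patient = c("A", "A", "B", "B"),
                      tube = c(1, 2, 1, 2), group = NA)
  # patient A: {1, e^2} -> CV 100*sqrt(e^2 - 1); patient B: constant -> 0
  x <- c(1, exp(2), 5, 5)
  pm <- pm_from_column(x, sheet$sample_id)
  res <- intra_individual_cv(pm, sheet)
  expect_equal(res$mean_cv_pct[1], (100 * sqrt(exp(2) - 1) + 0) / 2,
               tolerance = 1e-12)
  expect_equal(attr(res, "n_patients"), 2L)

  # identical tubes within every patient -> CV exactly 0
  pm0 <- pm_from_column(c(3, 3, 8, 8), sheet$sample_id)
  expect_equal(intra_individual_cv(pm0, sheet)$mean_cv_pct, c(0, 0))

  # unaffected by inter-individual spread, unlike the pooled CV
  pooled <- geometric_mean_cv(pm0)$cv_pct[1]
  expect_gt(pooled, 50)

  lone <- data.frame(sample_id = c("A1", "B1"), patient = c("A", "B"),
                     tube = c(1, 1), group = NA)
  expect_error(intra_individual_cv(pm_from_column(c(3, 8), lone$sample_id),
                                   lone), "two or more")
})

test_that("intra-individual CV recovers the generator's tube-level variation", {
  cfg <- simulation_config(n_patients = 22, seed = 63)
  prof <- simulate_profiles(cfg)
  pm <- peak_matrix(prof$true_pct, gu = cfg$template$gu,
                    neutral = cfg$template$neutral)
  res <- intra_individual_cv(pm, data.frame(prof$samples, group = NA))
  k <- which.max(cfg$template$mean_pct)
  # closed-form expectation for the largest peak: renormalization to 100
  # shrinks its effective log-sd to sigma * sqrt((1-w)^2 + sum(w_j^2)),
  # and sd from n = 3 tubes carries the c4 small-sample factor
  w <- prof$true_pct[1, ] / 100
  sigma_eff <- 0.02 * sqrt((1 - w[k])^2 + sum(w[-k]^2))
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)  # n = 3
  expected <- 100 * c4 * sigma_eff
  expect_lt(abs(res$mean_cv_pct[k] - expected), 0.3)
  # tube-level scale: an order of magnitude below the pooled CV
  pooled <- geometric_mean_cv(pm)$cv_pct[k]
  expect_lt(res$mean_cv_pct[k], pooled / 10)
})

test_that("pairwise Pearson matches the covariance-formula oracle and its invariances", {
  p <- rbind(c(10, 30, 60), c(20, 30, 50), c(35, 40, 25))
  pm <- pm_from_percent(p)
  r <- pairwise_pearson(pm)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(r[i, j], pearson_oracle(p[i, ], p[j, ]), tolerance = 1e-12)
  }
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))

  # duplicated sample and positive rescaling give r = 1
  areas <- rbind(A = c(10, 30, 60), B = c(10, 30, 60) * 7.3)
  pmd <- peak_matrix(areas)
  rd <- pairwise_pearson(pmd)
  expect_equal(rd[1, 2], 1)

  # zero-variance profile flagged
  flatp <- rbind(c(30, 30, 40), c(100 / 3, 100 / 3, 100 / 3))
  expect_warning(rz <- pairwise_pearson(pm_from_percent(flatp)),
                 "zero-variance")
  expect_true(is.na(rz[1, 2]))
})

test_that("sample clustering merges identical and anti-correlated profiles at height 0", {
  v <- c(20, 30, 50)
  w <- 50 - 0.5 * v  # exactly anti-correlated with v, sums to 100
  p <- rbind(A = v, B = v, C = w)
  r <- pairwise_pearson(pm_from_percent(p, c("A", "B", "C")))
  expect_equal(r["A", "C"], -1, tolerance = 1e-12)
  hc <- cluster_samples(r)
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  # |r| turns the anti-correlated pair into distance 0 as well
  d <- cor_distance(r)
  expect_equal(d["A", "C"], 0, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone merge heights
  rna <- r
  rna[1, 2] <- rna[2, 1] <- NA
  expect_error(cluster_samples(rna), "NA")
})

test_that("classical MDS embeds distances faithfully", {
  # 3 collinear points
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  fit <- pcoa(d3, k = 1)
  emb <- as.matrix(dist(fit$points))
  expect_equal(unname(emb), unname(d3), tolerance = 1e-9)

  # 4 known planar points, up to rotation/reflection
  set.seed(3)
  pts <- matrix(rnorm(8), 4, 2)
  d4 <- as.matrix(dist(pts))
  fit4 <- pcoa(d4, k = 2)
  expect_equal(unname(as.matrix(dist(fit4$points))), unname(d4),
               tolerance = 1e-9)

  # duplicated sample coincides
  p <- rbind(A = c(10, 30, 60), B = c(10, 30, 60), C = c(40, 35, 25))
  r <- pairwise_pearson(pm_from_percent(p, rownames(p)))
  # 3 points, one duplicated: a single positive eigenvalue remains
  expect_warning(f <- pcoa(cor_distance(r), k = 2), "positive eigenvalue")
  expect_equal(unname(f$points["A", ]), unname(f$points["B", ]),
               tolerance = 1e-9)
})

test_that("blocked ANOVA matches the textbook sum-of-squares oracle", {
  # 2 patients x 3 tubes, single peak of interest
  y <- c(10, 11, 12, 20, 19, 21)
  sheet <- data.frame(sample_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
                      patient = rep(c("A", "B"), each = 3),
                      tube = rep(1:3, 2), group = NA)
  pm <- pm_from_column(y, sheet$sample_id)
  res <- blocked_anova(pm, sheet)
  oracle <- anova_block_oracle(log(y), sheet$patient, sheet$tube)
  expect_equal(res$f_tube[1], unname(oracle["F"]), tolerance = 1e-9)
  expect_equal(res$p[1], unname(oracle["p"]), tolerance = 1e-9)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 2))
  expect_equal(attr(res, "n_patients"), 2L)
})

test_that("blocked ANOVA requires complete patients and is scale invariant", {
  sheet <- data.frame(sample_id = c("A1", "A2", "A3", "B1", "B2"),
                      patient = c("A", "A", "A", "B", "B"),
                      tube = c(1, 2, 3, 1, 2), group = NA)
  pm <- pm_from_column(c(10, 11, 12, 20, 19), sheet$sample_id)
  expect_error(blocked_anova(pm, sheet), "all three tube")

  sheet6 <- data.frame(sample_id = paste0(rep(c("A", "B"), each = 3), 1:3),
                       patient = rep(c("A", "B"), each = 3),
                       tube = rep(1:3, 2), group = NA)
  set.seed(8)
  areas <- matrix(rlnorm(6 * 4), 6, 4,
                  dimnames = list(sheet6$sample_id, NULL))
  p1 <- blocked_anova(peak_matrix(areas), sheet6)
  scaled <- areas
  scaled[2, ] <- scaled[2, ] * 13.7  # one sample's raw areas rescaled
  p2 <- blocked_anova(peak_matrix(scaled), sheet6)
  expect_equal(p1$p, p2$p, tolerance = 1e-12)
})

test_that("summary table assembles GU, means, CVs and corrected p-values", {
  cfg <- simulation_config(n_patients = 4, seed = 31)
  prof <- simulate_profiles(cfg)
  pm <- peak_matrix(prof$true_pct, gu = cfg$template$gu,
                    neutral = cfg$template$neutral)
  sheet <- data.frame(prof$samples, group = NA)
  tab <- summary_table(pm, sheet)
  expect_equal(nrow(tab), 42L)
  expect_true(all(tab$geo_mean_pct > 0))
  expect_true(all(tab$cv_pct >= 0))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_equal(tab$p_bonferroni, pmin(1, tab$p * 42))
  # neutral subset renormalizes to 100
  pn <- percent_areas(pm, "neutral")
  expect_equal(unname(rowSums(pn)), rep(100, nrow(pn)), tolerance = 1e-9)
  tabn <- summary_table(pm, sheet, subset = "neutral")
  expect_equal(nrow(tabn), 16L)
})
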