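test_that("well-separated apexes group one-to-one across samples", {
  set.seed(1)
  pl <- lapply(1:3, function(i) apex_peak_list(c(10, 12) + runif(2, -0.01, 0.01)))
  names(pl) <- paste0("S", 1:3)
  g <- group_peaks(pl, position_tolerance = 0.1)
  expect_equal(nrow(g$summary), 2L)
  expect_equal(g$summary$presence, c(1, 1))
  expect_equal(g$summary$consensus_time, c(10, 12), tolerance = 0.02)
  expect_error(group_peaks(pl, position_tolerance = 0), "positive")
})

test_that("one-per-sample constraint splits clusters with duplicate members", {
  pl <- list(S1 = apex_peak_list(c(10.0, 10.4)),
             S2 = apex_peak_list(10.2))
  g <- group_peaks(pl, position_tolerance = 0.5)
  expect_equal(nrow(g$summary), 2L)
  # S1 contributes to both groups, never twice to one
  tab <- table(g$assign$sample_id, g$assign$group)
  expect_true(all(tab <= 1))
})

test_that("grouping matches the nearest-template oracle on jittered samples", {
  tpl_rt <- default_rt_model()(glycan_peak_template()$gu)
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    pl <- lapply(1:20, function(i) apex_peak_list(tpl_rt + rnorm(42, 0, 0.02)))
    names(pl) <- paste0("S", 1:20)
    g <- group_peaks(pl, position_tolerance = 0.1)
    oracle <- apply(abs(outer(g$assign$apex, tpl_rt, "-")), 1, which.min)
    expect_equal(nrow(g$summary), 42L)
    # each group maps to exactly one template position and vice versa
    expect_true(all(tapply(oracle, g$assign$group,
                           function(x) length(unique(x)) == 1)))
    expect_equal(length(unique(tapply(oracle, g$assign$group, unique))), 42L)
  }
})

test_that("presence filter is inclusive at the threshold and monotone", {
  pl <- list(S1 = apex_peak_list(c(10, 12)), S2 = apex_peak_list(c(10, 12)),
             S3 = apex_peak_list(10), S4 = apex_peak_list(10))
  g <- group_peaks(pl, 0.1)
  expect_equal(g$summary$presence, c(1, 0.5))
  kept <- filter_presence(g, 0.5)
  expect_equal(nrow(kept$summary), 2L)  # 2/4 kept: boundary inclusive
  strict <- filter_presence(g, 0.6)
  expect_equal(nrow(strict$summary), 1L)
  universal <- filter_presence(g, 1.0)
  expect_equal(nrow(universal$summary), 1L)
  # presence monotonicity: retained count non-increasing in min_fraction
  counts <- vapply(c(0.25, 0.5, 0.75, 1), function(f) {
    nrow(filter_presence(g, f)$summary)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # below-threshold group dropped for a sample present in 1/4
  pl2 <- c(pl, list(S5 = apex_peak_list(14)))
  g2 <- group_peaks(pl2, 0.1)
  expect_false(14 %in% round(filter_presence(g2, 0.5)$summary$consensus_time))
  expect_error(filter_presence(g, 0), "min_fraction")
})

test_that("missing positions are imputed from the sample's neighbour offsets", {
  pl <- list(A = apex_peak_list(c(10, 11, 12)),
             B = apex_peak_list(c(10, 11, 12)),
             C = apex_peak_list(c(10.05, 12.05)))
  g <- group_peaks(pl, 0.1)
  expect_equal(nrow(g$summary), 3L)
  imp <- impute_missing_positions(g, "C")
  expect_equal(imp$imputed, c(FALSE, TRUE, FALSE))
  expect_equal(imp$apex[2], 11.05, tolerance = 1e-9)

  # one-sided: offset copied from the only flanking side
  pl2 <- list(A = apex_peak_list(c(10, 11, 12)),
              B = apex_peak_list(c(10, 11, 12)),
              C = apex_peak_list(c(10.08, 11.08)))
  g2 <- group_peaks(pl2, 0.1)
  imp2 <- impute_missing_positions(g2, "C")
  expect_equal(imp2$apex[3], 12.08, tolerance = 1e-9)

  pl3 <- list(A = apex_peak_list(c(10, 12)), B = apex_peak_list(c(10, 12)),
              C = apex_peak_list(20))
  g3 <- filter_presence(group_peaks(pl3, 0.1), 0.6)
  expect_error(impute_missing_positions(g3, "C"), "zero retained")
})

test_that("a deleted true peak is re-imputed at its position with its area", {
  cfg <- simulation_config(n_patients = 2, noise_sd = 0,
                           rt_jitter_sd_min = 0.01, shift_sd_min = 0,
                           baseline_amplitude = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  pr <- process_samples(ds$chromatograms)
  victim <- names(pr$peaks)[1]
  tpl_rt <- cfg$rt_model(cfg$template$gu)
  # delete the detected peak nearest template position 20 from one sample
  k <- which.min(abs(pr$peaks[[victim]]$apex - tpl_rt[20]))
  deleted_apex <- pr$peaks[[victim]]$apex[k]
  pr$peaks[[victim]] <- pr$peaks[[victim]][-k, ]
  groups <- filter_presence(group_peaks(pr$peaks, 0.1), 0.5)
  imp <- impute_missing_positions(groups, victim)
  row <- which(abs(groups$summary$consensus_time - tpl_rt[20]) ==
                 min(abs(groups$summary$consensus_time - tpl_rt[20])))
  expect_true(imp$imputed[row])
  true_apex <- ds$truth$apex[victim, 20]
  expect_lt(abs(imp$apex[row] - true_apex), 0.05)
  # re-integrated area reproduces the truth share
  pm <- build_peak_matrix(pr$chromatograms, groups)
  expect_equal(pm$percent[victim, row],
               unname(ds$truth$true_pct[victim, 20]), tolerance = 0.2)
  expect_true(pm$imputed[victim, row])
})

test_that("peak matrix rows are normalized, deterministic and complete", {
  cfg <- simulation_config(n_patients = 1, tubes_per_patient = 1,
                           intra_individual_log_sd = 0, noise_sd = 0,
                           rt_jitter_sd_min = 0, shift_sd_min = 0,
                           seed = 5)
  ds <- simulate_dataset(cfg)
  ch <- ds$chromatograms[[1]]
  twin <- ch
  twin$sample_id <- "twin"
  pr <- process_samples(list(A1 = ch, twin = twin))
  pm <- match_peaks(pr)
  expect_equal(unname(rowSums(pm$percent)), c(100, 100), tolerance = 1e-9)
  expect_equal(pm$percent[1, ], pm$percent[2, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})
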