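key10 <- scheme_key_matrix(scheme10)

test_that("hand-built events are scored as specified", {
  m <- rbind(perfect = c(1, 1, 1, 0, 0),
             doublet_like = c(1, 1, 1, 1, 0),
             dim = c(0.8, 0.7, 0.6, 0.1, 0.2),
             blank = c(0, 0, 0, 0, 0))
  colnames(m) <- default_barcode_channels()
  asg <- assign_events(m, scheme10)
  expect_identical(asg$sample[1], "BC01")
  expect_identical(asg$separation[1], 1)
  # a 4th hot channel violates every key's negative slot: best score 0,
  # which is also a tie across keys -> unassigned
  expect_identical(asg$separation[2], 0)
  expect_identical(asg$sample[3], "BC01")
  expect_equal(asg$separation[3], 0.6 - 0.2, tolerance = 1e-12)
  expect_true(is.na(asg$sample[4]))     # all-zero event ties every key

  final <- apply_threshold(asg, debarcode_params(separation_threshold = 0.35))
  expect_identical(final$sample, c("BC01", NA, "BC01", NA))
  strict <- apply_threshold(asg, 0.5)
  expect_identical(strict$sample, c("BC01", NA, NA, NA))
  # boundary is kept (comparison is >=)
  exact <- apply_threshold(asg, asg$separation[3])
  expect_true(!is.na(exact$sample[3]))
})

test_that("key-score assignment equals the brute-force and top-k oracles", {
  sim <- quick_sim(events_per_sample = 120, seed = 41, doublet_rate = 0.1)
  raw <- as.matrix(as.data.frame(sim$events))[, 1:5]
  rescaled <- rescale_barcode_channels(arcsinh_transform(raw))
  asg <- assign_events(rescaled, scheme10)

  bf <- brute_force_assign(rescaled, key10, scheme10$sample)
  expect_identical(asg$sample, bf$sample)
  expect_equal(asg$separation, bf$separation, tolerance = 1e-12)

  tk <- top_k_assign(rescaled, key10, scheme10$sample, k = 3)
  expect_identical(asg$sample, tk$sample)
  expect_equal(asg$separation, tk$separation, tolerance = 1e-12)
})

test_that("assignments partition events and capture is threshold-monotone", {
  sim <- quick_sim(events_per_sample = 150, seed = 43, doublet_rate = 0.08)
  asg0 <- debarcode_events(sim$events, scheme10,
                           debarcode_params(separation_threshold = 0))
  expect_true(all(is.na(asg0$sample) | asg0$sample %in% scheme10$sample))
  expect_true(all(asg0$separation >= 0 & asg0$separation <= 1))
  counts <- vapply(seq(0, 1, by = 0.05), function(th) {
    sum(!is.na(apply_threshold(asg0, th)$sample))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  # threshold 1.0 keeps only separation-1 events
  expect_identical(counts[length(counts)],
                   sum(asg0$separation == 1 & !is.na(asg0$sample)))
})

test_that("column mismatches are configuration errors", {
  m <- matrix(runif(20), 4, 5)
  expect_error(assign_events(m[, 1:4], scheme10),
               class = "cytobarcode_configuration_error")
  colnames(m) <- rev(default_barcode_channels())
  expect_error(assign_events(m, scheme10),
               class = "cytobarcode_configuration_error")
  expect_error(hierarchical_gate_debarcode(m[, 1:5] + 0, scheme10, 1:4),
               class = "cytobarcode_configuration_error")
})

test_that("Otsu-style channel thresholds split bimodal channels", {
  x <- c(rep(0.1, 40), rep(0.9, 60))
  thr <- estimate_channel_thresholds(cbind(ch = x))
  expect_false(thr$failed[1])
  expect_gt(thr$threshold[1], 0.1)
  expect_lt(thr$threshold[1], 0.9)

  thr2 <- estimate_channel_thresholds(cbind(a = rep(2, 10), b = c(rep(0, 5), rep(1, 5))))
  expect_true(thr2$failed[1])
  expect_identical(thr2$threshold[1], Inf)
  expect_false(thr2$failed[2])
  expect_error(estimate_channel_thresholds(matrix(1, 1, 2)),
               class = "cytobarcode_insufficient_data_error")
})

test_that("hierarchical gating recovers the noiseless truth exactly", {
  sim <- simulate_barcoded_events(
    scheme10, sim_config(events_per_sample = 50, log_cv = 0,
                         doublet_rate = 0, dead_rate = 0, seed = 47))
  raw <- as.matrix(as.data.frame(sim$events))[, 1:5]
  transformed <- arcsinh_transform(raw)
  mid <- mean(asinh(c(2, 200) / 5))
  asg <- hierarchical_gate_debarcode(transformed, scheme10, rep(mid, 5))
  expect_identical(asg$sample, sim$truth$true_sample)

  # an event below threshold everywhere matches no key
  cold <- matrix(0, 2, 5)
  asg2 <- hierarchical_gate_debarcode(cold, scheme10, rep(mid, 5))
  expect_true(all(is.na(asg2$sample)))
})

test_that("auto thresholds reproduce midpoint-oracle gating calls", {
  sim <- quick_sim(events_per_sample = 300, seed = 53,
                   doublet_rate = 0, dead_rate = 0)
  raw <- as.matrix(as.data.frame(sim$events))[, 1:5]
  transformed <- arcsinh_transform(raw)
  auto <- estimate_channel_thresholds(transformed)
  expect_true(all(!auto$failed))
  mid <- mean(asinh(c(2, 200) / 5))
  a_auto <- hierarchical_gate_debarcode(transformed, scheme10, auto)
  a_mid <- hierarchical_gate_debarcode(transformed, scheme10, rep(mid, 5))
  same <- (is.na(a_auto$sample) & is.na(a_mid$sample)) |
    (!is.na(a_auto$sample) & !is.na(a_mid$sample) & a_auto$sample == a_mid$sample)
  expect_gte(mean(same), 0.99)
})

test_that("gating and separation methods agree on well-separated singlets", {
  sim <- quick_sim(events_per_sample = 300, seed = 59,
                   doublet_rate = 0, dead_rate = 0)
  sep <- debarcode_events(sim$events, scheme10)
  gat <- debarcode_events(sim$events, scheme10, method = "gating")
  singlet <- sim$truth$true_sample %in% scheme10$sample
  both <- singlet & !is.na(sep$sample) & !is.na(gat$sample)
  expect_gte(mean(sep$sample[both] == gat$sample[both]), 0.99)
  expect_gte(mean(both[singlet]), 0.95)
})
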