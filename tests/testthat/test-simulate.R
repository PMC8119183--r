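test_that("bookkeeping: counts, truth length, determinism", {
  sim <- simulate_barcoded_events(scheme10,
                                  sim_config(events_per_sample = 1000,
                                             doublet_rate = 0, dead_rate = 0,
                                             seed = 5))
  expect_identical(nrow(sim$events), 10000L)
  expect_identical(nrow(sim$truth), nrow(sim$events))
  expect_true(all(sort(table(sim$truth$true_sample)) == 1000L))

  again <- simulate_barcoded_events(scheme10,
                                    sim_config(events_per_sample = 1000,
                                               doublet_rate = 0, dead_rate = 0,
                                               seed = 5))
  expect_identical(as.data.frame(sim$events), as.data.frame(again$events))
  expect_identical(sim$truth, again$truth)

  other <- simulate_barcoded_events(scheme10,
                                    sim_config(events_per_sample = 1000,
                                               doublet_rate = 0, dead_rate = 0,
                                               seed = 6))
  expect_false(identical(as.data.frame(sim$events), as.data.frame(other$events)))
})

test_that("noiseless limit: top-k channels are exactly the key positives", {
  sim <- simulate_barcoded_events(scheme10,
                                  sim_config(events_per_sample = 20, log_cv = 0,
                                             doublet_rate = 0, dead_rate = 0,
                                             seed = 2))
  key <- scheme_key_matrix(scheme10)
  bc <- as.matrix(as.data.frame(sim$events))[, 1:5]
  for (e in seq_len(nrow(bc))) {
    s <- match(sim$truth$true_sample[e], scheme10$sample)
    expect_identical(sort(order(bc[e, ], decreasing = TRUE)[1:3]),
                     unname(which(key[s, ] == 1L)))
  }
})

test_that("doublet fraction matches the configured rate (binomial oracle)", {
  rate <- 0.1
  sim <- simulate_barcoded_events(scheme10,
                                  sim_config(events_per_sample = 500,
                                             doublet_rate = rate, seed = 9))
  obs <- mean(sim$truth$true_sample == DOUBLET)
  n <- nrow(sim$truth)
  ci <- qnorm(c(0.005, 0.995), mean = rate, sd = sqrt(rate * (1 - rate) / n))
  expect_gt(obs, ci[1])
  expect_lt(obs, ci[2])
  expect_true(all(!sim$truth$is_dead[sim$truth$true_sample == DOUBLET]))
})

test_that("positive-channel medians converge to pos_median", {
  sim <- simulate_barcoded_events(scheme10,
                                  sim_config(events_per_sample = 2000,
                                             doublet_rate = 0, dead_rate = 0,
                                             seed = 13))
  key <- scheme_key_matrix(scheme10)
  bc <- as.matrix(as.data.frame(sim$events))[, 1:5]
  s1 <- sim$truth$true_sample == "BC01"        # key 1,1,1,0,0
  for (j in which(key[1, ] == 1L)) {
    expect_equal(median(bc[s1, j]), 200, tolerance = 0.1)
  }
  for (j in which(key[1, ] == 0L)) {
    expect_equal(median(bc[s1, j]), 2, tolerance = 0.15)
  }
})

test_that("doublets carry the union of two keys: weight >= k + 1", {
  sim <- simulate_barcoded_events(scheme10,
                                  sim_config(events_per_sample = 200, log_cv = 0,
                                             doublet_rate = 0.2, dead_rate = 0,
                                             seed = 21))
  bc <- as.matrix(as.data.frame(sim$events))[, 1:5]
  doub <- sim$truth$true_sample == DOUBLET
  expect_gt(sum(doub), 100)
  # noiseless: positive channels sit at 200 (one cell) or 400 (both); negatives <= 4
  npos <- rowSums(bc[doub, , drop = FALSE] > 100)
  expect_true(all(npos >= 4))
})

test_that("dead singlets keep their sample label and high Pd", {
  sim <- simulate_barcoded_events(scheme10,
                                  sim_config(events_per_sample = 500,
                                             doublet_rate = 0, dead_rate = 0.2,
                                             seed = 31))
  dead <- sim$truth$is_dead
  expect_gt(sum(dead), 500)
  expect_true(all(sim$truth$true_sample[dead] %in% scheme10$sample))
  pd <- sim$events$Pd106Di
  expect_gt(median(pd[dead]), 10 * median(pd[!dead]))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(doublet_rate = 1), class = "cytobarcode_parameter_error")
  expect_error(sim_config(neg_median = 5, pos_median = 2),
               class = "cytobarcode_parameter_error")
  expect_error(sim_config(events_per_sample = -1),
               class = "cytobarcode_parameter_error")
  expect_error(simulate_barcoded_events(scheme10, list()),
               class = "cytobarcode_parameter_error")
})
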