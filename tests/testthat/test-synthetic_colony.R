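test_that("degenerate stage probabilities behave as the rules dictate", {
  # everything succeeds: all detected, no non-detection events
  cfg <- colony_config(20, presence_prob = c(1, 1), availability_prob = 1,
                       identify_prob = 1, observer_prob = 1, cut_prob = 0)
  col <- simulate_colony(cfg)
  expect_true(all(col$detected == 1L))
  tab <- tabulate_nondetection_causes(col)
  expect_equal(tab$total, 0L)
  expect_false(tab$proportions_defined)
  # nobody home: zero detections, every cause is absence
  cfg0 <- colony_config(20, presence_prob = c(0, 0))
  col0 <- simulate_colony(cfg0)
  expect_true(all(col0$detected == 0L))
  expect_true(all(col0$cause == "absence"))
  # only availability can fail: all causes occlusion
  cfga <- colony_config(200, presence_prob = c(1, 1), availability_prob = 0.5,
                        seed = 3)
  taba <- tabulate_nondetection_causes(simulate_colony(cfga),
                                       restrict_to_observed = FALSE)
  expect_equal(unname(taba$proportions["occlusion"]), 1)
})

test_that("detection frequency converges to the stage product", {
  cfg <- colony_config(1e5, presence_prob = 0.8, availability_prob = 0.9,
                       identify_prob = 0.9, observer_prob = 0.9,
                       cut_prob = 0.05, seed = 41)
  col <- simulate_colony(cfg)
  p_implied <- implied_detection(cfg)
  expect_equal(p_implied, 0.95 * 0.8 * 0.9 * 0.9 * 0.9)
  expect_equal(mean(col$detected), p_implied, tolerance = 0.005)
  # per-occasion frequencies within 3 Monte-Carlo SEs of (1-c)*pi_t*a*q*o
  cfg2 <- colony_config(20000, presence_prob = c(0.9, 0.6, 0.8),
                        availability_prob = 0.85, identify_prob = 0.9,
                        observer_prob = 0.95, cut_prob = 0.03, seed = 42)
  col2 <- simulate_colony(cfg2)
  p_t <- implied_detection(cfg2)
  mc_se <- sqrt(p_t * (1 - p_t) / cfg2$n_nests)
  expect_true(all(abs(colMeans(col2$detected) - p_t) < 3 * mc_se))
})

test_that("simulation is reproducible and cause labels are exhaustive", {
  cfg <- colony_config(500, presence_prob = c(0.8, 0.7), availability_prob = 0.8,
                       identify_prob = 0.9, observer_prob = 0.9,
                       cut_prob = 0.05, seed = 9)
  c1 <- simulate_colony(cfg)
  c2 <- simulate_colony(cfg)
  expect_identical(c1$detected, c2$detected)
  expect_identical(c1$cause, c2$cause)
  # detected cells have no cause; non-detections exactly one
  expect_true(all(is.na(c1$cause[c1$detected == 1L])))
  expect_true(all(!is.na(c1$cause[c1$detected == 0L])))
  expect_true(all(c1$cause[!is.na(c1$cause)] %in%
                    c("cut", "absence", "occlusion", "misidentification",
                      "observer_miss")))
})

test_that("cause proportions match the analytic stage-failure mix", {
  cfg <- colony_config(4000, presence_prob = rep(0.85, 3),
                       availability_prob = 0.85, identify_prob = 0.88,
                       observer_prob = 0.93, cut_prob = 0.03, seed = 17)
  col <- simulate_colony(cfg)
  tab <- tabulate_nondetection_causes(col, restrict_to_observed = FALSE)
  expect_equal(sum(tab$proportions), 1, tolerance = 1e-9)
  expect_equal(sum(tab$counts), tab$total)
  analytic <- analytic_cause_props(cfg)
  mc_se <- sqrt(analytic * (1 - analytic) / tab$total)
  expect_true(all(abs(tab$proportions - analytic) < 4 * mc_se))
})

test_that("extract_dataset keeps exactly the nests seen at least once", {
  col <- simulate_colony(colony_config(3, presence_prob = c(1, 1)))
  col$detected <- matrix(c(1L, 0L,  0L, 0L,  1L, 1L), 3, 2, byrow = TRUE)
  ext <- extract_dataset(col, colony_labels = "A")
  expect_equal(nrow(ext$dataset$histories), 2L)
  expect_setequal(unname(history_strings(ext$dataset)), c("10", "11"))
  expect_equal(unname(ext$truth), 3)
  # all-zero colony: empty dataset that downstream fitting refuses
  col0 <- simulate_colony(colony_config(5, presence_prob = c(0, 0)))
  ext0 <- extract_dataset(col0, colony_labels = "B")
  expect_equal(nrow(ext0$dataset$histories), 0L)
  expect_equal(unname(ext0$truth), 5)
  expect_error(fit_closed(ext0$dataset), "empty")
  # observed fraction approaches the session detection probability
  colN <- simulate_colony(colony_config(1000, presence_prob = rep(0.6, 3),
                                        seed = 13))
  extN <- extract_dataset(colN)
  expect_equal(nrow(extN$dataset$histories) / 1000, 1 - 0.4^3,
               tolerance = 0.03)
})

test_that("end-to-end: closed fit recovers the true colony size", {
  set.seed(55)
  hits <- 0L; n_rep <- 40L
  for (r in seq_len(n_rep)) {
    cfg <- colony_config(150, presence_prob = rep(0.75, 3),
                         availability_prob = 0.9, identify_prob = 0.9,
                         observer_prob = 0.99, cut_prob = 0,
                         seed = sample.int(2^31 - 2, 1))
    ext <- extract_dataset(simulate_colony(cfg))
    fit <- fit_closed(ext$dataset, options = list(n_starts = 1))
    if (fit$N_lower <= 150 && fit$N_upper >= 150) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.80)  # nominal 95%; loose bound at 40 replicates
})

test_that("diurnal presence dips where and as much as configured", {
  prof <- list(base = 0.9, dip_depth = 0.3, dip_center = 10, dip_width = 1.5)
  expect_equal(diurnal_presence(10, prof), 0.63)
  expect_equal(diurnal_presence(0, prof), 0.9, tolerance = 1e-6)
  expect_gt(diurnal_presence(7, prof), diurnal_presence(10, prof))
  prof$dip_depth <- 0
  expect_equal(diurnal_presence(c(6, 10, 14), prof), rep(0.9, 3))
  expect_error(diurnal_presence(25, prof), "\\[0, 24\\]")
  expect_error(diurnal_presence(10, list(base = 2, dip_depth = 0.1,
                                         dip_center = 10, dip_width = 1)),
               "base")
})

test_that("peak-session selection follows the max-single-flyover rule", {
  expect_equal(select_peak_session(list(c(40, 55, 50), c(60, 48), c(20, 30, 25))), 2L)
  expect_equal(select_peak_session(list(10, 10)), 1L)
  expect_equal(select_peak_session(list(c(0, 0), c(0, 1))), 2L)
  expect_error(select_peak_session(list()), "non-empty")
})
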