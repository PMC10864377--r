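test_that("the four-model set has the advertised structure", {
  set <- closed_model_set()
  expect_length(set, 4L)
  expect_equal(vapply(set, function(s) s$name, character(1)),
               c("p(.)", "p(.)+colony", "p(t)", "p(t)+colony"))
  # K = (1 or T) + (0 or G-1) + G, here T = 3, G = 2
  d <- capture_dataset(c("101", "110", "011", "111"), c("A", "A", "B", "B"))
  expect_error(negloglik_full(set[[1]], c(0, 0), d), "length 3")
  expect_error(negloglik_full(set[[4]], rep(NA_real_, 6), d), "finite")
  expect_silent(negloglik_full(set[[4]], rep(0.1, 6), d))
})

test_that("negloglik matches a direct transcription of the closed likelihood", {
  d <- capture_dataset(c("111", "110", "101", "011", "100"), rep("A", 5))
  beta <- c(qlogis(0.5), log(2))
  expect_equal(negloglik_full(closed_model_spec(), beta, d),
               -loglik_direct_constant(d, p = 0.5, f0 = 2),
               tolerance = 1e-10)
  # saturated limit: p -> 1, f0 -> 0 drives the negative log-likelihood to 0
  d2 <- capture_dataset(c("11", "11"), c("A", "A"))
  expect_lt(negloglik_full(closed_model_spec(), c(qlogis(0.999999), log(1e-8)), d2),
            1e-4)
  # colony-relabelling symmetry: swapping f0 entries with identical colonies
  d3 <- capture_dataset(c("10", "11", "10", "11"), c("A", "A", "B", "B"))
  sp <- closed_model_spec("constant", "none")
  expect_equal(negloglik_full(sp, c(0.3, log(2), log(5)), d3),
               negloglik_full(sp, c(0.3, log(5), log(2)), d3))
})

test_that("fit_closed attains the grid-oracle maximum on small data", {
  d <- capture_dataset(c("111", "110", "101", "011", "100"), rep("A", 5))
  fit <- fit_closed(d)
  oracle <- grid_oracle_constant(d)
  expect_gte(fit$logLik, oracle$logLik - 1e-6)
  expect_lt(abs(unname(fit$p_hat[1, 1]) - oracle$p), 2e-3)
  expect_lt(abs(unname(fit$f0_hat) - oracle$f0), 2e-2)
})

test_that("saturated data force the boundary MLE with degenerate intervals", {
  d <- capture_dataset(rep("111", 4), rep("A", 4))
  fit <- fit_closed(d)
  expect_equal(unname(fit$N_hat), 4)
  expect_equal(unname(fit$f0_hat), 0)
  expect_equal(unname(fit$N_lower), 4)
  expect_equal(unname(fit$N_upper), 4)
  expect_gt(fit$p_hat[1, 1], 1 - 1e-6)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$K)
})

test_that("identical colonies give a near-zero additive offset", {
  hs <- c("111", "110", "101", "011", "100", "110")
  d <- capture_dataset(c(hs, hs), rep(c("A", "B"), each = 6))
  fit <- fit_closed(d, closed_model_spec("constant", "additive"))
  expect_lt(abs(fit$beta[2]), 1e-3)  # colony offset on the logit scale
  expect_equal(unname(fit$N_hat["A"]), unname(fit$N_hat["B"]), tolerance = 1e-4)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_closed(capture_dataset("1", "A")), "at least 2 occasions")
  empty <- capture_dataset(matrix(integer(), 0, 3), character(),
                           colony_levels = "A")
  expect_error(fit_closed(empty), "empty dataset")
})

test_that("abundance_ci transcribes the lognormal interval on f0", {
  stub <- structure(list(colony = "A", n = c(A = 100), f0_hat = c(A = 10),
                         se_f0 = c(A = 5), f0_boundary = c(A = FALSE),
                         N_hat = c(A = 110)),
                    class = "closed_fit")
  ci <- abundance_ci(stub, level = 0.95)
  z <- 1.959964
  C <- exp(z * sqrt(log(1 + (5 / 10)^2)))
  expect_equal(ci$lower, 100 + 10 / C, tolerance = 1e-6)
  expect_equal(ci$upper, 100 + 10 * C, tolerance = 1e-6)
  # degenerate cases: boundary f0 = 0 and zero-variance f0
  stub$f0_hat <- c(A = 0); stub$f0_boundary <- c(A = TRUE); stub$n <- c(A = 8)
  stub$N_hat <- c(A = 8)
  expect_equal(unlist(abundance_ci(stub)[, c("N_hat", "lower", "upper")]),
               c(N_hat = 8, lower = 8, upper = 8))
  stub$f0_hat <- c(A = 10); stub$f0_boundary <- c(A = FALSE)
  stub$se_f0 <- c(A = 0); stub$N_hat <- c(A = 18)
  expect_equal(unlist(abundance_ci(stub)[, c("lower", "upper")]),
               c(lower = 18, upper = 18))
  expect_error(abundance_ci(stub, level = 1.2), "between 0 and 1")
})

test_that("session_detection follows the complement-product rule", {
  expect_equal(session_detection(c(0.6, 0.6, 0.6)), 0.936)
  expect_equal(session_detection(1), 1)
  expect_equal(session_detection(c(0, 0, 0)), 0)
  expect_error(session_detection(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in each entry and in T
  expect_gt(session_detection(c(0.6, 0.7)), session_detection(c(0.6, 0.6)))
  expect_gt(session_detection(c(0.6, 0.6, 0.6)), session_detection(c(0.6, 0.6)))
})

test_that("rank_models orders by AIC with the documented tie-breaks", {
  set.seed(11)
  det <- cbind(rbinom(300, 1, 0.9), rbinom(300, 1, 0.3), rbinom(300, 1, 0.9))
  d <- capture_dataset(det[rowSums(det) > 0, ], rep("A", sum(rowSums(det) > 0)))
  rk <- rank_models(d, options = list(n_starts = 1))
  expect_equal(nrow(rk$table), 4L)
  expect_true(grepl("p(t)", rk$table$model[1], fixed = TRUE))
  expect_equal(rk$table$dAIC[1], 0)
  expect_true(all(diff(rk$table$AIC) >= 0))
  expect_equal(rk$table$AIC, -2 * rk$table$logLik + 2 * rk$table$K)
})

test_that("constant-p data keep the constant model competitive", {
  set.seed(12)
  hits <- 0L
  for (r in 1:20) {
    d <- simulate_histories(300, 3, 0.6, seed = sample.int(2^31 - 2, 1))
    rk <- rank_models(d, options = list(n_starts = 1))
    da <- rk$table$dAIC[rk$table$model == "p(.)"]
    if (da <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 14L)  # constant model within 2 AIC in most replicates
})

test_that("adding a detection never increases estimated f0 (constant model)", {
  set.seed(33)
  for (r in 1:10) {
    d <- random_tiny_dataset(n = sample(4:10, 1), T = 3)
    h <- d$histories
    zeros <- which(h == 0L)
    if (length(zeros) == 0L) next
    h2 <- h
    h2[sample(zeros, 1)] <- 1L
    d2 <- capture_dataset(h2, rep("A", nrow(h2)))
    f1 <- fit_closed(d)
    f2 <- fit_closed(d2)
    expect_lte(unname(f2$f0_hat), unname(f1$f0_hat) + 1e-4)
  }
})
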