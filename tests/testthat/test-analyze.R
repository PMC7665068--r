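test_that("confusion matrices count frames and normalize by true state", {
  r <- state_confusion(list(c(0L, 1L, 1L, 1L)), list(c(0L, 0L, 1L, 1L)))
  expect_equal(unname(r$per_state), c(0.5, 1.0))
  expect_equal(r$min_state_accuracy, 0.5)
  perfect <- state_confusion(list(0:3), list(0:3))
  expect_equal(unname(perfect$normalized), diag(4))
  expect_equal(perfect$min_state_accuracy, 1)
  # raw diagonal equals a brute-force frame loop on random toys
  set.seed(20)
  for (rep_i in 1:5) {
    truth <- lapply(1:3, function(i) sample(0:3, 30, TRUE))
    pred <- lapply(1:3, function(i) sample(0:3, 30, TRUE))
    r <- state_confusion(pred, truth, s_max = 3)
    expect_true(all(abs(rowSums(r$normalized, na.rm = TRUE) - 1) < 1e-12))
    brute <- sapply(0:3, function(s) {
      sum(mapply(function(p, y) sum(y == s & p == s), pred, truth))
    })
    expect_equal(unname(diag(r$counts)), brute)
    expect_true(all(r$min_state_accuracy <= r$per_state, na.rm = TRUE))
  }
  expect_error(state_confusion(list(1:3), list(1:4)), "misaligned")
})

test_that("bleach-step counting flags non-monotone paths", {
  expect_equal(as.integer(count_bleach_steps(rep(2L, 10))), 0L)
  s <- count_bleach_steps(c(3L, 3L, 2L, 1L, 1L, 0L))
  expect_equal(as.integer(s), 3L)
  expect_false(attr(s, "non_monotone"))
  s2 <- count_bleach_steps(c(2L, 1L, 2L, 1L, 0L))
  expect_equal(as.integer(s2), 2L)
  expect_true(attr(s2, "non_monotone"))
})

test_that("population distributions are exact on constructed cohorts", {
  same <- replicate(8, c(4L, 2L, 0L), simplify = FALSE)
  d <- population_distribution(same)
  expect_equal(unname(d[["4"]]), 1)
  expect_equal(sum(d), 1)
  mixed <- c(replicate(3, c(2L, 0L), simplify = FALSE),
             replicate(7, c(1L, 0L), simplify = FALSE))
  d2 <- population_distribution(mixed)
  expect_equal(unname(d2), c(0, 0.7, 0.3))
  expect_error(population_distribution(list()), "empty")
})

test_that("occupancies sum to one and match chain stationarity", {
  expect_equal(unname(state_occupancy(list(rep(3L, 9)))), c(0, 0, 0, 1))
  expect_equal(unname(state_occupancy(list(c(0L, 0L, 1L, 1L)))), c(0.5, 0.5))
  A <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  paths <- lapply(1:30, function(i) sim_dynamic_path(1, A, 2000,
                                                     seed = 100 + i))
  occ <- state_occupancy(paths)
  pi0 <- stationary_distribution(A)
  expect_true(all(abs(occ - pi0) < 3 * sqrt(pi0 * (1 - pi0) / 3000)))
  expect_lt(abs(sum(occ) - 1), 1e-9)
})

test_that("transition rates recover the generating chain", {
  expect_equal(unname(transition_rates(list(rep(1L, 20)),
                                       0.1)["1", "0"]), 0)
  alt <- rep(c(0L, 1L), 50)
  r <- transition_rates(list(alt), 0.1)
  expect_equal(unname(r["0", "1"]), 10)
  expect_equal(unname(r["1", "0"]), 10)
  # generator recovery: per-frame p = 0.147 at 0.1 s -> 1.47 per second
  A <- rbind(c(1 - 0.147, 0.147), c(0.128, 1 - 0.128))
  paths <- lapply(1:40, function(i) sim_dynamic_path(1, A, 1000,
                                                     seed = 200 + i))
  r2 <- transition_rates(paths, 0.1)
  n0 <- sum(vapply(paths, function(p) sum(p[-length(p)] == 0), 1))
  se01 <- sqrt(0.147 * (1 - 0.147) / n0) / 0.1
  expect_lt(abs(r2["0", "1"] - 1.47), 3 * se01)
  # diagonal completes the row to 1/frame_interval
  expect_equal(unname(rowSums(r2)), c(10, 10))
})

test_that("dwell durations censor boundary runs", {
  expect_equal(dwell_durations(list(c(1L, 2L, 2L, 2L, 1L)), 2L, 0.1), 0.3)
  expect_equal(dwell_durations(list(c(1L, 0L, 1L)), 5L, 0.1), numeric(0))
  expect_equal(dwell_durations(list(c(2L, 2L, 1L)), 2L, 0.1), numeric(0))
  expect_equal(dwell_durations(list(c(1L, 2L, 2L)), 2L, 0.1), numeric(0))
})

test_that("the exponential dwell fit is the sample mean", {
  expect_equal(fit_dwell_exp(rep(0.5, 6)), 0.5)
  expect_error(fit_dwell_exp(c(1, 2)), "insufficient")
  set.seed(30)
  d <- rexp(4e4, rate = 1 / 0.54)
  expect_lt(abs(fit_dwell_exp(d) - 0.54) / 0.54, 0.02)
  expect_equal(fit_dwell_exp(2 * d), 2 * fit_dwell_exp(d))
})

test_that("bootstrap resampling has the stated subset size and SD rules", {
  expect_equal(bootstrap_stat(as.list(1:2224), length, seed = 1)$subset_size,
               1601L)
  const <- bootstrap_stat(as.list(1:50), function(x) 7, seed = 2)
  expect_equal(const$sd, 0)
  full <- bootstrap_stat(as.list(1:40), function(x) mean(unlist(x)),
                         fraction = 1, seed = 3)
  expect_equal(full$sd, 0)
  expect_equal(length(full$values), 5L)
  expect_error(bootstrap_stat(as.list(1:10), length, replicates = 1),
               "replicates")
})

test_that("dynamics summaries assemble occupancy, rates and dwells", {
  paths <- lapply(1:20, function(i)
    sim_dynamic_path(2, rbind(c(0.8, 0.2, 0), c(0.1, 0.8, 0.1),
                              c(0, 0.3, 0.7)), 400, seed = 300 + i))
  s <- dynamics_summary(paths, frame_interval = 0.1)
  expect_s3_class(s, "dynamics_summary")
  expect_lt(abs(sum(s$occupancy) - 1), 1e-9)
  offdiag <- s$rates[!is.na(s$rates)]
  expect_true(all(s$rates[upper.tri(s$rates)] >= 0, na.rm = TRUE))
  expect_true(is.finite(s$dwell_tau[["1"]]))
})
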