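test_that("bleach paths honour trivial limits and argument checks", {
  p <- sim_bleach_path(5, 0, 10, seed = 1)
  expect_equal(as.integer(p), rep(5L, 10))
  expect_equal(as.integer(sim_bleach_path(0, 0.3, 8, s_max = 4, seed = 1)),
               rep(0L, 8))
  expect_true(all(diff(sim_bleach_path(8, 0.1, 200, seed = 2)) <= 0))
  expect_error(sim_bleach_path(7, 0.1, 10, s_max = 5), "s_max")
  expect_error(sim_bleach_path(2, 1.5, 10), "bleach_rate")
})

test_that("time of the first bleaching event matches the geometric law", {
  # with 3 fluorophores at rate 0.05 the per-frame survival is 0.95^3,
  # so the first drop is geometric with mean 1/(1-0.95^3) = 7.01 frames
  set.seed(11)
  first_drop <- replicate(4000, {
    p <- sim_bleach_path(3, 0.05, 60)
    which(diff(p) < 0)[1]
  })
  first_drop <- first_drop[!is.na(first_drop)]
  m_theory <- 1 / (1 - 0.95^3)
  se <- sd(first_drop) / sqrt(length(first_drop))
  expect_lt(abs(mean(first_drop) - m_theory), 3 * se + 0.05)
})

test_that("dynamic paths follow the chain and its stationary distribution", {
  A <- diag(3)
  expect_equal(length(unique(sim_dynamic_path(2, A, 50, init = 1,
                                              seed = 1))), 1L)
  expect_error(sim_dynamic_path(2, matrix(1, 3, 3), 10), "sum to 1")
  # occupancy of an arbitrary 3-state chain matches the left eigenvector
  A <- rbind(c(0.90, 0.08, 0.02),
             c(0.05, 0.90, 0.05),
             c(0.10, 0.20, 0.70))
  pi_oracle <- stationary_distribution(A)
  p <- sim_dynamic_path(2, A, 1e5, seed = 42)
  occ <- tabulate(p + 1L, 3) / length(p)
  # 3 SE with an effective sample size deflated by chain autocorrelation
  se <- sqrt(pi_oracle * (1 - pi_oracle) / (length(p) / 20))
  expect_true(all(abs(occ - pi_oracle) < 3 * se))
  # symmetric 2-state chain at p = 0.5 is iid uniform
  A2 <- matrix(0.5, 2, 2)
  p2 <- sim_dynamic_path(1, A2, 1e5, seed = 7)
  expect_lt(abs(mean(p2) - 0.5), 3 * 0.5 / sqrt(1e5))
})

test_that("blinking only darkens, keeps labels, and hits the renewal rate", {
  nm0 <- noise_model(blink_rate = 0)
  path <- sim_bleach_path(6, 0.05, 100, seed = 3)
  expect_equal(apply_blinking(path, nm0, seed = 1), as.integer(path))
  expect_equal(apply_blinking(state_path(rep(0L, 50), s_max = 2),
                              noise_model(blink_rate = 0.2), seed = 1),
               rep(0L, 50))
  # long constant path at count 1: dark fraction ~ r*d/(1 + r*d)
  nm <- noise_model(blink_rate = 0.05, blink_mean_duration = 3)
  const1 <- state_path(rep(1L, 4e4), s_max = 1)
  em <- apply_blinking(const1, nm, seed = 9)
  expect_true(all(em <= 1))
  dark_theory <- 0.05 * 3 / (1 + 0.05 * 3)
  expect_lt(abs(mean(em == 0) - dark_theory), 0.02)
})

test_that("trace rendering reproduces the noise budget", {
  nm_clean <- noise_model(unit_intensity = 100, gaussian_sd = 0,
                          shot_noise = FALSE, blink_rate = 0)
  expect_equal(render_trace(c(2L, 1L, 0L), nm_clean, seed = 1),
               c(200, 100, 0))
  # shot only: Var = n * unit
  nm_shot <- noise_model(unit_intensity = 100, shot_noise = TRUE,
                         blink_rate = 0)
  x <- render_trace(rep(4L, 1e5), nm_shot, seed = 2)
  expect_lt(abs(var(x) / 400 - 1), 0.05)
  # shot + gaussian: variances add
  nm_both <- noise_model(unit_intensity = 100, gaussian_sd = 30,
                         shot_noise = TRUE, blink_rate = 0)
  y <- render_trace(rep(4L, 1e5), nm_both, seed = 3)
  expect_lt(abs(var(y) / (400 + 900) - 1), 0.05)
})

test_that("aSNR follows its definition and is scale invariant", {
  expect_equal(compute_asnr(c(0, 1), c(1, 1)), 1)
  expect_equal(compute_asnr(c(2, 6, 10), c(1, 1, 1)), 4)
  expect_equal(compute_asnr(c(5, 5, 5), c(2, 2, 2)), 0)
  expect_error(compute_asnr(3, 1), ">= 2 states")
  mu <- c(0, 90, 210, 330); sds <- c(10, 14, 17, 21)
  expect_equal(compute_asnr(7 * mu, 7 * sds), compute_asnr(mu, sds))
})

test_that("noise calibration inverts the aSNR model", {
  # closed form with shot noise off
  expect_equal(calibrate_noise(2.5, unit_intensity = 1, s_max = 10,
                               shot_noise = FALSE), 1 / 2.5)
  # round trip within 1% across the working range
  for (a in c(0.5, 1.04, 2.98, 5)) {
    sg <- calibrate_noise(a, unit_intensity = 1000, s_max = 10)
    got <- dgntrace:::asnr_model(sg, 1000, 10, TRUE)
    expect_lt(abs(got - a) / a, 0.01)
  }
  # targets above the shot-noise floor are rejected
  floor_a <- dgntrace:::asnr_model(0, 1000, 10, TRUE)
  expect_error(calibrate_noise(floor_a * 1.01, 1000, 10), "infeasible")
})

test_that("synthesized datasets are reproducible and correctly partitioned", {
  d1 <- synthesize_dataset("photobleach", n_traces = 20, n_frames = 60,
                           target_asnr = 3, seed = 5)
  d2 <- synthesize_dataset("photobleach", n_traces = 20, n_frames = 60,
                           target_asnr = 3, seed = 5)
  expect_identical(d1, d2)
  tags <- vapply(d1$records, `[[`, "", "split")
  expect_equal(as.integer(table(factor(tags, c("train", "val", "test")))),
               c(14L, 3L, 3L))
  # equal mix over 10 initial states -> exactly 10% of traces per state
  d3 <- synthesize_dataset("photobleach", n_traces = 1000, n_frames = 3,
                           target_asnr = 3, bleach_rate = 0, seed = 6)
  inits <- vapply(d3$records, function(r) r$states[1L], 1L)
  expect_equal(as.integer(table(factor(inits, 1:10))), rep(100L, 10))
  expect_lt(abs(d1$achieved_asnr - 3) / 3, 0.35)
})

test_that("unit intensity is recovered by the mixture fit", {
  expect_equal(fit_unit_intensity(rep(55.5, 40), 2), 55.5)
  set.seed(8)
  one <- rnorm(1e4, 100, 10)
  expect_lt(abs(fit_unit_intensity(one, 1) - 100), 3 * 10 / sqrt(1e4) + 0.2)
  two <- c(rnorm(2000, 100, 8), rnorm(2000, 200, 8))
  expect_lt(abs(fit_unit_intensity(two, 2) - 100) / 100, 0.02)
  expect_error(fit_unit_intensity(rnorm(5), 2), "at least")
})
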