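test_that("posteriors are simplex rows of the input length", {
  m <- small_pb_model()
  for (T_ in c(2L, 50L, 400L)) {
    x <- rnorm(T_, 2000, 300)
    pm <- dgn_posterior(m$fit, x)
    expect_equal(dim(pm), c(T_, 11L))
    expect_true(all(abs(rowSums(pm) - 1) < 1e-6))
    expect_true(all(pm >= 0))
  }
  expect_error(dgn_posterior(m$fit, c(1, NA, 3)), "finite")
  expect_error(dgn_posterior(m$fit, 5), ">= 2")
})

test_that("forward passes are deterministic", {
  m <- small_pb_model()
  x <- m$train$records[[2]]$intensities
  expect_identical(dgn_posterior(m$fit, x), dgn_posterior(m$fit, x))
  pm <- dgn_posterior(m$fit, x)
  expect_identical(dgn_generate(m$fit, pm), dgn_generate(m$fit, pm))
})

test_that("argmax decoding breaks ties toward the lower state", {
  pm <- rbind(c(0.5, 0.5, 0), c(0.2, 0.2, 0.6), c(1, 0, 0))
  expect_equal(dgntrace:::posterior_to_states(pm), c(0L, 2L, 0L))
  onehot <- diag(4)[c(4, 2, 1, 3), ]
  expect_equal(dgntrace:::posterior_to_states(onehot), c(3L, 1L, 0L, 2L))
})

test_that("predicted paths keep trace length and respect the state range", {
  m <- small_pb_model()
  traces <- lapply(m$train$records[1:5], `[[`, "intensities")
  paths <- predict(m$fit, traces, type = "states")
  expect_equal(vapply(paths, length, 1L),
               vapply(traces, length, 1L))
  expect_true(all(unlist(paths) %in% 0:10))
})

test_that("a trained model decodes staircase traces", {
  m <- small_pb_model()
  u <- m$fit$unit_intensity
  truth <- rep(c(3L, 2L, 1L, 0L), each = 100)  # training trace length
  # in-distribution: the staircase rendered with the training noise model
  nm <- do.call(noise_model, m$train$noise)
  noisy <- render_trace(truth, nm, seed = 17)
  expect_gte(mean(predict(m$fit, noisy)[[1]] == truth), 0.9)
  # noiseless input is off-distribution; plateaus must still dominate even
  # though transition placement smears by a few frames
  path <- predict(m$fit, truth * u)[[1]]
  expect_gte(mean(path == truth), 0.75)
  for (s_lv in 0:3)
    expect_true(any(path[truth == s_lv] == s_lv))
})

test_that("the generator reconstructs held-out traces near the noise floor", {
  m <- small_pb_model()
  val <- dataset_split(m$train, "val")
  u <- m$fit$unit_intensity
  noise_var <- m$train$noise$gaussian_sd^2 +
    mean(unlist(lapply(val$records, `[[`, "states"))) * u
  mses <- vapply(val$records[1:12], function(r) {
    pm <- dgn_posterior(m$fit, r$intensities)
    rec <- dgn_generate(m$fit, pm, prev_values = r$intensities)
    mean((rec - r$intensities)^2)
  }, numeric(1))
  expect_lt(mean(mses), 1.5 * noise_var)
})

test_that("a constant one-hot posterior generates a flat trace at the level", {
  m <- small_pb_model()
  u <- m$fit$unit_intensity
  for (s in c(4L, 8L)) {
    pm <- matrix(0, 60, 11); pm[, s + 1L] <- 1
    out <- dgn_generate(m$fit, pm)
    # steady-state level away from the sequence edges
    mid <- out[10:50]
    expect_lt(abs(mean(mid) - s * u) / (s * u), 0.10)
  }
})

test_that("fits with the same seed are identical, different seeds differ", {
  ds <- synthesize_dataset("photobleach", s_max = 4, n_traces = 40,
                           n_frames = 60, target_asnr = 4, seed = 61)
  a <- dgn(ds, epochs = 2, seed = 9)
  b <- dgn(ds, epochs = 2, seed = 9)
  c <- dgn(ds, epochs = 2, seed = 10)
  expect_identical(a$history, b$history)
  expect_identical(coef(a), coef(b))
  expect_false(identical(a$history$train_loss, c$history$train_loss))
})

test_that("residuals and plot method run on a fitted model", {
  m <- small_pb_model()
  r <- residuals(m$fit, m$train$records[[1]]$intensities)
  expect_equal(length(r[[1]]), length(m$train$records[[1]]$intensities))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(m$fit))
  expect_output(print(m$fit), "Discriminator-generator")
  expect_output(summary(m$fit), "Last epochs")
})
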