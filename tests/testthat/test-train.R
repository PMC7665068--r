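test_that("reconstruction loss matches the quadratic definition", {
  x <- c(1.2, -0.5, 3)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x + 0.7, x), 0.7^2 / 2)
  expect_equal(reconstruction_loss(4, 2), 2)
  expect_error(reconstruction_loss(1:3, 1:4), "equal length")
})

test_that("hidden-space cross-entropy has its closed forms and floor", {
  onehot <- diag(10)[c(3, 7, 1), ]
  expect_equal(hidden_loss(onehot, c(2L, 6L, 0L)), 0)
  unif <- matrix(1 / 10, 4, 10)
  expect_equal(hidden_loss(unif, c(0L, 3L, 9L, 5L)), log(10))
  zero <- matrix(rep(c(1, 0), c(1, 9)), 1, 10)
  expect_equal(hidden_loss(zero, 9L), -log(1e-12))
  expect_error(hidden_loss(unif, c(1L, 2L)), "align")
})

test_that("the annealing weight starts at 0.5 and decays exponentially", {
  expect_equal(blend_weight(0, 60), 0.5)
  expect_equal(blend_weight(60, 60), 0.5 * exp(-2))
  ks <- 0:30
  expect_true(all(diff(blend_weight(ks, 30)) < 0))
})

test_that("weight thresholding clamps into [-c, c]", {
  p <- list(a = matrix(c(-3, 0.2, 1.7, 0.9), 2), b = c(5, -0.4))
  cl <- clip_weights(p, 1)
  expect_equal(cl$a, matrix(c(-1, 0.2, 1, 0.9), 2))
  expect_equal(cl$b, c(1, -0.4))
  expect_identical(clip_weights(p, 1e9), lapply(p, function(w) w))
  expect_true(all(vapply(clip_weights(p, 0.3),
                         function(w) max(abs(w)) <= 0.3, TRUE)))
  expect_error(clip_weights(p, -1), "> 0")
})

test_that("training is seeded, recorded per epoch, and inert at zero lr", {
  ds <- synthesize_dataset("photobleach", s_max = 4, n_traces = 48,
                           n_frames = 80, target_asnr = 4, seed = 31)
  f0 <- dgn(ds, epochs = 2, learning_rate = 0, optimizer = "sgd",
            momentum = 0, l2 = 0, select = "last", seed = 2)
  f1 <- dgn(ds, epochs = 2, learning_rate = 0, optimizer = "sgd",
            momentum = 0, l2 = 0, select = "last", seed = 2)
  expect_equal(nrow(f0$history), 2L)
  expect_identical(f0$history, f1$history)
  # lr = 0: weights never move from their (seeded) initialization
  f2 <- dgn(ds, epochs = 1, learning_rate = 0, optimizer = "sgd",
            momentum = 0, l2 = 0, select = "last", seed = 2)
  expect_equal(f0$params, f2$params)
  expect_error(dgn(dataset_split(ds, "test"), epochs = 1), "empty training")
})

test_that("a heavy L2 penalty shrinks the weights", {
  ds <- synthesize_dataset("photobleach", s_max = 4, n_traces = 48,
                           n_frames = 80, target_asnr = 4, seed = 32)
  f_small <- dgn(ds, epochs = 2, optimizer = "sgd", learning_rate = 0.01,
                 momentum = 0, l2 = 0, select = "last", seed = 5)
  f_big <- dgn(ds, epochs = 2, optimizer = "sgd", learning_rate = 0.01,
               momentum = 0, l2 = 5, select = "last", seed = 5)
  norm_of <- function(f) mean(abs(unlist(f$params)))
  expect_lt(norm_of(f_big), norm_of(f_small))
})

test_that("training loss trends down on the reference seeded run", {
  m <- small_pb_model()
  h <- m$fit$history
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
  expect_equal(h$alpha, 0.5 * exp(-2 * (h$epoch - 1) / nrow(h)))
})
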