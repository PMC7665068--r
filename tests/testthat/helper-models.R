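# Shared fixtures: trained models are expensive, so they are built lazily
# once per test session and cached in this environment.
.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# small, fast photobleach model at high aSNR for functional checks
small_pb_model <- function() {
  cached("small_pb", function() {
    train <- synthesize_dataset("photobleach", n_traces = 500,
                                target_asnr = 4.74,
                                state_mix = c(1:9, 25) / 70,
                                split = c(0.85, 0.15, 0), seed = 401)
    fit <- dgn(train, epochs = 30, seed = 1)
    list(fit = fit, train = train)
  })
}

# photobleach model trained across aSNR levels, shared by the scaled-down
# reproduction checks
mixed_pb_model <- function() {
  cached("mixed_pb", function() {
    levels <- c(1.04, 1.35, 1.69, 2.33, 2.98, 3.69, 4.74)
    parts <- lapply(seq_along(levels), function(i)
      synthesize_dataset("photobleach", n_traces = 160,
                         target_asnr = levels[i],
                         state_mix = c(1:9, 25) / 70,
                         split = c(0.85, 0.15, 0), seed = 500 + i))
    train <- merge_trace_datasets(parts)
    dgn(train, epochs = 40, seed = 7)
  })
}

dynamic_model <- function() {
  cached("dyn", function() {
    train <- synthesize_dataset("dynamic", s_max = 5, n_traces = 700,
                                target_asnr = 2.44,
                                split = c(0.85, 0.15, 0), seed = 601)
    dgn(train, epochs = 20, seed = 3)
  })
}

# evaluate a model's frame-wise confusion on a fresh single-level test set
eval_min_state <- function(fit, target_asnr, n = 400, states = NULL,
                           seed = 900, mode = "photobleach", s_max = 10,
                           frac_initial = NULL, exclude_zero_step = FALSE) {
  test <- synthesize_dataset(mode, s_max = s_max, n_traces = n,
                             target_asnr = target_asnr, split = c(0, 0, 1),
                             seed = seed, frac_initial = frac_initial,
                             exclude_zero_step = exclude_zero_step)
  test <- dataset_split(test, "test")
  pred <- predict(fit, test, type = "states")
  truth <- lapply(test$records, `[[`, "states")
  rep <- state_confusion(pred, truth, s_max = s_max)
  list(report = rep, pred = pred, truth = truth, records = test$records,
       min_acc = min_state_accuracy(rep, states = states))
}
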