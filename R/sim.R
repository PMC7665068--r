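#' Construct a hidden state path
#'
#' A state path is the per-frame sequence of nominal fluorophore counts
#' underlying a fluorescence trace; 0 is the fully bleached background.
#'
#' @param states integer vector of per-frame counts.
#' @param s_max maximum state cardinality (counts live in `0:s_max`).
#' @param frame_interval seconds per frame.
#' @return An integer vector of class `"state_path"` with attributes
#'   `s_max` and `frame_interval`.
#' @export
state_path <- function(states, s_max = max(states), frame_interval = 0.1) {
  states <- as.integer(states)
  if (length(states) < 2L) stop("a state path needs at least 2 frames")
  if (anyNA(states) || any(states < 0L) || any(states > s_max))
    stop("states must lie in [0, s_max]")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(states, s_max = as.integer(s_max),
            frame_interval = frame_interval, class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat("<state_path> ", length(x), " frames, s_max = ", attr(x, "s_max"),
      ", ", attr(x, "frame_interval"), " s/frame\n", sep = "")
  print(as.integer(x))
  invisible(x)
}

#' Noise model for trace synthesis
#'
#' Describes the three noise sources corrupting a synthetic fluorescence
#' trace: Poisson shot noise on the emitted photon count, additive Gaussian
#' read noise, and reversible per-fluorophore blinking (dark excursions).
#'
#' @param unit_intensity mean fluorescence per emitting fluorophore
#'   (arbitrary units, > 0).
#' @param gaussian_sd standard deviation of the additive Gaussian noise.
#' @param shot_noise logical; apply Poisson shot noise to the emission.
#' @param blink_rate per-fluorophore, per-frame probability of entering a
#'   dark state.
#' @param blink_mean_duration mean dark-state dwell in frames (geometric).
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(unit_intensity = 1000, gaussian_sd = 0,
                        shot_noise = TRUE, blink_rate = 0.003,
                        blink_mean_duration = 2) {
  if (unit_intensity <= 0) stop("unit_intensity must be > 0")
  if (gaussian_sd < 0) stop("gaussian_sd must be >= 0")
  if (blink_rate < 0 || blink_rate >= 1) stop("blink_rate must be in [0, 1)")
  if (blink_mean_duration < 1) stop("blink_mean_duration must be >= 1 frame")
  structure(list(unit_intensity = unit_intensity, gaussian_sd = gaussian_sd,
                 shot_noise = isTRUE(shot_noise), blink_rate = blink_rate,
                 blink_mean_duration = blink_mean_duration),
            class = "noise_model")
}

#' Simulate a photobleaching state path
#'
#' Each of `n_init` fluorophores bleaches independently with probability
#' `bleach_rate` per frame, giving a stepwise non-increasing count path
#' whose state-n dwell is geometric with mean `1 / (n * bleach_rate)`.
#'
#' @param n_init initial fluorophore count.
#' @param bleach_rate per-fluorophore, per-frame bleaching probability.
#' @param n_frames number of frames.
#' @param s_max maximum state cardinality (defaults to `n_init`).
#' @param frame_interval seconds per frame.
#' @param seed optional integer; when given, the path is a pure function of
#'   the arguments and the caller's RNG state is untouched.
#' @return A [state_path()].
#' @export
sim_bleach_path <- function(n_init, bleach_rate, n_frames,
                            s_max = max(n_init, 1L), frame_interval = 0.1,
                            seed = NULL) {
  if (n_init < 0 || n_init > s_max)
    stop("n_init must lie in [0, s_max]")
  if (bleach_rate < 0 || bleach_rate > 1)
    stop("bleach_rate must lie in [0, 1]")
  with_seed(seed, {
    states <- integer(n_frames)
    n <- as.integer(n_init)
    for (t in seq_len(n_frames)) {
      states[t] <- n
      if (n > 0L && bleach_rate > 0)
        n <- n - rbinom(1L, n, bleach_rate)
    }
    state_path(states, s_max = s_max, frame_interval = frame_interval)
  })
}

#' Simulate a state-switching (dynamics) path
#'
#' Samples a first-order Markov chain over states `0:s_max` from a
#' row-stochastic per-frame transition matrix. This is the generating
#' process for association/dissociation dynamics, where the count moves up
#' and down rather than monotonically down.
#'
#' @param s_max maximum state cardinality; `trans` is
#'   `(s_max+1) x (s_max+1)`.
#' @param trans row-stochastic per-frame transition matrix.
#' @param n_frames number of frames.
#' @param init initial state (single integer), a probability vector over
#'   `0:s_max`, or `NULL` to start from the chain's stationary distribution.
#' @param frame_interval seconds per frame.
#' @param seed optional integer seed.
#' @return A [state_path()].
#' @export
sim_dynamic_path <- function(s_max, trans, n_frames, init = NULL,
                             frame_interval = 0.1, seed = NULL) {
  S1 <- s_max + 1L
  trans <- as.matrix(trans)
  if (!all(dim(trans) == S1))
    stop("trans must be (s_max+1) x (s_max+1)")
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
    stop("trans rows must be non-negative and sum to 1")
  p0 <- if (is.null(init)) {
    stationary_distribution(trans)
  } else if (length(init) == 1L) {
    p <- numeric(S1); p[init + 1L] <- 1; p
  } else {
    if (length(init) != S1 || any(init < 0)) stop("bad init distribution")
    init / sum(init)
  }
  with_seed(seed, {
    states <- integer(n_frames)
    s <- sample.int(S1, 1L, prob = p0) - 1L
    for (t in seq_len(n_frames)) {
      states[t] <- s
      s <- sample.int(S1, 1L, prob = trans[s + 1L, ]) - 1L
    }
    state_path(states, s_max = s_max, frame_interval = frame_interval)
  })
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector for eigenvalue 1, normalized to a probability vector.
#' @param trans row-stochastic matrix.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  k <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, k]))
  v / sum(v)
}

#' Apply fluorophore blinking to a nominal state path
#'
#' Each emitting fluorophore enters a reversible dark state with
#' probability `model$blink_rate` per frame and recovers with probability
#' `1 / model$blink_mean_duration` per frame (geometric dark dwell). The
#' nominal path is unchanged: ground-truth labels ignore blinks, since the
#' network is scored on rejecting them. When the nominal count drops
#' (bleaching), the removed fluorophores are drawn uniformly, so dark ones
#' can be the ones that bleach.
#'
#' @param path a [state_path()] of nominal counts.
#' @param model a [noise_model()].
#' @param seed optional integer seed.
#' @return Integer vector of per-frame emitting counts, `<= path` everywhere.
#' @export
apply_blinking <- function(path, model, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  nominal <- as.integer(path)
  r <- model$blink_rate
  if (r == 0) return(nominal)
  q <- 1 / model$blink_mean_duration
  with_seed(seed, {
    emitting <- integer(length(nominal))
    n_dark <- 0L
    n_prev <- nominal[1L]
    for (t in seq_along(nominal)) {
      n <- nominal[t]
      if (n < n_prev && n_dark > 0L) {
        # bleached fluorophores drawn uniformly from the previous population
        gone_dark <- rhyper(1L, n_dark, n_prev - n_dark, n_prev - n)
        n_dark <- n_dark - gone_dark
      } else if (n > n_prev) {
        # arrivals (dynamics mode) come in bright
      }
      n_dark <- min(n_dark, n)
      n_dark <- n_dark - rbinom(1L, n_dark, q)        # recoveries
      n_dark <- n_dark + rbinom(1L, n - n_dark, r)    # new dark excursions
      emitting[t] <- n - n_dark
      n_prev <- n
    }
    emitting
  })
}

#' Render a noisy fluorescence trace from emitting counts
#'
#' Per frame, the intensity is a Poisson draw with mean
#' `count * unit_intensity` (or the exact product when shot noise is off)
#' plus additive Gaussian noise. Values are not clipped at zero, as in
#' baseline-subtracted EMCCD data.
#'
#' @param emitting integer vector of per-frame emitting counts.
#' @param model a [noise_model()].
#' @param seed optional integer seed.
#' @return Numeric vector of intensities.
#' @export
render_trace <- function(emitting, model, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  if (any(emitting < 0)) stop("emitting counts must be >= 0")
  with_seed(seed, {
    mean_i <- as.numeric(emitting) * model$unit_intensity
    x <- if (model$shot_noise) rpois(length(mean_i), mean_i) else mean_i
    if (model$gaussian_sd > 0)
      x <- x + rnorm(length(x), 0, model$gaussian_sd)
    as.numeric(x)
  })
}

#' Adjusted signal-to-noise ratio (aSNR)
#'
#' The mean over adjacent fluorescence states of twice the step height
#' divided by the sum of the two states' standard deviations:
#' `mean_i 2 (mu[i+1] - mu[i]) / (sd[i] + sd[i+1])`.
#'
#' @param means per-state mean intensities, sorted ascending.
#' @param sds per-state intensity standard deviations, all > 0.
#' @return The aSNR (dimensionless).
#' @export
compute_asnr <- function(means, sds) {
  n <- length(means)
  if (n < 2L || length(sds) != n)
    stop("need >= 2 states with matching means and sds")
  if (is.unsorted(means)) stop("means must be sorted ascending")
  if (any(sds <= 0)) stop("sds must be > 0")
  mean(2 * diff(means) / (sds[-n] + sds[-1L]))
}

# model-implied aSNR for equally spaced state means n * unit with
# per-state SD sqrt(n * unit * shot + sigma^2)
asnr_model <- function(sigma, unit_intensity, s_max, shot_noise) {
  n <- 0:s_max
  mu <- n * unit_intensity
  sds <- sqrt(n * unit_intensity * as.numeric(shot_noise) + sigma^2)
  if (any(sds == 0)) sds[sds == 0] <- 1e-12
  compute_asnr(mu, sds)
}

#' Calibrate Gaussian noise for a target aSNR
#'
#' Solves for the additive Gaussian SD that makes the model-implied aSNR of
#' equally spaced state means `n * unit_intensity` (with shot-noise variance
#' `n * unit_intensity` when enabled) equal the target, by monotone
#' bisection. With shot noise off the closed form
#' `sigma = unit_intensity / target` is returned.
#'
#' @param target_asnr desired aSNR (> 0).
#' @param unit_intensity mean intensity per fluorophore.
#' @param s_max maximum state cardinality used for the state grid.
#' @param shot_noise logical; include shot-noise variance.
#' @return The Gaussian SD achieving the target within 1 %.
#' @export
calibrate_noise <- function(target_asnr, unit_intensity = 1000, s_max = 10,
                            shot_noise = TRUE) {
  if (target_asnr <= 0) stop("target_asnr must be > 0")
  if (!shot_noise) return(unit_intensity / target_asnr)
  floor_asnr <- asnr_model(0, unit_intensity, s_max, TRUE)
  if (target_asnr >= floor_asnr)
    stop("infeasible: target aSNR ", target_asnr,
         " is at or above the shot-noise floor ", signif(floor_asnr, 4))
  hi <- unit_intensity / target_asnr
  while (asnr_model(hi, unit_intensity, s_max, TRUE) > target_asnr)
    hi <- hi * 2
  u <- stats::uniroot(function(s)
    asnr_model(s, unit_intensity, s_max, TRUE) - target_asnr,
    lower = 0, upper = hi, tol = 1e-10 * unit_intensity)
  u$root
}

# largest-remainder apportionment of n into fractions
largest_remainder <- function(n, fracs) {
  if (abs(sum(fracs) - 1) > 1e-8) stop("split fractions must sum to 1")
  raw <- n * fracs
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# default nearest-neighbour switching matrix over states 0:s_max for the
# dynamics mode: states 1:s_max communicate, state 0 is unused.
default_dynamic_trans <- function(s_max, p_switch = 0.15) {
  S1 <- s_max + 1L
  A <- matrix(0, S1, S1)
  A[1L, 1L] <- 1
  for (s in 1:s_max) {
    i <- s + 1L
    nb <- c(if (s > 1L) s - 1L, if (s < s_max) s + 1L)
    A[i, i] <- 1 - p_switch
    A[i, nb + 1L] <- p_switch / length(nb)
  }
  A
}

#' Synthesize a labelled trace dataset
#'
#' Generates ground-truth state paths (photobleaching or switching
#' dynamics), applies blinking, renders noisy traces calibrated to a target
#' aSNR, and partitions the records into train/validation/test subsets by
#' largest-remainder rounding. The result is a pure function of the
#' arguments including `seed`.
#'
#' @param mode `"photobleach"` (stepwise-decreasing paths) or `"dynamic"`
#'   (state-switching paths over states `1:s_max`).
#' @param s_max maximum state cardinality (classifier head has `s_max + 1`
#'   classes including background 0).
#' @param n_traces number of traces.
#' @param n_frames frames per trace.
#' @param target_asnr aSNR the Gaussian noise is calibrated to.
#' @param state_mix initial-state proportions over `1:s_max` (photobleach
#'   initial counts, or dynamic start states); default equal.
#' @param split train/validation/test fractions summing to 1.
#' @param seed integer seed; same seed gives a bit-identical dataset.
#' @param unit_intensity,shot_noise,blink_rate,blink_mean_duration noise
#'   model settings (see [noise_model()]).
#' @param bleach_rate per-fluorophore per-frame bleaching probability
#'   (photobleach mode).
#' @param trans per-frame transition matrix for dynamic mode; default
#'   nearest-neighbour switching with total leave probability 0.15.
#' @param frame_interval seconds per frame.
#' @param exclude_zero_step drop-and-redraw traces whose path shows no
#'   bleaching step (used for the 2-5 state comparison datasets).
#' @param frac_initial restrict initial states to this subset of `1:s_max`
#'   (e.g. `2:5` for the comparison datasets); overrides `state_mix` support.
#' @return A list of class `"trace_dataset"` with elements `records` (each
#'   a list with `intensities`, `states`, `split`), `mode`, `s_max`,
#'   `frame_interval`, `unit_intensity`, `noise`, `target_asnr`,
#'   `achieved_asnr`, `seed`.
#' @export
synthesize_dataset <- function(mode = c("photobleach", "dynamic"),
                               s_max = if (mode == "dynamic") 5L else 10L,
                               n_traces = 1000L, n_frames = 400L,
                               target_asnr = 3, state_mix = NULL,
                               split = c(0.70, 0.15, 0.15), seed = 1L,
                               unit_intensity = 1000, shot_noise = TRUE,
                               blink_rate = 0.003, blink_mean_duration = 2,
                               bleach_rate = 0.02, trans = NULL,
                               frame_interval = 0.1,
                               exclude_zero_step = FALSE,
                               frac_initial = NULL) {
  mode <- match.arg(mode)
  sigma <- calibrate_noise(target_asnr, unit_intensity, s_max, shot_noise)
  nm <- noise_model(unit_intensity = unit_intensity, gaussian_sd = sigma,
                    shot_noise = shot_noise, blink_rate = blink_rate,
                    blink_mean_duration = blink_mean_duration)
  init_support <- if (is.null(frac_initial)) 1:s_max else frac_initial
  if (is.null(state_mix)) state_mix <- rep(1 / length(init_support),
                                           length(init_support))
  if (length(state_mix) != length(init_support))
    stop("state_mix must match the initial-state support")
  if (mode == "dynamic" && is.null(trans))
    trans <- default_dynamic_trans(s_max)

  with_seed(seed, {
    # deterministic equal-count assignment when the mix divides n_traces
    counts <- largest_remainder(n_traces, state_mix / sum(state_mix))
    inits <- rep(init_support, counts)
    inits <- sample(inits)   # shuffle so splits are state-balanced
    records <- vector("list", n_traces)
    sum_emit <- numeric(s_max + 1L); sum_emit2 <- numeric(s_max + 1L)
    n_emit <- integer(s_max + 1L)
    for (i in seq_len(n_traces)) {
      repeat {
        path <- if (mode == "photobleach") {
          sim_bleach_path(inits[i], bleach_rate, n_frames, s_max = s_max,
                          frame_interval = frame_interval)
        } else {
          sim_dynamic_path(s_max, trans, n_frames, init = inits[i],
                           frame_interval = frame_interval)
        }
        if (!exclude_zero_step || path[1L] != path[n_frames]) break
      }
      emitting <- apply_blinking(path, nm)
      x <- render_trace(emitting, nm)
      for (s in unique(emitting)) {
        idx <- emitting == s
        n_emit[s + 1L] <- n_emit[s + 1L] + sum(idx)
        sum_emit[s + 1L] <- sum_emit[s + 1L] + sum(x[idx])
        sum_emit2[s + 1L] <- sum_emit2[s + 1L] + sum(x[idx]^2)
      }
      records[[i]] <- list(intensities = x, states = as.integer(path),
                           split = NA_character_)
    }
    sizes <- largest_remainder(n_traces, split)
    tags <- rep(c("train", "val", "test"), sizes)
    for (i in seq_len(n_traces)) records[[i]]$split <- tags[i]
    # empirical aSNR over emitting-count plateaus with enough frames
    keep <- which(n_emit >= 30L)
    achieved <- NA_real_
    if (length(keep) >= 2L) {
      mu <- sum_emit[keep] / n_emit[keep]
      vv <- sum_emit2[keep] / n_emit[keep] - mu^2
      ord <- order(mu)
      achieved <- compute_asnr(mu[ord], sqrt(pmax(vv[ord], 1e-12)))
    }
    structure(list(records = records, mode = mode, s_max = as.integer(s_max),
                   frame_interval = frame_interval,
                   unit_intensity = unit_intensity,
                   noise = unclass(nm), target_asnr = target_asnr,
                   achieved_asnr = achieved, seed = seed,
                   split_fractions = split),
              class = "trace_dataset")
  })
}

#' Merge trace datasets (e.g. different noise levels) into one
#'
#' Concatenates the records of several compatible datasets, typically to
#' build a mixed-aSNR training set: one network is trained on traces
#' spanning several noise levels and then evaluated on single-level test
#' sets.
#'
#' @param ... `trace_dataset` objects sharing mode, `s_max`, frame interval
#'   and unit intensity.
#' @return A `trace_dataset`; `target_asnr` and `achieved_asnr` hold the
#'   per-component vectors.
#' @export
merge_trace_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "trace_dataset"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "trace_dataset")))
  ref <- parts[[1L]]
  for (p in parts[-1L])
    if (!identical(p$mode, ref$mode) || p$s_max != ref$s_max ||
        p$frame_interval != ref$frame_interval ||
        p$unit_intensity != ref$unit_intensity)
      stop("datasets are not compatible (mode/s_max/frame/unit differ)")
  out <- ref
  out$records <- do.call(c, lapply(parts, `[[`, "records"))
  out$target_asnr <- vapply(parts, `[[`, 0, "target_asnr")
  out$achieved_asnr <- vapply(parts, `[[`, 0, "achieved_asnr")
  out$seed <- vapply(parts, function(p) as.integer(p$seed), 1L)
  out
}

#' @export
print.trace_dataset <- function(x, ...) {
  tags <- vapply(x$records, `[[`, "", "split")
  cat("<trace_dataset> ", length(x$records), " traces (", x$mode,
      "), s_max = ", x$s_max, "\n", sep = "")
  cat("  split: ", sum(tags == "train"), " train / ", sum(tags == "val"),
      " val / ", sum(tags == "test"), " test\n", sep = "")
  cat("  target aSNR ", format(x$target_asnr), ", achieved ",
      format(round(x$achieved_asnr, 3)), "\n", sep = "")
  invisible(x)
}

#' Subset a dataset by split tag
#' @param data a `trace_dataset`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return A `trace_dataset` containing only the tagged records.
#' @export
dataset_split <- function(data, split) {
  stopifnot(inherits(data, "trace_dataset"))
  keep <- vapply(data$records, function(r) identical(r$split, split), TRUE)
  out <- data
  out$records <- data$records[keep]
  out
}

#' Extract the single-fluorophore unit intensity by Gaussian mixture fitting
#'
#' Fits a Gaussian mixture to a sample of intensity values (EM via
#' \pkg{mclust}) and returns the mean of the lowest-mean component carrying
#' at least 5 % of the weight; lighter components are treated as
#' background/outliers.
#'
#' @param samples intensity values (e.g. pooled plateau intensities).
#' @param n_components number of mixture components.
#' @return Estimated unit intensity (scalar).
#' @export
fit_unit_intensity <- function(samples, n_components = 2) {
  if (length(samples) < 10 * n_components)
    stop("need at least 10 samples per component")
  if (sd(samples) == 0) return(samples[1L])
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(samples, G = n_components, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit))
    stop("Gaussian mixture EM failed to converge")
  w <- fit$parameters$pro
  mu <- fit$parameters$mean
  ok <- which(w >= 0.05)
  if (!length(ok)) ok <- seq_along(w)
  min(mu[ok])
}
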