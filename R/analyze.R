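as_path_list <- function(paths) {
  if (is.numeric(paths)) list(as.integer(paths))
  else lapply(paths, as.integer)
}

#' Frame-wise confusion matrix and per-state accuracy
#'
#' Pools all frames of all trace pairs into a true-state by predicted-state
#' confusion matrix, row-normalizes it, and reports each state's accuracy
#' (diagonal of the normalized matrix). The headline figure is the minimum
#' accuracy over represented states; states with no true frames are flagged
#' absent and excluded from the minimum.
#'
#' @param pred list of predicted state paths (integer vectors).
#' @param truth list of ground-truth paths, aligned with `pred`.
#' @param s_max state cardinality; default the largest state seen.
#' @return An object of class `"confusion_report"`: `counts`, `normalized`,
#'   `per_state` (named accuracies, `NA` for absent states),
#'   `min_state_accuracy`, `overall_accuracy`, `n_frames`.
#' @export
state_confusion <- function(pred, truth, s_max = NULL) {
  pred <- as_path_list(pred); truth <- as_path_list(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must pair up")
  lp <- vapply(pred, length, 1L); lt <- vapply(truth, length, 1L)
  if (any(lp != lt)) stop("misaligned pair: path lengths differ")
  p <- unlist(pred); y <- unlist(truth)
  if (is.null(s_max)) s_max <- max(p, y)
  S1 <- s_max + 1L
  counts <- matrix(0, S1, S1,
                   dimnames = list(true = 0:s_max, predicted = 0:s_max))
  tab <- table(factor(y, levels = 0:s_max), factor(p, levels = 0:s_max))
  counts[] <- as.numeric(tab)
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, NA_real_)
  per_state <- diag(normalized)
  names(per_state) <- 0:s_max
  represented <- rs > 0
  structure(list(counts = counts, normalized = normalized,
                 per_state = per_state,
                 min_state_accuracy = min(per_state[represented]),
                 overall_accuracy = sum(diag(counts)) / sum(counts),
                 n_frames = sum(counts)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> ", x$n_frames, " frames, ",
      sum(!is.na(x$per_state)), " represented states\n", sep = "")
  cat("  overall accuracy ", sprintf("%.4f", x$overall_accuracy),
      ", minimum per-state accuracy ",
      sprintf("%.4f", x$min_state_accuracy), "\n", sep = "")
  print(round(x$per_state, 4))
  invisible(x)
}

#' Minimum per-state accuracy over a chosen state set
#'
#' @param report a [state_confusion()] result.
#' @param states states to minimize over (default: all represented
#'   fluorophore-count states `1:s_max`, excluding background 0).
#' @return Scalar accuracy in `[0, 1]`.
#' @export
min_state_accuracy <- function(report, states = NULL) {
  stopifnot(inherits(report, "confusion_report"))
  acc <- report$per_state
  if (is.null(states)) states <- setdiff(as.integer(names(acc)), 0L)
  acc <- acc[as.character(states)]
  acc <- acc[!is.na(acc)]
  if (!length(acc)) stop("none of the requested states is represented")
  min(acc)
}

#' Count photobleaching steps in a path
#'
#' The step count is the initial minus the final state. A non-monotone path
#' (any upward transition, i.e. residual blinking in the prediction) is
#' flagged via the `"non_monotone"` attribute; the count itself is still
#' initial minus final.
#'
#' @param path integer state path.
#' @return Integer step count with logical attribute `non_monotone`.
#' @export
count_bleach_steps <- function(path) {
  path <- as.integer(path)
  structure(path[1L] - path[length(path)],
            non_monotone = any(diff(path) > 0L))
}

#' Population distribution of bleaching-step counts
#'
#' @param paths list of state paths.
#' @param max_steps largest step-count class to report (default: largest
#'   observed).
#' @return Named numeric vector of fractions over `0:max_steps`, summing
#'   to 1.
#' @export
population_distribution <- function(paths, max_steps = NULL) {
  paths <- as_path_list(paths)
  if (!length(paths)) stop("empty path list")
  steps <- vapply(paths, function(p) as.integer(count_bleach_steps(p)), 1L)
  if (is.null(max_steps)) max_steps <- max(steps)
  tab <- tabulate(steps + 1L, nbins = max_steps + 1L)
  structure(tab / length(steps), names = 0:max_steps)
}

#' State occupancies
#'
#' Fraction of all frames spent in each state, over a set of paths.
#'
#' @param paths list of state paths.
#' @param s_max state cardinality (default: largest state seen).
#' @return Named numeric vector over `0:s_max`, summing to 1.
#' @export
state_occupancy <- function(paths, s_max = NULL) {
  paths <- as_path_list(paths)
  if (!length(paths)) stop("empty path list")
  all_s <- unlist(paths)
  if (is.null(s_max)) s_max <- max(all_s)
  tab <- tabulate(all_s + 1L, nbins = s_max + 1L)
  structure(tab / length(all_s), names = 0:s_max)
}

#' Transition-rate matrix
#'
#' Off-diagonal rates `a_ij` (i != j) are the number of observed
#' frame-to-frame i-to-j transitions divided by the total time spent in
#' state i (each frame in i except trace-final frames, times the frame
#' interval), in 1/s. The diagonal is reported as
#' `1/frame_interval - sum_j a_ij`. Rows for states never visited are `NA`.
#'
#' @param paths list of state paths.
#' @param frame_interval seconds per frame.
#' @param s_max state cardinality (default: largest state seen).
#' @return `(s_max+1) x (s_max+1)` rate matrix in 1/s.
#' @export
transition_rates <- function(paths, frame_interval = 0.1, s_max = NULL) {
  paths <- as_path_list(paths)
  if (!length(paths)) stop("empty path list")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (is.null(s_max)) s_max <- max(unlist(paths))
  S1 <- s_max + 1L
  n_trans <- matrix(0, S1, S1)
  time_in <- numeric(S1)
  for (p in paths) {
    from <- p[-length(p)] + 1L
    to <- p[-1L] + 1L
    for (k in seq_along(from)) n_trans[from[k], to[k]] <-
        n_trans[from[k], to[k]] + 1
    time_in <- time_in + tabulate(from, nbins = S1) * frame_interval
  }
  rates <- matrix(NA_real_, S1, S1,
                  dimnames = list(from = 0:s_max, to = 0:s_max))
  for (i in seq_len(S1)) {
    if (time_in[i] > 0) {
      rates[i, ] <- n_trans[i, ] / time_in[i]
      rates[i, i] <- 1 / frame_interval - sum(rates[i, -i])
    }
  }
  rates
}

#' Dwell durations of a state
#'
#' Maximal runs of the state, converted to seconds. Runs touching either
#' trace boundary are right-/left-censored and excluded, so exponential
#' fits see only complete dwells.
#'
#' @param paths list of state paths.
#' @param state state index.
#' @param frame_interval seconds per frame.
#' @return Numeric vector of dwell times in seconds (possibly empty).
#' @export
dwell_durations <- function(paths, state, frame_interval = 0.1) {
  paths <- as_path_list(paths)
  out <- numeric(0)
  for (p in paths) {
    r <- rle(p == state)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts > 1L & ends < length(p)
    out <- c(out, r$lengths[keep] * frame_interval)
  }
  out
}

#' Exponential dwell-time fit
#'
#' Maximum-likelihood single-exponential time constant, which for complete
#' dwells is exactly the sample mean.
#'
#' @param durations dwell times in seconds (>= 5 required).
#' @return Time constant tau in seconds.
#' @export
fit_dwell_exp <- function(durations) {
  if (length(durations) < 5L)
    stop("insufficient data: need >= 5 complete dwells")
  mean(durations)
}

#' Bootstrap summary of a statistic
#'
#' Draws `replicates` sub-datasets of `round(fraction * n)` items without
#' replacement, applies `stat` to each, and reports per-replicate values,
#' mean and SD (n-1 denominator).
#'
#' @param items list (or vector) of records to resample.
#' @param stat function of a subset of `items` returning a scalar.
#' @param fraction subsample fraction (default 0.72).
#' @param replicates number of sub-datasets (default 5).
#' @param seed optional integer seed.
#' @return An object of class `"bootstrap_summary"`: `values`, `mean`,
#'   `sd`, `fraction`, `replicates`, `subset_size`.
#' @export
bootstrap_stat <- function(items, stat, fraction = 0.72, replicates = 5L,
                           seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (replicates < 2L) stop("need >= 2 replicates")
  n <- if (is.list(items)) length(items) else NROW(items)
  m <- round(fraction * n)
  with_seed(seed, {
    values <- vapply(seq_len(replicates), function(r) {
      idx <- sample.int(n, m)
      sub <- if (is.list(items)) items[idx] else items[idx]
      v <- tryCatch(stat(sub), error = function(e)
        stop("statistic failed on replicate ", r, ": ",
             conditionMessage(e)))
      as.numeric(v)
    }, numeric(1))
    structure(list(values = values, mean = mean(values), sd = sd(values),
                   fraction = fraction, replicates = replicates,
                   subset_size = m),
              class = "bootstrap_summary")
  })
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary> ", x$replicates, " replicates of ",
      x$subset_size, " items (", 100 * x$fraction, "%)\n", sep = "")
  cat("  mean ", format(x$mean), " +/- ", format(x$sd), " (SD)\n", sep = "")
  invisible(x)
}

#' Dynamics summary: occupancies, rates and dwell fits
#'
#' Convenience wrapper producing the downstream kinetics report from a set
#' of predicted state paths.
#'
#' @param paths list of state paths.
#' @param frame_interval seconds per frame.
#' @param s_max state cardinality.
#' @param dwell_states states for which exponential dwell constants are
#'   fitted (skipped when fewer than 5 complete dwells exist).
#' @return A list of class `"dynamics_summary"`: `occupancy`, `rates`,
#'   `dwell_tau` (named, `NA` when unfittable), `n_traces`.
#' @export
dynamics_summary <- function(paths, frame_interval = 0.1, s_max = NULL,
                             dwell_states = NULL) {
  paths <- as_path_list(paths)
  occ <- state_occupancy(paths, s_max = s_max)
  s_max <- length(occ) - 1L
  rates <- transition_rates(paths, frame_interval, s_max = s_max)
  if (is.null(dwell_states)) dwell_states <- 0:s_max
  tau <- vapply(dwell_states, function(s) {
    d <- dwell_durations(paths, s, frame_interval)
    if (length(d) >= 5L) mean(d) else NA_real_
  }, numeric(1))
  names(tau) <- dwell_states
  structure(list(occupancy = occ, rates = rates, dwell_tau = tau,
                 n_traces = length(paths)),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat("<dynamics_summary> ", x$n_traces, " traces\n", sep = "")
  cat("  occupancy:\n"); print(round(x$occupancy, 4))
  cat("  transition rates (1/s):\n"); print(round(x$rates, 3))
  cat("  dwell tau (s):\n"); print(round(x$dwell_tau, 3))
  invisible(x)
}
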