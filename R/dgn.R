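#' Quadratic reconstruction loss
#'
#' `L = (1 / 2T) * sum_t (xhat_t - x_t)^2`, the per-trace objective the
#' generator is trained to minimize.
#'
#' @param xhat predicted sequence.
#' @param x measured sequence of the same length.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(xhat, x) {
  if (length(xhat) != length(x)) stop("xhat and x must have equal length")
  sum((xhat - x)^2) / (2 * length(x))
}

#' Hidden-space cross-entropy loss
#'
#' Mean negative log-probability the posterior assigns to the true state:
#' `L_h = (1/T) * sum_t -log p_t(y_t)`, probabilities floored at 1e-12.
#' Applied to synthetic (labelled) traces during blended training.
#'
#' @param posterior `T x (s_max+1)` matrix of per-frame state probabilities.
#' @param truth integer vector of true states in `0:s_max`.
#' @return Scalar loss.
#' @export
hidden_loss <- function(posterior, truth) {
  posterior <- as.matrix(posterior)
  if (nrow(posterior) != length(truth))
    stop("posterior and truth must align")
  truth <- as.integer(truth)
  if (any(truth < 0L) || any(truth >= ncol(posterior)))
    stop("truth states outside the posterior's class range")
  p <- posterior[cbind(seq_along(truth), truth + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Annealed blending weight
#'
#' `alpha = alpha0 * exp(-decay * k / K)`: the weight of the hidden-space
#' loss starts at `alpha0` (default 0.5, so reconstruction and labels are
#' weighted equally at the first epoch) and decays so later epochs are
#' dominated by the unsupervised reconstruction objective.
#'
#' @param k current epoch (0-based).
#' @param K total epochs (>= 1).
#' @param alpha0 initial weight.
#' @param decay decay constant.
#' @return Scalar weight.
#' @export
blend_weight <- function(k, K, alpha0 = 0.5, decay = 2) {
  if (K < 1 || any(k < 0) || any(k > K)) stop("need 0 <= k <= K, K >= 1")
  alpha0 * exp(-decay * k / K)
}

#' Threshold network weights
#'
#' Clamps every weight into `[-c, c]` (the "weights thresholding" used to
#' keep training stable).
#'
#' @param params named list of weight matrices/vectors.
#' @param c positive clip bound.
#' @return The clipped parameter list.
#' @export
clip_weights <- function(params, c) {
  if (c <= 0) stop("clip bound must be > 0")
  lapply(params, function(w) pmin(pmax(w, -c), c))
}

# uniform weight init for one biLSTM + projection; forget-gate biases start
# at 1 so the memory path is open from the first epoch
init_dgn_params <- function(s_max, h_disc = 32L, h_gen = 16L, scale = 0.1) {
  S1 <- s_max + 1L
  u <- function(nr, nc) matrix(runif(nr * nc, -scale, scale), nr, nc)
  lb <- function(H) { b <- numeric(4 * H); b[(H + 1):(2 * H)] <- 1; b }
  list(
    d_Wx = u(4 * h_disc, 1L), d_Wh = u(4 * h_disc, h_disc), d_b = lb(h_disc),
    d_Wx_r = u(4 * h_disc, 1L), d_Wh_r = u(4 * h_disc, h_disc),
    d_b_r = lb(h_disc),
    d_Ws = u(S1, 2 * h_disc), d_bs = numeric(S1),
    g_Wx = u(4 * h_gen, S1 + 1L), g_Wh = u(4 * h_gen, h_gen), g_b = lb(h_gen),
    g_Wx_r = u(4 * h_gen, S1 + 1L), g_Wh_r = u(4 * h_gen, h_gen),
    g_b_r = lb(h_gen),
    g_Wo = u(1L, 2 * h_gen), g_bo = 0)
}

records_to_matrices <- function(records, unit_intensity) {
  lens <- vapply(records, function(r) length(r$intensities), 1L)
  if (length(unique(lens)) != 1L)
    stop("all traces in a training set must share one length ",
         "(batches are homogeneous; mixed lengths are not padded)")
  X <- vapply(records, function(r) r$intensities / unit_intensity,
              numeric(lens[1L]))
  Y <- vapply(records, function(r) {
    if (is.null(r$states)) rep(-1L, lens[1L]) else as.integer(r$states)
  }, integer(lens[1L]))
  list(X = matrix(X, nrow = lens[1L]), Y = matrix(Y, nrow = lens[1L]))
}

#' Fit a discriminator-generator network (DGN)
#'
#' Jointly trains the discriminator (biLSTM, 32 units per direction, softmax
#' head over `s_max + 1` fluorophore-count classes) and the generator
#' (biLSTM, 16 units per direction, linear head) by mini-batch SGD on the
#' blended objective: for labelled (synthetic) traces
#' `(1 - alpha) * L + alpha * L_h`, for unlabelled (experimental) traces the
#' plain reconstruction loss `L`, with `alpha` annealed per
#' [blend_weight()]. Inputs are normalized by `unit_intensity * s_max` so
#' the full state range spans `[0, 1]`, which keeps the LSTM gates out of
#' their saturated region for high fluorophore counts. L2 regularization and weight
#' thresholding are applied at every step.
#'
#' When no experimental traces are supplied, a held-aside fraction of the
#' synthetic training records is stripped of its labels and stands in for
#' the experimental subset, so the blended machinery is always exercised.
#'
#' @param data a [synthesize_dataset()] result (its `train` split is used
#'   for fitting, `val` for validation).
#' @param experimental optional `trace_dataset` (or list of numeric traces)
#'   of unlabelled experimental records mixed into training.
#' @param epochs total training epochs `K`.
#' @param batch_size mini-batch size (default 8).
#' @param optimizer `"adam"` (default) or `"sgd"` (plain mini-batch
#'   gradient descent with optional momentum).
#' @param learning_rate step size; defaults to 0.005 for Adam and 0.15 for
#'   SGD.
#' @param momentum SGD momentum (0 disables; ignored by Adam).
#' @param lr_decay exponential learning-rate decay constant: epoch k uses
#'   `learning_rate * exp(-lr_decay * k / epochs)`, damping late-epoch
#'   parameter churn (0 disables).
#' @param l2 L2 regularization coefficient.
#' @param clip weight-thresholding bound `c`.
#' @param alpha0,alpha_decay annealing schedule of the blending weight.
#' @param unlabeled_fraction fraction of synthetic training records held
#'   aside as unlabelled stand-ins when `experimental` is `NULL`.
#' @param select which epoch's weights to return: `"val_acc"` (default)
#'   picks the epoch with the highest minimum per-state accuracy on the
#'   labelled validation records (the deployed figure of merit, and a guard
#'   against late-epoch drift of the class-to-intensity anchoring),
#'   `"val_ce"` the lowest validation hidden-space cross-entropy, `"last"`
#'   the final epoch.
#' @param seed integer seed governing init and shuffling; identical seeds
#'   give identical fits.
#' @param verbose print one line per epoch.
#' @return An object of class `"dgn"`: list with `params`, `s_max`, `mode`,
#'   `unit_intensity`, `frame_interval`, `history` (per-epoch data frame
#'   with `alpha`, `train_loss`, `val_loss`), `config`.
#' @seealso [predict.dgn()], [dgn_posterior()], [ghmm()]
#' @export
dgn <- function(data, experimental = NULL, epochs = 30L, batch_size = 8L,
                optimizer = c("adam", "sgd"), learning_rate = NULL,
                momentum = 0.9, l2 = 1e-6, clip = 1, lr_decay = 2,
                alpha0 = 0.5, alpha_decay = 2, unlabeled_fraction = 0.25,
                select = c("val_acc", "val_ce", "last"),
                seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  select <- match.arg(select)
  if (is.null(learning_rate))
    learning_rate <- if (optimizer == "adam") 0.005 else 0.15
  stopifnot(inherits(data, "trace_dataset"))
  if (epochs < 1 || batch_size < 1 || learning_rate < 0 || clip <= 0)
    stop("invalid training configuration")
  train <- dataset_split(data, "train")$records
  val <- dataset_split(data, "val")$records
  if (!length(train)) stop("empty training set")
  unit <- data$unit_intensity
  if (is.null(unit) || !is.finite(unit))
    stop("dataset carries no unit intensity; estimate one with ",
         "fit_unit_intensity()")

  with_seed(seed, {
    if (!is.null(experimental)) {
      exp_rec <- if (inherits(experimental, "trace_dataset"))
        lapply(experimental$records, function(r) {
          r$states <- NULL; r
        })
      else lapply(experimental, function(x) list(intensities = x,
                                                 states = NULL,
                                                 split = "train"))
      train <- c(train, exp_rec)
    } else if (unlabeled_fraction > 0 && length(train) >= 8L) {
      n_u <- floor(unlabeled_fraction * length(train))
      if (n_u > 0) {
        idx <- sample(length(train), n_u)
        for (i in idx) train[[i]]$states <- NULL
      }
    }
    scale <- unit * data$s_max   # inputs scaled to [0, 1]
    tr <- records_to_matrices(train, scale)
    if (all(tr$Y[1L, ] < 0L))
      stop("training set contains no labelled record")
    va <- if (length(val)) records_to_matrices(val, scale)
          else list(X = tr$X[, 0, drop = FALSE], Y = tr$Y[, 0, drop = FALSE])
    params <- init_dgn_params(data$s_max)
    # softmax bias starts at the log class priors of the labelled frames,
    # so rare high-count states are not written off by the initial head
    lab <- tr$Y[, tr$Y[1L, ] >= 0L, drop = FALSE]
    prior <- tabulate(as.integer(lab) + 1L, nbins = data$s_max + 1L)
    params$d_bs <- log((prior + 1) / sum(prior + 1))
    cfg <- list(epochs = as.integer(epochs),
                batch_size = as.integer(batch_size),
                optimizer = optimizer,
                learning_rate = learning_rate, momentum = momentum,
                lr_decay = lr_decay,
                l2 = l2, clip = clip, alpha0 = alpha0,
                alpha_decay = alpha_decay, select = select,
                verbose = isTRUE(verbose))
    fit <- cpp_train_dgn(tr$X, tr$Y, va$X, va$Y, params, cfg)
    # keep the epoch with the best validation hidden-space CE: after the
    # annealing weight has decayed the class-to-level anchoring can drift
    # under the label-free reconstruction objective, and the validation CE
    # is the direct measure of the discriminator we actually deploy
    use_best <- select != "last" && fit$best_epoch > 0
    structure(list(params = if (use_best) fit$best_params else fit$params,
                   best_epoch = if (use_best) fit$best_epoch else epochs,
                   s_max = data$s_max,
                   mode = data$mode, unit_intensity = unit,
                   frame_interval = data$frame_interval,
                   history = fit$history,
                   config = c(cfg, list(seed = seed,
                                        n_train = ncol(tr$X),
                                        n_val = ncol(va$X)))),
              class = "dgn")
  })
}

# per-frame argmax of a posterior matrix, ties broken toward the lower state
posterior_to_states <- function(pm) {
  max.col(pm, ties.method = "first") - 1L
}

as_trace_list <- function(newdata) {
  if (inherits(newdata, "trace_dataset"))
    lapply(newdata$records, `[[`, "intensities")
  else if (is.numeric(newdata)) list(newdata)
  else if (is.list(newdata)) lapply(newdata, as.numeric)
  else stop("newdata must be a trace_dataset, a numeric trace, or a list")
}

#' Per-frame state posterior for one trace
#'
#' Runs the trained discriminator on a single intensity trace and returns
#' the full-sequence posterior over fluorophore-count states.
#'
#' @param object a fitted [dgn()] model.
#' @param x numeric intensity trace (raw units; normalization is applied
#'   internally).
#' @return `T x (s_max+1)` matrix; every row is a probability simplex.
#' @export
dgn_posterior <- function(object, x) {
  stopifnot(inherits(object, "dgn"))
  x <- as.numeric(x)
  if (length(x) < 2L) stop("trace must have >= 2 frames")
  if (!all(is.finite(x))) stop("trace contains non-finite values")
  scale <- object$unit_intensity * object$s_max
  P <- cpp_disc_forward(matrix(x / scale, ncol = 1), object$params)
  t(P[, 1, , drop = TRUE])   # -> T x S1
}

#' Reconstruct a trace from a state posterior
#'
#' Runs the trained generator conditioned on a posterior and the previous
#' intensity value. With `prev_values` supplied (the measured trace), the
#' generator is teacher-forced exactly as during training. Without it, the
#' autoregressive feed is resolved by fixed-point iteration: the first pass
#' feeds the posterior-weighted state mean sequence, subsequent passes feed
#' the previous pass's shifted output.
#'
#' @param object a fitted [dgn()] model.
#' @param posterior `T x (s_max+1)` posterior matrix (e.g. from
#'   [dgn_posterior()]).
#' @param prev_values optional measured trace (raw units, length `T`) used
#'   as the teacher-forced previous-value feed.
#' @param iterations fixed-point passes for the autoregressive mode.
#' @return Numeric reconstruction in raw intensity units.
#' @export
dgn_generate <- function(object, posterior, prev_values = NULL,
                         iterations = 2L) {
  stopifnot(inherits(object, "dgn"))
  posterior <- as.matrix(posterior)
  S1 <- object$s_max + 1L
  if (ncol(posterior) != S1) stop("posterior has the wrong class count")
  T_ <- nrow(posterior)
  scale <- object$unit_intensity * object$s_max
  P <- array(t(posterior), dim = c(S1, 1L, T_))
  # posterior-weighted state mean in normalized [0, 1] units
  pmean <- as.numeric(posterior %*% ((0:object$s_max) / object$s_max))
  if (!is.null(prev_values)) {
    if (length(prev_values) != T_) stop("prev_values must align")
    xn <- prev_values / scale
    prev <- matrix(c(pmean[1L], xn[-T_]), ncol = 1)
    return(as.numeric(cpp_gen_forward(P, prev, object$params)) * scale)
  }
  xhat <- pmean
  for (it in seq_len(max(1L, iterations))) {
    prev <- matrix(c(xhat[1L], xhat[-T_]), ncol = 1)
    xhat <- as.numeric(cpp_gen_forward(P, prev, object$params))
  }
  xhat * scale
}

#' Predict state paths, posteriors or reconstructions
#'
#' @param object a fitted [dgn()] model.
#' @param newdata a `trace_dataset`, a list of numeric traces, or a single
#'   numeric trace.
#' @param type `"states"` for per-frame argmax fluorophore counts (ties
#'   broken toward the lower state), `"posterior"` for the full posterior
#'   matrices, `"reconstruction"` for generator outputs in raw units.
#' @param batch traces decoded per forward call (speed only).
#' @param ... unused.
#' @return A list with one element per trace (integer path, posterior
#'   matrix, or numeric reconstruction).
#' @export
predict.dgn <- function(object, newdata, type = c("states", "posterior",
                                                  "reconstruction"),
                        batch = 64L, ...) {
  type <- match.arg(type)
  traces <- as_trace_list(newdata)
  lens <- vapply(traces, length, 1L)
  if (any(lens < 2L)) stop("every trace needs >= 2 frames")
  if (!all(vapply(traces, function(x) all(is.finite(x)), TRUE)))
    stop("traces contain non-finite values")
  out <- vector("list", length(traces))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    for (start in seq(1L, length(idx), by = batch)) {
      take <- idx[start:min(start + batch - 1L, length(idx))]
      X <- vapply(traces[take],
                  function(x) x / (object$unit_intensity * object$s_max),
                  numeric(L))
      P <- cpp_disc_forward(matrix(X, nrow = L), object$params)
      for (j in seq_along(take)) {
        pm <- t(P[, j, , drop = TRUE])   # T x S1
        out[[take[j]]] <- switch(type,
          states = posterior_to_states(pm),
          posterior = pm,
          reconstruction = dgn_generate(object, pm))
      }
    }
  }
  out
}

#' @export
print.dgn <- function(x, ...) {
  cat("Discriminator-generator network (", x$mode, " mode)\n", sep = "")
  cat("  states 0..", x$s_max, "; discriminator biLSTM 32/dir + softmax, ",
      "generator biLSTM 16/dir + linear\n", sep = "")
  h <- x$history
  cat("  trained ", nrow(h), " epochs on ", x$config$n_train,
      " traces; final train loss ", signif(h$train_loss[nrow(h)], 3),
      ", val loss ", signif(h$val_loss[nrow(h)], 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dgn <- function(object, ...) {
  print(object)
  cat("\nLast epochs:\n")
  print(tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.dgn <- function(object, ...) object$params

#' @export
plot.dgn <- function(x, ...) {
  h <- x$history
  matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
          col = c("black", "firebrick"), xlab = "epoch",
          ylab = "blended loss", ...)
  legend("topright", c("training", "validation"), lty = 1,
         col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.dgn <- function(object, newdata, ...) {
  traces <- as_trace_list(newdata)
  rec <- predict(object, traces, type = "reconstruction")
  Map(function(x, r) as.numeric(x) - r, traces, rec)
}

#' Save or load a fitted model container
#'
#' The container holds all weight arrays, the state cardinality, the
#' normalization constant and the training configuration, so a model can be
#' reloaded without retraining.
#'
#' @param object a fitted [dgn()] model.
#' @param path file path.
#' @return `read_dgn` returns the model object; `write_dgn` the path,
#'   invisibly.
#' @export
write_dgn <- function(object, path) {
  stopifnot(inherits(object, "dgn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_dgn
#' @export
read_dgn <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "dgn")) stop("not a dgn model container: ", path)
  obj
}
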