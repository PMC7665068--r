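#' Fit a Gaussian-emission hidden Markov model
#'
#' From-scratch Baum-Welch EM for an HMM with Gaussian per-state emissions,
#' used as the classical baseline against the DGN discriminator. Emission
#' means are initialized on an evenly spaced grid between the pooled 1st
#' and 99th intensity percentiles; `n_restarts` random perturbations of
#' that grid are fitted and the best final likelihood kept. After fitting,
#' states are reordered by increasing mean so the state index doubles as
#' the intensity rank (the fluorophore-count mapping).
#'
#' @param traces a numeric trace, list of numeric traces, or
#'   `trace_dataset`.
#' @param n_states number of hidden states (>= 2).
#' @param max_iter maximum EM iterations per restart.
#' @param tol stop when the log-likelihood gain drops below `tol`.
#' @param n_restarts random restarts (first uses the unperturbed grid).
#' @param seed optional integer seed for the restart perturbations.
#' @return An object of class `"ghmm"`: `n_states`, `init` (initial
#'   distribution), `trans`, `means`, `sds`, `loglik`, `loglik_trace`,
#'   `converged`, `iterations`.
#' @export
ghmm <- function(traces, n_states, max_iter = 100L, tol = 1e-4,
                 n_restarts = 3L, seed = NULL) {
  if (n_states < 2L) stop("n_states must be >= 2")
  xs <- as_trace_list_num(traces)
  if (!length(xs)) stop("no traces supplied")
  pooled <- unlist(xs)
  q <- quantile(pooled, c(0.01, 0.99), names = FALSE)
  grid <- seq(q[1L], q[2L], length.out = n_states)
  spacing <- if (n_states > 1) diff(grid)[1L] else diff(range(pooled))
  var_floor <- 1e-6 * diff(range(pooled))^2
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      mu0 <- if (r == 1L) grid else sort(grid + rnorm(n_states,
                                                      0, spacing / 4))
      fit <- ghmm_em(xs, mu0, rep(max(sd(pooled) / n_states,
                                      sqrt(var_floor)), n_states),
                     max_iter, tol, var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    ord <- order(best$means)
    structure(list(n_states = n_states, init = best$init[ord],
                   trans = best$trans[ord, ord, drop = FALSE],
                   means = best$means[ord], sds = best$sds[ord],
                   loglik = best$loglik, loglik_trace = best$loglik_trace,
                   converged = best$converged,
                   iterations = best$iterations),
              class = "ghmm")
  })
}

as_trace_list_num <- function(traces) {
  if (inherits(traces, "trace_dataset"))
    lapply(traces$records, `[[`, "intensities")
  else if (is.numeric(traces)) list(as.numeric(traces))
  else lapply(traces, as.numeric)
}

ghmm_em <- function(xs, mu, sds, max_iter, tol, var_floor) {
  S <- length(mu)
  init <- rep(1 / S, S)
  trans <- matrix(0.05 / (S - 1), S, S); diag(trans) <- 0.95
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  floored <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ll <- 0
    g_sum <- numeric(S); gx_sum <- numeric(S); gx2_sum <- numeric(S)
    xi_sum <- matrix(0, S, S); g1_sum <- numeric(S)
    for (x in xs) {
      e <- cpp_hmm_estep(x, init, trans, mu, sds)
      ll <- ll + e$loglik
      g <- e$gamma
      g_sum <- g_sum + colSums(g)
      gx_sum <- gx_sum + colSums(g * x)
      gx2_sum <- gx2_sum + colSums(g * x^2)
      xi_sum <- xi_sum + e$xi
      g1_sum <- g1_sum + e$gamma1
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    init <- g1_sum / sum(g1_sum)
    rs <- rowSums(xi_sum)
    for (i in seq_len(S))
      trans[i, ] <- if (rs[i] > 0) xi_sum[i, ] / rs[i] else 1 / S
    mu_new <- gx_sum / pmax(g_sum, 1e-12)
    var_new <- gx2_sum / pmax(g_sum, 1e-12) - mu_new^2
    if (any(var_new < var_floor)) floored <- TRUE
    mu <- mu_new
    sds <- sqrt(pmax(var_new, var_floor))
  }
  if (floored)
    warning("degenerate emission: variance floored during EM")
  list(init = init, trans = trans, means = mu, sds = sds,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, iterations = it)
}

#' Viterbi decoding under a fitted Gaussian HMM
#'
#' Most probable state sequence, computed in the log domain. State indices
#' follow the model's mean-rank ordering (0 = lowest-mean state), so they
#' map directly to fluorophore counts when the model levels are the count
#' plateaus.
#'
#' @param trace numeric intensity trace.
#' @param hmm a fitted [ghmm()] model.
#' @return Integer state path (0-based rank indices).
#' @export
viterbi_path <- function(trace, hmm) {
  stopifnot(inherits(hmm, "ghmm"))
  as.integer(cpp_viterbi(as.numeric(trace), hmm$init, hmm$trans,
                         hmm$means, hmm$sds))
}

#' @export
predict.ghmm <- function(object, newdata, ...) {
  xs <- as_trace_list_num(newdata)
  lapply(xs, viterbi_path, hmm = object)
}

#' @export
print.ghmm <- function(x, ...) {
  cat("Gaussian HMM, ", x$n_states, " states; logLik ",
      format(x$loglik), if (x$converged) " (converged in " else
        " (stopped at ", x$iterations, " iterations)\n", sep = "")
  cat("  means: ", paste(signif(x$means, 4), collapse = ", "), "\n",
      sep = "")
  cat("  sds:   ", paste(signif(x$sds, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.ghmm <- function(object, ...) {
  structure(object$loglik, df = with(object,
    n_states - 1 + n_states * (n_states - 1) + 2 * n_states),
    class = "logLik")
}
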