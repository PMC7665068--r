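# exhaustive enumeration oracles for small HMM instances
brute_force_hmm <- function(x, pi0, A, mu, sd) {
  S <- length(mu); T_ <- length(x)
  grid <- as.matrix(expand.grid(rep(list(1:S), T_)))
  scores <- apply(grid, 1, function(st) {
    lp <- log(pi0[st[1]]) + dnorm(x[1], mu[st[1]], sd[st[1]], log = TRUE)
    if (T_ > 1) for (t in 2:T_)
      lp <- lp + log(A[st[t - 1], st[t]]) +
        dnorm(x[t], mu[st[t]], sd[st[t]], log = TRUE)
    lp
  })
  m <- max(scores)
  list(path = grid[which.max(scores), ] - 1L,
       loglik = m + log(sum(exp(scores - m))))
}

test_that("Viterbi equals brute-force enumeration on random instances", {
  set.seed(77)
  for (i in 1:100) {
    S <- sample(2:3, 1); T_ <- sample(3:8, 1)
    mu <- sort(runif(S, 0, 10))
    sdv <- runif(S, 0.5, 2)
    A <- matrix(runif(S * S, 0.05, 1), S); A <- A / rowSums(A)
    pi0 <- runif(S, 0.05, 1); pi0 <- pi0 / sum(pi0)
    x <- rnorm(T_, sample(mu, T_, TRUE), 1)
    oracle <- brute_force_hmm(x, pi0, A, mu, sdv)
    got <- dgntrace:::cpp_viterbi(x, pi0, A, mu, sdv)
    expect_equal(as.integer(got), as.integer(oracle$path))
    e <- dgntrace:::cpp_hmm_estep(x, pi0, A, mu, sdv)
    expect_equal(e$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("EM separates noiseless two-level traces exactly", {
  x <- rep(c(0, 100), each = 150) + rnorm(300, 0, 1e-3)
  suppressWarnings(h <- ghmm(x, n_states = 2, seed = 1))
  expect_lt(max(abs(sort(h$means) - c(0, 100))), 1e-3 + 0.01)
  expect_true(all(diff(h$loglik_trace) > -1e-6))
})

test_that("EM recovers a known 3-state chain from long data", {
  A <- rbind(c(0.95, 0.04, 0.01),
             c(0.03, 0.94, 0.03),
             c(0.01, 0.05, 0.94))
  mu_true <- c(0, 50, 100); sd_true <- c(8, 8, 8)
  path <- sim_dynamic_path(2, A, 3e4, seed = 55)
  x <- mu_true[path + 1L] + rnorm(length(path), 0, 8)
  h <- ghmm(x, n_states = 3, max_iter = 100, seed = 2)
  n_per <- tabulate(path + 1L, 3)
  expect_true(all(abs(h$means - mu_true) < 3 * 8 / sqrt(n_per) + 0.5))
  expect_true(all(abs(h$sds - 8) < 0.5))
})

test_that("decoding noiseless sticky traces returns the generating path", {
  h <- structure(list(n_states = 3, init = rep(1 / 3, 3),
                      trans = rbind(c(0.98, 0.01, 0.01),
                                    c(0.01, 0.98, 0.01),
                                    c(0.01, 0.01, 0.98)),
                      means = c(0, 10, 20), sds = rep(0.5, 3)),
                 class = "ghmm")
  truth <- rep(c(2L, 1L, 0L), each = 20)
  x <- c(0, 10, 20)[truth + 1L]
  expect_equal(viterbi_path(x, h), truth)
  expect_equal(length(viterbi_path(rnorm(57, 10, 3), h)), 57L)
})
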