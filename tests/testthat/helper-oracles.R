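# Independent oracles, deliberately naive.

# Exhaustive path enumeration of the HMM posterior marginals: sums the joint
# probability of every state sequence (prior on day 0, stochastic matrix W,
# per-day likelihoods), then aggregates day marginals. Cost K^(days); use
# only where K^days is small.
enum_marginals <- function(prior, W, liks) {
  K <- length(prior)
  Tt <- length(liks)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tt + 1)))
  p <- prior[paths[, 1]]
  for (t in seq_len(Tt))
    p <- p * W[cbind(paths[, t], paths[, t + 1])] * liks[[t]][paths[, t + 1]]
  p <- p / sum(p)
  vapply(seq_len(Tt + 1), function(t)
    as.numeric(rowsum(p, factor(paths[, t], levels = seq_len(K)))),
    numeric(K))
}

# random HMM instance with joint size cap so enumeration stays exact and fast
random_hmm_instance <- function(max_cells = 25, max_days = 6,
                                max_paths = 2e5) {
  repeat {
    K <- sample(2:max_cells, 1)
    days <- sample(2:max_days, 1)       # total days including day 0
    if (K^days <= max_paths) break
  }
  W <- matrix(runif(K * K, 0.01, 1), K, K)
  W <- W / rowSums(W)
  prior <- runif(K); prior <- prior / sum(prior)
  liks <- replicate(days - 1, runif(K, 0.05, 1), simplify = FALSE)
  list(K = K, days = days, W = W, prior = prior, liks = liks)
}
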