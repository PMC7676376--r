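# Independent oracles used to cross-check the package's statistics.
# Deliberately written as plain accumulating loops / combinatorial sums so
# they share no code path with the implementation.

# straight-loop fixed/random-effects meta-analysis
loop_meta <- function(effects, vars) {
  k <- length(effects)
  sw <- 0; swy <- 0
  for (i in seq_len(k)) {
    w <- 1 / vars[i]
    sw <- sw + w
    swy <- swy + w * effects[i]
  }
  mu <- swy / sw
  Q <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / vars[i]
    Q <- Q + w * (effects[i] - mu)^2
    sw2 <- sw2 + w * w
  }
  C <- sw - sw2 / sw
  tau2 <- max(0, (Q - (k - 1)) / C)
  srw <- 0; srwy <- 0
  for (i in seq_len(k)) {
    w <- 1 / (vars[i] + tau2)
    srw <- srw + w
    srwy <- srwy + w * effects[i]
  }
  list(Q = Q, df = k - 1, tau2 = tau2,
       fixed = mu, fixed_se = sqrt(1 / sw),
       random = srwy / srw, random_se = sqrt(1 / srw))
}

# brute-force hypergeometric right tail: P(X >= obs) for X ~ Hyper(N, K, n)
hyper_tail_enum <- function(N, K, n, obs) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  total <- 0
  for (j in seq(lo, hi)) {
    if (j >= obs)
      total <- total + choose(K, j) * choose(N - K, n - j)
  }
  total / choose(N, n)
}

# hand-built two-group study from explicit control/case matrices
make_study <- function(id, genes, ctrl, case, country = "USA", age = 5) {
  ctrl <- matrix(ctrl, nrow = length(genes))
  case <- matrix(case, nrow = length(genes))
  m <- cbind(ctrl, case)
  rownames(m) <- genes
  colnames(m) <- c(sprintf("%s_C%d", id, seq_len(ncol(ctrl))),
                   sprintf("%s_T%d", id, seq_len(ncol(case))))
  study_dataset(id, m,
                groups = c(rep("control", ncol(ctrl)),
                           rep("case", ncol(case))),
                country = country, study_age = age)
}
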