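# Independent brute-force oracles and small fixture builders.

# Upper-tail hypergeometric P(overlap >= k) by exhaustive enumeration of all
# C(N, n) draws of the cluster/query from the universe.
hyper_oracle <- function(k, n_success, n_universe, n_draw) {
  draws <- utils::combn(n_universe, n_draw)
  succ <- seq_len(n_success)  # w.l.o.g. the first n_success ids are successes
  hits <- apply(draws, 2, function(d) sum(d %in% succ))
  mean(hits >= k)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every split of the
# pooled values into groups of the observed sizes (matches the exact
# two-sided convention: 2 * min(P(W <= w), P(W >= w)), capped at 1).
wilcox_oracle <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(pooled), m)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Benjamini-Hochberg step-up closed form: p * m / rank with a cumulative
# minimum from the largest p downwards.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# AUC as the pairwise Mann-Whitney probability with ties counted one half.
auc_oracle <- function(older, young) {
  g <- expand.grid(o = older, y = young)
  mean((g$o > g$y) + 0.5 * (g$o == g$y))
}

# A tiny complete abundance matrix with metadata.
toy_cohort <- function(n_prot = 6, n_young = 4, n_old = 5, seed = 1) {
  set.seed(seed)
  n <- n_young + n_old
  x <- matrix(rnorm(n_prot * n, 20, 1), n_prot, n,
              dimnames = list(sprintf("P%02d", 1:n_prot),
                              sprintf("S%02d", 1:n)))
  meta <- data.frame(
    sample_id = colnames(x),
    age = c(runif(n_young, 20, 35), runif(n_old, 50, 90)),
    sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 24, 2),
    group = rep(c("young", "older"), c(n_young, n_old)))
  list(x = x, meta = meta)
}
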