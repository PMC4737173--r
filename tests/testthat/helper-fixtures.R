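# Programmatic fixtures shared across test files.

fc <- function(X, full, target = "t", channel = "plus") {
  fragment_counts(target, channel, X, full)
}

# Random stop-count tables (not necessarily model-generated): total reads
# split multinomially over the n stop sites and the full-length outcome.
random_count_table <- function(n, total, seed) {
  set.seed(seed)
  pr_plus <- rgamma(n + 1, shape = 0.6); pr_plus <- pr_plus / sum(pr_plus)
  pr_minus <- rgamma(n + 1, shape = 0.6); pr_minus <- pr_minus / sum(pr_minus)
  cp <- rmultinom(1, total, pr_plus)[, 1]
  cm <- rmultinom(1, total, pr_minus)[, 1]
  list(plus = fc(cp[1:n], cp[n + 1], channel = "plus"),
       minus = fc(cm[1:n], cm[n + 1], channel = "minus"))
}

# Dual-channel Poisson background with an optional planted spike.
spike_fixture <- function(n = 50, lambda = 10, spike_pos = 26, spike = 0,
                          full = 200, seed = 1) {
  set.seed(seed)
  xp <- rpois(n, lambda); xm <- rpois(n, lambda)
  if (spike > 0) { xp[spike_pos] <- spike; xm[spike_pos] <- spike }
  list(plus = fc(xp, full, "rnaIN", "plus"),
       minus = fc(xm, full, "rnaIN", "minus"))
}
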