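# Independent brute-force oracles, kept deliberately naive so they stay
# independent of the implementation paths they check.

# auROC as the exhaustive all-pairs count: P(pos > neg) + 0.5 P(pos == neg)
oracle_auroc <- function(pos_vals, neg_vals) {
  cmp <- outer(pos_vals, neg_vals, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# High-performance filter as a literal double loop over trials and windows.
oracle_high_perf <- function(correct, window = 10L, threshold = 0.8) {
  n <- length(correct)
  sel <- logical(n)
  for (i in seq_len(n)) {
    if (!correct[i]) next
    for (s in (i - window + 1L):i) {
      lo <- max(1L, s)
      hi <- min(n, s + window - 1L)
      if (lo > i || hi < i) next
      if (mean(correct[lo:hi]) >= threshold) { sel[i] <- TRUE; break }
    }
  }
  which(sel)
}

# Replay the three rule-switch criteria over a recorded session using only
# the correctness sequence; returns 0-based switch indices.
oracle_replay_switches <- function(correct, min_trials = 75L, window = 30L,
                                   threshold = 0.85) {
  n <- length(correct)
  last_switch <- 0L
  switches <- integer(0)
  for (t in seq_len(n - 1L)) {           # 0-based boundary before trial t
    if (t - last_switch >= min_trials &&
        mean(correct[(t - window + 1L):t]) >= threshold &&
        correct[t]) {
      switches <- c(switches, t)
      last_switch <- t
    }
  }
  switches
}

# Sliding centered truncated percentile, sample by sample.
oracle_running_percentile <- function(x, window, p) {
  n <- length(x)
  half <- window %/% 2L
  sapply(seq_len(n), function(i)
    quantile(x[max(1, i - half):min(n, i + half)], p / 100, names = FALSE))
}
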