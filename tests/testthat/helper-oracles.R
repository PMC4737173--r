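# Independent oracles used to cross-check the package's closed-form /
# optimized implementations. Deliberately simple and slow.

# Dense grid-search maximization of the explicit stop-process likelihood.
# The per-read RT walk factorizes per site: with m_minus (m_plus) reads
# reaching site k and Y (X) of them stopping there, the log likelihood of the
# per-encounter stop probabilities gamma (control) and beta = combined (+)
# channel probability, beta >= gamma, is binomial in each channel. The grid
# is taken in u = -log(1-beta), v = -log(1-gamma) (the scale on which the
# modification intensity raw = u - v lives), bounded by the same 1 - 1e-6
# frequency cap the estimator uses.
grid_theta_oracle <- function(plus, minus, coarse_step = 0.1, zooms = 3L) {
  u_max <- -log(1e-6)
  n <- length(plus$X)
  reach_p <- cumsum(plus$X) + plus$X_full
  reach_m <- cumsum(minus$X) + minus$X_full
  raw <- numeric(n)
  for (k in seq_len(n)) {
    X <- plus$X[k]; mp <- reach_p[k]
    Y <- minus$X[k]; mm <- reach_m[k]
    loglik <- function(u, v) {
      dbinom(X, mp, 1 - exp(-u), log = TRUE) +
        dbinom(Y, mm, 1 - exp(-v), log = TRUE)
    }
    best <- c(0, 0)
    step <- coarse_step
    ug <- unique(pmin(c(seq(0, u_max, by = step), u_max), u_max))
    vg <- ug
    g <- expand.grid(u = ug, v = vg)
    g <- g[g$u >= g$v, ]
    ll <- loglik(g$u, g$v)
    best <- c(g$u[which.max(ll)], g$v[which.max(ll)])
    for (z in seq_len(zooms)) {
      ug <- unique(pmax(0, pmin(u_max, best[1] + seq(-step, step, length.out = 21))))
      vg <- unique(pmax(0, pmin(u_max, best[2] + seq(-step, step, length.out = 21))))
      g <- expand.grid(u = ug, v = vg)
      g <- g[g$u >= g$v, ]
      ll <- loglik(g$u, g$v)
      best <- c(g$u[which.max(ll)], g$v[which.max(ll)])
      step <- step / 10
    }
    raw[k] <- best[1] - best[2]
  }
  if (sum(raw) == 0) rep(0, n) else raw / sum(raw)
}

# Brute-force all-offsets Hamming aligner mirroring the stop-inference
# contract: lowest-mismatch stratum, unique placement, 3'-overhanging
# placements anchored on >= min_anchor nt, stop = start - 1 (0 = full
# length), no-hit when the stop falls past the probed region.
brute_force_stop <- function(read, targets, max_mismatches = 1L,
                             min_anchor = 12L) {
  hm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  hits <- NULL
  for (tg in targets) {
    subj <- target_dna(tg)
    len <- nchar(subj); nr <- nchar(read)
    if (nr == 0) next
    for (p in seq_len(len)) {
      ov <- min(nr, len - p + 1L)
      full <- ov == nr
      if (!full && ov < min_anchor) next
      mm <- hm(substr(read, 1, ov), substr(subj, p, p + ov - 1L))
      if (mm <= max_mismatches) {
        hits <- rbind(hits, data.frame(target = tg$name, start = p, mm = mm))
      }
    }
  }
  if (is.null(hits)) return(list(target = NA_character_, stop = NA_integer_))
  hits <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  if (nrow(hits) != 1L) return(list(target = NA_character_, stop = NA_integer_))
  tg <- Filter(function(t) t$name == hits$target[1], targets)[[1]]
  stop_site <- hits$start[1] - 1L
  if (stop_site > probed_length(tg)) {
    return(list(target = NA_character_, stop = NA_integer_))
  }
  list(target = hits$target[1], stop = as.integer(stop_site))
}

# Exhaustive window scan: every window sum computed by direct summation.
brute_force_window_scan <- function(on, off, wl) {
  n <- length(on)
  starts <- seq_len(n - wl + 1L)
  s_on <- vapply(starts, function(s) sum(on[s:(s + wl - 1L)], na.rm = TRUE), numeric(1))
  s_off <- vapply(starts, function(s) sum(off[s:(s + wl - 1L)], na.rm = TRUE), numeric(1))
  d <- s_on - s_off
  list(best_start = which.max(d), best_diff = max(d),
       sums_on = s_on, sums_off = s_off)
}

# Textbook Welch statistic: t, Satterthwaite df, one-sided p for mean(a) >
# mean(b) ("greater") or < ("less").
welch_manual <- function(a, b, direction = "greater") {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- if (direction == "greater") pt(t, df, lower.tail = FALSE) else pt(t, df)
  list(t = t, df = df, p = p)
}

# Exhaustive suffix-prefix adapter scan (longest qualifying suffix removed).
brute_force_trim <- function(read, adapter, min_overlap = 5L) {
  len <- nchar(read)
  hm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  best <- NULL
  for (s in seq_len(len)) {
    ov <- len - s + 1L
    if (ov < min_overlap || ov > nchar(adapter)) next
    if (hm(substr(read, s, len), substr(adapter, 1, ov)) <= ov %/% 10L) {
      best <- s
      break  # smallest s = longest suffix
    }
  }
  if (is.null(best)) read else substr(read, 1, best - 1L)
}
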