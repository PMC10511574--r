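# Independent brute-force oracles. These deliberately avoid the package's
# code paths: choose()-ratio enumeration for the exact test, double loops for
# window labelling, and direct permutation enumeration for the rank tests.

# Fisher 2x2 by full enumeration over the margin-fixed support.
oracle_fisher_2x2 <- function(a, b, c, d,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  N <- a + b + c + d; r1 <- a + b; c1 <- a + c
  if (N == 0 || r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  ks <- max(0, r1 - (N - c1)):min(r1, c1)
  pk <- vapply(ks, function(k)
    choose(c1, k) * choose(N - c1, r1 - k) / choose(N, r1), numeric(1))
  pobs <- pk[ks == a]
  switch(alternative,
         two_sided = sum(pk[pk <= pobs * (1 + 1e-7)]),
         greater = sum(pk[ks >= a]),
         less = sum(pk[ks <= a]))
}

# Reflux-positive window labels by direct per-window scanning.
oracle_reflux_labels <- function(trace, grid, threshold_ph = 4,
                                 sustained_s = 5, drop_units = 1,
                                 drop_span_s = 5) {
  t <- trace$time_s; ph <- trace$ph; dt <- trace$sample_interval_s
  vapply(seq_len(grid$n), function(w) {
    ws <- grid$starts[w]; we <- grid$ends[w]
    # criterion A: scan every maximal global sub-threshold run
    below <- ph < threshold_ph
    i <- 1
    while (i <= length(t)) {
      if (below[i]) {
        j <- i
        while (j < length(t) && below[j + 1]) j <- j + 1
        rs <- t[i]; re <- min(t[j] + dt, grid$duration_s)
        if (min(re, we) - max(rs, ws) >= sustained_s - 1e-9) return(TRUE)
        i <- j + 1
      } else i <- i + 1
    }
    # criterion B: every ordered sample pair inside the window
    inw <- which(t >= ws & t < we)
    for (i in inw) for (j in inw) {
      if (t[j] > t[i] && t[j] - t[i] <= drop_span_s + 1e-9 &&
          ph[i] - ph[j] > drop_units) return(TRUE)
    }
    FALSE
  }, logical(1))
}

oracle_count_table <- function(r, s) {
  out <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_along(r)) {
    k <- if (s[i] && r[i]) "a" else if (s[i]) "b" else if (r[i]) "c" else "d"
    out[k] <- out[k] + 1
  }
  out
}

# Small regular test trace: ph vector sampled at dt seconds, all upright.
make_trace <- function(ph, dt = 6, id = "test", posture = NULL, meals = NULL,
                       duration_s = NULL) {
  ph_trace(id, (seq_along(ph) - 1) * dt, ph, dt, posture = posture,
           meals = meals, duration_s = duration_s)
}

# Two-sided permutation p for the two-sample rank-sum statistic, via distance
# of the rank sum from its null mean over all label assignments.
oracle_ranksum_perm <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x); N <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  sets <- utils::combn(N, n1)
  stat <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}
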