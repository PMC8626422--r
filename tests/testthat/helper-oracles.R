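# Independent oracles: deliberately naive implementations, kept free of any
# code path they are used to check.

# Textbook Welch-Satterthwaite two-sample test.
welch_oracle <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  n1 <- length(a)
  n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(difference = mean(a) - mean(b), t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df))
}

# Unpaired unequal-variance t statistic, closed form.
t_stat_oracle <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Stack-based flood fill, 8-connectivity; returns the component count.
flood_fill_count <- function(binary) {
  nr <- nrow(binary)
  nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!binary[r, cc] || seen[r, cc]) next
      count <- count + 1L
      stack <- list(c(r, cc))
      seen[r, cc] <- TRUE
      while (length(stack) > 0) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- cur[1] + dr
          c2 <- cur[2] + dc
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
              binary[rr, c2] && !seen[rr, c2]) {
            seen[rr, c2] <- TRUE
            stack[[length(stack) + 1L]] <- c(rr, c2)
          }
        }
      }
    }
  }
  count
}

# Double-loop Gaussian weighted sum, interior positions only (no edge rule).
smooth_oracle_interior <- function(x, width = 9, sd = 2) {
  half <- (width - 1) / 2
  kern <- stats::dnorm(-half:half, 0, sd)
  kern <- kern / sum(kern)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    acc <- 0
    for (o in -half:half) acc <- acc + kern[o + half + 1] * x[i + o]
    out[i] <- acc
  }
  out
}

# Linear-interpolation percentile (type 7), written from the definition.
percentile_oracle <- function(x, pct) {
  x <- sort(x)
  h <- (length(x) - 1) * pct / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Quadrant truth table, written as explicit independent rules.
quadrant_oracle <- function(rel_d, rel_p, res_d, res_p, alpha, d_min) {
  rel_sig_dz <- rel_p < alpha && rel_d < -d_min
  res_sig_abk <- res_p < alpha && res_d > d_min
  res_sig_dz <- res_p < alpha && res_d < -d_min
  if (rel_sig_dz && res_sig_abk) "blue"
  else if (res_sig_dz) "green"
  else "grey"
}
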