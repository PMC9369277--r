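# Independent oracles used to cross-check the implementation paths.

# Brute-force flood-fill connected-component labeling (BFS over an explicit
# queue), independent of the EBImage-based path.
flood_fill_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% h) + 1L; c <- ((cur - 1L) %/% h) + 1L
      for (j in seq_len(nrow(nb))) {
        rr <- r + nb[j, 1]; cc <- c + nb[j, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          i <- (cc - 1L) * h + rr
          if (mask[i] && lab[i] == 0L) {
            lab[i] <- k
            queue <- c(queue, i)
          }
        }
      }
    }
  }
  lab
}

# Exact two-tailed Mann-Whitney p by full enumeration of all
# choose(n1 + n2, n1) group labelings (tie-free data).
mwu_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  us <- utils::combn(n, n1, u_of)
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# Kruskal-Wallis H by direct evaluation of the rank-sum formula with tie
# correction.
kw_direct <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  ns <- lengths(groups)
  idx <- rep(seq_along(groups), ns)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(ns * (rbar - (n + 1) / 2)^2)
  t <- table(x)
  h / (1 - sum(t^3 - t) / (n^3 - n))
}

# Between-class-variance search over 256 candidate thresholds on [0, 1].
otsu_brute <- function(plane) {
  breaks <- seq(0, 1, length.out = 257)
  hist_counts <- tabulate(findInterval(plane, breaks, all.inside = TRUE), 256)
  mids <- (breaks[-1] + breaks[-257]) / 2
  n <- sum(hist_counts)
  best <- -Inf; best_t <- NA_real_
  for (k in 1:255) {
    w0 <- sum(hist_counts[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(hist_counts[1:k] * mids[1:k]) / sum(hist_counts[1:k])
    mu1 <- sum(hist_counts[(k + 1):256] * mids[(k + 1):256]) /
      sum(hist_counts[(k + 1):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- breaks[k + 1] }
  }
  best_t
}

# Brute-force lookup table for the IHS percentage bins as printed.
percentage_score_lookup <- function(pct) {
  if (pct < 1) 0L else if (pct <= 10) 1L else if (pct <= 50) 2L
  else if (pct <= 80) 3L else 4L
}
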