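# Independent oracles used to cross-check the implementation. These are
# deliberately written as literal enumerations/recursions, not via the
# package's own code paths.

# isotonic max-min estimator by exhaustive (u, v) enumeration
iso_oracle <- function(xbar, n, increasing = TRUE) {
  K <- length(xbar)
  mu <- numeric(K)
  for (i in 1:K) {
    outer_best <- if (increasing) -Inf else Inf
    for (u in 1:i) {
      inner_best <- if (increasing) Inf else -Inf
      for (v in u:K) {
        m <- sum(n[u:v] * xbar[u:v]) / sum(n[u:v])
        inner_best <- if (increasing) min(inner_best, m) else
          max(inner_best, m)
      }
      outer_best <- if (increasing) max(outer_best, inner_best) else
        min(outer_best, inner_best)
    }
    mu[i] <- outer_best
  }
  mu
}

# Benjamini-Hochberg step-up by the literal recursion
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  q[m] <- min(1, ps[m])
  if (m > 1) {
    for (i in (m - 1):1) q[i] <- min(q[i + 1], min(1, m * ps[i] / i))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# two-tailed Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (standard float slack on the tie rule)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# pooled-sd Williams-type statistic computed directly from group summaries
williams_oracle <- function(y, grp) {
  grp <- as.factor(grp)
  xbar <- as.numeric(tapply(y, grp, mean))
  n <- as.numeric(table(grp))
  K <- length(xbar)
  s <- sqrt(sum((y - xbar[as.integer(grp)])^2) / (length(y) - K))
  if (s == 0) return(0)
  t_for <- function(mu) max(abs(mu[-1] - xbar[1]) /
                              (s * sqrt(1 / n[-1] + 1 / n[1])))
  max(t_for(iso_oracle(xbar, n, TRUE)), t_for(iso_oracle(xbar, n, FALSE)))
}

# deterministic toy dataset: 3 probes x 6 samples, 3 dose levels
toy_dataset <- function() {
  vals <- rbind(
    p_flat = c(5, 5, 5, 5, 5, 5),
    p_up = c(8.0, 8.2, 8.9, 9.1, 10.0, 10.2),
    p_down = c(9.5, 9.4, 8.8, 8.7, 8.1, 8.0))
  colnames(vals) <- paste0("s", 1:6)
  expression_dataset(vals, doses = c(0, 0, 1, 1, 10, 10), log_base = 2)
}
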