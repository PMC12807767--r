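# Independent oracles used to freeze expected values; these deliberately
# avoid the code paths they check.

# Upper binomial tail by direct pmf summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i)
    choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed)
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(na)])
  combos <- combn(n, na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form OLS
oracle_ols <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = beta, r_squared = r2)
}

# Leftmost representation of a single contiguous deletion/insertion that
# turns `ref` into `obs` (brute force over shift positions); returns the
# 0-based anchored (pos, ref, alt) triple, VCF-style
oracle_leftmost_indel <- function(ref, obs) {
  lr <- nchar(ref); lo <- nchar(obs)
  stopifnot(lr != lo)
  for (pos in 0:(min(lr, lo) - 1)) {
    if (lr > lo) {               # deletion of (lr - lo) bases after pos
      cand <- paste0(substr(ref, 1, pos), substr(ref, pos + (lr - lo) + 1, lr))
      if (cand == obs)
        return(list(pos = pos - 1,
                    ref = substr(ref, pos, pos + (lr - lo)),
                    alt = substr(ref, pos, pos)))
    } else {                     # insertion
      cand <- paste0(substr(obs, 1, pos), substr(obs, pos + (lo - lr) + 1, lo))
      if (cand == ref)
        return(list(pos = pos - 1,
                    ref = substr(obs, pos, pos),
                    alt = substr(obs, pos, pos + (lo - lr))))
    }
  }
  stop("no single indel explains the pair")
}
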