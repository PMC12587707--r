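# Independent oracles, deliberately implemented from first principles and
# never sharing code with the package paths they check.

# pooled-variance two-sample t with group sizes 1 and length(rest);
# the single observation contributes zero sum of squares.
oracle_pooled_t <- function(x, rest) {
  n1 <- 1L
  n2 <- length(rest)
  ss2 <- sum((rest - mean(rest))^2)
  sp2 <- (0 + ss2) / (n1 + n2 - 2L)
  tt <- (x - mean(rest)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2L, p = 2 * pt(-abs(tt), n1 + n2 - 2L))
}

# literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} min(1, p_(j)*n/j)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# two-sided Fisher exact p by full hypergeometric enumeration over the
# conditional distribution (sum of outcomes no more probable than observed)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# permutation p value for a Pearson correlation, B label shuffles
oracle_perm_cor_p <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  r_obs <- abs(cor(x, y))
  perm <- replicate(B, sample(y))
  r_perm <- abs(as.numeric(cor(x, perm)))
  (1 + sum(r_perm >= r_obs - 1e-12)) / (B + 1)
}

# build vectors with an exact Pearson correlation r
make_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))
  xu <- as.numeric(scale(x))
  zu <- as.numeric(scale(z))
  list(x = xu, y = r * xu + sqrt(1 - r^2) * zu)
}
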