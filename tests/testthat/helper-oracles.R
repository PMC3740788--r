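# Independent loop-based reference implementations used as oracles.
# Deliberately written with explicit loops and hand-rolled quantile /
# median helpers so they share no code path with the package.

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# linear-interpolation quantile (R type 7), written out by hand
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_mad <- function(x) {
  m <- oracle_median(x)
  dev <- numeric(length(x))
  for (i in seq_along(x)) dev[i] <- abs(x[i] - m)
  1.4826 * oracle_median(dev)
}

oracle_t <- function(x, is_tumor) {
  xn <- x[!is_tumor & !is.na(x)]
  xt <- x[is_tumor & !is.na(x)]
  n1 <- length(xn); n2 <- length(xt)
  s1 <- 0; for (v in xn) s1 <- s1 + v
  s2 <- 0; for (v in xt) s2 <- s2 + v
  m1 <- s1 / n1; m2 <- s2 / n2
  ss <- 0
  for (v in xn) ss <- ss + (v - m1)^2
  for (v in xt) ss <- ss + (v - m2)^2
  sp2 <- ss / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) return(NA_real_)
  (m2 - m1) / se
}

oracle_copa <- function(x, is_tumor, r = 90) {
  obs <- x[!is.na(x)]
  med <- oracle_median(obs)
  scale <- oracle_mad(obs)
  if (scale == 0) return(NA_real_)
  xt <- x[is_tumor & !is.na(x)]
  z <- numeric(length(xt))
  for (i in seq_along(xt)) z[i] <- (xt[i] - med) / scale
  oracle_quantile(z, r / 100)
}

oracle_os <- function(x, is_tumor) {
  obs <- x[!is.na(x)]
  med <- oracle_median(obs)
  scale <- oracle_mad(obs)
  if (scale == 0) return(NA_real_)
  z_all <- (obs - med) / scale
  q25 <- oracle_quantile(z_all, 0.25)
  q75 <- oracle_quantile(z_all, 0.75)
  cutoff <- q75 + (q75 - q25)
  total <- 0
  xt <- x[is_tumor & !is.na(x)]
  for (v in xt) {
    z <- (v - med) / scale
    if (z > cutoff) total <- total + z
  }
  total
}

oracle_ort <- function(x, is_tumor) {
  xn <- x[!is_tumor & !is.na(x)]
  xt <- x[is_tumor & !is.na(x)]
  med_n <- oracle_median(xn)
  med_t <- oracle_median(xt)
  resid <- c()
  for (v in xn) resid <- c(resid, abs(v - med_n))
  for (v in xt) resid <- c(resid, abs(v - med_t))
  scale <- 1.4826 * oracle_median(resid)
  if (scale == 0) return(NA_real_)
  q25 <- oracle_quantile(xn, 0.25)
  q75 <- oracle_quantile(xn, 0.75)
  cutoff <- q75 + (q75 - q25)
  total <- 0
  hit <- FALSE
  for (v in xt) {
    if (v > cutoff) {
      total <- total + (v - med_n)
      hit <- TRUE
    }
  }
  if (!hit) return(0)
  total / scale
}

oracle_most <- function(x, is_tumor, null_table) {
  xn <- x[!is_tumor & !is.na(x)]
  xt <- x[is_tumor & !is.na(x)]
  med_n <- oracle_median(xn)
  scale <- oracle_mad(xn)
  if (scale == 0) return(NA_real_)
  z <- sort((xt - med_n) / scale, decreasing = TRUE)
  best <- -Inf
  m <- 0
  for (k in seq_along(z)) {
    m <- m + z[k]
    val <- (m - null_table$mu[k]) / null_table$sigma[k]
    if (val > best) best <- val
  }
  best
}

# exact hypergeometric upper tail via factorials (valid for N <= 60)
oracle_hyper_tail <- function(k, K, n, N) {
  ch <- function(a, b) {
    if (b < 0 || b > a) return(0)
    factorial(a) / (factorial(b) * factorial(a - b))
  }
  total <- 0
  for (j in k:min(K, n)) total <- total + ch(K, j) * ch(N - K, n - j)
  total / ch(N, n)
}

# Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    adj[ord[i]] <- running
  }
  adj
}

# posterior mean E[S | X = x] of the normal + exponential convolution,
# by direct numerical integration
oracle_normexp_posterior <- function(x, mu, sigma, alpha) {
  num <- stats::integrate(function(s)
    s * stats::dexp(s, rate = 1 / alpha) * stats::dnorm(x - s, mu, sigma),
    0, Inf, rel.tol = 1e-12)$value
  den <- stats::integrate(function(s)
    stats::dexp(s, rate = 1 / alpha) * stats::dnorm(x - s, mu, sigma),
    0, Inf, rel.tol = 1e-12)$value
  num / den
}
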