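# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written as plain loops over the defining
# formulas, sharing no code with the implementation under test.

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

oracle_pr <- function(v) {
  s1 <- 0; s2 <- 0
  for (x in v) {
    s1 <- s1 + x
    s2 <- s2 + x^2
  }
  s1^2 / s2
}

oracle_rvl <- function(phases) {
  cs <- 0; sn <- 0
  for (p in phases) {
    cs <- cs + cos(p)
    sn <- sn + sin(p)
  }
  list(rvl = sqrt(cs^2 + sn^2) / length(phases),
       pref = atan2(sn, cs) %% (2 * pi))
}

# textbook Benjamini-Hochberg step-up: reject the smallest k p-values where
# k = max { i : p_(i) <= q * i / m }
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= q * i / m) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

oracle_band_accuracy <- function(conf, band) {
  hit <- 0; tot <- 0
  for (i in seq_len(nrow(conf))) {
    for (j in seq_len(ncol(conf))) {
      tot <- tot + conf[i, j]
      if (abs(i - j) <= band) hit <- hit + conf[i, j]
    }
  }
  hit / tot
}

oracle_poisson_deviance <- function(y, mu) {
  d <- 0
  for (i in seq_along(y)) {
    ll_sat <- if (y[i] > 0) y[i] * log(y[i]) - y[i] else 0
    ll_mod <- y[i] * log(mu[i]) - mu[i]
    d <- d + 2 * (ll_sat - ll_mod)
  }
  d
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
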