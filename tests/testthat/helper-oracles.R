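# Independent oracles used across tests. These are deliberately naive,
# literal implementations kept separate from the package's code paths.

# Benjamini-Hochberg by hand: q_i = min over j >= rank(i) of p_(j) * m / j
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact binomial lower tail by direct pmf summation
binom_lower_tail <- function(k, n, p) {
  sum(vapply(0:k, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# beta-binomial log-pmf, literal form
bb_logpmf <- function(k, n, a, b) {
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# grid-search ML overdispersion oracle: same grid definition as the spec,
# naive double loop over grid and colonies
bb_grid_ml_oracle <- function(alt, depth) {
  mu <- min(max(sum(alt) / sum(depth), 1e-9), 1 - 1e-9)
  grid <- c(1e-4, exp(seq(log(2e-4), log(0.999), length.out = 60)))
  ll <- vapply(grid, function(rho) {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    sum(mapply(function(k, n) bb_logpmf(k, n, a, b), alt, depth))
  }, 0)
  grid[which.max(ll)]
}

# KDE deepest-local-minimum oracle for valley finding
kde_valley_oracle <- function(scores) {
  d <- stats::density(scores, bw = "nrd0")
  s <- diff(sign(diff(d$y)))
  minima <- which(s == 2) + 1L
  maxima <- which(s == -2) + 1L
  if (length(maxima) < 2L) return(NA_real_)
  top2 <- sort(maxima[order(d$y[maxima], decreasing = TRUE)][1:2])
  between <- minima[minima > top2[1] & minima < top2[2]]
  if (!length(between)) return(NA_real_)
  d$x[between[which.min(d$y[between])]]
}

# exhaustive PWM score-tail oracle: enumerate all 4^L sequences
pwm_tail_oracle <- function(pwm, score) {
  L <- ncol(pwm)
  bases <- 1:4
  seqs <- as.matrix(expand.grid(rep(list(bases), L)))
  logodds <- log(pwm / 0.25)
  scores <- rowSums(matrix(logodds[cbind(as.vector(seqs),
                                         rep(seq_len(L), each = nrow(seqs)))],
                           nrow(seqs)))
  mean(scores >= score - 1e-6)
}

# small default config for fast end-to-end runs
small_config <- function(seed = 1L) {
  sim_config(seed = seed, n_colonies = 12L, n_germline_sites = 300L,
             n_somatic_sites = 300L, n_artifact_sites = 150L)
}
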