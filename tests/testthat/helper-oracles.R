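# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed-form antiderivatives, combinatorial
# enumeration, and textbook formulas.

# integral of mean*(1 + a*cos(2*pi*(t - peak)/24)) over [lo, hi]
cosine_integral_oracle <- function(lo, hi, peak, rel_amplitude, mean_level = 1) {
  a <- rel_amplitude - 1
  om <- 2 * pi / 24
  mean_level * ((hi - lo) + (a / om) * (sin(om * (hi - peak)) -
                                          sin(om * (lo - peak))))
}

# normalised abundance of a unit-mean rectangular pulse wholly inside the
# light (or dark) interval: numerator 24*R (or 24), denominator (R-1)*td + 24
pulse_pn_oracle <- function(t_dusk, R, in_light) {
  (if (in_light) 24 * R else 24) / ((R - 1) * t_dusk + 24)
}

# P(X >= k) for X ~ Hypergeometric(N, K, n), by direct combinatorial sum
hyper_upper_oracle <- function(N, K, n, k) {
  xs <- max(0, k):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# relative change score used throughout
delta_oracle <- function(p1, p2) (p2 - p1) / ((p1 + p2) / 2)
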