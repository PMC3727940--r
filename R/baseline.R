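# Baseline cumulative hazard utilities shared by the simulator and the likelihoods.
# Piecewise-constant hazard: rates lambda_k on half-open pieces (tau_{k-1}, tau_k].

# Lambda0(t) for a piecewise-constant hazard; vectorized over t
cumhaz_pem <- function(t, rates, cuts) {
  K <- length(cuts) + 1L
  stopifnot(length(rates) == K)
  lower <- c(0, cuts)
  upper <- c(cuts, Inf)
  out <- numeric(length(t))
  for (k in seq_len(K)) {
    out <- out + rates[k] * pmax(0, pmin(t, upper[k]) - lower[k])
  }
  out
}

# inverse of cumhaz_pem; requires all rates > 0
invcumhaz_pem <- function(v, rates, cuts) {
  lower <- c(0, cuts)
  cum_at_cut <- cumhaz_pem(cuts, rates, cuts)
  j <- findInterval(v, cum_at_cut, left.open = TRUE) + 1L
  lower[j] + (v - c(0, cum_at_cut)[j]) / rates[j]
}
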