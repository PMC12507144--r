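# Independent brute-force oracles used by the statistics tests.

# Two-sided Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins.
fisherBruteForce <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  aa <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(aa, c1, n - c1, r1)
  pObs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exact two-sided McNemar p by binomial enumeration.
mcnemarBruteForce <- function(b, c) {
  n <- b + c
  if (n == 0) return(NA_real_)
  k <- 0:n
  probs <- choose(n, k) / 2^n
  pObs <- choose(n, min(b, c)) / 2^n
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
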