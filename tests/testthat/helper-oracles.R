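# Independent brute-force oracles. These deliberately take a different route
# than the package: probabilities are computed from dnbinom/dpois products at
# an arbitrary fixed mean and normalized, and hypergeometric tails are summed
# from binomial coefficients.

# two-sided minimum-likelihood exact-test p for the split (z1 | z2) of a
# gene's total between groups of s1 and s2 samples under NB dispersion phi
oracle_exact_p <- function(z1, z2, s1, s2, phi, mu = 3.7) {
  t <- z1 + z2
  if (t == 0) return(1)
  y <- 0:t
  f <- function(z, s) {
    if (phi == 0) dpois(z, s * mu) else dnbinom(z, size = s / phi, mu = s * mu)
  }
  w <- f(y, s1) * f(t - y, s2)
  probs <- w / sum(w)
  min(sum(probs[probs <= probs[z1 + 1] * (1 + 1e-9)]), 1)
}

# hypergeometric upper tail P(X >= k) by summing binomial coefficients
oracle_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  if (length(kk) == 0 || k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# an evidence_set built directly, bypassing build_evidence, for enrichment
# oracle checks
fake_evidence <- function(evidence, drug_targets = character(0),
                          specimen = "SP1") {
  structure(list(specimen = specimen, de_genes = evidence,
                 aberrant_genes = character(0), mutated_genes = character(0),
                 drug_target_genes = drug_targets,
                 de_direction = setNames(rep(1, length(evidence)), evidence),
                 min_impact = "moderate", cnv = NULL),
            class = "evidence_set")
}
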