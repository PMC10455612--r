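# Independent brute-force oracles, written directly from the model
# definition.  They deliberately avoid the package's own kernels (no log-sum
# -exp, plain arithmetic) so the fast implementations are checked against a
# transparent reference.

oracle_ggum_probs <- function(theta, alpha, delta, tau) {
  C <- length(tau)
  M <- 2 * C + 1
  num <- sapply(0:C, function(z) {
    tsum <- if (z == 0) 0 else sum(tau[1:z])
    exp(alpha * (z * (theta - delta) - tsum)) +
      exp(alpha * ((M - z) * (theta - delta) - tsum))
  })
  num / sum(num)
}

oracle_loglik <- function(Z, theta, trait, alpha, delta, tau) {
  total <- 0
  for (j in seq_len(nrow(Z)))
    for (i in seq_len(ncol(Z))) {
      z <- Z[j, i]
      if (is.na(z)) next
      p <- oracle_ggum_probs(theta[j, trait[i]], alpha[i], delta[i], tau[i, ])
      total <- total + log(p[z + 1])
    }
  total
}

# small deterministic item bank used across tests
toy_bank <- function(C = 1, I = 4, D = 2) {
  set.seed(99)
  item_bank(trait = rep(seq_len(D), length.out = I),
            alpha = runif(I, 0.6, 1.8),
            delta = runif(I, -1.8, 1.8),
            tau = matrix(runif(I * C, -2.5, -0.5), nrow = I))
}
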