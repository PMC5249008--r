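# Shared fixtures built in code.

toy_counts <- function() {
  m <- matrix(c(0L, 0L, 4L,
                1L, 1L, 2L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  m
}

# A well-separated bimodal gene: low cluster ~Gamma(2,2), high ~Normal(10,1).
bimodal_values <- function(n_low = 100, n_high = 100, seed = 1,
                           low_mean = 1, high_mean = 10) {
  withr::with_seed(seed, {
    c(rgamma(n_low, shape = 2, rate = 2 / low_mean),
      rnorm(n_high, high_mean, 1))
  })
}

# Tiny binary activity matrix with anchors and two differential genes.
toy_binary <- function() {
  cells <- paste0("c", 1:8)
  m <- rbind(
    OMP    = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    GAP43  = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
    matgen = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
    immgen = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
    flat   = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  )
  colnames(m) <- cells
  m
}

# Independent enumeration oracle for the two-sided Fisher p-value:
# hypergeometric probabilities from lchoose sums, minimum-likelihood rule.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct density-ratio posterior (no logistic shortcut); e_step oracle.
posterior_ratio_oracle <- function(x, alpha, beta, mu, sigma2, rho) {
  fg <- dgamma(x, shape = alpha, rate = beta)
  fn <- dnorm(x, mu, sqrt(sigma2))
  rho * fn / (rho * fn + (1 - rho) * fg)
}
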