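# Independent oracle: simulate one line's trajectory by sampling each
# offspring status from the categorical distribution given by the mother's
# row of the transition matrix (never via per-strain Bernoulli retention).
oracle_simulate_line <- function(m, n_generations, founder = "coinfected") {
  statuses <- infection_statuses()
  s <- founder
  out <- character(n_generations + 1L)
  out[1L] <- s
  for (g in seq_len(n_generations)) {
    s <- sample(statuses, 1L, prob = unclass(m)[s, ])
    out[g + 1L] <- s
  }
  out
}

# Joint probability of (keep strain 1, keep strain 2) under independent
# Bernoulli retention, for a mother of the given status — closed form used
# to prove the factorisation of each matrix row.
bernoulli_row <- function(status, p1, p2) {
  has1 <- status %in% c("strain1", "coinfected")
  has2 <- status %in% c("strain2", "coinfected")
  k1 <- if (has1) c(1 - p1, p1) else c(1, 0)
  k2 <- if (has2) c(1 - p2, p2) else c(1, 0)
  c(
    uninfected = k1[1] * k2[1],
    strain1    = k1[2] * k2[1],
    strain2    = k1[1] * k2[2],
    coinfected = k1[2] * k2[2]
  )
}

random_params <- function() {
  strain_params(runif(1), runif(1))
}
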