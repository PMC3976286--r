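# Independent Monte-Carlo oracles used to validate closed-form results.

# Branching-process simulation of the two-stage model: initiation events are
# a Poisson process with rate nu; each initiated clone is a birth-death-
# mutation process (division alpha, death beta, transformation mu2) followed
# by Gillespie steps. Returns the fraction of replicates with no malignant
# cell by time t.
mc_tsce_survival <- function(t, nu, alpha, beta, mu2, n_rep = 2e4) {
  tot <- alpha + beta + mu2
  ok <- 0L
  for (i in seq_len(n_rep)) {
    k <- rpois(1, nu * t)
    mal <- FALSE
    if (k > 0) {
      for (u in runif(k, 0, t)) {
        s <- u
        pop <- 1L
        while (pop > 0L && s < t) {
          s <- s + rexp(1, pop * tot)
          if (s >= t) break
          e <- runif(1)
          if (e < alpha / tot) pop <- pop + 1L
          else if (e < (alpha + beta) / tot) pop <- pop - 1L
          else { mal <- TRUE; break }
        }
        if (mal) break
      }
    }
    if (!mal) ok <- ok + 1L
  }
  ok / n_rep
}

# First event of an inhomogeneous Poisson process with hazard
# h(t) = rate0 * lambda * exp(lambda * t), simulated by year-by-year
# thinning (candidates at the segment's upper-bound rate, accepted with
# probability h(u)/bound). Returns event times, Inf when none by t_max.
mc_first_event_times <- function(n_rep, lambda, rate0, t_max = 40) {
  out <- rep(Inf, n_rep)
  h <- function(u) rate0 * lambda * exp(lambda * u)
  for (i in seq_len(n_rep)) {
    for (k in seq_len(ceiling(t_max))) {
      bound <- h(k)
      m <- rpois(1, bound)
      if (m == 0) next
      u <- sort(runif(m, k - 1, k))
      acc <- u[runif(m) < h(u) / bound]
      if (length(acc)) { out[i] <- acc[1]; break }
    }
  }
  out
}

# small balanced parameter set (cell-count metastasis units) giving a rich
# stage mix, used where a property needs all three stages populated
balanced_params <- function() {
  progression_params(met_size_unit = "cells")
}
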