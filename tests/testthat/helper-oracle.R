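# Brute-force, term-by-term evaluation of the similarity measure, kept
# deliberately independent of the package's vectorized implementation:
# scalar loops, linear id search, iterative angle wrapping.

oracle_wrap <- function(a) {
  while (a > 180) a <- a - 360
  while (a < -180) a <- a + 360
  a
}

oracle_firing_rate <- function(stored, current, params,
                               weight_mode = "current") {
  if (current$n == 0 || stored$n == 0) return(0)
  denom <- if (weight_mode == "current") {
    sum(current$saliency)
  } else {
    d <- 0
    for (i in seq_len(current$n)) {
      for (k in seq_len(stored$n)) {
        if (stored$id[k] == current$id[i]) d <- d + current$saliency[i]
      }
    }
    if (d == 0) return(0)
    d
  }
  f <- 0
  for (i in seq_len(current$n)) {
    for (k in seq_len(stored$n)) {
      if (stored$id[k] == current$id[i]) {
        dd <- current$distance[i] - stored$distance[k]
        dth <- oracle_wrap(current$bearing[i] - stored$bearing[k])
        f <- f + (current$saliency[i] / denom) *
          exp(-(params$w_d * dd^2 / params$sigma_d2 +
                params$w_theta * dth^2 / params$sigma_theta2))
      }
    }
  }
  f
}

# Random small place code drawing ids from a shared pool so that stored
# and current codes overlap partially.
random_code <- function(n_max = 5, id_pool = 0:7) {
  n <- sample(0:n_max, 1)
  new_place_code(
    id = if (n > 0) sample(id_pool, n) else integer(0),
    saliency = runif(n, 0.1, 2),
    bearing = runif(n, 0, 360),
    distance = runif(n, 0, 30)
  )
}

random_params <- function() {
  firing_params(sigma_d2 = runif(1, 1, 100),
                sigma_theta2 = runif(1, 1, 400),
                w_d = sample(0:1, 1), w_theta = sample(0:1, 1),
                frt = runif(1))
}

baseline_config <- function(...) {
  run_config(...)
}
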