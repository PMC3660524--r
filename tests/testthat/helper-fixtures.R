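# shared fixtures built in code

# report every failure rather than stopping at the default cap
options(testthat.progress.max_fails = 100)

# theta scores drawn around the class means of a configuration
sim_theta_for_config <- function(n, config, means = c(0.02, 0.26, 0.50, 0.74, 0.98),
                                 sd = 0.02) {
  p <- dosage_probabilities(config[1], config[2])
  g <- sample(0:4, n, replace = TRUE, prob = p)
  list(
    dosage = g,
    theta = pmin(pmax(means[g + 1] + rnorm(n, 0, sd), 0), 1)
  )
}

# a small phased chromosome with mixed configurations and its map tibble
toy_chromosome <- function() {
  p1pat <- c("BAAA", "AABB", "BAAA", "ABAA", "AABA", "BBAA", "AAAB", "ABAA", "AABB", "BAAA")
  p2pat <- c("AAAA", "AAAA", "BAAA", "AABA", "AAAA", "ABAA", "AAAB", "AAAA", "ABBA", "AABA")
  list(
    parent1 = phased_parent(p1pat),
    parent2 = phased_parent(p2pat),
    map = tibble::tibble(
      snp = paste0("S", 1:10), position_cm = seq(0, 18, 2),
      phase_p1 = p1pat, phase_p2 = p2pat
    )
  )
}
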