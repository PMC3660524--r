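# 36-state genotype reconstruction

test_that("state compatibility counts match the worked example", {
  expect_identical(sum(compatible_genotypes("AABB", "AABB", 4)), 1L)
  expect_identical(sum(compatible_genotypes("AAAA", "ABAA", 1)), 18L)
  expect_identical(sum(compatible_genotypes("AAAB", "BBAA", 2)), 15L)
  expect_identical(sum(compatible_genotypes("AABB", "ABAB", 4)), 1L)
  st <- genotype_states()
  expect_identical(st$name[compatible_genotypes("AABB", "AABB", 4) == 1], "cdgh")
  expect_identical(st$name[compatible_genotypes("AABB", "ABAB", 4) == 1], "cdfh")
  # missing dosage is compatible with everything
  expect_identical(sum(compatible_genotypes("AABB", "AABB", NA)), 36L)
})

test_that("recombination distances for pairing (ab)(cd)x(ef)(gh) are right", {
  ps <- pairing_states(1, 1)
  st <- genotype_states()
  nm <- st$name[ps$states]
  d_from_aceg <- setNames(ps$d[which(nm == "aceg"), ], nm)
  expected <- c(
    aceg = 0, aceh = 1, acfg = 1, acfh = 2,
    adeg = 1, adeh = 2, adfg = 2, adfh = 3,
    bceg = 1, bceh = 2, bcfg = 2, bcfh = 3,
    bdeg = 2, bdeh = 3, bdfg = 3, bdfh = 4
  )
  expect_equal(d_from_aceg[names(expected)], expected)
  # symmetry and zero diagonal
  expect_identical(ps$d, t(ps$d))
  expect_true(all(diag(ps$d) == 0))
  # the union of reachable states over the 9 pairings covers all 36
  all_states <- unique(unlist(lapply(1:3, function(p1) {
    lapply(1:3, function(p2) pairing_states(p1, p2)$states)
  })))
  expect_identical(sort(all_states), 1:36)
})

test_that("transition matrices are stochastic with the stated entries", {
  ps <- pairing_states(1, 1)
  st <- genotype_states()
  nm <- st$name[ps$states]
  for (r in c(0.01, 0.1, 0.3)) {
    A <- transition_matrix(r, ps)
    expect_equal(unname(rowSums(A)), rep(1, 16))
    expect_equal(A[which(nm == "aceg"), which(nm == "bdfh")], r^4)
  }
  expect_equal(transition_matrix(0, ps), diag(16))
})

test_that("emission probabilities implement the error model", {
  expect_equal(emission_probability(c(1, 0), 0), c(1, 0))
  expect_equal(emission_probability(c(1, 0), 0.01), c(0.99, 0.01))
  expect_error(emission_probability(1, 0.6), "0, 0.5")
})

test_that("forward-backward matches brute-force path enumeration", {
  set.seed(401)
  for (rep in 1:8) {
    K <- sample(3:4, 1)
    pats1 <- replicate(K, paste(sample(c("A", "B"), 4, TRUE), collapse = ""))
    pats2 <- replicate(K, paste(sample(c("A", "B"), 4, TRUE), collapse = ""))
    map <- tibble::tibble(
      snp = paste0("M", 1:K), position_cm = cumsum(c(0, runif(K - 1, 1, 8))),
      phase_p1 = pats1, phase_p2 = pats2
    )
    p1 <- phased_parent(pats1)
    p2 <- phased_parent(pats2)
    sim <- simulate_population(p1, p2, map_cm = map$position_cm, n = 1)
    dos <- sim$dosage
    colnames(dos) <- map$snp
    h <- hmm_genotype_probs(dos, map, lambda = 0.01)
    bf <- hmm_brute_force(as.vector(sim$dosage), map, lambda = 0.01)
    expect_lt(max(abs(h$prob[1, , ] - bf$prob)), 1e-10)
    expect_equal(unname(h$pairing_loglik[1, ]), bf$pairing_loglik,
      tolerance = 1e-10
    )
    expect_equal(unname(rowSums(h$prob[1, , ])), rep(1, K))
  }
})

test_that("the worked four-SNP reconstruction concentrates on cdfh", {
  map <- tibble::tibble(
    snp = paste0("M", 1:4), position_cm = c(0, 1, 2, 3),
    phase_p1 = c("AABB", "AAAA", "AAAB", "AABB"),
    phase_p2 = c("AABB", "ABAA", "BBAA", "ABAB")
  )
  dos <- matrix(c(4, 1, 2, 4), 1, 4)
  colnames(dos) <- map$snp
  h <- hmm_genotype_probs(dos, map, lambda = 0.001)
  st <- genotype_states()
  # after the recombination between M1 and M2, the genotype is cdfh
  expect_identical(st$name[which.max(h$prob[1, 2, ])], "cdfh")
  expect_identical(st$name[which.max(h$prob[1, 3, ])], "cdfh")
  expect_identical(st$name[which.max(h$prob[1, 1, ])], "cdgh")
  # an impossible sequence under every pairing needs lambda > 0
  dos2 <- dos
  dos2[1, 2] <- 3
  expect_error(
    hmm_genotype_probs(dos2, map, lambda = 0),
    "lambda"
  )
  expect_silent(hmm_genotype_probs(dos2, map, lambda = 0.001))
})

test_that("grid interpolation passes through knots and renormalises", {
  chrom <- toy_chromosome()
  sim <- simulate_population(chrom$parent1, chrom$parent2,
    map_cm = chrom$map$position_cm, n = 20, seed = 411
  )
  dos <- sim$dosage
  colnames(dos) <- chrom$map$snp
  h <- hmm_genotype_probs(dos, chrom$map)
  g <- interpolate_grid(h, step = 1)
  # knot positions reproduce the SNP posteriors
  at <- match(chrom$map$position_cm, g$grid_cm)
  expect_lt(max(abs(g$prob[, at, ] - h$prob)), 1e-8)
  # every column is a distribution
  expect_equal(range(apply(g$prob, c(1, 2), sum)), c(1, 1))
  expect_true(all(g$prob >= 0 & g$prob <= 1))
})

test_that("genotype recovery is high on an informative chromosome", {
  # a dense chromosome mixing configurations with varied phases, so every
  # homologue carries a distinct allele signature (a chromosome of
  # identically phased double-duplex SNPs would confound the two parents'
  # contributions, since only their sum is observed)
  chrom <- toy_chromosome()
  bench <- genotype_recovery_benchmark(chrom$parent1, chrom$parent2,
    chrom$map, n = 80, seed = 421)
  expect_gt(bench$prop_correct, 0.8)

  # a chromosome of parent-1 simplex SNPs cannot resolve parent 2
  pats1 <- c("BAAA", "ABAA", "AABA", "AAAB", "BAAA", "ABAA", "AABA", "AAAB")
  mapS <- tibble::tibble(
    snp = paste0("s", 1:8), position_cm = seq(0, 14, 2),
    phase_p1 = pats1, phase_p2 = rep("AAAA", 8)
  )
  benchS <- genotype_recovery_benchmark(
    phased_parent(pats1),
    phased_parent(rep("AAAA", 8)), mapS,
    n = 60, seed = 422
  )
  expect_lt(benchS$prop_correct, bench$prop_correct)
  expect_lt(benchS$prop_correct, 0.5)
})
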