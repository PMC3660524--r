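# recombination fraction, LOD and phase estimation

test_that("phase enumeration counts and labels are right", {
  ss <- enumerate_phases(c(1, 0), c(1, 0))
  expect_identical(nrow(ss), 2L)
  expect_setequal(ss$phase, c("C", "R"))

  dd <- enumerate_phases(c(2, 0), c(2, 0))
  expect_identical(nrow(dd), 3L)
  expect_setequal(dd$phase, c("C", "M", "R"))

  # triplex loci behave like simplex under the minor-allele labels
  tt <- enumerate_phases(c(3, 0), c(3, 0))
  expect_setequal(tt$phase, c("C", "R"))

  # the census of distinct configuration/phase pairings
  expect_identical(nrow(linkage_pairings()), 67L)
})

test_that("EM recombination estimates match closed forms", {
  set.seed(21)
  sp <- pairing_spec("S+S coupling")
  pp <- phased_pair(sp$config1, sp$config2, sp$t1, sp$t2)
  sim <- simulate_population(pp$parent1, pp$parent2, rf = 0.1, n = 200)
  fit <- linkage_pair(
    sim$dosage[, 1], sim$dosage[, 2],
    sp$config1, sp$config2
  )
  k <- sum(sim$dosage[, 1] != sim$dosage[, 2])
  # simplex coupling ML estimate is the discordance rate
  expect_equal(fit$rf, k / 200, tolerance = 1e-7)
  expect_identical(fit$phase, "C")
  # and the closed-form LOD agrees with the engine
  sxf <- simplex_rf(sim$dosage[, 1], sim$dosage[, 2])
  expect_equal(sxf$rf, fit$rf, tolerance = 1e-7)
  expect_equal(sxf$lod, fit$lod, tolerance = 1e-5)

  # identical columns sit at the boundary with LOD n log10(2)
  same <- simplex_rf(sim$dosage[, 1], sim$dosage[, 1])
  expect_equal(same$rf, 0)
  expect_equal(same$lod, 200 * log10(2))

  # the grouping-threshold calibration: r = 0.25 at n = 190
  expect_equal(simplex_coupling_lod(0.25, 190), 10.8, tolerance = 0.05)
})

test_that("EM maximiser agrees with a grid-search oracle", {
  set.seed(31)
  specs <- linkage_pairings()
  for (rep in 1:40) {
    i <- sample(nrow(specs), 1)
    c1 <- c(specs$d11[i], specs$d21[i])
    c2 <- c(specs$d12[i], specs$d22[i])
    zt <- tetramap:::make_zygote_table(c1, c2, specs$t1[i], specs$t2[i])
    n_i <- as.vector(stats::rmultinom(
      1, 200,
      zygote_probs(zt, runif(1, 0.02, 0.45))
    ))
    fit <- estimate_rf(n_i, zt)
    grid <- seq(1e-6, 0.5, length.out = 20001)
    ll <- vapply(grid, function(r) tetramap:::zygote_loglik(n_i, zt$Y, r),
      numeric(1)
    )
    expect_lte(max(ll) - tetramap:::zygote_loglik(n_i, zt$Y, fit$rf), 1e-6)
    if (diff(range(ll)) > 1e-3) {
      expect_lt(abs(fit$rf - grid[which.max(ll)]), 1e-4)
    }
  }
})

test_that("independent SNPs give rf near 0.5 and LOD near 0", {
  set.seed(41)
  rfs <- lods <- numeric(20)
  for (i in 1:20) {
    d1 <- sample(0:2, 200, TRUE, dosage_probabilities(1, 1)[1:3])
    d2 <- sample(0:2, 200, TRUE, dosage_probabilities(1, 1)[1:3])
    fit <- linkage_pair(d1, d2, c(1, 1), c(1, 1))
    rfs[i] <- fit$rf
    lods[i] <- fit$lod
  }
  # maximising over phases biases the null estimate slightly below 0.5
  expect_gt(mean(rfs), 0.40)
  expect_lt(mean(lods), 1)
})

test_that("phase identification works where the pairing is informative", {
  set.seed(51)
  c1 <- c(2L, 1L) # DS at both loci, coupling in both parents
  pp <- phased_pair(c1, c1, 2L, 1L)
  hits <- 0
  for (rep in 1:10) {
    sim <- simulate_population(pp$parent1, pp$parent2, rf = 0.1, n = 200)
    fit <- linkage_pair(sim$dosage[, 1], sim$dosage[, 2], c1, c1)
    if (fit$phase == "CxC") hits <- hits + 1
  }
  expect_gte(hits, 9)

  # CxM and MxC cannot be distinguished for a double-duplex pair
  cc <- c(2L, 2L)
  ph <- linkage_pair(
    simulate_population(phased_pair(cc, cc, 2, 1)$parent1,
      phased_pair(cc, cc, 2, 1)$parent2,
      rf = 0.1, n = 200, seed = 5
    )$dosage[, 1],
    simulate_population(phased_pair(cc, cc, 2, 1)$parent1,
      phased_pair(cc, cc, 2, 1)$parent2,
      rf = 0.1, n = 200, seed = 5
    )$dosage[, 2],
    cc, cc,
    all_phases = TRUE
  )
  cxm <- ph$loglik[ph$phase == "CxM"]
  mxc <- ph$loglik[ph$phase == "MxC"]
  expect_equal(cxm, mxc, tolerance = 1e-8)
})

test_that("dominant-scoring expected LOD has the right structure", {
  # at r = 0.5 there is no information
  expect_equal(expected_lod_dominant(c(1, 1), c(1, 1), 1, 1, 0.5, 200), 0)
  # monotone decreasing in r
  r <- seq(0.05, 0.45, by = 0.05)
  el <- vapply(r, function(rr) {
    expected_lod_dominant(c(1, 1), c(1, 1), 1, 1, rr, 200)
  }, numeric(1))
  expect_true(all(diff(el) < 0))
  # dosage scoring beats dominant scoring for a duplex pair
  set.seed(61)
  ss <- simulation_study("D+D coupling", r_true = 0.1, n = 200, reps = 5)
  expect_gt(
    ss$mean_lod,
    expected_lod_dominant(c(2, 0), c(2, 0), 2, 0, 0.1, 200)
  )
})

test_that("pairwise output carries uncertainty columns used downstream", {
  set.seed(71)
  pp <- phased_pair(c(1, 0), c(1, 0), 1, 0)
  sim <- simulate_population(pp$parent1, pp$parent2, rf = 0.1, n = 150)
  dos <- sim$dosage
  colnames(dos) <- c("a", "b")
  cfg <- tibble::tibble(
    snp = c("a", "b"), parent1_dosage = 1L,
    parent2_dosage = 0L
  )
  pw <- pairwise_linkage(dos, cfg)
  expect_identical(nrow(pw), 1L)
  expect_true(all(c("rf", "lod", "rf_se", "phase_gap", "tied") %in% names(pw)))
  expect_gt(pw$rf_se, 0)
  expect_lt(pw$rf_se, 0.05)
})
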