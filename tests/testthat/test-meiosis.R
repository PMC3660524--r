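# the exact two-locus machinery against the printed gamete and zygote tables

test_that("duplex-coupling gamete coefficients reproduce the printed table", {
  parent <- phased_parent(c("AABB", "AABB"))
  byp <- gamete_coefficients(parent, by_pairing = TRUE)

  # the homozygous pairing (bivalents 1+2 and 3+4) yields gamete (1,1) with
  # coefficients 4, 8, 4 regardless of recombination
  hom <- byp[byp$pairing == 1, ]
  expect_identical(nrow(hom), 1L)
  expect_identical(c(hom$d1, hom$d2), c(1L, 1L))
  expect_identical(c(hom$x0, hom$x1, hom$x2), c(4L, 8L, 4L))

  # the two heterozygous pairings combine to the second (1,1) row: 4, 0, 4
  het <- byp[byp$pairing > 1 & byp$d1 == 1 & byp$d2 == 1, ]
  expect_identical(c(sum(het$x0), sum(het$x1), sum(het$x2)), c(4L, 0L, 4L))

  # the merged table row-for-row (dosage pairs x0 x1 x2)
  merged <- gamete_coefficients(parent)
  expected <- tibble::tribble(
    ~d1, ~d2, ~x0, ~x1, ~x2,
    0L, 0L, 2L, 0L, 0L,
    0L, 1L, 0L, 4L, 0L,
    0L, 2L, 0L, 0L, 2L,
    1L, 0L, 0L, 4L, 0L,
    1L, 1L, 8L, 8L, 8L,
    1L, 2L, 0L, 4L, 0L,
    2L, 0L, 0L, 0L, 2L,
    2L, 1L, 0L, 4L, 0L,
    2L, 2L, 2L, 0L, 0L
  )
  expect_equal(as.data.frame(merged), as.data.frame(expected))
})

test_that("gamete coefficient totals and frequencies are exact", {
  set.seed(42)
  for (rep in 1:10) {
    pats <- replicate(2, paste(sample(c("A", "B"), 4, replace = TRUE),
      collapse = ""
    ))
    g <- gamete_coefficients(phased_parent(pats))
    # 3 pairings x (4 nonrecombinant, 8 single, 4 double) chromatid outcomes
    expect_identical(sum(g$x0), 12L)
    expect_identical(sum(g$x1), 24L)
    expect_identical(sum(g$x2), 12L)
    for (r in c(0, 0.1, 0.3, 0.5)) {
      expect_equal(sum(gamete_frequency(as.matrix(g[, 3:5]), r)), 1)
    }
  }
  expect_equal(gamete_frequency(c(2, 0, 0), 0), 1 / 6)
  expect_equal(gamete_frequency(c(4, 8, 4), 0.37), 1 / 3)
  expect_error(gamete_frequency(c(2, 0, 0), 0.7), "0, 0.5")
})

test_that("zygote tables reproduce the simplex+duplex / double-simplex rows", {
  p_null <- phased_parent(c("AAAA", "AAAA"))
  # simplex at locus 1, duplex at locus 2, in the same parent
  for (r in c(0, 0.1, 0.25, 0.5)) {
    zc <- zygote_table(p_null, phased_parent(c("BAAA", "BBAA"))) # coupling
    expect_equal(
      zygote_probs(zc, r),
      c((1 - r) / 6, 2 / 6, r / 6, r / 6, 2 / 6, (1 - r) / 6)
    )
    zr <- zygote_table(p_null, phased_parent(c("BAAA", "ABBA"))) # repulsion
    expect_equal(
      zygote_probs(zr, r),
      c(r / 6, 2 / 6, (1 - r) / 6, (1 - r) / 6, 2 / 6, r / 6)
    )
    # simplex + double-simplex: simplex in parent 2, SS split across parents
    zsc <- zygote_table(
      phased_parent(c("AAAA", "BAAA")),
      phased_parent(c("BAAA", "BAAA"))
    )
    expect_equal(
      zygote_probs(zsc, r),
      c((1 - r) / 4, 1 / 4, r / 4, r / 4, 1 / 4, (1 - r) / 4)
    )
    zsr <- zygote_table(
      phased_parent(c("AAAA", "BAAA")),
      phased_parent(c("BAAA", "ABAA"))
    )
    expect_equal(
      zygote_probs(zsr, r),
      c(
        (1 + r) / 12, 3 / 12, (2 - r) / 12, (2 - r) / 12, 3 / 12,
        (1 + r) / 12
      )
    )
  }
})

test_that("zygote classes are normalised, independent at r = 0.5, and marginalise", {
  set.seed(7)
  for (rep in 1:8) {
    p1 <- phased_parent(replicate(2, paste(sample(c("A", "B"), 4, TRUE),
      collapse = ""
    )))
    p2 <- phased_parent(replicate(2, paste(sample(c("A", "B"), 4, TRUE),
      collapse = ""
    )))
    zt <- zygote_table(p1, p2)
    for (r in c(0, 0.17, 0.5)) {
      p <- zygote_probs(zt, r)
      expect_equal(sum(p), 1)
      # collapsing over locus 2 recovers the single-locus distribution
      marg <- tapply(p, zt$classes$d1, sum)
      single <- dosage_probabilities(sum(p1[, 1]), sum(p2[, 1]))
      expect_equal(as.numeric(marg), single[as.integer(names(marg)) + 1])
    }
    # relabeling A and B at both loci reverses both class axes but leaves
    # the probabilities untouched
    ztr <- zygote_table(1L - p1, 1L - p2)
    key <- paste(zt$classes$d1, zt$classes$d2)
    keyr <- paste(4L - ztr$classes$d1, 4L - ztr$classes$d2)
    for (r in c(0.08, 0.3, 0.5)) {
      expect_equal(
        zygote_probs(zt, r)[order(key)],
        zygote_probs(ztr, r)[order(keyr)]
      )
    }
  }
})

test_that("simulated populations match the exact class probabilities", {
  # two simplex SNPs in coupling at r = 0.1: recombinant fraction recovers r
  pp <- phased_pair(c(1L, 0L), c(1L, 0L), 1L, 0L)
  sim <- simulate_population(pp$parent1, pp$parent2,
    rf = 0.1, n = 1e5,
    seed = 11
  )
  rec <- mean(sim$dosage[, 1] != sim$dosage[, 2])
  expect_lt(abs(rec - 0.1), 0.003)

  # single double-duplex SNP: dosage frequencies within sampling error
  dd <- phased_parent("AABB")
  sim2 <- simulate_population(dd, dd, rf = numeric(0), n = 1e5, seed = 12)
  freq <- tabulate(sim2$dosage[, 1] + 1, 5) / 1e5
  expect_true(all(abs(freq - c(1, 8, 18, 8, 1) / 36) < 0.005))

  # r = 0 produces no recombinant gametes
  sim3 <- simulate_population(pp$parent1, pp$parent2, rf = 0, n = 2000)
  expect_identical(sum(sim3$dosage[, 1] != sim3$dosage[, 2]), 0L)

  expect_error(simulate_population(dd, dd, rf = numeric(0), n = 0), "at least 1")
})

test_that("zygote probabilities agree with Monte-Carlo frequencies", {
  # a spread of configuration/phase pairings against the simulator
  specs <- list(
    list(c(1L, 0L), c(1L, 0L), 1L, 0L),
    list(c(1L, 0L), c(1L, 0L), 0L, 0L),
    list(c(2L, 0L), c(2L, 0L), 1L, 0L),
    list(c(2L, 2L), c(2L, 2L), 2L, 1L),
    list(c(1L, 3L), c(1L, 1L), 0L, 1L),
    list(c(1L, 2L), c(2L, 1L), 1L, 1L)
  )
  n <- 4e4
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    pp <- phased_pair(s[[1]], s[[2]], s[[3]], s[[4]])
    zt <- zygote_table(pp$parent1, pp$parent2)
    for (r in c(0.1, 0.35)) {
      sim <- simulate_population(pp$parent1, pp$parent2,
        rf = r, n = n,
        seed = 100 + i
      )
      key <- paste(sim$dosage[, 1], sim$dosage[, 2])
      lev <- paste(zt$classes$d1, zt$classes$d2)
      obs <- as.vector(table(factor(key, levels = lev))) / n
      expect_true(all(key %in% lev))
      p <- zygote_probs(zt, r)
      se <- sqrt(p * (1 - p) / n)
      expect_true(all(abs(obs - p) < 4 * se + 1e-9))
    }
  }
})

test_that("map distances convert through the Haldane function", {
  r <- c(0.01, 0.1, 0.25)
  expect_equal(tetramap:::haldane_rf(tetramap:::haldane_cm(r)), r)
})
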