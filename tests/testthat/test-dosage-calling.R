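# theta pre-processing, mixture EM, configuration selection, segregation

test_that("pre-processing applies the range, trend and missing criteria", {
  set.seed(101)
  n <- 100
  th <- cbind(
    flat = rep(0.4, n),
    five = pmin(pmax(
      c(0.02, 0.26, 0.5, 0.74, 0.98)[sample(0:4, n, TRUE) + 1] +
        rnorm(n, 0, 0.02), 0
    ), 1),
    drift = pmin(pmax(
      c(0.02, 0.27)[sample(1:2, n, TRUE)] + rnorm(n, 0, 0.02) +
        0.3 * (seq_len(n) / n), 0
    ), 1),
    holes = ifelse(seq_len(n) %% 25 == 0, NA,
      c(0.02, 0.27)[sample(1:2, n, TRUE)]
    )
  )
  rep <- preprocess_theta(th)
  expect_false(rep$pass[rep$snp == "flat"])
  expect_match(rep$reason[rep$snp == "flat"], "range")
  expect_true(rep$pass[rep$snp == "five"])
  expect_gt(rep$trimmed_range[rep$snp == "five"], 0.9)
  expect_false(rep$pass[rep$snp == "drift"])
  expect_lt(rep$trend_p[rep$snp == "drift"], 1e-4)
  expect_false(rep$pass[rep$snp == "holes"])
  expect_match(rep$reason[rep$snp == "holes"], "missing")
  expect_error(preprocess_theta(th[1:10, ]), "20 samples")
})

test_that("the fixed-weight mixture EM recovers simplex structure", {
  set.seed(111)
  truth <- rep(0:1, c(95, 95))
  y <- pmin(pmax(c(0.02, 0.27)[truth + 1] + rnorm(190, 0, 0.02), 0), 1)
  fit <- fit_dosage_mixture(y, c(0, 1))
  expect_lt(abs(fit$means[1] - 0.02), 0.01)
  expect_lt(abs(fit$means[2] - 0.27), 0.01)
  expect_gte(mean(fit$calls == truth), 0.95)
  expect_true(all(abs(rowSums(fit$posteriors) - 1) < 1e-12))
  # clean data: called-class posteriors are high
  expect_gt(mean(fit$max_posterior), 0.98)

  # single-class fit equals the closed-form normal log-likelihood
  yn <- rnorm(100, 0.45, 0.02)
  f1 <- fit_dosage_mixture(yn, c(0, 0))
  expect_equal(f1$means[1], mean(yn))
  expect_equal(
    f1$loglik,
    sum(dnorm(yn, mean(yn), sqrt(mean((yn - mean(yn))^2)), log = TRUE))
  )

  # tidy/glance accessors
  td <- tidy(fit)
  expect_identical(td$dosage, 0:1)
  expect_identical(glance(fit)$label, "NxS")
})

test_that("BIC selects the generating configuration", {
  set.seed(121)
  means <- c(0.02, 0.26, 0.50, 0.74, 0.98)
  types <- list(c(2L, 2L), c(0L, 1L), c(1L, 1L), c(1L, 2L))
  for (cfg in types) {
    wins <- 0
    for (rep in 1:10) {
      sim <- sim_theta_for_config(190, cfg, means = means, sd = 0.02)
      sel <- select_dosage_configuration(
        sim$theta,
        theta_parents = means[cfg + 1]
      )
      got <- c(sel$best$config$parent1_dosage, sel$best$config$parent2_dosage)
      # accept the allele-relabelled representation as the same configuration
      if (all(got == cfg) || all(got == 4 - cfg)) wins <- wins + 1
    }
    expect_gte(wins, 9)
  }
  # a single cluster selects the null configuration
  seln <- select_dosage_configuration(rnorm(190, 0.45, 0.02),
    theta_parents = c(0.45, 0.45)
  )
  expect_identical(seln$best$config$type, "N")
})

test_that("segregation chi-square matches hand computation and thresholds", {
  ok <- segregation_test(c(95, 95), c(0, 1))
  expect_equal(ok$statistic, 0)
  expect_equal(ok$p, 1)

  bad <- segregation_test(c(40, 150), c(0, 1))
  expect_equal(bad$statistic, 2 * 55^2 / 95, tolerance = 1e-9)
  expect_lt(bad$p, 0.001)

  # sparse classes are merged with a df reduction
  m <- segregation_test(c(3, 40, 100, 40, 2), c(2, 2))
  expect_true(is.finite(m$statistic))

  # a 3-class count far from duplex expectation is distorted at the
  # duplex-and-higher threshold
  dx <- segregation_test(c(60, 70, 60), c(0, 2))
  expect_lt(dx$p, 0.01)
})

test_that("double-reduction screening flags and confirms individuals", {
  set.seed(131)
  n <- 190
  truth <- rep(0:1, c(95, 95))
  theta <- sapply(1:3, function(i) {
    pmin(pmax(c(0.02, 0.27)[truth + 1] + rnorm(n, 0, 0.02), 0), 1)
  })
  colnames(theta) <- c("sA", "sB", "sC")
  rownames(theta) <- sprintf("off%03d", 1:n)
  calls <- matrix(truth, n, 3, dimnames = dimnames(theta))
  # clean data: no flags
  clean <- detect_double_reduction(theta, calls)
  expect_identical(nrow(clean$flags), 0L)

  # spike individual 160 to a double-reduction-like dosage at two coupled
  # SNPs 10 cM apart, and at a third unlinked SNP position only once
  theta[160, c("sA", "sB")] <- 0.52
  ctx <- tibble::tibble(
    snp = c("sA", "sB", "sC"), homologue = c("1a", "1a", "2c"),
    position_cm = c(0, 10, 5)
  )
  dr <- detect_double_reduction(theta, calls, map_context = ctx)
  expect_setequal(unique(dr$flags$snp), c("sA", "sB"))
  expect_identical(dr$confirmed$individual, "off160")

  # a single-SNP spike is flagged but not confirmed
  theta2 <- theta
  theta2[160, "sB"] <- 0.27
  dr2 <- detect_double_reduction(theta2, calls, map_context = ctx)
  expect_true("off160" %in% dr2$flags$individual)
  expect_identical(nrow(dr2$confirmed), 0L)
})

test_that("calling a matrix produces calls, reports and distortion flags", {
  set.seed(141)
  means <- c(0.02, 0.26, 0.50, 0.74, 0.98)
  cfgs <- list(a = c(0L, 1L), b = c(2L, 2L), c = c(1L, 1L))
  th <- sapply(cfgs, function(cfg) {
    sim_theta_for_config(120, cfg, means = means, sd = 0.02)$theta
  })
  th <- rbind(th, P1 = means[c(1, 3, 2)], P2 = means[c(2, 3, 2)])
  rownames(th)[1:120] <- sprintf("off%03d", 1:120)
  res <- call_dosages(th, c("P1", "P2"))
  expect_identical(dim(res$dosage), c(120L, 3L))
  expect_setequal(res$report$type[res$report$snp == "a"], "S")
  expect_setequal(res$report$type[res$report$snp == "b"], "DD")
  expect_true(all(res$report$mean_posterior > 0.9))
})
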