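# independence-test distances, linkage-group clustering, frameworks

test_that("independence test separates associated from independent pairs", {
  set.seed(201)
  # identical simplex columns: overwhelming association
  x <- sample(0:1, 190, TRUE)
  expect_lt(snp_independence_test(x, x)$p, 1e-30)

  # null calibration: roughly uniform p-values for independent pairs
  ps <- replicate(300, {
    snp_independence_test(
      sample(0:1, 190, TRUE),
      sample(0:1, 190, TRUE)
    )$p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  # the 2x2 chi-square without continuity correction runs a little hot
  expect_lt(mean(ps < 0.05), 0.10)

  # simplex + duplex coupling at r = 0.1 is detected nearly always
  pp <- phased_pair(c(0L, 1L), c(0L, 2L), 0L, 1L)
  hits <- 0
  for (i in 1:20) {
    sim <- simulate_population(pp$parent1, pp$parent2, rf = 0.1, n = 200)
    if (snp_independence_test(sim$dosage[, 1], sim$dosage[, 2])$p < 0.001) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("average-linkage clustering recovers independent linkage groups", {
  set.seed(211)
  # parent-1-informative SNPs only: the full pipeline clusters per parent
  gen <- synth_genome(
    n_chrom = 4, n_snps = 12, length_cm = 12,
    type_counts = c(S1 = 6, D1 = 3, SS = 2, DD = 1)
  )
  pop <- synth_population(gen, n = 150)
  pm <- independence_distance(pop$dosage)
  cl <- cluster_linkage_groups(pm, threshold = 0.1)
  expect_identical(length(unique(cl$group)), 4L)
  truth <- pop$map$chrom[match(cl$snp, pop$map$snp)]
  expect_identical(
    length(unique(paste(cl$group, truth))),
    length(unique(cl$group))
  )
  # threshold 0 leaves every SNP alone
  cl0 <- cluster_linkage_groups(pm, threshold = 0)
  expect_identical(length(unique(cl0$group)), ncol(pop$dosage))
})

test_that("two-run merging enforces the both-parents support rule", {
  run1 <- tibble::tibble(
    snp = c("a1", "a2", "h1", "h2", "b1", "b2"),
    group = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
  run2 <- tibble::tibble(
    snp = c("c1", "c2", "h1", "h2", "d1"),
    group = c(7L, 7L, 7L, 7L, 9L)
  )
  merged <- merge_cluster_runs(run1, run2, shared = c("h1", "h2"))
  # h1: run-1 group 1 matches run-2 group 7 (mapped back to 1) -> supported
  expect_true(merged$supported[merged$snp == "h1"])
  expect_identical(merged$group[merged$snp == "h1"], 1L)
  # h2: run 1 says group 2 but run 2 puts it with group-1 material
  expect_false(merged$supported[merged$snp == "h2"])
  expect_true(is.na(merged$group[merged$snp == "h2"]))
})

test_that("simplex frameworks group homologues by coupling linkage", {
  set.seed(221)
  # one chromosome, 3 simplex SNPs on each of 4 homologues of parent 1
  K <- 16
  hom <- rep(1:4, times = 4) # interleaved along the chromosome
  p1 <- matrix(0L, 4, K)
  for (k in 1:K) p1[hom[k], k] <- 1L
  colnames(p1) <- paste0("s", 1:K)
  p2 <- matrix(0L, 4, K, dimnames = dimnames(p1))
  sim <- simulate_population(p1, p2, map_cm = seq(0, 30, 2), n = 190)
  cfg <- tibble::tibble(
    snp = colnames(p1), parent1_dosage = 1L,
    parent2_dosage = 0L
  )
  pw <- pairwise_linkage(sim$dosage, cfg, min_n = 50)
  fw <- build_simplex_framework(pw, colnames(p1))
  expect_identical(length(unique(fw$homologue_group)), 4L)
  expect_identical(
    length(unique(paste(fw$homologue_group, hom[match(fw$snp, colnames(p1))]))),
    4L
  )
  expect_false(any(fw$fragile))

  # repulsion pairs never join a coupling group: homologue 1 vs 2 SNPs stay
  # apart no matter the threshold
  rep_pairs <- pw[hom[match(pw$snp1, colnames(p1))] !=
    hom[match(pw$snp2, colnames(p1))], ]
  expect_false(any(rep_pairs$phase == "C" & rep_pairs$rf <= 0.25 &
    !is.na(rep_pairs$rf)))
})

test_that("duplex SNPs link homologue frameworks into chromosome groups", {
  set.seed(231)
  # parent 1: 2 simplex SNPs per homologue + a duplex SNP on homologues 1+2
  pats <- c(
    "BAAA", "BAAA", "ABAA", "ABAA", "AABA", "AABA", "AAAB", "AAAB",
    "BBAA"
  )
  p1 <- phased_parent(pats)
  colnames(p1) <- c(paste0("s", 1:8), "dup")
  p2 <- matrix(0L, 4, 9, dimnames = dimnames(p1))
  sim <- simulate_population(p1, p2, map_cm = c(seq(0, 14, 2), 16),
    n = 190)
  cfg <- tibble::tibble(
    snp = colnames(p1),
    parent1_dosage = c(rep(1L, 8), 2L), parent2_dosage = 0L
  )
  pw <- pairwise_linkage(sim$dosage[, 1:8], cfg[1:8, ], min_n = 50)
  fw <- build_simplex_framework(pw, colnames(p1)[1:8])
  framework <- tibble::tibble(
    snp = fw$snp, parent = 1L,
    homologue_group = fw$homologue_group
  )
  out <- associate_homologues(
    framework, sim$dosage,
    duplex = tibble::tibble(snp = "dup", parent = 1L),
    double_simplex = character(0), configs = cfg
  )
  # the duplex carries B on homologues 1+2; its associations (coupling with
  # those, repulsion with the others - both deviate from independence) pull
  # all four homologue frameworks into a single chromosome group
  expect_gt(nrow(out$homologue_links), 0)
  cg <- out$chromosome_groups
  expect_identical(length(unique(cg$chromosome)), 1L)
  # and the strongest link involves a homologue the duplex actually carries
  best <- out$homologue_links[which.min(out$homologue_links$p), ]
  carried <- vapply(c(best$group_a, best$group_b), function(g) {
    which(p1[, fw$snp[fw$homologue_group == g][1]] == 1)[1]
  }, numeric(1))
  expect_true(any(carried %in% c(1, 2)))
})
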