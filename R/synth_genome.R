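# Synthetic genomes with known truth. The generator emulates the study
# conditions of a dense autotetraploid mapping population: ~190 offspring,
# ~1.2 SNPs per cM, a mixture of simplex through double-duplex configurations
# per chromosome, simplex SNPs covering all four homologues of each parent so
# the framework step can identify them.

#' Generate a synthetic phased genome
#'
#' Each chromosome carries `n_snps` SNPs at density `n_snps / length_cm`,
#' composed of (by default) eight simplex SNPs per parent (two per
#' homologue), four duplex SNPs per parent, and a balance of double-simplex,
#' simplex-duplex, duplex-simplex and double-duplex SNPs, with B-carrying
#' homologues drawn at random. SNP types are shuffled along the chromosome.
#'
#' @param n_chrom Number of chromosomes (default 12).
#' @param n_snps SNPs per chromosome (default 32).
#' @param length_cm Chromosome length in cM (default 26).
#' @param type_counts Named integer vector of per-chromosome counts for types
#'   `S1`, `S2`, `D1`, `D2`, `SS`, `SD`, `DS`, `DD` (recycled/truncated to
#'   `n_snps`).
#' @param seed Optional seed.
#' @return List of per-chromosome elements: `parent1`, `parent2` (4 x K
#'   matrices), `map` (tibble `snp`, `chrom`, `position_cm`, `phase_p1`,
#'   `phase_p2`, `parent1_dosage`, `parent2_dosage`, `type`).
#' @export
synth_genome <- function(n_chrom = 12, n_snps = 32, length_cm = 26,
                         type_counts = c(
                           S1 = 8, S2 = 8, D1 = 4, D2 = 4,
                           SS = 3, SD = 2, DS = 2, DD = 1
                         ),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- rep(names(type_counts), type_counts)
  # thin or extend to n_snps while preserving the composition
  types <- types[round(seq(1, length(types), length.out = n_snps))]
  genome <- list()
  for (ch in seq_len(n_chrom)) {
    tv <- sample(types)
    pos <- sort(c(0, length_cm, runif(n_snps - 2, 0, length_cm)))
    p1 <- matrix(0L, 4, n_snps)
    p2 <- matrix(0L, 4, n_snps)
    hsx1 <- rep_len(sample(1:4), sum(tv == "S1"))
    hsx2 <- rep_len(sample(1:4), sum(tv == "S2"))
    i1 <- 0L
    i2 <- 0L
    for (k in seq_len(n_snps)) {
      tp <- tv[k]
      if (tp == "S1") {
        i1 <- i1 + 1L
        p1[hsx1[i1], k] <- 1L
      } else if (tp == "S2") {
        i2 <- i2 + 1L
        p2[hsx2[i2], k] <- 1L
      } else if (tp == "D1") {
        p1[sample(1:4, 2), k] <- 1L
      } else if (tp == "D2") {
        p2[sample(1:4, 2), k] <- 1L
      } else if (tp == "SS") {
        p1[sample(1:4, 1), k] <- 1L
        p2[sample(1:4, 1), k] <- 1L
      } else if (tp == "SD") {
        p1[sample(1:4, 1), k] <- 1L
        p2[sample(1:4, 2), k] <- 1L
      } else if (tp == "DS") {
        p1[sample(1:4, 2), k] <- 1L
        p2[sample(1:4, 1), k] <- 1L
      } else if (tp == "DD") {
        p1[sample(1:4, 2), k] <- 1L
        p2[sample(1:4, 2), k] <- 1L
      }
    }
    snp <- sprintf("c%02d_s%02d", ch, seq_len(n_snps))
    colnames(p1) <- colnames(p2) <- snp
    pat <- function(m) {
      apply(m, 2, function(x) paste(c("A", "B")[x + 1], collapse = ""))
    }
    genome[[ch]] <- list(
      parent1 = p1, parent2 = p2,
      map = tibble(
        snp = snp, chrom = ch, position_cm = pos,
        phase_p1 = pat(p1), phase_p2 = pat(p2),
        parent1_dosage = as.integer(colSums(p1)),
        parent2_dosage = as.integer(colSums(p2)),
        type = tv
      )
    )
  }
  genome
}

#' Simulate a population over a synthetic genome
#'
#' Chromosomes segregate independently; dosages (and optionally theta scores)
#' are concatenated across chromosomes.
#'
#' @param genome Output of [synth_genome()].
#' @param n Number of offspring (default 190).
#' @param seed Optional seed.
#' @param theta Emit theta scores too.
#' @param ... Passed to [simulate_population()] (theta parameters).
#' @return List with `dosage`, optional `theta` (offspring x all SNPs),
#'   `truth` (per chromosome), `map` (combined map tibble) and `configs`.
#' @export
synth_population <- function(genome, n = 190, seed = NULL, theta = FALSE,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  dos <- list()
  th <- list()
  truth <- list()
  for (ch in seq_along(genome)) {
    g <- genome[[ch]]
    sim <- simulate_population(g$parent1, g$parent2,
      map_cm = g$map$position_cm, n = n, theta = theta, ...
    )
    dos[[ch]] <- sim$dosage
    if (theta) th[[ch]] <- sim$theta
    truth[[ch]] <- list(truth1 = sim$truth1, truth2 = sim$truth2)
  }
  map <- bind_rows(lapply(genome, function(g) g$map))
  out <- list(
    dosage = do.call(cbind, dos), truth = truth, map = map,
    configs = map[, c("snp", "parent1_dosage", "parent2_dosage")]
  )
  rownames(out$dosage) <- sprintf("off%03d", seq_len(n))
  if (theta) {
    out$theta <- do.call(cbind, th)
    rownames(out$theta) <- rownames(out$dosage)
  }
  out
}
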