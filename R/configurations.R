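# Single-locus SNP configurations in an autotetraploid F1 cross under random
# chromosomal segregation: bivalent pairing only, no preferential pairing, no
# double reduction. A parent of dosage d (copies of the B allele among its four
# homologues) transmits a gamete of dosage k with probability
# choose(d, k) * choose(4 - d, 2 - k) / choose(4, 2).

#' Gamete dosage distribution of a tetraploid parent
#'
#' Probability that a parent carrying `dosage` copies of the B allele transmits
#' a diploid gamete with 0, 1 or 2 copies, under random chromosomal
#' segregation.
#'
#' @param dosage Integer 0-4, the parental B-allele dosage.
#' @return Numeric vector of length 3 (gamete dosage 0, 1, 2); sums to 1.
#' @export
#' @examples
#' gamete_dosage_probs(2) # 1/6, 4/6, 1/6
gamete_dosage_probs <- function(dosage) {
  check_dosage(dosage)
  k <- 0:2
  choose(dosage, k) * choose(4 - dosage, 2 - k) / 6
}

#' Offspring dosage probabilities for a parental dosage pair
#'
#' Convolves the two parental gamete dosage distributions to give the expected
#' offspring dosage distribution at a SNP. Probabilities are computed as
#' integer numerators over 36 so that comparisons with the tabulated exact
#' fractions are bit-stable.
#'
#' @param parent1_dosage,parent2_dosage Integer 0-4 B-allele dosages.
#' @return Numeric vector of length 5, probabilities for offspring dosage 0-4.
#' @export
#' @examples
#' dosage_probabilities(2, 2) # 1/36 8/36 18/36 8/36 1/36
dosage_probabilities <- function(parent1_dosage, parent2_dosage) {
  check_dosage(parent1_dosage)
  check_dosage(parent2_dosage)
  k <- 0:2
  n1 <- choose(parent1_dosage, k) * choose(4 - parent1_dosage, 2 - k)
  n2 <- choose(parent2_dosage, k) * choose(4 - parent2_dosage, 2 - k)
  num <- numeric(5)
  for (a in 0:2) {
    for (b in 0:2) {
      num[a + b + 1] <- num[a + b + 1] + n1[a + 1] * n2[b + 1]
    }
  }
  num / 36
}

config_type_code <- function(d1, d2) {
  het1 <- d1 %in% 1:3
  het2 <- d2 %in% 1:3
  if (!het1 && !het2) {
    return("N")
  }
  if (xor(het1, het2)) {
    dh <- if (het1) d1 else d2
    dhom <- if (het1) d2 else d1
    if (dh == 2) {
      return("D")
    }
    # minor-allele copy number in the heterozygous parent
    minor <- if (dhom == 0) dh else 4 - dh
    return(if (minor == 1) "S" else "T")
  }
  if (d1 == 2 && d2 == 2) {
    return("DD")
  }
  if (d1 == 2) {
    return("DS")
  }
  if (d2 == 2) {
    return("SD")
  }
  if (d1 == d2) {
    return("SS")
  }
  "XSS"
}

config_label <- function(d1, d2, type) {
  het1 <- d1 %in% 1:3
  het2 <- d2 %in% 1:3
  if (het1 && het2) {
    return(type)
  }
  if (!het1 && !het2) {
    return("N")
  }
  if (het1) paste0(type, "xN") else paste0("Nx", type)
}

#' Classify a parental dosage pair
#'
#' Returns the SNP configuration for an ordered pair of parental dosages:
#' the type code (`N`, `S`, `T`, `D`, `SS`, `XSS`, `SD`, `DS`, `DD`), a label
#' carrying the parent orientation (e.g. `"NxS"` vs `"SxN"`), the expected
#' offspring dosage distribution, and the number of segregating dosage classes.
#'
#' @inheritParams dosage_probabilities
#' @return A one-row tibble with columns `parent1_dosage`, `parent2_dosage`,
#'   `type`, `label`, `n_classes` and list-column `offspring_probs`.
#' @export
#' @examples
#' classify_configuration(1, 3) # X-double-simplex
classify_configuration <- function(parent1_dosage, parent2_dosage) {
  check_dosage(parent1_dosage)
  check_dosage(parent2_dosage)
  probs <- dosage_probabilities(parent1_dosage, parent2_dosage)
  type <- config_type_code(parent1_dosage, parent2_dosage)
  tibble(
    parent1_dosage = as.integer(parent1_dosage),
    parent2_dosage = as.integer(parent2_dosage),
    type = type,
    label = config_label(parent1_dosage, parent2_dosage, type),
    n_classes = sum(probs > 0),
    offspring_probs = list(probs)
  )
}

#' The canonical table of segregation configurations
#'
#' All 13 canonical parental configurations at a biallelic SNP (every ordered
#' dosage pair maps onto one of these by relabeling the two alleles, possibly
#' combined with a parent swap). Expected parental theta anchors are
#' `dosage / 4`.
#'
#' @return A 13-row tibble with the parental dosages, type code, expected
#'   parental theta values and offspring dosage probabilities.
#' @export
snp_configurations <- function() {
  pairs <- list(
    c(0L, 4L), c(0L, 1L), c(3L, 4L), c(0L, 3L), c(1L, 4L), c(0L, 2L),
    c(2L, 4L), c(1L, 1L), c(3L, 3L), c(1L, 3L), c(1L, 2L), c(2L, 3L),
    c(2L, 2L)
  )
  out <- purrr::map(pairs, function(p) classify_configuration(p[1], p[2]))
  out <- bind_rows(out)
  out$parent1_theta <- out$parent1_dosage / 4
  out$parent2_theta <- out$parent2_dosage / 4
  out[, c(
    "parent1_dosage", "parent2_dosage", "type", "label",
    "parent1_theta", "parent2_theta", "n_classes", "offspring_probs"
  )]
}

check_dosage <- function(d) {
  if (length(d) != 1 || is.na(d) || d %% 1 != 0 || d < 0 || d > 4) {
    abort("`dosage` must be a single integer in 0..4.")
  }
  invisible(d)
}
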