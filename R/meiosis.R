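# Exact two-locus gamete and zygote frequency machinery under random
# chromosomal segregation. At meiosis the four homologues pair into two
# bivalents; all three pairings are equally likely (probability 1/3 each).
# Within a bivalent the transmitted chromatid is non-recombinant or
# recombinant across the interval, so a full gamete (one segment from each
# bivalent) carries 0, 1 or 2 recombinations with probabilities
# (1-r)^2/4, r(1-r)/4 and r^2/4 per constituent genotype.

.bivalent_pairings <- list(
  list(c(1L, 2L), c(3L, 4L)),
  list(c(1L, 3L), c(2L, 4L)),
  list(c(1L, 4L), c(2L, 3L))
)

#' Construct a phased parental genotype
#'
#' A phased parent over K SNPs is a 4 x K 0/1 matrix: rows are the four
#' homologues (labelled a-d for parent 1, e-h for parent 2), columns are SNPs,
#' entries indicate the B allele. Input is one 4-character `A`/`B` pattern per
#' SNP, e.g. `"AABA"` places B on the third homologue.
#'
#' @param patterns Character vector of per-SNP patterns over `{A,B}`, each of
#'   length 4 (homologue order a,b,c,d or e,f,g,h).
#' @return Integer matrix 4 x K with homologue rownames.
#' @export
#' @examples
#' phased_parent(c("AABB", "AABA"))
phased_parent <- function(patterns) {
  if (!all(grepl("^[AB]{4}$", patterns))) {
    abort("each phase pattern must be 4 characters over {A,B}")
  }
  m <- vapply(strsplit(patterns, ""), function(x) as.integer(x == "B"),
    integer(4)
  )
  m <- matrix(m, nrow = 4)
  rownames(m) <- c("h1", "h2", "h3", "h4")
  colnames(m) <- names(patterns)
  m
}

#' Two-locus gamete recombination-count coefficients
#'
#' Enumerates all three bivalent pairings and all chromatid transmissions for a
#' parent phased at two SNPs, tallying for every distinct gamete dosage pair
#' the counts `x0`, `x1`, `x2` of non-recombinant, single-recombinant and
#' double-recombinant origins. The gamete frequency at recombination fraction
#' r is `(x0 (1-r)^2 + x1 r (1-r) + x2 r^2) / 12`.
#'
#' @param parent A 4 x 2 phased parent matrix (see [phased_parent()]).
#' @param by_pairing If `TRUE`, keep the tallies separate per bivalent pairing
#'   (as in the tabulated duplex-coupling example); otherwise merge.
#' @return A tibble with columns `pairing` (if `by_pairing`), `d1`, `d2`,
#'   `x0`, `x1`, `x2`.
#' @export
gamete_coefficients <- function(parent, by_pairing = FALSE) {
  stopifnot(is.matrix(parent), nrow(parent) == 4, ncol(parent) == 2)
  rows <- list()
  for (p in 1:3) {
    tal <- array(0L, dim = c(3, 3, 3)) # d1+1, d2+1, nrec+1
    biv <- .bivalent_pairings[[p]]
    for (i1 in 1:2) {
      for (j1 in 1:2) {
        a1 <- parent[biv[[1]][i1], 1]
        b1 <- parent[biv[[1]][j1], 2]
        r1 <- as.integer(i1 != j1)
        for (i2 in 1:2) {
          for (j2 in 1:2) {
            a2 <- parent[biv[[2]][i2], 1]
            b2 <- parent[biv[[2]][j2], 2]
            nrec <- r1 + as.integer(i2 != j2)
            d1 <- a1 + a2
            d2 <- b1 + b2
            tal[d1 + 1, d2 + 1, nrec + 1] <- tal[d1 + 1, d2 + 1, nrec + 1] + 1L
          }
        }
      }
    }
    idx <- which(apply(tal, c(1, 2), sum) > 0, arr.ind = TRUE)
    dimnames(idx) <- NULL
    rows[[p]] <- tibble(
      pairing = p,
      d1 = idx[, 1] - 1L,
      d2 = idx[, 2] - 1L,
      x0 = tal[cbind(idx, 1L)],
      x1 = tal[cbind(idx, 2L)],
      x2 = tal[cbind(idx, 3L)]
    )
  }
  out <- bind_rows(rows)
  if (by_pairing) {
    return(arrange(out, .data$pairing, .data$d1, .data$d2))
  }
  out |>
    group_by(.data$d1, .data$d2) |>
    summarise(
      x0 = sum(.data$x0), x1 = sum(.data$x1), x2 = sum(.data$x2),
      .groups = "drop"
    ) |>
    arrange(.data$d1, .data$d2)
}

#' Gamete genotype frequency at recombination fraction r
#'
#' @param x Numeric vector `c(x0, x1, x2)` of recombination-count coefficients,
#'   or a 3-column matrix of such rows.
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return Gamete frequency (or vector of frequencies).
#' @export
gamete_frequency <- function(x, r) {
  if (any(r < 0 | r > 0.5)) abort("`r` must lie in [0, 0.5]")
  if (is.matrix(x)) {
    return((x[, 1] * (1 - r)^2 + x[, 2] * r * (1 - r) + x[, 3] * r^2) / 12)
  }
  (x[1] * (1 - r)^2 + x[2] * r * (1 - r) + x[3] * r^2) / 12
}

#' Two-locus zygote dosage-class coefficients
#'
#' Convolves the gamete coefficient tables of the two parents: a random union
#' of gametes yields zygotes carrying 0-4 recombinations, and the probability
#' of the observable dosage-pair class i is
#' `P_i(r) = sum_j y_ij r^j (1-r)^(4-j) / 144`.
#'
#' @param parent1,parent2 4 x 2 phased parent matrices.
#' @return An object of class `zygote_table`: list with `classes` (tibble of
#'   observable dosage pairs `d1`, `d2`) and `Y` (classes x 5 coefficient
#'   matrix, columns j = 0..4 recombinations).
#' @export
zygote_table <- function(parent1, parent2) {
  g1 <- gamete_coefficients(parent1)
  g2 <- gamete_coefficients(parent2)
  x1 <- as.matrix(g1[, c("x0", "x1", "x2")])
  x2 <- as.matrix(g2[, c("x0", "x1", "x2")])
  ymap <- new.env()
  for (i in seq_len(nrow(g1))) {
    for (j in seq_len(nrow(g2))) {
      d1 <- g1$d1[i] + g2$d1[j]
      d2 <- g1$d2[i] + g2$d2[j]
      # polynomial product: coefficients on r^k (1-r)^(4-k)
      y <- numeric(5)
      for (a in 0:2) {
        for (b in 0:2) {
          y[a + b + 1] <- y[a + b + 1] + x1[i, a + 1] * x2[j, b + 1]
        }
      }
      key <- paste(d1, d2)
      prev <- ymap[[key]]
      ymap[[key]] <- if (is.null(prev)) y else prev + y
    }
  }
  keys <- ls(ymap)
  dd <- do.call(rbind, strsplit(keys, " "))
  ord <- order(as.integer(dd[, 1]), as.integer(dd[, 2]))
  keys <- keys[ord]
  dd <- dd[ord, , drop = FALSE]
  Y <- do.call(rbind, lapply(keys, function(k) ymap[[k]]))
  structure(
    list(
      classes = tibble(
        d1 = as.integer(dd[, 1]),
        d2 = as.integer(dd[, 2])
      ),
      Y = Y
    ),
    class = "zygote_table"
  )
}

#' Zygote class probabilities at recombination fraction r
#'
#' @param zt A [zygote_table()].
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return Numeric vector of class probabilities (sums to 1).
#' @export
zygote_probs <- function(zt, r) {
  if (any(r < 0 | r > 0.5)) abort("`r` must lie in [0, 0.5]")
  as.vector(zt$Y %*% (r^(0:4) * (1 - r)^(4:0))) / 144
}

#' @export
print.zygote_table <- function(x, ...) {
  cat("Two-locus zygote table:", nrow(x$Y), "observable dosage classes\n")
  df <- x$classes
  df$y <- apply(x$Y, 1, paste, collapse = " ")
  print(as_tibble(df))
  invisible(x)
}

# --- population simulation -------------------------------------------------

# Simulate n two-segment gametes from a phased parent along K loci.
# Returns an n x 2 x K integer array of transmitted homologue indices (1..4).
sim_parent_gametes <- function(parent, rf, n) {
  K <- ncol(parent)
  pair_idx <- sample.int(3, n, replace = TRUE)
  H <- array(0L, dim = c(n, 2, K))
  biv_mat <- array(0L, dim = c(3, 2, 2))
  for (p in 1:3) {
    for (b in 1:2) biv_mat[p, b, ] <- .bivalent_pairings[[p]][[b]]
  }
  for (b in 1:2) {
    opts1 <- biv_mat[pair_idx, b, 1]
    opts2 <- biv_mat[pair_idx, b, 2]
    cur <- runif(n) < 0.5 # TRUE = first homologue of the bivalent
    H[, b, 1] <- ifelse(cur, opts1, opts2)
    if (K > 1) {
      for (k in 2:K) {
        flip <- runif(n) < rf[k - 1]
        cur <- xor(cur, flip)
        H[, b, k] <- ifelse(cur, opts1, opts2)
      }
    }
  }
  H
}

haldane_rf <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

haldane_cm <- function(r) -50 * log(1 - 2 * pmin(r, 0.4999))

#' Simulate a full-sib autotetraploid population
#'
#' Simulates meiosis for both phased parents under random chromosomal
#' segregation: each meiosis draws one of the three bivalent pairings uniformly
#' and walks each bivalent along the SNP sequence with per-interval crossover
#' probability given by the recombination fraction (Haldane, no interference).
#' Optionally emits noisy theta scores around per-dosage class means.
#'
#' @param parent1,parent2 4 x K phased parent matrices ([phased_parent()]).
#' @param map_cm Numeric vector of K non-decreasing positions in cM, or `NULL`
#'   if `rf` is given directly.
#' @param rf Optional numeric vector of K-1 adjacent recombination fractions
#'   (overrides `map_cm`).
#' @param n Number of offspring.
#' @param seed Optional integer seed.
#' @param theta If `TRUE`, also emit a theta matrix.
#' @param theta_means Class means for theta emission (dosage 0-4).
#' @param theta_sd Common standard deviation of the theta noise.
#' @param theta_trend Linear drift in theta across sample order (total span).
#' @return List with `dosage` (n x K integer matrix), `truth1`, `truth2`
#'   (n x 2 x K arrays of inherited homologue indices) and optionally `theta`.
#' @export
simulate_population <- function(parent1, parent2, map_cm = NULL, rf = NULL,
                                n, seed = NULL, theta = FALSE,
                                theta_means = c(0.02, 0.26, 0.50, 0.74, 0.98),
                                theta_sd = 0.02, theta_trend = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) abort("`n` must be at least 1")
  K <- ncol(parent1)
  if (ncol(parent2) != K) abort("parents must be phased at the same SNPs")
  if (K == 0) abort("empty map")
  if (is.null(rf)) {
    if (is.null(map_cm)) abort("supply `map_cm` or `rf`")
    if (is.unsorted(map_cm)) abort("map positions must be non-decreasing")
    rf <- haldane_rf(diff(map_cm))
  }
  H1 <- sim_parent_gametes(parent1, rf, n)
  H2 <- sim_parent_gametes(parent2, rf, n)
  dos <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    dos[, k] <- parent1[H1[, 1, k], k] + parent1[H1[, 2, k], k] +
      parent2[H2[, 1, k], k] + parent2[H2[, 2, k], k]
  }
  colnames(dos) <- colnames(parent1)
  out <- list(dosage = dos, truth1 = H1, truth2 = H2)
  if (theta) {
    out$theta <- sim_theta_matrix(dos,
      means = theta_means, sd = theta_sd,
      trend = theta_trend
    )
  }
  out
}

#' Emit theta scores around dosage class means
#'
#' @param dosage Integer matrix (samples x SNPs) of dosages 0-4.
#' @param means Length-5 class means for dosages 0-4.
#' @param sd Common standard deviation.
#' @param trend Total linear drift across sample order (applied to all SNPs).
#' @return Numeric matrix of theta scores clipped to `[0, 1]`.
#' @export
sim_theta_matrix <- function(dosage, means = c(0.02, 0.26, 0.50, 0.74, 0.98),
                             sd = 0.02, trend = 0) {
  n <- nrow(dosage)
  th <- matrix(means[dosage + 1L], n, ncol(dosage)) +
    matrix(rnorm(length(dosage), 0, sd), n, ncol(dosage)) +
    trend * (seq_len(n) / n - 0.5)
  th <- pmin(pmax(th, 0), 1)
  dimnames(th) <- dimnames(dosage)
  th
}
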