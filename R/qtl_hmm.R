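# Offspring genotype reconstruction along a chromosome with a hidden Markov
# model. The hidden state at a SNP is the quadruple of homologues the
# offspring inherited: one 2-subset of a-d (parent 1) crossed with one
# 2-subset of e-h (parent 2), 36 states in all. Conditional on a bivalent
# pairing in each parent (3 x 3 = 9 combinations) only 16 states are
# reachable; transitions between states k and l have probability
# r^d_kl (1-r)^(4-d_kl) where d_kl counts the bivalents whose transmitted
# homologue changes. Emissions compare the state's B-allele total with the
# observed dosage, allowing a mis-scoring probability lambda. Posterior state
# probabilities come from scaled forward-backward recursions per pairing and
# are combined weighted by the sequence likelihood p(x|B).

.state_pairs <- utils::combn(4, 2) # 6 unordered pairs, columns

#' The 36-state genotype space
#'
#' @return Tibble with `state` (1-36), `p1_pair`, `p2_pair` (columns of the
#'   six 2-subsets), and `name` (e.g. `"aceg"`).
#' @export
genotype_states <- function() {
  l1 <- c("a", "b", "c", "d")
  l2 <- c("e", "f", "g", "h")
  rows <- list()
  s <- 0L
  for (i in 1:6) {
    for (j in 1:6) {
      s <- s + 1L
      rows[[s]] <- tibble(
        state = s, p1_pair = i, p2_pair = j,
        name = paste0(
          paste(l1[.state_pairs[, i]], collapse = ""),
          paste(l2[.state_pairs[, j]], collapse = "")
        )
      )
    }
  }
  bind_rows(rows)
}

# For a pairing (1..3), the four gametes as rows of (choice in bivalent 1,
# choice in bivalent 2) -> which 2-subset of 1..4 they form, plus the
# per-bivalent choice index used for recombination distances.
pairing_gametes <- function(pairing) {
  biv <- .bivalent_pairings[[pairing]]
  out <- matrix(0L, 4, 3) # columns: pair index (1..6), choice1, choice2
  r <- 0L
  for (c1 in 1:2) {
    for (c2 in 1:2) {
      r <- r + 1L
      pair <- sort(c(biv[[1]][c1], biv[[2]][c2]))
      idx <- which(.state_pairs[1, ] == pair[1] & .state_pairs[2, ] == pair[2])
      out[r, ] <- c(idx, c1, c2)
    }
  }
  out
}

#' Reachable states and recombination distances for a bivalent pairing pair
#'
#' @param pairing1,pairing2 Bivalent pairing index (1-3) in each parent;
#'   pairing 1 is (ab)(cd) / (ef)(gh).
#' @return List with `states` (16 state indices into [genotype_states()]) and
#'   `d` (16 x 16 matrix of recombination counts 0-4).
#' @export
pairing_states <- function(pairing1, pairing2) {
  g1 <- pairing_gametes(pairing1)
  g2 <- pairing_gametes(pairing2)
  states <- integer(16)
  choice <- matrix(0L, 16, 4)
  k <- 0L
  for (i in 1:4) {
    for (j in 1:4) {
      k <- k + 1L
      states[k] <- (g1[i, 1] - 1L) * 6L + g2[j, 1]
      choice[k, ] <- c(g1[i, 2:3], g2[j, 2:3])
    }
  }
  d <- matrix(0L, 16, 16)
  for (i in 1:16) {
    for (j in 1:16) d[i, j] <- sum(choice[i, ] != choice[j, ])
  }
  list(states = states, d = d)
}

#' Transition matrix for one map interval under a bivalent pairing pair
#'
#' @param r Recombination fraction of the interval.
#' @param pairing A list from [pairing_states()] (or a pairing pair
#'   `c(p1, p2)`).
#' @return 16 x 16 stochastic matrix `r^d (1-r)^(4-d)`.
#' @export
transition_matrix <- function(r, pairing) {
  if (is.numeric(pairing)) pairing <- pairing_states(pairing[1], pairing[2])
  r^pairing$d * (1 - r)^(4 - pairing$d)
}

#' Dosage-compatibility indicators over the 36 states
#'
#' `s_k = 1` when the B-allele total over the four inherited homologues of
#' state k equals the observed dosage; a missing dosage is compatible with
#' every state.
#'
#' @param phase_p1,phase_p2 4-character `A`/`B` phase patterns of the SNP.
#' @param dosage Observed offspring dosage (0-4 or NA).
#' @return Integer vector of length 36.
#' @export
compatible_genotypes <- function(phase_p1, phase_p2, dosage) {
  b1 <- as.integer(strsplit(phase_p1, "")[[1]] == "B")
  b2 <- as.integer(strsplit(phase_p2, "")[[1]] == "B")
  tot <- integer(36)
  s <- 0L
  for (i in 1:6) {
    for (j in 1:6) {
      s <- s + 1L
      tot[s] <- sum(b1[.state_pairs[, i]]) + sum(b2[.state_pairs[, j]])
    }
  }
  if (is.na(dosage)) {
    return(rep(1L, 36))
  }
  as.integer(tot == dosage)
}

#' Emission probability of a dosage match
#'
#' @param s Compatibility indicator (0/1, vectorised).
#' @param lambda Mis-scoring probability in `[0, 0.5)`.
#' @return Probability of emitting the observed symbol.
#' @export
emission_probability <- function(s, lambda = 0.001) {
  if (lambda < 0 || lambda >= 0.5) abort("`lambda` must be in [0, 0.5)")
  ifelse(s == 1, 1 - lambda, lambda)
}

# scaled forward-backward for one offspring under one pairing pair.
# emis: K x 16 emission probabilities restricted to the pairing's states.
# trans: list of K-1 16x16 matrices.
forward_backward_scaled <- function(emis, trans) {
  K <- nrow(emis)
  alpha <- matrix(0, K, 16)
  scale <- numeric(K)
  a <- emis[1, ] / 16
  scale[1] <- sum(a)
  if (scale[1] <= 0) {
    return(list(post = NULL, loglik = -Inf))
  }
  alpha[1, ] <- a / scale[1]
  if (K > 1) {
    for (k in 2:K) {
      a <- as.vector(alpha[k - 1, ] %*% trans[[k - 1]]) * emis[k, ]
      scale[k] <- sum(a)
      if (scale[k] <= 0) {
        return(list(post = NULL, loglik = -Inf))
      }
      alpha[k, ] <- a / scale[k]
    }
  }
  beta <- matrix(0, K, 16)
  beta[K, ] <- 1
  if (K > 1) {
    for (k in (K - 1):1) {
      b <- as.vector(trans[[k]] %*% (emis[k + 1, ] * beta[k + 1, ]))
      beta[k, ] <- b / scale[k + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(post = post, loglik = sum(log(scale)))
}

#' HMM genotype probabilities for offspring along a chromosome
#'
#' Runs the scaled forward-backward recursions for each of the nine bivalent
#' pairing combinations (uniform 1/16 initial distribution over the pairing's
#' reachable states) and combines the posterior state probabilities weighted
#' by the per-pairing sequence likelihoods `p(x|B)`.
#'
#' @param dosage Offspring x SNP dosage matrix for one chromosome (columns in
#'   map order).
#' @param map Tibble `snp`, `position_cm` (map order; used for interval rf by
#'   inverse Haldane) and optionally `phase_p1`, `phase_p2`.
#' @param phases Tibble `snp`, `phase_p1`, `phase_p2` when not part of `map`.
#' @param lambda Emission error probability (default 0.001).
#' @param rf Optional length K-1 vector of adjacent recombination fractions
#'   overriding the map distances.
#' @return An object of class `tetra_hmm`: list with `prob` (offspring x SNP x
#'   36 array of combined genotype probabilities), `pairing_loglik`
#'   (offspring x 9), `map`, `lambda`, `states`.
#' @export
hmm_genotype_probs <- function(dosage, map, phases = NULL, lambda = 0.001,
                               rf = NULL) {
  if (!is.null(phases)) {
    map <- left_join(map, phases, by = "snp")
  }
  if (!all(c("phase_p1", "phase_p2") %in% names(map))) {
    abort("phases missing: supply `phase_p1`/`phase_p2` in `map` or `phases`")
  }
  K <- nrow(map)
  if (!is.null(colnames(dosage))) {
    dosage <- dosage[, map$snp, drop = FALSE]
  } else if (ncol(dosage) != K) {
    abort("`dosage` has no column names and does not match the map")
  }
  n <- nrow(dosage)
  if (is.null(rf)) rf <- haldane_rf(diff(map$position_cm))
  rf <- pmin(pmax(rf, 1e-6), 0.4999)
  # compatibility per SNP: K x 36
  S <- t(vapply(seq_len(K), function(k) {
    compatible_genotypes(map$phase_p1[k], map$phase_p2[k], NA)
  }, integer(36)))
  # B totals per state per SNP for observed-dosage matching
  tot <- t(vapply(seq_len(K), function(k) {
    b1 <- as.integer(strsplit(map$phase_p1[k], "")[[1]] == "B")
    b2 <- as.integer(strsplit(map$phase_p2[k], "")[[1]] == "B")
    v <- integer(36)
    s <- 0L
    for (i in 1:6) {
      for (j in 1:6) {
        s <- s + 1L
        v[s] <- sum(b1[.state_pairs[, i]]) + sum(b2[.state_pairs[, j]])
      }
    }
    v
  }, integer(36)))
  pairings <- list()
  trans <- list()
  idx <- 0L
  for (p1 in 1:3) {
    for (p2 in 1:3) {
      idx <- idx + 1L
      ps <- pairing_states(p1, p2)
      pairings[[idx]] <- ps
      trans[[idx]] <- lapply(rf, function(r) transition_matrix(r, ps))
    }
  }
  prob <- array(0, dim = c(n, K, 36))
  pll <- matrix(-Inf, n, 9)
  for (o in seq_len(n)) {
    dos <- dosage[o, ]
    post_b <- vector("list", 9)
    for (b in 1:9) {
      st <- pairings[[b]]$states
      emis <- matrix(0, K, 16)
      for (k in seq_len(K)) {
        s_k <- if (is.na(dos[k])) rep(1L, 16) else {
          as.integer(tot[k, st] == dos[k])
        }
        emis[k, ] <- emission_probability(s_k, lambda)
      }
      fb <- forward_backward_scaled(emis, trans[[b]])
      pll[o, b] <- fb$loglik
      post_b[[b]] <- fb$post
    }
    mx <- max(pll[o, ])
    if (!is.finite(mx)) {
      abort(paste0(
        "offspring ", o, ": dosage sequence impossible under every ",
        "bivalent pairing; use lambda > 0"
      ))
    }
    w <- exp(pll[o, ] - mx)
    w <- w / sum(w)
    for (b in 1:9) {
      if (w[b] > 0 && !is.null(post_b[[b]])) {
        st <- pairings[[b]]$states
        for (k in seq_len(K)) {
          prob[o, k, st] <- prob[o, k, st] + w[b] * post_b[[b]][k, ]
        }
      }
    }
  }
  structure(
    list(
      prob = prob, pairing_loglik = pll, map = map, lambda = lambda,
      states = genotype_states()
    ),
    class = "tetra_hmm"
  )
}

#' @export
print.tetra_hmm <- function(x, ...) {
  d <- dim(x$prob)
  cat(
    "HMM genotype probabilities:", d[1], "offspring x", d[2],
    "SNPs x 36 states (lambda =", x$lambda, ")\n"
  )
  invisible(x)
}

#' Interpolate genotype probabilities onto a cM grid
#'
#' Natural cubic-spline interpolation of each state trajectory, clipped to
#' `[0, 1]` and renormalised over the 36 states at every grid point; beyond
#' the terminal SNPs the probabilities are held constant.
#'
#' @param hmm A `tetra_hmm`.
#' @param step Grid spacing in cM (default 1).
#' @return List with `grid_cm` and `prob` (offspring x grid x 36 array).
#' @export
interpolate_grid <- function(hmm, step = 1) {
  pos <- hmm$map$position_cm
  if (length(pos) < 2) abort("need at least 2 mapped SNPs")
  grid <- seq(min(pos), max(pos), by = step)
  if (grid[length(grid)] < max(pos)) grid <- c(grid, max(pos))
  n <- dim(hmm$prob)[1]
  out <- array(0, dim = c(n, length(grid), 36))
  for (o in seq_len(n)) {
    for (s in 1:36) {
      y <- hmm$prob[o, , s]
      if (all(y == y[1])) {
        out[o, , s] <- y[1]
      } else {
        sp <- spline(pos, y, xout = grid, method = "natural", ties = mean)
        out[o, , s] <- pmin(pmax(sp$y, 0), 1)
      }
    }
    out[o, , ] <- out[o, , ] / rowSums(out[o, , ])
  }
  list(grid_cm = grid, prob = out)
}

#' Brute-force path-enumeration reference for the HMM
#'
#' Enumerates all 16^K state paths per bivalent pairing combination, weighting
#' each by initial x transitions x emissions, and accumulates exact posterior
#' state probabilities and sequence likelihoods. Only feasible for short maps
#' (K <= 5); used to validate the scaled forward-backward recursion.
#'
#' @inheritParams hmm_genotype_probs
#' @param dosage_row A single offspring's dosage vector.
#' @return List with `prob` (K x 36) and `pairing_loglik` (length 9).
#' @export
hmm_brute_force <- function(dosage_row, map, lambda = 0.001, rf = NULL) {
  K <- nrow(map)
  if (16^K > 2e6) abort("brute force limited to short maps")
  if (is.null(rf)) rf <- haldane_rf(diff(map$position_cm))
  rf <- pmin(pmax(rf, 1e-6), 0.4999)
  tot <- t(vapply(seq_len(K), function(k) {
    b1 <- as.integer(strsplit(map$phase_p1[k], "")[[1]] == "B")
    b2 <- as.integer(strsplit(map$phase_p2[k], "")[[1]] == "B")
    v <- integer(36)
    s <- 0L
    for (i in 1:6) {
      for (j in 1:6) {
        s <- s + 1L
        v[s] <- sum(b1[.state_pairs[, i]]) + sum(b2[.state_pairs[, j]])
      }
    }
    v
  }, integer(36)))
  prob <- matrix(0, K, 36)
  pll <- numeric(9)
  idx <- 0L
  total_by_pairing <- numeric(9)
  post_list <- list()
  for (p1 in 1:3) {
    for (p2 in 1:3) {
      idx <- idx + 1L
      ps <- pairing_states(p1, p2)
      st <- ps$states
      emis <- matrix(0, K, 16)
      for (k in seq_len(K)) {
        s_k <- if (is.na(dosage_row[k])) rep(1L, 16) else {
          as.integer(tot[k, st] == dosage_row[k])
        }
        emis[k, ] <- emission_probability(s_k, lambda)
      }
      paths <- as.matrix(expand.grid(rep(list(1:16), K)))
      wts <- emis[1, paths[, 1]] / 16
      if (K > 1) {
        for (k in 2:K) {
          A <- transition_matrix(rf[k - 1], ps)
          wts <- wts * A[cbind(paths[, k - 1], paths[, k])] *
            emis[k, paths[, k]]
        }
      }
      tot_w <- sum(wts)
      total_by_pairing[idx] <- tot_w
      pll[idx] <- log(tot_w)
      pk <- matrix(0, K, 16)
      for (k in seq_len(K)) {
        pk[k, ] <- vapply(1:16, function(j) {
          sum(wts[paths[, k] == j])
        }, numeric(1)) / tot_w
      }
      post_list[[idx]] <- list(states = st, post = pk)
    }
  }
  w <- total_by_pairing / sum(total_by_pairing)
  for (b in 1:9) {
    st <- post_list[[b]]$states
    for (k in seq_len(K)) {
      prob[k, st] <- prob[k, st] + w[b] * post_list[[b]]$post[k, ]
    }
  }
  list(prob = prob, pairing_loglik = pll)
}

#' Genotype-recovery benchmark on simulated offspring
#'
#' Simulates offspring with known inherited homologues from phased parents
#' along a map, reconstructs genotype probabilities with the HMM, and scores
#' the maximum-probability state against the truth at every SNP position.
#'
#' @param parent1,parent2 4 x K phased parent matrices.
#' @param map Tibble `snp`, `position_cm`, `phase_p1`, `phase_p2`.
#' @param n Number of simulated offspring (default 100).
#' @param lambda Emission error.
#' @param seed Optional seed.
#' @return One-row tibble: `prop_correct` (all four homologues right),
#'   `prop_3of4`, `n`, `n_snps`.
#' @export
genotype_recovery_benchmark <- function(parent1, parent2, map, n = 100,
                                        lambda = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_population(parent1, parent2,
    map_cm = map$position_cm, n = n
  )
  hmm <- hmm_genotype_probs(sim$dosage, map, lambda = lambda)
  st <- genotype_states()
  K <- nrow(map)
  correct4 <- 0L
  correct3 <- 0L
  for (o in seq_len(n)) {
    for (k in seq_len(K)) {
      est <- which.max(hmm$prob[o, k, ])
      est_p1 <- .state_pairs[, st$p1_pair[est]]
      est_p2 <- .state_pairs[, st$p2_pair[est]]
      true_p1 <- sort(sim$truth1[o, , k])
      true_p2 <- sort(sim$truth2[o, , k])
      nmatch <- length(intersect(est_p1, true_p1)) +
        length(intersect(est_p2, true_p2))
      if (nmatch == 4) correct4 <- correct4 + 1L
      if (nmatch == 3) correct3 <- correct3 + 1L
    }
  }
  tibble(
    prop_correct = correct4 / (n * K), prop_3of4 = correct3 / (n * K),
    n = n, n_snps = K
  )
}
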