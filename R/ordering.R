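# Ordering SNPs within a linkage group by weighted least squares on the
# pairwise recombination fractions and LOD scores. Only pairs with rf < 0.45
# and LOD > 0.05 enter; rf is converted to distance with the Haldane map
# function and pairs are weighted by LOD^2. The initial order (first principal
# coordinate of the distance matrix) is refined by a windowed ripple search
# (all permutations of a sliding window of 5), accepting permutations that
# decrease the WLS stress. A second round drops poorly fitting SNPs and
# re-fits.

#' Remove near-duplicate SNPs before ordering
#'
#' Greedy clustering by Hamming distance on the dosage calls: scanning SNPs in
#' id order, a SNP differing from an already retained representative in at
#' most `max_diff` offspring (missing counts as a mismatch) is recorded as a
#' duplicate of that representative. Duplicates are compared against
#' representatives only.
#'
#' @param dosage Offspring x SNP dosage matrix.
#' @param max_diff Maximum number of differing offspring (default 2).
#' @return Tibble `snp`, `representative` (equal to `snp` for retained SNPs),
#'   `n_diff`.
#' @export
remove_near_duplicates <- function(dosage, max_diff = 2) {
  snps <- sort(colnames(dosage))
  reps <- character(0)
  out <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    x <- dosage[, s]
    hit <- NA_character_
    nd <- NA_integer_
    for (r in reps) {
      y <- dosage[, r]
      d <- sum(is.na(x) | is.na(y) | x != y)
      if (d <= max_diff) {
        hit <- r
        nd <- as.integer(d)
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, s)
      out[[i]] <- tibble(snp = s, representative = s, n_diff = 0L)
    } else {
      out[[i]] <- tibble(snp = s, representative = hit, n_diff = nd)
    }
  }
  bind_rows(out)
}

# Weighted least-squares positions for a given order.
# D, W are symmetric matrices over the SNPs (in original label order); `ord`
# is an integer permutation. Interval lengths are solved from the normal
# equations of sum w_ij (D_ij - sum_k L_k)^2 and clamped at 0.
wls_positions <- function(ord, D, W) {
  k <- length(ord)
  if (k == 2) {
    d <- D[ord[1], ord[2]]
    return(list(pos = c(0, ifelse(is.na(d), 0, d)), stress = 0))
  }
  pr <- which(upper.tri(D), arr.ind = TRUE)
  # map to positions within the order
  io <- match(pr[, 1], ord)
  jo <- match(pr[, 2], ord)
  w <- W[pr]
  d <- D[pr]
  keep <- !is.na(d) & !is.na(w) & w > 0
  io <- io[keep]
  jo <- jo[keep]
  w <- w[keep]
  d <- d[keep]
  lo <- pmin(io, jo)
  hi <- pmax(io, jo)
  cols <- seq_len(k - 1)
  A <- 1 * (outer(lo, cols, `<=`) & outer(hi, cols, `>`))
  # non-negative weighted least squares on the interval lengths (active set:
  # drop the most negative interval and refit until feasible)
  active <- seq_len(k - 1)
  L <- numeric(k - 1)
  repeat {
    fit <- lm.wfit(A[, active, drop = FALSE], d, w)
    b <- coef(fit)
    b[is.na(b)] <- 0
    if (all(b >= -1e-12) || length(active) == 1) {
      L[active] <- pmax(b, 0)
      break
    }
    active <- active[-which.min(b)]
  }
  pos <- c(0, cumsum(L))
  fitted <- pos[hi] - pos[lo]
  stress <- sum(w * (d - fitted)^2)
  list(pos = pos, stress = stress)
}

order_stress <- function(ord, D, W) wls_positions(ord, D, W)$stress

# principal-coordinate seriation of the distance matrix completed by shortest
# paths through reliable edges only (LOD at or above the threshold); distance
# estimates from weakly supported pairs are too biased to seed the global
# order
isomap_order <- function(D, W, w_min = NULL) {
  k <- nrow(D)
  wpos <- W[W > 0]
  if (is.null(w_min)) w_min <- quantile(wpos, 0.75)
  for (thr in unique(c(w_min, quantile(wpos, c(0.5, 0.25)), 0))) {
    Dc <- D
    Dc[W < thr] <- NA
    diag(Dc) <- 0
    Dc[is.na(Dc)] <- Inf
    for (m in seq_len(k)) { # Floyd-Warshall
      Dc <- pmin(Dc, outer(Dc[, m], Dc[m, ], `+`))
    }
    if (all(is.finite(Dc))) break
  }
  if (any(!is.finite(Dc))) {
    Dc[!is.finite(Dc)] <- max(Dc[is.finite(Dc)]) * 1.5
  }
  cs <- stats::cmdscale(stats::as.dist(Dc), k = 1)
  order(cs[, 1])
}

# greedy chain extension on LOD: start from the strongest pair and repeatedly
# attach, at either chain end, the unplaced SNP with the highest LOD to that
# end (the reliable linkages drive the global order; weak distant pairs do
# not)
initial_order <- function(D, W) {
  k <- nrow(D)
  if (k <= 2) {
    return(seq_len(k))
  }
  Wl <- sqrt(W) # attachment strength
  diag(Wl) <- 0
  start <- which(Wl == max(Wl), arr.ind = TRUE)[1, ]
  chain <- as.integer(start)
  left <- setdiff(seq_len(k), chain)
  while (length(left)) {
    head_w <- Wl[chain[1], left]
    tail_w <- Wl[chain[length(chain)], left]
    if (max(head_w) >= max(tail_w)) {
      pick <- left[which.max(head_w)]
      chain <- c(pick, chain)
    } else {
      pick <- left[which.max(tail_w)]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  chain
}

# sequential map build: start from the strongest pair and add one SNP at a
# time (strongest total linkage to the mapped set first), inserting it at the
# slot that minimises the WLS stress of the partial map; a windowed ripple
# runs after every five additions
sequential_order <- function(D, W, window = 5) {
  k <- nrow(D)
  if (k <= 2) {
    return(seq_len(k))
  }
  Wl <- sqrt(W)
  diag(Wl) <- 0
  start <- which(Wl == max(Wl), arr.ind = TRUE)[1, ]
  ord <- as.integer(start)
  left <- setdiff(seq_len(k), ord)
  added <- 0L
  while (length(left)) {
    strength <- vapply(left, function(s) sum(Wl[s, ord]), numeric(1))
    s <- left[which.max(strength)]
    left <- setdiff(left, s)
    best_st <- Inf
    best_cand <- NULL
    for (pos in 0:length(ord)) {
      cand <- append(ord, s, after = pos)
      st <- order_stress(seq_along(cand), D[cand, cand, drop = FALSE],
        W[cand, cand, drop = FALSE])
      if (st < best_st) {
        best_st <- st
        best_cand <- cand
      }
    }
    ord <- best_cand
    added <- added + 1L
    if (added %% 5L == 0L && length(ord) > window) {
      sub_d <- D[ord, ord, drop = FALSE]
      sub_w <- W[ord, ord, drop = FALSE]
      fit <- wls_positions(seq_along(ord), sub_d, sub_w)
      rip <- ripple_pass(seq_along(ord), fit$pos,
        make_pairlist(sub_d, sub_w), window)
      ord <- ord[rip]
    }
  }
  ord
}

# pair list for fast stress evaluation
make_pairlist <- function(D, W) {
  pr <- which(upper.tri(D) & !is.na(D) & W > 0, arr.ind = TRUE)
  list(i = pr[, 1], j = pr[, 2], w = W[pr], d = D[pr], k = nrow(D))
}

# stress of a candidate order with the current slot positions held fixed
# (cheap screen used inside the search passes; the accepted order is re-fitted
# by full weighted least squares between sweeps)
slot_stress <- function(ord, slots, pl) {
  x <- numeric(pl$k)
  x[ord] <- slots
  sum(pl$w * (pl$d - abs(x[pl$i] - x[pl$j]))^2)
}

# reverse every contiguous segment; keep improvements (2-opt)
reversal_pass <- function(ord, slots, pl) {
  k <- length(ord)
  best <- slot_stress(ord, slots, pl)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cand <- ord
      cand[i:j] <- rev(cand[i:j])
      st <- slot_stress(cand, slots, pl)
      if (st < best - 1e-12) {
        ord <- cand
        best <- st
      }
    }
  }
  ord
}

ripple_pass <- function(ord, slots, pl, window = 5) {
  k <- length(ord)
  if (k <= 2) {
    return(ord)
  }
  window <- min(window, k)
  perms <- permutations_of(window)
  best <- slot_stress(ord, slots, pl)
  for (start in seq_len(k - window + 1)) {
    idx <- start:(start + window - 1)
    seg <- ord[idx]
    for (p in seq_len(nrow(perms))) {
      cand <- ord
      cand[idx] <- seg[perms[p, ]]
      if (identical(cand, ord)) next
      st <- slot_stress(cand, slots, pl)
      if (st < best - 1e-12) {
        ord <- cand
        best <- st
      }
    }
  }
  ord
}

# try moving each SNP to every other position, keeping improvements
relocation_pass <- function(ord, slots, pl) {
  k <- length(ord)
  best <- slot_stress(ord, slots, pl)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      cand <- append(ord[-i], ord[i], after = j - 1)
      st <- slot_stress(cand, slots, pl)
      if (st < best - 1e-12) {
        ord <- cand
        best <- st
        break
      }
    }
  }
  ord
}

# alternate ripple, relocation and reversal sweeps; positions are re-fitted by
# weighted least squares after each sweep and the sweep is kept only when the
# full WLS stress improves
refine_order <- function(ord, D, W, window, max_sweeps = 8) {
  pl <- make_pairlist(D, W)
  fit <- wls_positions(ord, D, W)
  best_ord <- ord
  best_st <- fit$stress
  slots <- fit$pos
  for (sw in seq_len(max_sweeps)) {
    ord <- ripple_pass(ord, slots, pl, window)
    ord <- relocation_pass(ord, slots, pl)
    ord <- reversal_pass(ord, slots, pl)
    fit <- wls_positions(ord, D, W)
    if (fit$stress >= best_st - 1e-10) break
    best_ord <- ord
    best_st <- fit$stress
    slots <- fit$pos
  }
  best_ord
}

permutations_of <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Order and space the SNPs of one linkage group
#'
#' @param pairs Pairwise linkage tibble (`snp1`, `snp2`, `rf`, `lod`) for the
#'   group.
#' @param snps SNP ids to order.
#' @param max_rf,min_lod Pair filters (defaults 0.45 and 0.05).
#' @param min_phase_gap Pairs whose best phase beats the runner-up by less
#'   than this log-likelihood margin (default 2.3, i.e. 10:1 odds) are
#'   excluded: a wrong phase choice biases the recombination fraction far
#'   more than sampling noise. Ignored when the pair table has no
#'   `phase_gap` column.
#' @param window Ripple window (default 5).
#' @param drop_factor Round-2 rule: drop SNPs whose mean stress contribution
#'   exceeds `drop_factor` times the group median (default 3).
#' @param two_rounds Run the drop-and-refit second round (default TRUE).
#' @return An object of class `tetra_map_group`: list with `map` (tibble
#'   `snp`, `position_cm`), `dropped`, `stress`, `disconnected` (SNP ids in
#'   components other than the largest, ordered separately and flagged).
#' @export
order_and_space <- function(pairs, snps, max_rf = 0.45, min_lod = 0.05,
                            min_phase_gap = 2.3, window = 5,
                            drop_factor = 3, two_rounds = TRUE) {
  pr <- pairs[pairs$snp1 %in% snps & pairs$snp2 %in% snps &
    !is.na(pairs$rf) & pairs$rf < max_rf & pairs$lod > min_lod, ]
  if ("phase_gap" %in% names(pr)) {
    pr <- pr[is.na(pr$phase_gap) | !is.finite(pr$phase_gap) |
      pr$phase_gap > min_phase_gap, ]
  }
  if (length(snps) < 3) abort("need at least 3 SNPs with usable pairs")
  comp <- connected_components(snps, pr[, c("snp1", "snp2")])
  main <- names(comp)[comp == as.integer(names(which.max(table(comp))))]
  disconnected <- setdiff(snps, main)
  use <- main
  k <- length(use)
  D <- matrix(NA_real_, k, k, dimnames = list(use, use))
  W <- matrix(0, k, k, dimnames = list(use, use))
  sub <- pr[pr$snp1 %in% use & pr$snp2 %in% use, ]
  for (i in seq_len(nrow(sub))) {
    a <- sub$snp1[i]
    b <- sub$snp2[i]
    D[a, b] <- D[b, a] <- haldane_cm(sub$rf[i])
    W[a, b] <- W[b, a] <- sub$lod[i]^2
  }
  ord <- best_order(D, W, window)
  fit <- wls_positions(ord, D, W)
  # trim pairs whose fitted residual is far from the round-1 map (the
  # recombination fraction of weakly informative pair types can be badly
  # biased at long range); re-fit on the trimmed weights
  pos <- setNames(fit$pos, use[ord])[use]
  res <- abs(D - abs(outer(pos, pos, `-`)))
  wr <- sqrt(sum(W * res^2, na.rm = TRUE) / sum(W[!is.na(res)]))
  cut <- max(15, 3 * wr)
  if (any(res > cut, na.rm = TRUE)) {
    W[!is.na(res) & res > cut] <- 0
    ord <- best_order(D, W, window)
    fit <- wls_positions(ord, D, W)
  }
  dropped <- character(0)
  if (two_rounds && k > 4) {
    contrib <- snp_stress_contribution(ord, D, W, fit$pos)
    med <- median(contrib, na.rm = TRUE)
    bad <- names(contrib)[!is.na(contrib) & med > 0 &
      contrib > drop_factor * med]
    if (length(bad) && length(bad) < k - 3) {
      dropped <- bad
      use2 <- setdiff(use, bad)
      idx <- match(use2, use)
      D2 <- D[idx, idx]
      W2 <- W[idx, idx]
      ord <- best_order(D2, W2, window)
      fit <- wls_positions(ord, D2, W2)
      use <- use2
      D <- D2
    }
  }
  map <- tibble(
    snp = use[ord],
    position_cm = fit$pos
  )
  structure(
    list(
      map = map, dropped = dropped, stress = fit$stress,
      disconnected = disconnected
    ),
    class = "tetra_map_group"
  )
}

# multi-start order search: refine from the reliable-edge seriation, a looser
# seriation and the greedy LOD chain; keep the lowest-stress order
best_order <- function(D, W, window) {
  wpos <- W[W > 0]
  seeds <- list(
    sequential_order(D, W, window),
    isomap_order(D, W, w_min = quantile(wpos, 0.75)),
    isomap_order(D, W, w_min = quantile(wpos, 0.5)),
    initial_order(D, W)
  )
  seeds <- unique(seeds)
  best <- NULL
  best_st <- Inf
  for (s in seeds) {
    o <- refine_order(s, D, W, window)
    st <- order_stress(o, D, W)
    if (st < best_st) {
      best <- o
      best_st <- st
    }
  }
  best
}

snp_stress_contribution <- function(ord, D, W, pos) {
  use <- rownames(D)
  x <- setNames(pos[match(seq_along(ord), seq_along(ord))], use[ord])
  x <- x[use]
  contrib <- setNames(numeric(length(use)), use)
  cnt <- setNames(numeric(length(use)), use)
  pr <- which(upper.tri(D), arr.ind = TRUE)
  for (p in seq_len(nrow(pr))) {
    i <- pr[p, 1]
    j <- pr[p, 2]
    if (is.na(D[i, j]) || W[i, j] <= 0) next
    e <- W[i, j] * (D[i, j] - abs(x[i] - x[j]))^2
    contrib[i] <- contrib[i] + e
    contrib[j] <- contrib[j] + e
    cnt[i] <- cnt[i] + 1
    cnt[j] <- cnt[j] + 1
  }
  ifelse(cnt > 0, contrib / cnt, NA_real_)
}

#' @export
print.tetra_map_group <- function(x, ...) {
  cat(
    "Ordered linkage group:", nrow(x$map), "SNPs,",
    round(max(x$map$position_cm), 1), "cM; stress",
    signif(x$stress, 4), "\n"
  )
  if (length(x$dropped)) cat("dropped in round 2:", x$dropped, "\n")
  if (length(x$disconnected)) cat("disconnected:", x$disconnected, "\n")
  invisible(x)
}

#' Bin unplaced SNPs next to their best mapped anchor
#'
#' Each unplaced SNP is anchored next to the mapped SNP with which it has the
#' highest LOD, provided the recombination fraction is below `max_rf`
#' (default 0.05); LOD ties go to the anchor with the smaller rf.
#'
#' @param unplaced Character vector of SNP ids.
#' @param map Tibble `snp`, `position_cm` of mapped SNPs.
#' @param pairs Pairwise linkage tibble.
#' @param max_rf Binning threshold.
#' @return Tibble `snp`, `anchor`, `rf`, `lod`, `position_cm` (anchor
#'   position; NA when the SNP stays unplaced).
#' @export
bin_unplaced <- function(unplaced, map, pairs, max_rf = 0.05) {
  if (!length(unplaced)) {
    return(tibble(
      snp = character(), anchor = character(), rf = numeric(),
      lod = numeric(), position_cm = numeric()
    ))
  }
  out <- lapply(unplaced, function(s) {
    pr <- pairs[(pairs$snp1 == s & pairs$snp2 %in% map$snp) |
      (pairs$snp2 == s & pairs$snp1 %in% map$snp), ]
    if (!nrow(pr)) {
      return(tibble(
        snp = s, anchor = NA_character_, rf = NA_real_,
        lod = NA_real_, position_cm = NA_real_
      ))
    }
    pr$anchor <- ifelse(pr$snp1 == s, pr$snp2, pr$snp1)
    pr <- pr[order(-pr$lod, pr$rf), ]
    best <- pr[1, ]
    if (is.na(best$rf) || best$rf >= max_rf) {
      return(tibble(
        snp = s, anchor = NA_character_, rf = NA_real_,
        lod = NA_real_, position_cm = NA_real_
      ))
    }
    tibble(
      snp = s, anchor = best$anchor, rf = best$rf, lod = best$lod,
      position_cm = map$position_cm[match(best$anchor, map$snp)]
    )
  })
  bind_rows(out)
}

#' Reconstruct full parental phase against the simplex framework
#'
#' For each target SNP and each parent, tests the phase against every
#' framework simplex SNP of that parent; a B allele is assigned to a homologue
#' when coupling is supported at LOD greater than `min_lod` (default 5).
#' When fewer homologues are supported than the parental dosage requires, the
#' assignment is completed from the highest-LOD informative pair with the
#' largest log-likelihood margin over its second phase; SNPs whose supported
#' homologues exceed the dosage are flagged as contradictory and left
#' unphased.
#'
#' @param targets Character vector of SNP ids to phase.
#' @param framework Tibble `snp`, `parent`, `homologue` (1-4 within parent)
#'   for framework simplex SNPs.
#' @param dosage Offspring x SNP dosage matrix.
#' @param configs Tibble `snp`, `parent1_dosage`, `parent2_dosage`.
#' @param min_lod Coupling support threshold.
#' @return Tibble `snp`, `phase_p1`, `phase_p2` (4-character `A`/`B` patterns;
#'   NA when unresolved), `flag` (`ok`, `incomplete`, `contradiction`).
#' @export
reconstruct_phase <- function(targets, framework, dosage, configs,
                              min_lod = 5) {
  cfg <- setNames(
    lapply(seq_len(nrow(configs)), function(i) {
      c(configs$parent1_dosage[i], configs$parent2_dosage[i])
    }), configs$snp
  )
  out <- lapply(targets, function(s) {
    d <- cfg[[s]]
    pats <- character(2)
    flag <- "ok"
    for (pa in 1:2) {
      dos <- d[pa]
      if (dos == 0 || dos == 4) {
        pats[pa] <- paste(rep(if (dos == 0) "A" else "B", 4), collapse = "")
        next
      }
      fw <- framework[framework$parent == pa, ]
      # minor-allele placement: for dosage > 2 we place the A alleles
      n_place <- if (dos <= 2) dos else 4L - dos
      support <- rep(NA_real_, 4) # best LOD supporting coupling per homologue
      gapv <- rep(NA_real_, 4)
      for (j in seq_len(nrow(fw))) {
        sx <- fw$snp[j]
        lk <- linkage_pair(dosage[, s], dosage[, sx], cfg[[s]], cfg[[sx]])
        if (is.na(lk$lod) || lk$lod <= min_lod) next
        tt <- if (pa == 1) lk$t1 else lk$t2
        # coupling with the simplex allele (minor-allele overlap 1)
        u <- minor_overlap(d[pa], 1L, tt)
        h <- fw$homologue[j]
        if (u == 1) {
          if (is.na(support[h]) || lk$lod > support[h]) {
            support[h] <- lk$lod
            gapv[h] <- lk$phase_gap
          }
        } else {
          support[h] <- if (is.na(support[h])) -lk$lod else support[h]
        }
      }
      coupled <- which(!is.na(support) & support > 0)
      if (length(coupled) > n_place) {
        flag <- "contradiction"
        pats[pa] <- NA_character_
        next
      }
      if (length(coupled) < n_place) {
        # complete from the strongest remaining candidates
        cand <- setdiff(which(!is.na(support)), coupled)
        flag <- if (flag == "ok") "incomplete" else flag
        need <- n_place - length(coupled)
        extra <- cand[order(-abs(support[cand]))]
        coupled <- c(coupled, head(extra, need))
        if (length(coupled) < n_place) {
          pats[pa] <- NA_character_
          next
        }
      }
      pat <- rep(if (dos <= 2) "A" else "B", 4)
      pat[coupled] <- if (dos <= 2) "B" else "A"
      pats[pa] <- paste(pat, collapse = "")
    }
    tibble(snp = s, phase_p1 = pats[1], phase_p2 = pats[2], flag = flag)
  })
  bind_rows(out)
}

#' Plot a genetic map
#'
#' @param object A tibble with `snp`, `position_cm` and optionally `chrom`.
#' @param ... Unused.
#' @return A ggplot of marker positions per linkage group.
#' @export
plot_genetic_map <- function(object, ...) {
  df <- as_tibble(object)
  if (!"chrom" %in% names(df)) df$chrom <- "LG"
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$chrom),
    y = .data$position_cm
  )) +
    ggplot2::geom_point(shape = 95, size = 6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (cM)")
}
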