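# Linkage-group assembly. Pairwise chi-square tests of independent
# segregation give a distance (the p-value; small = close) that is comparable
# across SNP pairs with different numbers of dosage classes; groups come from
# average-linkage clustering of that distance. Simplex SNPs additionally form
# per-homologue framework groups by coupling linkage, and duplex+simplex /
# simplex+double-simplex tests associate homologues and parental groups.

#' Chi-square test of independent segregation for one SNP pair
#'
#' Contingency-table chi-square on the joint dosage classes. Rows/columns
#' whose expected count is everywhere below 1 are merged into their nearest
#' neighbour; degrees of freedom follow the table actually used.
#'
#' @param dos1,dos2 Integer dosage vectors on a shared offspring set.
#' @return One-row tibble `statistic`, `df`, `p` (floored at 1e-300), `n`.
#' @export
snp_independence_test <- function(dos1, dos2) {
  ok <- !is.na(dos1) & !is.na(dos2)
  tab <- table(dos1[ok], dos2[ok])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(tibble(
      statistic = NA_real_, df = NA_integer_, p = NA_real_,
      n = sum(ok)
    ))
  }
  tab <- merge_sparse_margins(tab)
  n <- sum(tab)
  ex <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - ex)^2 / ex)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- max(pchisq(stat, df, lower.tail = FALSE), 1e-300)
  tibble(statistic = stat, df = df, p = p, n = sum(ok))
}

merge_sparse_margins <- function(tab) {
  repeat {
    n <- sum(tab)
    ex <- outer(rowSums(tab), colSums(tab)) / n
    bad_r <- which(apply(ex, 1, max) < 1)
    if (length(bad_r) && nrow(tab) > 2) {
      i <- bad_r[1]
      j <- if (i == 1) 2L else i - 1L
      tab[j, ] <- tab[j, ] + tab[i, ]
      tab <- tab[-i, , drop = FALSE]
      next
    }
    bad_c <- which(apply(ex, 2, max) < 1)
    if (length(bad_c) && ncol(tab) > 2) {
      i <- bad_c[1]
      j <- if (i == 1) 2L else i - 1L
      tab[, j] <- tab[, j] + tab[, i]
      tab <- tab[, -i, drop = FALSE]
      next
    }
    return(tab)
  }
}

#' Pairwise independence p-value matrix
#'
#' @param dosage Offspring x SNP dosage matrix.
#' @return Symmetric matrix of p-value distances (diagonal 0).
#' @export
independence_distance <- function(dosage) {
  snps <- colnames(dosage)
  k <- length(snps)
  pm <- matrix(1, k, k, dimnames = list(snps, snps))
  diag(pm) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- snp_independence_test(dosage[, i], dosage[, j])$p
      if (is.na(p)) p <- 1
      pm[i, j] <- pm[j, i] <- p
    }
  }
  pm
}

#' Average-linkage clustering of SNPs into linkage groups
#'
#' Group-average hierarchical clustering on the p-value distance matrix, cut
#' at `threshold` (default 0.1).
#'
#' @param pmat Symmetric p-value distance matrix (e.g. from
#'   [independence_distance()]).
#' @param threshold Cut height.
#' @return Tibble `snp`, `group` (integer; groups ordered by size).
#' @export
cluster_linkage_groups <- function(pmat, threshold = 0.1) {
  hc <- hclust(stats::as.dist(pmat), method = "average")
  grp <- cutree(hc, h = threshold)
  sizes <- sort(table(grp), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  tibble(
    snp = names(grp),
    group = as.integer(relabel[as.character(grp)])
  ) |> arrange(.data$group, .data$snp)
}

#' Merge the two parent-wise cluster runs
#'
#' Higher-dosage SNPs (informative in both parents) enter both cluster runs;
#' they are retained only when the two runs place them in corresponding
#' groups. Correspondence between run-1 and run-2 groups is established by
#' maximal overlap on the shared SNPs.
#'
#' @param run1,run2 Tibbles `snp`, `group` from [cluster_linkage_groups()].
#' @param shared Character vector of SNP ids present in both runs.
#' @return Tibble `snp`, `group`, `supported` (FALSE for shared SNPs whose two
#'   placements disagree; such SNPs are excluded from `group`, reported with
#'   `group = NA`).
#' @export
merge_cluster_runs <- function(run1, run2, shared) {
  s1 <- run1[run1$snp %in% shared, ]
  s2 <- run2[run2$snp %in% shared, ]
  joint <- left_join(s1, s2, by = "snp", suffix = c("1", "2"))
  map21 <- joint |>
    count(.data$group2, .data$group1) |>
    group_by(.data$group2) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup()
  lut <- setNames(map21$group1, map21$group2)
  joint$group2_mapped <- lut[as.character(joint$group2)]
  joint$supported <- !is.na(joint$group2_mapped) &
    joint$group1 == joint$group2_mapped
  out1 <- run1[!run1$snp %in% shared, ]
  out1$supported <- TRUE
  sh <- tibble(
    snp = joint$snp,
    group = unname(ifelse(joint$supported, joint$group1, NA_integer_)),
    supported = joint$supported
  )
  # run-2-only SNPs join the run-1 group their run-2 cluster maps onto;
  # run-2 clusters with no shared anchor get fresh group ids
  out2 <- run2[!run2$snp %in% shared & !run2$snp %in% run1$snp, ]
  if (nrow(out2)) {
    g2 <- unname(lut[as.character(out2$group)])
    if (any(is.na(g2))) {
      base <- max(c(run1$group, 0L), na.rm = TRUE)
      fresh <- setNames(
        base + seq_along(unique(out2$group[is.na(g2)])),
        unique(out2$group[is.na(g2)])
      )
      g2[is.na(g2)] <- fresh[as.character(out2$group[is.na(g2)])]
    }
    out2$group <- as.integer(g2)
    out2$supported <- TRUE
  }
  bind_rows(out1, sh, out2) |> arrange(.data$group, .data$snp)
}

#' Simplex framework groups (candidate homologues)
#'
#' Single-linkage grouping of same-parent simplex SNPs: two SNPs join a group
#' when their coupling recombination fraction is at most `max_rf` (default
#' 0.25 which, for a population near 190 offspring, corresponds to a coupling
#' LOD close to 10.8). Each resulting group is a candidate homologue. Groups
#' smaller than 4 SNPs are flagged fragile.
#'
#' @param pairs Tibble of pairwise results for simplex SNPs of one parent:
#'   columns `snp1`, `snp2`, `rf`, `phase` (only `"C"` rows are used).
#' @param snps All simplex SNP ids considered.
#' @param max_rf Coupling recombination-fraction threshold.
#' @return Tibble `snp`, `homologue_group`, `fragile`.
#' @export
build_simplex_framework <- function(pairs, snps, max_rf = 0.25) {
  edges <- pairs[pairs$phase == "C" & !is.na(pairs$rf) &
    pairs$rf <= max_rf, c("snp1", "snp2")]
  comp <- connected_components(snps, edges)
  sizes <- table(comp)
  tibble(
    snp = names(comp),
    homologue_group = as.integer(comp),
    fragile = as.vector(sizes[as.character(comp)] < 4)
  ) |> arrange(.data$homologue_group, .data$snp)
}

# union-find connected components on an edge list
connected_components <- function(nodes, edges) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(match(edges[[1]][e], nodes))
      b <- find(match(edges[[2]][e], nodes))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  comp <- as.integer(factor(roots, levels = unique(roots)))
  setNames(comp, nodes)
}

#' Associate homologue frameworks via duplex and double-simplex SNPs
#'
#' Duplex+simplex pairs from the same parent are the most informative for
#' linking homologues of one parent into chromosome groups; significant
#' simplex+double-simplex *coupling* pairs match parental groups across the
#' two parents (repulsion pairs have much lower power and are excluded).
#'
#' @param framework Tibble `snp`, `parent` (1 or 2), `homologue_group` for the
#'   simplex frameworks of both parents.
#' @param dosage Offspring x SNP dosage matrix.
#' @param duplex Tibble `snp`, `parent` for duplex SNPs.
#' @param double_simplex Character vector of double-simplex SNP ids.
#' @param configs Tibble `snp`, `parent1_dosage`, `parent2_dosage`.
#' @param p_threshold Association significance threshold (default 0.001).
#' @return List: `homologue_links` (tibble `parent`, `group_a`, `group_b`,
#'   `duplex_snp`, `p`), `parent_matches` (tibble `group_p1`, `group_p2`,
#'   `n_pairs`) and `chromosome_groups` (tibble `parent`, `homologue_group`,
#'   `chromosome`).
#' @export
associate_homologues <- function(framework, dosage, duplex, double_simplex,
                                 configs, p_threshold = 0.001) {
  links <- list()
  for (i in seq_len(nrow(duplex))) {
    ds <- duplex$snp[i]
    pa <- duplex$parent[i]
    fw <- framework[framework$parent == pa, ]
    hits <- list()
    for (j in seq_len(nrow(fw))) {
      p <- snp_independence_test(dosage[, ds], dosage[, fw$snp[j]])$p
      if (!is.na(p) && p < p_threshold) {
        hits[[length(hits) + 1]] <- tibble(
          group = fw$homologue_group[j], p = p
        )
      }
    }
    if (length(hits)) {
      hit_groups <- bind_rows(hits) |>
        group_by(.data$group) |>
        summarise(p = min(.data$p), .groups = "drop")
      if (nrow(hit_groups) >= 2) {
        gg <- utils::combn(hit_groups$group, 2)
        for (k in seq_len(ncol(gg))) {
          links[[length(links) + 1]] <- tibble(
            parent = pa, group_a = gg[1, k], group_b = gg[2, k],
            duplex_snp = ds, p = max(hit_groups$p)
          )
        }
      }
    }
  }
  links <- if (length(links)) bind_rows(links) else {
    tibble(
      parent = integer(), group_a = integer(), group_b = integer(),
      duplex_snp = character(), p = numeric()
    )
  }
  # chromosome groups per parent = components of the homologue-link graph
  chrom <- list()
  for (pa in unique(framework$parent)) {
    gids <- sort(unique(framework$homologue_group[framework$parent == pa]))
    e <- links[links$parent == pa, c("group_a", "group_b")]
    comp <- connected_components(
      as.character(gids),
      tibble(a = as.character(e$group_a), b = as.character(e$group_b))
    )
    chrom[[length(chrom) + 1]] <- tibble(
      parent = pa, homologue_group = gids,
      chromosome = as.integer(comp)
    )
  }
  chrom <- bind_rows(chrom)
  # cross-parent matching via simplex + double-simplex coupling pairs
  cfg <- setNames(
    lapply(seq_len(nrow(configs)), function(i) {
      c(configs$parent1_dosage[i], configs$parent2_dosage[i])
    }), configs$snp
  )
  matches <- list()
  for (ss in double_simplex) {
    for (pa in 1:2) {
      fw <- framework[framework$parent == pa, ]
      for (j in seq_len(nrow(fw))) {
        sx <- fw$snp[j]
        p <- snp_independence_test(dosage[, ss], dosage[, sx])$p
        if (is.na(p) || p >= p_threshold) next
        lk <- linkage_pair(dosage[, ss], dosage[, sx], cfg[[ss]], cfg[[sx]])
        # keep only coupling in the informative parent
        lab <- strsplit(lk$phase, "x")[[1]][pa]
        if (!is.na(lab) && lab == "C") {
          matches[[length(matches) + 1]] <- tibble(
            ss_snp = ss, parent = pa,
            group = fw$homologue_group[j], p = p
          )
        }
      }
    }
  }
  parent_matches <- tibble(
    group_p1 = integer(), group_p2 = integer(),
    n_pairs = integer()
  )
  if (length(matches)) {
    m <- bind_rows(matches)
    both <- m |>
      group_by(.data$ss_snp, .data$parent) |>
      summarise(group = .data$group[which.min(.data$p)], .groups = "drop") |>
      tidyr::pivot_wider(names_from = "parent", values_from = "group",
        names_prefix = "p")
    if (all(c("p1", "p2") %in% names(both))) {
      parent_matches <- both |>
        filter(!is.na(.data$p1), !is.na(.data$p2)) |>
        count(group_p1 = .data$p1, group_p2 = .data$p2, name = "n_pairs")
    }
  }
  list(
    homologue_links = links, parent_matches = parent_matches,
    chromosome_groups = chrom
  )
}
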