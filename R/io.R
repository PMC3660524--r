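# Delimited-text formats for every artefact of the pipeline. All files are
# TSV with a header; missing values are accepted as "" or "NA" on read and
# written as "NA".

#' Read a theta matrix
#'
#' Samples in rows, SNPs in columns; first column is the sample id, header
#' row carries the SNP ids.
#'
#' @param path File path (TSV or CSV by extension).
#' @return Numeric matrix with sample-id rownames.
#' @export
read_theta_matrix <- function(path) {
  df <- read_delim_auto(path)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    abort("theta values outside [0, 1]")
  }
  m
}

#' Read / write a dosage matrix
#'
#' Same layout as the theta matrix with integer dosages 0-4.
#'
#' @param path File path.
#' @return Integer matrix with sample-id rownames.
#' @export
read_dosage_matrix <- function(path) {
  df <- read_delim_auto(path)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  if (any(m < 0 | m > 4, na.rm = TRUE)) abort("dosages must be 0..4")
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_dosage_matrix
#' @param x Matrix to write (rownames = sample ids).
#' @export
write_dosage_matrix <- function(x, path) {
  df <- as_tibble(x, rownames = "sample")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname read_theta_matrix
#' @param x Matrix to write.
#' @export
write_theta_matrix <- function(x, path) {
  df <- as_tibble(x, rownames = "sample")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path,
    delim = delim, na = c("", "NA"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Read / write a map file
#'
#' Columns: `snp`, `chrom`, `position_cm`, `status` (`mapped`,
#' `binned:<anchor>`, `duplicate:<representative>` or `unplaced`),
#' `phase_p1`, `phase_p2`, `rf_to_anchor`.
#'
#' @param path File path.
#' @return Tibble in the layout above.
#' @export
read_map_file <- function(path) {
  df <- read_delim_auto(path)
  need <- c(
    "snp", "chrom", "position_cm", "status", "phase_p1", "phase_p2",
    "rf_to_anchor"
  )
  if (!all(need %in% names(df))) {
    abort(paste("map file must have columns:", paste(need, collapse = ", ")))
  }
  df
}

#' @rdname read_map_file
#' @param x Map tibble to write.
#' @export
write_map_file <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read / write a pairwise linkage file
#'
#' Columns as produced by [pairwise_linkage()].
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_pairwise_file <- function(path) read_delim_auto(path)

#' @rdname read_pairwise_file
#' @param x Pairwise tibble.
#' @export
write_pairwise_file <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read a trait file
#'
#' First column offspring id, remaining columns traits.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_trait_file <- function(path) read_delim_auto(path)

#' Parse a phase pattern pair
#'
#' `"AABA AABA"` parses positionally over homologues a-d (parent 1) and
#' e-h (parent 2).
#'
#' @param x Character vector of space-separated pattern pairs.
#' @return Tibble `phase_p1`, `phase_p2`, `b_homologues` (list of homologue
#'   letters carrying B).
#' @export
parse_phase <- function(x) {
  parts <- strsplit(x, " +")
  lets <- c(letters[1:4], letters[5:8])
  out <- lapply(parts, function(p) {
    if (length(p) != 2 || !all(grepl("^[AB]{4}$", p))) {
      abort("phase must be two 4-character A/B patterns")
    }
    b <- lets[c(
      which(strsplit(p[1], "")[[1]] == "B"),
      4 + which(strsplit(p[2], "")[[1]] == "B")
    )]
    tibble(phase_p1 = p[1], phase_p2 = p[2], b_homologues = list(b))
  })
  bind_rows(out)
}

#' Default pipeline configuration
#'
#' All thresholds of the pipeline with their defaults: trimmed range 0.1,
#' trend p 1e-4, distortion p 0.001 (simplex) / 0.01 (higher), cluster cut
#' 0.1, pair filters rf < 0.45 and LOD > 0.05, binning rf < 0.05, phase
#' LOD > 5, near-duplicate Hamming distance 2, emission error lambda 0.001,
#' grid step 1 cM, QTL iteration cap 10, double-reduction residual factor
#' 0.75.
#'
#' @param ... Overrides.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_range = 0.1, trend_p = 1e-4,
    distortion_p = c(simplex = 0.001, higher = 0.01),
    cluster_threshold = 0.1, max_rf = 0.45, min_lod = 0.05,
    bin_rf = 0.05, phase_lod = 5, duplicate_hamming = 2,
    lambda = 0.001, grid_step = 1, qtl_max_iter = 10, dr_factor = 0.75,
    framework_rf = 0.25, seed = 1L, parent_ids = c("P1", "P2")
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full mapping pipeline on a theta matrix
#'
#' Executes the stages in order: pre-processing, dosage calling and
#' configuration selection, segregation filtering, simplex frameworks,
#' clustering into linkage groups (two parent-wise runs merged with the
#' both-parents support rule), pairwise linkage within groups, near-duplicate
#' removal, ordering, binning, phase reconstruction, HMM genotype
#' probabilities, and the theta-as-trait map check with one automated
#' exclusion-and-rerun round. Stage counts are logged via `message()`.
#'
#' @param theta Samples x SNPs theta matrix (or data frame with id column).
#' @param config A [pipeline_config()].
#' @return List with the stage outputs: `preprocess`, `calls`, `groups`,
#'   `pairwise`, `maps` (per group: map tibble with phases, bins,
#'   duplicates), `hmm` (per group), `map_check`, `excluded`, `config`.
#' @export
run_pipeline <- function(theta, config = pipeline_config()) {
  set.seed(config$seed)
  theta <- as_theta_matrix(theta)
  off_ids <- setdiff(rownames(theta), config$parent_ids)
  pp <- preprocess_theta(theta[off_ids, , drop = FALSE],
    min_range = config$min_range, trend_p = config$trend_p
  )
  keep <- pp$snp[pp$pass]
  message("preprocess: ", length(keep), "/", ncol(theta), " SNPs pass")
  cl <- call_dosages(theta[, keep, drop = FALSE], config$parent_ids,
    distortion_p = config$distortion_p
  )
  seg <- cl$report[cl$report$type != "N" & !cl$report$distorted, ]
  message("dosage calling: ", nrow(seg), " segregating undistorted SNPs")
  dosage <- cl$dosage[, seg$snp, drop = FALSE]
  configs <- seg[, c("snp", "parent1_dosage", "parent2_dosage")]
  res <- map_population(dosage, configs, config)
  # theta-as-trait map check with one automated exclusion-and-rerun round
  check <- list()
  excluded <- character(0)
  off_theta <- theta[off_ids, , drop = FALSE]
  for (g in names(res$hmm)) {
    grid <- interpolate_grid(res$hmm[[g]], step = config$grid_step)
    mp <- res$maps[[g]]$map
    mp <- mp[!is.na(mp$phase_p1) & !is.na(mp$phase_p2), ]
    chk <- theta_map_check(off_theta, mp, grid)
    chk$group <- g
    check[[g]] <- chk
    excluded <- c(excluded, chk$snp[chk$exclude])
  }
  check <- bind_rows(check)
  if (length(excluded)) {
    message("map check: re-running without ", length(excluded), " SNPs")
    keep2 <- setdiff(configs$snp, excluded)
    res2 <- map_population(dosage[, keep2, drop = FALSE],
      configs[configs$snp %in% keep2, ], config
    )
    res$maps <- res2$maps
    res$hmm <- res2$hmm
    res$pairwise <- res2$pairwise
    res$groups <- res2$groups
  }
  res$map_check <- check
  res$excluded <- excluded
  res$preprocess <- pp
  res$calls <- cl
  res$config <- config
  res
}

#' Map a called dosage matrix
#'
#' The mapping stages of [run_pipeline()] starting from called dosages:
#' clustering, pairwise linkage, ordering, binning, phasing, HMM and the
#' theta-free parts of the map check.
#'
#' @param dosage Offspring x SNP dosage matrix of segregating SNPs.
#' @param configs Tibble `snp`, `parent1_dosage`, `parent2_dosage`.
#' @param config A [pipeline_config()].
#' @return List with `groups`, `pairwise`, `maps`, `hmm`.
#' @export
map_population <- function(dosage, configs, config = pipeline_config()) {
  simplex1 <- configs$snp[configs$parent1_dosage %in% c(1, 3) &
    configs$parent2_dosage %in% c(0, 4)]
  simplex2 <- configs$snp[configs$parent2_dosage %in% c(1, 3) &
    configs$parent1_dosage %in% c(0, 4)]
  duplex1 <- configs$snp[configs$parent1_dosage == 2 &
    configs$parent2_dosage %in% c(0, 4)]
  duplex2 <- configs$snp[configs$parent2_dosage == 2 &
    configs$parent1_dosage %in% c(0, 4)]
  shared <- configs$snp[configs$parent1_dosage %in% 1:3 &
    configs$parent2_dosage %in% 1:3]
  run1_snps <- c(simplex1, duplex1, shared)
  run2_snps <- c(simplex2, duplex2, shared)
  pm1 <- independence_distance(dosage[, run1_snps, drop = FALSE])
  pm2 <- independence_distance(dosage[, run2_snps, drop = FALSE])
  run1 <- cluster_linkage_groups(pm1, config$cluster_threshold)
  run2 <- cluster_linkage_groups(pm2, config$cluster_threshold)
  groups <- merge_cluster_runs(run1, run2, shared)
  message("clustering: ", length(unique(stats::na.omit(groups$group))),
    " groups; ", sum(!groups$supported), " unsupported higher-dosage SNPs")
  maps <- list()
  hmms <- list()
  pairwise_all <- list()
  for (g in sort(unique(stats::na.omit(groups$group)))) {
    gsnps <- groups$snp[!is.na(groups$group) & groups$group == g]
    if (length(gsnps) < 4) next
    dup <- remove_near_duplicates(dosage[, gsnps, drop = FALSE],
      max_diff = config$duplicate_hamming
    )
    reps <- dup$snp[dup$snp == dup$representative]
    pw <- pairwise_linkage(dosage[, reps, drop = FALSE],
      configs[configs$snp %in% reps, ],
      min_n = min(50, nrow(dosage))
    )
    pairwise_all[[as.character(g)]] <- pw
    # frameworks from the group's simplex SNPs, per parent
    fw <- list()
    for (pa in 1:2) {
      sx <- intersect(reps, if (pa == 1) simplex1 else simplex2)
      if (length(sx) < 2) next
      pws <- pw[pw$snp1 %in% sx & pw$snp2 %in% sx, ]
      fr <- build_simplex_framework(pws, sx, max_rf = config$framework_rf)
      fw[[pa]] <- tibble(
        snp = fr$snp, parent = pa,
        homologue = fr$homologue_group
      )
    }
    framework <- bind_rows(fw)
    # exclude XSS and isolated simplex SNPs from ordering; keep at most the
    # four largest framework groups per parent as candidate homologues
    xss <- configs$snp[configs$parent1_dosage %in% c(1, 3) &
      configs$parent2_dosage %in% c(1, 3) &
      configs$parent1_dosage != configs$parent2_dosage]
    iso <- character(0)
    if (nrow(framework)) {
      sizes <- framework |> count(.data$parent, .data$homologue)
      iso <- framework$snp[paste(framework$parent, framework$homologue) %in%
        paste(sizes$parent, sizes$homologue)[sizes$n == 1]]
      keep_h <- sizes |>
        group_by(.data$parent) |>
        dplyr::slice_max(.data$n, n = 4, with_ties = FALSE) |>
        ungroup()
      framework <- framework |>
        filter(paste(.data$parent, .data$homologue) %in%
          paste(keep_h$parent, keep_h$homologue)) |>
        group_by(.data$parent) |>
        mutate(homologue = match(
          .data$homologue,
          sort(unique(.data$homologue))
        )) |>
        ungroup()
    }
    order_snps <- setdiff(reps, c(xss, iso))
    om <- tryCatch(
      order_and_space(pw, order_snps,
        max_rf = config$max_rf,
        min_lod = config$min_lod
      ),
      error = function(e) NULL
    )
    if (is.null(om)) next
    unplaced <- setdiff(reps, om$map$snp)
    bins <- bin_unplaced(unplaced, om$map, pw, max_rf = config$bin_rf)
    phase_targets <- c(om$map$snp, bins$snp[!is.na(bins$anchor)])
    phases <- reconstruct_phase(phase_targets, framework, dosage,
      configs,
      min_lod = config$phase_lod
    )
    mapg <- om$map
    mapg$chrom <- g
    mapg <- left_join(mapg, phases, by = "snp")
    maps[[as.character(g)]] <- list(
      map = mapg, bins = bins, duplicates = dup[dup$snp != dup$representative, ],
      dropped = om$dropped, framework = framework
    )
    phased <- mapg[!is.na(mapg$phase_p1) & !is.na(mapg$phase_p2), ]
    if (nrow(phased) >= 2) {
      hmms[[as.character(g)]] <- hmm_genotype_probs(
        dosage[, phased$snp, drop = FALSE],
        phased[, c("snp", "position_cm", "phase_p1", "phase_p2")],
        lambda = config$lambda
      )
    }
    message(
      "group ", g, ": ", nrow(mapg), " mapped, ",
      sum(!is.na(bins$anchor)), " binned, ",
      nrow(dup) - length(reps), " duplicates"
    )
  }
  list(
    groups = groups, pairwise = bind_rows(pairwise_all, .id = "group"),
    maps = maps, hmm = hmms
  )
}
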