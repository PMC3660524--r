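# Dosage calling from theta scores (allele-intensity ratios in [0,1]) by
# normal mixture models. The mixture proportions are fixed at the expected
# offspring dosage probabilities of each candidate configuration; only the
# class means (one per dosage class, allowing uneven spacing) and a common
# variance are estimated, by EM. Configurations are compared by BIC on the
# full likelihood (offspring plus parents).

#' Pre-process a theta matrix
#'
#' Screens each SNP on three criteria: trimmed range (2%-98% quantile span)
#' at least `min_range`; no strong trend of theta on sample order (an F-test
#' of a 4-df regression-spline smooth against a constant model, failing at
#' `p < trend_p`); and no missing values.
#'
#' @param theta Numeric matrix, samples x SNPs (column names = SNP ids), or a
#'   data frame whose first column is a sample id.
#' @param sample_order Integer order of the samples on the plates (defaults to
#'   row order).
#' @param min_range Trimmed-range threshold (default 0.1).
#' @param trend_p Trend significance threshold (default 1e-4).
#' @param trend_df Effective degrees of freedom of the smooth (default 4).
#' @return A tibble per SNP: `snp`, `trimmed_range`, `trend_p`, `n_missing`,
#'   `pass`, `reason`.
#' @export
preprocess_theta <- function(theta, sample_order = NULL, min_range = 0.1,
                             trend_p = 1e-4, trend_df = 4) {
  theta <- as_theta_matrix(theta)
  n <- nrow(theta)
  if (n < 20) abort("need at least 20 samples for pre-processing")
  if (is.null(sample_order)) sample_order <- seq_len(n)
  out <- lapply(colnames(theta), function(s) {
    y <- theta[, s]
    miss <- sum(is.na(y))
    yy <- y[!is.na(y)]
    rng <- if (length(yy) >= 2) {
      diff(quantile(yy, c(0.02, 0.98), names = FALSE))
    } else {
      0
    }
    pv <- NA_real_
    if (length(yy) >= trend_df + 2 && var(yy) > 0) {
      ord <- sample_order[!is.na(y)]
      fit <- lm(yy ~ splines::ns(ord, df = trend_df))
      an <- stats::anova(fit)
      pv <- an[["Pr(>F)"]][1]
    }
    reason <- character(0)
    if (rng < min_range) reason <- c(reason, "range")
    if (!is.na(pv) && pv < trend_p) reason <- c(reason, "trend")
    if (miss > 0) reason <- c(reason, "missing")
    tibble(
      snp = s, trimmed_range = rng, trend_p = pv,
      n_missing = as.integer(miss), pass = length(reason) == 0,
      reason = paste(reason, collapse = ",")
    )
  })
  bind_rows(out)
}

as_theta_matrix <- function(theta) {
  if (is.data.frame(theta)) {
    ids <- theta[[1]]
    theta <- as.matrix(theta[, -1, drop = FALSE])
    rownames(theta) <- as.character(ids)
  }
  storage.mode(theta) <- "double"
  if (any(theta < 0 | theta > 1, na.rm = TRUE)) {
    theta <- pmin(pmax(theta, 0), 1)
  }
  theta
}

#' Fit a fixed-weight normal mixture for one configuration
#'
#' Runs the five-step algorithm: k-means seeded at the expected theta anchors
#' `g/4` of the admissible dosage classes; then EM with fixed mixture weights
#' `p_C(g)` - the E-step computes posteriors `w(g|y) ~ p_C(g) N(y; mu_g,
#' sigma^2)` and the M-step re-estimates one mean per class (dosage treated as
#' categorical) and a pooled variance - iterated to log-likelihood
#' convergence. Offspring are called by maximum posterior.
#'
#' @param y Numeric vector of offspring theta scores (no missing values).
#' @param config A parental dosage pair `c(p1, p2)` or a one-row tibble from
#'   [classify_configuration()].
#' @param theta_parents Optional length-2 numeric of parental theta scores;
#'   when given, the full likelihood and BIC include the parent densities at
#'   their configuration dosage classes.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter EM iteration cap (default 200).
#' @return An object of class `tetra_mixture`: list with `config` (tibble
#'   row), `classes` (admissible dosages), `means` (full length-5 vector;
#'   classes absent from the offspring keep their `g/4` anchors), `sigma`,
#'   `loglik`, `bic`, `n_param`, `posteriors` (n x classes), `calls`,
#'   `max_posterior`, `converged`.
#' @export
fit_dosage_mixture <- function(y, config, theta_parents = NULL, tol = 1e-6,
                               max_iter = 200) {
  if (is.numeric(config)) config <- classify_configuration(config[1], config[2])
  if (any(is.na(y))) abort("offspring theta must be non-missing")
  probs <- config$offspring_probs[[1]]
  classes <- which(probs > 0) - 1L
  w_fix <- probs[classes + 1]
  k <- length(classes)
  anchors <- classes / 4
  mu <- anchors
  sig2 <- NULL
  if (k > 1) {
    km <- tryCatch(
      kmeans(y, centers = matrix(anchors, ncol = 1)),
      error = function(e) NULL
    )
    if (!is.null(km) && all(km$size > 0)) {
      mu <- sort(as.vector(km$centers))
      sig2 <- max(km$tot.withinss / length(y), 1e-8)
    }
  }
  if (is.null(sig2)) sig2 <- max(var(y) / max(k^2, 1), 1e-8)
  if (k == 1) {
    mu <- mean(y)
    sig2 <- max(mean((y - mu)^2), 1e-8)
  }
  n <- length(y)
  loglik_off <- function(mu, sig2) {
    dens <- vapply(seq_len(k), function(j) {
      w_fix[j] * dnorm(y, mu[j], sqrt(sig2))
    }, numeric(n))
    if (k == 1) dens <- matrix(dens, ncol = 1)
    list(ll = sum(log(pmax(rowSums(dens), 1e-300))), dens = dens)
  }
  cur <- loglik_off(mu, sig2)
  ll <- cur$ll
  converged <- (k == 1)
  if (k > 1) {
    for (it in seq_len(max_iter)) {
      w <- cur$dens / pmax(rowSums(cur$dens), 1e-300)
      cs <- colSums(w)
      mu_new <- ifelse(cs > 0, colSums(w * y) / cs, mu)
      # enforce monotone means by sorting (classes keep their fixed weights)
      mu_new <- sort(mu_new)
      sig2_new <- max(
        sum(w * (matrix(y, n, k) -
          matrix(mu_new, n, k, byrow = TRUE))^2) / n,
        1e-10
      )
      nxt <- loglik_off(mu_new, sig2_new)
      if (nxt$ll >= ll - 1e-12) {
        mu <- mu_new
        sig2 <- sig2_new
        if (abs(nxt$ll - ll) < tol) {
          ll <- nxt$ll
          cur <- nxt
          converged <- TRUE
          break
        }
        ll <- nxt$ll
        cur <- nxt
      } else {
        break # keep the best iterate
      }
    }
  }
  post <- cur$dens / pmax(rowSums(cur$dens), 1e-300)
  calls <- classes[max.col(post, ties.method = "first")]
  means_full <- (0:4) / 4
  means_full[classes + 1] <- mu
  ll_full <- ll
  n_obs <- n
  if (!is.null(theta_parents)) {
    pd <- c(config$parent1_dosage, config$parent2_dosage)
    for (i in 1:2) {
      if (!is.na(theta_parents[i])) {
        ll_full <- ll_full +
          dnorm(theta_parents[i], means_full[pd[i] + 1], sqrt(sig2),
            log = TRUE
          )
        n_obs <- n_obs + 1
      }
    }
  }
  p_par <- k + 1
  structure(
    list(
      config = config, classes = classes, means = means_full,
      sigma = sqrt(sig2), loglik = ll_full, loglik_offspring = ll,
      bic = -2 * ll_full + p_par * log(n_obs), n_param = p_par,
      posteriors = post, calls = calls,
      max_posterior = post[cbind(seq_len(n), max.col(post,
        ties.method = "first"
      ))],
      converged = converged
    ),
    class = "tetra_mixture"
  )
}

#' @export
print.tetra_mixture <- function(x, ...) {
  cat(
    "Normal mixture fit:", x$config$label, "|", length(x$classes),
    "classes | BIC", round(x$bic, 1), "\n"
  )
  cat(
    "means:", paste(round(x$means[x$classes + 1], 3), collapse = " "),
    "| sigma:", signif(x$sigma, 3), "\n"
  )
  invisible(x)
}

#' @method tidy tetra_mixture
#' @export
tidy.tetra_mixture <- function(x, ...) {
  tibble(
    dosage = x$classes,
    mean = x$means[x$classes + 1],
    weight = x$config$offspring_probs[[1]][x$classes + 1],
    n_called = vapply(x$classes, function(g) sum(x$calls == g), integer(1))
  )
}

#' @method glance tetra_mixture
#' @export
glance.tetra_mixture <- function(x, ...) {
  tibble(
    type = x$config$type, label = x$config$label,
    parent1_dosage = x$config$parent1_dosage,
    parent2_dosage = x$config$parent2_dosage,
    n_classes = length(x$classes), sigma = x$sigma, loglik = x$loglik,
    bic = x$bic, mean_posterior = mean(x$max_posterior),
    converged = x$converged
  )
}

#' Select the best configuration for a SNP by minimum BIC
#'
#' Fits the fixed-weight mixture for every ordered parental dosage pair
#' (including the non-segregating single-class configurations) and returns the
#' minimum-BIC fit; ties are broken toward fewer classes. When a selected fit
#' with three or more classes is segregation-distorted, a two-class
#' alternative within `recode_delta_bic` of its BIC that is not distorted is
#' preferred (an automated stand-in for a graphical re-check of such SNPs).
#'
#' @param y Offspring theta scores.
#' @param theta_parents Length-2 parental theta scores (NA allowed).
#' @param recode_delta_bic BIC window for the simplex recoding rule
#'   (default 10).
#' @param distortion_p Thresholds used by the recoding rule; see
#'   [segregation_test()].
#' @return List with `best` (a `tetra_mixture`), `ranking` (tibble of all
#'   fits, ascending BIC) and `recoded` (logical).
#' @export
select_dosage_configuration <- function(y, theta_parents = c(NA, NA),
                                        recode_delta_bic = 10,
                                        distortion_p = c(
                                          simplex = 0.001,
                                          higher = 0.01
                                        )) {
  fits <- list()
  for (d1 in 0:4) {
    for (d2 in 0:4) {
      f <- fit_dosage_mixture(y, c(d1, d2), theta_parents = theta_parents)
      fits[[paste(d1, d2)]] <- f
    }
  }
  ranking <- bind_rows(lapply(fits, glance))
  ord <- order(ranking$bic, ranking$n_classes)
  ranking <- ranking[ord, ]
  fits <- fits[ord]
  best <- fits[[1]]
  recoded <- FALSE
  if (length(best$classes) >= 3) {
    st <- segregation_test(best)
    thr <- if (length(best$classes) == 2) {
      distortion_p[["simplex"]]
    } else {
      distortion_p[["higher"]]
    }
    if (!is.na(st$p) && st$p < thr) {
      for (j in seq_along(fits)[-1]) {
        if (ranking$bic[j] - ranking$bic[1] > recode_delta_bic) break
        if (ranking$n_classes[j] == 2) {
          st2 <- segregation_test(fits[[j]])
          if (!is.na(st2$p) && st2$p >= distortion_p[["simplex"]]) {
            best <- fits[[j]]
            recoded <- TRUE
            break
          }
        }
      }
    }
  }
  list(best = best, ranking = ranking, recoded = recoded)
}

#' Chi-square goodness-of-fit test of segregation
#'
#' Compares observed dosage class counts with the expected proportions of the
#' configuration. Classes with expected count below 1 are merged into their
#' nearest neighbour and the degrees of freedom reduced accordingly.
#'
#' @param calls Either a `tetra_mixture` fit, or an integer vector of observed
#'   counts per admissible class (in which case `config` is required).
#' @param config Parental dosage pair `c(p1, p2)` when `calls` is a count
#'   vector.
#' @return One-row tibble: `statistic`, `df`, `p`, `merged`.
#' @export
segregation_test <- function(calls, config = NULL) {
  if (inherits(calls, "tetra_mixture")) {
    fit <- calls
    classes <- fit$classes
    probs <- fit$config$offspring_probs[[1]][classes + 1]
    counts <- vapply(classes, function(g) sum(fit$calls == g), numeric(1))
  } else {
    cfg <- classify_configuration(config[1], config[2])
    probs <- cfg$offspring_probs[[1]]
    classes <- which(probs > 0) - 1L
    probs <- probs[classes + 1]
    counts <- as.numeric(calls)
    if (length(counts) != length(classes)) {
      abort("`calls` must have one count per admissible class")
    }
  }
  if (length(classes) < 2) {
    return(tibble(statistic = NA_real_, df = NA_integer_, p = NA_real_,
      merged = FALSE))
  }
  n <- sum(counts)
  exp_cnt <- n * probs
  merged <- FALSE
  while (length(counts) > 2 && any(exp_cnt < 1)) {
    i <- which.min(exp_cnt)
    j <- if (i == 1) 2 else if (i == length(counts)) i - 1 else {
      if (exp_cnt[i - 1] < exp_cnt[i + 1]) i - 1 else i + 1
    }
    counts[j] <- counts[j] + counts[i]
    exp_cnt[j] <- exp_cnt[j] + exp_cnt[i]
    counts <- counts[-i]
    exp_cnt <- exp_cnt[-i]
    merged <- TRUE
  }
  stat <- sum((counts - exp_cnt)^2 / exp_cnt)
  df <- length(counts) - 1L
  tibble(
    statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
    merged = merged
  )
}

#' Call dosages for a theta matrix
#'
#' Runs configuration selection per SNP and assembles the dosage-call matrix
#' plus a per-SNP report (selected type, BIC, segregation test, distortion
#' flag at the simplex/higher thresholds, mean posterior).
#'
#' @param theta Samples x SNPs theta matrix (or data frame with id column).
#' @param parent_ids Character vector of the two parent sample ids (rows of
#'   `theta`).
#' @param distortion_p Named thresholds `c(simplex = 0.001, higher = 0.01)`.
#' @return List with `dosage` (offspring x SNP integer matrix), `report`
#'   (tibble per SNP) and `fits` (list of `tetra_mixture`).
#' @export
call_dosages <- function(theta, parent_ids,
                         distortion_p = c(simplex = 0.001, higher = 0.01)) {
  theta <- as_theta_matrix(theta)
  if (!all(parent_ids %in% rownames(theta))) {
    abort("parent ids not found among theta rows")
  }
  off <- theta[!rownames(theta) %in% parent_ids, , drop = FALSE]
  par <- theta[parent_ids, , drop = FALSE]
  fits <- list()
  report <- list()
  dosage <- matrix(NA_integer_, nrow(off), ncol(off),
    dimnames = dimnames(off)
  )
  for (s in colnames(theta)) {
    sel <- select_dosage_configuration(off[, s],
      theta_parents = par[, s],
      distortion_p = distortion_p
    )
    fit <- sel$best
    fits[[s]] <- fit
    dosage[, s] <- fit$calls
    st <- segregation_test(fit)
    thr <- if (length(fit$classes) == 2) {
      distortion_p[["simplex"]]
    } else {
      distortion_p[["higher"]]
    }
    report[[s]] <- tibble(
      snp = s, type = fit$config$type, label = fit$config$label,
      parent1_dosage = fit$config$parent1_dosage,
      parent2_dosage = fit$config$parent2_dosage,
      n_classes = length(fit$classes), bic = fit$bic, sigma = fit$sigma,
      seg_p = st$p, distorted = !is.na(st$p) && st$p < thr,
      recoded = sel$recoded, mean_posterior = mean(fit$max_posterior)
    )
  }
  list(dosage = dosage, report = bind_rows(report), fits = fits)
}

#' Screen simplex/triplex SNPs for double-reduction products
#'
#' For each two-class SNP, regresses the theta scores on the called dosage
#' class to estimate the inter-class gap `d`, and flags individuals whose
#' residual exceeds `factor * d` (default 0.75). Double reduction is confirmed
#' for an individual only when it is flagged at two or more SNPs in coupling
#' on the same homologue at separate map positions.
#'
#' @param theta Offspring x SNP theta matrix.
#' @param calls Offspring x SNP dosage-call matrix.
#' @param snps Character vector of two-class (simplex/triplex) SNP ids to
#'   screen.
#' @param map_context Optional tibble `snp`, `homologue`, `position_cm` used
#'   for the confirmation rule.
#' @param factor Residual threshold as a multiple of the class gap.
#' @return List with `flags` (tibble `snp`, `individual`, `residual`, `gap`)
#'   and `confirmed` (tibble `individual`, `homologue`, `n_snps`; empty
#'   without map context).
#' @export
detect_double_reduction <- function(theta, calls, snps = colnames(theta),
                                    map_context = NULL, factor = 0.75) {
  flags <- list()
  for (s in snps) {
    y <- theta[, s]
    g <- calls[, s]
    ok <- !is.na(y) & !is.na(g)
    lev <- sort(unique(g[ok]))
    if (length(lev) != 2) next
    m <- tapply(y[ok], g[ok], mean)
    d <- abs(diff(m))
    resid <- y - m[as.character(g)]
    hit <- which(ok & abs(resid) > factor * d)
    if (length(hit)) {
      flags[[s]] <- tibble(
        snp = s, individual = if (!is.null(rownames(theta))) {
          rownames(theta)[hit]
        } else {
          as.character(hit)
        },
        residual = resid[hit], gap = d
      )
    }
  }
  flags <- if (length(flags)) bind_rows(flags) else {
    tibble(
      snp = character(), individual = character(),
      residual = numeric(), gap = numeric()
    )
  }
  confirmed <- tibble(
    individual = character(), homologue = character(),
    n_snps = integer()
  )
  if (!is.null(map_context) && nrow(flags)) {
    fl <- left_join(flags, map_context, by = "snp")
    fl <- fl[!is.na(fl$homologue), ]
    if (nrow(fl)) {
      confirmed <- fl |>
        group_by(.data$individual, .data$homologue) |>
        summarise(
          n_snps = dplyr::n_distinct(.data$snp),
          n_pos = dplyr::n_distinct(.data$position_cm),
          .groups = "drop"
        ) |>
        filter(.data$n_snps >= 2, .data$n_pos >= 2) |>
        select("individual", "homologue", "n_snps")
    }
  }
  list(flags = flags, confirmed = confirmed)
}

#' Plot a mixture fit over the theta scores
#'
#' @param object A `tetra_mixture`.
#' @param y Theta scores the fit was made on.
#' @param ... Unused.
#' @return A ggplot: theta against sample index, coloured by called dosage,
#'   with class means as horizontal lines.
#' @method autoplot tetra_mixture
#' @export
autoplot.tetra_mixture <- function(object, y, ...) {
  df <- tibble(
    index = seq_along(y), theta = y,
    dosage = factor(object$calls, levels = 0:4)
  )
  mu <- tibble(
    mean = object$means[object$classes + 1],
    dosage = factor(object$classes, levels = 0:4)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$theta,
    colour = .data$dosage
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(
      data = mu,
      ggplot2::aes(yintercept = .data$mean, colour = .data$dosage),
      linetype = 2
    ) +
    ggplot2::labs(x = "sample order", y = "theta") +
    ggplot2::ylim(0, 1)
}
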