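# Measurement-error validation: group-wise pairwise distance
# distributions, Kruskal-Wallis rank test, homogeneity of multivariate
# dispersions with permutation inference, and Tukey comparisons.

# coerce gpa_result / morphospace / matrix input to an n x q numeric
# matrix of tangent/score coordinates with specimen ids as rownames
.as_coord_matrix <- function(x) {
  if (inherits(x, "gpa_result")) return(.flatten_aligned(x))
  if (inherits(x, "morphospace")) return(x$scores)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  x
}

.match_groups <- function(coords, groups) {
  if (!is.null(names(groups))) {
    idx <- match(rownames(coords), names(groups))
    if (anyNA(idx))
      stop(sprintf("no group for specimen(s): %s",
                   paste(rownames(coords)[is.na(idx)], collapse = ", ")))
    groups <- groups[idx]
  } else if (length(groups) != nrow(coords)) {
    stop("groups must be named by specimen id or match the number of rows")
  }
  factor(as.character(groups))
}

#' Within-group pairwise distances
#'
#' For each group, all `choose(n_g, 2)` pairwise Euclidean distances in
#' the tangent/score space — the raw material of the measurement-error
#' comparison (within-observer vs among-observer vs among-genus spread).
#'
#' @param x a `gpa_result`, `morphospace`, or numeric matrix (rows =
#'   specimens).
#' @param groups group labels, named by specimen id or positional.
#' @return list with `distances` (named list of numeric vectors) and
#'   `means` (named numeric vector of group means).
#' @export
groupwise_pairwise_distances <- function(x, groups) {
  coords <- .as_coord_matrix(x)
  g <- .match_groups(coords, groups)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop(sprintf("singleton group(s): %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  dists <- lapply(levels(g), function(lv) {
    as.vector(stats::dist(coords[g == lv, , drop = FALSE]))
  })
  names(dists) <- levels(g)
  list(distances = dists,
       means = vapply(dists, mean, numeric(1)))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based one-way comparison of `>= 2` samples with the standard tie
#' correction; the statistic is referred to the chi-squared upper tail
#' with `k - 1` degrees of freedom.
#'
#' @param samples list of `>= 2` numeric vectors (each non-empty,
#'   total `N >= 3`).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of at least 2 samples")
  sizes <- lengths(samples)
  if (any(sizes == 0L)) stop("empty sample group")
  x <- unlist(samples, use.names = FALSE)
  N <- length(x)
  if (N < 3L) stop("need at least 3 observations in total")
  g <- rep(seq_along(samples), sizes)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C > 0) H / C else 0  # all values tied: no evidence, H = 0
  H <- max(H, 0)
  df <- length(samples) - 1L
  list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Homogeneity of multivariate dispersions
#'
#' PERMDISP-style test: the distance of each specimen to its own group
#' centroid (mean) in the tangent/score space is computed, a one-way
#' ANOVA F statistic on these distances gives the parametric p value,
#' and a permutation p value is obtained by shuffling group labels
#' `n_perm` times (seeded; add-one correction).  Tukey honest significant
#' difference intervals on the same distances identify which group pairs
#' differ (family-wise coverage 95%).
#'
#' @param x a `gpa_result`, `morphospace`, or numeric matrix.
#' @param groups group labels (named by specimen id or positional);
#'   every group needs `>= 2` members.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed for the permutations (mandatory when
#'   `n_perm > 0`).
#' @return a `dispersion_test` result: list with `group_dispersions`,
#'   `distances_to_centroid`, `F`, `df_between`, `df_within`,
#'   `p_parametric`, `p_permutation`, `n_perm`, `tukey` (data frame
#'   `pair`, `difference`, `lower`, `upper`, `p_adjusted`).
#' @export
dispersion_test <- function(x, groups, n_perm = 9999L, seed = NULL) {
  coords <- .as_coord_matrix(x)
  g <- .match_groups(coords, groups)
  sizes <- table(g)
  if (length(levels(g)) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop(sprintf("group(s) with < 2 members: %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  if (n_perm > 0L && is.null(seed))
    stop("a seed is required for the permutation test")

  dists <- numeric(nrow(coords))
  for (lv in levels(g)) {
    sel <- g == lv
    ctr <- colMeans(coords[sel, , drop = FALSE])
    dists[sel] <- sqrt(rowSums(sweep(coords[sel, , drop = FALSE], 2L, ctr)^2))
  }

  f_stat <- function(d, gg) {
    m <- tapply(d, gg, mean)
    nn <- tabulate(gg)
    grand <- mean(d)
    ssb <- sum(nn * (m - grand)^2)
    ssw <- sum((d - m[as.integer(gg)])^2)
    dfb <- nlevels(gg) - 1L
    dfw <- length(d) - nlevels(gg)
    (ssb / dfb) / (ssw / dfw)
  }
  Fobs <- f_stat(dists, g)
  dfb <- nlevels(g) - 1L
  dfw <- length(dists) - nlevels(g)
  p_param <- stats::pf(Fobs, dfb, dfw, lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0L) {
    set.seed(as.integer(seed))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Fb <- f_stat(dists, g[sample.int(length(g))])
      if (Fb >= Fobs - 1e-12) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (n_perm + 1)
  }

  fit <- stats::aov(dists ~ g, data = data.frame(dists = dists, g = g))
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  tukey <- data.frame(
    pair = rownames(tk),
    difference = tk[, "diff"],
    lower = tk[, "lwr"],
    upper = tk[, "upr"],
    p_adjusted = tk[, "p adj"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  out <- list(
    group_dispersions = tapply(dists, g, mean),
    distances_to_centroid = stats::setNames(dists, rownames(coords)),
    F = Fobs,
    df_between = dfb,
    df_within = dfw,
    p_parametric = p_param,
    p_permutation = p_perm,
    n_perm = n_perm,
    tukey = tukey
  )
  class(out) <- "dispersion_test"
  out
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Homogeneity of multivariate dispersions: F = %.3f (df = %d, %d)\n",
              x$F, x$df_between, x$df_within))
  cat(sprintf("  parametric p = %.4g; permutation p = %.4g (%d permutations)\n",
              x$p_parametric, x$p_permutation, x$n_perm))
  cat("  group dispersions:\n")
  print(round(x$group_dispersions, 4))
  cat("  Tukey comparisons:\n")
  print(x$tukey, digits = 3)
  invisible(x)
}

#' Measurement-error report
#'
#' Runs the full error-validation workflow on replicate digitisations:
#' all configurations (within-observer replicate sets, the among-observer
#' set, and the across-taxon reference set) are assembled and jointly
#' superimposed, then within-group pairwise tangent distances, their
#' ratios to the reference (among-genus) group, a Kruskal-Wallis test on
#' the distance distributions, and the dispersion homogeneity test with
#' Tukey contrasts are reported.  When `landmark_only = TRUE` the whole
#' analysis is repeated on the fixed landmarks alone (curves excluded),
#' exposing the inflation caused by misplacing a curve-endpoint landmark.
#'
#' @param within_groups named list of lists of [landmark_config()]:
#'   each element one observer's replicate digitisations.
#' @param among_group list of configurations, one per observer.
#' @param reference_group list of configurations across taxa (the
#'   among-genus yardstick).
#' @param template,k_per_curve passed to [fix_shapes()].
#' @param n_perm,seed passed to [dispersion_test()].
#' @param landmark_only also report the landmark-only comparison.
#' @return an `error_report`: list with `group_means`, `ratios` (group
#'   mean / reference mean), `kruskal`, `dispersion`, and optionally
#'   `landmark_only` (list `group_means`, `ratios`).
#' @export
error_report <- function(within_groups, among_group, reference_group,
                         template = NULL, k_per_curve = c(12L, 20L, 20L, 20L),
                         n_perm = 999L, seed = 1L, landmark_only = FALSE) {
  if (is.null(names(within_groups)))
    names(within_groups) <- paste0("within_obs_", seq_along(within_groups))
  sets <- c(within_groups, list(among_obs = among_group,
                                among_genus = reference_group))
  configs <- list()
  labels <- character(0)
  for (grp in names(sets)) {
    for (cfg in sets[[grp]]) {
      cfg$specimen_id <- sprintf("%s.%s.%d", grp, cfg$specimen_id,
                                 length(configs) + 1L)
      configs[[length(configs) + 1L]] <- cfg
      labels <- c(labels, grp)
    }
  }
  structs <- unique(vapply(configs, `[[`, "", "structure"))
  if (length(structs) != 1L) stop("all groups must share one structure")
  if (is.null(template)) template <- structure_template(structs)

  arr <- fix_shapes(configs, template, k_per_curve)
  if (nrow(arr$exclusions))
    stop(sprintf("non-conforming configurations in error experiment: %s",
                 paste(arr$exclusions$specimen_id, collapse = ", ")))
  names(labels) <- arr$specimen_ids
  fit <- gpa(arr)
  gw <- groupwise_pairwise_distances(fit, labels)
  disp <- dispersion_test(fit, labels, n_perm = n_perm, seed = seed)
  kw <- kruskal_wallis(gw$distances)
  ref_mean <- gw$means[["among_genus"]]
  out <- list(
    group_means = gw$means,
    ratios = gw$means / ref_mean,
    kruskal = kw,
    dispersion = disp
  )

  if (landmark_only) {
    lm_idx <- which(arr$point_roles$role == "fixed")
    fit_lm <- gpa(arr$coords[lm_idx, , , drop = FALSE])
    gw_lm <- groupwise_pairwise_distances(
      fit_lm, stats::setNames(labels, fit_lm$specimen_ids))
    out$landmark_only <- list(
      group_means = gw_lm$means,
      ratios = gw_lm$means / gw_lm$means[["among_genus"]]
    )
  }
  class(out) <- "error_report"
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat("Measurement-error report\n")
  cat("  mean within-group pairwise distances:\n")
  print(round(x$group_means, 4))
  cat("  ratio to among-genus variation:\n")
  print(round(x$ratios, 3))
  cat(sprintf("  Kruskal-Wallis: chi-sq = %.2f, df = %d, p = %.3g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p))
  cat(sprintf("  dispersion test: F = %.3f, permutation p = %.3g\n",
              x$dispersion$F, x$dispersion$p_permutation))
  if (!is.null(x$landmark_only)) {
    cat("  landmark-only means:\n")
    print(round(x$landmark_only$group_means, 4))
  }
  invisible(x)
}
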