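# Arc-length resampling of semilandmark curves and assembly of conforming
# specimens into the standard p x 2 x n landmark array.

#' Resample a polyline to equally spaced points by arc length
#'
#' Places `k` points on the piecewise-linear interpolant of `polyline` at
#' arc-length positions `j * L / (k - 1)`, `j = 0, ..., k - 1`, where `L`
#' is the total length.  The first and last output points equal the input
#' endpoints exactly.  Piecewise-linear (rather than spline) interpolation
#' is used deliberately: it is deterministic and cannot overshoot sparsely
#' digitised curves.
#'
#' @param polyline numeric `m x 2` matrix, `m >= 2`, finite.
#' @param k number of output points (`>= 3`).
#' @return numeric `k x 2` matrix.
#' @export
#' @examples
#' resample_curve(rbind(c(0, 0), c(4, 0)), 5)
resample_curve <- function(polyline, k) {
  polyline <- as.matrix(polyline)
  k <- as.integer(k)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L || any(!is.finite(polyline)))
    stop("polyline must be a finite m x 2 matrix with m >= 2")
  if (k < 3L) stop("k must be >= 3")
  seg <- sqrt(rowSums((polyline[-1L, , drop = FALSE] -
                       polyline[-nrow(polyline), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate curve: all points identical")
  cum <- c(0, cumsum(seg))
  # drop zero-length duplicate vertices so approx() sees strictly increasing t
  keep <- c(TRUE, diff(cum) > 0)
  cum <- cum[keep]
  pl <- polyline[keep, , drop = FALSE]
  t_out <- seq(0, L, length.out = k)
  out <- cbind(
    stats::approx(cum, pl[, 1L], xout = t_out, ties = "ordered")$y,
    stats::approx(cum, pl[, 2L], xout = t_out, ties = "ordered")$y
  )
  out[1L, ] <- polyline[1L, ]
  out[k, ] <- polyline[nrow(polyline), ]
  out
}

#' Assemble validated configurations into a shape array
#'
#' The second phase of the data-fixing step: every configuration is checked
#' against the template, semilandmark curves are resampled to the requested
#' counts, and the survivors are stacked into a `p x 2 x n` array.
#'
#' Two policies handle non-conforming input:
#' \describe{
#'   \item{`drop_specimen` (default)}{specimens with missing required
#'     landmarks or wrong landmark/curve counts are excluded and listed
#'     in the exclusion report.}
#'   \item{`drop_trait`}{landmarks missing in \emph{any} specimen are
#'     removed from \emph{all} specimens, together with every curve bound
#'     to a removed landmark, before assembly (the recommended treatment
#'     for traits absent in some taxa, e.g. eyes of blind ones).}
#' }
#'
#' Because each curve starts and ends exactly at a template-bound fixed
#' landmark, a curve resampled to `k` points contributes only its `k - 2`
#' interior points to the array (endpoint deduplication); with the default
#' cephalic counts `c(12, 20, 20, 20)` this gives
#' `16 + 10 + 18 + 18 + 18 = 80` points per specimen.
#'
#' @param configs list of [landmark_config()] of one structure.
#' @param template a [structure_template()]; default built-in.
#' @param k_per_curve integer vector, one `k >= 3` per template curve.
#' @param policy `"drop_specimen"` or `"drop_trait"`.
#' @param require_scale treat a missing scale as an exclusion reason
#'   (default `FALSE`: superimposition removes size anyway).
#' @return a `shape_array`: list with `coords` (`p x 2 x n`),
#'   `specimen_ids`, `point_roles` (data frame `role`, `landmark`,
#'   `curve`, `within`), `k_per_curve`, `structure` and `exclusions`
#'   (data frame `specimen_id`, `reason`).
#' @export
fix_shapes <- function(configs, template = NULL,
                       k_per_curve = c(12L, 20L, 20L, 20L),
                       policy = c("drop_specimen", "drop_trait"),
                       require_scale = FALSE) {
  policy <- match.arg(policy)
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  if (!length(configs)) stop("no configurations supplied")
  structs <- unique(vapply(configs, `[[`, "", "structure"))
  if (length(structs) != 1L)
    stop(sprintf("inconsistent structures in input: %s",
                 paste(structs, collapse = ", ")))
  if (is.null(template)) template <- structure_template(structs)
  n_cv <- nrow(template$curve_defs)
  k_per_curve <- as.integer(k_per_curve)
  if (length(k_per_curve) != n_cv)
    stop(sprintf("k_per_curve must have %d entries", n_cv))
  if (any(k_per_curve < 3L)) stop("every k must be >= 3")

  p_lm <- nrow(template$landmark_defs)
  exclusions <- list()
  kept <- list()

  drop_lm <- integer(0)
  drop_cv <- integer(0)
  if (policy == "drop_trait") {
    ok_counts <- vapply(configs, function(cfg) {
      nrow(cfg$landmarks) == p_lm && length(cfg$curves) == n_cv
    }, logical(1))
    for (i in which(!ok_counts))
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        specimen_id = configs[[i]]$specimen_id,
        reason = "wrong landmark or curve count", stringsAsFactors = FALSE)
    configs <- configs[ok_counts]
    if (!length(configs)) stop("no specimens survive the counts check")
    miss_any <- Reduce(`|`, lapply(configs, `[[`, "missing"))
    drop_lm <- which(miss_any)
    drop_cv <- which(template$curve_defs$start %in% drop_lm |
                     template$curve_defs$end %in% drop_lm)
  }

  for (cfg in configs) {
    rep <- validate_configuration(cfg, template, require_scale = require_scale,
                                  allow_absent = FALSE)
    issues <- rep$issues
    if (policy == "drop_trait") {
      drop_named <- c(sprintf("missing_landmark(%d)", drop_lm),
                      sprintf("short_curve(%s)",
                              template$curve_defs$name[drop_cv]))
      issues <- setdiff(issues, drop_named)
    }
    if (length(issues)) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        specimen_id = cfg$specimen_id,
        reason = paste(issues, collapse = "; "), stringsAsFactors = FALSE)
    } else {
      kept[[length(kept) + 1L]] <- cfg
    }
  }
  if (!length(kept)) stop("zero specimens survive fixing")

  keep_lm <- setdiff(seq_len(p_lm), drop_lm)
  keep_cv <- setdiff(seq_len(n_cv), drop_cv)

  roles <- data.frame(
    role = rep("fixed", length(keep_lm)),
    landmark = keep_lm,
    curve = NA_character_,
    within = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (ci in keep_cv) {
    k <- k_per_curve[ci]
    roles <- rbind(roles, data.frame(
      role = rep("semilandmark", k - 2L),
      landmark = NA_integer_,
      curve = template$curve_defs$name[ci],
      within = seq_len(k - 2L) + 1L,
      stringsAsFactors = FALSE
    ))
  }
  p <- nrow(roles)

  n <- length(kept)
  coords <- array(NA_real_, c(p, 2L, n))
  ids <- character(n)
  for (si in seq_len(n)) {
    cfg <- kept[[si]]
    ids[si] <- cfg$specimen_id
    pts <- cfg$landmarks[keep_lm, , drop = FALSE]
    for (ci in keep_cv) {
      nm <- template$curve_defs$name[ci]
      cv <- if (!is.null(cfg$curves[[nm]])) cfg$curves[[nm]]
            else cfg$curves[[ci]]
      rs <- resample_curve(cv, k_per_curve[ci])
      pts <- rbind(pts, rs[-c(1L, nrow(rs)), , drop = FALSE])
    }
    coords[, , si] <- pts
  }
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "#")
  dimnames(coords) <- list(NULL, c("x", "y"), ids)

  out <- list(
    coords = coords,
    specimen_ids = ids,
    point_roles = roles,
    k_per_curve = k_per_curve,
    structure = template$structure,
    exclusions = if (length(exclusions)) do.call(rbind, exclusions)
      else data.frame(specimen_id = character(0), reason = character(0))
  )
  class(out) <- "shape_array"
  if (nrow(out$exclusions))
    warning(sprintf("removed %d specimen(s): %s", nrow(out$exclusions),
                    paste(out$exclusions$specimen_id, collapse = ", ")))
  out
}

#' @export
print.shape_array <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<shape_array> %s: %d points x %d dims x %d specimens (%d excluded)\n",
              x$structure, d[1], d[2], d[3], nrow(x$exclusions)))
  invisible(x)
}
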