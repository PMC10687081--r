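# Covariance-based PCA of superimposed coordinates, score/shape
# round-trips, and per-interval morphospace occupancy.

#' Covariance-based PCA of aligned shapes
#'
#' Flattens the aligned coordinates to an `n x 2p` matrix, column-centres
#' it, and eigendecomposes the sample covariance (denominator `n - 1`).
#' Components with eigenvalue below `1e-12` times the leading one are
#' dropped as numerical noise.  Eigenvector signs are fixed by making each
#' column's largest-magnitude entry positive, so scores and plots are
#' reproducible across platforms.
#'
#' @param result a `gpa_result` from [gpa()] (`n >= 3`).
#' @return a `morphospace`: list with `scores` (`n x m`), `eigenvectors`
#'   (`2p x m`, unit columns), `eigenvalues` (length `m`, descending),
#'   `variance_explained`, `mean_flat` (length `2p`), `p` (points),
#'   `specimen_ids`, `total_variance`.
#' @export
shape_pca <- function(result) {
  stopifnot(inherits(result, "gpa_result"))
  flat <- .flatten_aligned(result)
  n <- nrow(flat)
  if (n < 3L) stop("need at least 3 specimens for a morphospace")
  mean_flat <- colMeans(flat)
  Xc <- sweep(flat, 2L, mean_flat)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  total <- sum(Xc^2) / (n - 1)
  keep <- which(eig > 1e-12 * eig[1])
  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(V))) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- result$specimen_ids
  out <- list(
    scores = scores,
    eigenvectors = V,
    eigenvalues = eig[keep],
    variance_explained = eig[keep] / total,
    mean_flat = mean_flat,
    p = dim(result$aligned)[1],
    specimen_ids = result$specimen_ids,
    total_variance = total
  )
  class(out) <- "morphospace"
  out
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace> %d specimens, %d components\n",
              nrow(x$scores), length(x$eigenvalues)))
  ve <- utils::head(x$variance_explained, 5)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve), collapse = ", "),
      "\n")
  invisible(x)
}

#' Reconstruct a (virtual) shape from morphospace scores
#'
#' Returns `mean + sum_j s_j v_j` reshaped to a `p x 2` configuration.
#' With the score vector of a specimen this recovers its aligned shape;
#' with arbitrary scores it produces the virtual shapes used to annotate
#' morphospace plots.
#'
#' @param space a `morphospace` from [shape_pca()].
#' @param score_vector numeric vector, length `<=` number of components
#'   (missing trailing entries are treated as zero).
#' @return numeric `p x 2` matrix.
#' @export
reconstruct_shape <- function(space, score_vector) {
  stopifnot(inherits(space, "morphospace"))
  m <- length(space$eigenvalues)
  score_vector <- as.numeric(score_vector)
  if (length(score_vector) > m)
    stop(sprintf("score vector longer (%d) than the number of components (%d)",
                 length(score_vector), m))
  s <- c(score_vector, rep(0, m - length(score_vector)))
  flat <- space$mean_flat + as.vector(space$eigenvectors %*% s)
  matrix(flat, ncol = 2L, dimnames = list(NULL, c("x", "y")))
}

#' Morphospace occupancy by time interval
#'
#' Builds the presence/absence table behind per-interval morphospace
#' plots: for each interval, which specimens (morphotypes) are present
#' and which are absent, over the union of all specimens in the space.
#'
#' @param space a `morphospace`.
#' @param bin_map named list mapping specimen id to a character vector of
#'   interval names (possibly empty), e.g. from [assign_bins()].
#' @return data frame (`interval`, `specimen`, `present`) with one row
#'   per interval/specimen combination, plus the PC1/PC2 coordinates.
#' @export
occupancy_grid <- function(space, bin_map) {
  stopifnot(inherits(space, "morphospace"))
  ids <- space$specimen_ids
  unknown <- setdiff(names(bin_map), ids)
  if (length(unknown))
    stop(sprintf("unknown specimen(s) in bin map: %s",
                 paste(unknown, collapse = ", ")))
  intervals <- unique(unlist(bin_map, use.names = FALSE))
  if (is.null(intervals) || !length(intervals))
    stop("bin map assigns no intervals")
  rows <- expand.grid(interval = intervals, specimen = ids,
                      stringsAsFactors = FALSE)
  rows$present <- mapply(function(iv, sp) {
    sp %in% names(bin_map) && iv %in% bin_map[[sp]]
  }, rows$interval, rows$specimen)
  idx <- match(rows$specimen, ids)
  rows$PC1 <- space$scores[idx, 1L]
  rows$PC2 <- if (ncol(space$scores) >= 2L) space$scores[idx, 2L] else 0
  rows
}
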