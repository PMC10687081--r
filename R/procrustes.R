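# Ordinary and generalised Procrustes superimposition, implemented from
# first principles on 2D configurations.

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the points from
#' their centroid — the size measure removed by Procrustes scaling.
#'
#' @param config numeric `p x 2` matrix, finite, not all points identical.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (any(!is.finite(config))) stop("configuration must be finite")
  if (nrow(config) < 2L) stop("need at least 2 points")
  ctr <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2L, ctr)^2))
  if (cs <= 0) stop("zero-size configuration: all points identical")
  cs
}

# centre and scale to unit centroid size
.preshape <- function(config) {
  config <- as.matrix(config)
  ctr <- colMeans(config)
  x <- sweep(config, 2L, ctr)
  cs <- sqrt(sum(x^2))
  if (cs <= 0) stop("zero-size configuration: all points identical")
  x / cs
}

# optimal rotation of preshape B onto preshape A (2x2, det +1 unless
# reflections allowed), plus the achieved residual norm
.opa_preshapes <- function(Ah, Bh, allow_reflection = FALSE) {
  M <- crossprod(Bh, Ah)              # minimise ||Ah - Bh R||
  sv <- svd(M)
  s <- c(1, 1)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) s <- c(1, -1)
  R <- sv$u %*% diag(s) %*% t(sv$v)
  # direct residual: the closed form 2 - 2*sum(d) loses half the digits
  # to cancellation for nearly identical shapes
  list(rotation = R, distance = sqrt(sum((Ah - Bh %*% R)^2)))
}

#' Ordinary Procrustes analysis of two configurations
#'
#' Centres and scales both configurations to unit centroid size, then
#' finds the rotation `R` minimising the Frobenius norm of
#' `A_hat - B_hat %*% R` via singular value decomposition.  Reflections
#' are disallowed by default (`det(R) = +1`, enforced by flipping the sign
#' of the smallest singular value), because specimens are pre-mirrored to
#' the right side by the digitising protocol.
#'
#' @param A,B numeric `p x 2` matrices with the same `p >= 3`.
#' @param allow_reflection permit improper rotations.
#' @return list with `rotation` (2 x 2), `distance` (the minimised norm,
#'   i.e. the full Procrustes distance), and the two pre-shapes
#'   `A_hat`, `B_aligned` (`B` pre-shape after rotation).
#' @export
opa <- function(A, B, allow_reflection = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("configurations differ in point count")
  if (nrow(A) < 3L) stop("need at least 3 points")
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("configurations must be finite")
  Ah <- .preshape(A)
  Bh <- .preshape(B)
  fit <- .opa_preshapes(Ah, Bh, allow_reflection)
  list(rotation = fit$rotation, distance = fit$distance,
       A_hat = Ah, B_aligned = Bh %*% fit$rotation)
}

#' Full Procrustes distance between two configurations
#'
#' @inheritParams opa
#' @return non-negative scalar; symmetric in its arguments.
#' @export
procrustes_distance <- function(A, B, allow_reflection = FALSE) {
  opa(A, B, allow_reflection)$distance
}

#' Generalised Procrustes analysis
#'
#' Iterative superimposition of `n >= 2` configurations: each is centred
#' (and scaled to unit centroid size when `scale = TRUE`), rotated onto
#' the current consensus, and the consensus is recomputed as the
#' coordinate-wise mean (renormalised to unit size under scaling) until
#' its change drops below `tol`.  The consensus is initialised from the
#' lexically first specimen id, which removes any dependence on input
#' order.
#'
#' @param shapes a `shape_array` from [fix_shapes()], or a `p x 2 x n`
#'   array, or a list of `p x 2` matrices.
#' @param scale remove size (unit centroid size)?  Default `TRUE` (full
#'   Procrustes).
#' @param tol convergence tolerance on the consensus change (Frobenius).
#' @param max_iter iteration cap; hitting it flags non-convergence.
#' @param allow_reflection permit improper rotations.
#' @return a `gpa_result`: list with `aligned` (`p x 2 x n`), `consensus`
#'   (`p x 2`), `centroid_sizes`, `iterations`, `final_delta`,
#'   `converged`, `scale`, `specimen_ids`.
#' @export
gpa <- function(shapes, scale = TRUE, tol = 1e-8, max_iter = 100L,
                allow_reflection = FALSE) {
  if (inherits(shapes, "shape_array")) {
    arr <- shapes$coords
    ids <- shapes$specimen_ids
  } else if (is.array(shapes) && length(dim(shapes)) == 3L) {
    arr <- shapes
    ids <- dimnames(arr)[[3]]
  } else if (is.list(shapes)) {
    arr <- simplify2array(lapply(shapes, as.matrix))
    ids <- names(shapes)
  } else stop("unsupported input for gpa()")
  n <- dim(arr)[3]
  if (is.null(n) || n < 2L) stop("need at least 2 specimens")
  if (any(!is.finite(arr)))
    stop("missing or non-finite coordinates; run fix_shapes() first")
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))

  sizes <- numeric(n)
  pre <- array(NA_real_, dim(arr))
  for (i in seq_len(n)) {
    x <- arr[, , i]
    ctr <- colMeans(x)
    x <- sweep(x, 2L, ctr)
    sizes[i] <- sqrt(sum(x^2))
    if (sizes[i] <= 0) stop(sprintf("zero-size configuration: %s", ids[i]))
    pre[, , i] <- if (scale) x / sizes[i] else x
  }

  consensus <- pre[, , order(ids)[1]]
  if (scale) consensus <- consensus / sqrt(sum(consensus^2))
  delta <- Inf
  iter <- 0L
  while (iter < max_iter && delta >= tol) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      fit <- .opa_preshapes(consensus / sqrt(sum(consensus^2)),
                            pre[, , i] / sqrt(sum(pre[, , i]^2)),
                            allow_reflection)
      pre[, , i] <- pre[, , i] %*% fit$rotation
    }
    new_cons <- apply(pre, c(1L, 2L), mean)
    if (scale) new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations (delta %.3g)",
                    max_iter, delta))
  dimnames(pre) <- list(NULL, c("x", "y"), ids)
  out <- list(
    aligned = pre,
    consensus = consensus,
    centroid_sizes = stats::setNames(sizes, ids),
    iterations = iter,
    final_delta = delta,
    converged = converged,
    scale = scale,
    specimen_ids = ids
  )
  class(out) <- "gpa_result"
  out
}

#' @export
print.gpa_result <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("<gpa_result> %d specimens x %d points; %d iteration(s), delta %.3g%s\n",
              d[3], d[1], x$iterations, x$final_delta,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Pairwise tangent-space distances among aligned specimens
#'
#' Euclidean norms between the aligned pre-shapes — the tangent-space
#' approximation of Procrustes distance used by all downstream statistics.
#'
#' @param result a `gpa_result` from [gpa()].
#' @return symmetric `n x n` matrix with zero diagonal, dimnames from the
#'   specimen ids.
#' @export
pairwise_distances <- function(result) {
  stopifnot(inherits(result, "gpa_result"))
  n <- dim(result$aligned)[3]
  flat <- t(apply(result$aligned, 3L, as.vector))
  d <- as.matrix(stats::dist(flat))
  dimnames(d) <- list(result$specimen_ids, result$specimen_ids)
  d
}

# flatten aligned coordinates to an n x 2p matrix (x1..xp then y1..yp)
.flatten_aligned <- function(result) {
  flat <- t(apply(result$aligned, 3L, as.vector))
  rownames(flat) <- result$specimen_ids
  flat
}
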