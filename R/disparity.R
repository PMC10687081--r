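# Disparity metrics on morphospace scores, stage binning, bootstrap
# disparity-through-time, and range-through richness standardisation.

#' Sum of variances
#'
#' Sum over score axes of the sample variance (denominator `n - 1`) — a
#' measure of dispersion around the group centroid, and the headline
#' disparity metric of the workflow.
#'
#' @param scores numeric `n x m` matrix (`n >= 2`).
#' @return non-negative scalar.
#' @export
sov <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 observations")
  sum(apply(scores, 2L, stats::var))
}

#' Sum of ranges
#'
#' Sum over score axes of `max - min`.  Unlike [sov()], sensitive to
#' extreme specimens and monotone under adding points.
#'
#' @inheritParams sov
#' @return non-negative scalar.
#' @export
sor <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 observations")
  sum(apply(scores, 2L, function(x) diff(range(x))))
}

#' Mean nearest-neighbour distance
#'
#' Mean over points of the Euclidean distance to the nearest other point —
#' a packing measure of morphospace occupation.
#'
#' @inheritParams sov
#' @return non-negative scalar.
#' @export
nnd <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 observations")
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Devonian stage table
#'
#' The seven Devonian stages with ICS 2023 boundary ages (Ma), ordered
#' old to young; the default binning for disparity-through-time.  A
#' plain-text copy ships in `inst/extdata/devonian_stages.csv`.
#'
#' @return data frame (`stage`, `base_age`, `top_age`).
#' @export
devonian_stages <- function() {
  data.frame(
    stage = c("Lochkovian", "Pragian", "Emsian", "Eifelian", "Givetian",
              "Frasnian", "Famennian"),
    base_age = c(419.2, 410.8, 407.6, 393.3, 387.7, 382.7, 372.2),
    top_age = c(410.8, 407.6, 393.3, 387.7, 382.7, 372.2, 358.9),
    stringsAsFactors = FALSE
  )
}

#' Read a stage table from CSV
#'
#' @param path CSV with header `stage,base_age,top_age`, rows ordered old
#'   to young, contiguous and non-overlapping.
#' @return validated stage table data frame.
#' @export
read_stage_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_stage_table(df)
}

#' Validate a stage table
#'
#' Checks column names, per-row `base_age > top_age`, and that
#' consecutive intervals tile the covered span without gaps or overlaps.
#'
#' @param stages data frame (`stage`, `base_age`, `top_age`).
#' @return the stage table, invisibly usable.
#' @export
validate_stage_table <- function(stages) {
  if (!all(c("stage", "base_age", "top_age") %in% names(stages)))
    stop("stage table needs columns stage, base_age, top_age")
  if (any(stages$base_age <= stages$top_age))
    stop("each stage must have base_age > top_age (ages in Ma)")
  if (nrow(stages) > 1L) {
    gaps <- abs(stages$top_age[-nrow(stages)] - stages$base_age[-1L])
    if (any(gaps > 1e-9))
      stop("stages must be contiguous (top age of each equals base of next)")
  }
  if (anyDuplicated(stages$stage)) stop("duplicate stage names")
  stages
}

.stage_index <- function(names, stages, what = "stage") {
  idx <- match(names, stages$stage)
  if (anyNA(idx))
    stop(sprintf("unresolvable %s name(s): %s", what,
                 paste(unique(names[is.na(idx)]), collapse = ", ")))
  idx
}

#' Assign specimens or taxa to stage bins
#'
#' `overlap` mode (specimens): each record is assigned to every stage
#' whose interval intersects the record's age range, from the base of its
#' `max_age` stage to the top of its `min_age` stage.  `range_through`
#' mode (taxa, for richness): a taxon is counted as present in every
#' stage between its first and last occupied stage inclusive.
#'
#' @param records data frame with columns `id`, `max_age`, `min_age`
#'   (stage names; `max_age` the older bound), or a list of
#'   `specimen_record`s from [read_metadata()].
#' @param stages a stage table (see [devonian_stages()]).
#' @param mode `"overlap"` or `"range_through"`.
#' @return named list: for each id, the character vector of stage names.
#' @export
assign_bins <- function(records, stages = devonian_stages(),
                        mode = c("overlap", "range_through")) {
  mode <- match.arg(mode)
  validate_stage_table(stages)
  if (is.list(records) && !is.data.frame(records)) {
    records <- data.frame(
      id = vapply(records, `[[`, "", "id"),
      max_age = vapply(records, function(r) as.character(
        .get_field(r, "stratigraphy.max_age")), ""),
      min_age = vapply(records, function(r) as.character(
        .get_field(r, "stratigraphy.min_age")), ""),
      stringsAsFactors = FALSE
    )
  }
  i_old <- .stage_index(records$max_age, stages, "max_age stage")
  i_young <- .stage_index(records$min_age, stages, "min_age stage")
  swap <- i_old > i_young
  if (any(swap)) {  # tolerate reversed bounds
    tmp <- i_old[swap]; i_old[swap] <- i_young[swap]; i_young[swap] <- tmp
  }
  out <- lapply(seq_len(nrow(records)), function(r)
    stages$stage[i_old[r]:i_young[r]])
  names(out) <- records$id
  out
}

#' Disparity through time
#'
#' Computes SoV, SoR and NND per time bin on the morphospace scores of
#' the specimens assigned to it, with percentile bootstrap intervals from
#' resampling specimens within bin with replacement.  Bins with fewer
#' than 2 specimens are reported with `NA` metrics.
#'
#' @param space a `morphospace` from [shape_pca()].
#' @param bin_map named list specimen id -> stage names ([assign_bins()]).
#' @param stages stage table ordering the output rows.
#' @param n_boot bootstrap replicates (0 disables the intervals).
#' @param coverage interval coverage (default 0.95).
#' @param seed integer seed (mandatory when `n_boot > 0`).
#' @param n_axes number of leading PC axes to use; `NULL` = all retained.
#' @return a `disparity_result` data frame: one row per bin with `n`,
#'   point estimates and `<metric>_lo`/`<metric>_hi` bounds.
#' @export
disparity_through_time <- function(space, bin_map, stages = devonian_stages(),
                                   n_boot = 500L, coverage = 0.95,
                                   seed = NULL, n_axes = NULL) {
  stopifnot(inherits(space, "morphospace"))
  validate_stage_table(stages)
  if (n_boot > 0L && is.null(seed))
    stop("a seed is required for the bootstrap")
  scores <- space$scores
  if (!is.null(n_axes))
    scores <- scores[, seq_len(min(n_axes, ncol(scores))), drop = FALSE]
  unknown <- setdiff(names(bin_map), rownames(scores))
  if (length(unknown))
    stop(sprintf("bin map names unknown specimens: %s",
                 paste(unknown, collapse = ", ")))

  metrics <- function(sc) c(SoV = sov(sc), SoR = sor(sc), NND = nnd(sc))
  alpha <- (1 - coverage) / 2
  if (!is.null(seed)) set.seed(as.integer(seed))

  rows <- lapply(stages$stage, function(st) {
    members <- names(bin_map)[vapply(bin_map, function(b) st %in% b,
                                     logical(1))]
    n <- length(members)
    row <- data.frame(bin = st, n = n, SoV = NA_real_, SoR = NA_real_,
                      NND = NA_real_, SoV_lo = NA_real_, SoV_hi = NA_real_,
                      SoR_lo = NA_real_, SoR_hi = NA_real_,
                      NND_lo = NA_real_, NND_hi = NA_real_,
                      stringsAsFactors = FALSE)
    if (n >= 2L) {
      sc <- scores[members, , drop = FALSE]
      row[, c("SoV", "SoR", "NND")] <- as.list(metrics(sc))
      if (n_boot > 0L) {
        boots <- replicate(n_boot, {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(idx)) < 2L) c(SoV = NA, SoR = NA, NND = NA)
          else metrics(sc[idx, , drop = FALSE])
        })
        for (m in c("SoV", "SoR", "NND")) {
          q <- stats::quantile(boots[m, ], c(alpha, 1 - alpha), na.rm = TRUE)
          row[[paste0(m, "_lo")]] <- q[[1]]
          row[[paste0(m, "_hi")]] <- q[[2]]
        }
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("disparity_result", class(out))
  out
}

#' Range-through taxonomic richness per stage
#'
#' Counts, for each stage, the taxa whose range-through interval (first
#' to last occupied stage, inclusive) covers it — the standardisation
#' applied to occurrence-database richness before comparing it with
#' disparity trends.
#'
#' @param occurrences data frame (`taxon`, `stage_first`, `stage_last`);
#'   `stage_first` the older stage.  Multiple rows per taxon are merged
#'   into the taxon's overall first/last range.
#' @param stages stage table.
#' @return data frame (`stage`, `richness`) in stage-table order.
#' @export
richness_range_through <- function(occurrences, stages = devonian_stages()) {
  validate_stage_table(stages)
  if (!all(c("taxon", "stage_first", "stage_last") %in% names(occurrences)))
    stop("occurrences needs columns taxon, stage_first, stage_last")
  i_first <- .stage_index(occurrences$stage_first, stages, "stage_first")
  i_last <- .stage_index(occurrences$stage_last, stages, "stage_last")
  lo <- pmin(i_first, i_last)
  hi <- pmax(i_first, i_last)
  taxa <- unique(occurrences$taxon)
  counts <- integer(nrow(stages))
  for (tx in taxa) {
    sel <- occurrences$taxon == tx
    rng <- min(lo[sel]):max(hi[sel])
    counts[rng] <- counts[rng] + 1L
  }
  data.frame(stage = stages$stage, richness = counts,
             stringsAsFactors = FALSE)
}
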