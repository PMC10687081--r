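# Readers/writers for the two shape-file dialects (tps, StereoMorph text),
# the specimen metadata (YAML) and the references table (CSV), plus the
# file-naming convention linking files to specimens and structures.

#' Resolve the structure suffix of a shape or image file name
#'
#' Landmark and image files are named `<specimen id>_C` (cephalon) or
#' `<specimen id>_P` (pygidium), matched case-insensitively on the last
#' underscore token of the file stem.
#'
#' @param filename file name or path.
#' @return list with `specimen_id` and `structure`.
#' @export
#' @examples
#' resolve_structure_suffix("CEGH-UNC_7316_C.txt")
resolve_structure_suffix <- function(filename) {
  stem <- tools::file_path_sans_ext(basename(filename))
  if (!nzchar(stem)) stop("empty file name")
  m <- regmatches(stem, regexec("^(.*)_([CcPp])$", stem))[[1]]
  if (length(m) != 3L)
    stop(sprintf("file name '%s' lacks a _C/_P structure suffix", filename))
  list(
    specimen_id = m[2],
    structure = if (toupper(m[3]) == "C") "cephalon" else "pygidium"
  )
}

.infer_structure <- function(path, n_landmarks = NA_integer_) {
  res <- tryCatch(resolve_structure_suffix(path), error = function(e) NULL)
  if (!is.null(res)) return(res$structure)
  if (!is.na(n_landmarks)) {
    if (n_landmarks == 16L) return("cephalon")
    if (n_landmarks == 7L) return("pygidium")
  }
  stop(sprintf(
    "cannot infer structure of '%s': no _C/_P suffix and %s landmarks",
    path, n_landmarks))
}

.parse_num2 <- function(line, path, lineno) {
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  xy <- suppressWarnings(as.numeric(parts))
  if (length(xy) != 2L || anyNA(xy))
    stop(sprintf("%s:%d: expected 'x y' coordinate line, got '%s'",
                 path, lineno, line))
  xy
}

#' Read a tps shape file
#'
#' Parses the tpsDig dialect: one record per specimen, each starting with
#' `LM=<n>` followed by `n` coordinate lines, optionally `CURVES=<m>` with
#' `POINTS=<k>` sub-blocks, then `IMAGE=`, `ID=` and `SCALE=` lines.
#' Coordinates are multiplied by the scale when present; records without a
#' scale are flagged `unscaled`.  When `missing_as_negative` is `TRUE`, a
#' landmark whose two raw coordinates are both negative is treated as
#' missing (a common tpsDig encoding; the released files do not document
#' theirs, so the toggle covers both possibilities).
#'
#' @param path file path.
#' @param missing_as_negative interpret all-negative landmarks as missing.
#' @param structure `"cephalon"`/`"pygidium"`; default: inferred from the
#'   `_C`/`_P` file suffix, falling back on the landmark count (16 vs 7).
#' @return list of [landmark_config()] (one per `LM=` record).
#' @export
read_tps <- function(path, missing_as_negative = TRUE, structure = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  n <- length(lines)
  configs <- list()

  kw <- function(line) {
    m <- regmatches(line, regexec("^([A-Za-z]+)=(.*)$", trimws(line)))[[1]]
    if (length(m) == 3L) list(key = toupper(m[2]), value = trimws(m[3])) else NULL
  }

  while (i <= n) {
    h <- kw(lines[i])
    if (is.null(h) || h$key != "LM")
      stop(sprintf("%s:%d: expected LM=<n>, got '%s'", path, i, lines[i]))
    p <- suppressWarnings(as.integer(h$value))
    if (is.na(p) || p < 0)
      stop(sprintf("%s:%d: malformed LM= count", path, i))
    i <- i + 1L
    if (i + p - 1L > n)
      stop(sprintf("%s:%d: LM=%d but only %d lines remain", path, i - 1L, p,
                   n - i + 1L))
    lm <- matrix(NA_real_, p, 2L)
    for (j in seq_len(p)) {
      if (!is.null(kw(lines[i])))
        stop(sprintf("%s:%d: LM=%d declared but found keyword before %d coordinate lines",
                     path, i, p, p))
      lm[j, ] <- .parse_num2(lines[i], path, i)
      i <- i + 1L
    }

    curves <- list()
    image <- NA_character_; id <- NA_character_; scale <- NA_real_
    while (i <= n) {
      h <- kw(lines[i])
      if (is.null(h))
        stop(sprintf("%s:%d: unexpected line '%s'", path, i, lines[i]))
      if (h$key == "LM") break
      i <- i + 1L
      if (h$key == "CURVES") {
        m_cv <- suppressWarnings(as.integer(h$value))
        if (is.na(m_cv)) stop(sprintf("%s:%d: malformed CURVES=", path, i - 1L))
        for (ci in seq_len(m_cv)) {
          hp <- if (i <= n) kw(lines[i]) else NULL
          if (is.null(hp) || hp$key != "POINTS")
            stop(sprintf("%s:%d: expected POINTS=<k> for curve %d", path, i, ci))
          k <- suppressWarnings(as.integer(hp$value))
          if (is.na(k) || k < 2L)
            stop(sprintf("%s:%d: malformed POINTS= count", path, i))
          i <- i + 1L
          if (i + k - 1L > n)
            stop(sprintf("%s:%d: POINTS=%d but file ends early", path, i - 1L, k))
          cv <- matrix(NA_real_, k, 2L)
          for (j in seq_len(k)) {
            if (!is.null(kw(lines[i])))
              stop(sprintf("%s:%d: POINTS=%d not matched by coordinate lines",
                           path, i, k))
            cv[j, ] <- .parse_num2(lines[i], path, i)
            i <- i + 1L
          }
          curves[[ci]] <- cv
        }
      } else if (h$key == "IMAGE") {
        image <- h$value
      } else if (h$key == "ID") {
        id <- h$value
      } else if (h$key == "SCALE") {
        scale <- suppressWarnings(as.numeric(h$value))
        if (is.na(scale) || scale <= 0)
          stop(sprintf("%s:%d: malformed SCALE=", path, i - 1L))
      } else {
        warning(sprintf("%s:%d: ignoring unknown keyword %s=", path, i - 1L,
                        h$key))
      }
    }

    if (missing_as_negative && nrow(lm)) {
      neg <- lm[, 1L] < 0 & lm[, 2L] < 0
      lm[neg, ] <- NA_real_
    }
    if (!is.na(scale)) {
      lm <- lm * scale
      curves <- lapply(curves, function(cv) cv * scale)
    }
    struct <- if (is.null(structure)) .infer_structure(path, p) else structure
    if (is.na(id)) {
      id <- tryCatch(resolve_structure_suffix(path)$specimen_id,
                     error = function(e) tools::file_path_sans_ext(basename(path)))
      if (length(configs)) id <- sprintf("%s_%d", id, length(configs) + 1L)
    }
    tpl <- structure_template(struct)
    if (length(curves) == nrow(tpl$curve_defs))
      names(curves) <- tpl$curve_defs$name
    else if (length(curves))
      names(curves) <- paste0("curve", seq_along(curves))
    configs[[length(configs) + 1L]] <- landmark_config(
      specimen_id = id, structure = struct, landmarks = lm, curves = curves,
      scale = scale, source_path = path, dialect = "tps")
  }
  configs
}

#' Write configurations to a tps file
#'
#' Emits `LM=`/`CURVES=`/`POINTS=`/`ID=`/`SCALE=` records re-readable by
#' [read_tps()].  Coordinates are written in physical units with
#' `SCALE=1`; missing landmarks are encoded as `-1 -1` (the
#' `missing_as_negative` convention).  Unscaled configurations omit the
#' `SCALE=` line.
#'
#' @param configs list of [landmark_config()] sharing one structure.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  if (!length(configs)) stop("nothing to write")
  structs <- unique(vapply(configs, `[[`, "", "structure"))
  if (length(structs) != 1L)
    stop("all configurations must share one structure")
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  for (cfg in configs) {
    lm <- cfg$landmarks
    lm[cfg$missing, ] <- -1
    writeLines(sprintf("LM=%d", nrow(lm)), con)
    writeLines(paste(fmt(lm[, 1L]), fmt(lm[, 2L])), con)
    if (length(cfg$curves)) {
      writeLines(sprintf("CURVES=%d", length(cfg$curves)), con)
      for (cv in cfg$curves) {
        writeLines(sprintf("POINTS=%d", nrow(cv)), con)
        writeLines(paste(fmt(cv[, 1L]), fmt(cv[, 2L])), con)
      }
    }
    writeLines(sprintf("ID=%s", cfg$specimen_id), con)
    if (!cfg$unscaled) writeLines("SCALE=1", con)
  }
  invisible(path)
}

#' Read a StereoMorph-style shapes text file
#'
#' Parses the plain-text shapes dialect exported by interactive landmark
#' digitisers: named blocks, each a header line followed by tab- or
#' space-separated rows.  Recognised blocks: `landmarks.pixel`
#' (`name x y` rows), `curves.pixel` (`curve_name x y` rows, consecutive
#' rows of one name forming the polyline), `scaling` (one number, units
#' per pixel) and `ruler.pixel` + `ruler.interval` (two ruler points and
#' their physical distance, from which the scale is derived).  Unknown
#' blocks are ignored with a warning.  Landmarks are reordered to the
#' template's name order (`LM1`, `LM2`, ...); names absent from the file
#' are flagged missing.
#'
#' @param path file path.
#' @param structure `"cephalon"`/`"pygidium"`; default inferred from the
#'   `_C`/`_P` file suffix.
#' @param template optional [structure_template()] overriding the built-in.
#' @return a single [landmark_config()].
#' @export
read_stereomorph <- function(path, structure = NULL, template = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(structure)) structure <- .infer_structure(path)
  if (is.null(template)) template <- structure_template(structure)

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- grepl("^[A-Za-z][A-Za-z0-9._]*$", trimws(lines))
  if (!any(is_header)) stop(sprintf("%s: no block headers found", path))

  blocks <- list()
  cur <- NULL
  for (ln in lines) {
    tln <- trimws(ln)
    if (grepl("^[A-Za-z][A-Za-z0-9._]*$", tln)) {
      cur <- tln
      blocks[[cur]] <- character(0)
    } else {
      if (is.null(cur)) stop(sprintf("%s: data before first block header", path))
      blocks[[cur]] <- c(blocks[[cur]], tln)
    }
  }

  known <- c("landmarks.pixel", "curves.pixel", "scaling", "ruler.pixel",
             "ruler.interval")
  for (nm in setdiff(names(blocks), known))
    warning(sprintf("%s: ignoring unknown block '%s'", path, nm))

  if (is.null(blocks[["landmarks.pixel"]]))
    stop(sprintf("%s: no landmarks.pixel block", path))

  parse_named_rows <- function(rows, block) {
    out <- lapply(seq_along(rows), function(i) {
      parts <- strsplit(rows[i], "[\t ]+")[[1]]
      if (length(parts) != 3L)
        stop(sprintf("%s: malformed row in %s: '%s'", path, block, rows[i]))
      xy <- suppressWarnings(as.numeric(parts[2:3]))
      if (anyNA(xy))
        stop(sprintf("%s: non-numeric coordinates in %s: '%s'", path, block,
                     rows[i]))
      list(name = parts[1], xy = xy)
    })
    out
  }

  lm_rows <- parse_named_rows(blocks[["landmarks.pixel"]], "landmarks.pixel")
  lm_names <- vapply(lm_rows, `[[`, "", "name")
  p <- nrow(template$landmark_defs)
  lm <- matrix(NA_real_, p, 2L)
  for (r in lm_rows) {
    idx <- match(r$name, template$landmark_defs$name)
    if (is.na(idx)) {
      warning(sprintf("%s: unknown landmark name '%s' ignored", path, r$name))
      next
    }
    lm[idx, ] <- r$xy
  }

  curves <- list()
  if (!is.null(blocks[["curves.pixel"]])) {
    cv_rows <- parse_named_rows(blocks[["curves.pixel"]], "curves.pixel")
    cv_names <- vapply(cv_rows, `[[`, "", "name")
    for (nm in unique(cv_names)) {
      pts <- do.call(rbind, lapply(cv_rows[cv_names == nm], `[[`, "xy"))
      curves[[nm]] <- pts
    }
    # template order where known
    ord <- c(intersect(template$curve_defs$name, names(curves)),
             setdiff(names(curves), template$curve_defs$name))
    curves <- curves[ord]
  }

  scale <- NA_real_
  if (!is.null(blocks[["scaling"]])) {
    scale <- suppressWarnings(as.numeric(blocks[["scaling"]][1]))
    if (is.na(scale) || scale <= 0)
      stop(sprintf("%s: malformed scaling block", path))
  } else if (!is.null(blocks[["ruler.pixel"]]) &&
             !is.null(blocks[["ruler.interval"]])) {
    rp <- parse_named_rows(blocks[["ruler.pixel"]], "ruler.pixel")
    if (length(rp) != 2L)
      stop(sprintf("%s: ruler.pixel must contain exactly two points", path))
    px <- sqrt(sum((rp[[1]]$xy - rp[[2]]$xy)^2))
    interval <- suppressWarnings(as.numeric(blocks[["ruler.interval"]][1]))
    if (is.na(interval) || interval <= 0 || px <= 0)
      stop(sprintf("%s: malformed ruler blocks", path))
    scale <- interval / px
  }

  if (!is.na(scale)) {
    lm <- lm * scale
    curves <- lapply(curves, function(cv) cv * scale)
  }
  id <- tryCatch(resolve_structure_suffix(path)$specimen_id,
                 error = function(e) tools::file_path_sans_ext(basename(path)))
  landmark_config(specimen_id = id, structure = structure, landmarks = lm,
                  curves = curves, scale = scale, source_path = path,
                  dialect = "stereomorph")
}

#' Write a configuration as a StereoMorph-style shapes text file
#'
#' Inverse of [read_stereomorph()]: emits `landmarks.pixel` (present
#' landmarks only, named `LM<i>`), `curves.pixel` and, unless the
#' configuration is unscaled, a `scaling` block of 1 (coordinates are
#' stored in physical units).
#'
#' @param config a [landmark_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stereomorph <- function(config, path) {
  stopifnot(inherits(config, "landmark_config"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)
  writeLines("landmarks.pixel", con)
  pres <- which(!config$missing)
  writeLines(sprintf("LM%d\t%s\t%s", pres,
                     fmt(config$landmarks[pres, 1L]),
                     fmt(config$landmarks[pres, 2L])), con)
  if (length(config$curves)) {
    writeLines("curves.pixel", con)
    for (nm in names(config$curves)) {
      cv <- config$curves[[nm]]
      writeLines(sprintf("%s\t%s\t%s", nm, fmt(cv[, 1L]), fmt(cv[, 2L])), con)
    }
  }
  if (!config$unscaled) {
    writeLines("scaling", con)
    writeLines("1", con)
  }
  invisible(path)
}

#' Read a directory of shape files
#'
#' Reads every `*.tps` and `*.txt` file in `dir`, resolving specimen ids
#' and structures from the `_C`/`_P` suffixes, and returns the
#' configurations for one structure.
#'
#' @param dir directory containing shape files.
#' @param structure keep only this structure (`"cephalon"`/`"pygidium"`).
#' @param missing_as_negative passed to [read_tps()].
#' @return list of [landmark_config()], named by specimen id.
#' @export
read_shape_dir <- function(dir, structure = c("cephalon", "pygidium"),
                           missing_as_negative = TRUE) {
  structure <- match.arg(structure)
  files <- list.files(dir, pattern = "\\.(tps|txt)$", ignore.case = TRUE,
                      full.names = TRUE)
  out <- list()
  for (f in files) {
    res <- tryCatch(resolve_structure_suffix(f), error = function(e) NULL)
    if (is.null(res) || res$structure != structure) next
    cfgs <- if (grepl("\\.tps$", f, ignore.case = TRUE))
      read_tps(f, missing_as_negative = missing_as_negative)
    else
      list(read_stereomorph(f))
    for (cfg in cfgs) out[[cfg$specimen_id]] <- cfg
  }
  out
}

.MANDATORY_FIELDS <- c(
  "ref_pic", "enter_metadata", "enter_landmark",
  "taxonomy.orig_genus", "taxonomy.genus", "taxonomy.sp",
  "morphology.cephalon", "morphology.cranidium", "morphology.pygidium",
  "morphology.eyes", "morphology.ontogeny",
  "geography.locality", "geography.lat", "geography.long",
  "stratigraphy.min_age", "stratigraphy.max_age"
)

.ONTOGENY_LEVELS <- c("early Holaspis", "Holaspis", "Meraspis")

.norm_key <- function(x) gsub("[. ]", "_", x)

.get_field <- function(entry, dotted) {
  parts <- strsplit(dotted, ".", fixed = TRUE)[[1]]
  cur <- entry
  for (p in parts) {
    if (!is.list(cur)) return(NULL)
    names(cur) <- .norm_key(names(cur))
    cur <- cur[[.norm_key(p)]]
    if (is.null(cur)) return(NULL)
  }
  cur
}

#' Read the specimen metadata file
#'
#' Parses the YAML metadata document: one entry per specimen id, with
#' nested `taxonomy`, `morphology`, `geography` and `stratigraphy`
#' sub-records.  Mandatory-field violations, out-of-range coordinates,
#' unknown ontogeny levels and all-false structure flags are collected per
#' record in `$violations` (and summarised in the `"violations"`
#' attribute) rather than dropped or repaired.
#'
#' @param path YAML file path.
#' @return named list of `specimen_record` objects; attribute
#'   `"violations"` is a data frame (`id`, `violation`).
#' @export
read_metadata <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc) || is.null(names(doc)) || !all(nzchar(names(doc))))
    stop(sprintf("%s: metadata must map specimen ids to records", path))
  if (anyDuplicated(names(doc)))
    stop(sprintf("%s: duplicate specimen id(s): %s", path,
                 paste(unique(names(doc)[duplicated(names(doc))]),
                       collapse = ", ")))

  records <- list()
  viol_tab <- list()
  for (id in names(doc)) {
    entry <- doc[[id]]
    violations <- character(0)
    for (f in .MANDATORY_FIELDS) {
      v <- .get_field(entry, f)
      if (is.null(v) || (is.character(v) && !nzchar(trimws(v))) ||
          (length(v) == 1L && is.na(v)))
        violations <- c(violations, sprintf("missing mandatory field %s", f))
    }
    lat <- .get_field(entry, "geography.lat")
    lon <- .get_field(entry, "geography.long")
    if (!is.null(lat) && is.numeric(lat) && !is.na(lat) &&
        (lat < -90 || lat > 90))
      violations <- c(violations, "lat out of range")
    if (!is.null(lon) && is.numeric(lon) && !is.na(lon) &&
        (lon < -180 || lon > 180))
      violations <- c(violations, "long out of range")
    morph <- vapply(c("morphology.cephalon", "morphology.cranidium",
                      "morphology.pygidium"),
                    function(f) isTRUE(.get_field(entry, f)), logical(1))
    if (!any(morph))
      violations <- c(violations, "no digitised structure flagged true")
    ont <- .get_field(entry, "morphology.ontogeny")
    if (!is.null(ont) && !ont %in% .ONTOGENY_LEVELS)
      violations <- c(violations, sprintf("unknown ontogeny level '%s'", ont))

    rec <- list(
      id = id,
      ref_pic = .get_field(entry, "ref_pic"),
      enter_metadata = .get_field(entry, "enter_metadata"),
      enter_landmark = .get_field(entry, "enter_landmark"),
      taxonomy = .get_field(entry, "taxonomy"),
      morphology = .get_field(entry, "morphology"),
      geography = .get_field(entry, "geography"),
      stratigraphy = .get_field(entry, "stratigraphy"),
      violations = violations
    )
    class(rec) <- "specimen_record"
    records[[id]] <- rec
    if (length(violations))
      viol_tab[[id]] <- data.frame(id = id, violation = violations,
                                   stringsAsFactors = FALSE)
  }
  attr(records, "violations") <- if (length(viol_tab))
    do.call(rbind, unname(viol_tab))
  else data.frame(id = character(0), violation = character(0))
  records
}

#' Write specimen metadata to YAML
#'
#' Serialises `specimen_record`-style entries (named list of nested lists)
#' back to the metadata YAML layout; used mainly by the synthetic-data
#' generator.
#'
#' @param records named list of records (the `violations` field, if any,
#'   is dropped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  doc <- lapply(records, function(r) {
    r$violations <- NULL
    r$id <- NULL
    r
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read the references table
#'
#' @param path CSV with header `ref_id,citation`.
#' @return data frame with unique `ref_id`.
#' @export
read_references <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ref_id", "citation") %in% names(df)))
    stop(sprintf("%s: expected columns ref_id, citation", path))
  if (anyDuplicated(df$ref_id))
    stop(sprintf("%s: duplicate ref_id(s): %s", path,
                 paste(unique(df$ref_id[duplicated(df$ref_id)]),
                       collapse = ", ")))
  df
}
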