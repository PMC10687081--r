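# Landmark templates for the two digitised trilobite structures and the
# homogeneity check that configurations must pass before assembly.

.CEPHALON_LANDMARKS <- c(
  "Anteriormost point of the sagittal cephalic length without spine",
  "Anteriormost point of the sagittal glabellar length",
  "Intersection between the sagittal axis and the occipital furrow",
  "Posteriormost point of the sagittal cephalic length",
  "Maximum transversal glabellar width",
  "Intersection between the occipital and axial furrows",
  "Intersection between the posterior margin and the axial furrow",
  "Anteriormost end of the eye",
  "Posteriormost end of the eye",
  "Anterior facial suture at the sagittal line",
  "Intersection between the posterior branch of facial suture and the posterior or lateral border furrow",
  "Intersection between the posterior branch of facial suture and the posterior or lateral margin",
  "Anteriormost point of the sagittal (or ex-sagittal) cephalic length (if spiny, LM13 at the tip of the spine)",
  "Lateralmost external point of the eye",
  "Cephalic width at the level of the posterior margin of the occipital ring (LM4). If that point cannot be located, it is defined as the extreme of the genal angle",
  "Tip of the genal angle or spine"
)

.PYGIDIUM_LANDMARKS <- c(
  "Anteriormost point of the pygidial axis",
  "Posteriormost point of the pygidial axis",
  "Border furrow at the sagittal point",
  "Posteriormost point of pygidium at the sagittal line (if spiny LM 4 at the tip of the spine)",
  "Intersection between the axial furrow and the anterior pygidial margin",
  "Intersection between the anterior pygidial margin and the border furrow",
  "Intersection between the anterior and the lateral pygidial margin"
)

.CEPHALON_CURVES <- data.frame(
  name  = c("glabella", "facial_suture", "anterior_margin", "posterior_margin"),
  label = c("Glabella (C.1)", "Facial suture (C.2)", "Anterior margin (C.3)",
            "Posterior margin (C.4)"),
  start = c(2L, 10L, 13L, 4L),
  end   = c(7L, 12L, 15L, 15L),
  stringsAsFactors = FALSE
)

.PYGIDIUM_CURVES <- data.frame(
  name  = c("axis", "border_furrow", "margin"),
  label = c("Axis (C.1)", "Border furrow (C.2)", "Margin (C.3)"),
  start = c(1L, 3L, 4L),
  end   = c(2L, 6L, 5L),
  stringsAsFactors = FALSE
)

#' Built-in landmarking templates
#'
#' Returns the community landmarking standard for one of the two digitised
#' trilobite structures: 16 fixed landmarks and 4 semilandmark curves for the
#' cephalon, 7 landmarks and 3 curves for the pygidium.  Each curve is bound
#' at both ends to a fixed landmark (e.g. the glabellar outline runs from
#' LM2 to LM7).  Eye landmarks (LM8, LM9, LM14 of the cephalon) are
#' optionally absent, covering blind taxa.
#'
#' @param structure `"cephalon"` or `"pygidium"`.
#' @return A `structure_template` object: list with `structure`,
#'   `landmark_defs` (data frame `index`, `name`, `definition`),
#'   `curve_defs` (data frame `name`, `label`, `start`, `end`) and
#'   `optionally_absent` (integer landmark indices).
#' @export
#' @examples
#' tpl <- structure_template("cephalon")
#' nrow(tpl$landmark_defs)  # 16
structure_template <- function(structure = c("cephalon", "pygidium")) {
  structure <- match.arg(structure)
  if (structure == "cephalon") {
    defs <- .CEPHALON_LANDMARKS
    curves <- .CEPHALON_CURVES
    absent <- c(8L, 9L, 14L)
  } else {
    defs <- .PYGIDIUM_LANDMARKS
    curves <- .PYGIDIUM_CURVES
    absent <- integer(0)
  }
  out <- list(
    structure = structure,
    landmark_defs = data.frame(
      index = seq_along(defs),
      name = paste0("LM", seq_along(defs)),
      definition = defs,
      stringsAsFactors = FALSE
    ),
    curve_defs = curves,
    optionally_absent = absent
  )
  class(out) <- "structure_template"
  out
}

#' @export
print.structure_template <- function(x, ...) {
  cat(sprintf("Structure template: %s (%d landmarks, %d curves)\n",
              x$structure, nrow(x$landmark_defs), nrow(x$curve_defs)))
  for (i in seq_len(nrow(x$curve_defs)))
    cat(sprintf("  %s: LM%d - LM%d\n", x$curve_defs$label[i],
                x$curve_defs$start[i], x$curve_defs$end[i]))
  invisible(x)
}

#' Export a template as JSON
#'
#' Serialises a [structure_template()] (landmark names, definitions, curve
#' bindings, optionally-absent set) so that external digitisers can drive
#' their name order from it.
#'
#' @param template a `structure_template`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
template_to_json <- function(template, path = NULL) {
  stopifnot(inherits(template, "structure_template"))
  doc <- list(
    structure = template$structure,
    landmarks = template$landmark_defs,
    curves = template$curve_defs,
    optionally_absent = template$optionally_absent
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Landmark configuration constructor
#'
#' One digitised specimen of one structure: a matrix of fixed landmarks
#' (rows of `NA` mark missing landmarks), a named list of semilandmark
#' curves (polylines, each a `k x 2` matrix), and an optional scale factor.
#' Coordinates are stored in physical units (the scale is applied by the
#' readers); files without a scale are kept but flagged `unscaled`.
#'
#' @param specimen_id repository code of the specimen.
#' @param structure `"cephalon"` or `"pygidium"`.
#' @param landmarks numeric `p x 2` matrix; `NA` rows flag missing landmarks.
#' @param curves named list of numeric `k_i x 2` matrices (`k_i >= 2`).
#' @param scale physical units per digitiser unit, or `NA` when absent.
#' @param source_path,dialect provenance (optional).
#' @return a `landmark_config` object.
#' @export
landmark_config <- function(specimen_id, structure, landmarks,
                            curves = list(), scale = NA_real_,
                            source_path = NA_character_,
                            dialect = NA_character_) {
  structure <- match.arg(structure, c("cephalon", "pygidium"))
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 2L)
    stop("landmarks must be a p x 2 matrix")
  storage.mode(landmarks) <- "double"
  miss <- is.na(landmarks[, 1L]) | is.na(landmarks[, 2L])
  landmarks[miss, ] <- NA_real_
  present <- landmarks[!miss, , drop = FALSE]
  if (length(present) && any(!is.finite(present)))
    stop("present landmarks must have finite coordinates")
  curves <- lapply(curves, function(cv) {
    cv <- as.matrix(cv)
    storage.mode(cv) <- "double"
    if (ncol(cv) != 2L || nrow(cv) < 2L || any(!is.finite(cv)))
      stop("each curve must be a finite k x 2 matrix with k >= 2")
    cv
  })
  if (!is.na(scale) && scale <= 0)
    stop("scale must be positive")
  out <- list(
    specimen_id = as.character(specimen_id),
    structure = structure,
    landmarks = landmarks,
    missing = miss,
    curves = curves,
    scale = as.numeric(scale),
    unscaled = is.na(scale),
    source_path = source_path,
    dialect = dialect
  )
  class(out) <- "landmark_config"
  out
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s [%s]: %d landmarks (%d missing), %d curves%s\n",
              x$specimen_id, x$structure, nrow(x$landmarks), sum(x$missing),
              length(x$curves), if (x$unscaled) ", UNSCALED" else ""))
  invisible(x)
}

#' Validate a configuration against a template
#'
#' The homogeneity check run before array assembly: landmark count, curve
#' count and names, curve length, presence of a scale, and missing
#' landmarks.  Missing landmarks in the template's optionally-absent set
#' (the eye landmarks, for blind taxa) do not break conformity when
#' `allow_absent` is `TRUE`.  As an informational aid the validator also
#' warns when cephalic LM10 coincides with LM1 (the marginal-suture
#' placement convention), without affecting conformity.
#'
#' @param config a [landmark_config()].
#' @param template a [structure_template()]; defaults to the built-in
#'   template for `config$structure`.
#' @param require_scale flag a missing scale as an issue.
#' @param allow_absent tolerate missing optionally-absent landmarks.
#' @param min_curve_points minimum points per digitised curve (default 3;
#'   2-point curves carry no shape beyond their endpoints).
#' @return a `validation_report`: list with `specimen_id`, `conforms`,
#'   `issues` (character codes), `absent_ok` (tolerated absences) and
#'   `notes`.
#' @export
validate_configuration <- function(config, template = NULL,
                                   require_scale = TRUE,
                                   allow_absent = TRUE,
                                   min_curve_points = 3L) {
  stopifnot(inherits(config, "landmark_config"))
  if (is.null(template)) template <- structure_template(config$structure)
  stopifnot(inherits(template, "structure_template"))
  if (config$structure != template$structure)
    stop(sprintf("structure mismatch: config is %s, template is %s",
                 config$structure, template$structure))

  issues <- character(0)
  notes <- character(0)
  absent_ok <- integer(0)

  p_tpl <- nrow(template$landmark_defs)
  if (nrow(config$landmarks) != p_tpl)
    issues <- c(issues, sprintf("wrong_landmark_count(%d!=%d)",
                                nrow(config$landmarks), p_tpl))

  n_cv <- nrow(template$curve_defs)
  if (length(config$curves) != n_cv) {
    issues <- c(issues, sprintf("wrong_curve_count(%d!=%d)",
                                length(config$curves), n_cv))
  } else if (!is.null(names(config$curves)) &&
             any(nzchar(names(config$curves))) &&
             !setequal(names(config$curves), template$curve_defs$name)) {
    issues <- c(issues, "wrong_curve_names")
  }

  for (nm in names(config$curves)) {
    if (nrow(config$curves[[nm]]) < min_curve_points)
      issues <- c(issues, sprintf("short_curve(%s)", nm))
  }

  if (nrow(config$landmarks) == p_tpl) {
    miss_idx <- which(config$missing)
    for (i in miss_idx) {
      if (allow_absent && i %in% template$optionally_absent)
        absent_ok <- c(absent_ok, i)
      else
        issues <- c(issues, sprintf("missing_landmark(%d)", i))
    }
  }

  if (require_scale && config$unscaled)
    issues <- c(issues, "missing_scale")

  if (template$structure == "cephalon" && nrow(config$landmarks) >= 10 &&
      !config$missing[1L] && !config$missing[10L]) {
    if (sqrt(sum((config$landmarks[1L, ] - config$landmarks[10L, ])^2)) < 1e-6)
      notes <- c(notes, "LM10 coincides with LM1 (marginal suture placement)")
  }

  out <- list(
    specimen_id = config$specimen_id,
    conforms = length(issues) == 0L,
    issues = issues,
    absent_ok = absent_ok,
    notes = notes
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %s\n", x$specimen_id,
              if (x$conforms) "conforms" else "NOT conforming"))
  if (length(x$issues)) cat("  issues:", paste(x$issues, collapse = ", "), "\n")
  if (length(x$absent_ok))
    cat("  tolerated absences: LM", paste(x$absent_ok, collapse = ", LM"), "\n",
        sep = "")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Mirror a configuration across the sagittal axis
#'
#' Negates all x-coordinates (landmarks and curve points).  The digitising
#' protocol refers landmarks to the right half in dorsal view; pictures of
#' specimens with a better preserved left side are mirrored before
#' landmarking, and this operation applies the same reflection to an
#' already-digitised configuration.  Applying it twice is the identity.
#'
#' @param config a [landmark_config()].
#' @return the mirrored `landmark_config`.
#' @export
mirror_configuration <- function(config) {
  stopifnot(inherits(config, "landmark_config"))
  config$landmarks[, 1L] <- -config$landmarks[, 1L]
  config$curves <- lapply(config$curves, function(cv) {
    cv[, 1L] <- -cv[, 1L]
    cv
  })
  config
}
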