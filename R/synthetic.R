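# Seeded generator of template-conforming synthetic datasets: idealised
# base shapes, genus/specimen-level Gaussian shape noise, nuisance
# similarity transforms, file output in both dialects, and the replicate
# digitisation (measurement-error) designs.

.CEPHALON_BASE <- local({
  lm <- rbind(
    c(0.00,  1.00),  # LM1  anterior cephalic margin, sagittal
    c(0.00,  0.85),  # LM2  anterior glabella
    c(0.00,  0.05),  # LM3  occipital furrow, sagittal
    c(0.00, -0.10),  # LM4  posterior cephalic margin, sagittal
    c(0.35,  0.45),  # LM5  max transversal glabellar width
    c(0.30,  0.05),  # LM6  occipital x axial furrow
    c(0.32, -0.08),  # LM7  posterior margin x axial furrow
    c(0.45,  0.55),  # LM8  anterior end of eye
    c(0.50,  0.30),  # LM9  posterior end of eye
    c(0.00,  0.92),  # LM10 anterior facial suture, sagittal
    c(0.55,  0.00),  # LM11 posterior facial suture x border furrow
    c(0.60, -0.05),  # LM12 posterior facial suture x margin
    c(0.00,  1.05),  # LM13 anteriormost point (spine tip)
    c(0.55,  0.42),  # LM14 lateralmost point of eye
    c(0.95, -0.10),  # LM15 cephalic width at occipital ring level
    c(1.00, -0.35)   # LM16 genal spine tip
  )
  curves <- list(
    glabella = rbind(lm[2, ], c(0.20, 0.80), c(0.33, 0.60), c(0.35, 0.45),
                     c(0.33, 0.25), c(0.30, 0.05), lm[7, ]),
    facial_suture = rbind(lm[10, ], c(0.30, 0.88), c(0.45, 0.70),
                          c(0.52, 0.40), c(0.55, 0.15), lm[12, ]),
    anterior_margin = rbind(lm[13, ], c(0.40, 0.98), c(0.70, 0.75),
                            c(0.88, 0.45), c(0.95, 0.15), lm[15, ]),
    posterior_margin = rbind(lm[4, ], c(0.30, -0.12), c(0.60, -0.13),
                             c(0.80, -0.12), lm[15, ])
  )
  list(landmarks = lm, curves = curves)
})

.PYGIDIUM_BASE <- local({
  lm <- rbind(
    c(0.00,  0.50),  # LM1 anterior axis
    c(0.00, -0.10),  # LM2 posterior axis
    c(0.00, -0.28),  # LM3 border furrow, sagittal
    c(0.00, -0.42),  # LM4 posterior margin, sagittal
    c(0.25,  0.50),  # LM5 axial furrow x anterior margin
    c(0.68,  0.42),  # LM6 anterior margin x border furrow
    c(0.75,  0.50)   # LM7 anterior x lateral margin
  )
  curves <- list(
    axis = rbind(lm[1, ], c(0.22, 0.40), c(0.18, 0.15), c(0.10, -0.02),
                 lm[2, ]),
    border_furrow = rbind(lm[3, ], c(0.30, -0.25), c(0.55, -0.05),
                          c(0.65, 0.20), lm[6, ]),
    margin = rbind(lm[4, ], c(0.40, -0.36), c(0.65, -0.15), c(0.75, 0.10),
                   c(0.74, 0.35), lm[5, ])
  )
  list(landmarks = lm, curves = curves)
})

#' Idealised base configuration
#'
#' A hard-coded right-half configuration honouring every template curve
#' binding exactly (each curve's first and last points coincide with its
#' start and end landmarks) and passing [validate_configuration()] with
#' no issues.  Used as the latent "true shape" by the simulators.
#'
#' @param structure `"cephalon"` or `"pygidium"`.
#' @return a [landmark_config()] with scale 1.
#' @export
base_shape <- function(structure = c("cephalon", "pygidium")) {
  structure <- match.arg(structure)
  b <- if (structure == "cephalon") .CEPHALON_BASE else .PYGIDIUM_BASE
  landmark_config(specimen_id = paste0("base_", structure),
                  structure = structure, landmarks = b$landmarks,
                  curves = b$curves, scale = 1, dialect = "synthetic")
}

# apply a per-landmark displacement field D (p x 2) to a configuration;
# curve interiors inherit a blend of their endpoint displacements,
# interpolated along normalised arc length, so bindings stay exact
.deform_config <- function(config, D, template = NULL) {
  if (is.null(template)) template <- structure_template(config$structure)
  config$landmarks <- config$landmarks + D
  for (ci in seq_len(nrow(template$curve_defs))) {
    nm <- template$curve_defs$name[ci]
    a <- template$curve_defs$start[ci]
    b <- template$curve_defs$end[ci]
    cv <- config$curves[[nm]]
    seg <- sqrt(rowSums((cv[-1L, , drop = FALSE] -
                         cv[-nrow(cv), , drop = FALSE])^2))
    t <- c(0, cumsum(seg)) / sum(seg)
    config$curves[[nm]] <- cv + outer(1 - t, D[a, ]) + outer(t, D[b, ])
  }
  config
}

# random similarity transform applied to landmarks and curves; the result
# is shifted into the positive quadrant because digitisers emit image
# pixel coordinates (and all-negative points encode missing landmarks in
# the tps dialect)
.apply_nuisance <- function(config, angle_deg, translation, scale_factor,
                            margin = 0.1) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  tr <- function(x) sweep(scale_factor * (x %*% R), 2L, translation, `+`)
  config$landmarks <- tr(config$landmarks)
  config$curves <- lapply(config$curves, tr)
  lo <- suppressWarnings(pmin(
    apply(config$landmarks, 2L, min, na.rm = TRUE),
    Reduce(pmin, lapply(config$curves, function(cv) apply(cv, 2L, min)))))
  shift <- pmax(margin - lo, 0)
  config$landmarks <- sweep(config$landmarks, 2L, shift, `+`)
  config$curves <- lapply(config$curves, function(cv)
    sweep(cv, 2L, shift, `+`))
  config
}

#' Simulate a multi-genus landmark dataset
#'
#' Generates a dataset with known group structure: genus mean shapes are
#' the base shape plus isotropic Gaussian landmark displacements of
#' standard deviation `sigma_between`; specimens add displacements of
#' standard deviation `sigma_within`; each specimen then receives a
#' random similarity nuisance (rotation, translation, scale).  Half the
#' specimens are written as tps files and half as StereoMorph text files,
#' together with a metadata YAML (genus, stage range, eyes flag) and a
#' truth table of every latent value.  Defects are injected with the
#' stated probabilities: a random missing landmark, a missing scale, and
#' "blind" genera whose specimens lack the eye landmarks (cephalon only)
#' and carry `morphology.eyes: false`.
#'
#' Fully reproducible: the same `seed` yields byte-identical files.
#'
#' @param out_dir output directory (created); `NULL` keeps everything in
#'   memory.
#' @param structure `"cephalon"` or `"pygidium"`.
#' @param n_genera,n_per_genus design size.
#' @param sigma_between,sigma_within shape noise standard deviations, in
#'   units of the base shape (overall extent about 1).
#' @param rotation_range nuisance rotation, degrees (uniform in
#'   `[-r, r]`).
#' @param translation_range nuisance translation per coordinate (uniform
#'   in `[-t, t]`).
#' @param scale_range nuisance size factor (uniform in `[lo, hi]`).
#' @param p_missing_landmark,p_missing_scale per-specimen defect
#'   probabilities.
#' @param blind_fraction fraction of genera lacking eyes.
#' @param stage_pool stage names from which each genus draws a contiguous
#'   age range.
#' @param seed integer seed (mandatory).
#' @return list with `configs` (list of [landmark_config()]), `truth`
#'   (data frame of latent values), `metadata` (records as written), and
#'   when `out_dir` is given, `files` and `metadata_path`.
#' @export
simulate_dataset <- function(out_dir = NULL,
                             structure = c("cephalon", "pygidium"),
                             n_genera = 10L, n_per_genus = 3L,
                             sigma_between = 0.1, sigma_within = 0.01,
                             rotation_range = 180, translation_range = 1,
                             scale_range = c(0.5, 2),
                             p_missing_landmark = 0, p_missing_scale = 0,
                             blind_fraction = 0,
                             stage_pool = devonian_stages()$stage,
                             seed) {
  structure <- match.arg(structure)
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(as.integer(seed))
  template <- structure_template(structure)
  base <- base_shape(structure)
  p <- nrow(base$landmarks)
  suffix <- if (structure == "cephalon") "_C" else "_P"

  blind <- rep(FALSE, n_genera)
  if (structure == "cephalon" && blind_fraction > 0)
    blind <- stats::runif(n_genera) < blind_fraction

  configs <- list()
  truth <- list()
  metadata <- list()
  for (gi in seq_len(n_genera)) {
    D_genus <- matrix(stats::rnorm(2L * p, 0, sigma_between), p, 2L)
    genus <- sprintf("Genus%02d", gi)
    st_hi <- sample.int(length(stage_pool), 1L)
    st_lo <- st_hi + sample.int(length(stage_pool) - st_hi + 1L, 1L) - 1L
    for (si in seq_len(n_per_genus)) {
      D_spec <- D_genus + matrix(stats::rnorm(2L * p, 0, sigma_within), p, 2L)
      cfg <- .deform_config(base, D_spec, template)
      ang <- stats::runif(1, -rotation_range, rotation_range)
      trl <- stats::runif(2, -translation_range, translation_range)
      scl <- stats::runif(1, scale_range[1], scale_range[2])
      cfg <- .apply_nuisance(cfg, ang, trl, scl)

      miss_lm <- NA_integer_
      if (blind[gi]) {
        cfg$landmarks[template$optionally_absent, ] <- NA_real_
      }
      if (p_missing_landmark > 0 && stats::runif(1) < p_missing_landmark) {
        miss_lm <- sample.int(p, 1L)
        cfg$landmarks[miss_lm, ] <- NA_real_
      }
      miss_scale <- p_missing_scale > 0 && stats::runif(1) < p_missing_scale
      id <- sprintf("SYN-%s-%02d", genus, si)
      dialect <- if (si %% 2L == 1L) "tps" else "stereomorph"
      cfg <- landmark_config(id, structure, cfg$landmarks, cfg$curves,
                             scale = if (miss_scale) NA_real_ else 1,
                             dialect = dialect)
      configs[[id]] <- cfg
      truth[[id]] <- data.frame(
        specimen_id = id, genus = genus, blind = blind[gi],
        missing_landmark = miss_lm, missing_scale = miss_scale,
        dialect = dialect, rotation = ang, translation_x = trl[1],
        translation_y = trl[2], scale_factor = scl,
        stage_max = stage_pool[st_hi], stage_min = stage_pool[st_lo],
        stringsAsFactors = FALSE
      )
      metadata[[id]] <- list(
        ref_pic = "synthetic", enter_metadata = "SYN", enter_landmark = "SYN",
        taxonomy = list(orig_genus = genus, genus = genus,
                        sp = sprintf("%s sp%d", genus, si)),
        morphology = list(cephalon = structure == "cephalon",
                          cranidium = FALSE,
                          pygidium = structure == "pygidium",
                          eyes = !blind[gi], ontogeny = "Holaspis"),
        geography = list(locality = "synthetic locality", lat = 0, long = 0),
        stratigraphy = list(min_age = stage_pool[st_lo],
                            max_age = stage_pool[st_hi])
      )
    }
  }
  out <- list(configs = configs, truth = do.call(rbind, unname(truth)),
              metadata = metadata)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    shapes_dir <- file.path(out_dir, if (structure == "cephalon")
      "cephala" else "pygidia")
    dir.create(shapes_dir, showWarnings = FALSE)
    files <- character(0)
    for (cfg in configs) {
      if (cfg$dialect == "tps") {
        f <- file.path(shapes_dir, paste0(cfg$specimen_id, suffix, ".tps"))
        write_tps(list(cfg), f)
      } else {
        f <- file.path(shapes_dir, paste0(cfg$specimen_id, suffix, ".txt"))
        write_stereomorph(cfg, f)
      }
      files <- c(files, f)
    }
    meta_path <- file.path(out_dir, "metadata.yml")
    write_metadata(metadata, meta_path)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    out$files <- files
    out$metadata_path <- meta_path
  }
  out
}

#' Simulate a replicate-digitisation (measurement-error) experiment
#'
#' Emulates the error-validation design: several within-observer sets of
#' replicate digitisations of one specimen (noise `sigma_within` per
#' replicate), one among-observer set in which each observer carries a
#' persistent bias of standard deviation `sigma_among` plus replicate
#' noise, and a reference set of distinct genera (spread
#' `sigma_between`) serving as the natural-variation yardstick.
#'
#' With `perturb_lm15 = TRUE` the last among-set observer misplaces
#' cephalic LM15 by `perturb_offset` (applied to the landmark only — the
#' digitised curves still follow the true outline), the scenario that
#' inflates landmark-only variability more than the full configuration's.
#'
#' @param seed integer seed (mandatory).
#' @param sigma_within within-observer digitising noise sd.
#' @param sigma_among among-observer bias sd.
#' @param sigma_between between-genus shape spread sd.
#' @param n_replicates replicates per within-observer set (`>= 2`).
#' @param n_observers observers in the among set (`>= 2`).
#' @param n_within_sets number of within-observer sets.
#' @param n_genera reference genera.
#' @param structure digitised structure.
#' @param perturb_lm15 apply the misplaced-LM15 variant.
#' @param perturb_offset physical offset of the misplaced landmark.
#' @param out_dir optional directory: writes every configuration as tps
#'   plus a `truth.csv`.
#' @return list with `within` (named list of config lists), `among`
#'   (config list), `reference` (config list), `truth` (data frame).
#' @export
simulate_error_experiment <- function(seed, sigma_within = 0.01,
                                      sigma_among = 0.02,
                                      sigma_between = 0.2,
                                      n_replicates = 10L, n_observers = 8L,
                                      n_within_sets = 2L, n_genera = 20L,
                                      structure = "cephalon",
                                      perturb_lm15 = FALSE,
                                      perturb_offset = 0.05,
                                      out_dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_replicates < 2L || n_observers < 2L)
    stop("need at least 2 replicates and 2 observers")
  set.seed(as.integer(seed))
  template <- structure_template(structure)
  base <- base_shape(structure)
  p <- nrow(base$landmarks)
  noise <- function(sd) matrix(stats::rnorm(2L * p, 0, sd), p, 2L)

  truth <- list()
  record <- function(id, group, note = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      specimen_id = id, group = group, note = note, stringsAsFactors = FALSE)
  }

  within <- list()
  for (w in seq_len(n_within_sets)) {
    obs_bias <- noise(sigma_among)   # the observer's persistent style
    set_name <- sprintf("within_obs_%d", w)
    within[[set_name]] <- lapply(seq_len(n_replicates), function(r) {
      cfg <- .deform_config(base, obs_bias + noise(sigma_within), template)
      cfg$specimen_id <- sprintf("W%d-R%02d", w, r)
      record(cfg$specimen_id, set_name)
      cfg
    })
  }

  among <- lapply(seq_len(n_observers), function(o) {
    cfg <- .deform_config(base, noise(sigma_among) + noise(sigma_within),
                          template)
    cfg$specimen_id <- sprintf("A-O%02d", o)
    note <- ""
    if (perturb_lm15 && o == n_observers && structure == "cephalon") {
      cfg$landmarks[15L, 1L] <- cfg$landmarks[15L, 1L] + perturb_offset
      note <- sprintf("LM15 offset %+g in x", perturb_offset)
    }
    record(cfg$specimen_id, "among_obs", note)
    cfg
  })

  reference <- lapply(seq_len(n_genera), function(gi) {
    cfg <- .deform_config(base, noise(sigma_between) + noise(sigma_within),
                          template)
    cfg$specimen_id <- sprintf("G%02d", gi)
    record(cfg$specimen_id, "among_genus")
    cfg
  })

  out <- list(within = within, among = among, reference = reference,
              truth = do.call(rbind, truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    all_cfg <- c(unlist(within, recursive = FALSE), among, reference)
    for (cfg in all_cfg) {
      # files carry image-like positive coordinates so that the tps
      # all-negative missing convention cannot bite
      cfg <- .apply_nuisance(cfg, 0, c(0, 0), 1)
      write_tps(list(cfg), file.path(out_dir,
                                     paste0(cfg$specimen_id, "_C.tps")))
    }
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  out
}
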