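# Shared fixtures and independent oracles, all built in code.

# seeded random p-point configuration
rand_config <- function(p, seed) {
  set.seed(seed)
  matrix(stats::rnorm(2 * p), p, 2)
}

# similarity transform of a p x 2 matrix
similarity <- function(x, angle, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(scale * (x %*% R), 2, shift, `+`)
}

# brute-force full Procrustes distance by grid search over the rotation
# angle; independent of the SVD route used by opa()
oracle_opa_grid <- function(A, B, step = 1e-4) {
  pre <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  Ah <- pre(A); Bh <- pre(B)
  M <- crossprod(Bh, Ah)
  a <- M[1, 1] + M[2, 2]
  b <- M[2, 1] - M[1, 2]
  th <- seq(0, 2 * pi, by = step)
  sqrt(max(min(2 - 2 * (a * cos(th) + b * sin(th))), 0))
}

# jittered copies of the base cephalon: Gaussian displacement applied to
# landmarks, with curves deformed consistently through the public
# simulator so endpoint bindings stay exact
noisy_cephala <- function(n, sigma, seed, structure = "cephalon") {
  ee <- simulate_error_experiment(seed = seed, sigma_within = sigma,
                                  sigma_among = 0, sigma_between = sigma,
                                  n_replicates = max(n, 2), n_observers = 2,
                                  n_within_sets = 1, n_genera = 2,
                                  structure = structure)
  cfgs <- ee$within[[1]][seq_len(n)]
  for (i in seq_along(cfgs)) cfgs[[i]]$specimen_id <- sprintf("N%02d", i)
  cfgs
}

# n complete copies of the base cephalon with distinct ids
base_copies <- function(n, structure = "cephalon") {
  lapply(seq_len(n), function(i) {
    cfg <- base_shape(structure)
    cfg$specimen_id <- sprintf("C%02d", i)
    cfg
  })
}

# write text lines to a temp file, return the path
write_fixture <- function(lines, ext = ".tps", name = NULL) {
  path <- if (is.null(name)) tempfile(fileext = ext)
          else file.path(tempdir(), name)
  writeLines(lines, path)
  path
}

# a minimal valid metadata entry as an R list
meta_entry <- function(genus = "Paradoxides", sp = "Paradoxides davidis",
                       lat = -31.4, long = -64.2,
                       min_age = "Eifelian", max_age = "Eifelian",
                       eyes = TRUE) {
  list(
    ref_pic = "Author 2001 pl. 3 fig. 2",
    enter_metadata = "AB", enter_landmark = "AB",
    taxonomy = list(orig_genus = genus, genus = genus, sp = sp),
    morphology = list(cephalon = TRUE, cranidium = FALSE, pygidium = FALSE,
                      eyes = eyes, ontogeny = "Holaspis"),
    geography = list(locality = "Somewhere", lat = lat, long = long),
    stratigraphy = list(min_age = min_age, max_age = max_age)
  )
}
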