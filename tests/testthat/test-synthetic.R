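test_that("base shapes conform and honour curve bindings exactly", {
  for (structure in c("cephalon", "pygidium")) {
    b <- base_shape(structure)
    expect_true(validate_configuration(b)$conforms)
    tpl <- structure_template(structure)
    for (ci in seq_len(nrow(tpl$curve_defs))) {
      cv <- b$curves[[tpl$curve_defs$name[ci]]]
      expect_identical(cv[1, ], b$landmarks[tpl$curve_defs$start[ci], ])
      expect_identical(cv[nrow(cv), ], b$landmarks[tpl$curve_defs$end[ci], ])
      expect_gte(nrow(cv), 3L)
    }
  }
  # the two named binding examples: glabella LM2/LM7, pygidial axis LM1/LM2
  ceph <- base_shape("cephalon")
  expect_identical(ceph$curves$glabella[1, ], ceph$landmarks[2, ])
  expect_identical(ceph$curves$glabella[nrow(ceph$curves$glabella), ],
                   ceph$landmarks[7, ])
  pyg <- base_shape("pygidium")
  expect_identical(pyg$curves$axis[1, ], pyg$landmarks[1, ])
  expect_identical(pyg$curves$axis[nrow(pyg$curves$axis), ],
                   pyg$landmarks[2, ])
})

test_that("simulation is byte-identical for a fixed seed", {
  d1 <- file.path(tempdir(), "sim_rep1")
  d2 <- file.path(tempdir(), "sim_rep2")
  s1 <- simulate_dataset(d1, n_genera = 3, n_per_genus = 4, seed = 7,
                         p_missing_landmark = 0.2, p_missing_scale = 0.2,
                         blind_fraction = 0.3)
  s2 <- simulate_dataset(d2, n_genera = 3, n_per_genus = 4, seed = 7,
                         p_missing_landmark = 0.2, p_missing_scale = 0.2,
                         blind_fraction = 0.3)
  expect_equal(basename(s1$files), basename(s2$files))
  for (i in seq_along(s1$files))
    expect_identical(readLines(s1$files[i]), readLines(s2$files[i]))
  expect_identical(readLines(s1$metadata_path), readLines(s2$metadata_path))
  # a different seed changes the data
  s3 <- simulate_dataset(file.path(tempdir(), "sim_rep3"), n_genera = 3,
                         n_per_genus = 4, seed = 8)
  expect_false(identical(readLines(s1$files[1]), readLines(s3$files[1])))
})

test_that("the zero-noise limit collapses within-genus variation", {
  sim <- simulate_dataset(NULL, n_genera = 2, n_per_genus = 3,
                          sigma_between = 0.1, sigma_within = 0,
                          rotation_range = 0, translation_range = 0,
                          scale_range = c(1, 1), seed = 5)
  arr <- fix_shapes(sim$configs)
  for (g in unique(sim$truth$genus)) {
    ids <- sim$truth$specimen_id[sim$truth$genus == g]
    idx <- match(ids, arr$specimen_ids)
    for (i in idx[-1])
      expect_lt(procrustes_distance(arr$coords[, , idx[1]],
                                    arr$coords[, , i]), 1e-9)
  }
})

test_that("defect injection is recorded in the truth table and files", {
  d <- file.path(tempdir(), "sim_defects")
  sim <- simulate_dataset(d, n_genera = 4, n_per_genus = 2,
                          p_missing_landmark = 1, p_missing_scale = 1,
                          blind_fraction = 1, seed = 3)
  expect_true(all(!is.na(sim$truth$missing_landmark)))
  expect_true(all(sim$truth$missing_scale))
  expect_true(all(sim$truth$blind))
  # files read back with the injected defects visible
  cfgs <- read_shape_dir(file.path(d, "cephala"), "cephalon")
  expect_length(cfgs, 8L)
  for (id in names(cfgs)) {
    cfg <- cfgs[[id]]
    row <- sim$truth[sim$truth$specimen_id == id, ]
    expect_true(cfg$unscaled)
    expect_true(all(cfg$missing[c(8, 9, 14)]))
    expect_true(cfg$missing[row$missing_landmark])
  }
  # metadata mirrors blindness
  recs <- read_metadata(sim$metadata_path)
  expect_true(all(!vapply(recs, function(r) r$morphology$eyes, TRUE)))
})

test_that("generated datasets pass the round-trip and validation gate", {
  sim <- simulate_dataset(file.path(tempdir(), "sim_clean"), n_genera = 4,
                          n_per_genus = 2, seed = 21)
  cfgs <- read_shape_dir(file.path(tempdir(), "sim_clean", "cephala"),
                         "cephalon")
  expect_length(cfgs, 8L)
  for (cfg in cfgs)
    expect_true(validate_configuration(cfg)$conforms)
  # in-memory and on-disk configurations agree after the write/read cycle
  arr_mem <- fix_shapes(sim$configs)
  arr_disk <- fix_shapes(cfgs)
  idx <- match(arr_mem$specimen_ids, arr_disk$specimen_ids)
  expect_lt(max(abs(arr_mem$coords - arr_disk$coords[, , idx])), 1e-8)
})

test_that("error experiments are reproducible and degenerate cleanly", {
  e0 <- simulate_error_experiment(seed = 2, sigma_within = 0, sigma_among = 0,
                                  n_replicates = 3, n_observers = 2,
                                  n_genera = 2)
  reps <- e0$within[[1]]
  for (r in reps[-1]) {
    expect_identical(r$landmarks, reps[[1]]$landmarks)
    expect_identical(r$curves, reps[[1]]$curves)
  }
  e1 <- simulate_error_experiment(seed = 9, n_replicates = 4,
                                  n_observers = 3, n_genera = 5)
  e2 <- simulate_error_experiment(seed = 9, n_replicates = 4,
                                  n_observers = 3, n_genera = 5)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$among[[2]]$landmarks, e2$among[[2]]$landmarks)
  expect_error(simulate_error_experiment(seed = 1, n_replicates = 1), "2")
})

test_that("latent noise ordering is recovered through the full pipeline", {
  for (seed in c(101, 202, 303)) {
    ee <- simulate_error_experiment(seed = seed, sigma_within = 0.01,
                                    sigma_among = 0.03, sigma_between = 0.2,
                                    n_replicates = 6, n_observers = 6,
                                    n_within_sets = 1, n_genera = 12)
    rep <- error_report(ee$within, ee$among, ee$reference, n_perm = 0,
                        seed = 1)
    m <- rep$group_means
    expect_lt(m[["within_obs_1"]], m[["among_obs"]])
    expect_lt(m[["among_obs"]], m[["among_genus"]])
  }
})
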