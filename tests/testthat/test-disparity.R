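unit_square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))

test_that("disparity metrics match closed forms", {
  expect_equal(sov(unit_square), 2 / 3)
  expect_equal(sor(unit_square), 2)
  expect_equal(nnd(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(nnd(cbind(0:4, 0)), 1)          # collinear unit spacing
  expect_equal(sov(matrix(1, 5, 3)), 0)
  expect_equal(sor(matrix(1, 5, 3)), 0)
  for (f in list(sov, sor, nnd)) expect_error(f(matrix(1, 1, 2)), "at least 2")
})

test_that("sov equals the mean squared distance to the centroid, rescaled", {
  for (seed in 1:5) {
    x <- matrix(rnorm(40), 10)
    ctr <- colMeans(x)
    msd <- mean(rowSums(sweep(x, 2, ctr)^2))
    expect_equal(sov(x), msd * 10 / 9, tolerance = 1e-12)
  }
})

test_that("sor is monotone and nnd matches the brute-force oracle", {
  set.seed(3)
  x <- matrix(rnorm(40), 20)
  expect_gte(sor(rbind(x, c(10, 10))), sor(x))
  # O(n^2) double loop oracle
  for (seed in 1:3) {
    set.seed(seed)
    y <- matrix(rnorm(60), 20)
    brute <- mean(vapply(seq_len(20), function(i) {
      min(vapply(setdiff(seq_len(20), i), function(j)
        sqrt(sum((y[i, ] - y[j, ])^2)), 1))
    }, 1))
    expect_equal(nnd(y), brute, tolerance = 1e-12)
  }
})

test_that("sov and nnd are rotation-invariant, sor is permutation-stable", {
  set.seed(8)
  x <- matrix(rnorm(30), 10)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(sov(x %*% q), sov(x), tolerance = 1e-10)
  expect_equal(nnd(x %*% q), nnd(x), tolerance = 1e-10)
  perm <- x[, c(2, 3, 1)]
  expect_equal(sor(perm), sor(x))
})

test_that("stage tables are validated for contiguity", {
  st <- devonian_stages()
  expect_equal(nrow(st), 7L)
  expect_true(all(st$base_age > st$top_age))
  expect_silent(validate_stage_table(st))
  bad <- st; bad$base_age[3] <- 400
  expect_error(validate_stage_table(bad), "contiguous")
  # the shipped CSV parses to the same table
  csv <- read_stage_table(system.file("extdata", "devonian_stages.csv",
                                      package = "trilodisp"))
  expect_equal(csv, st)
})

test_that("bin assignment covers the age-range overlap", {
  recs <- data.frame(
    id = c("a", "b", "c"),
    max_age = c("Eifelian", "Lochkovian", "Famennian"),
    min_age = c("Eifelian", "Emsian", "Famennian"),
    stringsAsFactors = FALSE
  )
  bins <- assign_bins(recs)
  expect_equal(bins$a, "Eifelian")
  expect_equal(bins$b, c("Lochkovian", "Pragian", "Emsian"))
  expect_equal(bins$c, "Famennian")
  expect_error(assign_bins(data.frame(id = "x", max_age = "Wenlock",
                                      min_age = "Wenlock")), "Wenlock")
})

test_that("range-through richness fills taxon ranges", {
  one <- data.frame(taxon = "t", stage_first = "Lochkovian",
                    stage_last = "Famennian")
  expect_equal(richness_range_through(one)$richness, rep(1L, 7))
  two <- data.frame(taxon = c("u", "v"),
                    stage_first = c("Pragian", "Frasnian"),
                    stage_last = c("Pragian", "Frasnian"))
  expect_equal(richness_range_through(two)$richness,
               c(0L, 1L, 0L, 0L, 0L, 1L, 0L))
  # a taxon occupying Lochkovian and Famennian ranges through all stages
  split_occ <- data.frame(taxon = c("w", "w"),
                          stage_first = c("Lochkovian", "Famennian"),
                          stage_last = c("Lochkovian", "Famennian"))
  expect_equal(richness_range_through(split_occ)$richness, rep(1L, 7))
})

test_that("random occurrence tables match a per-stage membership scan", {
  set.seed(17)
  st <- devonian_stages()
  n <- 50
  i1 <- sample.int(7, n, replace = TRUE)
  i2 <- pmin(i1 + sample(0:3, n, replace = TRUE), 7)
  occ <- data.frame(taxon = sprintf("T%02d", seq_len(n)),
                    stage_first = st$stage[i1], stage_last = st$stage[i2])
  got <- richness_range_through(occ)
  brute <- vapply(seq_len(7), function(s) sum(i1 <= s & s <= i2), 1L)
  expect_equal(got$richness, brute)
})

test_that("disparity through time reduces to the plain metrics per bin", {
  set.seed(30)
  cfgs <- noisy_cephala(10, 0.05, seed = 30)
  sp <- shape_pca(gpa(fix_shapes(cfgs)))
  ids <- sp$specimen_ids
  bins <- c(lapply(ids[1:8], function(i) "Emsian"),
            lapply(ids[9:10], function(i) character(0)))
  names(bins) <- ids
  bins[[ids[9]]] <- "Givetian"   # a singleton bin
  res <- disparity_through_time(sp, bins, n_boot = 200, seed = 5)
  em <- res[res$bin == "Emsian", ]
  expect_equal(em$n, 8L)
  expect_equal(em$SoV, sov(sp$scores[ids[1:8], ]))
  expect_equal(em$SoR, sor(sp$scores[ids[1:8], ]))
  expect_equal(em$NND, nnd(sp$scores[ids[1:8], ]))
  gv <- res[res$bin == "Givetian", ]
  expect_equal(gv$n, 1L)
  expect_true(is.na(gv$SoV) && is.na(gv$SoR) && is.na(gv$NND))
  expect_true(all(is.na(res[res$bin == "Famennian",
                            c("SoV", "SoR", "NND")])))
  # intervals are ordered and the run is seed-deterministic
  expect_true(all(em$SoV_lo <= em$SoV_hi))
  res2 <- disparity_through_time(sp, bins, n_boot = 200, seed = 5)
  expect_identical(res, res2)
  expect_error(disparity_through_time(sp, bins, n_boot = 10), "seed")
  # restricting axes restricts the metric
  res1 <- disparity_through_time(sp, bins, n_boot = 0, n_axes = 1)
  expect_equal(res1$SoV[res1$bin == "Emsian"],
               sov(sp$scores[ids[1:8], 1, drop = FALSE]))
})

test_that("bootstrap intervals bracket the estimate for variance metrics", {
  # percentile intervals from within-bin resampling: for SoV at moderate n
  # the point estimate sits inside the interval in nearly all seeds
  set.seed(77)
  scores <- matrix(rnorm(30 * 3), 30)
  sp <- structure(list(scores = scores), class = "morphospace")
  rownames(sp$scores) <- sprintf("S%02d", 1:30)
  sp$specimen_ids <- rownames(sp$scores)
  bins <- stats::setNames(rep(list("Emsian"), 30), sp$specimen_ids)
  hits <- 0L
  for (s in 1:50) {
    r <- disparity_through_time(sp, bins, n_boot = 200, seed = s)
    r <- r[r$bin == "Emsian", ]
    if (r$SoV_lo <= r$SoV && r$SoV <= r$SoV_hi) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})
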