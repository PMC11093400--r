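test_that("top-fraction thresholding selects exactly k voxels with fixed ties", {
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  z <- withr::with_seed(1, array(rnorm(1000), dims))
  sel <- threshold_top_fraction(z, mask, 0.05)
  expect_equal(sum(sel), 50)
  expect_equal(sort(which(sel)), oracle_topk(z, mask, 50))
  # all-equal values: the 50 lowest-index voxels
  flat <- array(1, dims)
  self <- threshold_top_fraction(flat, mask, 0.05)
  expect_equal(which(self), 1:50)
  expect_error(threshold_top_fraction(z, array(FALSE, dims), 0.05), "empty")
})

test_that("top-fraction selection matches the full-sort oracle across seeds", {
  dims <- c(12, 9, 7)
  for (seed in 1:5) {
    z <- withr::with_seed(seed, array(rnorm(prod(dims)), dims))
    mask <- withr::with_seed(seed + 100,
                             array(runif(prod(dims)) < 0.8, dims))
    frac <- 0.07
    sel <- threshold_top_fraction(z, mask, frac)
    k <- round(frac * sum(mask))
    expect_equal(sum(sel), k)
    expect_equal(sort(which(sel)), oracle_topk(z, mask, k))
  }
})

test_that("overlap maps count subjects exactly", {
  dims <- c(6, 6, 6)
  m1 <- array(FALSE, dims); m1[1:3, , ] <- TRUE
  m2 <- array(FALSE, dims); m2[2:4, , ] <- TRUE
  m3 <- array(FALSE, dims); m3[3:5, , ] <- TRUE
  om <- overlap_map(list(m1, m2, m3))
  expect_equal(om$n_subjects, 3)
  expect_equal(om$counts[3, 1, 1], 3L)
  # pairwise-disjoint masks never exceed one
  d1 <- array(FALSE, dims); d1[1, , ] <- TRUE
  d2 <- array(FALSE, dims); d2[4, , ] <- TRUE
  expect_equal(max(overlap_map(list(d1, d2))$counts), 1L)
  # 41 random masks vs the brute-force sum
  masks <- lapply(1:41, function(s)
    withr::with_seed(s, array(runif(prod(dims)) < 0.3, dims)))
  om41 <- overlap_map(masks)
  brute <- array(0L, dims)
  for (m in masks) for (v in which(m)) brute[v] <- brute[v] + 1L
  expect_identical(om41$counts, brute)
  expect_error(overlap_map(list(m1, array(FALSE, c(2, 2, 2)))), "mismatch")
})

test_that("the overlap threshold implements the strict more-than-five rule", {
  dims <- c(4, 4, 4)
  counts <- array(0L, dims)
  counts[1] <- 5L; counts[2] <- 6L; counts[3] <- 41L
  om <- structure(list(counts = counts, n_subjects = 41), class = "overlap_map")
  p <- threshold_overlap(om, min_subjects = 6)
  expect_equal(p[1], 0)            # five participants: excluded
  expect_equal(p[2], 6 / 41)       # six participants: retained
  expect_equal(p[3], 1)
  p1 <- threshold_overlap(om, min_subjects = 1)
  expect_equal(p1[1], 5 / 41)      # min_subjects = 1 keeps every nonzero voxel
  expect_error(threshold_overlap(om, min_subjects = 42))
})

test_that("raising min_subjects never increases the retained voxel count", {
  masks <- lapply(1:12, function(s)
    withr::with_seed(s, array(runif(512) < 0.4, c(8, 8, 8))))
  om <- overlap_map(masks)
  kept <- sapply(1:12, function(ms) sum(threshold_overlap(om, ms) > 0))
  expect_true(all(diff(kept) <= 0))
})

test_that("Gaussian smoothing conserves mass and reproduces the delta response", {
  # delta far enough from the boundary that the truncated kernel fits inside
  p <- array(0, c(24, 24, 24)); p[12, 12, 12] <- 1
  expect_identical(smooth_probability_map(p, 0), p)
  sm <- smooth_probability_map(p, 8, c(2, 2, 2))
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 2
  expect_equal(sm, oracle_gaussian_response(c(24, 24, 24), c(12, 12, 12),
                                            rep(sigma, 3)), tolerance = 1e-6)
  # mass conservation, including reflective boundaries
  r <- withr::with_seed(5, array(runif(12^3), c(12, 12, 12)))
  expect_equal(sum(smooth_probability_map(r, 8, c(2, 2, 2))), sum(r),
               tolerance = 1e-6 * sum(r))
  # anisotropic voxels are honoured axis by axis
  sm2 <- smooth_probability_map(p, 8, c(2, 4, 8))
  expect_equal(sm2, oracle_gaussian_response(c(24, 24, 24), c(12, 12, 12),
                                             8 / (2 * sqrt(2 * log(2))) / c(2, 4, 8)),
               tolerance = 1e-6)
})

test_that("watershed segments bumps into one basin each", {
  m <- make_bump_map(c(20, 20, 8), rbind(c(6, 6, 4), c(15, 14, 4)))
  m[m < 1e-4] <- 0
  at <- watershed_parcellate(m)
  expect_equal(nrow(at$table), 2)
  expect_true(at$labels[6, 6, 4] != at$labels[15, 14, 4])
  expect_true(all(at$labels[m > 0] > 0))
  one <- watershed_parcellate(make_bump_map(c(10, 10, 8), rbind(c(5, 5, 4))))
  expect_equal(nrow(one$table), 1)
  zero <- watershed_parcellate(array(0, c(5, 5, 5)))
  expect_equal(nrow(zero$table), 0)
  expect_error(watershed_parcellate(array(-1, c(3, 3, 3))), "nonnegative")
})

test_that("watershed basins equal the steepest-ascent oracle on random maps", {
  for (seed in 1:5) {
    m <- random_smooth_map(c(14, 12, 10), seed)
    m[m < quantile(m, 0.4)] <- 0
    at <- watershed_parcellate(m)
    orc <- oracle_watershed(m)
    expect_true(same_partition(at$labels, orc))
  }
})

test_that("watershed parcels are 6-connected and bit-stable", {
  m <- random_smooth_map(c(16, 14, 10), 42)
  m[m < quantile(m, 0.5)] <- 0
  a <- watershed_parcellate(m)
  b <- watershed_parcellate(m)
  expect_identical(a$labels, b$labels)
  for (pid in a$table$id) {
    parcel <- a$labels == pid
    expect_equal(length(unique(label_components(parcel)[parcel])), 1L)
  }
})

test_that("small-parcel exclusion follows the mean-subject-size rule", {
  dims <- c(10, 10, 4)
  labels <- array(0L, dims)
  labels[1:5, 1:5, 1] <- 1L      # parcel 1: 25 voxels
  labels[7:10, 7:10, 1] <- 2L    # parcel 2: 16 voxels
  atlas <- structure(list(labels = labels,
                          table = data.frame(id = 1:2, n_vox = c(25L, 16L),
                                             peak_value = c(1, 0.5))),
                     class = "parcel_atlas")
  # every subject has exactly 10 voxels inside parcel 1, none inside parcel 2
  subj <- lapply(1:4, function(i) {
    m <- array(FALSE, dims); m[1:5, 1:2, 1] <- TRUE; m
  })
  filt <- filter_small_parcels(atlas, subj, min_mean_size = 10)
  expect_equal(filt$table$id, 1)               # boundary: 10 is not < 10
  expect_equal(nrow(filt$table), 1)
  expect_true(all(filt$labels[labels == 2L] == 0))
  # mixed case vs brute force
  subj2 <- lapply(1:5, function(i)
    withr::with_seed(i, array(runif(prod(dims)) < 0.3, dims)))
  brute_mean <- sapply(1:2, function(pid)
    mean(sapply(subj2, function(m) sum(m & labels == pid))))
  for (thr in c(0, 3, 5, 8, 100)) {
    f <- filter_small_parcels(atlas, subj2, thr)
    expect_equal(nrow(f$table), sum(brute_mean >= thr))
  }
})

test_that("raising the size threshold never increases the parcel count", {
  m <- random_smooth_map(c(14, 14, 8), 7)
  m[m < quantile(m, 0.5)] <- 0
  atlas <- watershed_parcellate(m)
  subj <- lapply(1:6, function(i)
    withr::with_seed(i, array(runif(prod(dim(m))) < 0.4, dim(m))))
  counts <- sapply(c(0, 2, 4, 8, 16, 32),
                   function(thr) nrow(filter_small_parcels(atlas, subj, thr)$table))
  expect_true(all(diff(counts) <= 0))
})

test_that("parcel validation counts supra-threshold clusters per subject", {
  dims <- c(8, 8, 4)
  labels <- array(0L, dims); labels[2:7, 2:7, 2] <- 1L
  atlas <- structure(list(labels = labels,
                          table = data.frame(id = 1L, n_vox = sum(labels),
                                             peak_value = 1)),
                     class = "parcel_atlas")
  strong <- array(0, dims); strong[3:6, 3:6, 2] <- 5     # 16-voxel cluster
  weak <- array(0, dims)
  v1 <- parcel_validation(atlas, list(strong, strong, strong), 2, 5)
  expect_equal(v1$table$validation_rate, 1)
  v0 <- parcel_validation(atlas, list(weak, weak), 2, 5)
  expect_equal(v0$table$validation_rate, 0)
  vm <- parcel_validation(atlas, list(strong, weak, strong, weak), 2, 5)
  expect_equal(vm$table$validation_rate, 0.5)
  # oracle check on noisy maps: cluster search from first principles
  for (seed in 1:3) {
    z <- withr::with_seed(seed, array(rnorm(prod(dims), 1, 1.2), dims))
    got <- parcel_validation(atlas, list(z), 2, 4)$table$validation_rate
    want <- as.numeric(oracle_max_cluster(z > 2 & labels == 1L) >= 4)
    expect_equal(got, want)
  }
})

test_that("the full GSS chain is deterministic and respects its oracle stages", {
  dims <- c(14, 14, 10)
  z_maps <- lapply(1:8, function(s) {
    m <- make_bump_map(dims, rbind(c(5, 5, 5), c(11, 10, 5)), height = 6)
    m + withr::with_seed(s, array(rnorm(prod(dims)), dims))
  })
  cfg <- gss_config(min_subjects = 4, min_mean_parcel_size_vox = 2,
                    validation_min_cluster_vox = 2)
  a <- gss_parcellate(z_maps, config = cfg)
  b <- gss_parcellate(z_maps, config = cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(a$table, b$table)
  expect_gte(nrow(a$table), 1)
  expect_true(all(a$table$validation_rate >= 0 & a$table$validation_rate <= 1))
})

test_that("cluster-extent calibration reports a monotone FWE curve", {
  cal <- calibrate_cluster_extent(c(12, 12, 12), n_sims = 40, seed = 3)
  expect_true(all(diff(cal$fwe_by_extent) <= 0))
  expect_gte(cal$min_cluster_vox, 1)
  expect_lte(cal$fwe_by_extent[as.character(cal$min_cluster_vox)], 0.05)
})

test_that("atlas files round-trip through NIfTI + TSV", {
  m <- make_bump_map(c(10, 10, 6), rbind(c(5, 5, 3)))
  at <- watershed_parcellate(m)
  attr(at, "config") <- gss_config()
  g <- volume_grid(c(10, 10, 6))
  prefix <- file.path(tempdir(), "atlas_test")
  files <- write_parcel_atlas(at, g, prefix)
  lab <- read_volume(paste0(prefix, ".nii"))
  expect_equal(array(as.integer(lab$data), dim(lab$data)), at$labels)
  tab <- read.delim(paste0(prefix, "_parcels.tsv"))
  expect_equal(tab$id, at$table$id)
  cfg <- jsonlite::read_json(paste0(prefix, "_config.json"))
  expect_equal(cfg$top_fraction, 0.05)
})
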