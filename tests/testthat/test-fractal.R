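test_that("box counts match cube arithmetic and handle degenerate masks", {
  cube <- array(TRUE, c(4, 4, 4))
  bc <- box_counts(cube, c(1, 2, 4))
  expect_equal(bc$counts, c(64L, 8L, 1L))
  single <- array(FALSE, c(4, 4, 4)); single[2, 3, 1] <- TRUE
  expect_equal(box_counts(single, c(1, 2, 4))$counts, c(1L, 1L, 1L))
  # oversize boxes are allowed and count 1
  expect_equal(box_counts(cube, 99)$counts, 1L)
  expect_error(box_counts(array(FALSE, c(3, 3, 3)), 1),
               class = "fdnet_domain_error")
  expect_error(box_counts(cube, 0), class = "fdnet_validation_error")
})

test_that("box counts agree with a brute-force triple-loop counter", {
  set.seed(42)
  for (rep in 1:12) {
    occ <- random_mask(dmax = 16)
    sizes <- default_sizes(occ)
    bc <- box_counts(occ, sizes)
    oracle <- vapply(sizes, function(r) brute_box_count(occ, r), integer(1))
    expect_equal(bc$counts, oracle)
  }
})

test_that("box counts are non-increasing along the default progression", {
  set.seed(7)
  for (rep in 1:10) {
    occ <- random_mask(dmax = 20)
    sizes <- tryCatch(default_sizes(occ), error = function(e) NULL)
    if (is.null(sizes)) next
    bc <- box_counts(occ, sizes)
    expect_true(all(diff(bc$counts) <= 0))
    expect_true(all(bc$counts >= 1))
    # a box at least as large as the bounding box covers everything
    idx <- which(occ, arr.ind = TRUE)
    extent <- max(apply(idx, 2, max) - apply(idx, 2, min) + 1)
    expect_equal(box_counts(occ, extent)$counts, 1L)
  }
})

test_that("default size progressions are geometric and bounded by extent", {
  expect_equal(default_sizes(array(TRUE, c(64, 64, 64)), base = 2),
               c(1L, 2L, 4L, 8L, 16L, 32L, 64L))
  expect_equal(default_sizes(make_phantom("menger_sponge", 2), base = 3),
               c(1L, 3L, 9L))
  expect_error(default_sizes(array(TRUE, c(2, 2, 2)), base = 3),
               class = "fdnet_domain_error")
})

test_that("the log-log regression recovers exact power laws", {
  est <- estimate_fd(list(sizes = c(1, 2, 4), counts = c(64, 8, 1)))
  expect_equal(est$fd, 3, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  flat <- estimate_fd(list(sizes = c(1, 2, 4), counts = c(1, 1, 1)))
  expect_equal(flat$fd, 0)
  expect_equal(flat$r_squared, 1)
  sponge <- estimate_fd(list(sizes = c(1, 3, 9), counts = c(400, 20, 1)))
  expect_equal(sponge$fd, log(400) / log(9), tolerance = 1e-12)
  expect_equal(sponge$fd, log(20) / log(3), tolerance = 1e-12)
  expect_error(estimate_fd(list(sizes = 2, counts = 5)),
               class = "fdnet_domain_error")
})

test_that("analytic phantoms recover their dimensions", {
  for (case in list(list("cube", 16, 2), list("slab", 16, 2),
                    list("line", 16, 2), list("menger_sponge", 2, 3),
                    list("cantor_dust", 2, 3))) {
    ph <- make_phantom(case[[1]], case[[2]])
    est <- estimate_fd(box_counts(ph, default_sizes(ph, base = case[[3]])))
    expect_equal(est$fd, attr(ph, "analytic_fd"), tolerance = 0.05,
                 label = case[[1]])
  }
})

test_that("estimated dimension stays within [0, 3] plus tolerance", {
  set.seed(99)
  for (rep in 1:15) {
    occ <- random_mask(dmax = 24, p = stats::runif(1, 0.05, 0.9))
    sizes <- tryCatch(default_sizes(occ), error = function(e) NULL)
    if (is.null(sizes)) next
    fd <- estimate_fd(box_counts(occ, sizes))$fd
    expect_gte(fd, 0)
    expect_lte(fd, 3.1)
  }
})

test_that("translation inside a larger empty grid does not change the estimate", {
  ph <- make_phantom("menger_sponge", 2)
  base_fd <- estimate_fd(box_counts(ph, default_sizes(ph, base = 3)))$fd
  big <- array(FALSE, c(30, 25, 21))
  big[5:13, 9:17, 2:10] <- ph$occupancy
  shifted_fd <- estimate_fd(box_counts(big, default_sizes(big, base = 3)))$fd
  expect_equal(shifted_fd, base_fd, tolerance = 1e-12)
})

test_that("fd_per_roi extracts per-region estimates and flags missing regions", {
  vol <- array(0L, c(44, 28, 28))
  vol[1:27, 1:27, 1:27] <- 5L        # filled 27^3 block -> fd = 3 (base 3)
  vol[32:40, 2:10, 2:10][make_phantom("menger_sponge", 2)$occupancy] <- 61L
  vol[1, 28, 28] <- 9L               # single voxel, below min_voxels
  fd <- fd_per_roi(vol, base = 3)
  expect_length(fd, 68)
  expect_equal(unname(fd["roi_5"]), 3, tolerance = 0.05)
  expect_equal(unname(fd["roi_61"]), log(20) / log(3), tolerance = 0.05)
  expect_true(is.na(fd["roi_7"]))    # absent region
  expect_true(is.na(fd["roi_9"]))    # sub-threshold region
  bad <- vol; bad[1, 1, 1] <- 99L
  expect_error(fd_per_roi(bad), class = "fdnet_validation_error")
})

test_that("lobe FD aggregation matches its definition", {
  atlas <- load_default_atlas()
  fd <- matrix(2.2, nrow = 4, ncol = 68)
  cohort <- fd_cohort(paste0("s", 1:4), rep("g", 4), rep(c("F", "M"), 2), fd)
  agg <- aggregate_lobe_fd(cohort, atlas)
  expect_equal(nrow(agg), 12)
  expect_true(all(agg$mean == 2.2))
  expect_true(all(agg$sd == 0))
  # single-subject: SD over regions only
  one <- fd_cohort("s1", "g", "F", matrix(seq(2, 2.67, length.out = 68), 1))
  agg1 <- aggregate_lobe_fd(one, atlas)
  occ_l <- rois_in(atlas, "occipital", "left")
  row <- agg1[agg1$lobe == "occipital" & agg1$hemisphere == "left", ]
  expect_equal(row$mean, mean(seq(2, 2.67, length.out = 68)[occ_l]))
  expect_equal(row$sd, stats::sd(seq(2, 2.67, length.out = 68)[occ_l]))
})

test_that("sampled cohorts recover the configured lobe means", {
  cfg <- cohort_config(n_per_group = 60,
                       effect_rois = data.frame(roi = integer(),
                                                delta = numeric()),
                       seed = 21)
  cohort <- make_cohort(cfg)
  agg <- aggregate_lobe_fd(cohort[cohort$group == "middle", ])
  ref <- reference_lobe_fd()
  for (i in seq_len(nrow(agg))) {
    target <- ref$middle_mean[ref$lobe == agg$lobe[i] &
                                ref$hemisphere == ifelse(agg$hemisphere[i] == "both",
                                                         "both", agg$hemisphere[i])]
    # lobe means include the 16 region-specific overrides, so allow a wider
    # margin than pure sampling error
    expect_equal(agg$mean[i], target, tolerance = 0.05)
  }
})
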