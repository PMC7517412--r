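test_that("within-module degree z-scores follow the population-SD definition", {
  # 3-node module, binary within-degrees {2, 1, 1}
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 1
  W[4, 5] <- W[5, 4] <- 1
  comm <- c(1, 1, 1, 2, 2)
  z <- within_module_z(W, comm, weighted = FALSE)
  expect_equal(unname(z[1:3]), c(sqrt(2), -1 / sqrt(2), -1 / sqrt(2)),
               tolerance = 1e-12)
  # uniform module: sigma = 0 convention gives z = 0
  expect_equal(unname(z[4:5]), c(0, 0))
  # singleton module
  z2 <- within_module_z(W, c(1, 1, 1, 2, 3), weighted = FALSE)
  expect_equal(unname(z2[4:5]), c(0, 0))
})

test_that("z has zero mean within modules whose SD is positive", {
  set.seed(17)
  for (rep in 1:8) {
    W <- random_network(12, density = 0.5)
    comm <- sample(1:3, 12, replace = TRUE)
    z <- within_module_z(W, comm)
    for (c in unique(comm)) {
      members <- which(comm == c)
      if (length(members) > 1 && stats::sd(z[members]) > 0)
        expect_lt(abs(mean(z[members])), 1e-9)
    }
  }
})

test_that("participation coefficients match their definition on canonical cases", {
  # degree-4 node split equally across 4 modules: P = 0.75
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 1
  comm <- c(1, 1, 2, 3, 4)
  p <- participation_coeff(W, comm, weighted = FALSE)
  expect_equal(unname(p[1]), 0.75, tolerance = 1e-12)
  # all edges inside own module -> P = 0; isolated node -> P = 0
  W2 <- two_cliques(3)
  W2 <- rbind(cbind(W2, 0), 0)  # append isolated node
  p2 <- participation_coeff(W2, c(1, 1, 1, 2, 2, 2, 3))
  expect_equal(unname(p2), rep(0, 7))
})

test_that("z and P match brute-force loop implementations", {
  set.seed(29)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    W <- random_network(n, density = stats::runif(1, 0.2, 0.8))
    comm <- sample(1:3, n, replace = TRUE)
    for (weighted in c(TRUE, FALSE)) {
      expect_equal(unname(within_module_z(W, comm, weighted)),
                   brute_within_z(W, comm, weighted), tolerance = 1e-12)
      expect_equal(unname(participation_coeff(W, comm, weighted)),
                   brute_participation(W, comm, weighted), tolerance = 1e-12)
    }
  }
})

test_that("z and P are invariant to uniform weight scaling; P bounded by module spread", {
  set.seed(41)
  W <- random_network(15, density = 0.4)
  comm <- sample(1:4, 15, replace = TRUE)
  expect_equal(within_module_z(W, comm), within_module_z(3.7 * W, comm),
               tolerance = 1e-12)
  p <- participation_coeff(W, comm)
  expect_equal(p, participation_coeff(3.7 * W, comm), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  k <- rowSums(W)
  for (i in seq_len(15)) {
    if (k[i] == 0) next
    touched <- length(unique(comm[W[i, ] > 0]))
    expect_lte(p[i], 1 - 1 / touched + 1e-12)
  }
})

test_that("hub classification applies the z threshold inclusively", {
  expect_equal(classify_hubs(c(2.6, 2.4)), c(TRUE, FALSE))
  expect_equal(classify_hubs(c(2.5, 0)), c(TRUE, FALSE))
  expect_false(any(classify_hubs(rep(0, 5))))
  expect_equal(classify_hubs(c(-1, 0, 1), z_threshold = 0),
               c(FALSE, TRUE, TRUE))
})

test_that("lobe means select the right regions", {
  atlas <- load_default_atlas()
  expect_equal(lobe_mean(rep(1, 68), atlas, "temporal"), 1)
  vals <- seq_len(68)
  expect_equal(lobe_mean(vals, atlas, "occipital", "left"),
               mean(c(61, 63, 65, 67)))
  expect_equal(lobe_mean(vals, atlas), mean(1:68))  # whole-network mean
  rep_tab <- node_metric_report(vals, atlas)
  expect_equal(rep_tab$total[rep_tab$lobe == "frontal"], mean(1:28))
  expect_equal(rep_tab$right[rep_tab$lobe == "parietal"],
               mean(seq(48, 60, by = 2)))
})

test_that("lobe weight connectivity sums and means follow their definitions", {
  atlas <- load_default_atlas()
  W <- matrix(0, 68, 68)
  fl <- rois_in(atlas, "frontal", "left")
  W[fl[1], fl[2]] <- W[fl[2], fl[1]] <- 0.5
  W[fl[3], fl[4]] <- W[fl[4], fl[3]] <- 0.5
  W[fl[5], fl[6]] <- W[fl[6], fl[5]] <- 0.5
  expect_equal(lobe_weight_connectivity(W, atlas, "intra", "frontal", "left",
                                        "sum"), 1.5)
  expect_equal(lobe_weight_connectivity(W, atlas, "intra", "frontal", "left",
                                        "mean"), 1.5 / choose(14, 2))
  # those edges are invisible to the inter-lobe scope
  expect_equal(lobe_weight_connectivity(W, atlas, "inter", "frontal", "left",
                                        "sum"), 0)
  # empty network: zero everywhere
  Z <- matrix(0, 68, 68)
  for (scope in c("intra", "inter"))
    expect_equal(lobe_weight_connectivity(Z, atlas, scope, "temporal"), 0)
})

test_that("intra- plus crossing inter-lobe weight conserves total strength", {
  atlas <- load_default_atlas()
  set.seed(53)
  for (rep in 1:5) {
    W <- random_network(68, density = 0.1)
    total <- sum(W) / 2
    intra <- sum(vapply(c("frontal", "temporal", "parietal", "occipital"),
                        function(l) lobe_weight_connectivity(W, atlas, "intra", l),
                        0))
    # each lobe-crossing edge is seen from exactly two lobes
    inter <- sum(vapply(c("frontal", "temporal", "parietal", "occipital"),
                        function(l) lobe_weight_connectivity(W, atlas, "inter", l),
                        0)) / 2
    expect_equal(intra + inter, total, tolerance = 1e-10)
  }
})

test_that("group ratios reproduce printed two-group percentage rows", {
  ref <- reference_lobe_connectivity()
  intra <- ref[ref$scope == "intra", ]
  num <- data.frame(lobe = intra$lobe, value = intra$elderly)
  den <- data.frame(lobe = intra$lobe, value = intra$middle)
  ratio <- group_ratio(num, den)
  tt <- intra$lobe == "temporal" & intra$column == "total"
  expect_equal(round(ratio$value[tt], 1), 126.5)
  # equal reports give 100 everywhere; zero denominators give NA
  expect_equal(group_ratio(den, den)$value, rep(100, nrow(den)))
  den0 <- den; den0$value[1] <- 0
  expect_true(is.na(group_ratio(num, den0)$value[1]))
  expect_error(group_ratio(num, den[-1, ]), class = "fdnet_validation_error")
})
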