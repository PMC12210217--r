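test_that("rmsd is zero under rigid motion and matches a rotational search oracle", {
  set.seed(42)
  a <- as.matrix(make_backbone(12, "coiled_C", noise_sigma = 0.4, seed = 3))
  expect_equal(rmsd(a, a), 0)
  moved <- a %*% random_rotation() + matrix(c(3, -2, 7), nrow(a), 3, byrow = TRUE)
  expect_lt(rmsd(moved, a), 1e-9)
  expect_equal(rmsd(a, moved), rmsd(moved, a), tolerance = 1e-9)
  # 5-atom asymmetric toy displaced atom-wise: compare against brute force
  toy <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.1, 1.2, 0.3, 3.0, 1.1, 1.4,
                  2.2, 2.5, 2.0), ncol = 3, byrow = TRUE)
  displaced <- toy + matrix(rnorm(15, sd = 0.5), ncol = 3)
  expect_equal(rmsd(displaced, toy), rmsd_bruteforce(displaced, toy),
               tolerance = 1e-6)
  expect_error(rmsd(toy, toy[1:4, ]), "atom counts")
})

test_that("rmsd uses proper rotations only: a mirrored chiral chain keeps nonzero RMSD", {
  h <- helix_chain(14)
  expect_gt(rmsd(mirror_z(h), h), 0.1)
  # cross-check the aligned deviation against bio3d's least-squares fit
  fitted <- bio3d::fit.xyz(as.numeric(t(h)), as.numeric(t(mirror_z(h))),
                           fixed.inds = 1:42, mobile.inds = 1:42)
  dev_bio3d <- sqrt(mean(colSums(matrix(
    (fitted - as.numeric(t(h)))^2, nrow = 3))))
  expect_equal(rmsd(mirror_z(h), h), dev_bio3d, tolerance = 1e-6)
})

test_that("radius of gyration matches direct summation", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(-1, 0, 0), c(1, 0, 0))), 1)
  set.seed(7)
  cloud <- matrix(rnorm(30), ncol = 3)
  m <- runif(10, 0.5, 16)
  com <- colSums(cloud * m) / sum(m)
  direct <- sqrt(sum(m * rowSums(sweep(cloud, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(cloud, m), direct, tolerance = 1e-12)
  expect_error(radius_of_gyration(cloud, c(-1, m[-1])), "positive")
})

test_that("end-to-end distance covers collinear, closed and targeted chains", {
  straight <- cbind(seq(0, by = 1.5, length.out = 10), 0, 0)
  expect_equal(end_to_end(straight), 13.5)
  ring <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(end_to_end(ring), 0)
  expect_equal(end_to_end(make_backbone(20, "extended", target_end_to_end = 26)),
               26, tolerance = 1e-9)
  expect_error(end_to_end(matrix(1:3, 1)), "2 atoms")
})

test_that("featurization is rigid-motion invariant and matches pairwise distances", {
  set.seed(11)
  chain <- as.matrix(make_backbone(12, "semi_open", noise_sigma = 0.3, seed = 8))
  f <- featurize(chain)
  for (i in 1:5) {
    moved <- chain %*% random_rotation() +
      matrix(rnorm(3, sd = 10), nrow(chain), 3, byrow = TRUE)
    expect_equal(featurize(moved), f, tolerance = 1e-9)
  }
  # entries equal the plain pairwise distances to atoms 1-3
  for (j in 1:3) {
    expect_equal(f[, j], sqrt(rowSums(sweep(chain, 2, chain[j, ])^2)),
                 tolerance = 1e-12)
  }
  expect_equal(diag(f[1:3, 1:3]), rep(0, 3))
  expect_equal(f[1, 2], f[2, 1])
  # unit tetrahedron: all off-anchor entries are 1
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  ft <- featurize(tet)
  expect_equal(ft[ft > 0], rep(1, 9), tolerance = 1e-12)
  expect_warning(featurize(cbind(0:4, 0, 0) * 1.5), "collinear")
})

test_that("reconstruct inverts featurize up to rigid motion (and mirror for chiral chains)", {
  planar <- as.matrix(make_backbone(16, "extended"))
  expect_lt(rmsd(reconstruct(featurize(planar)), planar), 1e-9)
  helix <- helix_chain(20)
  expect_lt(rmsd_up_to_mirror(reconstruct(featurize(helix)), helix), 1e-6)
  # idempotence: the mean of two identical features is the same conformation
  f <- featurize(helix)
  expect_lt(rmsd_up_to_mirror(reconstruct((f + f) / 2), helix), 1e-6)
  arc <- as.matrix(make_backbone(14, "coiled_C"))
  expect_lt(rmsd_up_to_mirror(reconstruct(featurize(arc)), arc), 1e-9)
})

test_that("rmsd histograms are normalised and resolve planted families", {
  ref <- make_backbone(14, "coiled_C")
  same <- conformation_set(replicate(20, make_backbone(14, "coiled_C"),
                                     simplify = FALSE), solvent_label = "w")
  h <- rmsd_histogram(same, ref, bin_width = 0.5)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_left, 0)
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1)
  # two families at distinct RMSD from the reference -> bimodal histogram
  far <- conformation_set(replicate(
    30, make_backbone(14, "extended", noise_sigma = 0.1), simplify = FALSE),
    solvent_label = "thf")
  near <- conformation_set(replicate(
    30, make_backbone(14, "coiled_C", noise_sigma = 0.1), simplify = FALSE),
    solvent_label = "thf")
  mixed <- dplyr::bind_rows(near, far)
  hm <- rmsd_histogram(mixed, ref, bin_width = 0.5)
  dens <- hm$density[order(hm$bin_left)]
  # two separated modes with an empty valley between them
  peaks <- which(dens > 0)
  expect_gte(max(peaks) - min(peaks), 2)
  expect_true(any(dens[min(peaks):max(peaks)] == 0))
  expect_equal(sum(hm$density * 0.5), 1, tolerance = 1e-9)
})

test_that("pooled Rg series summarise agglomerate compactness", {
  still <- replicate(5, make_agglomerate(6, 10), simplify = FALSE)
  g <- glance(aggregate_rg_series(still))
  expect_equal(g$sd_rg, 0)
  two <- aggregate_rg_series(list(
    rbind(c(-10, 0, 0), c(10, 0, 0)), rbind(c(-12, 0, 0), c(12, 0, 0))))
  g2 <- glance(two)
  expect_equal(g2$mean_rg, 11)
  expect_equal(g2$sd_rg, 1)
  tight <- replicate(4, make_agglomerate(6, 10, scale = 0.7), simplify = FALSE)
  loose <- replicate(4, make_agglomerate(6, 10, scale = 1.3), simplify = FALSE)
  expect_lt(glance(aggregate_rg_series(tight))$mean_rg,
            glance(aggregate_rg_series(loose))$mean_rg)
  expect_error(aggregate_rg_series(list()), "nonempty")
})
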