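test_that("surface distance obeys the minimum-image convention", {
  box <- c(50, 50, 50)
  solute <- rbind(c(25, 25, 25))
  expect_equal(min_surface_distance(c(25, 25, 25), solute, box), 0)
  expect_equal(min_surface_distance(c(28, 29, 25), solute, box), 5)
  # near a face the periodic image is closer than the direct vector
  expect_equal(min_surface_distance(c(48, 25, 25), rbind(c(1, 25, 25)), box), 3)
  # 100 random configurations against the 27-image oracle
  set.seed(5)
  for (i in 1:100) {
    b <- runif(3, 10, 40)
    sol <- matrix(runif(9, 0, max(b)), ncol = 3) %% matrix(b, 3, 3, byrow = TRUE)
    p <- runif(3, 0, max(b)) %% b
    expect_equal(min_surface_distance(p, sol, b),
                 min_dist_27_images(p, sol, b), tolerance = 1e-9)
  }
  expect_error(min_surface_distance(c(0, 0, 0), solute, box,
                                    blocks = "Ndc", selection = "Nte"),
               "empty")
})

test_that("profiles conserve molecule counts and flag THF-free systems", {
  solute <- make_backbone(10, "extended")
  fr <- make_solvated_frame(solute, n_thf = 40, n_water = 400,
                            box = c(50, 50, 50), seed = 2)
  pr <- solvation_profile(fr, bin_width = 2, bulk_cutoff = 16)
  expect_equal(sum(pr$n_thf) + attr(pr, "bulk_n_thf"), 40)
  expect_equal(sum(pr$n_water) + attr(pr, "bulk_n_water"), 400)
  # all-water frame: ratios zero, enhancement flagged undefined
  fw <- make_solvated_frame(solute, n_thf = 0, n_water = 400,
                            box = c(50, 50, 50), seed = 3)
  expect_warning(pw <- solvation_profile(fw, bulk_cutoff = 16), "zero")
  expect_true(all(pw$molar_ratio[pw$n_water > 0] == 0))
  expect_true(all(is.na(pw$enhancement)))
  # tiny box: everything is within the cutoff -> no bulk region
  ft <- make_solvated_frame(solute, n_thf = 5, n_water = 50,
                            box = c(30, 30, 30), seed = 4)
  expect_error(solvation_profile(ft, bulk_cutoff = 40), "bulk")
})

test_that("uniform mixtures show no preferential solvation", {
  slab <- make_agglomerate(10, 20, "sheet")
  frames <- lapply(1:60, function(i) {
    make_solvated_frame(slab, 495, 6800, seed = 4000 + i)
  })
  pr <- solvation_profile(frames)
  expect_true(all(abs(pr$enhancement - 1) < 0.2))
  expect_equal(attr(pr, "bulk_ratio"), 495 / 6800, tolerance = 0.05)
})

test_that("density maps conserve mass and match the uniform expectation", {
  solute <- make_backbone(10, "extended")
  # one molecule fixed in a known voxel
  one <- solvated_frame(
    solute = as.matrix(solute),
    solvent = tibble::tibble(x = 1.2, y = 1.2, z = 1.2, species = "THF",
                             mass = 72.11),
    box = c(20, 20, 20)
  )
  m1 <- density_map(one, voxel = 2, species = "THF")
  expect_equal(m1[1, 1, 1], 72.11 / 8 * 1.6605, tolerance = 1e-9)
  expect_equal(sum(m1 > 0), 1)
  # mass conservation: sum(density * voxel volume) == total mass
  fr <- make_solvated_frame(solute, 80, 600, box = c(40, 40, 40), seed = 6)
  for (sp in c("THF", "water")) {
    mm <- density_map(fr, voxel = 3, species = sp)
    total_amu <- sum(mm) * prod(attr(mm, "voxel")) / 1.6605
    expected <- sum(fr$solvent$mass[fr$solvent$species == sp])
    expect_equal(total_amu, expected, tolerance = 1e-6)
  }
  # uniform fill stays within Poisson bounds of the analytic mean
  frames <- lapply(1:50, function(i) {
    make_solvated_frame(make_backbone(4, "extended"), 0, 2700,
                        box = c(45, 45, 45), seed = 100 + i)
  })
  mu <- density_map(frames, voxel = 15, species = "water")
  vox_vol <- 15^3
  sigma <- sqrt(2700 / 27 * 50) / 50 / vox_vol * 18.015 * 1.6605
  mean_dens <- 2700 * 18.015 / 45^3 * 1.6605
  expect_true(all(abs(mu - mean_dens) < 4 * sigma))
  # identical frames leave the average unchanged
  m_one <- density_map(fr, voxel = 4, species = "THF")
  m_rep <- density_map(list(fr, fr), voxel = 4, species = "THF")
  expect_equal(unclass(m_rep), unclass(m_one), tolerance = 1e-12)
  expect_error(density_map(fr, voxel = 100), "voxel larger")
})

test_that("isolevel masks are nested and consistent with the density", {
  fr <- make_solvated_frame(make_backbone(10, "extended"), 60, 500,
                            box = c(40, 40, 40),
                            enhancement = list(factor = 4, decay = 4),
                            seed = 12)
  mm <- density_map(fr, voxel = 4, species = "THF")
  masks <- isolevel_mask(mm)
  expect_named(masks, format(c(0.5, 0.3, 0.2, 0.1)))
  for (k in 1:3) expect_true(all(masks[[k]] <= masks[[k + 1]]))
  expect_true(all(isolevel_mask(mm, max(mm) * 2)[[1]] == FALSE))
  low <- isolevel_mask(mm, min(mm[mm > 0]) / 2)[[1]]
  expect_true(all(low == (unclass(mm) > 0)))
  # nestedness on random maps
  set.seed(8)
  for (i in 1:5) {
    rnd <- structure(array(runif(64), c(4, 4, 4)),
                     class = c("density_map", "array"))
    ms <- isolevel_mask(rnd, c(0.7, 0.4, 0.1))
    expect_true(all(ms[[1]] <= ms[[2]]) && all(ms[[2]] <= ms[[3]]))
  }
})

test_that("triclinic boxes are rejected", {
  tric <- matrix(c(30, 0, 0, 5, 30, 0, 0, 0, 30), 3, byrow = TRUE)
  expect_error(
    solvated_frame(make_backbone(4, "extended"),
                   tibble::tibble(x = 1, y = 1, z = 1, species = "water",
                                  mass = 18),
                   box = tric),
    "orthorhombic"
  )
})
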